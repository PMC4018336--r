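# Defensin repertoire modelling: functional/pseudogene classification of
# coding sequences, cysteine-motif validation of mature peptides, and
# theta-defensin maturation (nonapeptide excision and head-to-tail ligation).

#' Motif specification for defensin mature peptides
#'
#' Three motif kinds are supported, each with fixed cysteine anchors and
#' bounded wildcard spacers:
#' \describe{
#'   \item{`alpha_mature`}{`C-x-C-x(3,4)-C-x(9)-C-x(6,9)-C-C` -- the six
#'     conserved cysteines of the alpha-defensin mature peptide (the last two
#'     adjacent).}
#'   \item{`theta_nonapeptide`}{`x-C-x-C-x(4)-C` -- the three conserved
#'     cysteines of the theta-defensin nonapeptide (9 residues).}
#'   \item{`theta_nonapeptide_variant`}{`x-C-x-C-x(8)-C` -- the 13-residue
#'     colobus variant.}
#' }
#'
#' @param kind One of `"alpha_mature"`, `"theta_nonapeptide"`,
#'   `"theta_nonapeptide_variant"`.
#' @return An object of class `motif_spec` with fields `kind`, `pattern`
#'   (regular expression with one capture group per cysteine anchor) and
#'   `n_cys`.
#' @export
motif_spec <- function(kind = c("alpha_mature", "theta_nonapeptide",
                                "theta_nonapeptide_variant")) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    alpha_mature = list(pattern = "(C).(C).{3,4}(C).{9}(C).{6,9}(C)(C)",
                        n_cys = 6L),
    theta_nonapeptide = list(pattern = ".(C).(C).{4}(C)", n_cys = 3L),
    theta_nonapeptide_variant = list(pattern = ".(C).(C).{8}(C)", n_cys = 3L)
  )
  structure(c(list(kind = kind), spec), class = "motif_spec")
}

#' Validate a peptide against a defensin cysteine motif
#'
#' Tests whether the motif matches anywhere in the peptide.  Wildcard spacer
#' positions match any residue including the unknown symbol `X`; cysteine
#' anchors must be literal `C` (an `X` never satisfies an anchor).
#'
#' @param peptide Amino-acid string (`X` allowed).  An empty string never
#'   matches.
#' @param spec A [motif_spec()] or a kind name accepted by [motif_spec()].
#' @return A list with `match` (logical) and `cys_positions` (1-based
#'   positions of the matched cysteine anchors, or `integer(0)`).
#' @examples
#' validate_motif("RCICRRGVC", "theta_nonapeptide")$match # TRUE
#' validate_motif("RCICRRGVA", "theta_nonapeptide")$match # FALSE
#' @export
validate_motif <- function(peptide, spec) {
  if (is.character(spec)) spec <- motif_spec(spec)
  stopifnot(inherits(spec, "motif_spec"), is.character(peptide),
            length(peptide) == 1L)
  peptide <- toupper(peptide)
  if (nchar(peptide) == 0L) {
    return(list(match = FALSE, cys_positions = integer(0)))
  }
  m <- regexec(spec$pattern, peptide)[[1]]
  if (m[1] == -1L) {
    return(list(match = FALSE, cys_positions = integer(0)))
  }
  list(match = TRUE, cys_positions = as.integer(m[-1]))
}

#' Classify a coding sequence as functional gene or pseudogene
#'
#' A sequence is functional when its reading frame carries no internal stop
#' codon before the terminal position and its ungapped length deviates from
#' `expected_codon_length * 3` by a multiple of three.  A length deviation
#' that is not a multiple of three is called a frameshift; an internal stop a
#' premature stop, reported with the 1-based codon index of the first stop.
#'
#' One exception implements the birth of theta-defensins: a stop codon at the
#' position homologous to the theta-defining site (`theta_site`, alignment
#' position 77 in the defensin family frame) is not a pseudogenizing lesion
#' when the 12 residues immediately upstream start with a valid
#' theta-nonapeptide motif -- such a precursor is classified functional with
#' `theta = TRUE`.  A stop at any other internal position (e.g. codon 17)
#' always pseudogenizes.
#'
#' @param cds Coding DNA string (IUPAC symbols; gap characters `-` are
#'   removed before classification).
#' @param expected_codon_length Expected length in codons (including the
#'   terminal stop if the family convention carries one), used to judge
#'   frameshifts against the family alignment.
#' @param theta_site Optional 1-based codon index of the theta-defining stop
#'   (default `NULL`: no theta exception).
#' @return A list with `status` (`"functional"`/`"pseudogene"`),
#'   `pseudo_reason` (`"none"`, `"premature_stop"`, `"frameshift"`),
#'   `stop_site` (codon index or `NA`), `theta` (logical) and `protein`
#'   (translation up to the first stop).
#' @examples
#' classify_coding_sequence(encode_peptide("MKKC"), expected_codon_length = 4)
#' @export
classify_coding_sequence <- function(cds, expected_codon_length,
                                     theta_site = NULL) {
  stopifnot(is.character(cds), length(cds) == 1L)
  if (nchar(cds) == 0L) stop("empty sequence")
  cds <- toupper(gsub("-", "", cds))
  if (grepl("[^ACGTRYSWKMBDHVN]", cds)) stop("non-IUPAC symbol in sequence")
  stopifnot(is.numeric(expected_codon_length), expected_codon_length >= 1)
  dev <- nchar(cds) - expected_codon_length * 3L
  if (dev %% 3L != 0L) {
    return(list(status = "pseudogene", pseudo_reason = "frameshift",
                stop_site = NA_integer_, theta = FALSE,
                protein = NA_character_))
  }
  codons <- split_codons(cds)
  n <- length(codons)
  aa <- vapply(codons, function(cd) {
    a <- .CODON_AA[cd]
    if (is.na(a)) "X" else a
  }, character(1), USE.NAMES = FALSE)
  internal_stops <- which(aa == "*")
  internal_stops <- internal_stops[internal_stops < n]
  if (length(internal_stops) > 0L) {
    k <- internal_stops[1L]
    if (!is.null(theta_site) && k == theta_site && k > 12L) {
      tail12 <- paste(aa[(k - 12L):(k - 1L)], collapse = "")
      nona <- substr(tail12, 1L, 9L)
      # translation ends at the theta stop; downstream codons are untranslated
      if (validate_motif(nona, "theta_nonapeptide")$match) {
        return(list(status = "functional", pseudo_reason = "none",
                    stop_site = NA_integer_, theta = TRUE,
                    protein = paste(aa[seq_len(k - 1L)], collapse = "")))
      }
    }
    return(list(status = "pseudogene", pseudo_reason = "premature_stop",
                stop_site = k, theta = FALSE,
                protein = paste(aa[seq_len(k - 1L)], collapse = "")))
  }
  prot_end <- if (aa[n] == "*") n - 1L else n
  list(status = "functional", pseudo_reason = "none",
       stop_site = NA_integer_, theta = FALSE,
       protein = paste(aa[seq_len(prot_end)], collapse = ""))
}

#' Gene record for one coding sequence
#'
#' Bundles a coding sequence with its species and cluster labels and its
#' functional/pseudogene classification ([classify_coding_sequence()]).
#'
#' @param id Sequence identifier.
#' @param species Species label.
#' @param cluster Gene-cluster label (e.g. `"DEFA1"`, `"DEFT"`).
#' @param cds Coding DNA string.
#' @inheritParams classify_coding_sequence
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(id, species, cluster, cds,
                        expected_codon_length = nchar(gsub("-", "", cds)) / 3,
                        theta_site = NULL) {
  cl <- classify_coding_sequence(cds, expected_codon_length, theta_site)
  structure(
    list(id = id, species = species, cluster = cluster, cds = cds,
         status = cl$status, pseudo_reason = cl$pseudo_reason,
         stop_site = cl$stop_site, theta = cl$theta, protein = cl$protein),
    class = "gene_record"
  )
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("gene_record %s (%s, %s): %s", x$id, x$species, x$cluster,
              x$status))
  if (x$status == "pseudogene") {
    cat(sprintf(" [%s%s]", x$pseudo_reason,
                if (!is.na(x$stop_site)) paste0(" at codon ", x$stop_site)
                else ""))
  } else if (isTRUE(x$theta)) {
    cat(" [theta precursor]")
  }
  cat("\n")
  invisible(x)
}

#' Classify a whole repertoire of coding sequences
#'
#' Applies [classify_coding_sequence()] to every sequence and flags the
#' alpha-mature and theta-nonapeptide motifs on the translated protein.
#'
#' @param seqs Named character vector of coding DNA (ids as names), e.g. from
#'   [read_fasta()].
#' @param expected_codon_length Expected length in codons.
#' @param species,cluster Optional vectors (recycled) of labels.
#' @param theta_site Optional theta-defining stop position, see
#'   [classify_coding_sequence()].
#' @return A data frame with one row per sequence: `id`, `species`,
#'   `cluster`, `status`, `pseudo_reason`, `stop_site`, `theta`,
#'   `alpha_motif`, `theta_motif`.
#' @export
classify_repertoire <- function(seqs, expected_codon_length,
                                species = NA_character_,
                                cluster = NA_character_, theta_site = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  species <- rep_len(species, length(seqs))
  cluster <- rep_len(cluster, length(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    cl <- classify_coding_sequence(seqs[[i]], expected_codon_length,
                                   theta_site)
    prot <- if (is.na(cl$protein)) "" else cl$protein
    data.frame(
      id = names(seqs)[i], species = species[i], cluster = cluster[i],
      status = cl$status, pseudo_reason = cl$pseudo_reason,
      stop_site = cl$stop_site, theta = cl$theta,
      alpha_motif = validate_motif(prot, "alpha_mature")$match,
      theta_motif = validate_motif(prot, "theta_nonapeptide")$match,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Excise the theta-defensin nonapeptide from its 12-residue tail
#'
#' The theta-defensin precursor ends in a 12-residue segment upstream of the
#' theta-defining stop; maturation removes the three C-terminal residues
#' (typically `RLL` or `QLL`), leaving the 9-residue unit that is ligated
#' into the cyclic peptide.
#'
#' @param tail12 Amino-acid string of length 12.
#' @return A list with `nonapeptide` (first 9 residues) and `removed_tail`
#'   (last 3 residues).
#' @examples
#' excise_nonapeptide("RCICRRGVCRLL")
#' @export
excise_nonapeptide <- function(tail12) {
  stopifnot(is.character(tail12), length(tail12) == 1L)
  tail12 <- toupper(tail12)
  if (nchar(tail12) != 12L) stop("input must be exactly 12 residues")
  list(nonapeptide = substr(tail12, 1L, 9L),
       removed_tail = substr(tail12, 10L, 12L))
}

#' Mature a theta-defensin from two nonapeptides
#'
#' Models the posttranslational head-to-tail ligation of two 9-residue units
#' into the cyclic octadecapeptide, with the tridisulfide ladder pairing the
#' three cysteines of one unit to the three of the other.  The default
#' `"antiparallel"` connectivity pairs A-Cys1 with B-Cys3, A-Cys2 with
#' B-Cys2, and A-Cys3 with B-Cys1; `"parallel"` pairs them in order.
#'
#' @param nonaA,nonaB Amino-acid strings of length 9 that each satisfy the
#'   theta-nonapeptide motif (A and B may be identical -- a homodimer -- or
#'   different -- a heterodimer).
#' @param connectivity Disulfide ladder connectivity.
#' @return An object of class `cyclic_peptide`: `sequence` (the 18-mer read
#'   around the cycle from position 1 of `nonaA`), `length`, `disulfides`
#'   (3 x 2 matrix of paired cysteine positions on the cycle).
#' @examples
#' mature_theta("RCICRRGVC", "RCVCTRGVC")
#' @export
mature_theta <- function(nonaA, nonaB,
                         connectivity = c("antiparallel", "parallel")) {
  connectivity <- match.arg(connectivity)
  vA <- validate_motif(nonaA, "theta_nonapeptide")
  vB <- validate_motif(nonaB, "theta_nonapeptide")
  if (nchar(nonaA) != 9L || !vA$match) {
    stop("`nonaA` is not a valid theta nonapeptide")
  }
  if (nchar(nonaB) != 9L || !vB$match) {
    stop("`nonaB` is not a valid theta nonapeptide")
  }
  seq18 <- paste0(toupper(nonaA), toupper(nonaB))
  cysA <- vA$cys_positions
  cysB <- vB$cys_positions + 9L
  pairs <- switch(connectivity,
    antiparallel = cbind(cysA, rev(cysB)),
    parallel = cbind(cysA, cysB)
  )
  dimnames(pairs) <- list(NULL, c("A", "B"))
  structure(
    list(sequence = seq18, length = 18L, disulfides = pairs,
         connectivity = connectivity),
    class = "cyclic_peptide"
  )
}

#' @export
print.cyclic_peptide <- function(x, ...) {
  cat(sprintf("cyclic octadecapeptide (head-to-tail): %s\n", x$sequence))
  cat(sprintf("  tridisulfide ladder (%s): %s\n", x$connectivity,
              paste(sprintf("%d-%d", x$disulfides[, 1], x$disulfides[, 2]),
                    collapse = ", ")))
  invisible(x)
}
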