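# Seeded synthetic-data generator: codon families evolving under
# region-specific dN/dS on a known tree, pseudogenization lesions, and
# jittered dimer trajectories.  The generator is first-class, tested code;
# its defaults define the study conditions the rest of the package is
# exercised under.

#' Deterministically encode a peptide as DNA
#'
#' Maps each amino acid to its alphabetically first codon under the standard
#' nuclear code (`*` encodes `TAA`).  Useful for constructing coding
#' sequences with prescribed motifs.
#'
#' @param peptide Amino-acid string (may include `*`).
#' @return A DNA string of length `3 * nchar(peptide)`.
#' @examples
#' encode_peptide("RCICRRGVC")
#' @export
encode_peptide <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  aa <- strsplit(toupper(peptide), "")[[1]]
  tab <- vapply(split(.CODONS, .CODON_AA), min, character(1))
  cods <- tab[aa]
  if (anyNA(cods)) stop("unknown amino-acid symbol(s): ",
                        paste(unique(aa[is.na(cods)]), collapse = ", "))
  paste(cods, collapse = "")
}

# uniform random sense-codon sequence
random_sense_cds <- function(n_codons) {
  paste(sample(.SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# evolve one codon sequence along one branch under the accept/reject omega
# scheme; returns the sequence and the accepted syn/nonsyn event counts per
# region label
evolve_branch <- function(codons, branch_length, region, omegas) {
  n <- length(codons)
  n_events <- stats::rpois(n, branch_length)
  counts <- list()
  for (site in which(n_events > 0L)) {
    om <- omegas[[region[site]]]
    for (e in seq_len(n_events[site])) {
      pos <- sample.int(3L, 1L)
      old <- codons[site]
      ref <- substr(old, pos, pos)
      b <- sample(setdiff(.BASES, ref), 1L)
      nb <- old
      substr(nb, pos, pos) <- b
      if (.CODON_AA[nb] == "*") next  # stop-creating proposal rejected
      syn <- .CODON_AA[nb] == .CODON_AA[old]
      accept_p <- if (syn) min(1, 1 / om) else min(1, om)
      if (om == 0 && !syn) accept_p <- 0
      if (om == 0 && syn) accept_p <- 1
      if (stats::runif(1) < accept_p) {
        codons[site] <- nb
        key <- paste0(region[site], if (syn) ".syn" else ".nonsyn")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  list(codons = codons, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a codon family under region-specific dN/dS on a known tree
#'
#' Evolves an ancestral sense-codon sequence along a rooted tree with branch
#' lengths in expected substitution proposals per codon site.  Per branch and
#' codon site, the number of proposal events is Poisson with mean equal to
#' the branch length; each event proposes a uniform single-nucleotide change.
#' Stop-creating proposals are rejected.  Synonymous proposals are accepted
#' with probability `min(1, 1/omega)` and nonsynonymous ones with
#' `min(1, omega)`, where `omega` is the dN/dS dial of the precursor region
#' the site falls in, so the realized Ka/Ks tracks `omega` in both regimes.
#' The output is gap-free and codon-aligned by construction.
#'
#' The default conditions emulate a defensin precursor family: 94 codons
#' partitioned into signal (1--19, omega 0.2), prosegment (20--64, omega 0.5)
#' and mature peptide (65--94, omega 2.0), i.e. a conserved signal peptide
#' and a positively selected mature peptide.
#'
#' @param tree An `ape::phylo` tree with branch lengths, or `NULL` to use a
#'   preset.
#' @param preset `"star"` or `"balanced"` topology used when `tree` is
#'   `NULL`.
#' @param n Number of leaves for the preset.
#' @param branch_length Branch length (substitution proposals per codon site)
#'   for every edge of the preset.
#' @param omegas Named numeric vector of dN/dS per region; must name every
#'   region of `partition`.
#' @param codon_length Sequence length in codons.
#' @param partition A [precursor_partition()] (default: [default_partition()]
#'   of `codon_length`).
#' @param seed Integer seed (mandatory: the generator is deterministic given
#'   its configuration).
#' @param lesions Optional list of lesions applied to leaves after evolution;
#'   each element is `list(leaf = <id or index>, type = "stop"|"indel"|
#'   "theta_stop", codon = <position>, n_del = 1 or 2)`.  See
#'   [inject_lesion()].
#' @return A [codon_alignment()] of the leaf sequences with attribute
#'   `history` (a list with the ancestral sequence, per-region accepted
#'   event counts, the tree, omegas, seed, and applied lesions).  Lesioned
#'   sequences containing indels are returned unaligned in
#'   `history$lesioned` and excluded from the alignment rows.
#' @examples
#' aln <- simulate_family(n = 6, branch_length = 0.2, seed = 42)
#' @export
simulate_family <- function(tree = NULL, preset = c("star", "balanced"),
                            n = 12L, branch_length = 0.3,
                            omegas = c(signal = 0.2, prosegment = 0.5,
                                       mature = 2.0),
                            codon_length = 94L, partition = NULL,
                            seed, lesions = NULL) {
  if (missing(seed)) stop("`seed` is mandatory")
  preset <- match.arg(preset)
  if (is.null(partition)) partition <- default_partition(codon_length)
  partition <- validate_partition(partition, codon_length)
  region <- region_of_columns(partition, codon_length)
  missing_regions <- setdiff(unique(region), names(omegas))
  if (length(missing_regions) > 0L) {
    stop("`omegas` missing region(s): ",
         paste(missing_regions, collapse = ", "))
  }
  if (any(omegas < 0)) stop("omega values must be >= 0")
  set.seed(as.integer(seed))
  if (is.null(tree)) {
    tree <- ape::stree(n, type = preset)
    tree$edge.length <- rep(branch_length, nrow(tree$edge))
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  n_tips <- length(tree$tip.label)
  root <- n_tips + 1L
  anc_codons <- split_codons(random_sense_cds(codon_length))
  seqs_at <- vector("list", max(tree$edge))
  seqs_at[[root]] <- anc_codons
  counts <- list()
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]
    child <- edges[e, 2L]
    ev <- evolve_branch(seqs_at[[parent]], tree$edge.length[e], region,
                        omegas)
    seqs_at[[child]] <- ev$codons
    for (key in names(ev$counts)) {
      counts[[key]] <- (counts[[key]] %||% 0L) + ev$counts[[key]]
    }
  }
  ids <- tree$tip.label
  seqs <- vapply(seq_len(n_tips),
                 function(i) paste(seqs_at[[i]], collapse = ""), character(1))
  names(seqs) <- ids
  lesioned <- character(0)
  applied <- list()
  if (!is.null(lesions)) {
    for (les in lesions) {
      leaf <- les$leaf
      if (is.numeric(leaf)) leaf <- ids[leaf]
      if (!leaf %in% ids) stop("lesion leaf not found: ", leaf)
      seqs[[leaf]] <- inject_lesion(seqs[[leaf]], les$type, les$codon,
                                    n_del = les$n_del %||% 1L)
      applied <- c(applied, list(c(les, list(leaf = leaf))))
      if (les$type == "indel") lesioned <- c(lesioned, leaf)
    }
  }
  aln_seqs <- seqs[!names(seqs) %in% lesioned]
  aln <- codon_alignment(aln_seqs, partition = partition)
  attr(aln, "history") <- list(
    ancestor = paste(anc_codons, collapse = ""),
    event_counts = counts, tree = tree, omegas = omegas,
    seed = as.integer(seed), lesions = applied,
    lesioned = seqs[lesioned]
  )
  aln
}

#' Inject a pseudogenizing or theta-deriving lesion into a coding sequence
#'
#' Three lesion types emulate the mutational events of defensin gene
#' birth-and-death: `"stop"` replaces the codon at `codon` with `TAA`
#' (premature stop); `"indel"` deletes 1 or 2 nucleotides at the start of
#' that codon (frameshift); `"theta_stop"` places a `TAA` at the
#' theta-defining position, leaving the 12-residue tail upstream intact (a
#' theta precursor when that tail carries the nonapeptide motif).
#'
#' @param cds Coding DNA string (no gaps).
#' @param type `"stop"`, `"indel"` or `"theta_stop"`.
#' @param codon 1-based codon position of the lesion.
#' @param n_del Number of nucleotides deleted for `"indel"` (1 or 2).
#' @return The mutated DNA string.
#' @examples
#' cds <- encode_peptide(strrep("A", 30))
#' classify_coding_sequence(inject_lesion(cds, "stop", 17), 30)
#' @export
inject_lesion <- function(cds, type = c("stop", "indel", "theta_stop"),
                          codon, n_del = 1L) {
  type <- match.arg(type)
  stopifnot(is.character(cds), length(cds) == 1L)
  n_codons <- nchar(cds) %/% 3L
  if (codon < 1L || codon > n_codons) stop("lesion position out of range")
  start <- 3L * (codon - 1L) + 1L
  switch(type,
    stop = ,
    theta_stop = paste0(substr(cds, 1L, start - 1L), "TAA",
                        substr(cds, start + 3L, nchar(cds))),
    indel = {
      if (!n_del %in% c(1L, 2L)) stop("`n_del` must be 1 or 2")
      paste0(substr(cds, 1L, start - 1L),
             substr(cds, start + n_del, nchar(cds)))
    }
  )
}

#' Synthetic reference dimer structure
#'
#' Builds an idealized two-chain hairpin dimer with backbone atoms (N, CA, C,
#' O) for geometry testing: each chain is a beta-hairpin-like trace whose
#' loop tip is residue 11, with residues 18 and 20 of the two chains facing
#' each other across the dimer interface (about 5 Angstrom apart) and the
#' residue-11 tips far apart (about 35 Angstrom), mimicking the geometry of
#' an alpha-defensin dimer.  The construction is deterministic.  This is a
#' synthetic stand-in geometry, not a model of any deposited structure.
#'
#' @param n_res Residues per chain (default 30; must be >= 24).
#' @return A single-frame [dimer_structure()] with attribute
#'   `loop_residues` (the loop residues, 9--13).
#' @export
synthetic_dimer_reference <- function(n_res = 30L) {
  stopifnot(n_res >= 24L)
  ca_chain <- function(i) {
    # residues 1..11 outgoing strand, 12..13 turn, 14..24 return strand,
    # 25.. tail; small z-wiggle keeps the trace non-planar
    t(vapply(i, function(k) {
      if (k <= 11L) {
        c(-2 - 3.3 * (11L - k), 5.5, 0.4 * sin(1.3 * k))
      } else if (k <= 13L) {
        c(-2 + 1.8 * (k - 11L), 5.5 - 2.6 * (k - 11L), 0.4 * sin(1.3 * k))
      } else if (k <= 24L) {
        c(-2 - 3.3 * (k - 14L), 0, 0.4 * cos(1.3 * k))
      } else {
        c(-2 - 3.3 * 10 + 1.0 * (k - 24L), -4.5, 0.4 * cos(1.3 * k))
      }
    }, numeric(3)))
  }
  caA <- ca_chain(seq_len(n_res))
  # chain B: two-fold rotation about z then translation placing B20 against
  # A18 and B18 against A20 across the interface
  rot <- diag(c(-1, -1, 1))
  tx <- c(caA[18L, 1] + caA[20L, 1], -4.8, 0)
  caB <- sweep(caA %*% rot, 2, tx, "+")
  offs <- list(N = c(-0.9, 0.8, 0.4), CA = c(0, 0, 0),
               C = c(1.0, 0.7, -0.3), O = c(1.2, 1.8, -0.4))
  build <- function(ca, chain) {
    rows <- lapply(seq_len(n_res), function(k) {
      do.call(rbind, lapply(names(offs), function(at) {
        data.frame(chain = chain, resno = k, resname = "ALA", atom = at,
                   x = ca[k, 1] + offs[[at]][1], y = ca[k, 2] + offs[[at]][2],
                   z = ca[k, 3] + offs[[at]][3], stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  }
  df <- rbind(build(caA, "A"), build(caB, "B"))
  xyz <- array(as.matrix(df[, c("x", "y", "z")]), dim = c(nrow(df), 3L, 1L))
  st <- dimer_structure(df[, c("chain", "resno", "resname", "atom")], xyz)
  attr(st, "loop_residues") <- 9:13
  st
}

#' Simulate a jittered dimer trajectory
#'
#' Produces a multi-frame trajectory from a reference dimer by independent
#' Gaussian coordinate jitter: atoms of loop residues receive `loop_sigma`
#' noise, all others `core_sigma`.  Frame 1 is the unperturbed reference.
#' This emulates a near-rigid dimer with flexible loops.
#'
#' @param reference A single-frame [dimer_structure()].
#' @param n_frames Number of frames (>= 1).
#' @param loop_sigma,core_sigma Jitter standard deviations in Angstrom.
#' @param loop_residues Residues (reference numbering) treated as loops;
#'   default: the reference's `loop_residues` attribute, else 9--13.
#' @param seed Integer seed (mandatory).
#' @return A [dimer_structure()] with `n_frames` frames.
#' @export
simulate_trajectory <- function(reference, n_frames = 50L, loop_sigma = 1.0,
                                core_sigma = 0.1, loop_residues = NULL,
                                seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  stopifnot(inherits(reference, "dimer_structure"), n_frames >= 1L,
            loop_sigma >= 0, core_sigma >= 0)
  if (is.null(loop_residues)) {
    loop_residues <- attr(reference, "loop_residues") %||% 9:13
  }
  set.seed(as.integer(seed))
  ref_xyz <- reference$xyz[, , 1L]
  n_atoms <- nrow(ref_xyz)
  sigma <- ifelse(ref_resno(reference) %in% loop_residues,
                  loop_sigma, core_sigma)
  xyz <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
  xyz[, , 1L] <- ref_xyz
  for (f in seq_len(n_frames)[-1L]) {
    xyz[, , f] <- ref_xyz + matrix(stats::rnorm(3L * n_atoms, sd = sigma),
                                   n_atoms, 3L)
  }
  out <- dimer_structure(reference$atoms, xyz,
                         numbering_map = reference$numbering_map,
                         chains = reference$chains)
  attr(out, "loop_residues") <- loop_residues
  out
}
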