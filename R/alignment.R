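#' Codon alignment container
#'
#' A light container for a codon-partitioned alignment: equal-length aligned
#' DNA rows (gap character `-`), a column count divisible by three, and an
#' optional precursor-region partition in amino-acid columns.
#'
#' @param seqs Named character vector of aligned DNA strings (names are
#'   sequence ids), or an unnamed vector together with `ids`.
#' @param ids Optional character vector of sequence ids.
#' @param partition Optional [precursor_partition()] describing the
#'   signal/prosegment/mature spans on the alignment coordinate system.
#' @return An object of class `codon_alignment` with elements `ids`, `seqs`,
#'   `n_codons` and `partition`.
#' @export
codon_alignment <- function(seqs, ids = names(seqs), partition = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (length(ids) != length(seqs)) stop("`ids` and `seqs` lengths differ")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("all rows must have equal length")
  if (len %% 3L != 0L) stop("alignment length must be a multiple of 3")
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", seqs)
  if (any(bad)) stop("non-IUPAC symbol in sequence(s): ",
                     paste(ids[bad], collapse = ", "))
  n_codons <- len %/% 3L
  if (!is.null(partition)) {
    partition <- validate_partition(partition, n_codons)
  }
  names(seqs) <- ids
  structure(
    list(ids = ids, seqs = seqs, n_codons = n_codons, partition = partition),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequences x %d codons\n",
              length(x$ids), x$n_codons))
  if (!is.null(x$partition)) {
    p <- x$partition
    cat(sprintf("  partition: signal %d-%d | prosegment %d-%d | mature %d-%d\n",
                p$signal[1], p$signal[2], p$prosegment[1], p$prosegment[2],
                p$mature[1], p$mature[2]))
  }
  invisible(x)
}

# matrix of codon indices (rows = sequences, cols = amino-acid columns);
# NA marks gapped or ambiguous codons
codon_index_matrix <- function(aln) {
  t(vapply(aln$seqs, function(s) codon_index(split_codons(s)),
           integer(aln$n_codons)))
}

# amino-acid matrix with "-" for all-gap codons and "X" for ambiguity
aa_matrix <- function(aln) {
  t(vapply(aln$seqs, function(s) {
    cods <- split_codons(s)
    vapply(cods, translate_codon, character(1), USE.NAMES = FALSE)
  }, character(aln$n_codons)))
}

#' Precursor-region partition
#'
#' Defines the signal peptide, prosegment, and mature peptide spans of a
#' defensin precursor on the alignment coordinate system (1-based inclusive
#' amino-acid columns).  Spans must be disjoint, ordered
#' signal < prosegment < mature, and contiguous.
#'
#' @param signal,prosegment,mature Length-2 integer vectors `c(start, end)`.
#' @return An object of class `precursor_partition`.
#' @examples
#' precursor_partition(c(1, 19), c(20, 64), c(65, 94))
#' @export
precursor_partition <- function(signal, prosegment, mature) {
  p <- list(signal = as.integer(signal),
            prosegment = as.integer(prosegment),
            mature = as.integer(mature))
  for (nm in names(p)) {
    if (length(p[[nm]]) != 2L || p[[nm]][1] > p[[nm]][2]) {
      stop("`", nm, "` must be c(start, end) with start <= end")
    }
  }
  if (p$signal[2] + 1L != p$prosegment[1] ||
      p$prosegment[2] + 1L != p$mature[1]) {
    stop("spans must be contiguous and ordered signal < prosegment < mature")
  }
  if (p$signal[1] != 1L) stop("signal span must start at column 1")
  structure(p, class = "precursor_partition")
}

#' Default defensin precursor partition
#'
#' Signal peptide columns 1--19, prosegment 20--64, mature peptide from 65 to
#' the end of the alignment.  These boundaries follow the conventional
#' defensin precursor architecture (prosegment fragments such as 26--35 and
#' 56--65; mature-peptide sites from 65 onward) and are configurable.
#'
#' @param n_codons Total amino-acid columns of the alignment.
#' @return A [precursor_partition()].
#' @export
default_partition <- function(n_codons = 94L) {
  if (n_codons < 66L) stop("alignment too short for the default partition")
  precursor_partition(c(1L, 19L), c(20L, 64L), c(65L, n_codons))
}

validate_partition <- function(partition, n_codons) {
  if (!inherits(partition, "precursor_partition")) {
    stop("`partition` must be a precursor_partition")
  }
  if (partition$mature[2] > n_codons) {
    stop("partition extends past the alignment (", n_codons, " columns)")
  }
  partition
}

#' Columns of a precursor region
#'
#' @param partition A [precursor_partition()].
#' @param region One of `"signal"`, `"prosegment"`, `"mature"`.
#' @return Integer vector of 1-based amino-acid columns.
#' @export
region_columns <- function(partition, region = c("signal", "prosegment", "mature")) {
  region <- match.arg(region)
  span <- partition[[region]]
  seq.int(span[1], span[2])
}

# region label of each amino-acid column
region_of_columns <- function(partition, n_codons) {
  out <- character(n_codons)
  for (r in c("signal", "prosegment", "mature")) {
    cols <- region_columns(partition, r)
    out[cols[cols <= n_codons]] <- r
  }
  out
}
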