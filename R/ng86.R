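#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts the synonymous (S) and nonsynonymous (N) site content of a single
#' sense codon under the Nei--Gojobori (1986) scheme.  At each codon position
#' the synonymous fraction is the number of synonymous single-base changes
#' divided by the number of changes that do not create a stop codon;
#' `N = 3 - S`, so every sense codon carries exactly three sites.
#'
#' @param codon A DNA triplet (character scalar, e.g. `"TTT"`).
#' @return A list with elements `S`, `N` and `defined`.  For stop codons or
#'   codons containing gaps/ambiguity `defined` is `FALSE` and `S`/`N` are
#'   `NA`.
#' @examples
#' codon_sites("TTT") # S = 1/3, N = 8/3
#' codon_sites("ATG") # S = 0,   N = 3
#' @export
codon_sites <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- toupper(codon)
  if (nchar(codon) != 3L) stop("`codon` must be a DNA triplet")
  s <- .NG86_SITES[codon]
  if (is.na(match(codon, .CODONS)) || is.na(s)) {
    return(list(S = NA_real_, N = NA_real_, defined = FALSE))
  }
  list(S = unname(s), N = unname(3 - s), defined = TRUE)
}

#' Pathway-averaged substitution counts between two codons
#'
#' For two sense codons differing at `k` positions, averages the synonymous
#' and nonsynonymous step counts over all `k!` single-step mutational
#' pathways.  Pathways passing through a stop codon are excluded; if every
#' pathway hits a stop, all pathways are used.  `Sd + Nd` always equals the
#' number of differing positions.
#'
#' @param codon1,codon2 DNA triplets.
#' @return A list with elements `Sd`, `Nd` and `defined`.
#' @examples
#' codon_diffs("TTT", "TTC") # (1, 0): a synonymous Phe change
#' codon_diffs("TTT", "GTA") # (0.5, 1.5): average of the two pathways
#' @export
codon_diffs <- function(codon1, codon2) {
  stopifnot(is.character(codon1), is.character(codon2))
  codon1 <- toupper(codon1)
  codon2 <- toupper(codon2)
  i <- match(codon1, .CODONS)
  j <- match(codon2, .CODONS)
  if (is.na(i) || is.na(j) ||
      codon1 %in% .STOP_CODONS || codon2 %in% .STOP_CODONS) {
    return(list(Sd = NA_real_, Nd = NA_real_, defined = FALSE))
  }
  list(Sd = unname(.NG86_SD[i, j]), Nd = unname(.NG86_ND[i, j]),
       defined = TRUE)
}

# Jukes-Cantor multiple-hit correction; NA when p >= 3/4 (divergent).
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

# Internal fast path: codon index vectors (1..64, NA for gap/ambiguity),
# already restricted to the columns of interest.
.ng86_from_indices <- function(idx1, idx2) {
  usable <- !is.na(idx1) & !is.na(idx2) &
    !(.CODONS[idx1] %in% .STOP_CODONS) &
    !(.CODONS[idx2] %in% .STOP_CODONS)
  idx1 <- idx1[usable]
  idx2 <- idx2[usable]
  n_codons <- length(idx1)
  if (n_codons == 0L) {
    return(list(Ka = NA_real_, Ks = NA_real_, S = 0, N = 0,
                Sd = NA_real_, Nd = NA_real_, n_codons = 0L,
                defined = FALSE, reason = "no usable codons"))
  }
  s1 <- sum(.NG86_SITES[idx1])
  s2 <- sum(.NG86_SITES[idx2])
  S <- (s1 + s2) / 2
  N <- 3 * n_codons - S
  Sd <- sum(.NG86_SD[cbind(idx1, idx2)])
  Nd <- sum(.NG86_ND[cbind(idx1, idx2)])
  reason <- NULL
  if (S <= 0 || N <= 0) {
    return(list(Ka = NA_real_, Ks = NA_real_, S = S, N = N, Sd = Sd, Nd = Nd,
                n_codons = n_codons, defined = FALSE,
                reason = "zero synonymous or nonsynonymous sites"))
  }
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  defined <- !is.na(Ka) && !is.na(Ks)
  if (!defined) reason <- "proportion of differences >= 3/4 (correction diverges)"
  list(Ka = Ka, Ks = Ks, S = S, N = N, Sd = Sd, Nd = Nd,
       n_codons = n_codons, defined = defined, reason = reason)
}

#' Pairwise Ka and Ks by the Nei--Gojobori (1986) method
#'
#' Computes nonsynonymous (`Ka`) and synonymous (`Ks`) substitutions per site
#' between two aligned coding sequences over an amino-acid column span.
#' Codons containing a gap or an ambiguity symbol in either sequence, and
#' codons that are stop codons, are skipped (pairwise deletion).  Proportions
#' `pN = Nd/N` and `pS = Sd/S` receive the Jukes--Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`; the result is undefined when `S = 0`,
#' `N = 0`, or either proportion reaches 3/4.
#'
#' @param seq1,seq2 Aligned DNA strings of equal length (multiple of 3), gaps
#'   as `-`.
#' @param columns Optional integer vector of 1-based amino-acid columns to
#'   include (default: all).
#' @return A list with `Ka`, `Ks`, `S`, `N`, `Sd`, `Nd`, `n_codons`,
#'   `defined`, and `reason` (when undefined).
#' @examples
#' pairwise_ng86("AAATTTGGGCCC", "AAGTTTGGGCCC") # one synonymous Lys change
#' @export
pairwise_ng86 <- function(seq1, seq2, columns = NULL) {
  stopifnot(is.character(seq1), is.character(seq2),
            length(seq1) == 1L, length(seq2) == 1L)
  if (nchar(seq1) != nchar(seq2)) {
    stop("aligned sequences must have equal length")
  }
  if (nchar(seq1) %% 3L != 0L) stop("alignment length must be a multiple of 3")
  idx1 <- codon_index(split_codons(seq1))
  idx2 <- codon_index(split_codons(seq2))
  if (!is.null(columns)) {
    if (any(columns < 1L | columns > length(idx1))) {
      stop("`columns` out of range")
    }
    idx1 <- idx1[columns]
    idx2 <- idx2[columns]
  }
  .ng86_from_indices(idx1, idx2)
}

#' @keywords internal
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
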