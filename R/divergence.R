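# Type-I functional divergence distances and per-cluster functional branch
# lengths on a star topology.

#' Type-I functional distance from a divergence coefficient
#'
#' Transforms a pairwise type-I functional-divergence coefficient
#' `theta` in `[0, 1)` into the additive functional distance
#' `dF = -ln(1 - theta)`.
#'
#' @param theta Numeric vector of coefficients, each in `[0, 1)`.
#' @return Numeric vector of distances.
#' @examples
#' functional_distance(0.5) # ln 2
#' @export
functional_distance <- function(theta) {
  stopifnot(is.numeric(theta))
  if (any(theta < 0, na.rm = TRUE)) stop("`theta` must be >= 0")
  if (any(theta >= 1, na.rm = TRUE)) {
    stop("`theta` must be < 1 (distance is infinite at 1)")
  }
  -log(1 - theta)
}

#' Divergence coefficient from a functional distance
#'
#' Inverse of [functional_distance()]: `theta = 1 - exp(-dF)`.
#'
#' @param dF Numeric vector of nonnegative distances.
#' @return Numeric vector of coefficients in `[0, 1)`.
#' @export
theta_from_distance <- function(dF) {
  stopifnot(is.numeric(dF))
  if (any(dF < 0, na.rm = TRUE)) stop("`dF` must be >= 0")
  1 - exp(-dF)
}

#' Functional branch lengths on a star topology by least squares
#'
#' Under the additive star model `dF(A, B) = bF(A) + bF(B)`, solves for the
#' per-cluster functional branch lengths `bF` minimizing
#' `sum_{i<j} (dF_ij - bF_i - bF_j)^2`.  For three clusters the least-squares
#' solution is exact: `bF_i = (dF_ij + dF_ik - dF_jk) / 2` and all residuals
#' vanish.  Negative solutions are permitted (the model does not constrain
#' them) but are flagged with a warning.
#'
#' @param dF Symmetric numeric matrix of pairwise functional distances over
#'   `k >= 3` clusters (dimnames give cluster labels); the diagonal is
#'   ignored.
#' @return An object of class `fd_star` with components `bF` (named numeric),
#'   `dF`, `fitted`, `residuals` (matrix `dF - (bF_i + bF_j)`),
#'   `max_abs_residual` and `negative` (labels of negative branch lengths).
#'   Methods: `coef`, `fitted`, `residuals`, `print`, `summary`.
#' @examples
#' dF <- matrix(c(0, 1.26, 1.40,
#'                1.26, 0, 0.78,
#'                1.40, 0.78, 0), 3, 3,
#'              dimnames = list(c("DEFA1", "DEFA4", "DEFA8"),
#'                              c("DEFA1", "DEFA4", "DEFA8")))
#' coef(star_branch_lengths(dF)) # 0.94, 0.32, 0.46
#' @export
star_branch_lengths <- function(dF) {
  stopifnot(is.matrix(dF), is.numeric(dF))
  k <- nrow(dF)
  if (k != ncol(dF)) stop("`dF` must be square")
  if (k < 3L) stop("at least 3 clusters are required (underdetermined)")
  labels <- rownames(dF)
  if (is.null(labels)) labels <- paste0("cluster", seq_len(k))
  ut <- which(upper.tri(dF), arr.ind = TRUE)
  d <- dF[ut]
  if (any(!is.finite(d))) stop("all off-diagonal entries must be finite")
  if (max(abs(dF[ut] - t(dF)[ut])) > 1e-8) {
    stop("`dF` must be symmetric")
  }
  A <- matrix(0, nrow(ut), k)
  A[cbind(seq_len(nrow(ut)), ut[, 1])] <- 1
  A[cbind(seq_len(nrow(ut)), ut[, 2])] <- 1
  bF <- as.numeric(qr.solve(A, d))
  names(bF) <- labels
  fitted <- outer(bF, bF, "+")
  diag(fitted) <- 0
  dimnames(fitted) <- list(labels, labels)
  res <- dF - fitted
  diag(res) <- 0
  negative <- labels[bF < 0]
  if (length(negative) > 0L) {
    warning("negative functional branch length(s): ",
            paste(negative, collapse = ", "))
  }
  structure(
    list(bF = bF, dF = dF, fitted = fitted, residuals = res,
         max_abs_residual = max(abs(res)), negative = negative),
    class = "fd_star"
  )
}

#' @export
coef.fd_star <- function(object, ...) object$bF

#' @export
fitted.fd_star <- function(object, ...) object$fitted

#' @export
residuals.fd_star <- function(object, ...) object$residuals

#' @export
print.fd_star <- function(x, digits = 3, ...) {
  cat("Functional branch lengths (star least squares):\n")
  print(round(x$bF, digits))
  cat(sprintf("max |residual| = %.3g\n", x$max_abs_residual))
  invisible(x)
}

#' @export
summary.fd_star <- function(object, ...) {
  print(object)
  rng <- distance_range(object$dF)
  cat(sprintf("pairwise dF range: %.3g-%.3g\n", rng[1], rng[2]))
  if (length(object$negative) > 0L) {
    cat("note: negative branch length(s): ",
        paste(object$negative, collapse = ", "), "\n", sep = "")
  }
  invisible(object)
}

#' Range of pairwise functional distances
#'
#' @param dF Symmetric distance matrix over at least two clusters.
#' @return Named numeric vector `c(min, max)` over the upper-triangle
#'   entries.
#' @export
distance_range <- function(dF) {
  stopifnot(is.matrix(dF), nrow(dF) == ncol(dF), nrow(dF) >= 2L)
  v <- dF[upper.tri(dF)]
  c(min = min(v), max = max(v))
}

#' Fit the functional-divergence star model from a coefficient table
#'
#' High-level wrapper: converts a table (or symmetric matrix) of pairwise
#' type-I divergence coefficients into functional distances and solves the
#' star branch lengths.
#'
#' @param theta Either a symmetric matrix of coefficients, or a data frame
#'   with columns `cluster_i`, `cluster_j`, `theta` (e.g. from
#'   [read_theta_table()]).
#' @return An `fd_star` fit, see [star_branch_lengths()].
#' @export
fd_star <- function(theta) {
  if (is.data.frame(theta)) theta <- theta_pairs_to_matrix(theta)
  stopifnot(is.matrix(theta))
  dF <- theta
  off <- row(theta) != col(theta)
  dF[off] <- functional_distance(theta[off])
  diag(dF) <- 0
  star_branch_lengths(dF)
}

theta_pairs_to_matrix <- function(df, value = "theta") {
  stopifnot(all(c("cluster_i", "cluster_j", value) %in% names(df)))
  labels <- unique(c(df$cluster_i, df$cluster_j))
  k <- length(labels)
  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  diag(m) <- 0
  for (r in seq_len(nrow(df))) {
    i <- df$cluster_i[r]
    j <- df$cluster_j[r]
    m[i, j] <- m[j, i] <- df[[value]][r]
  }
  if (anyNA(m)) stop("incomplete pairwise table: missing cluster pair(s)")
  m
}
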