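# Sliding-window selection scan: mean pairwise amino-acid identity and
# average pairwise Ka/Ks per window, with a directional bootstrap test of the
# average ratio against 1.

# All pairwise NG86 statistics over a set of amino-acid columns.
# Returns n x n symmetric matrices: ka, ks, ratio (NA where undefined or
# Ks = 0 under the mean-of-ratios convention).
pairwise_window_stats <- function(idx_mat, columns,
                                  ratio_method = c("mean_of_ratios",
                                                   "ratio_of_means")) {
  ratio_method <- match.arg(ratio_method)
  n <- nrow(idx_mat)
  ka <- ks <- ratio <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- .ng86_from_indices(idx_mat[i, columns], idx_mat[j, columns])
      if (r$defined) {
        ka[i, j] <- ka[j, i] <- r$Ka
        ks[i, j] <- ks[j, i] <- r$Ks
        if (r$Ks > 0) {
          ratio[i, j] <- ratio[j, i] <- r$Ka / r$Ks
        }
      }
    }
  }
  list(ka = ka, ks = ks, ratio = ratio, ratio_method = ratio_method)
}

mean_upper <- function(m) {
  v <- m[upper.tri(m)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else mean(v)
}

# window average Ka/Ks for a (multi)set of sequence indices; pairs whose two
# members are copies of the same original sequence are excluded
window_avg_ratio <- function(stats, members = seq_len(nrow(stats$ratio))) {
  pairs <- utils::combn(length(members), 2L)
  a <- members[pairs[1L, ]]
  b <- members[pairs[2L, ]]
  keep <- a != b
  if (!any(keep)) return(NA_real_)
  if (stats$ratio_method == "mean_of_ratios") {
    v <- stats$ratio[cbind(a[keep], b[keep])]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  } else {
    ka <- stats$ka[cbind(a[keep], b[keep])]
    ks <- stats$ks[cbind(a[keep], b[keep])]
    ok <- !is.na(ka) & !is.na(ks)
    if (!any(ok) || mean(ks[ok]) <= 0) NA_real_ else mean(ka[ok]) / mean(ks[ok])
  }
}

#' Directional bootstrap test of an average Ka/Ks against 1
#'
#' Resamples the N sequences of an alignment window with replacement and
#' recomputes the window's average pairwise Ka/Ks for each replicate (pairs
#' formed by two copies of the same original sequence are excluded, as are
#' pairs with undefined rates or Ks = 0).  A normal distribution is fitted to
#' the replicate averages by their mean and standard deviation, and the
#' one-sided p-value is the fitted normal's tail probability beyond 1 on the
#' null side: when the observed average exceeds 1 the alternative is
#' "Ka/Ks > 1" and `p = P(X <= 1)`; otherwise the alternative is "Ka/Ks < 1"
#' and `p = P(X >= 1)`.
#'
#' @param stats Pairwise statistics for the window, as produced internally by
#'   [window_scan()]; alternatively a plain symmetric matrix of per-pair
#'   Ka/Ks ratios (NA for undefined pairs).
#' @param observed_avg The observed window average Ka/Ks.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for the resampling RNG.
#' @param max_redraws Maximum redraws for replicates whose average is
#'   undefined before the replicate is dropped (default 100).
#' @return A list with `p_value`, `direction` (`"greater"` or `"less"`),
#'   `boot_mean`, `boot_sd` and `n_replicates_used`.
#' @export
bootstrap_test <- function(stats, observed_avg, replicates = 1000L,
                           seed = NULL, max_redraws = 100L) {
  if (is.matrix(stats)) {
    stats <- list(ka = stats, ks = stats, ratio = stats,
                  ratio_method = "mean_of_ratios")
  }
  if (is.na(observed_avg)) stop("`observed_avg` must be defined")
  if (replicates < 2L) stop("`replicates` must be >= 2")
  n <- nrow(stats$ratio)
  if (!is.null(seed)) set.seed(seed)
  reps <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    val <- NA_real_
    for (try in seq_len(max_redraws + 1L)) {
      members <- sample.int(n, n, replace = TRUE)
      val <- window_avg_ratio(stats, members)
      if (!is.na(val)) break
    }
    reps[r] <- val
  }
  reps <- reps[!is.na(reps)]
  direction <- if (observed_avg > 1) "greater" else "less"
  if (length(reps) < 2L) {
    return(list(p_value = NA_real_, direction = direction,
                boot_mean = NA_real_, boot_sd = NA_real_,
                n_replicates_used = length(reps)))
  }
  m <- mean(reps)
  s <- stats::sd(reps)
  p <- if (s == 0) {
    # degenerate normal: point mass at the replicate mean
    if (m == 1) 0.5 else if (direction == "greater") {
      as.numeric(m <= 1)
    } else {
      as.numeric(m >= 1)
    }
  } else if (direction == "greater") {
    stats::pnorm(1, mean = m, sd = s)
  } else {
    stats::pnorm(1, mean = m, sd = s, lower.tail = FALSE)
  }
  list(p_value = p, direction = direction, boot_mean = m, boot_sd = s,
       n_replicates_used = length(reps))
}

#' Sliding-window Ka/Ks and identity scan of a codon alignment
#'
#' Slides a window of `size` amino-acid columns in steps of `step` columns
#' along the alignment (trailing windows shorter than `size` are dropped) and
#' reports, per window, the mean pairwise amino-acid identity (pairwise gap
#' exclusion), the average pairwise Ka, Ks and Ka/Ks by the Nei--Gojobori
#' (1986) method, and a directional bootstrap test of the average Ka/Ks
#' against 1 ([bootstrap_test()]).
#'
#' The average Ka/Ks is the mean of per-pair ratios over pairs with defined
#' rates and Ks > 0 (`ratio_method = "mean_of_ratios"`, the default); the
#' ratio of the average Ka to the average Ks is available as
#' `"ratio_of_means"`.  Average Ka and Ks are means over all defined pairs.
#'
#' @param aln A [codon_alignment()] with at least two sequences.
#' @param size Window size in amino-acid columns (default 10).
#' @param step Step size in amino-acid columns (default 5).
#' @param replicates Bootstrap replicates per window (default 1000); set to 0
#'   to skip the bootstrap.
#' @param seed Optional integer seed controlling the bootstrap resampling.
#' @param max_redraws Redraw limit for undefined bootstrap replicates.
#' @param ratio_method Average-ratio convention, see Details.
#' @return An object of class `kaks_scan`: a data frame with columns
#'   `start`, `end`, `identity_pct`, `avg_Ka`, `avg_Ks`, `avg_KaKs`,
#'   `n_pairs_used`, `direction`, `boot_mean`, `boot_sd`, `p_value`,
#'   plus attributes recording the window spec and seed.
#' @examples
#' aln <- simulate_family(n = 6, branch_length = 0.2, seed = 1)
#' sc <- window_scan(aln, replicates = 0)
#' head(as.data.frame(sc))
#' @export
window_scan <- function(aln, size = 10L, step = 5L, replicates = 1000L,
                        seed = NULL, max_redraws = 100L,
                        ratio_method = c("mean_of_ratios", "ratio_of_means")) {
  stopifnot(inherits(aln, "codon_alignment"))
  ratio_method <- match.arg(ratio_method)
  if (length(aln$ids) < 2L) stop("at least two sequences are required")
  if (size < 2L) stop("`size` must be >= 2")
  if (step < 1L) stop("`step` must be >= 1")
  n_col <- aln$n_codons
  starts <- seq.int(1L, n_col, by = step)
  starts <- starts[starts + size - 1L <= n_col]
  if (length(starts) == 0L) stop("alignment shorter than one window")
  idx_mat <- codon_index_matrix(aln)
  aam <- aa_matrix(aln)
  n <- length(aln$ids)
  pair_idx <- utils::combn(n, 2L)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(starts))
  for (w in seq_along(starts)) {
    cols <- seq.int(starts[w], starts[w] + size - 1L)
    st <- pairwise_window_stats(idx_mat, cols, ratio_method)
    # mean pairwise identity with pairwise gap exclusion
    ident <- apply(pair_idx, 2L, function(p) {
      a <- aam[p[1L], cols]
      b <- aam[p[2L], cols]
      keep <- a != "-" & b != "-"
      if (!any(keep)) NA_real_ else 100 * mean(a[keep] == b[keep])
    })
    ratios <- st$ratio[upper.tri(st$ratio)]
    n_used <- sum(!is.na(ratios))
    avg_ratio <- window_avg_ratio(st)
    boot <- list(p_value = NA_real_, direction = NA_character_,
                 boot_mean = NA_real_, boot_sd = NA_real_)
    if (replicates > 0L && !is.na(avg_ratio)) {
      boot <- bootstrap_test(st, avg_ratio, replicates = replicates,
                             max_redraws = max_redraws)
    }
    rows[[w]] <- data.frame(
      start = starts[w], end = starts[w] + size - 1L,
      identity_pct = mean(ident, na.rm = TRUE),
      avg_Ka = mean_upper(st$ka), avg_Ks = mean_upper(st$ks),
      avg_KaKs = avg_ratio, n_pairs_used = n_used,
      direction = boot$direction, boot_mean = boot$boot_mean,
      boot_sd = boot$boot_sd, p_value = boot$p_value,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("kaks_scan", "data.frame"),
            window_size = as.integer(size), window_step = as.integer(step),
            replicates = as.integer(replicates), seed = seed,
            n_sequences = n, ratio_method = ratio_method,
            partition = aln$partition)
}

#' @export
print.kaks_scan <- function(x, ...) {
  cat(sprintf(
    "Sliding-window Ka/Ks scan: %d windows (size %d, step %d), %d sequences\n",
    nrow(x), attr(x, "window_size"), attr(x, "window_step"),
    attr(x, "n_sequences")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.kaks_scan <- function(object, alpha = 0.05, ...) {
  pos <- !is.na(object$p_value) & object$direction == "greater" &
    object$p_value < alpha
  cat(sprintf("%d windows; avg Ka/Ks range: %.3f-%.3f\n", nrow(object),
              min(object$avg_KaKs, na.rm = TRUE),
              max(object$avg_KaKs, na.rm = TRUE)))
  if (any(pos)) {
    lab <- sprintf("%d-%d", object$start[pos], object$end[pos])
    cat(sprintf("windows with Ka/Ks significantly > 1 (p < %.2g): %s\n",
                alpha, paste(lab, collapse = ", ")))
  } else {
    cat(sprintf("no window with Ka/Ks significantly > 1 at p < %.2g\n", alpha))
  }
  invisible(object)
}

#' @export
plot.kaks_scan <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(mid, x$identity_pct, type = "b", pch = 16,
                 xlab = "", ylab = "identity (%)", ...)
  graphics::plot(mid, x$avg_KaKs, type = "b", pch = 16,
                 xlab = "alignment position (aa)", ylab = "avg Ka/Ks", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Average Ka/Ks of an alignment region with its bootstrap test
#'
#' Convenience wrapper treating a whole column span as a single window:
#' computes the average pairwise Ka/Ks over the span and, optionally, its
#' directional bootstrap test against 1.
#'
#' @inheritParams window_scan
#' @param columns Integer vector of amino-acid columns (default: all).
#' @return A list with `avg_KaKs`, `n_pairs_used`, and the [bootstrap_test()]
#'   fields when `replicates > 0`.
#' @export
kaks_region <- function(aln, columns = NULL, replicates = 1000L, seed = NULL,
                        max_redraws = 100L,
                        ratio_method = c("mean_of_ratios", "ratio_of_means")) {
  stopifnot(inherits(aln, "codon_alignment"))
  ratio_method <- match.arg(ratio_method)
  if (length(aln$ids) < 2L) stop("at least two sequences are required")
  if (is.null(columns)) columns <- seq_len(aln$n_codons)
  idx_mat <- codon_index_matrix(aln)
  st <- pairwise_window_stats(idx_mat, columns, ratio_method)
  avg <- window_avg_ratio(st)
  out <- list(avg_KaKs = avg,
              n_pairs_used = sum(!is.na(st$ratio[upper.tri(st$ratio)])))
  if (replicates > 0L && !is.na(avg)) {
    if (!is.null(seed)) set.seed(seed)
    out <- c(out, bootstrap_test(st, avg, replicates = replicates,
                                 max_redraws = max_redraws))
  }
  out
}
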