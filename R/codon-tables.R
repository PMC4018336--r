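# Precomputed codon tables for the Nei-Gojobori (1986) counting method.
# Built once at install time from the standard nuclear genetic code; every
# per-pair computation afterwards is a table lookup, which keeps sliding-window
# scans and bootstrap resampling cheap.

.BASES <- c("A", "C", "G", "T")

.CODONS <- names(Biostrings::GENETIC_CODE)
.CODON_AA <- unname(Biostrings::GENETIC_CODE)
names(.CODON_AA) <- .CODONS
.STOP_CODONS <- .CODONS[.CODON_AA == "*"]
.SENSE_CODONS <- .CODONS[.CODON_AA != "*"]

#' @keywords internal
codon_index <- function(codons) match(codons, .CODONS)

# amino acid encoded by a codon string; ambiguity / gaps give "X" or "-"
translate_codon <- function(codon) {
  if (identical(codon, "---")) return("-")
  aa <- .CODON_AA[codon]
  ifelse(is.na(aa), "X", aa)
}

.single_base_neighbors <- function(codon) {
  out <- character(9)
  k <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in setdiff(.BASES, ref)) {
      k <- k + 1
      nb <- codon
      substr(nb, pos, pos) <- b
      out[k] <- nb
    }
  }
  out
}

# Per-codon synonymous/nonsynonymous site fractions.  At each of the three
# positions the synonymous fraction is (synonymous single-base changes) /
# (changes not creating a stop); N = 3 - S, so every sense codon carries
# exactly three sites.
.compute_codon_sites <- function() {
  S <- rep(NA_real_, 64)
  names(S) <- .CODONS
  for (codon in .SENSE_CODONS) {
    aa <- .CODON_AA[codon]
    s <- 0
    for (pos in 1:3) {
      syn <- 0L
      counted <- 0L
      ref <- substr(codon, pos, pos)
      for (b in setdiff(.BASES, ref)) {
        nb <- codon
        substr(nb, pos, pos) <- b
        if (.CODON_AA[nb] == "*") next
        counted <- counted + 1L
        if (.CODON_AA[nb] == aa) syn <- syn + 1L
      }
      if (counted > 0) s <- s + syn / counted
    }
    S[codon] <- s
  }
  S
}

# Pathway-averaged synonymous difference counts for every ordered codon pair.
# For k differing positions all k! single-step pathways are enumerated;
# pathways passing through a stop codon are dropped (all pathways are used if
# every one hits a stop).  Sd + Nd equals the number of differing positions.
.compute_codon_diffs <- function() {
  n <- length(.CODONS)
  Sd <- matrix(NA_real_, n, n, dimnames = list(.CODONS, .CODONS))
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(
    c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
  )
  for (c1 in .SENSE_CODONS) {
    for (c2 in .SENSE_CODONS) {
      d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
      k <- length(d)
      if (k == 0) {
        Sd[c1, c2] <- 0
        next
      }
      perms <- switch(k, list(1L), perms2, perms3)
      syn_per_path <- numeric(0)
      syn_all <- numeric(0)
      for (ord in perms) {
        cur <- c1
        syn <- 0
        ok <- TRUE
        for (pos in d[ord]) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (.CODON_AA[nxt] == "*") ok <- FALSE
          if (ok && .CODON_AA[nxt] == .CODON_AA[cur]) syn <- syn + 1
          if (!ok) break
          cur <- nxt
        }
        if (ok) syn_per_path <- c(syn_per_path, syn)
        # fallback accounting: count through-stop pathways too
        cur <- c1
        syn <- 0
        for (pos in d[ord]) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(c2, pos, pos)
          if (.CODON_AA[nxt] != "*" && .CODON_AA[nxt] == .CODON_AA[cur]) {
            syn <- syn + 1
          }
          cur <- nxt
        }
        syn_all <- c(syn_all, syn)
      }
      Sd[c1, c2] <- if (length(syn_per_path) > 0) {
        mean(syn_per_path)
      } else {
        mean(syn_all)
      }
    }
  }
  Sd
}

.NG86_SITES <- .compute_codon_sites()
.NG86_SD <- .compute_codon_diffs()
.NG86_NDIFF <- {
  n <- length(.CODONS)
  m <- matrix(0L, n, n, dimnames = list(.CODONS, .CODONS))
  split1 <- strsplit(.CODONS, "")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sum(split1[[i]] != split1[[j]])
    }
  }
  m
}
.NG86_ND <- .NG86_NDIFF - .NG86_SD
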