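# Independent brute-force oracles for the Nei-Gojobori counting method and
# the rigid-fit geometry, plus small fixture builders.  The oracles are kept
# deliberately naive (direct enumeration over the genetic code) and share no
# code path with the package internals they check.

GC <- Biostrings::GENETIC_CODE
SENSE <- names(GC)[GC != "*"]
BASES4 <- c("A", "C", "G", "T")

mutate_at <- function(codon, pos, base) {
  substr(codon, pos, pos) <- base
  codon
}

# per-codon site counts: per-position synonymous fraction among non-stop
# changes; N = 3 - S
oracle_codon_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    counted <- 0
    for (b in setdiff(BASES4, substr(codon, pos, pos))) {
      nb <- mutate_at(codon, pos, b)
      if (GC[[nb]] == "*") next
      counted <- counted + 1
      if (GC[[nb]] == GC[[codon]]) syn <- syn + 1
    }
    if (counted > 0) s <- s + syn / counted
  }
  c(S = s, N = 3 - s)
}

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# pathway-averaged difference counts, excluding through-stop pathways
# (falling back to all pathways when every one hits a stop)
oracle_codon_diffs <- function(c1, c2) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0L) return(c(Sd = 0, Nd = 0))
  walk <- function(order, skip_stops) {
    cur <- c1
    syn <- 0
    for (pos in order) {
      nxt <- mutate_at(cur, pos, substr(c2, pos, pos))
      if (GC[[nxt]] == "*" && skip_stops) return(NULL)
      if (GC[[nxt]] != "*" && GC[[nxt]] == GC[[cur]]) syn <- syn + 1
      cur <- nxt
    }
    syn
  }
  perms <- all_perms(d)
  syns <- unlist(lapply(perms, walk, skip_stops = TRUE))
  if (is.null(syns)) syns <- unlist(lapply(perms, walk, skip_stops = FALSE))
  c(Sd = mean(syns), Nd = length(d) - mean(syns))
}

oracle_ng86 <- function(seq1, seq2) {
  n <- nchar(seq1) %/% 3
  c1 <- substring(seq1, 3 * seq_len(n) - 2, 3 * seq_len(n))
  c2 <- substring(seq2, 3 * seq_len(n) - 2, 3 * seq_len(n))
  keep <- c1 %in% SENSE & c2 %in% SENSE
  c1 <- c1[keep]
  c2 <- c2[keep]
  S <- mean(c(sum(sapply(c1, function(x) oracle_codon_sites(x)["S"])),
              sum(sapply(c2, function(x) oracle_codon_sites(x)["S"]))))
  N <- 3 * length(c1) - S
  diffs <- mapply(function(a, b) oracle_codon_diffs(a, b), c1, c2)
  Sd <- sum(diffs["Sd", ])
  Nd <- sum(diffs["Nd", ])
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  list(Ka = jc(Nd / N), Ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

random_sense_seq <- function(n_codons) {
  paste(sample(SENSE, n_codons, replace = TRUE), collapse = "")
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# 93-residue defensin-like precursor protein: 19-residue signal,
# 45-residue prosegment, 29-residue mature peptide carrying the
# six-cysteine alpha motif (spacers 1, 4, 9, 9 then the adjacent CC pair)
defensin_protein <- function() {
  signal <- "MRTLALLAAILLVALQAQA"
  pro <- paste(rep("EPLQARADEVAAAPEQIAADIPEVVVSLAWDESLAPKHPGSRKNM", 1),
               collapse = "")
  mature <- "CYCRIPACIAGERRYGTCIYQGRLWAFCC"
  stopifnot(nchar(signal) == 19, nchar(pro) == 45, nchar(mature) == 29)
  paste0(signal, pro, mature)
}

# 94-codon coding sequence (93 residues + terminal stop)
defensin_cds <- function() encode_peptide(paste0(defensin_protein(), "*"))

# theta-precursor variant: nonapeptide + RLL tail at residues 65-76,
# theta-defining stop at codon 77
theta_cds <- function() {
  prot <- defensin_protein()
  prot <- paste0(substr(prot, 1, 64), "RCICRRGVC", "RLL",
                 substr(prot, 77, 93))
  stopifnot(nchar(prot) == 93)
  inject_lesion(encode_peptide(paste0(prot, "*")), "theta_stop", 77)
}
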