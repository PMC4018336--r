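# Synthetic-data generator: codon families, lesions, trajectories.

test_that("the generator is deterministic given its seed", {
  a1 <- simulate_family(n = 6, branch_length = 0.3, seed = 99)
  a2 <- simulate_family(n = 6, branch_length = 0.3, seed = 99)
  expect_identical(a1$seqs, a2$seqs)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(a1$seqs, f1)
  write_fasta(a2$seqs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  a3 <- simulate_family(n = 6, branch_length = 0.3, seed = 100)
  expect_false(identical(a1$seqs, a3$seqs))
  expect_error(simulate_family(n = 4), "seed")
})

test_that("omega zero fixes the protein while omega governs acceptance", {
  aln <- simulate_family(n = 8, branch_length = 0.5,
                         omegas = c(signal = 0, prosegment = 0, mature = 0),
                         seed = 7)
  prots <- vapply(aln$seqs, function(s) {
    paste(vapply(defevol:::split_codons(s), defevol:::translate_codon,
                 character(1)), collapse = "")
  }, character(1))
  expect_equal(length(unique(prots)), 1L)
  hist <- attr(aln, "history")
  expect_true(all(!grepl("nonsyn", names(hist$event_counts))))
})

test_that("no simulated functional sequence contains an internal stop", {
  for (s in 1:10) {
    aln <- simulate_family(n = 6, branch_length = 0.6, seed = 3000 + s)
    for (seq in aln$seqs) {
      cl <- classify_coding_sequence(seq, aln$n_codons)
      expect_equal(cl$pseudo_reason, "none")
    }
  }
})

test_that("injected lesions classify as designed", {
  aln <- simulate_family(
    n = 6, branch_length = 0.2, seed = 12,
    lesions = list(list(leaf = 1, type = "stop", codon = 17),
                   list(leaf = 2, type = "indel", codon = 30))
  )
  cl1 <- classify_coding_sequence(aln$seqs[[1]], aln$n_codons)
  expect_equal(cl1$pseudo_reason, "premature_stop")
  expect_equal(cl1$stop_site, 17L)
  fs <- attr(aln, "history")$lesioned[[1]]
  expect_equal(nchar(fs) %% 3, 2)
  expect_equal(classify_coding_sequence(fs, aln$n_codons)$pseudo_reason,
               "frameshift")
  expect_error(inject_lesion("AAATTT", "stop", 3), "out of range")
})

test_that("a theta stop on a motif-bearing sequence yields a theta precursor", {
  cds <- theta_cds()
  cl <- classify_coding_sequence(cds, 94, theta_site = 77)
  expect_equal(cl$status, "functional")
  expect_true(cl$theta)
  expect_equal(excise_nonapeptide(substr(cl$protein, 65, 76))$nonapeptide,
               "RCICRRGVC")
})

test_that("realized regional Ka/Ks tracks the omega dial within a factor of two", {
  for (omega in c(0.5, 2.0)) {
    vals <- numeric(0)
    for (s in 1:15) {
      aln <- simulate_family(
        n = 12, branch_length = 0.3,
        omegas = c(signal = 0.2, prosegment = 0.5, mature = omega),
        seed = 4000 + 100 * omega + s
      )
      reg <- kaks_region(aln, columns = 65:94, replicates = 0)
      vals <- c(vals, reg$avg_KaKs)
    }
    m <- mean(vals, na.rm = TRUE)
    expect_gt(m, omega / 2)
    expect_lt(m, omega * 2)
  }
})

test_that("scaling branch lengths up does not decrease expected Ks", {
  ks_at <- function(bl) {
    mean(vapply(1:8, function(s) {
      aln <- simulate_family(n = 6, branch_length = bl,
                             omegas = c(signal = 1, prosegment = 1,
                                        mature = 1),
                             seed = 5000 + s)
      idx <- defevol:::codon_index_matrix(aln)
      st <- defevol:::pairwise_window_stats(idx, seq_len(aln$n_codons))
      defevol:::mean_upper(st$ks)
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(ks_at(0.1), ks_at(0.4))
})

test_that("trajectories jitter loops more than the core", {
  ref <- synthetic_dimer_reference()
  frozen <- simulate_trajectory(ref, n_frames = 5, loop_sigma = 0,
                                core_sigma = 0, seed = 1)
  s <- trajectory_summary(frame_metrics(frozen))
  expect_true(all(s$sd == 0))
  expect_equal(frozen$xyz[, , 5], ref$xyz[, , 1])
  one <- simulate_trajectory(ref, n_frames = 1, loop_sigma = 1, seed = 2)
  expect_true(all(trajectory_summary(frame_metrics(one))$sd == 0))
  # with flexible loops at residue 11 and a rigid core, d11 varies more
  wins <- 0
  for (s in 1:10) {
    tr <- simulate_trajectory(ref, n_frames = 40, loop_sigma = 1.0,
                              core_sigma = 0.1, seed = 6000 + s)
    sm <- trajectory_summary(frame_metrics(tr))
    if (sm$sd[sm$metric == "d11"] > sm$sd[sm$metric == "d22"]) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("jitter recovery: metric SDs track the injected noise scale", {
  ref <- synthetic_dimer_reference()
  sds <- vapply(1:5, function(s) {
    tr <- simulate_trajectory(ref, n_frames = 60, loop_sigma = 0.5,
                              core_sigma = 0.5, seed = 7000 + s)
    sm <- trajectory_summary(frame_metrics(tr))
    sm$sd[sm$metric == "d11"]
  }, numeric(1))
  # distance of two points jittered with sigma = 0.5 per coordinate has
  # SD close to sqrt(2) * 0.5 ~ 0.71; accept a generous band
  expect_true(all(sds > 0.3 & sds < 1.2))
})
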