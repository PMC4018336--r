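# Repertoire classification, motif validation and theta maturation.

test_that("an intact 94-codon ORF with six mature cysteines is functional", {
  cds <- defensin_cds()
  cl <- classify_coding_sequence(cds, expected_codon_length = 94)
  expect_equal(cl$status, "functional")
  expect_equal(cl$pseudo_reason, "none")
  expect_true(is.na(cl$stop_site))
  expect_true(validate_motif(cl$protein, "alpha_mature")$match)
})

test_that("a nonsense mutation at codon 17 pseudogenizes with its site reported", {
  cds <- inject_lesion(defensin_cds(), "stop", 17)
  cl <- classify_coding_sequence(cds, 94, theta_site = 77)
  expect_equal(cl$status, "pseudogene")
  expect_equal(cl$pseudo_reason, "premature_stop")
  expect_equal(cl$stop_site, 17L)
})

test_that("single-nucleotide deletions are called frameshifts", {
  cds <- inject_lesion(defensin_cds(), "indel", 30, n_del = 1)
  cl <- classify_coding_sequence(cds, 94)
  expect_equal(cl$status, "pseudogene")
  expect_equal(cl$pseudo_reason, "frameshift")
  # a 3-nt (whole-codon) deviation is not a frameshift
  trimmed <- substr(defensin_cds(), 4, nchar(defensin_cds()))
  expect_equal(classify_coding_sequence(trimmed, 94)$pseudo_reason, "none")
})

test_that("the theta-defining stop creates a functional theta precursor", {
  cds <- theta_cds()
  with_theta <- classify_coding_sequence(cds, 94, theta_site = 77)
  expect_equal(with_theta$status, "functional")
  expect_true(with_theta$theta)
  # without the theta exception the same stop pseudogenizes
  plain <- classify_coding_sequence(cds, 94)
  expect_equal(plain$pseudo_reason, "premature_stop")
  expect_equal(plain$stop_site, 77L)
  # a stop at 77 without the upstream nonapeptide motif also pseudogenizes
  alpha_stop <- inject_lesion(defensin_cds(), "stop", 77)
  expect_equal(classify_coding_sequence(alpha_stop, 94,
                                        theta_site = 77)$status,
               "pseudogene")
})

test_that("classification rejects empty and non-IUPAC input", {
  expect_error(classify_coding_sequence("", 10), "empty")
  expect_error(classify_coding_sequence("AAZAAA", 2), "non-IUPAC")
})

test_that("the alpha-mature motif requires all six cysteine anchors", {
  # minimal instance: spacers 1, 3, 9, 6 and the adjacent CC pair
  minimal <- "CACAAACAAAAAAAAACAAAAAACC"
  v <- validate_motif(minimal, "alpha_mature")
  expect_true(v$match)
  expect_length(v$cys_positions, 6)
  expect_equal(v$cys_positions, c(1L, 3L, 7L, 17L, 24L, 25L))
  # dropping the sixth cysteine must break the match
  five_anchor <- substr(minimal, 1, nchar(minimal) - 1)
  expect_false(validate_motif(five_anchor, "alpha_mature")$match)
  # X never satisfies an anchor
  x_anchor <- sub("CC$", "CX", minimal)
  expect_false(validate_motif(x_anchor, "alpha_mature")$match)
})

test_that("theta nonapeptide motifs validate with three anchors", {
  v <- validate_motif("RCICRRGVC", "theta_nonapeptide")
  expect_true(v$match)
  expect_equal(v$cys_positions, c(2L, 4L, 9L))
  expect_false(validate_motif("RCICRRGVA", "theta_nonapeptide")$match)
  expect_false(validate_motif("", "theta_nonapeptide")$match)
  # colobus 13-mer variant
  expect_true(validate_motif("RCMCRRAAAAVFC",
                             "theta_nonapeptide_variant")$match)
})

test_that("motif matching is invariant to flanking residues", {
  set.seed(3)
  cases <- list(c("RCICRRGVC", "theta_nonapeptide"),
                c("CACAAACAAAAAAAAACAAAAAACC", "alpha_mature"))
  for (case in cases) {
    for (i in 1:20) {
      flank1 <- paste(sample(c("A", "G", "R", "L", "X"),
                             sample(0:8, 1), replace = TRUE), collapse = "")
      flank2 <- paste(sample(c("A", "G", "R", "L", "X"),
                             sample(0:8, 1), replace = TRUE), collapse = "")
      expect_true(validate_motif(paste0(flank1, case[1], flank2),
                                 case[2])$match)
    }
  }
})

test_that("nonapeptide excision removes the three C-terminal residues", {
  expect_equal(excise_nonapeptide("RCICRRGVCRLL"),
               list(nonapeptide = "RCICRRGVC", removed_tail = "RLL"))
  expect_equal(excise_nonapeptide("RCVCTRGVCQLL")$nonapeptide, "RCVCTRGVC")
  expect_equal(excise_nonapeptide("AAAAAAAAAXYZ")$nonapeptide, "AAAAAAAAA")
  expect_error(excise_nonapeptide("RCICRRGVC"), "12")
})

test_that("theta maturation forms an 18-residue cycle containing both units", {
  homo <- mature_theta("RCICRRGVC", "RCICRRGVC")
  expect_s3_class(homo, "cyclic_peptide")
  expect_equal(homo$length, 18L)
  expect_equal(nchar(homo$sequence), 18L)
  hetero <- mature_theta("RCICRRGVC", "RCVCTRGVC")
  doubled <- paste0(hetero$sequence, hetero$sequence)
  expect_true(grepl("RCICRRGVC", doubled, fixed = TRUE))
  expect_true(grepl("RCVCTRGVC", doubled, fixed = TRUE))
  # every rotation of the cycle still contains both units
  for (rot in c(5, 9, 14)) {
    rotated <- paste0(substr(hetero$sequence, rot + 1, 18),
                      substr(hetero$sequence, 1, rot))
    rotated2 <- paste0(rotated, rotated)
    expect_true(grepl("RCICRRGVC", rotated2, fixed = TRUE))
    expect_true(grepl("RCVCTRGVC", rotated2, fixed = TRUE))
  }
})

test_that("the tridisulfide ladder pairs cysteines only, per connectivity", {
  pep <- mature_theta("ACACAAAAC", "ACACAAAAC")
  residues <- strsplit(pep$sequence, "")[[1]]
  expect_true(all(residues[pep$disulfides] == "C"))
  anti <- mature_theta("RCICRRGVC", "RCVCTRGVC", "antiparallel")
  expect_equal(anti$disulfides[, "A"], c(2L, 4L, 9L))
  expect_equal(anti$disulfides[, "B"], c(18L, 13L, 11L))
  par <- mature_theta("RCICRRGVC", "RCVCTRGVC", "parallel")
  expect_equal(par$disulfides[, "B"], c(11L, 13L, 18L))
  expect_error(mature_theta("RCICRRGVA", "RCICRRGVC"), "not a valid")
})

test_that("repertoire classification flags motifs per sequence", {
  seqs <- c(fun = defensin_cds(),
            stop17 = inject_lesion(defensin_cds(), "stop", 17),
            fs = inject_lesion(defensin_cds(), "indel", 30),
            theta = theta_cds())
  rep <- classify_repertoire(seqs, 94, theta_site = 77)
  expect_equal(rep$status, c("functional", "pseudogene", "pseudogene",
                             "functional"))
  expect_equal(rep$pseudo_reason[2:3], c("premature_stop", "frameshift"))
  expect_equal(rep$stop_site[2], 17L)
  expect_true(rep$alpha_motif[1])
  expect_true(rep$theta[4])
  expect_true(rep$theta_motif[4])
  expect_false(rep$theta_motif[1] && rep$alpha_motif[4])
})
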