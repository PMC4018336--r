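# Dimer geometry: torsion, distances, superposition, trajectory summaries.

test_that("constructed four-point dihedrals match closed forms", {
  # coplanar cis arrangement
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  # coplanar trans arrangement
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, -1, 0))), 180)
  # right angle
  expect_equal(abs(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                                  c(1, 0, 1))), 90)
})

test_that("torsion is preserved under reversal of the four points", {
  set.seed(5)
  for (i in 1:20) {
    p <- lapply(1:4, function(i) rnorm(3))
    fwd <- dihedral_angle(p[[1]], p[[2]], p[[3]], p[[4]])
    rev <- dihedral_angle(p[[4]], p[[3]], p[[2]], p[[1]])
    expect_equal(fwd, rev, tolerance = 1e-10)
  }
})

test_that("frame metrics compute Euclidean distances on reference numbering", {
  atoms <- data.frame(
    chain = rep(c("A", "B"), each = 2),
    resno = c(11, 22, 11, 22),
    resname = "ALA", atom = "CA",
    stringsAsFactors = FALSE
  )
  xyz <- array(NA_real_, dim = c(4, 3, 1))
  xyz[, , 1] <- matrix(c(0, 0, 5,
                         0, 0, 0,
                         4, 3, 5,
                         0, 0, 9.6), 4, 3, byrow = TRUE)
  st <- dimer_structure(atoms, xyz)
  m <- frame_metrics(st)
  expect_equal(m$d22, 9.6)
  expect_equal(m$d11, 5)
  # missing atoms are named in errors
  st2 <- dimer_structure(atoms[-1, ], xyz[-1, , , drop = FALSE])
  expect_error(frame_metrics(st2), "A/11/CA")
})

test_that("a numbering map relabels structure residues onto the reference", {
  ref <- synthetic_dimer_reference()
  shifted <- ref
  shifted$atoms$resno <- shifted$atoms$resno + 100L
  expect_error(frame_metrics(shifted), "11")
  map <- structure(1:30, names = as.character(101:130))
  shifted$numbering_map <- map
  expect_equal(frame_metrics(shifted), frame_metrics(ref))
})

test_that("all metrics are invariant under global rigid transforms", {
  ref <- synthetic_dimer_reference()
  m0 <- frame_metrics(ref)
  set.seed(9)
  for (i in 1:10) {
    rot <- random_rotation()
    trans <- rnorm(3, sd = 20)
    moved <- transform_structure(ref, rot, trans)
    m1 <- frame_metrics(moved)
    expect_equal(m1$d22, m0$d22, tolerance = 1e-8)
    expect_equal(m1$d11, m0$d11, tolerance = 1e-8)
    expect_equal(m1$dihedral, m0$dihedral, tolerance = 1e-6)
  }
})

test_that("superposing a structure onto itself is the identity", {
  ref <- synthetic_dimer_reference()
  fit <- superpose_interface(ref, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a rigidly moved copy superposes back exactly", {
  ref <- synthetic_dimer_reference()
  set.seed(13)
  moved <- transform_structure(ref, random_rotation(), rnorm(3, sd = 15))
  fit <- superpose_interface(moved, ref)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$structure$xyz[, , 1], ref$xyz[, , 1], tolerance = 1e-6)
  # idempotence: re-fitting an already-fitted structure barely moves it
  fit2 <- superpose_interface(fit$structure, ref)
  expect_lt(abs(fit2$rmsd - fit$rmsd), 1e-10)
})

test_that("the rigid fit matches an independent best-fit RMSD oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- 12
    a <- matrix(rnorm(3 * n, sd = 5), n, 3)
    b <- matrix(rnorm(3 * n, sd = 5), n, 3)
    ours <- defevol:::kabsch_fit(a, b)$rmsd
    bvec <- as.vector(t(b))
    fitted <- bio3d::fit.xyz(fixed = bvec, mobile = as.vector(t(a)),
                             fixed.inds = seq_len(3 * n),
                             mobile.inds = seq_len(3 * n))
    oracle <- sqrt(sum((as.numeric(fitted) - bvec)^2) / n)
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("missing interface atoms are reported by name", {
  ref <- synthetic_dimer_reference()
  drop <- !(ref$atoms$chain == "B" & ref$atoms$resno == 20 &
              ref$atoms$atom == "CA")
  broken <- dimer_structure(ref$atoms[drop, ],
                            ref$xyz[drop, , , drop = FALSE])
  expect_error(superpose_interface(broken, ref), "B/20/CA")
})

test_that("trajectory summaries give per-metric moments and ranges", {
  m <- data.frame(frame = 1:2, d22 = c(10, 10), d11 = c(30, 37),
                  dihedral = c(80, -100))
  s <- trajectory_summary(m)
  d11 <- s[s$metric == "d11", ]
  expect_equal(d11$mean, 33.5)
  expect_equal(c(d11$min, d11$max), c(30, 37))
  dih <- s[s$metric == "abs_dihedral", ]
  expect_equal(dih$mean, 90)
  single <- trajectory_summary(m[1, ])
  expect_true(all(single$sd == 0))
  expect_error(trajectory_summary(m[0, ]), "nrow")
})
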