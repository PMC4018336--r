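# Dimer geometry: two-chain structures, interface superposition (Kabsch),
# and per-frame flexibility metrics (two C-alpha distances and a four-point
# dihedral) from coordinate trajectories.

#' Two-chain dimer structure with coordinate frames
#'
#' Holds per-atom metadata and a `n_atoms x 3 x n_frames` coordinate array
#' (Angstrom) for a two-chain peptide structure, together with an optional
#' residue-numbering map onto a reference coordinate system (HNP4 numbering),
#' which the metric functions use to resolve residues 11, 18, 20 and 22.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`, `atom`
#'   (atom name, e.g. `"CA"`).
#' @param xyz Numeric array `n_atoms x 3 x n_frames` (a matrix is treated as
#'   one frame).
#' @param numbering_map Optional named integer vector mapping structure
#'   residue numbers (names) to reference numbering (values); applied to both
#'   chains.  Default: identity.
#' @param chains Length-2 character vector naming which chain labels map to
#'   A and B (default: the first two labels in file order).
#' @return An object of class `dimer_structure`.
#' @export
dimer_structure <- function(atoms, xyz, numbering_map = NULL, chains = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resname", "atom") %in% names(atoms)))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L,
            dim(xyz)[1] == nrow(atoms))
  labels <- unique(atoms$chain)
  if (is.null(chains)) {
    if (length(labels) < 2L) stop("a dimer needs two chains; found: ",
                                  paste(labels, collapse = ", "))
    chains <- labels[1:2]
  }
  if (!all(chains %in% labels)) {
    stop("chain label(s) not present: ",
         paste(setdiff(chains, labels), collapse = ", "))
  }
  structure(
    list(atoms = atoms, xyz = xyz, numbering_map = numbering_map,
         chains = chains, n_frames = dim(xyz)[3]),
    class = "dimer_structure"
  )
}

#' @export
print.dimer_structure <- function(x, ...) {
  cat(sprintf("dimer_structure: %d atoms, chains %s/%s, %d frame(s)\n",
              nrow(x$atoms), x$chains[1], x$chains[2], x$n_frames))
  invisible(x)
}

# reference residue numbers of every atom (identity map unless supplied)
ref_resno <- function(structure) {
  rn <- structure$atoms$resno
  map <- structure$numbering_map
  if (is.null(map)) return(rn)
  out <- map[as.character(rn)]
  ifelse(is.na(out), rn, as.integer(out))
}

# row indices of the requested atoms; errors name every absence
select_atoms <- function(structure, residues, atoms = c("N", "CA", "C", "O"),
                         chains = structure$chains) {
  rr <- ref_resno(structure)
  idx <- integer(0)
  missing <- character(0)
  for (ch in chains) {
    for (res in residues) {
      for (at in atoms) {
        hit <- which(structure$atoms$chain == ch & rr == res &
                       structure$atoms$atom == at)
        if (length(hit) == 0L) {
          missing <- c(missing, sprintf("%s/%d/%s", ch, res, at))
        } else {
          idx <- c(idx, hit[1L])
        }
      }
    }
  }
  if (length(missing) > 0L) {
    stop("missing atom(s): ", paste(missing, collapse = ", "))
  }
  idx
}

ca_coord <- function(structure, chain, residue, frame = 1L) {
  idx <- select_atoms(structure, residue, atoms = "CA", chains = chain)
  structure$xyz[idx, , frame]
}

#' Signed dihedral angle over four points
#'
#' Standard torsion formula: the angle between the plane of points 1--2--3
#' and the plane of 2--3--4, signed by the right-hand rule about the 2--3
#' axis, in degrees within (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-frame dimer flexibility metrics
#'
#' For every coordinate frame, extracts the two interface-flexibility
#' distances and the dihedral angle used to monitor alpha-defensin dimer
#' geometry (reference numbering): `d22` = distance A22CA--B22CA, `d11` =
#' distance A11CA--B11CA, and the signed dihedral over A11CA, A22CA, B22CA,
#' B11CA.
#'
#' @param structure A [dimer_structure()] whose numbering map resolves
#'   residues 11 and 22 in both chains.
#' @param residues Length-2 integer vector: the loop-tip residues measured
#'   (default `c(11, 22)` in reference numbering).
#' @return A data frame with columns `frame`, `d22`, `d11`, `dihedral`
#'   (degrees, in (-180, 180]).
#' @export
frame_metrics <- function(structure, residues = c(11L, 22L)) {
  stopifnot(inherits(structure, "dimer_structure"))
  chA <- structure$chains[1]
  chB <- structure$chains[2]
  r11 <- residues[1]
  r22 <- residues[2]
  iA11 <- select_atoms(structure, r11, "CA", chA)
  iA22 <- select_atoms(structure, r22, "CA", chA)
  iB11 <- select_atoms(structure, r11, "CA", chB)
  iB22 <- select_atoms(structure, r22, "CA", chB)
  out <- lapply(seq_len(structure$n_frames), function(f) {
    a11 <- structure$xyz[iA11, , f]
    a22 <- structure$xyz[iA22, , f]
    b11 <- structure$xyz[iB11, , f]
    b22 <- structure$xyz[iB22, , f]
    data.frame(
      frame = f,
      d22 = sqrt(sum((a22 - b22)^2)),
      d11 = sqrt(sum((a11 - b11)^2)),
      dihedral = dihedral_angle(a11, a22, b22, b11)
    )
  })
  do.call(rbind, out)
}

#' Summarize dimer metrics over a trajectory
#'
#' Arithmetic mean, sample standard deviation, minimum and maximum for each
#' metric of a [frame_metrics()] table.  The dihedral is summarized on its
#' absolute value (the signed per-frame values remain available in the
#' input); the sign convention of a torsion depends on chain-order choices,
#' while its magnitude is what the flexibility comparison uses.
#'
#' @param metrics Data frame from [frame_metrics()] with at least one row.
#' @return A data frame with one row per metric (`d22`, `d11`,
#'   `abs_dihedral`) and columns `metric`, `mean`, `sd`, `min`, `max`,
#'   `n_frames`.
#' @export
trajectory_summary <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1L,
            all(c("d22", "d11", "dihedral") %in% names(metrics)))
  vals <- list(d22 = metrics$d22, d11 = metrics$d11,
               abs_dihedral = abs(metrics$dihedral))
  out <- do.call(rbind, lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    data.frame(metric = nm, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v), n_frames = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Kabsch/orthogonal-Procrustes rigid fit of point set `from` onto `to`
# (rows = points).  Returns rotation (applied on the right: x %*% R),
# translation, and RMSD of the fitted points.
kabsch_fit <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3L, ncol(to) == 3L)
  cf <- colMeans(from)
  ct <- colMeans(to)
  A <- sweep(from, 2, cf)
  B <- sweep(to, 2, ct)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  translation <- ct - as.numeric(cf %*% R)
  fitted <- sweep(from %*% R, 2, translation, "+")
  rmsd <- sqrt(mean(rowSums((fitted - to)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Superpose a dimer onto a reference at the interface
#'
#' Rigid-body least-squares (orthogonal Procrustes / Kabsch) fit of a mobile
#' structure onto a reference over a selection of interface atoms.  The
#' default selection is the backbone (N, CA, C, O) of residues 18 and 20 of
#' both chains -- the residues forming the four intermolecular hydrogen bonds
#' of the alpha-defensin dimer interface.  The fitted transform from the
#' chosen frame is applied to every frame of the mobile structure.
#'
#' @param mobile,reference [dimer_structure()] objects whose numbering maps
#'   resolve the selected residues.
#' @param residues Interface residues in reference numbering (default
#'   `c(18, 20)`).
#' @param atoms Atom names of the selection (default backbone
#'   `c("N", "CA", "C", "O")`).
#' @param frame Frame of each structure used to compute the fit (default 1).
#' @return A list of class `superposition`: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd` over the fit atoms, and `structure` (the transformed
#'   mobile structure).
#' @export
superpose_interface <- function(mobile, reference, residues = c(18L, 20L),
                                atoms = c("N", "CA", "C", "O"), frame = 1L) {
  stopifnot(inherits(mobile, "dimer_structure"),
            inherits(reference, "dimer_structure"))
  im <- select_atoms(mobile, residues, atoms)
  ir <- select_atoms(reference, residues, atoms)
  fit <- kabsch_fit(mobile$xyz[im, , frame], reference$xyz[ir, , frame])
  out <- mobile
  for (f in seq_len(mobile$n_frames)) {
    out$xyz[, , f] <- sweep(mobile$xyz[, , f] %*% fit$rotation, 2,
                            fit$translation, "+")
  }
  structure(
    list(rotation = fit$rotation, translation = fit$translation,
         rmsd = fit$rmsd, structure = out),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("interface superposition: RMSD = %.4g A over fit atoms\n",
              x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to all frames of a structure
#'
#' @param structure A [dimer_structure()].
#' @param rotation 3 x 3 rotation matrix (applied on the right).
#' @param translation Length-3 translation vector.
#' @return The transformed structure.
#' @export
transform_structure <- function(structure, rotation,
                                translation = c(0, 0, 0)) {
  stopifnot(inherits(structure, "dimer_structure"))
  for (f in seq_len(structure$n_frames)) {
    structure$xyz[, , f] <- sweep(structure$xyz[, , f] %*% rotation, 2,
                                  translation, "+")
  }
  structure
}
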