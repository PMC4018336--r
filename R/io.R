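# Readers and writers: FASTA (via Biostrings), fixed-column ATOM/MODEL
# coordinate files (via bio3d), and headered TSV reports.  All coordinates
# in files and reports are 1-based inclusive; undefined statistics print as
# 'NA', never as silent zeros.

#' Read sequences from a FASTA file
#'
#' Ids and record order are preserved; wrapped lines and CRLF endings are
#' accepted; lowercase bases are normalized to uppercase; gap characters are
#' retained for aligned input.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a multi-model coordinate file as a dimer structure
#'
#' Parses fixed-column ATOM records (single- or multi-MODEL) and returns a
#' [dimer_structure()] whose frames are the MODEL blocks in file order.
#'
#' @param path Path to the coordinate file.
#' @param chains Optional length-2 vector mapping chain labels to A and B
#'   (default: first two labels in file order).
#' @param numbering_map Optional named integer vector mapping structure
#'   residue numbers to reference numbering.
#' @return A [dimer_structure()].
#' @export
read_dimer_pdb <- function(path, chains = NULL, numbering_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- pdb$atom$type == "ATOM"
  atoms <- data.frame(
    chain = pdb$atom$chain[sel],
    resno = pdb$atom$resno[sel],
    resname = pdb$atom$resid[sel],
    atom = pdb$atom$elety[sel],
    stringsAsFactors = FALSE
  )
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1L)
  n_frames <- nrow(xyz_mat)
  n_atoms_all <- ncol(xyz_mat) %/% 3L
  keep <- which(sel)
  xyz <- array(NA_real_, dim = c(length(keep), 3L, n_frames))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz_mat[f, ], ncol = 3L, byrow = TRUE)
    xyz[, , f] <- m[keep, , drop = FALSE]
  }
  dimer_structure(atoms, xyz, numbering_map = numbering_map, chains = chains)
}

#' Write a dimer structure as a (multi-)MODEL coordinate file
#'
#' Emits fixed-column ATOM records; structures with more than one frame are
#' wrapped in MODEL/ENDMDL blocks with the frame index as MODEL number.
#'
#' @param structure A [dimer_structure()].
#' @param path Output path.
#' @export
write_dimer_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "dimer_structure"))
  at <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- structure$n_frames > 1L
  serial0 <- 0L
  for (f in seq_len(structure$n_frames)) {
    if (multi) writeLines(sprintf("MODEL %8d", f), con)
    for (i in seq_len(nrow(at))) {
      name <- at$atom[i]
      # PDB atom-name column convention: 1-3 letter names start in column 14
      name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
      writeLines(sprintf(
        "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
        (serial0 + i - 1L) %% 99999L + 1L, name_fmt, "", at$resname[i],
        at$chain[i], at$resno[i], "",
        structure$xyz[i, 1L, f], structure$xyz[i, 2L, f],
        structure$xyz[i, 3L, f], 1, 0), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a pairwise type-I divergence coefficient table
#'
#' Expects a TSV with columns `cluster_i`, `cluster_j`, `theta` and
#' optionally `se` and `lrt` (comment lines starting with `#` are skipped).
#'
#' @param path Path to the TSV file.
#' @return A data frame with the listed columns.
#' @export
read_theta_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("cluster_i", "cluster_j", "theta")
  if (!all(need %in% names(df))) {
    stop("theta table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$theta < 0 | df$theta >= 1)) {
    stop("theta coefficients must lie in [0, 1)")
  }
  df
}

#' Write a data frame as a headered TSV report
#'
#' Every report starts with comment lines recording the package version, the
#' stage name, the full parameter set, and the seed, so that a report is
#' reproducible from its own header.  Undefined values are written as `NA`.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param stage Short stage name recorded in the header.
#' @param params Named list of parameters recorded in the header.
#' @export
write_tsv_report <- function(df, path, stage, params = list()) {
  stopifnot(is.data.frame(df))
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("defevol"))
  writeLines(sprintf("# defevol %s | stage=%s", version, stage), con)
  if (length(params) > 0L) {
    kv <- vapply(names(params), function(k) {
      sprintf("%s=%s", k, paste(format(params[[k]]), collapse = ","))
    }, character(1))
    writeLines(paste0("# ", paste(kv, collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a sliding-window scan as a TSV report
#'
#' Columns, in order: `start`, `end`, `identity_pct`, `avg_Ka`, `avg_Ks`,
#' `avg_KaKs`, `n_pairs_used`, `direction`, `boot_mean`, `boot_sd`,
#' `p_value`.  The header records window size, step, bootstrap replicates
#' and seed.
#'
#' @param scan A `kaks_scan` object from [window_scan()].
#' @param path Output path.
#' @export
write_scan_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "kaks_scan"))
  params <- list(
    window_size = attr(scan, "window_size"),
    window_step = attr(scan, "window_step"),
    replicates = attr(scan, "replicates"),
    seed = attr(scan, "seed") %||% "NA",
    n_sequences = attr(scan, "n_sequences"),
    ratio_method = attr(scan, "ratio_method")
  )
  write_tsv_report(as.data.frame(scan), path, "scan", params)
}

#' Write a functional-divergence fit as TSV reports
#'
#' Writes two files: `<prefix>_dF.tsv` with the pairwise functional
#' distances and residuals, and `<prefix>_bF.tsv` with the per-cluster
#' branch lengths.  Negative branch lengths are annotated in the header.
#'
#' @param fit An `fd_star` fit from [star_branch_lengths()] or [fd_star()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths written.
#' @export
write_divergence_tsv <- function(fit, prefix) {
  stopifnot(inherits(fit, "fd_star"))
  ut <- which(upper.tri(fit$dF), arr.ind = TRUE)
  labels <- rownames(fit$dF)
  pairs <- data.frame(
    cluster_i = labels[ut[, 1]], cluster_j = labels[ut[, 2]],
    dF = fit$dF[ut], fitted = fit$fitted[ut], residual = fit$residuals[ut],
    stringsAsFactors = FALSE
  )
  bf <- data.frame(cluster = names(fit$bF), bF = unname(fit$bF),
                   stringsAsFactors = FALSE)
  params <- list(max_abs_residual = format(fit$max_abs_residual),
                 negative_bF = if (length(fit$negative) > 0L) {
                   paste(fit$negative, collapse = ",")
                 } else "none")
  p1 <- paste0(prefix, "_dF.tsv")
  p2 <- paste0(prefix, "_bF.tsv")
  write_tsv_report(pairs, p1, "divergence", params)
  write_tsv_report(bf, p2, "divergence", params)
  invisible(c(p1, p2))
}
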