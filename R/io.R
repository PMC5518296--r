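# Plain-text persistence for cohorts, designs and connectivity matrices,
# plus a thin adapter for volumetric input.

#' Write / read a cohort as a plain-text directory
#'
#' Layout: `spec.json`, `traits.csv`, `ground_truth.json`, and per
#' subject-session directories `sub-XX/ses-Y/` holding one TSV per ROI
#' (`roi-ZZZ.tsv`, voxels x timepoints), `motion.tsv`, `wm.tsv`, `csf.tsv`
#' and `voxels.tsv` (lattice and mm coordinates with ROI labels).
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(cohort$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"), digits = NA)
  tsv <- function(m, path) utils::write.table(m, path, sep = "\t",
                                              row.names = FALSE, col.names = FALSE)
  for (s in seq_len(spec$n_subjects)) {
    for (k in seq_along(spec$session_lengths)) {
      sd <- file.path(dir, sprintf("sub-%02d", s), sprintf("ses-%d", k))
      dir.create(sd, recursive = TRUE, showWarnings = FALSE)
      ses <- cohort$sessions[[s]][[k]]
      for (r in sort(unique(ses$roi))) {
        tsv(roi_matrix(ses, r), file.path(sd, sprintf("roi-%03d.tsv", r)))
      }
      tsv(ses$motion_params, file.path(sd, "motion.tsv"))
      tsv(ses$wm_pool, file.path(sd, "wm.tsv"))
      tsv(ses$csf_pool, file.path(sd, "csf.tsv"))
      vox <- cbind(ses$ijk, ses$coords, ses$roi)
      colnames(vox) <- c("i", "j", "k", "x_mm", "y_mm", "z_mm", "roi")
      utils::write.table(vox, file.path(sd, "voxels.tsv"), sep = "\t",
                         row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  spec_l <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- do.call(cohort_spec, spec_l[setdiff(names(spec_l), c())])
  traits <- utils::read.csv(file.path(dir, "traits.csv"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  tc <- gt$true_connectivity
  gt$true_connectivity <- lapply(seq_len(spec$n_subjects), function(s) {
    m <- if (is.array(tc) && length(dim(tc)) == 3) tc[s, , ] else tc[[s]]
    if (is.list(m)) m <- do.call(rbind, m)
    as.matrix(m)
  })
  gt$planted_age_effect <- as.matrix(gt$planted_age_effect)
  gt$global_signal_amplitude <- as.matrix(gt$global_signal_amplitude)
  read_tsv <- function(path) as.matrix(utils::read.table(path, sep = "\t"))
  sessions <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sessions[[s]] <- vector("list", length(spec$session_lengths))
    for (k in seq_along(spec$session_lengths)) {
      sd <- file.path(dir, sprintf("sub-%02d", s), sprintf("ses-%d", k))
      vox <- utils::read.table(file.path(sd, "voxels.tsv"), sep = "\t",
                               header = TRUE)
      rois <- sort(unique(vox$roi))
      data <- matrix(0, nrow(vox), spec$session_lengths[k])
      for (r in rois) {
        data[vox$roi == r, ] <- read_tsv(file.path(sd, sprintf("roi-%03d.tsv", r)))
      }
      sessions[[s]][[k]] <- structure(list(
        data = data, roi = vox$roi,
        coords = as.matrix(vox[, c("x_mm", "y_mm", "z_mm")]),
        ijk = as.matrix(vox[, c("i", "j", "k")]),
        motion_params = read_tsv(file.path(sd, "motion.tsv")),
        wm_pool = read_tsv(file.path(sd, "wm.tsv")),
        csf_pool = read_tsv(file.path(sd, "csf.tsv")),
        tr = spec$tr
      ), class = "fc_session")
    }
  }
  structure(list(spec = spec, geometry = NULL, traits = traits,
                 sessions = sessions, ground_truth = gt),
            class = "fc_cohort")
}

#' Export a confound design as TSV
#'
#' @param design a [confound_design()].
#' @param path output file.
#' @export
write_design <- function(design, path) {
  m <- design$matrix
  colnames(m) <- design$labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a connectivity matrix as square TSV with ROI-id header
#'
#' @param conn connectivity matrix.
#' @param path output file.
#' @export
write_connectivity <- function(conn, path) {
  m <- as.matrix(conn)
  colnames(m) <- paste0("roi", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an `fc_session` from volumetric files
#'
#' Thin adapter for user-supplied 4D data: reads a 4D volume and an integer
#' ROI label volume (same grid), extracts labelled voxels, and derives world
#' mm coordinates from the affine (0-based voxel indexing). Optional WM/CSF
#' mask volumes populate the nuisance pools. Requires the RNifti package.
#'
#' @param bold_file 4D NIfTI path.
#' @param label_file 3D integer ROI label volume (0 = background).
#' @param motion_params 6 x timepoints matrix (realignment output).
#' @param wm_file,csf_file optional binary mask volumes.
#' @param tr repetition time in seconds (defaults to the header pixdim).
#' @return an `fc_session`.
#' @export
session_from_nifti <- function(bold_file, label_file, motion_params,
                               wm_file = NULL, csf_file = NULL, tr = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("session_from_nifti requires the RNifti package")
  }
  bold <- RNifti::readNifti(bold_file)
  lab <- RNifti::readNifti(label_file)
  dm <- dim(bold)
  T <- dm[4]
  lab <- as.array(lab)
  vox <- which(lab > 0, arr.ind = TRUE)
  roi <- lab[vox]
  flat <- matrix(as.numeric(bold), prod(dm[1:3]), T)
  lin <- (vox[, 3] - 1) * dm[1] * dm[2] + (vox[, 2] - 1) * dm[1] + vox[, 1]
  data <- flat[lin, , drop = FALSE]
  xf <- RNifti::xform(bold)
  ijk0 <- vox - 1                                  # 0-based indices
  coords <- t(xf %*% rbind(t(ijk0), 1))[, 1:3]
  pool_from <- function(f) {
    if (is.null(f)) return(matrix(0, 0, T))
    m <- as.array(RNifti::readNifti(f))
    idx <- which(m > 0, arr.ind = TRUE)
    lin2 <- (idx[, 3] - 1) * dm[1] * dm[2] + (idx[, 2] - 1) * dm[1] + idx[, 1]
    flat[lin2, , drop = FALSE]
  }
  structure(list(
    data = data, roi = as.integer(roi), coords = coords, ijk = ijk0,
    motion_params = motion_params,
    wm_pool = pool_from(wm_file), csf_pool = pool_from(csf_file),
    tr = tr %||% RNifti::pixdim(bold)[4]
  ), class = "fc_session")
}
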