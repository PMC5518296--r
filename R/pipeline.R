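# End-to-end pipeline runner: smoothing -> confound GLM (+DCT filter) ->
# optional pre-whitening -> connectivity -> group standardization, and the
# evaluation report computed from the result.

#' Run one preprocessing/connectivity pipeline over a cohort
#'
#' Applies, per subject and session: Gaussian smoothing (`fwhm` mm), the
#' chosen confound design with simultaneous DCT filtering, optional per-ROI
#' ReML pre-whitening, and connectivity estimation. Pearson matrices are
#' Fisher z-transformed before group statistics by default; distance
#' correlation is left on its natural scale. Group standardization (mean
#' regression per session, then harmonization of session grand means) is
#' applied when requested.
#'
#' @param cohort an [generate_cohort()] result.
#' @param nuisance `"N"`, `"C"`, `"CW"` or `"CC"`.
#' @param filter `"HP"` or `"BP"` (DCT columns in the GLM).
#' @param prewhiten logical; per-ROI autocorrelation fit and whitening.
#' @param fwhm smoothing kernel FWHM in mm (0 = none).
#' @param method `"pcor"`, `"abs_pcor"` or `"dcor"`.
#' @param mean_regress logical; apply [mean_regression()] per session and
#'   [harmonize_session_means()] across sessions.
#' @param fisher_z logical; z-transform (absolute) Pearson correlations.
#' @param sessions session indices to process (default all).
#' @param autocorr_method `"whittle"` (fast frequency-domain ReML; default
#'   for cohort sweeps) or `"reml"` (covariance-domain Fisher scoring).
#' @param band filter band in Hz.
#' @return object of class `fc_pipeline_result`: list with `conn`
#'   (`[[session]][[subject]]` connectivity matrices), `options`, and the
#'   cohort's traits/geometry references.
#' @export
run_pipeline <- function(cohort, nuisance = "CW", filter = "HP",
                         prewhiten = TRUE, fwhm = 8, method = "pcor",
                         mean_regress = TRUE, fisher_z = TRUE,
                         sessions = seq_along(cohort$spec$session_lengths),
                         autocorr_method = "whittle", band = c(0.008, 0.1)) {
  W <- if (fwhm > 0) smoothing_matrix(cohort$geometry$coords, fwhm) else NULL
  conn <- vector("list", length(sessions))
  names(conn) <- paste0("session", sessions)
  for (si in seq_along(sessions)) {
    k <- sessions[si]
    mats <- vector("list", cohort$spec$n_subjects)
    for (s in seq_len(cohort$spec$n_subjects)) {
      res <- preprocess_session(cohort$sessions[[s]][[k]], W, nuisance, filter,
                                prewhiten, autocorr_method, band)
      m <- switch(method,
        pcor = pearson_connectivity(res),
        abs_pcor = {
          pc <- pearson_connectivity(res)
          new_conn(abs(unclass(pc)), "abs_pcor")
        },
        dcor = dcor_connectivity(res),
        stopf("unknown connectivity method '%s'", method)
      )
      if (fisher_z && method %in% c("pcor", "abs_pcor")) m <- fisher_transform_conn(m)
      attr(m, "subject") <- s
      attr(m, "session") <- k
      mats[[s]] <- m
    }
    conn[[si]] <- mats
  }
  if (mean_regress) {
    conn <- lapply(conn, mean_regression)
    if (length(conn) == 2) {
      h <- harmonize_session_means(conn[[1]], conn[[2]])
      conn[[1]] <- h$session1
      conn[[2]] <- h$session2
    }
  }
  structure(list(
    conn = conn, sessions = sessions,
    options = list(nuisance = nuisance, filter = filter,
                   prewhiten = prewhiten, fwhm = fwhm, method = method,
                   mean_regress = mean_regress, fisher_z = fisher_z,
                   autocorr_method = autocorr_method, band = band)
  ), class = "fc_pipeline_result")
}

preprocess_session <- function(ses, W, nuisance, filter, prewhiten,
                               autocorr_method, band) {
  if (!is.null(W)) ses$data <- W %*% ses$data
  des <- confound_design(ses, nuisance, filter, band)
  res <- fit_glm(ses, des)
  if (prewhiten) {
    for (r in sort(unique(res$roi))) {
      idx <- res$roi == r
      M <- res$data[idx, , drop = FALSE]
      mod <- estimate_autocorr(M, res$tr, method = autocorr_method,
                               whitener = "chol")
      res$data[idx, ] <- M %*% t(mod$whitener)
    }
    res$whitened <- TRUE
  }
  res
}

#' Evaluation report for one pipeline result
#'
#' Computes the evaluation battery from a two-session pipeline result:
#' within-participant reliability (RP: mean per-participant ICC of
#' vectorized matrices across sessions), per-connection reliability averaged
#' over within-/between-network connections (RSW/RSB), reliability of the
#' age effect (RA: ICC between session-wise age-connectivity maps), peer
#' similarity (SP: mean correlation with the average matrix of the
#' nearest-age peers), and the mean absolute (age-adjusted) association of
#' connectivity with vascular health (VH) and head motion (HM). Trait maps
#' and peer similarity use session 1; reliability indices use both sessions.
#'
#' @param result an [run_pipeline()] result covering two sessions.
#' @param cohort the cohort the result came from.
#' @param k_peers age-matched peer count for SP.
#' @param icc_type ICC variant, see [icc()].
#' @return object of class `fc_report`: list of the named indices plus the
#'   per-participant vectors and per-connection maps behind them.
#' @export
evaluate_pipeline <- function(result, cohort, k_peers = 30,
                              icc_type = "agreement") {
  two <- length(result$conn) >= 2
  s1 <- result$conn[[1]]
  ages <- cohort$traits$age
  k_peers <- min(k_peers, length(s1) - 1)
  map1 <- age_effect_map(s1, ages)
  sp <- peer_similarity(s1, ages, k_peers)
  vh <- trait_association_map(s1, cohort$traits$vascular_s1, adjust_for = ages)
  hm <- trait_association_map(s1, cohort$traits$motion_s1, adjust_for = ages)
  out <- list(
    SP = attr(sp, "mean"), VH = vh$mean_abs, HM = hm$mean_abs,
    sp = as.numeric(sp), age_map_s1 = map1, vh_map = vh, hm_map = hm,
    options = result$options
  )
  if (two) {
    s2 <- result$conn[[2]]
    map2 <- age_effect_map(s2, ages)
    rp <- within_participant_reliability(s1, s2, icc_type)
    rs <- per_connection_reliability(s1, s2, cohort$geometry$networks, icc_type)
    out <- c(list(
      RA = age_effect_reliability(map1, map2, icc_type),
      RP = attr(rp, "mean"), RSW = rs$rsw, RSB = rs$rsb,
      rp = as.numeric(rp), rs = rs, age_map_s2 = map2
    ), out)
  }
  structure(out, class = "fc_report")
}

#' @export
print.fc_report <- function(x, ...) {
  keys <- intersect(c("RA", "RP", "SP", "RSW", "RSB", "VH", "HM"), names(x))
  vals <- vapply(keys, function(k) x[[k]], 0)
  cat("pipeline evaluation:\n")
  print(round(vals, 3))
  invisible(x)
}

#' Run a grid of pipeline options and tabulate the evaluation indices
#'
#' Runs [run_pipeline()] + [evaluate_pipeline()] for every row of an option
#' grid and assembles the indices into a metrics-by-options table. When
#' `out_dir` is given the table is written as `report.csv` (and each
#' option's per-connection maps as a JSON file), which is byte-reproducible
#' for a fixed cohort.
#'
#' @param cohort an [generate_cohort()] result.
#' @param grid data frame with columns among `nuisance`, `filter`,
#'   `prewhiten`, `fwhm`, `method`, `mean_regress` (missing columns take the
#'   [run_pipeline()] defaults); an optional `name` column labels the
#'   output columns.
#' @param out_dir optional output directory.
#' @param k_peers peer count for the SP index.
#' @param autocorr_method passed to [run_pipeline()].
#' @param write_maps also write each option's per-connection maps as JSON.
#' @return data frame, rows = indices (RA, RP, SP, RSW, RSB, VH, HM),
#'   columns = grid options.
#' @export
run_grid <- function(cohort, grid, out_dir = NULL, k_peers = 30,
                     autocorr_method = "whittle", write_maps = FALSE) {
  defaults <- list(nuisance = "CW", filter = "HP", prewhiten = TRUE,
                   fwhm = 8, method = "pcor", mean_regress = TRUE)
  keys <- c("RA", "RP", "SP", "RSW", "RSB", "VH", "HM")
  tab <- matrix(NA_real_, length(keys), nrow(grid),
                dimnames = list(keys, NULL))
  labels <- character(nrow(grid))
  reports <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    opt <- defaults
    for (nm in intersect(names(defaults), names(grid))) {
      v <- grid[[nm]][i]
      if (!is.na(v)) opt[[nm]] <- v
    }
    labels[i] <- if ("name" %in% names(grid)) as.character(grid$name[i]) else {
      paste0(opt$nuisance, "_", opt$filter, if (opt$prewhiten) "PW" else "",
             "_S", opt$fwhm, "_", opt$method, if (opt$mean_regress) "_MR" else "")
    }
    res <- run_pipeline(cohort, nuisance = opt$nuisance, filter = opt$filter,
                        prewhiten = opt$prewhiten, fwhm = opt$fwhm,
                        method = opt$method, mean_regress = opt$mean_regress,
                        autocorr_method = autocorr_method)
    rep <- evaluate_pipeline(res, cohort, k_peers)
    reports[[i]] <- rep
    for (k in keys) tab[k, i] <- rep[[k]] %||% NA_real_
  }
  colnames(tab) <- labels
  df <- data.frame(metric = keys, tab, check.names = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(out_dir, "report.csv"), row.names = FALSE)
    if (write_maps) for (i in seq_len(nrow(grid))) {
      maps <- list(age_map_s1 = unclass(reports[[i]]$age_map_s1),
                   vh_map = reports[[i]]$vh_map$map,
                   hm_map = reports[[i]]$hm_map$map)
      jsonlite::write_json(maps, file.path(out_dir, paste0(labels[i], ".json")),
                           digits = NA)
    }
  }
  df
}
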