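# Replicate-cohort battery backing the directional acceptance checks.
# Built once per test run (memoised); each cohort uses the evaluation-scale
# conditions: 60 subjects, 40 ROIs x 12 voxels, sessions of 150 and 100
# volumes at TR 1.97 s, default planted effects.

battery_cohort_spec <- function(seed) {
  cohort_spec(session_lengths = c(150, 100), seed = seed)
}

# all quantities the directional criteria need, for one cohort
battery_one <- function(seed) {
  co <- generate_cohort(battery_cohort_spec(seed))
  ages <- co$traits$age

  # vascular confound under motion-only nuisance regression (the condition
  # where residual physiological signal is largest), with vs without MR
  vn <- run_pipeline(co, nuisance = "N", filter = "HP", prewhiten = FALSE,
                     fwhm = 8, method = "pcor", mean_regress = FALSE,
                     sessions = 1)
  vn_mr <- mean_regression(vn$conn[[1]])
  mean_conn <- vapply(vn$conn[[1]], function(m) attr(m, "mean_connectivity"), 0)
  vh_detect_p <- stats::cor.test(mean_conn, co$traits$vascular_s1)$p.value
  vh_nomr <- trait_association_map(vn$conn[[1]], co$traits$vascular_s1,
                                   adjust_for = ages)$mean_abs
  vh_mr <- trait_association_map(vn_mr, co$traits$vascular_s1,
                                 adjust_for = ages)$mean_abs

  # CW + HP + prewhitening + 8 mm, Pearson, MR + session harmonization
  raw <- run_pipeline(co, nuisance = "CW", filter = "HP", prewhiten = TRUE,
                      fwhm = 8, method = "pcor", mean_regress = FALSE)
  mr <- lapply(raw$conn, mean_regression)
  h <- harmonize_session_means(mr[[1]], mr[[2]])
  mr <- list(h$session1, h$session2)
  rp_hppw <- attr(within_participant_reliability(mr[[1]], mr[[2]]), "mean")

  # band-pass comparison (no pre-whitening, as analyzed)
  bp <- run_pipeline(co, nuisance = "CW", filter = "BP", prewhiten = FALSE,
                     fwhm = 8, method = "pcor", mean_regress = TRUE)
  rp_bp <- attr(within_participant_reliability(bp$conn[[1]], bp$conn[[2]]), "mean")

  # smoothing contrast for the age-effect strength (high-pass, session 1)
  s0 <- run_pipeline(co, nuisance = "CW", filter = "HP", prewhiten = FALSE,
                     fwhm = 0, method = "pcor", mean_regress = TRUE,
                     sessions = 1)
  s8 <- run_pipeline(co, nuisance = "CW", filter = "HP", prewhiten = FALSE,
                     fwhm = 8, method = "pcor", mean_regress = TRUE,
                     sessions = 1)
  age_s0 <- mean(abs(age_effect_map(s0$conn[[1]], ages)[upper.tri(diag(40))]))
  age_s8 <- mean(abs(age_effect_map(s8$conn[[1]], ages)[upper.tri(diag(40))]))

  # participant-specific parcellations (6 mm, CW, band-pass residuals)
  W6 <- fcsweep:::smoothing_matrix(co$geometry$coords, 6)
  parcs <- lapply(seq_len(co$spec$n_subjects), function(s) {
    ses <- co$sessions[[s]][[1]]
    ses$data <- W6 %*% ses$data
    res <- fit_glm(ses, confound_design(ses, "CW", "BP"))
    g <- neighbor_graph(res$data, res$ijk, 0.5)
    ncut_cluster(g, co$spec$n_rois, seed = seed * 1000 + s)
  })
  parc_age_r <- cor(parcellation_peer_nmi(parcs, ages, k = 30), ages)

  c(vh_detect_p = vh_detect_p, vh_nomr = vh_nomr, vh_mr = vh_mr,
    rp_hppw = rp_hppw, rp_bp = rp_bp, age_s0 = age_s0, age_s8 = age_s8,
    parc_age_r = parc_age_r)
}

acceptance_battery <- function(n_cohorts = 20) {
  memo("acceptance_battery", {
    t(vapply(seq_len(n_cohorts), function(i) battery_one(400 + i), numeric(8)))
  })
}
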