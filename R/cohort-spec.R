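#' Specification of a synthetic resting-state cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. The defaults
#' emulate the acquisition and population structure of a two-session,
#' adult-lifespan resting-state study: two sessions of unequal length
#' (261 and 152 volumes at TR 1.97 s), ages uniform on 18--88, a
#' "vascular health" trait that declines with age (target r = -0.50) and
#' drives the amplitude of a global physiological signal, a head-motion
#' trait that increases with age (target r = +0.50) and is reliable across
#' sessions (target r = 0.77), per-voxel AR(1) autocorrelation that
#' declines with age (lag-1 about 0.32 at the mid-age of the range), and an
#' age-increasing idiosyncratic shift of functional-region boundaries.
#'
#' @param n_subjects number of participants.
#' @param age_range min/max age in years; ages are sampled uniformly.
#' @param n_rois number of regions of interest (lattice blocks).
#' @param n_networks number of functional networks the ROIs are grouped into.
#' @param voxels_per_roi voxels in each ROI block (must factor into a 3D box).
#' @param lattice_spacing voxel spacing in mm.
#' @param session_lengths integer vector of volumes per session.
#' @param tr repetition time in seconds.
#' @param global_signal_gain baseline amplitude of the shared physiological
#'   signal; per subject-session amplitude is
#'   `global_signal_gain * exp(0.35 * vascular_health)`, so better vascular
#'   health means a stronger global signal and higher raw connectivity.
#'   `0` disables the global signal.
#' @param vascular_age_corr target correlation between age and vascular health.
#' @param motion_age_corr target correlation between age and trait motion.
#' @param trait_reliability target across-session correlation of the
#'   session-specific vascular and motion traits.
#' @param lag1_young,lag1_slope per-voxel AR(1) coefficient model:
#'   `rho(age) = lag1_young + lag1_slope * (age - age_range[1])`.
#' @param misalignment_scale_per_year mm of functional-boundary displacement
#'   per year of age; `0` disables boundary misalignment.
#' @param spike_rate baseline fraction of volumes carrying a motion-locked
#'   artefact spike for a subject with reference trait motion (0.15 mm);
#'   the per-subject fraction scales with trait motion.
#' @param network_coupling,between_coupling population within- and
#'   between-network ROI-latent correlations at the mid age of `age_range`.
#' @param voxel_homogeneity variance share of a voxel signal carried by its
#'   ROI latent (sets within-ROI homogeneity away from boundaries).
#' @param effect_map optional `n_rois x n_rois` symmetric matrix of
#'   per-connection age slopes (correlation units per year) planted on the
#'   true ROI-latent correlation. Default: within-network connectivity
#'   declines by 0.002/yr, between-network connectivity rises by 0.0004/yr.
#' @param n_wm_voxels,n_csf_voxels sizes of the white-matter and CSF
#'   nuisance-voxel pools.
#' @param seed RNG seed; cohorts are bit-reproducible given an identical specification.
#'
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 60,
                        age_range = c(18, 88),
                        n_rois = 40,
                        n_networks = 16,
                        voxels_per_roi = 12,
                        lattice_spacing = 3,
                        session_lengths = c(261, 152),
                        tr = 1.97,
                        global_signal_gain = 0.7,
                        vascular_age_corr = -0.50,
                        motion_age_corr = 0.50,
                        trait_reliability = 0.77,
                        lag1_young = 0.45,
                        lag1_slope = -0.0037,
                        misalignment_scale_per_year = 0.02,
                        spike_rate = 0.03,
                        network_coupling = 0.45,
                        between_coupling = 0.10,
                        voxel_homogeneity = 0.5,
                        effect_map = NULL,
                        n_wm_voxels = 30,
                        n_csf_voxels = 30,
                        seed = 1) {
  spec <- list(
    n_subjects = as.integer(n_subjects), age_range = as.numeric(age_range),
    n_rois = as.integer(n_rois), n_networks = as.integer(n_networks),
    voxels_per_roi = as.integer(voxels_per_roi),
    lattice_spacing = lattice_spacing,
    session_lengths = as.integer(session_lengths), tr = tr,
    global_signal_gain = global_signal_gain,
    vascular_age_corr = vascular_age_corr,
    motion_age_corr = motion_age_corr,
    trait_reliability = trait_reliability,
    lag1_young = lag1_young, lag1_slope = lag1_slope,
    misalignment_scale_per_year = misalignment_scale_per_year,
    spike_rate = spike_rate,
    network_coupling = network_coupling,
    between_coupling = between_coupling,
    voxel_homogeneity = voxel_homogeneity,
    effect_map = effect_map,
    n_wm_voxels = as.integer(n_wm_voxels),
    n_csf_voxels = as.integer(n_csf_voxels),
    seed = as.integer(seed)
  )
  validate_cohort_spec(structure(spec, class = "cohort_spec"))
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 2) stopf("n_subjects must be >= 2")
  if (any(spec$session_lengths <= 4)) {
    stopf("all session_lengths must exceed 4 (distance correlation needs more than 3 timepoints)")
  }
  if (spec$n_rois < spec$n_networks) {
    stopf("n_rois (%d) must be >= n_networks (%d)", spec$n_rois, spec$n_networks)
  }
  if (spec$voxels_per_roi < 2) stopf("every ROI needs at least 2 voxels")
  for (nm in c("vascular_age_corr", "motion_age_corr", "trait_reliability")) {
    if (abs(spec[[nm]]) >= 1) stopf("%s must lie in (-1, 1)", nm)
  }
  rng <- spec$age_range
  if (length(rng) != 2 || rng[1] >= rng[2]) stopf("age_range must be an increasing pair")
  rho <- spec$lag1_young + spec$lag1_slope * (rng - rng[1])
  if (any(abs(rho) >= 1)) stopf("lag-1 model leaves (-1, 1) over the age range")
  if (!is.null(spec$effect_map)) {
    em <- spec$effect_map
    if (!is.matrix(em) || nrow(em) != spec$n_rois || ncol(em) != spec$n_rois ||
        max(abs(em - t(em))) > 1e-12) {
      stopf("effect_map must be a symmetric n_rois x n_rois matrix")
    }
  }
  if (spec$misalignment_scale_per_year < 0) stopf("misalignment_scale_per_year must be >= 0")
  if (spec$global_signal_gain < 0) stopf("global_signal_gain must be >= 0")
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "cohort_spec: %d subjects, %d ROIs x %d voxels (%d networks), sessions [%s] @ TR %.3gs, seed %d\n",
    x$n_subjects, x$n_rois, x$voxels_per_roi, x$n_networks,
    paste(x$session_lengths, collapse = ", "), x$tr, x$seed
  ))
  invisible(x)
}

# Default planted age-effect map: within-network decline, slight
# between-network increase (correlation units per year of age).
default_effect_map <- function(networks) {
  same <- outer(networks, networks, "==")
  em <- ifelse(same, -0.002, 0.0004)
  diag(em) <- 0
  em
}
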