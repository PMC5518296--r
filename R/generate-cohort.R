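#' Generate a synthetic two-session resting-state cohort
#'
#' Simulates, for every participant and session, ROI-voxel timeseries on a
#' 3D lattice together with six motion-parameter channels and white-matter /
#' CSF nuisance-voxel pools. The generative model plants the population
#' structure the evaluation battery is designed to detect:
#'
#' * ROI latents follow a stationary AR(1) process whose cross-sectional
#'   correlation is the participant's true connectivity matrix
#'   (network block structure plus a per-connection age slope);
#' * a shared "global physiological" signal is added to every ROI voxel and
#'   every nuisance-pool voxel, with an amplitude that increases with the
#'   participant's session-specific vascular-health trait (itself negatively
#'   correlated with age);
#' * heavy-tailed artefact spikes are added at timepoints where the simulated
#'   head displacement exceeds a quantile of its own trace; spike amplitude
#'   and frequency scale with a trait-motion score that is positively
#'   correlated with age and reliable across sessions;
#' * the per-voxel AR(1) coefficient declines linearly with age;
#' * each participant carries a smooth random boundary-displacement field with
#'   magnitude proportional to age: voxels at ROI boundaries mix the latent
#'   of the neighboring ROI in proportion to the displacement, emulating
#'   idiosyncratic misalignment of functional regions in older adults.
#'
#' Session 2 regenerates all noise but reuses the participant's true
#' connectivity, misalignment field and artefact spatial pattern, giving
#' nonzero test-retest reliability by construction.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `fc_cohort`: list with elements `spec`,
#'   `geometry` (voxel coordinates, ROI and network labels, ROI adjacency),
#'   `traits` (one row per participant: age, session-specific vascular and
#'   motion traits, achieved spike percentages), `sessions` (list indexed
#'   `[[subject]][[session]]` of `fc_session` objects) and `ground_truth`
#'   (per-subject true connectivity, the planted age-effect map, per
#'   subject-session global-signal amplitudes, per-subject misalignment
#'   fields).
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  with_seed(spec$seed, {
    geom <- build_geometry(spec)
    traits <- sample_traits(spec)
    n <- spec$n_subjects
    mid_age <- mean(spec$age_range)
    em <- spec$effect_map %||% default_effect_map(geom$networks)

    C0 <- base_connectivity(geom$networks, spec$network_coupling, spec$between_coupling)
    amp <- matrix(0, n, 2)
    true_conn <- vector("list", n)
    misalign <- vector("list", n)
    sessions <- vector("list", n)
    spike_pct <- matrix(0, n, 2)

    for (s in seq_len(n)) {
      age <- traits$age[s]
      Cs <- nearest_corr(C0 + (age - mid_age) * em)
      true_conn[[s]] <- Cs
      mis <- misalignment_field(spec, geom, age)
      misalign[[s]] <- mis
      mix <- mixing_matrix(geom, mis, Cs)
      # artefact spatial pattern is a stable property of the head/coil setup
      spat <- 1 + 0.3 * stats::rnorm(geom$n_vox)
      rho <- spec$lag1_young + spec$lag1_slope * (age - spec$age_range[1])
      subj_sessions <- vector("list", length(spec$session_lengths))
      for (k in seq_along(spec$session_lengths)) {
        vh <- traits[[paste0("vascular_s", k)]][s]
        mo <- traits[[paste0("motion_s", k)]][s]
        a <- if (spec$global_signal_gain > 0) spec$global_signal_gain * exp(0.35 * vh) else 0
        amp[s, k] <- a
        ses <- simulate_session(spec, geom, Cs, mix, rho, a, mo, spat,
                                T = spec$session_lengths[k])
        spike_pct[s, k] <- ses$spike_fraction
        subj_sessions[[k]] <- ses
      }
      sessions[[s]] <- subj_sessions
    }
    traits$spike_pct_s1 <- spike_pct[, 1]
    traits$spike_pct_s2 <- spike_pct[, 2]

    structure(list(
      spec = spec, geometry = geom, traits = traits, sessions = sessions,
      ground_truth = list(
        true_connectivity = true_conn,
        planted_age_effect = em,
        global_signal_amplitude = amp,
        misalignment_field = misalign
      )
    ), class = "fc_cohort")
  })
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf(
    "fc_cohort: %d subjects x %d sessions, %d ROIs x %d voxels, ages %.0f-%.0f\n",
    x$spec$n_subjects, length(x$spec$session_lengths), x$spec$n_rois,
    x$spec$voxels_per_roi, min(x$traits$age), max(x$traits$age)
  ))
  invisible(x)
}

#' Extract one ROI's voxels-by-timepoints matrix from a session
#' @param session an `fc_session`.
#' @param r ROI index.
#' @return numeric matrix, voxels x timepoints.
#' @export
roi_matrix <- function(session, r) session$data[session$roi == r, , drop = FALSE]

# ---- geometry -------------------------------------------------------------

# split n into three near-equal integer factors (nx >= ny >= nz)
factor3 <- function(n) {
  best <- c(n, 1, 1)
  for (a in seq_len(floor(n^(1 / 3)) + 1)) {
    if (n %% a != 0) next
    m <- n / a
    for (b in a:floor(sqrt(m) + 1)) {
      if (m %% b != 0) next
      dims <- sort(c(a, b, m / b), decreasing = TRUE)
      if (max(dims) < max(best)) best <- dims
    }
  }
  as.integer(best)
}

# smallest near-cubic grid holding at least n cells
grid3 <- function(n) {
  g <- c(1L, 1L, 1L)
  while (prod(g) < n) g[which.min(g)] <- g[which.min(g)] + 1L
  g
}

build_geometry <- function(spec) {
  R <- spec$n_rois
  bdim <- factor3(spec$voxels_per_roi)        # voxels per ROI block
  gdim <- grid3(R)                            # ROI blocks per axis
  roi_pos <- arrayInd(seq_len(R), gdim)       # block grid coordinates
  off <- as.matrix(expand.grid(x = seq_len(bdim[1]), y = seq_len(bdim[2]),
                               z = seq_len(bdim[3])))
  V <- spec$voxels_per_roi
  ijk <- matrix(0L, R * V, 3)
  roi <- rep(seq_len(R), each = V)
  for (r in seq_len(R)) {
    origin <- (roi_pos[r, ] - 1L) * bdim
    ijk[roi == r, ] <- sweep(off, 2, origin, "+")
  }
  coords <- ijk * spec$lattice_spacing
  # ROI adjacency: blocks touching along a grid axis
  adj <- abs(outer(roi_pos[, 1], roi_pos[, 1], "-")) +
    abs(outer(roi_pos[, 2], roi_pos[, 2], "-")) +
    abs(outer(roi_pos[, 3], roi_pos[, 3], "-")) == 1
  # contiguous network assignment (near-equal chunk sizes)
  cuts <- round(seq(0, R, length.out = spec$n_networks + 1))
  networks <- rep(seq_len(spec$n_networks), times = diff(cuts))
  # per-voxel foreign ROIs across a face (6-neighborhood)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
  lut <- stats::setNames(roi, key)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  boundary_nbs <- vector("list", R * V)
  for (v in seq_len(R * V)) {
    hits <- NULL
    for (h in seq_len(6)) {
      p <- ijk[v, ] + shifts[h, ]
      hit <- lut[paste(p[1], p[2], p[3], sep = ",")]
      if (!is.na(hit) && hit != roi[v]) {
        hits <- rbind(hits, c(hit, shifts[h, ]))
      }
    }
    boundary_nbs[v] <- list(hits)   # keep NULL entries for interior voxels
  }
  list(n_vox = R * V, ijk = ijk, coords = coords, roi = roi,
       networks = networks, roi_adjacency = adj, roi_grid = roi_pos,
       boundary_nbs = boundary_nbs, block_dim = bdim)
}

base_connectivity <- function(networks, within, between) {
  same <- outer(networks, networks, "==")
  C <- ifelse(same, within, between)
  diag(C) <- 1
  C
}

# clamp eigenvalues and restore unit diagonal
nearest_corr <- function(C, eps = 1e-4) {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) >= eps) return(C)
  v <- pmax(e$values, eps)
  C2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(C2))
  C2 / tcrossprod(d)
}

# ---- traits ---------------------------------------------------------------

# Gaussian copula over (age, vascular s1/s2, motion s1/s2). The latent
# normal correlations are inflated to undo the attenuation caused by the
# uniform (age) and lognormal (motion, sdlog s) margins, so the planted
# Pearson targets hold on the observed scale:
#   normal-uniform:    r_obs = r_lat * sqrt(3/pi)
#   normal-lognormal:  r_obs = r_lat * s / sqrt(exp(s^2) - 1)
#   lognormal pair:    r_obs = (exp(r_lat s^2) - 1) / (exp(s^2) - 1)
sample_traits <- function(spec) {
  s <- 0.4                                  # motion lognormal sdlog
  a_u <- sqrt(3 / pi)                       # uniform-margin attenuation
  a_l <- s / sqrt(expm1(s^2))               # lognormal-margin attenuation
  va <- spec$vascular_age_corr / a_u
  ma <- spec$motion_age_corr / (a_u * a_l)
  rl_v <- spec$trait_reliability
  rl_m <- log1p(spec$trait_reliability * expm1(s^2)) / s^2
  cross <- spec$vascular_age_corr * spec$motion_age_corr / a_l
  if (max(abs(c(va, ma))) >= 1) {
    stopf("infeasible targets: |%s| too large for the trait margins",
          if (abs(va) >= 1) "vascular_age_corr" else "motion_age_corr")
  }
  if (1 + rl_v < 2 * va^2) {
    stopf("infeasible targets: vascular_age_corr = %.2f with trait_reliability = %.2f is not positive semi-definite", spec$vascular_age_corr, spec$trait_reliability)
  }
  if (1 + rl_m < 2 * ma^2) {
    stopf("infeasible targets: motion_age_corr = %.2f with trait_reliability = %.2f is not positive semi-definite", spec$motion_age_corr, spec$trait_reliability)
  }
  S <- diag(5)
  S[1, 2:3] <- S[2:3, 1] <- va
  S[1, 4:5] <- S[4:5, 1] <- ma
  S[2, 3] <- S[3, 2] <- rl_v
  S[4, 5] <- S[5, 4] <- rl_m
  S[2:3, 4:5] <- S[4:5, 2:3] <- cross      # traits linked only through age
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stopf("infeasible targets: joint trait correlation matrix is not positive semi-definite (check vascular_age_corr/motion_age_corr against trait_reliability)")
  }
  L <- chol(S + diag(1e-10, 5))
  Z <- matrix(stats::rnorm(spec$n_subjects * 5), spec$n_subjects, 5) %*% L
  data.frame(
    subject = seq_len(spec$n_subjects),
    age = stats::qunif(stats::pnorm(Z[, 1]), spec$age_range[1], spec$age_range[2]),
    vascular_s1 = Z[, 2], vascular_s2 = Z[, 3],
    motion_s1 = exp(log(0.15) + s * Z[, 4]),
    motion_s2 = exp(log(0.15) + s * Z[, 5])
  )
}

# ---- misalignment ---------------------------------------------------------

# per-ROI displacement vectors (mm), spatially smoothed over the block grid,
# magnitude proportional to age
misalignment_field <- function(spec, geom, age) {
  mag <- spec$misalignment_scale_per_year * (age - spec$age_range[1])
  Z <- matrix(stats::rnorm(spec$n_rois * 3), spec$n_rois, 3)
  if (mag == 0) return(Z * 0)
  W <- exp(-as.matrix(stats::dist(geom$roi_grid))^2 / 2)
  W <- W / rowSums(W)
  D <- W %*% Z
  nrm <- sqrt(rowSums(D^2))
  D / mean(nrm) * mag
}

# voxel x ROI latent mixing matrix: boundary voxels take a convex mixture of
# their own and the adjacent ROI's latent, weight set by the displacement
# component toward that neighbor; rows normalized to unit latent variance
mixing_matrix <- function(geom, field, Cs) {
  n_vox <- geom$n_vox
  M <- matrix(0, n_vox, nrow(Cs))
  M[cbind(seq_len(n_vox), geom$roi)] <- 1
  for (v in seq_len(n_vox)) {
    nbs <- geom$boundary_nbs[[v]]
    if (is.null(nbs)) next
    own <- geom$roi[v]
    # mix toward the foreign neighbor best aligned with the displacement
    projs <- as.vector(nbs[, 2:4, drop = FALSE] %*% field[own, ])
    b <- which.max(projs)
    w <- min(max(projs[b], 0) / 3, 0.5)   # one lattice spacing => half mixture
    if (w == 0) next
    nb <- nbs[b, 1]
    c_on <- Cs[own, nb]
    nrm <- sqrt((1 - w)^2 + w^2 + 2 * w * (1 - w) * c_on)
    M[v, own] <- (1 - w) / nrm
    M[v, nb] <- w / nrm
  }
  M
}

# ---- session simulation ---------------------------------------------------

# stationary AR(1) series (rows = channels) with innovation covariance
# chol_cov' z, marginal covariance equal to chol_cov' chol_cov
ar1_series <- function(chol_cov, rho, T) {
  k <- ncol(chol_cov)
  E <- crossprod(chol_cov, matrix(stats::rnorm(k * T), k, T))
  X <- E
  if (rho != 0) {
    sc <- sqrt(1 - rho^2)
    for (t in 2:T) X[, t] <- rho * X[, t - 1] + sc * E[, t]
  }
  X
}

ar1_noise <- function(n, T, rho) {
  E <- matrix(stats::rnorm(n * T), n, T)
  if (rho == 0) return(E)
  X <- E
  sc <- sqrt(1 - rho^2)
  for (t in 2:T) X[, t] <- rho * X[, t - 1] + sc * E[, t]
  X
}

simulate_session <- function(spec, geom, Cs, mix, rho, amp, motion, spat, T) {
  h <- spec$voxel_homogeneity
  # motion channels: random walk with occasional large events
  n_events <- if (spec$spike_rate == 0) 0L else {
    f_spike <- min(max(spec$spike_rate * motion / 0.15, 0.004), 0.12)
    max(1L, round(f_spike * T))
  }
  innov <- matrix(stats::rnorm(6 * T, sd = 0.02 * motion / 0.15), 6, T)
  if (n_events > 0) {
    events <- sample(2:T, n_events)
    innov[, events] <- innov[, events] * 8
  }
  mp <- t(apply(innov, 1, cumsum))
  disp <- c(0, sqrt(rowMeans(diff(t(mp))^2)))
  # spikes: timepoints where displacement exceeds the (1 - f) quantile
  spikes <- integer(0)
  if (n_events > 0) {
    thr <- stats::quantile(disp, 1 - n_events / T, names = FALSE)
    spikes <- which(disp > thr)
  }
  # latent signals
  L <- ar1_series(chol(Cs), rho, T)
  g <- as.vector(ar1_noise(1, T, 0.85))
  vox_noise <- ar1_noise(geom$n_vox, T, rho)
  X <- sqrt(h) * (mix %*% L) + sqrt(1 - h) * vox_noise
  if (amp > 0) X <- X + amp * matrix(g, geom$n_vox, T, byrow = TRUE)
  art <- numeric(T)
  if (length(spikes)) {
    amp_spike <- 1.2 * motion / 0.15
    art[spikes] <- amp_spike * stats::rt(length(spikes), df = 3)
    X <- X + outer(spat, art)
  }
  pool <- function(n) {
    P <- ar1_noise(n, T, 0.3)
    if (amp > 0) P <- P + amp * matrix(g, n, T, byrow = TRUE)
    if (length(spikes)) P <- P + outer(1 + 0.3 * stats::rnorm(n), 0.5 * art)
    P
  }
  structure(list(
    data = X, roi = geom$roi, coords = geom$coords, ijk = geom$ijk,
    motion_params = mp, wm_pool = pool(spec$n_wm_voxels),
    csf_pool = pool(spec$n_csf_voxels), tr = spec$tr,
    spike_times = spikes, spike_fraction = 100 * length(spikes) / T,
    global_signal = g
  ), class = "fc_session")
}

# ---- smoothing ------------------------------------------------------------

#' Gaussian spatial smoothing of a session's voxel timeseries
#'
#' Applies a volumetric Gaussian kernel with the stated full width at half
#' maximum over voxel positions. Smoothing crosses ROI boundaries, as in
#' whole-volume smoothing before ROI extraction. Kernel rows are normalized
#' so a spatially constant field is preserved exactly; `fwhm = 0` is the
#' identity. Nuisance pools are not smoothed (they are extracted from
#' separate masks before smoothing).
#'
#' @param session an `fc_session`.
#' @param fwhm kernel full width at half maximum in mm.
#' @return the session with smoothed `data`.
#' @export
smooth_voxels <- function(session, fwhm) {
  if (fwhm < 0) stopf("fwhm must be >= 0")
  if (fwhm == 0) return(session)
  W <- smoothing_matrix(session$coords, fwhm)
  session$data <- W %*% session$data
  session
}

# row-normalized truncated Gaussian kernel over mm coordinates
smoothing_matrix <- function(coords, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  D2 <- as.matrix(stats::dist(coords))^2
  W <- exp(-D2 / (2 * sigma^2))
  W[D2 > (3.5 * sigma)^2] <- 0   # truncate negligible tails
  W / rowSums(W)
}

# ---- exclusion ------------------------------------------------------------

#' Spike-based subject exclusion rule
#'
#' Flags subjects whose average artefact-spike percentage in either session
#' exceeds the mean plus two standard deviations of the pooled two-session
#' distribution (strict inequality; with zero spread nobody is excluded).
#' This emulates a despiking-based exclusion step; the generator's artefact
#' channel provides the spike percentages.
#'
#' @param spike_pct numeric matrix, subjects x sessions, of spike percentages.
#' @return integer vector of retained subject indices, with the threshold in
#'   attribute `"threshold"` and the excluded indices in `"excluded"`.
#' @export
exclude_high_spike <- function(spike_pct) {
  spike_pct <- as.matrix(spike_pct)
  if (nrow(spike_pct) < 3) stopf("need at least 3 subjects to define the exclusion threshold")
  pooled <- as.vector(spike_pct)
  thr <- mean(pooled) + 2 * stats::sd(pooled)
  out <- which(apply(spike_pct, 1, max) > thr)
  keep <- setdiff(seq_len(nrow(spike_pct)), out)
  structure(keep, threshold = thr, excluded = out)
}
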