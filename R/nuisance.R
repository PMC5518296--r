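# Confound designs: motion expansions, DCT filter columns, CompCor
# components, and simultaneous nuisance regression via a voxelwise GLM.

#' Volterra-style expansion of motion parameters
#'
#' Expands six rigid-body motion channels into 24 regressors: each parameter,
#' its backward temporal difference (first element zero), its square, and the
#' squared difference.
#'
#' @param motion_params numeric matrix, 6 x timepoints.
#' @return numeric matrix, 24 x timepoints, rows ordered
#'   `p1, dp1, p1^2, dp1^2, p2, ...`, with rownames.
#' @export
motion_expansion <- function(motion_params) {
  if (!is.matrix(motion_params) || nrow(motion_params) != 6) {
    stopf("motion_params must be a 6 x T matrix")
  }
  T <- ncol(motion_params)
  if (T < 3) stopf("need at least 3 timepoints")
  out <- matrix(0, 24, T)
  labs <- character(24)
  for (p in seq_len(6)) {
    x <- motion_params[p, ]
    d <- c(0, diff(x))
    i <- (p - 1) * 4
    out[i + 1, ] <- x
    out[i + 2, ] <- d
    out[i + 3, ] <- x^2
    out[i + 4, ] <- d^2
    labs[i + 1:4] <- paste0("mp", p, c("", "_d", "_sq", "_dsq"))
  }
  rownames(out) <- labs
  out
}

#' Discrete cosine transform filter columns
#'
#' Returns the orthonormal DCT-II columns that a GLM regresses out to
#' implement filtering. Column `k` has frequency `k / (2 * T * tr)` Hz. In
#' `highpass` mode the columns at frequencies at or below `band[1]` are
#' returned (removing slow drifts), i.e. `K = floor(2 * T * tr * band[1])`
#' columns. In `bandpass` mode the union of those drift columns and all
#' columns above `band[2]` is returned, so regressing them out retains only
#' the passband.
#'
#' @param T number of timepoints (at least 8).
#' @param tr repetition time in seconds.
#' @param band numeric pair `(f_low, f_high)` in Hz; only `band[1]` is used
#'   in `highpass` mode.
#' @param mode `"highpass"` or `"bandpass"`.
#' @return numeric matrix, T x K, orthonormal columns labelled by DCT order.
#' @export
dct_basis <- function(T, tr, band = c(0.008, 0.1), mode = c("highpass", "bandpass")) {
  mode <- match.arg(mode)
  if (T < 8) stopf("T must be >= 8")
  nyq <- 1 / (2 * tr)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stopf("need 0 < f_low < f_high < Nyquist (%.4g Hz)", nyq)
  }
  k_low <- floor(2 * T * tr * band[1])
  ks <- seq_len(k_low)
  if (mode == "bandpass") {
    k_high <- floor(2 * T * tr * band[2])
    ks <- c(ks, seq.int(k_high + 1, T - 1))
  }
  ks <- ks[ks >= 1 & ks <= T - 1]
  if (length(ks) == 0) {
    warnf("cutoff below the first DCT frequency: empty filter basis")
    return(matrix(0, T, 0))
  }
  t <- seq_len(T)
  B <- sqrt(2 / T) * cos(pi * outer(2 * t - 1, ks) / (2 * T))
  colnames(B) <- paste0("dct", ks)
  B
}

#' CompCor nuisance components from WM and CSF voxel pools
#'
#' Variance-normalizes each nuisance voxel timeseries, pools CSF and WM
#' voxels jointly, and returns the top `k` principal-component timecourses
#' (mutually orthogonal, unit norm, first nonzero voxel loading positive).
#'
#' @param wm_pool,csf_pool numeric matrices, voxels x timepoints.
#' @param k number of components (default 5).
#' @return numeric matrix, k x timepoints (fewer rows with a warning if the
#'   pool has lower rank).
#' @export
compcor_components <- function(wm_pool, csf_pool, k = 5) {
  M <- rbind(csf_pool, wm_pool)
  if (nrow(M) < k) stopf("combined pool has fewer voxels (%d) than components (%d)", nrow(M), k)
  M <- M - rowMeans(M)
  sdv <- sqrt(rowSums(M^2))
  keep <- sdv > 1e-12
  M <- M[keep, , drop = FALSE] / sdv[keep]
  sv <- svd(t(M))                       # T x V: left vectors are timecourses
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  kk <- min(k, rank)
  if (kk < k) warnf("pool rank %d < %d requested components; returning %d", rank, k, kk)
  U <- sv$u[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    load <- sv$v[, j]
    nz <- which(abs(load) > 1e-12)[1]
    if (!is.na(nz) && load[nz] < 0) U[, j] <- -U[, j]
  }
  out <- t(U)
  rownames(out) <- paste0("compcor", seq_len(kk))
  out
}

#' Build a confound design for one session
#'
#' Assembles the regressor matrix for one of four nuisance options, together
#' with the DCT filter columns that implement high- or band-pass filtering in
#' the same model (so nuisance regression and filtering are simultaneous):
#'
#' * `N`: 24 motion-expansion regressors only;
#' * `C`: motion expansions plus the expanded mean CSF signal (28);
#' * `CW`: motion expansions plus expanded mean CSF and WM signals (32);
#' * `CC`: motion expansions plus 5 CompCor components of the joint
#'   CSF + WM pool (29).
#'
#' All confound columns are mean-centered; the intercept is the first column.
#' Constant-zero columns are dropped (names kept in attribute `"dropped"`).
#'
#' @param session an `fc_session`.
#' @param nuisance one of `"N"`, `"C"`, `"CW"`, `"CC"`.
#' @param filter `"HP"`, `"BP"` or `"none"`.
#' @param band filter band in Hz.
#' @param compcor_k number of CompCor components for option `"CC"`.
#' @return object of class `confound_design`: list with `matrix`
#'   (timepoints x regressors), `labels`, `option`, `filter`, `filter_band`,
#'   and `n_confounds` (confound count excluding intercept and DCT columns).
#' @export
confound_design <- function(session, nuisance = c("CW", "C", "N", "CC"),
                            filter = c("HP", "BP", "none"),
                            band = c(0.008, 0.1), compcor_k = 5) {
  nuisance <- match.arg(nuisance)
  filter <- match.arg(filter)
  T <- ncol(session$data)
  blocks <- list(intercept = matrix(1, T, 1))
  colnames(blocks$intercept) <- "intercept"
  me <- t(motion_expansion(session$motion_params))
  blocks$motion <- me
  expand1 <- function(x, name) {
    d <- c(0, diff(x))
    m <- cbind(x, d, x^2, d^2)
    colnames(m) <- paste0(name, c("", "_d", "_sq", "_dsq"))
    m
  }
  if (nuisance %in% c("C", "CW")) {
    blocks$csf <- expand1(colMeans(session$csf_pool), "csf")
  }
  if (nuisance == "CW") {
    blocks$wm <- expand1(colMeans(session$wm_pool), "wm")
  }
  if (nuisance == "CC") {
    blocks$compcor <- t(compcor_components(session$wm_pool, session$csf_pool, compcor_k))
  }
  n_conf <- sum(vapply(blocks, ncol, 0L)) - 1L
  if (filter != "none") {
    blocks$dct <- dct_basis(T, session$tr, band,
                            mode = if (filter == "HP") "highpass" else "bandpass")
  }
  X <- do.call(cbind, blocks)
  labs <- colnames(X)
  keep <- labs == "intercept" | startsWith(labs, "dct")
  X[, !keep] <- sweep(X[, !keep, drop = FALSE], 2,
                      colMeans(X[, !keep, drop = FALSE]), "-")
  zero <- apply(X, 2, function(col) all(abs(col) < 1e-12))
  dropped <- labs[zero]
  X <- X[, !zero, drop = FALSE]
  structure(list(matrix = X, labels = colnames(X), option = nuisance,
                 filter = filter, filter_band = band,
                 n_confounds = n_conf - sum(zero & !keep)),
            class = "confound_design", dropped = dropped)
}

#' Voxelwise nuisance GLM
#'
#' Regresses the confound design out of every voxel timeseries by ordinary
#' least squares and returns the residuals. Collinear columns are dropped
#' (names recorded in attribute `"dropped_collinear"`).
#'
#' @param x an `fc_session`, or a plain voxels x timepoints matrix.
#' @param design a [confound_design()], or a plain timepoints x regressors
#'   matrix.
#' @return for a session input, an `fc_residuals` object (the session with
#'   `data` replaced by residuals, `whitened = FALSE` and design provenance);
#'   for a matrix input, the residual matrix.
#' @export
fit_glm <- function(x, design) {
  X <- if (inherits(design, "confound_design")) design$matrix else design
  Y <- if (inherits(x, "fc_session")) x$data else x
  T <- ncol(Y)
  if (nrow(X) != T) stopf("design has %d rows but data has %d timepoints", nrow(X), T)
  if (ncol(X) >= T) stopf("more regressors (%d) than timepoints (%d)", ncol(X), T)
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    nms <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
    dropped <- nms[-keep]
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  resid <- t(qr.resid(qrX, t(Y)))
  if (inherits(x, "fc_session")) {
    out <- x
    out$data <- resid
    out$whitened <- FALSE
    out$design <- if (inherits(design, "confound_design")) {
      design[c("option", "filter", "filter_band", "n_confounds")]
    } else {
      list(option = "custom")
    }
    attr(out, "dropped_collinear") <- dropped
    class(out) <- c("fc_residuals", "fc_session")
    out
  } else {
    attr(resid, "dropped_collinear") <- dropped
    resid
  }
}
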