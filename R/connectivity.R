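# Connectivity estimation: Pearson ROI-mean correlation, unbiased distance
# correlation over ROI voxel sets, and group-level standardization.

new_conn <- function(values, method, standardized = "none",
                     subject = NA, session = NA) {
  structure(values, class = "fc_conn", method = method,
            standardized = standardized, subject = subject, session = session,
            mean_connectivity = mean(values[upper.tri(values)]))
}

#' @export
print.fc_conn <- function(x, ...) {
  cat(sprintf("fc_conn %dx%d, method=%s, standardized=%s, mean=%.3f\n",
              nrow(x), ncol(x), attr(x, "method"), attr(x, "standardized"),
              attr(x, "mean_connectivity")))
  invisible(x)
}

#' Pearson (ROI-mean) connectivity matrix
#'
#' Averages each ROI's voxel timeseries and correlates the ROI means
#' pairwise.
#'
#' @param res an `fc_session`/`fc_residuals` object.
#' @return `fc_conn` matrix (symmetric, unit diagonal). A zero-variance ROI
#'   mean yields `NaN` in its row/column, with a warning.
#' @export
pearson_connectivity <- function(res) {
  T <- ncol(res$data)
  if (T < 3) stopf("need at least 3 timepoints")
  R <- max(res$roi)
  means <- t(rowsum(res$data, res$roi) / as.vector(table(res$roi)))
  sds <- apply(means, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("zero-variance ROI mean in ROI(s) %s", paste(which(sds == 0), collapse = ", "))
  }
  C <- suppressWarnings(stats::cor(means))
  C[sds == 0, ] <- NaN
  C[, sds == 0] <- NaN
  diag(C) <- 1
  new_conn(C, "pcor")
}

# U-centered (unbiased) Euclidean distance matrix over timepoints for one
# ROI's z-scored voxel set (voxels x timepoints)
ucentered_dist <- function(X) {
  T <- ncol(X)
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  sdv[sdv == 0] <- 1
  X <- (X - mu) / sdv
  ss <- colSums(X^2)
  D2 <- outer(ss, ss, "+") - 2 * crossprod(X)
  a <- sqrt(pmax(D2, 0))
  rs <- rowSums(a)
  A <- a - outer(rs, rep(1, T)) / (T - 2) - outer(rep(1, T), rs) / (T - 2) +
    sum(rs) / ((T - 1) * (T - 2))
  diag(A) <- 0
  A
}

#' Unbiased distance correlation between two voxel sets
#'
#' Szekely-Rizzo U-centered estimator: timepoints are the samples, voxels the
#' variables (each voxel z-scored first). The unbiased squared distance
#' covariance is `sum(A * B) / (T * (T - 3))` over U-centered Euclidean
#' distance matrices; the returned statistic is
#' `sqrt(max(0, dCov2u / sqrt(dVarX * dVarY)))`. The signed squared
#' estimator (negative under independence about half the time) is kept in
#' attribute `"dcor2_signed"`.
#'
#' @param X,Y numeric matrices, voxels x timepoints, same timepoint count.
#' @return scalar in `[0, 1]` with attributes `dcor2_signed` and `dcov2`.
#' @export
unbiased_dcor <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, 1)
  if (is.vector(Y)) Y <- matrix(Y, 1)
  T <- ncol(X)
  if (T <= 3) stopf("unbiased distance correlation needs more than 3 timepoints")
  if (ncol(Y) != T) stopf("X and Y must share the timepoint dimension")
  A <- ucentered_dist(X)
  B <- ucentered_dist(Y)
  dcor_from_ucentered(A, B, T)
}

dcor_from_ucentered <- function(A, B, T) {
  sc <- T * (T - 3)
  dcov2 <- sum(A * B) / sc
  vx <- sum(A * A) / sc
  vy <- sum(B * B) / sc
  if (vx <= 0 || vy <= 0) {
    warnf("zero distance variance: distance correlation set to 0")
    return(structure(0, dcor2_signed = 0, dcov2 = dcov2))
  }
  d2 <- dcov2 / sqrt(vx * vy)
  structure(sqrt(max(0, d2)), dcor2_signed = d2, dcov2 = dcov2)
}

#' Distance-correlation connectivity matrix
#'
#' Applies [unbiased_dcor()] to every ROI pair, using all voxel timeseries
#' within each ROI (no averaging). The diagonal is set to 1 by convention so
#' the matrix is comparable with Pearson connectivity; only off-diagonal
#' entries enter downstream statistics. Per-pair failures produce `NaN`
#' without aborting the rest of the matrix.
#'
#' @param res an `fc_session`/`fc_residuals` object.
#' @return `fc_conn` matrix with entries in `[0, 1]`; the signed squared
#'   estimates are kept in attribute `"dcor2_signed"`.
#' @export
dcor_connectivity <- function(res) {
  T <- ncol(res$data)
  if (T <= 3) stopf("unbiased distance correlation needs more than 3 timepoints")
  R <- max(res$roi)
  U <- lapply(seq_len(R), function(r) ucentered_dist(roi_matrix(res, r)))
  sc <- T * (T - 3)
  dv <- vapply(U, function(A) sum(A * A) / sc, 0)
  C <- diag(1, R)
  C2 <- diag(1, R)
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      if (dv[i] <= 0 || dv[j] <= 0) {
        C[i, j] <- C[j, i] <- C2[i, j] <- C2[j, i] <- NaN
        next
      }
      d2 <- (sum(U[[i]] * U[[j]]) / sc) / sqrt(dv[i] * dv[j])
      C[i, j] <- C[j, i] <- sqrt(max(0, d2))
      C2[i, j] <- C2[j, i] <- d2
    }
  }
  if (anyNA(C)) warnf("distance correlation undefined for %d pair(s)", sum(is.na(ut(C))))
  out <- new_conn(C, "dcor")
  attr(out, "dcor2_signed") <- C2
  out
}

#' Mean regression across participants
#'
#' For every off-diagonal connection, regresses the across-participant vector
#' of connectivity values on each participant's mean connectivity (over all
#' connections, upper triangle) with an intercept, and replaces values by the
#' residual plus the group mean of that connection. After the operation every
#' participant's mean connectivity equals the group mean exactly, while the
#' pattern of individual differences orthogonal to mean connectivity is
#' preserved. Applying it twice equals applying it once (the second pass sees
#' a zero-variance predictor and returns its input with a warning).
#'
#' @param mats list of connectivity matrices, one per participant (same ROI
#'   set, one session).
#' @return list of matrices with `standardized = "MR"`.
#' @export
mean_regression <- function(mats) {
  n <- length(mats)
  if (n < 3) stopf("mean regression needs at least 3 participants")
  V <- vapply(mats, ut, numeric(length(ut(as.matrix(mats[[1]])))))
  m <- colMeans(V)
  if (stats::var(m) < 1e-20) {
    warnf("zero variance in participant mean connectivity: mean regression is the identity")
    return(lapply(mats, function(x) {
      attr(x, "standardized") <- "MR"
      x
    }))
  }
  mc <- m - mean(m)
  beta <- as.vector((V %*% mc)) / sum(mc^2)
  Vnew <- V - outer(beta, mc)
  R <- nrow(as.matrix(mats[[1]]))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    M <- unvec_ut(Vnew[, i], R, diag = diag(as.matrix(mats[[i]])))
    out[[i]] <- new_conn(M, attr(mats[[i]], "method") %||% "unknown", "MR",
                         subject = attr(mats[[i]], "subject"),
                         session = attr(mats[[i]], "session"))
  }
  names(out) <- names(mats)
  out
}

#' Replace per-session grand means by the two-session average
#'
#' Shifts every off-diagonal entry of each session's matrices so that the
#' session grand mean (over participants and connections) equals the average
#' of the two sessions' grand means; within-session differences between
#' participants are unchanged. Intended to follow [mean_regression()] applied
#' per session; it is idempotent.
#'
#' @param session1,session2 lists of connectivity matrices (same ROI set).
#' @return list with adjusted `session1` and `session2`.
#' @export
harmonize_session_means <- function(session1, session2) {
  R1 <- nrow(as.matrix(session1[[1]]))
  R2 <- nrow(as.matrix(session2[[1]]))
  if (R1 != R2) stopf("sessions have different ROI sets (%d vs %d)", R1, R2)
  g1 <- mean(vapply(session1, function(m) mean(ut(as.matrix(m))), 0))
  g2 <- mean(vapply(session2, function(m) mean(ut(as.matrix(m))), 0))
  target <- (g1 + g2) / 2
  shift <- function(mats, delta) {
    lapply(mats, function(m) {
      v <- ut(as.matrix(m)) + delta
      new_conn(unvec_ut(v, nrow(as.matrix(m)), diag = diag(as.matrix(m))),
               method = attr(m, "method") %||% "unknown",
               standardized = attr(m, "standardized") %||% "none",
               subject = attr(m, "subject"), session = attr(m, "session"))
    })
  }
  list(session1 = shift(session1, target - g1),
       session2 = shift(session2, target - g2))
}

#' Fisher z-transform of a connectivity matrix's off-diagonal entries
#'
#' Stabilizes the sampling variance of Pearson correlations before group
#' statistics; the diagonal is left at its conventional value.
#'
#' @param m connectivity matrix.
#' @return matrix of the same class with transformed off-diagonals.
#' @export
fisher_transform_conn <- function(m) {
  v <- fisher_z(ut(as.matrix(m)))
  new_conn(unvec_ut(v, nrow(as.matrix(m)), diag = diag(as.matrix(m))),
           method = paste0(attr(m, "method") %||% "unknown", "_z"),
           standardized = attr(m, "standardized") %||% "none",
           subject = attr(m, "subject"), session = attr(m, "session"))
}
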