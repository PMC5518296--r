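# Shared fixtures (memoised so expensive objects are built once per run)
# and independent oracles used across test files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# a small default-structure cohort reused by several files
tiny_cohort <- function() {
  memo("tiny_cohort", generate_cohort(cohort_spec(
    n_subjects = 16, n_rois = 12, n_networks = 4, voxels_per_roi = 8,
    session_lengths = c(80, 60), seed = 11
  )))
}

# ---- oracles --------------------------------------------------------------

# O(T^2) double-loop U-centering oracle for the unbiased distance
# correlation (textbook formula, independent of the package implementation)
dcor_oracle <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, 1)
  if (is.vector(Y)) Y <- matrix(Y, 1)
  zs <- function(M) {
    out <- M
    for (v in seq_len(nrow(M))) {
      s <- stats::sd(M[v, ])
      out[v, ] <- (M[v, ] - mean(M[v, ])) / ifelse(s == 0, 1, s)
    }
    out
  }
  X <- zs(X); Y <- zs(Y)
  T <- ncol(X)
  a <- as.matrix(stats::dist(t(X)))
  b <- as.matrix(stats::dist(t(Y)))
  ucent <- function(d) {
    U <- matrix(0, T, T)
    tot <- sum(d)
    for (i in seq_len(T)) {
      for (j in seq_len(T)) {
        if (i == j) next
        U[i, j] <- d[i, j] - sum(d[i, ]) / (T - 2) - sum(d[, j]) / (T - 2) +
          tot / ((T - 1) * (T - 2))
      }
    }
    U
  }
  A <- ucent(a); B <- ucent(b)
  s <- 0; vx <- 0; vy <- 0
  for (i in seq_len(T)) {
    for (j in seq_len(T)) {
      if (i == j) next
      s <- s + A[i, j] * B[i, j]
      vx <- vx + A[i, j]^2
      vy <- vy + B[i, j]^2
    }
  }
  sc <- T * (T - 3)
  d2 <- (s / sc) / sqrt((vx / sc) * (vy / sc))
  list(dcor = sqrt(max(0, d2)), dcor2_signed = d2)
}

# ICC(2,1) via R's own two-way ANOVA machinery
icc_oracle <- function(x, y) {
  n <- length(x)
  df <- data.frame(v = c(x, y), t = factor(rep(seq_len(n), 2)),
                   r = factor(rep(1:2, each = n)))
  a <- suppressWarnings(stats::anova(stats::lm(v ~ t + r, df)))
  msr <- a["t", "Mean Sq"]; msc <- a["r", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# simulate paired measurements with a known variance-component ICC
planted_icc_pairs <- function(n, icc_true) {
  subj <- stats::rnorm(n, sd = sqrt(icc_true))
  list(x = subj + stats::rnorm(n, sd = sqrt(1 - icc_true)),
       y = subj + stats::rnorm(n, sd = sqrt(1 - icc_true)))
}

# random small session-like object for connectivity tests
fake_session <- function(R = 4, vox = 3, T = 40, seed = 1) {
  set.seed(seed)
  structure(list(
    data = matrix(stats::rnorm(R * vox * T), R * vox, T),
    roi = rep(seq_len(R), each = vox),
    coords = cbind(seq_len(R * vox) * 3, 0, 0),
    ijk = cbind(seq_len(R * vox), 1, 1),
    motion_params = matrix(stats::rnorm(6 * T, sd = 0.02), 6, T),
    wm_pool = matrix(stats::rnorm(6 * T), 6, T),
    csf_pool = matrix(stats::rnorm(6 * T), 6, T),
    tr = 1.97
  ), class = "fc_session")
}

# random connectivity-matrix list for group-level operations
fake_conn_list <- function(n, R, seed = 1, base = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    v <- if (is.null(base)) stats::rnorm(R * (R - 1) / 2, 0.3, 0.2) else
      base + stats::rnorm(R * (R - 1) / 2, 0, 0.05)
    unvec_ut_test(v, R)
  })
}

unvec_ut_test <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- 1
  m
}

ut_test <- function(m) m[upper.tri(m)]
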