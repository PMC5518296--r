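# Evaluation battery: ICC reliability indices, peer similarity, trait
# association maps, mediation, and permutation / signed-rank / Steiger tests.

# stack a list of connectivity matrices into connections x participants
conn_vecs <- function(mats) {
  vapply(mats, function(m) ut(as.matrix(m)), ut(as.matrix(mats[[1]])))
}

#' Intraclass correlation for paired measurements
#'
#' Single-measure ICC from the two-way ANOVA decomposition of an
#' n-targets-by-2-raters table. The default `"agreement"` variant is
#' ICC(2,1): two-way random effects, absolute agreement, so a constant shift
#' between the two measurements lowers the coefficient. `"consistency"` is
#' ICC(3,1).
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`.
#' @return scalar ICC (can be negative; a degenerate between-target variance
#'   yields a value at or below 0 with a warning).
#' @export
icc <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stopf("need at least 3 complete pairs")
  icc_compute(x, y, type)
}

icc_compute <- function(x, y, type = "agreement") {
  n <- length(x)
  g <- (mean(x) + mean(y)) / 2
  pm <- (x + y) / 2
  ssr <- 2 * sum((pm - g)^2)
  ssc <- n * ((mean(x) - g)^2 + (mean(y) - g)^2)
  sst <- sum((x - g)^2) + sum((y - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc
  mse <- sse / (n - 1)
  den <- if (type == "agreement") msr + mse + 2 * (msc - mse) / n else msr + mse
  if (den <= 0 || !is.finite(den)) {
    warnf("degenerate variance decomposition: ICC not positive")
    return(0)
  }
  out <- (msr - mse) / den
  if (out <= 0 && msr <= mse * (1 + 1e-12) && stats::var(pm) < 1e-30) {
    warnf("no between-target variance: ICC <= 0")
  }
  out
}

#' Within-participant reliability of connectivity matrices
#'
#' For each participant, the ICC between the vectorized upper triangles of
#' their session-1 and session-2 matrices: do absolute values and regional
#' differences in connectivity strength remain stable across sessions?
#'
#' @param mats_s1,mats_s2 lists of connectivity matrices indexed by
#'   participant; participants missing either session are omitted (message).
#' @param type ICC variant, see [icc()].
#' @return numeric vector of per-participant ICCs, mean in attribute
#'   `"mean"`.
#' @export
within_participant_reliability <- function(mats_s1, mats_s2, type = "agreement") {
  n <- max(length(mats_s1), length(mats_s2))
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m1 <- if (i <= length(mats_s1)) mats_s1[[i]] else NULL
    m2 <- if (i <= length(mats_s2)) mats_s2[[i]] else NULL
    if (is.null(m1) || is.null(m2)) next
    out[i] <- icc(ut(as.matrix(m1)), ut(as.matrix(m2)), type)
  }
  if (anyNA(out)) message(sum(is.na(out)), " participant(s) missing a session omitted")
  structure(out[!is.na(out)], mean = mean(out, na.rm = TRUE))
}

#' Between-participant reliability of single connections
#'
#' For every ROI pair, the ICC across participants between sessions (are
#' individual differences in that connection stable?), averaged over all
#' within-network and all between-network connections.
#'
#' @param mats_s1,mats_s2 lists of connectivity matrices (same participants,
#'   both sessions).
#' @param networks integer network label per ROI.
#' @param type ICC variant, see [icc()].
#' @return list with `rs` (ROI x ROI ICC matrix), `rsw`, `rsb` (unweighted
#'   means over within-/between-network connections; connections with zero
#'   across-participant variance are excluded, with a message).
#' @export
per_connection_reliability <- function(mats_s1, mats_s2, networks, type = "agreement") {
  if (length(mats_s1) != length(mats_s2)) stopf("sessions must contain the same participants")
  V1 <- conn_vecs(mats_s1)
  V2 <- conn_vecs(mats_s2)
  n <- ncol(V1)
  g <- (rowMeans(V1) + rowMeans(V2)) / 2
  pm <- (V1 + V2) / 2
  ssr <- 2 * rowSums((pm - g)^2)
  ssc <- n * ((rowMeans(V1) - g)^2 + (rowMeans(V2) - g)^2)
  sst <- rowSums((V1 - g)^2) + rowSums((V2 - g)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc
  mse <- sse / (n - 1)
  den <- if (type == "agreement") msr + mse + 2 * (msc - mse) / n else msr + mse
  r <- (msr - mse) / den
  degenerate <- ssr + sse < 1e-24
  if (any(degenerate)) {
    message(sum(degenerate), " zero-variance connection(s) excluded from averages")
    r[degenerate] <- NA_real_
  }
  R <- nrow(as.matrix(mats_s1[[1]]))
  rs <- unvec_ut(r, R, diag = 1)
  same <- ut(outer(networks, networks, "=="))
  list(rs = rs, per_connection = r,
       rsw = mean(r[same == 1], na.rm = TRUE),
       rsb = mean(r[same == 0], na.rm = TRUE))
}

#' Per-connection association between a trait and connectivity
#'
#' Correlates each connection's across-participant values with a trait,
#' optionally as a partial correlation after residualizing both sides on
#' covariates (e.g. age). Reports the mean absolute association over all
#' connections and the percentage of connections significantly positive /
#' negative at `alpha` (two-sided, uncorrected by default; `fdr = TRUE`
#' applies Benjamini-Hochberg).
#'
#' @param mats list of connectivity matrices (one session).
#' @param trait numeric vector, one value per participant.
#' @param adjust_for optional numeric covariate vector/matrix (e.g. ages).
#' @param alpha significance level for the percentage summaries.
#' @param fdr logical; adjust p-values by BH before thresholding.
#' @return list with `map` (ROI x ROI partial correlations), `r`
#'   (per-connection vector), `p`, `mean_abs`, `pct_pos`, `pct_neg`, `df`.
#' @export
trait_association_map <- function(mats, trait, adjust_for = NULL,
                                  alpha = 0.05, fdr = FALSE) {
  V <- conn_vecs(mats)
  n <- ncol(V)
  if (!is.numeric(trait) || length(trait) != n) stopf("trait must be numeric, one value per participant")
  q <- 0
  if (!is.null(adjust_for)) {
    Z <- cbind(1, as.matrix(adjust_for))
    for (j in 2:ncol(Z)) {
      rr <- suppressWarnings(stats::cor(trait, Z[, j]))
      if (is.finite(rr) && abs(rr) > 0.999) stopf("covariate %d is collinear with the trait", j - 1)
    }
    qz <- qr(Z)
    trait <- qr.resid(qz, trait)
    V <- t(qr.resid(qz, t(V)))
    q <- ncol(Z) - 1
  }
  r <- cor_vec_mat(trait, t(V))
  df <- n - 2 - q
  tstat <- r * sqrt(df / pmax(1 - r^2, 1e-15))
  p <- 2 * stats::pt(-abs(tstat), df)
  p_thr <- if (fdr) stats::p.adjust(p, "BH") else p
  R <- nrow(as.matrix(mats[[1]]))
  list(map = unvec_ut(r, R, diag = 0), r = r, p = p,
       mean_abs = mean(abs(r), na.rm = TRUE),
       pct_pos = 100 * mean(p_thr < alpha & r > 0, na.rm = TRUE),
       pct_neg = 100 * mean(p_thr < alpha & r < 0, na.rm = TRUE),
       df = df)
}

#' Age-effect map and its across-session reliability
#'
#' `age_effect_map()` correlates every connection with age across
#' participants. `age_effect_reliability()` is the ICC between the
#' vectorized age-effect maps of the two sessions (reliability of the age
#' effect).
#'
#' @param mats list of connectivity matrices (one session).
#' @param ages numeric vector of participant ages.
#' @return `age_effect_map()`: ROI x ROI matrix of age-connectivity
#'   correlations (class `fc_effect_map`); `age_effect_reliability()`:
#'   scalar ICC.
#' @export
age_effect_map <- function(mats, ages) {
  if (length(mats) < 10) stopf("need at least 10 participants")
  if (stats::var(ages) == 0) stopf("ages are constant")
  V <- conn_vecs(mats)
  r <- cor_vec_mat(ages, t(V))
  structure(unvec_ut(r, nrow(as.matrix(mats[[1]])), diag = 0),
            class = "fc_effect_map", trait = "age")
}

#' @rdname age_effect_map
#' @param map_s1,map_s2 effect maps from the two sessions.
#' @param type ICC variant, see [icc()].
#' @export
age_effect_reliability <- function(map_s1, map_s2, type = "agreement") {
  icc(ut(as.matrix(map_s1)), ut(as.matrix(map_s2)), type)
}

#' Similarity of connectivity to age-matched peers
#'
#' For each participant, finds the `k` other participants closest in age
#' (ties in age distance broken by participant index) and correlates the
#' participant's vectorized matrix with the elementwise mean matrix of those
#' peers.
#'
#' @param mats list of connectivity matrices (one session).
#' @param ages numeric participant ages.
#' @param k number of age-matched peers (default 30; must be below the
#'   number of participants).
#' @return numeric vector of per-participant Pearson similarities, mean in
#'   attribute `"mean"`.
#' @export
peer_similarity <- function(mats, ages, k = 30) {
  n <- length(mats)
  if (k >= n) stopf("k (%d) must be smaller than the number of participants (%d)", k, n)
  V <- conn_vecs(mats)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(ages - ages[i])
    d[i] <- Inf
    peers <- order(d, seq_len(n))[seq_len(k)]
    out[i] <- stats::cor(V[, i], rowMeans(V[, peers, drop = FALSE]))
  }
  structure(out, mean = mean(out))
}

#' Simple mediation with Sobel inference
#'
#' Standardizes all variables, estimates the `a` path (mediator on
#' predictor), the `b` and direct `c'` paths (outcome on predictor and
#' mediator jointly) and the total effect `c` (outcome on predictor), and
#' tests the indirect effect `ab` with the Sobel normal-theory standard
#' error `sqrt(a^2 se_b^2 + b^2 se_a^2)`. On standardized variables
#' `c = c' + ab` holds exactly. An optional percentile bootstrap for `ab`
#' is available.
#'
#' @param x predictor (e.g. age), `m` mediator (e.g. vascular health),
#'   `y` outcome (e.g. mean connectivity); complete cases required.
#' @param m,y see `x`.
#' @param n_boot bootstrap replicates for a percentile CI on `ab` (0 = none).
#' @param seed RNG seed for the bootstrap.
#' @return list with `a`, `b`, `ab`, `c`, `c_prime`, `t`, `p`,
#'   `pct_reduction` (`100 (c - c') / c`; `NA` with a warning when `c` is
#'   near zero) and optionally `ab_ci`.
#' @export
mediation <- function(x, m, y, n_boot = 0, seed = 1) {
  ok <- is.finite(x) & is.finite(m) & is.finite(y)
  x <- scale(x[ok])[, 1]; m <- scale(m[ok])[, 1]; y <- scale(y[ok])[, 1]
  fit_a <- stats::lm(m ~ x)
  fit_b <- stats::lm(y ~ x + m)
  a <- stats::coef(fit_a)[["x"]]
  se_a <- summary(fit_a)$coefficients["x", "Std. Error"]
  b <- stats::coef(fit_b)[["m"]]
  se_b <- summary(fit_b)$coefficients["m", "Std. Error"]
  c_prime <- stats::coef(fit_b)[["x"]]
  cc <- stats::coef(stats::lm(y ~ x))[["x"]]
  ab <- a * b
  se_ab <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  t <- ab / se_ab
  p <- 2 * stats::pnorm(-abs(t))
  pct <- if (abs(cc) < 1e-10) {
    warnf("total effect is (near) zero: percent reduction undefined")
    NA_real_
  } else {
    100 * (cc - c_prime) / cc
  }
  out <- list(a = a, b = b, ab = ab, c = cc, c_prime = c_prime,
              t = t, p = p, pct_reduction = pct, n = length(x))
  if (n_boot > 0) {
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(x), replace = TRUE)
      ai <- stats::coef(stats::lm(m[idx] ~ x[idx]))[[2]]
      bi <- stats::coef(stats::lm(y[idx] ~ x[idx] + m[idx]))[[3]]
      ai * bi
    }, 0))
    out$ab_ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  }
  out
}

#' Permutation test comparing two effect maps
#'
#' Paired label-swap test: each connection's pair of values (option A,
#' option B) is randomly reassigned between the two groups, the difference of
#' group means recomputed, and the two-sided p-value estimated as the
#' smoothed proportion `(b + 1) / (n_perm + 1)` of permuted absolute
#' differences at least as large as the observed one.
#'
#' @param map_a,map_b effect maps (matrices or vectors) on the same
#'   connections.
#' @param n_perm number of random assignments (default 5000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return list with `p`, `observed` (difference of means) and `n_perm`.
#' @export
permutation_compare_maps <- function(map_a, map_b, n_perm = 5000, seed = 1) {
  a <- if (is.matrix(map_a)) ut(as.matrix(map_a)) else as.numeric(map_a)
  b <- if (is.matrix(map_b)) ut(as.matrix(map_b)) else as.numeric(map_b)
  if (length(a) != length(b)) stopf("maps must cover the same connections")
  if (n_perm < 100) warnf("n_perm < 100 gives a coarse p-value")
  d <- a - b
  obs <- mean(d)
  perm <- with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE), n_perm)
    as.vector(S %*% d) / length(d)
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(p = p, observed = obs, n_perm = n_perm)
}

#' Permutation test comparing the reliability of two age-effect maps
#'
#' Given age-connectivity maps for two processing options in each of two
#' sessions, randomly swaps the option labels per connection -- identically
#' in both sessions -- recomputes the across-session ICC of each shuffled
#' option, and compares the observed reliability difference with the
#' permuted distribution (two-sided, smoothed as in
#' [permutation_compare_maps()]).
#'
#' @param map_a1,map_a2 option-A maps for sessions 1 and 2.
#' @param map_b1,map_b2 option-B maps for sessions 1 and 2.
#' @param n_perm,seed as in [permutation_compare_maps()].
#' @param type ICC variant.
#' @return list with `p`, `observed` (ICC difference A - B) and `n_perm`.
#' @export
permutation_compare_age_reliability <- function(map_a1, map_a2, map_b1, map_b2,
                                                n_perm = 5000, seed = 1,
                                                type = "agreement") {
  v <- function(m) if (is.matrix(m)) ut(as.matrix(m)) else as.numeric(m)
  a1 <- v(map_a1); a2 <- v(map_a2); b1 <- v(map_b1); b2 <- v(map_b2)
  if (length(unique(c(length(a1), length(a2), length(b1), length(b2)))) != 1) {
    stopf("all four maps must cover the same connections")
  }
  if (n_perm < 100) warnf("n_perm < 100 gives a coarse p-value")
  obs <- icc_compute(a1, a2, type) - icc_compute(b1, b2, type)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    sw <- stats::runif(length(a1)) < 0.5
    pa1 <- ifelse(sw, b1, a1); pb1 <- ifelse(sw, a1, b1)
    pa2 <- ifelse(sw, b2, a2); pb2 <- ifelse(sw, a2, b2)
    icc_compute(pa1, pa2, type) - icc_compute(pb1, pb2, type)
  }, 0))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(p = p, observed = obs, n_perm = n_perm)
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' Paired test for comparing an evaluation index across processing options.
#' Zero differences are dropped; an all-zero difference vector returns
#' `z = 0, p = 1`.
#'
#' @param x,y paired numeric vectors.
#' @return list with `z`, `p`, `n` (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) return(list(z = 0, p = 1, n = 0L))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sig2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Compares `cor(j, k)` with `cor(j, h)` measured on the same sample, using
#' Fisher z-transformed coefficients and the covariance term implied by
#' `cor(k, h)` (pooled-correlation form).
#'
#' @param r_jk,r_jh the two correlations sharing variable `j`.
#' @param r_kh correlation between the non-shared variables.
#' @param n sample size (> 10).
#' @return list with `z`, `p`.
#' @export
steiger_overlapping_r <- function(r_jk, r_jh, r_kh, n) {
  if (n <= 10) stopf("Steiger's test needs n > 10")
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) stopf("correlations must lie in (-1, 1)")
  z1 <- fisher_z(r_jk)
  z2 <- fisher_z(r_jh)
  rb <- (r_jk + r_jh) / 2
  psi <- (r_kh * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r_kh^2)) /
    (1 - rb^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * psi))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
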