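# Reliability indices, effect maps, peer similarity, mediation, and the
# permutation / signed-rank / Steiger machinery.

test_that("ICC(2,1) matches the two-way ANOVA oracle and penalizes shifts", {
  set.seed(1)
  x <- rnorm(200)
  expect_equal(icc(x, x), 1, tolerance = 1e-12)
  y <- x + 0.8              # constant shift: absolute agreement drops
  expect_equal(icc(x, y), icc_oracle(x, y), tolerance = 1e-12)
  expect_lt(icc(x, y), 1)
  expect_gt(icc(x, y, type = "consistency"), 0.999)
  for (i in 1:10) {
    a <- rnorm(30)
    b <- 0.5 * a + rnorm(30)
    expect_equal(icc(a, b), icc_oracle(a, b), tolerance = 1e-12)
  }
  # independent inputs: near zero
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(icc(a, b)), 0.05)
  expect_error(icc(1:2, 1:2), "3 complete pairs")
})

test_that("within-participant reliability behaves on duplicated and shuffled sessions", {
  mats <- fake_conn_list(8, 6, seed = 2)
  rp <- within_participant_reliability(mats, mats)
  expect_equal(as.numeric(rp), rep(1, 8), tolerance = 1e-12)
  # shuffling connections destroys reliability
  set.seed(3)
  shuf <- lapply(mats, function(m) {
    v <- ut_test(m)
    unvec_ut_test(sample(v), 6)
  })
  rp0 <- within_participant_reliability(mats, shuf)
  expect_lt(abs(mean(rp0)), 0.35)
  # matches a manual icc on a 3-ROI fixture
  m1 <- list(unvec_ut_test(c(0.1, 0.4, 0.3), 3))
  m2 <- list(unvec_ut_test(c(0.2, 0.5, 0.2), 3))
  expect_equal(as.numeric(within_participant_reliability(m1, m2)),
               icc(c(0.1, 0.4, 0.3), c(0.2, 0.5, 0.2)))
  # a participant missing one session is omitted
  expect_message(rp2 <- within_participant_reliability(mats, mats[1:6]), "omitted")
  expect_length(as.numeric(rp2), 6)
})

test_that("per-connection reliability recovers planted variance components", {
  networks <- rep(1:2, each = 3)
  mats1 <- fake_conn_list(10, 6, seed = 4)
  pc <- per_connection_reliability(mats1, mats1, networks)
  expect_true(all(abs(pc$per_connection - 1) < 1e-12))
  ind <- per_connection_reliability(mats1, fake_conn_list(10, 6, seed = 5), networks)
  expect_lt(abs(ind$rsw), 0.5)   # single-draw ICC per connection is noisy
  expect_lt(abs(mean(ind$per_connection)), 0.2)
  # planted ICC = 0.5 across many connections, n = 200 participants
  set.seed(6)
  n <- 200; m <- 45
  subj <- matrix(rnorm(m * n, sd = sqrt(0.5)), m, n)
  V1 <- subj + matrix(rnorm(m * n, sd = sqrt(0.5)), m, n)
  V2 <- subj + matrix(rnorm(m * n, sd = sqrt(0.5)), m, n)
  l1 <- lapply(seq_len(n), function(i) unvec_ut_test(V1[, i], 10))
  l2 <- lapply(seq_len(n), function(i) unvec_ut_test(V2[, i], 10))
  pc5 <- per_connection_reliability(l1, l2, rep(1:2, each = 5))
  expect_lt(abs(mean(pc5$per_connection) - 0.5), 0.07)
})

test_that("age-effect maps recover planted signs and reliability limits", {
  set.seed(7)
  n <- 40; R <- 6
  ages <- runif(n, 18, 88)
  slopes <- unvec_ut_test(rnorm(R * (R - 1) / 2, 0, 0.004), R); diag(slopes) <- 0
  mats <- lapply(seq_len(n), function(i) {
    unvec_ut_test(0.3 + ut_test(slopes) * (ages[i] - 50) + rnorm(15, 0, 0.05), R)
  })
  map <- age_effect_map(mats, ages)
  strong <- abs(ut_test(slopes)) > 0.003
  expect_gte(mean(sign(ut_test(map))[strong] == sign(ut_test(slopes))[strong]), 0.95)
  expect_equal(age_effect_reliability(map, map), 1, tolerance = 1e-12)
  # no planted effect: reliability of the map across sessions is near zero
  null_maps <- replicate(2, age_effect_map(lapply(seq_len(n), function(i) {
    unvec_ut_test(rnorm(15, 0.3, 0.05), R)
  }), ages), simplify = FALSE)
  expect_lt(abs(age_effect_reliability(null_maps[[1]], null_maps[[2]])), 0.35)
  expect_error(age_effect_map(mats, rep(50, n)), "constant")
  expect_error(age_effect_map(mats[1:5], ages[1:5]), "10 participants")
})

test_that("peer similarity identifies outliers and honors k", {
  mats <- fake_conn_list(1, 6, seed = 8)
  same <- rep(mats, 12)
  ages <- seq(20, 80, length.out = 12)
  sp <- peer_similarity(same, ages, k = 5)
  expect_equal(as.numeric(sp), rep(1, 12), tolerance = 1e-12)
  # an independent outlier participant scores lowest
  mats2 <- fake_conn_list(12, 6, seed = 9, base = ut_test(same[[1]]))
  mats2[[7]] <- unvec_ut_test(rnorm(15, 0, 0.5), 6)
  sp2 <- peer_similarity(mats2, ages, k = 5)
  expect_equal(which.min(sp2), 7L)
  # k = 1 reduces to the nearest-age peer's matrix
  sp1 <- peer_similarity(mats2, ages, k = 1)
  expect_equal(sp1[1], cor(ut_test(mats2[[1]]), ut_test(mats2[[2]])))
  expect_error(peer_similarity(mats2, ages, k = 12), "smaller")
})

test_that("trait association maps match the null expectation and flag collinearity", {
  set.seed(10)
  n <- 60
  mats <- fake_conn_list(n, 8, seed = 10)
  trait <- rnorm(n)
  ta <- trait_association_map(mats, trait)
  expect_lt(abs(ta$mean_abs - sqrt(2 / pi) / sqrt(n - 1)), 0.03)
  expect_equal(dim(ta$map), c(8L, 8L))
  # age adjustment: partialling the trait itself out errors
  expect_error(trait_association_map(mats, trait, adjust_for = trait), "collinear")
  # a shared per-participant offset (global-signal-like) is detected
  offs <- rnorm(n, 0, 0.15)
  mats3 <- lapply(seq_len(n), function(i) mats[[i]] + offs[i] * (1 - diag(8)))
  tr2 <- offs + rnorm(n, 0, 0.02)
  ta2 <- trait_association_map(mats3, tr2)
  expect_gt(ta2$mean_abs, 3 * sqrt(2 / pi) / sqrt(n - 1))
  expect_gt(ta2$pct_pos, 50)
})

test_that("mediation recovers planted paths and satisfies path algebra", {
  set.seed(11)
  n <- 1e4
  x <- rnorm(n)
  # planted a = -0.5, b = 0.3
  m <- -0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  y <- 0.3 * m + 0.2 * x + rnorm(n)
  md <- mediation(x, m, y)
  expect_lt(abs(md$ab - (-0.15)), 0.03)
  expect_equal(md$ab, md$a * md$b, tolerance = 1e-12)
  expect_equal(md$c, md$c_prime + md$ab, tolerance = 1e-10)
  # full mediation: direct path vanishes, reduction ~ 100%
  y2 <- 0.6 * m + rnorm(n)
  md2 <- mediation(x, m, y2)
  expect_lt(abs(md2$c_prime), 0.03)
  expect_gt(md2$pct_reduction, 90)
  # independent mediator: no indirect effect
  md3 <- mediation(x, rnorm(n), y)
  expect_lt(abs(md3$ab), 0.02)
  expect_lt(abs(md3$pct_reduction), 10)
  # bootstrap CI covers the planted value
  md4 <- mediation(x[1:500], m[1:500], y[1:500], n_boot = 200, seed = 2)
  expect_true(md4$ab_ci[1] < -0.15 && -0.15 < md4$ab_ci[2])
})

test_that("map-comparison permutation test is seeded and calibrated at the extremes", {
  set.seed(12)
  a <- rnorm(100, 0.3, 0.1)
  expect_equal(permutation_compare_maps(a, a, 500, seed = 1)$p, 1)
  pbig <- permutation_compare_maps(a, a + 1, 1000, seed = 1)$p
  expect_lte(pbig, 2 / 1001)
  p1 <- permutation_compare_maps(a, a + 0.01, 500, seed = 3)
  p2 <- permutation_compare_maps(a, a + 0.01, 500, seed = 3)
  expect_identical(p1, p2)
  expect_warning(permutation_compare_maps(a, a + 1, 50, seed = 1), "coarse")
  # null calibration: p-values roughly uniform
  set.seed(13)
  ps <- replicate(200, {
    permutation_compare_maps(rnorm(60), rnorm(60), 200,
                             seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("age-reliability permutation test distinguishes reliable from noise maps", {
  set.seed(14)
  base <- rnorm(80, 0, 0.2)
  a1 <- base + rnorm(80, 0, 0.05)
  a2 <- base + rnorm(80, 0, 0.05)
  expect_equal(permutation_compare_age_reliability(a1, a2, a1, a2, 500, seed = 1)$p, 1)
  pr <- permutation_compare_age_reliability(a1, a2, rnorm(80, 0, 0.2),
                                            rnorm(80, 0, 0.2), 1000, seed = 1)
  expect_lt(pr$p, 0.01)
  expect_gt(pr$observed, 0.5)
  # calibration under an exchangeable null
  ps <- replicate(100, {
    b <- rnorm(40, 0, 0.2)
    permutation_compare_age_reliability(
      b + rnorm(40, 0, 0.1), b + rnorm(40, 0, 0.1),
      b + rnorm(40, 0, 0.1), b + rnorm(40, 0, 0.1),
      200, seed = sample.int(1e6, 1)
    )$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("signed-rank test matches R's implementation and handles ties", {
  set.seed(15)
  x <- rnorm(40); y <- x + rnorm(40, 0.2)
  got <- wilcoxon_signed_rank(x, y)
  want <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE, correct = FALSE))
  expect_equal(got$p, want$p.value, tolerance = 1e-10)
  expect_equal(wilcoxon_signed_rank(x, x), list(z = 0, p = 1, n = 0L))
  # ties: rounded data still agrees with the tie-corrected reference
  xr <- round(x, 1); yr <- round(y, 1)
  gotr <- wilcoxon_signed_rank(xr, yr)
  wantr <- suppressWarnings(stats::wilcox.test(xr, yr, paired = TRUE,
                                               exact = FALSE, correct = FALSE))
  expect_equal(gotr$p, wantr$p.value, tolerance = 1e-10)
})

test_that("Steiger's test is zero for equal correlations and rejects sanely", {
  expect_equal(steiger_overlapping_r(0.5, 0.5, 0.3, 100)$z, 0)
  st <- steiger_overlapping_r(0.7, 0.2, 0.3, 100)
  expect_gt(st$z, 3)
  expect_lt(st$p, 0.01)
  expect_error(steiger_overlapping_r(0.5, 0.4, 0.3, 8), "n > 10")
  expect_error(steiger_overlapping_r(1, 0.4, 0.3, 100), "\\(-1, 1\\)")
})
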