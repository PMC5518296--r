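# Pearson and unbiased distance-correlation connectivity; mean regression
# and session harmonization.

test_that("Pearson connectivity equals the per-pair scalar oracle", {
  ses <- fake_session(R = 5, vox = 3, T = 50, seed = 1)
  pc <- pearson_connectivity(ses)
  means <- vapply(1:5, function(r) colMeans(roi_matrix(ses, r)), numeric(50))
  expect_equal(unclass(pc), cor(means), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(diag(unclass(pc))), rep(1, 5))

  # duplicated / negated ROI
  ses$data[ses$roi == 2, ] <- ses$data[ses$roi == 1, ]
  ses$data[ses$roi == 3, ] <- -ses$data[ses$roi == 1, ]
  pc <- pearson_connectivity(ses)
  expect_equal(pc[1, 2], 1)
  expect_equal(pc[1, 3], -1)

  # zero-variance ROI propagates NaN with a warning
  ses$data[ses$roi == 4, ] <- 1
  expect_warning(pcz <- pearson_connectivity(ses), "zero-variance")
  expect_true(all(is.nan(pcz[4, -4])))
})

test_that("unbiased distance correlation matches the double-loop oracle", {
  set.seed(2)
  for (i in 1:50) {
    T <- sample(6:20, 1)
    X <- matrix(rnorm(sample(1:4, 1) * T), ncol = T)
    Y <- matrix(rnorm(sample(1:4, 1) * T), ncol = T)
    got <- unbiased_dcor(X, Y)
    want <- dcor_oracle(X, Y)
    expect_equal(as.numeric(got), want$dcor, tolerance = 1e-12)
    expect_equal(attr(got, "dcor2_signed"), want$dcor2_signed, tolerance = 1e-12)
  }
})

test_that("distance correlation is exactly 1 for affinely related univariate inputs", {
  set.seed(3)
  x <- rnorm(30)
  expect_equal(as.numeric(unbiased_dcor(x, 2 * x)), 1, tolerance = 1e-12)
  expect_error(unbiased_dcor(rnorm(3), rnorm(3)), "3 timepoints")
})

test_that("unbiased estimator is centered at zero under independence", {
  set.seed(4)
  d2 <- replicate(300, {
    attr(unbiased_dcor(matrix(rnorm(3 * 40), 3), matrix(rnorm(3 * 40), 3)),
         "dcor2_signed")
  })
  expect_lt(abs(mean(d2)), 3 * sd(d2) / sqrt(length(d2)))
})

test_that("dcor connectivity matrix matches the pairwise operation", {
  ses <- fake_session(R = 4, vox = 3, T = 40, seed = 5)
  dc <- dcor_connectivity(ses)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(dc[i, j],
                   as.numeric(unbiased_dcor(roi_matrix(ses, i), roi_matrix(ses, j))),
                   tolerance = 1e-12)
    }
  }
  expect_equal(diag(unclass(dc)), rep(1, 4))
  # identical ROIs give 1; independent ROIs stay near zero
  ses$data[ses$roi == 2, ] <- ses$data[ses$roi == 1, ]
  expect_equal(dcor_connectivity(ses)[1, 2], 1, tolerance = 1e-12)
  ses2 <- fake_session(R = 8, vox = 3, T = 150, seed = 6)
  dc2 <- dcor_connectivity(ses2)
  expect_lt(mean(ut_test(unclass(dc2))), 0.1)
})

test_that("dcor is invariant to voxel order and argument order", {
  set.seed(7)
  X <- matrix(rnorm(4 * 30), 4)
  Y <- matrix(rnorm(3 * 30), 3)
  expect_equal(as.numeric(unbiased_dcor(X, Y)), as.numeric(unbiased_dcor(Y, X)),
               tolerance = 1e-12)
  expect_equal(as.numeric(unbiased_dcor(X[sample(4), ], Y)),
               as.numeric(unbiased_dcor(X, Y)), tolerance = 1e-12)
})

test_that("for single-voxel ROIs dcor approximates absolute Pearson correlation", {
  # population dCor for bivariate normals sits below |r| by up to ~0.05
  # (gap largest near |r| ~ 0.5-0.7), so the 0.05 equivalence band is
  # checked where it genuinely holds: strong correlations
  set.seed(8)
  for (rt in c(0.85, 0.9, 0.95)) {
    devs <- replicate(10, {
      x <- rnorm(261)
      y <- rt * x + sqrt(1 - rt^2) * rnorm(261)
      abs(as.numeric(unbiased_dcor(x, y)) - abs(cor(x, y)))
    })
    expect_lt(mean(devs), 0.05)
  }
})

test_that("mean regression equalizes participant means and is a projection", {
  mats <- fake_conn_list(12, 6, seed = 9)
  # plant a connection proportional to participant mean + noise
  m0 <- vapply(mats, function(x) mean(ut_test(x)), 0)
  for (i in seq_along(mats)) mats[[i]][1, 2] <- mats[[i]][2, 1] <- 2 * m0[i] + rnorm(1, 0, 1e-3)
  m <- vapply(mats, function(x) mean(ut_test(x)), 0)
  mr <- mean_regression(mats)
  mmr <- vapply(mr, function(x) mean(ut_test(unclass(x))), 0)
  expect_lt(var(mmr), 1e-20)
  expect_equal(mean(mmr), mean(m), tolerance = 1e-12)
  # planted connection decorrelated from participant means
  c12 <- vapply(mr, function(x) x[1, 2], 0)
  expect_lt(abs(cor(c12, m)), 1e-8)
  # idempotent (second pass sees zero-variance means and warns)
  expect_warning(mr2 <- mean_regression(mr), "identity")
  expect_equal(lapply(mr2, unclass), lapply(mr, unclass), tolerance = 1e-12,
               ignore_attr = TRUE)
  # identical participants: output equals input
  same <- fake_conn_list(1, 5, seed = 10)
  same <- rep(same, 4)
  expect_warning(mrs <- mean_regression(same), "identity")
  expect_equal(lapply(mrs, unclass), lapply(same, unclass), ignore_attr = TRUE)
})

test_that("session harmonization averages grand means, preserving differences", {
  s1 <- fake_conn_list(6, 5, seed = 11)
  s2 <- fake_conn_list(6, 5, seed = 12)
  g1 <- mean(vapply(s1, function(m) mean(ut_test(m)), 0))
  g2 <- mean(vapply(s2, function(m) mean(ut_test(m)), 0))
  h <- harmonize_session_means(s1, s2)
  ng1 <- mean(vapply(h$session1, function(m) mean(ut_test(as.matrix(m))), 0))
  ng2 <- mean(vapply(h$session2, function(m) mean(ut_test(as.matrix(m))), 0))
  expect_equal(ng1, (g1 + g2) / 2, tolerance = 1e-12)
  expect_equal(ng2, (g1 + g2) / 2, tolerance = 1e-12)
  # between-participant differences unchanged
  v_before <- ut_test(s1[[1]]) - ut_test(s1[[2]])
  v_after <- ut_test(as.matrix(h$session1[[1]])) - ut_test(as.matrix(h$session1[[2]]))
  expect_equal(v_after, v_before, tolerance = 1e-12)
  # idempotent; identical sessions unchanged
  h2 <- harmonize_session_means(h$session1, h$session2)
  expect_equal(lapply(h2$session1, unclass), lapply(h$session1, unclass),
               tolerance = 1e-12, ignore_attr = TRUE)
  hs <- harmonize_session_means(s1, s1)
  expect_equal(lapply(hs$session1, unclass), lapply(s1, unclass),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(harmonize_session_means(s1, fake_conn_list(6, 4)), "ROI set")
})
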