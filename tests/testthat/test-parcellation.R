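# Neighbor graphs, normalized-cut clustering, NMI, homogeneity,
# co-membership similarity.

# two well-separated signal blocks on a lattice line
two_block_session <- function(T = 50, seed = 1) {
  set.seed(seed)
  s1 <- rnorm(T); s2 <- rnorm(T)
  data <- rbind(
    matrix(rep(s1, 8), 8, T, byrow = TRUE) + 0.3 * matrix(rnorm(8 * T), 8),
    matrix(rep(s2, 8), 8, T, byrow = TRUE) + 0.3 * matrix(rnorm(8 * T), 8)
  )
  ijk <- cbind(c(1:8, 31:38), 1, 1)
  list(data = data, ijk = ijk, truth = rep(1:2, each = 8))
}

test_that("neighbor graph respects the lattice and the strict threshold", {
  tb <- two_block_session()
  g <- neighbor_graph(tb$data, tb$ijk, 0.5)
  expect_equal(igraph::components(g)$no, 2)   # blocks are disconnected
  # weights equal the pairwise-correlation oracle
  el <- igraph::as_edgelist(g)
  for (e in sample(nrow(el), 10)) {
    expect_equal(igraph::E(g)$weight[e],
                 cor(tb$data[el[e, 1], ], tb$data[el[e, 2], ]),
                 tolerance = 1e-12)
  }
  # strict inequality at the threshold: set the threshold to an edge's exact
  # weight and verify that edge disappears
  w1 <- igraph::E(g)$weight[1]
  g2 <- neighbor_graph(tb$data, tb$ijk, w1)
  expect_false(any(abs(igraph::E(g2)$weight - w1) < 1e-15))
  expect_error(neighbor_graph(tb$data, tb$ijk, 0.9999), "threshold")
})

test_that("ncut recovers planted blocks, is deterministic, handles edge cases", {
  tb <- two_block_session()
  g <- neighbor_graph(tb$data, tb$ijk, 0.5)
  p2 <- ncut_cluster(g, 2, seed = 1)
  expect_equal(nmi(p2$labels, tb$truth), 1)
  expect_identical(ncut_cluster(g, 2, seed = 1)$labels, p2$labels)
  p1 <- ncut_cluster(g, 1, seed = 1)
  expect_equal(p1$k_nonempty, 2L)   # two components cannot merge into one
  expect_error(ncut_cluster(g, 40, seed = 1), "voxel count")
  p4 <- ncut_cluster(g, 4, seed = 1)
  expect_lte(p4$k_nonempty, p4$k_requested)
})

test_that("group parcellation reproduces consensus and is seeded", {
  tb <- two_block_session()
  g <- neighbor_graph(tb$data, tb$ijk, 0.5)
  p <- ncut_cluster(g, 2, seed = 1)
  gp <- group_parcellation(list(p, p, p), 2, seed = 2)
  expect_equal(nmi(gp, p), 1)
  expect_identical(group_parcellation(list(p, p), 2, seed = 2)$labels,
                   group_parcellation(list(p, p), 2, seed = 2)$labels)
  # two orthogonal labelings: the output is no closer to one than the other
  set.seed(3)
  q1 <- p; q1$labels <- rep(1:2, times = 8)
  gp2 <- group_parcellation(list(p, q1), 2, seed = 4)
  expect_lt(abs(nmi(gp2, p) - nmi(gp2, q1)), 1 + 1e-9)  # both defined
  pbad <- p; pbad$ijk <- p$ijk + 1
  expect_error(group_parcellation(list(p, pbad), 2), "voxel set")
})

test_that("NMI: relabeling invariance, null level, contingency oracle, symmetry", {
  set.seed(5)
  l1 <- sample(1:4, 200, replace = TRUE)
  relab <- c(3, 1, 4, 2)[l1]
  expect_equal(nmi(l1, relab), 1, tolerance = 1e-12)
  # independent labelings at 1e4 voxels stay near zero
  a <- sample(1:10, 1e4, replace = TRUE)
  b <- sample(1:10, 1e4, replace = TRUE)
  expect_lt(nmi(a, b), 0.02)
  # contingency-table oracle on a 12-voxel fixture
  p1 <- c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  p2 <- c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 1, 1)
  tab <- table(p1, p2) / 12
  px <- rowSums(tab); py <- colSums(tab)
  mi <- 0
  for (i in 1:3) for (j in 1:3) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
  }
  want <- mi / sqrt(sum(-px * log(px)) * sum(-py * log(py)))
  expect_equal(nmi(p1, p2), unname(want), tolerance = 1e-12)
  expect_equal(nmi(p1, p2), nmi(p2, p1), tolerance = 1e-12)
  # single-cluster conventions
  expect_equal(nmi(rep(1, 10), rep(2, 10)), 1)
  expect_warning(v <- nmi(rep(1, 10), rep(1:2, 5)), "single-cluster")
  expect_equal(v, 0)
})

test_that("homogeneity: identical, independent and mixture ROIs", {
  T <- 1000
  set.seed(6)
  s <- rnorm(T)
  ses <- structure(list(
    data = rbind(matrix(rep(s, 3), 3, T, byrow = TRUE),
                 matrix(rnorm(3 * T), 3, T)),
    roi = rep(1:2, each = 3), tr = 2
  ), class = "fc_session")
  h <- homogeneity(ses)
  expect_equal(unname(h$per_roi[1]), 1)
  expect_lt(abs(h$per_roi[2]), 0.05)
  # a two-latent mixture ROI is less homogeneous than a pure one
  l1 <- rnorm(200); l2 <- rnorm(200)
  pure <- matrix(rep(l1, 4), 4, 200, byrow = TRUE) + 0.5 * matrix(rnorm(800), 4)
  mixed <- rbind(pure[1:2, ],
                 matrix(rep(l2, 2), 2, 200, byrow = TRUE) + 0.5 * matrix(rnorm(400), 2))
  ses2 <- structure(list(data = rbind(pure, mixed), roi = rep(1:2, each = 4),
                         tr = 2), class = "fc_session")
  h2 <- homogeneity(ses2)
  expect_lt(h2$per_roi[2], h2$per_roi[1])
  # single-voxel ROIs are excluded with a message
  ses3 <- structure(list(data = rbind(pure, rnorm(200)), roi = c(1, 1, 1, 1, 2),
                         tr = 2), class = "fc_session")
  expect_message(h3 <- homogeneity(ses3), "excluded")
  expect_true(is.na(h3$per_roi["2"]))
})

test_that("co-membership similarity: identical parcellations and planted noise", {
  tb <- two_block_session()
  g <- neighbor_graph(tb$data, tb$ijk, 0.5)
  p <- ncut_cluster(g, 2, seed = 1)
  ages <- seq(20, 80, length.out = 24)
  same <- rep(list(p), 24)
  cs <- comembership_similarity(same, ages, k = 5)
  expect_true(all(abs(cs$age_corr) < 1e-12))
  # label noise that increases with age lowers peer similarity with age
  set.seed(7)
  noisy <- lapply(seq_len(24), function(i) {
    q <- p
    nflip <- round((i - 1) / 23 * 6)
    if (nflip > 0) {
      idx <- sample(length(q$labels), nflip)
      q$labels[idx] <- 3 - q$labels[idx]
    }
    q
  })
  cs2 <- comembership_similarity(noisy, ages, k = 5, n_perm = 50, seed = 1)
  expect_lt(mean(cs2$age_corr), 0)
  expect_length(cs2$p, length(p$labels))
  cs2b <- comembership_similarity(noisy, ages, k = 5, n_perm = 50, seed = 1)
  expect_identical(cs2$p, cs2b$p)   # seeded permutations reproduce
  expect_error(comembership_similarity(same[1:10], ages[1:10], k = 3), "20")
})

test_that("parcellation peer NMI declines under age-increasing label noise", {
  tb <- two_block_session(seed = 8)
  g <- neighbor_graph(tb$data, tb$ijk, 0.5)
  p <- ncut_cluster(g, 4, seed = 1)
  ages <- seq(20, 80, length.out = 30)
  set.seed(9)
  noisy <- lapply(seq_len(30), function(i) {
    q <- p
    nflip <- round((i - 1) / 29 * 8)
    if (nflip > 0) {
      idx <- sample(length(q$labels), nflip)
      q$labels[idx] <- sample(4, nflip, replace = TRUE)
    }
    q
  })
  pn <- parcellation_peer_nmi(noisy, ages, k = 6)
  expect_lt(cor(pn, ages), 0)
})
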