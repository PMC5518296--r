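# Participant-specific parcellation: lattice neighbor-correlation graphs,
# normalized-cut spectral clustering, NMI, homogeneity, co-membership.

#' Neighborhood correlation graph over lattice voxels
#'
#' Correlates every voxel timeseries with those of its 26 lattice neighbors
#' and keeps edges with correlation strictly above `threshold`, weighted by
#' the correlation.
#'
#' @param voxel_data numeric matrix, voxels x timepoints.
#' @param ijk integer lattice coordinates, voxels x 3.
#' @param threshold correlation threshold (strict; default 0.5).
#' @return an undirected weighted `igraph` graph with vertex attribute
#'   coordinates; errors if no edge survives.
#' @export
neighbor_graph <- function(voxel_data, ijk, threshold = 0.5) {
  n <- nrow(voxel_data)
  if (ncol(voxel_data) < 3) stopf("need timeseries of length >= 3")
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
  lut <- stats::setNames(seq_len(n), key)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (h in seq_len(nrow(shifts))) {
    nb <- lut[paste(ijk[, 1] + shifts[h, 1], ijk[, 2] + shifts[h, 2],
                    ijk[, 3] + shifts[h, 3], sep = ",")]
    hit <- which(!is.na(nb) & nb > seq_len(n))   # each pair once
    pairs_i <- c(pairs_i, hit)
    pairs_j <- c(pairs_j, unname(nb[hit]))
  }
  X <- voxel_data - rowMeans(voxel_data)
  X <- X / sqrt(rowSums(X^2))
  w <- rowSums(X[pairs_i, , drop = FALSE] * X[pairs_j, , drop = FALSE])
  keep <- is.finite(w) & w > threshold
  if (!any(keep)) stopf("no neighbor correlation exceeds %.2f; lower the threshold", threshold)
  g <- igraph::graph_from_edgelist(cbind(pairs_i[keep], pairs_j[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  igraph::V(g)$x <- ijk[, 1]; igraph::V(g)$y <- ijk[, 2]; igraph::V(g)$z <- ijk[, 3]
  g
}

#' Normalized-cut spectral clustering of a voxel graph
#'
#' Embeds each connected component with the top eigenvectors of its
#' symmetric normalized adjacency and discretizes with seeded k-means
#' (20 restarts). The requested number of clusters is allocated to
#' components proportionally to their size (each component keeps at least
#' one cluster, so a graph with more components than `k` yields more than
#' `k` parcels). The result is deterministic given `seed`; empty clusters
#' can arise in principle and the realized count is reported.
#'
#' @param graph a [neighbor_graph()] result (or any weighted igraph graph).
#' @param k requested number of clusters.
#' @param seed RNG seed for the k-means discretization.
#' @return object of class `fc_parcellation`: list with `labels` (integer
#'   per voxel), `k_requested`, `k_nonempty`, `ijk`, `provenance`.
#' @export
ncut_cluster <- function(graph, k, seed = 1) {
  n <- igraph::vcount(graph)
  if (k > n) stopf("k (%d) exceeds the voxel count (%d)", k, n)
  comp <- igraph::components(graph)
  sizes <- comp$csize
  alloc <- pmax(1L, floor(k * sizes / n))
  while (sum(alloc) < k) {
    frac <- k * sizes / n - alloc
    cand <- which(frac == max(frac))[1]
    alloc[cand] <- alloc[cand] + 1L
  }
  while (sum(alloc) > k && any(alloc > 1)) {
    over <- which(alloc > 1)
    cand <- over[which.min((k * sizes / n - alloc)[over])]
    alloc[cand] <- alloc[cand] - 1L
  }
  alloc <- pmin(alloc, sizes)
  labels <- integer(n)
  offset <- 0L
  W_all <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  for (cidx in seq_along(sizes)) {
    vs <- which(comp$membership == cidx)
    kc <- alloc[cidx]
    if (kc <= 1 || length(vs) <= kc) {
      labels[vs] <- if (kc <= 1) offset + 1L else offset + seq_along(vs)
      offset <- offset + max(1L, min(kc, length(vs)))
      next
    }
    W <- as.matrix(W_all[vs, vs])
    d <- rowSums(W)
    d[d == 0] <- 1
    S <- W / sqrt(outer(d, d))
    e <- eigen(S, symmetric = TRUE)
    U <- e$vectors[, seq_len(kc), drop = FALSE]
    # fix eigenvector sign for reproducibility
    for (j in seq_len(kc)) {
      mx <- which.max(abs(U[, j]))
      if (U[mx, j] < 0) U[, j] <- -U[, j]
    }
    nrm <- sqrt(rowSums(U^2))
    nrm[nrm == 0] <- 1
    U <- U / nrm
    km <- with_seed(seed + cidx, stats::kmeans(U, centers = kc, nstart = 20,
                                               iter.max = 50))
    labels[vs] <- offset + km$cluster
    offset <- offset + kc
  }
  ijk <- cbind(igraph::V(graph)$x, igraph::V(graph)$y, igraph::V(graph)$z)
  structure(list(labels = labels, k_requested = as.integer(k),
                 k_nonempty = length(unique(labels)), ijk = ijk,
                 provenance = "ncut"),
            class = "fc_parcellation")
}

#' @export
print.fc_parcellation <- function(x, ...) {
  cat(sprintf("fc_parcellation: %d voxels, %d/%d non-empty clusters (%s)\n",
              length(x$labels), x$k_nonempty, x$k_requested, x$provenance))
  invisible(x)
}

#' Group-level parcellation from individual parcellations
#'
#' Builds a consensus graph in which the affinity of two lattice-neighbor
#' voxels is the fraction of input parcellations assigning them to the same
#' parcel, then applies normalized-cut clustering.
#'
#' @param parcellations list of `fc_parcellation` objects on the same voxels.
#' @param k requested cluster count.
#' @param seed RNG seed.
#' @return an `fc_parcellation` with provenance `"group"`.
#' @export
group_parcellation <- function(parcellations, k, seed = 1) {
  if (length(parcellations) < 2) stopf("need at least 2 parcellations")
  L <- vapply(parcellations, function(p) p$labels, parcellations[[1]]$labels)
  if (any(vapply(parcellations, function(p) length(p$labels), 0L) != nrow(L))) {
    stopf("parcellations cover different voxel sets")
  }
  ijk <- parcellations[[1]]$ijk
  for (p in parcellations) {
    if (!identical(dim(p$ijk), dim(ijk)) || any(p$ijk != ijk)) {
      stopf("parcellations cover different voxel sets")
    }
  }
  n <- nrow(L)
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")
  lut <- stats::setNames(seq_len(n), key)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  pi_ <- integer(0); pj_ <- integer(0)
  for (h in seq_len(nrow(shifts))) {
    nb <- lut[paste(ijk[, 1] + shifts[h, 1], ijk[, 2] + shifts[h, 2],
                    ijk[, 3] + shifts[h, 3], sep = ",")]
    hit <- which(!is.na(nb) & nb > seq_len(n))
    pi_ <- c(pi_, hit); pj_ <- c(pj_, unname(nb[hit]))
  }
  w <- rowMeans(L[pi_, , drop = FALSE] == L[pj_, , drop = FALSE])
  keep <- w > 0
  g <- igraph::graph_from_edgelist(cbind(pi_[keep], pj_[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[keep]
  igraph::V(g)$x <- ijk[, 1]; igraph::V(g)$y <- ijk[, 2]; igraph::V(g)$z <- ijk[, 3]
  out <- ncut_cluster(g, k, seed)
  out$provenance <- "group"
  out
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the geometric mean of the two label
#' entropies; 1 for identical assignments up to relabeling, near 0 for
#' independent labelings. If exactly one input has a single cluster the
#' value is 0 (with a warning); if both do, it is 1.
#'
#' @param p1,p2 `fc_parcellation` objects or integer label vectors of equal
#'   length.
#' @return scalar in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  l1 <- if (inherits(p1, "fc_parcellation")) p1$labels else as.integer(p1)
  l2 <- if (inherits(p2, "fc_parcellation")) p2$labels else as.integer(p2)
  if (length(l1) != length(l2)) stopf("labelings must cover the same voxels")
  n <- length(l1)
  tab <- table(l1, l2) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  h1 <- -sum(px * log(px))
  h2 <- -sum(py * log(py))
  if (h1 == 0 || h2 == 0) {
    if (h1 == 0 && h2 == 0) return(1)
    warnf("single-cluster labeling: NMI defined as 0")
    return(0)
  }
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  mi / sqrt(h1 * h2)
}

#' Within-ROI timeseries homogeneity
#'
#' Mean off-diagonal pairwise correlation between voxel timeseries within
#' each ROI. The subject summary averages per-ROI values on the Fisher-z
#' scale and back-transforms. Single-voxel ROIs are excluded (message).
#'
#' @param session an `fc_session`/`fc_residuals` object.
#' @param roi_set optional subset of ROI indices.
#' @return list with `per_roi` and `mean`.
#' @export
homogeneity <- function(session, roi_set = NULL) {
  rois <- roi_set %||% sort(unique(session$roi))
  vals <- rep(NA_real_, length(rois))
  skipped <- 0
  for (i in seq_along(rois)) {
    M <- roi_matrix(session, rois[i])
    if (nrow(M) < 2) { skipped <- skipped + 1; next }
    C <- suppressWarnings(stats::cor(t(M)))
    vals[i] <- mean(C[upper.tri(C)], na.rm = TRUE)
  }
  if (skipped > 0) message(skipped, " single-voxel ROI(s) excluded")
  list(per_roi = stats::setNames(vals, rois),
       mean = inv_fisher_z(mean(fisher_z(vals), na.rm = TRUE)))
}

#' Mean NMI of a participant's parcellation to age-matched peers
#'
#' For each participant, the average normalized mutual information between
#' their parcellation and those of the `k` nearest-age other participants
#' (ties broken by index). Declining values with age indicate increasing
#' idiosyncrasy in the location of functional regions.
#'
#' @param parcellations list of `fc_parcellation`, one per participant.
#' @param ages numeric participant ages.
#' @param k number of age-matched peers.
#' @return numeric vector of per-participant mean NMI values.
#' @export
parcellation_peer_nmi <- function(parcellations, ages, k = 30) {
  n <- length(parcellations)
  if (k >= n) stopf("k must be below the number of participants")
  P <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
    if (i >= j) 0 else nmi(parcellations[[i]], parcellations[[j]])
  }))
  P <- P + t(P)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(ages - ages[i])
    d[i] <- Inf
    peers <- order(d, seq_len(n))[seq_len(k)]
    out[i] <- mean(P[i, peers])
  }
  out
}

#' Age association of voxelwise parcel co-membership similarity
#'
#' For every voxel, each participant's binary co-membership vector (1 for
#' voxels sharing their parcel) is correlated with those of their `k`
#' nearest-age peers; similarities are averaged on the Fisher-z scale. The
#' function returns the per-voxel correlation of that peer similarity with
#' age, optionally with permutation p-values obtained by permuting age
#' labels.
#'
#' @param parcellations list of `fc_parcellation`, one per participant
#'   (at least 20).
#' @param ages numeric participant ages.
#' @param k number of age-matched peers.
#' @param n_perm permutations for per-voxel p-values (0 = none).
#' @param seed RNG seed for the permutations.
#' @return list with `age_corr` (per voxel) and optionally `p`.
#' @export
comembership_similarity <- function(parcellations, ages, k = 30,
                                    n_perm = 0, seed = 1) {
  n <- length(parcellations)
  if (n < 20) stopf("need at least 20 participants")
  if (k >= n) stopf("k must be below the number of participants")
  L <- vapply(parcellations, function(p) p$labels, parcellations[[1]]$labels)
  V <- nrow(L)
  peers <- lapply(seq_len(n), function(i) {
    d <- abs(ages - ages[i]); d[i] <- Inf
    order(d, seq_len(n))[seq_len(k)]
  })
  sim <- matrix(0, V, n)
  for (v in seq_len(V)) {
    B <- L == matrix(L[v, ], V, n, byrow = TRUE)   # co-membership with voxel v
    C <- suppressWarnings(stats::cor(B))
    C[!is.finite(C)] <- 0
    Z <- fisher_z(C)
    for (i in seq_len(n)) sim[v, i] <- inv_fisher_z(mean(Z[i, peers[[i]]]))
  }
  age_corr <- as.vector(suppressWarnings(stats::cor(t(sim), ages)))
  age_corr[!is.finite(age_corr)] <- 0   # constant similarity => no association
  out <- list(age_corr = age_corr)
  if (n_perm > 0) {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        as.vector(stats::cor(t(sim), sample(ages)))
      }, numeric(V))
    })
    out$p <- (1 + rowSums(abs(perm) >= abs(age_corr))) / (n_perm + 1)
  }
  out
}
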