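# shared fixtures and independent oracles (kept free of package internals
# so they can disagree with the implementation)

# one right triangle
tri1_spots <- function() spot_set(rbind(c(0, 0), c(1, 0), c(0, 1)))

# 3x3 unit grid
grid3_spots <- function() spot_set(as.matrix(expand.grid(x = 0:2, y = 0:2)))

# small jittered point cloud
cloud_spots <- function(n = 12, seed = 42) {
  set.seed(seed)
  spot_set(cbind(runif(n), runif(n)))
}

# a fake basis carrying an arbitrary penalty (for closed-form GCV cases)
fake_basis <- function(P) {
  structure(list(penalty = Matrix::Matrix(P), K = nrow(P)),
            class = "basis_system")
}

# brute-force average-linkage agglomeration: merge the pair of clusters
# with the smallest mean cross-pair distance while that distance is at
# most `h`; ties broken by smallest first-member index
oracle_average_linkage <- function(dist, h) {
  dist <- as.matrix(dist)
  clusters <- as.list(seq_len(nrow(dist)))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(dist[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > h + 1e-12) break
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(dist))
  for (p in seq_along(clusters)) labels[clusters[[p]]] <- p
  # renumber by first appearance, matching the package convention
  match(labels, unique(labels))
}

# coefficient matrix with planted module structure: module archetypes are
# independent random vectors, members are rank-preserving noisy copies
planted_coefs <- function(sizes, K = 30, noise = 0.01, seed = 7) {
  set.seed(seed)
  arch <- matrix(rnorm(length(sizes) * K), length(sizes), K)
  C <- do.call(rbind, lapply(seq_along(sizes), function(m) {
    t(replicate(sizes[m], arch[m, ] + rnorm(K, sd = noise)))
  }))
  rownames(C) <- paste0("g", seq_len(nrow(C)))
  list(C = C, truth = rep(seq_along(sizes), times = sizes))
}

# binary k-nearest-neighbour Moran's I (independent spatial statistic)
moran_i <- function(values, coords, k = 4) {
  n <- length(values)
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(d[i, ])[seq_len(k)]] <- 1
  z <- values - mean(values)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}
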