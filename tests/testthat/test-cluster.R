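test_that("spearman_distance matches the rank-formula hand case", {
  C <- rbind(a = c(1, 2, 3), b = c(1, 3, 2), c = c(3, 2, 1))
  gd <- spearman_distance(C)
  expect_equal(gd$rho["a", "b"], 0.5)          # 1 - 6*2/(3*8)
  expect_equal(gd$dist["a", "b"], 0.5)
  expect_equal(gd$rho["a", "c"], -1)           # strict reversal
  expect_equal(gd$dist["a", "c"], 2)
  expect_equal(unname(diag(gd$rho)), rep(1, 3))
  expect_equal(gd$dist, t(gd$dist))
  # identical rows: rho 1, distance 0
  gd2 <- spearman_distance(rbind(c(1, 5, 2, 4), c(1, 5, 2, 4), c(4, 1, 5, 2)))
  expect_equal(gd2$dist[1, 2], 0)
  # constant row errors with the gene named
  expect_error(spearman_distance(rbind(x = c(1, 1, 1), y = c(1, 2, 3))),
               "constant.*x")
})

test_that("make_alpha_grid spans the correlation range", {
  gd <- list(alpha_min = 0, alpha_max = 1)
  expect_equal(make_alpha_grid(gd, 5), c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(make_alpha_grid(gd, 2), c(0, 1))
  gd0 <- list(alpha_min = 0.3, alpha_max = 0.3)
  expect_warning(g <- make_alpha_grid(gd0, 7), "single-value")
  expect_equal(g, 0.3)
})

test_that("cut_hierarchy matches a brute-force average-linkage oracle", {
  # hand cases
  d3 <- matrix(0, 3, 3)                        # three identical genes
  expect_equal(cut_hierarchy(d3, 0.9), rep(1L, 3))
  d2g <- rbind(c(0, 0.01, 1.9, 1.9), c(0.01, 0, 1.9, 1.9),
               c(1.9, 1.9, 0, 0.01), c(1.9, 1.9, 0.01, 0))
  expect_equal(cut_hierarchy(d2g, 0.5), c(1L, 1L, 2L, 2L))
  # random instances, all G <= 8
  set.seed(21)
  for (rep in 1:25) {
    G <- sample(3:8, 1)
    M <- matrix(runif(G * G), G)
    d <- (M + t(M)); diag(d) <- 0
    alpha <- runif(1, -0.5, 0.9)
    expect_equal(cut_hierarchy(d, alpha),
                 oracle_average_linkage(d, 1 - alpha))
  }
})

test_that("compute_centers averages member rows (or picks medoids)", {
  C <- rbind(c(1, 2, 3, 4), c(3, 2, 1, 0), c(5, 5, 5, 8))
  expect_equal(compute_centers(c(1, 1, 2), C),
               rbind(c(2, 2, 2, 2), c(5, 5, 5, 8)))
  expect_equal(compute_centers(c(1, 2, 3), C), C)       # singletons
  expect_equal(compute_centers(c(1, 1, 2), rbind(C[1, ], -C[1, ], C[3, ]))[1, ],
               rep(0, 4))
  # medoid of 3 near-identical rows is a member row
  Cm <- rbind(c(1, 2, 3, 4), c(1.1, 2, 3, 4), c(1, 2, 3.2, 4))
  med <- compute_centers(rep(1, 3), Cm, method = "medoid")
  expect_true(any(apply(Cm, 1, identical, drop(med))))
})

test_that("merge_step unions co-clustering centers only", {
  K <- 10
  set.seed(31)
  r1 <- rnorm(K)
  r2 <- r1; r2[1:2] <- r2[2:1]            # rank-similar, not identical
  r3 <- -r1
  C <- rbind(r1, r1, r2, r2, r3, r3)
  labels <- c(1L, 1L, 2L, 2L, 3L, 3L)
  st <- list(labels = labels, centers = compute_centers(labels, C))
  rho12 <- cor(r1, r2, method = "spearman")  # just below 1
  # threshold above rho12: nothing merges
  st_hi <- merge_step(st, (1 + rho12) / 2, C)
  expect_equal(st_hi$labels, labels)
  # moderate threshold: clusters 1 and 2 (rank-correlated centers) merge
  st_lo <- merge_step(st, 0.8, C)
  expect_equal(st_lo$labels, c(1L, 1L, 1L, 1L, 2L, 2L))
  # identical centers always merge
  Cid <- rbind(r1, r1, r1, r1)
  stid <- list(labels = c(1L, 1L, 2L, 2L),
               centers = compute_centers(c(1L, 1L, 2L, 2L), Cid))
  expect_equal(merge_step(stid, 0.99, Cid)$labels, rep(1L, 4))
  # single cluster returned unchanged
  st1 <- list(labels = rep(1L, 4), centers = compute_centers(rep(1L, 4), Cid))
  expect_identical(merge_step(st1, 0.5, Cid), st1)
})

test_that("prune_step splits off poorly correlated members simultaneously", {
  K <- 12
  set.seed(32)
  arch <- rnorm(K)
  good <- t(replicate(4, arch + rnorm(K, sd = 0.01)))
  outlier <- sample(arch)                      # same values, scrambled ranks
  C <- rbind(good, outlier)
  labels <- rep(1L, 5)
  st <- list(labels = labels, centers = compute_centers(labels, C))
  out <- prune_step(st, 0.9, C)
  expect_equal(out$n_pruned, 1L)
  expect_equal(out$labels, c(1L, 1L, 1L, 1L, 2L))
  # all members satisfying the threshold: unchanged, S = 0
  st2 <- list(labels = rep(1L, 4), centers = compute_centers(rep(1L, 4), good))
  out2 <- prune_step(st2, 0.5, good)
  expect_equal(out2$n_pruned, 0L)
  expect_equal(out2$labels, rep(1L, 4))
  # singletons are never pruned
  st3 <- list(labels = 1:5, centers = compute_centers(1:5, C))
  expect_equal(prune_step(st3, 0.999, C)$labels, 1:5)
})

test_that("iterate_to_convergence reaches a checked fixpoint", {
  pc <- planted_coefs(c(5, 4, 3), K = 20, noise = 0.02, seed = 41)
  # plant one outlier into module 1
  set.seed(42)
  pc$C[1, ] <- sample(pc$C[1, ])
  gd <- spearman_distance(pc$C)
  alpha <- 0.8
  labels <- cut_hierarchy(gd$dist, alpha)
  st <- iterate_to_convergence(list(labels = labels,
                                    centers = compute_centers(labels, pc$C)),
                               alpha, pc$C)
  # one further merge+prune pass leaves labels unchanged
  st2 <- prune_step(merge_step(st, alpha, pc$C), alpha, pc$C)
  expect_equal(st2$labels, st$labels)
  # between-center correlations all below alpha
  if (nrow(st$centers) > 1L) {
    rho <- suppressWarnings(cor(t(st$centers), method = "spearman"))
    expect_lt(max(rho[upper.tri(rho)]), alpha)
  }
  # members of multi-gene clusters correlate with their center at >= alpha
  sizes <- table(st$labels)
  for (p in as.integer(names(sizes)[sizes >= 2])) {
    members <- which(st$labels == p)
    rho <- cor(t(pc$C[members, , drop = FALSE]), st$centers[p, ],
               method = "spearman")
    expect_true(all(rho >= alpha))
  }
  # the planted outlier ends up alone
  expect_equal(sum(st$labels == st$labels[1]), 1L)
})

test_that("silhouette_scores implements the formula and its conventions", {
  # hand case: A,B together, C alone
  d <- rbind(c(0, 0.1, 0.9), c(0.1, 0, 0.8), c(0.9, 0.8, 0))
  s <- silhouette_scores(c(1, 1, 2), d)
  expect_equal(s$sil[1], (0.9 - 0.1) / 0.9)
  expect_equal(s$sil[2], (0.8 - 0.1) / 0.8)
  expect_equal(s$sil[3], 0)                    # singleton convention
  expect_equal(s$mean, mean(c(8 / 9, 7 / 8, 0)))
  # two tight clusters: mean silhouette 1
  d2 <- matrix(1, 4, 4); d2[1:2, 1:2] <- 0; d2[3:4, 3:4] <- 0
  expect_equal(silhouette_scores(c(1, 1, 2, 2), d2)$mean, 1)
  # single-cluster sentinel
  expect_equal(silhouette_scores(rep(1, 4), d2)$mean, -1)
  # bounds on random partitions
  set.seed(51)
  for (rep in 1:20) {
    G <- sample(4:10, 1)
    M <- matrix(runif(G * G), G); dd <- M + t(M); diag(dd) <- 0
    lab <- sample(1:3, G, replace = TRUE)
    s <- silhouette_scores(lab, dd)
    expect_true(all(s$sil >= -1 & s$sil <= 1))
  }
})

test_that("run_stihc recovers planted structure and is deterministic", {
  pc <- planted_coefs(c(10, 10), K = 25, noise = 0.05, seed = 61)
  res <- run_stihc(pc$C, U = 15)
  expect_equal(adjusted_rand_index(res$labels, pc$truth), 1)
  # all genes identical: one cluster at every alpha
  Cid <- t(replicate(5, sin(seq_len(12))))       # 5 identical rows
  expect_warning(res_id <- run_stihc(Cid, U = 5), "single-value")
  expect_equal(length(unique(res_id$labels)), 1L)
  # determinism: identical repeated runs
  res2 <- run_stihc(pc$C, U = 15)
  expect_identical(res, res2)
  # alpha_opt maximizes mean silhouette, ties to the larger alpha
  pa <- res$per_alpha
  expect_equal(res$alpha_opt,
               max(pa$alpha[pa$mean_silhouette == max(pa$mean_silhouette)]))
})

test_that("imbalanced planted modules keep the 2-gene module separate", {
  pc <- planted_coefs(c(6, 2, 16, 25), K = 40, noise = 0.03, seed = 71)
  res <- run_stihc(pc$C, U = 20)
  expect_equal(adjusted_rand_index(res$labels, pc$truth), 1)
  two <- which(pc$truth == 2)
  expect_equal(unname(res$labels[two[1]]), unname(res$labels[two[2]]))
  expect_equal(sum(res$labels == res$labels[two[1]]), 2L)
})
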