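# renumber cluster labels 1..k in order of first appearance
.canonical_labels <- function(labels) {
  u <- unique(labels)
  out <- match(labels, u)
  names(out) <- names(labels)
  out
}

# Spearman correlation between rows of A and rows of B (or A with itself)
.spearman_rows <- function(A, B = NULL) {
  if (is.null(B)) stats::cor(t(A), method = "spearman")
  else stats::cor(t(A), t(B), method = "spearman")
}

#' Spearman distance between genes' coefficient vectors
#'
#' The dissimilarity between genes i and j is one minus the Spearman rank
#' correlation of their basis-coefficient rows, so genes whose smoothed
#' spatial fields rise and fall together are close regardless of scale.
#' Also records the range of off-diagonal correlations, which bounds the
#' grid of candidate clustering thresholds.
#'
#' @param C a `coef_matrix` from [fit_all()] or a plain G x K matrix with
#'   genes in rows.
#' @return object of class `gene_distance`: `rho` (G x G correlations),
#'   `dist` (1 - rho), `alpha_min`, `alpha_max`, `gene_ids`.
#' @export
spearman_distance <- function(C) {
  M <- if (inherits(C, "coef_matrix")) C$C else as.matrix(C)
  if (nrow(M) < 2L) stop("at least 2 genes are required")
  if (ncol(M) < 3L) stop("at least 3 coefficients per gene are required")
  rng <- apply(M, 1, function(r) diff(range(r)))
  if (any(rng == 0)) {
    ids <- rownames(M)
    if (is.null(ids)) ids <- as.character(which(rng == 0))
    stop("constant coefficient row(s); Spearman correlation undefined for: ",
         paste(utils::head(ids[rng == 0], 10L), collapse = ", "))
  }
  rho <- .spearman_rows(M)
  od <- rho[upper.tri(rho)]
  structure(list(rho = rho, dist = 1 - rho,
                 alpha_min = min(od), alpha_max = max(od),
                 gene_ids = rownames(M)),
            class = "gene_distance")
}

#' Grid of candidate correlation thresholds
#'
#' @param gd a `gene_distance`.
#' @param U number of equally spaced values spanning
#'   `[alpha_min, alpha_max]`, endpoints included.
#' @return numeric vector of length U (length 1 with a warning when the
#'   correlation range is degenerate).
#' @export
make_alpha_grid <- function(gd, U = 20L) {
  U <- as.integer(U)
  if (U < 1L) stop("U must be >= 1")
  if (gd$alpha_min == gd$alpha_max) {
    warning("all pairwise correlations equal; single-value alpha grid")
    return(gd$alpha_min)
  }
  if (U == 1L) return((gd$alpha_min + gd$alpha_max) / 2)
  seq(gd$alpha_min, gd$alpha_max, length.out = U)
}

#' Cut an average-linkage hierarchy at a correlation threshold
#'
#' Agglomerates with average linkage, merging while the linkage distance is
#' at most `1 - alpha`, and returns labels renumbered in first-gene order.
#'
#' @param dist square distance matrix (e.g. `gene_distance$dist`).
#' @param alpha correlation threshold.
#' @return integer vector of cluster labels.
#' @export
cut_hierarchy <- function(dist, alpha) {
  dist <- as.matrix(dist)
  G <- nrow(dist)
  if (G == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(dist), method = "average")
  # cutree(h) keeps merges with height <= h; nudge so exact ties merge
  h <- (1 - alpha) + 1e-12
  labels <- stats::cutree(hc, h = h)
  .canonical_labels(unname(labels))
}

#' Cluster centers in coefficient space
#'
#' The center of a cluster is the arithmetic mean of its members'
#' coefficient rows (`"mean"`, the default) or the member minimizing the
#' summed Spearman distance to the others (`"medoid"`).
#'
#' @param labels integer cluster labels over genes.
#' @param C G x K coefficient matrix (or `coef_matrix`).
#' @param method `"mean"` or `"medoid"`.
#' @return R x K matrix, row p = center of cluster p.
#' @export
compute_centers <- function(labels, C, method = c("mean", "medoid")) {
  method <- match.arg(method)
  M <- if (inherits(C, "coef_matrix")) C$C else as.matrix(C)
  ids <- sort(unique(labels))
  out <- matrix(NA_real_, length(ids), ncol(M))
  for (p in seq_along(ids)) {
    rows <- which(labels == ids[p])
    if (method == "mean" || length(rows) <= 2L) {
      out[p, ] <- colMeans(M[rows, , drop = FALSE])
    } else {
      d <- 1 - .spearman_rows(M[rows, , drop = FALSE])
      out[p, ] <- M[rows[which.min(rowSums(d))], ]
    }
  }
  out
}

# Spearman correlation of each gene with each center; centers that are
# constant (degenerate) get correlation 0 so they behave as maximally
# uninformative rather than erroring deep inside the iteration.
.gene_center_rho <- function(M, centers) {
  cr <- apply(centers, 1, function(r) diff(range(r)))
  ok <- cr > 0
  out <- matrix(0, nrow(M), nrow(centers))
  if (any(ok))
    out[, ok] <- .spearman_rows(M, centers[ok, , drop = FALSE])
  out
}

#' Merge clusters whose centers co-cluster
#'
#' Treats each cluster center as a pseudo-gene and reapplies the
#' average-linkage cut at the same threshold; clusters whose centers land
#' in one group are unioned and centers recomputed.
#'
#' @param state list with `labels` and `centers`.
#' @param alpha correlation threshold.
#' @param C coefficient matrix.
#' @param center_method passed to [compute_centers()].
#' @return updated state list (`labels`, `centers`, `n_clusters`).
#' @export
merge_step <- function(state, alpha, C, center_method = "mean") {
  centers <- state$centers
  if (nrow(centers) <= 1L) return(state)
  rho <- .spearman_rows(centers)
  rho[!is.finite(rho)] <- 0
  grp <- cut_hierarchy(1 - rho, alpha)
  if (length(unique(grp)) == nrow(centers)) return(state)
  labels <- .canonical_labels(grp[state$labels])
  centers <- compute_centers(labels, C, center_method)
  list(labels = labels, centers = centers, n_clusters = nrow(centers))
}

#' Prune members poorly correlated with their cluster center
#'
#' Every gene in a multi-gene cluster whose Spearman correlation with the
#' cluster's center (as of entry to the pass) falls below the threshold is
#' split off into its own singleton cluster; removals are simultaneous and
#' centers are recomputed once afterwards, so the result does not depend
#' on gene order.
#'
#' @inheritParams merge_step
#' @return updated state; attribute `n_pruned` counts removed genes.
#' @export
prune_step <- function(state, alpha, C, center_method = "mean") {
  M <- if (inherits(C, "coef_matrix")) C$C else as.matrix(C)
  labels <- state$labels
  sizes <- table(labels)
  multi <- as.integer(names(sizes)[sizes >= 2L])
  if (length(multi) == 0L) { state$n_pruned <- 0L; return(state) }
  rho <- .gene_center_rho(M, state$centers)
  drop_gene <- rep(FALSE, length(labels))
  for (p in multi) {
    members <- which(labels == p)
    drop_gene[members] <- rho[members, p] < alpha
  }
  S <- sum(drop_gene)
  if (S > 0L) {
    labels[drop_gene] <- max(labels) + seq_len(S)
    labels <- .canonical_labels(labels)
  }
  centers <- compute_centers(labels, C, center_method)
  out <- list(labels = labels, centers = centers, n_clusters = nrow(centers))
  out$n_pruned <- S
  out
}

#' Iterate merge and prune to a fixpoint
#'
#' Alternates [merge_step()] and [prune_step()] until the assignment stops
#' changing, then applies merge-only passes until every pair of cluster
#' centers has Spearman correlation below the threshold. Both loops are
#' capped; hitting the cap returns the current state with a warning.
#'
#' @param state initial state from the hierarchy cut.
#' @param alpha correlation threshold.
#' @param C coefficient matrix.
#' @param center_method passed to [compute_centers()].
#' @param max_pass iteration cap for each loop.
#' @return converged state list.
#' @export
iterate_to_convergence <- function(state, alpha, C, center_method = "mean",
                                   max_pass = 100L) {
  for (i in seq_len(max_pass)) {
    prev <- state$labels
    state <- merge_step(state, alpha, C, center_method)
    state <- prune_step(state, alpha, C, center_method)
    if (identical(.canonical_labels(prev), state$labels)) break
    if (i == max_pass)
      warning("merge/prune did not converge in ", max_pass, " passes")
  }
  for (i in seq_len(max_pass)) {
    prev <- state$labels
    state <- merge_step(state, alpha, C, center_method)
    if (identical(.canonical_labels(prev), state$labels)) break
    if (i == max_pass)
      warning("final merge passes did not converge in ", max_pass, " passes")
  }
  state
}

#' Silhouette scores of a partition
#'
#' For gene i, `a_i` is its mean distance to co-members and `b_i` the
#' smallest mean distance to any other cluster;
#' `sil_i = (b_i - a_i) / max(a_i, b_i)`, in `[-1, 1]`. Singleton genes
#' score 0 (the neutral convention, so deliberately created singletons
#' neither reward nor punish a threshold). A single-cluster partition has
#' mean silhouette defined as -1 so it is never selected.
#'
#' @param labels cluster labels.
#' @param dist square distance matrix over the genes.
#' @return list with `sil` (per-gene scores), `a`, `b`, `mean`.
#' @export
silhouette_scores <- function(labels, dist) {
  dist <- as.matrix(dist)
  G <- length(labels)
  if (nrow(dist) != G) stop("labels and dist dimensions differ")
  ids <- sort(unique(labels))
  if (length(ids) < 2L) {
    return(list(sil = rep(0, G), a = rep(NA_real_, G), b = rep(NA_real_, G),
                mean = -1))
  }
  a <- b <- rep(NA_real_, G)
  sil <- rep(0, G)
  memb <- lapply(ids, function(p) which(labels == p))
  for (i in seq_len(G)) {
    own <- labels[i]
    mine <- memb[[match(own, ids)]]
    if (length(mine) == 1L) { sil[i] <- 0; next }
    a[i] <- mean(dist[i, setdiff(mine, i)])
    b[i] <- min(vapply(memb[ids != own], function(m) mean(dist[i, m]),
                       numeric(1)))
    sil[i] <- (b[i] - a[i]) / max(a[i], b[i])
  }
  list(sil = sil, a = a, b = b, mean = mean(sil))
}

#' Iterative hierarchical clustering of genes into spatial modules
#'
#' The full second stage: Spearman distances between coefficient rows; a
#' grid of U candidate thresholds spanning the observed correlation range;
#' for each threshold an average-linkage cut followed by merge/prune
#' iteration to a fixpoint; and selection of the threshold maximizing the
#' mean silhouette (ties break toward the larger threshold, i.e. the finer
#' partition). Entirely deterministic: repeated runs on the same input
#' give identical results.
#'
#' @param C a `coef_matrix` or G x K matrix of basis coefficients.
#' @param U size of the threshold grid.
#' @param center_method cluster-center rule, `"mean"` or `"medoid"`.
#' @return object of class `stihc_result`: `labels` (named by gene),
#'   `alpha_opt`, `per_alpha` (data frame of alpha, n_clusters,
#'   mean_silhouette), `per_gene_sil`, `gene_ids`, `cluster_sizes`.
#' @export
run_stihc <- function(C, U = 20L, center_method = c("mean", "medoid")) {
  center_method <- match.arg(center_method)
  M <- if (inherits(C, "coef_matrix")) C$C else as.matrix(C)
  gd <- spearman_distance(M)
  grid <- make_alpha_grid(gd, U)
  nA <- length(grid)
  res_labels <- vector("list", nA)
  msil <- numeric(nA)
  ncl <- integer(nA)
  for (u in seq_len(nA)) {
    alpha <- grid[u]
    labels <- cut_hierarchy(gd$dist, alpha)
    state <- list(labels = labels,
                  centers = compute_centers(labels, M, center_method))
    state <- iterate_to_convergence(state, alpha, M, center_method)
    res_labels[[u]] <- state$labels
    ncl[u] <- length(unique(state$labels))
    msil[u] <- silhouette_scores(state$labels, gd$dist)$mean
  }
  best <- max(msil)
  u_opt <- max(which(msil == best))      # ties toward the larger alpha
  labels <- res_labels[[u_opt]]
  names(labels) <- gd$gene_ids
  sil <- silhouette_scores(labels, gd$dist)
  structure(list(labels = labels, alpha_opt = grid[u_opt],
                 per_alpha = data.frame(alpha = grid, n_clusters = ncl,
                                        mean_silhouette = msil),
                 per_gene_sil = sil, gene_ids = gd$gene_ids,
                 cluster_sizes = as.integer(table(labels))),
            class = "stihc_result")
}

#' @export
print.stihc_result <- function(x, ...) {
  cat("stihc_result:", length(unique(x$labels)), "modules over",
      length(x$labels), "genes; alpha_opt =", format(x$alpha_opt),
      "; mean silhouette =", format(max(x$per_alpha$mean_silhouette)), "\n")
  cat("module sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}
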