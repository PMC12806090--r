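#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement (Hubert-Arabie form) computed from the
#' contingency table of the two labelings. 1 means identical partitions;
#' values near 0 are chance-level; negative values are worse than chance.
#' Invariant to relabeling of either partition.
#'
#' @param labels_a,labels_b equal-length cluster assignments over the same
#'   items.
#' @return the ARI.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must have equal length")
  n <- length(labels_a)
  if (n < 2L) stop("at least 2 items are required")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  total <- n * (n - 1) / 2
  expected <- sum_a * sum_b / total
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)       # both partitions all-singletons or all-one
  (sum_ij - expected) / (maxi - expected)
}

#' Davies-Bouldin index of a clustering
#'
#' Mean over clusters of the worst-case ratio
#' \eqn{(\sigma_p + \sigma_q) / d(\mu_p, \mu_q)}, where \eqn{\sigma_p} is
#' the mean Euclidean distance of cluster members to their centroid and
#' \eqn{d} the Euclidean distance between centroids. Lower is better. By
#' default the feature space is the matrix the clustering ran on (here,
#' basis coefficients).
#'
#' @param features G x K numeric matrix (rows = items).
#' @param labels cluster assignment.
#' @return the DBI (nonnegative).
#' @export
davies_bouldin <- function(features, labels) {
  features <- if (inherits(features, "coef_matrix")) features$C
              else as.matrix(features)
  ids <- sort(unique(labels))
  R <- length(ids)
  if (R < 2L) stop("Davies-Bouldin requires at least 2 clusters")
  cent <- t(vapply(ids, function(p)
    colMeans(features[labels == p, , drop = FALSE]), numeric(ncol(features))))
  sig <- vapply(seq_len(R), function(p) {
    rows <- features[labels == ids[p], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cent[p, ])^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(cent))
  if (any(dc[upper.tri(dc)] == 0))
    stop("coincident cluster centroids; DBI undefined (clusters ",
         "indistinguishable in feature space)")
  ratio <- outer(sig, sig, "+") / dc
  diag(ratio) <- -Inf
  mean(apply(ratio, 1, max))
}

#' Per-cluster mean spatial expression patterns
#'
#' Standardizes each gene's expression across spots (zero mean, unit
#' variance), averages within clusters, and optionally refits the mean
#' profile through the basis for a smoothed surface — the standard way to
#' display what spatial pattern a module represents.
#'
#' @param Y G x n expression matrix (genes x spots).
#' @param labels cluster assignment over the rows of Y.
#' @param basis optional `basis_system`; when supplied a smoothed surface
#'   (fitted at the unified-lambda default grid midpoint) is returned.
#' @param standardize standardize genes before averaging (default TRUE).
#' @return list with `means` (clusters x spots matrix, rows named by
#'   cluster id) and `smoothed` (same shape, or NULL).
#' @export
cluster_mean_patterns <- function(Y, labels, basis = NULL,
                                  standardize = TRUE) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(labels)) stop("labels must cover the rows of Y")
  sds <- apply(Y, 1, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " zero-variance gene(s)")
    Y <- Y[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  Z <- if (standardize) t(scale(t(Y))) else Y
  ids <- sort(unique(labels))
  means <- t(vapply(ids, function(p)
    colMeans(Z[labels == p, , drop = FALSE]), numeric(ncol(Z))))
  rownames(means) <- ids
  smoothed <- NULL
  if (!is.null(basis)) {
    cfg <- fit_config(family = "normal")
    fit <- fit_all(means, basis, cfg)
    smoothed <- fit$C %*% t(as.matrix(
      evaluate_basis(basis$mesh, basis$mesh$nodes)))
    rownames(smoothed) <- ids
  }
  list(means = means, smoothed = smoothed)
}
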