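# run expr with a private RNG stream seeded by `seed`, restoring any
# pre-existing state afterwards (generation never perturbs the session RNG)
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Jittered rectangular spot grid
#'
#' Stand-in for a spatial transcriptomics spot lattice: an `nx` x `ny`
#' lattice on the unit square with optional uniform jitter (as a fraction
#' of the lattice spacing), deterministic under the seed.
#'
#' @param nx,ny lattice dimensions (>= 2).
#' @param jitter jitter amplitude as a fraction of the spacing (0 = exact
#'   lattice; values near 1 risk spot collisions, which error).
#' @param seed RNG seed.
#' @return a [spot_set()] with `nx * ny` spots.
#' @export
make_spot_grid <- function(nx, ny, jitter = 0, seed = 1L) {
  if (nx < 2L || ny < 2L) stop("nx and ny must be >= 2")
  g <- expand.grid(x = seq(0, 1, length.out = nx),
                   y = seq(0, 1, length.out = ny))
  h <- min(1 / (nx - 1), 1 / (ny - 1))
  if (jitter > 0) {
    g <- .with_seed(seed, {
      g$x <- g$x + stats::runif(nrow(g), -jitter / 2, jitter / 2) * h
      g$y <- g$y + stats::runif(nrow(g), -jitter / 2, jitter / 2) * h
      g
    })
  }
  tryCatch(spot_set(as.matrix(g), dedup_tol = 1e-9 * h),
           error = function(e) stop("jitter caused colliding spots: ",
                                    conditionMessage(e)))
}

# one smooth nonnegative field of the given kind on [0,1]^2 coordinates
.pattern_field <- function(coords, kind) {
  x <- coords[, 1]; y <- coords[, 2]
  f <- switch(kind,
    bump = {
      cx <- stats::runif(1, 0.2, 0.8); cy <- stats::runif(1, 0.2, 0.8)
      s <- stats::runif(1, 0.12, 0.2)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
    },
    band = {
      th <- stats::runif(1, 0, pi)
      c0 <- stats::runif(1, 0.25, 0.75)
      w <- stats::runif(1, 0.08, 0.15)
      pr <- x * cos(th) + y * sin(th)
      exp(-(pr - c0)^2 / (2 * w^2))
    },
    plateau = {
      cx <- sample(c(0, 1), 1); cy <- sample(c(0, 1), 1)
      r0 <- stats::runif(1, 0.35, 0.55)
      tau <- 0.06
      r <- sqrt((x - cx)^2 + (y - cy)^2)
      1 / (1 + exp((r - r0) / tau))
    },
    ring = {
      cx <- stats::runif(1, 0.35, 0.65); cy <- stats::runif(1, 0.35, 0.65)
      r0 <- stats::runif(1, 0.25, 0.4)
      w <- stats::runif(1, 0.06, 0.12)
      r <- sqrt((x - cx)^2 + (y - cy)^2)
      exp(-(r - r0)^2 / (2 * w^2))
    },
    stop("unknown pattern kind: ", kind))
  f <- f - min(f)
  f / max(f)
}

#' Distinct smooth spatial mean patterns
#'
#' Generates `n_patterns` smooth nonnegative fields over the spots, cycling
#' through four geometries (Gaussian bump, oriented band, corner plateau,
#' ring) with placements drawn deterministically from the seed. Placements
#' are redrawn (up to 50 attempts) until all pairwise Spearman
#' correlations between patterns are at most 0.5, guaranteeing genuinely
#' distinct module archetypes.
#'
#' @param spots a [spot_set()].
#' @param n_patterns number of patterns (>= 1).
#' @param seed RNG seed.
#' @param max_rho separation requirement on pairwise |Spearman| (0.5).
#' @return `n_patterns` x n matrix, rows scaled to `[0, 1]`.
#' @export
make_patterns <- function(spots, n_patterns, seed = 1L, max_rho = 0.5) {
  if (n_patterns < 1L) stop("n_patterns must be >= 1")
  kinds <- rep(c("bump", "band", "plateau", "ring"),
               length.out = n_patterns)
  coords <- spots$coords
  .with_seed(seed, {
    for (attempt in seq_len(50L)) {
      pat <- t(vapply(kinds, function(k) .pattern_field(coords, k),
                      numeric(nrow(coords))))
      if (n_patterns == 1L) return(pat)
      rho <- .spearman_rows(pat)
      if (max(abs(rho[upper.tri(rho)])) <= max_rho) {
        rownames(pat) <- paste0("pattern_", seq_len(n_patterns))
        return(pat)
      }
    }
    stop("could not achieve pattern separation |rho| <= ", max_rho,
         " in 50 attempts")
  })
}

#' Simulate gene expression with known module structure
#'
#' Each gene in module m has spot-wise mean
#' `spatial_fraction * mu_m(s) + (1 - spatial_fraction) * mu_m(perm(s))`,
#' where `perm` is one seed-fixed random spot permutation — a spatially
#' scrambled copy of the same intensity distribution, so
#' `spatial_fraction` interpolates between a fully spatial mean (1) and a
#' spatially uninformative one (0). Means are scaled to a target average
#' count depth with a mild per-gene depth factor, and counts are drawn
#' from the configured noise model.
#'
#' @param patterns pattern matrix from [make_patterns()].
#' @param module_sizes integer vector of genes per pattern (all >= 1).
#' @param spots the [spot_set()] the patterns live on.
#' @param noise list: `family` `"nb"` (negative binomial, default,
#'   dispersion `theta = 10`: var = mu + mu^2/theta) or `"normal"`
#'   (`sigma`); see Details in the package vignette.
#' @param spatial_fraction mixing weight in `[0, 1]`.
#' @param seed RNG seed.
#' @param target_mean average expected count per spot (default 5).
#' @return object of class `sim_result`: `expression` (G x n count
#'   matrix), `truth_labels`, `patterns`, `spots`, `mu` (G x n expected
#'   values).
#' @export
simulate_genes <- function(patterns, module_sizes, spots,
                           noise = list(family = "nb", theta = 10),
                           spatial_fraction = 1, seed = 1L,
                           target_mean = 5) {
  patterns <- as.matrix(patterns)
  if (length(module_sizes) != nrow(patterns))
    stop("module_sizes must have one entry per pattern")
  if (any(module_sizes < 1L)) stop("module sizes must be >= 1")
  if (spatial_fraction < 0 || spatial_fraction > 1)
    stop("spatial_fraction must be in [0, 1]")
  n <- ncol(patterns)
  G <- sum(module_sizes)
  truth <- rep(seq_along(module_sizes), times = module_sizes)
  .with_seed(seed, {
    perm <- sample.int(n)
    depth <- stats::runif(G, 0.8, 1.2)   # mild per-gene library-depth variation
    Y <- matrix(0, G, n)
    mu_mat <- matrix(0, G, n)
    for (g in seq_len(G)) {
      base <- patterns[truth[g], ]
      mixed <- spatial_fraction * base + (1 - spatial_fraction) * base[perm]
      rel <- 0.2 + mixed                 # floor keeps count means positive
      mu <- target_mean * depth[g] * rel / mean(rel)
      mu_mat[g, ] <- mu
      Y[g, ] <- if (identical(noise$family, "normal")) {
        stats::rnorm(n, mu, noise$sigma)
      } else {
        theta <- if (is.null(noise$theta)) 10 else noise$theta
        stats::rnbinom(n, mu = mu, size = theta)
      }
    }
    rownames(Y) <- rownames(mu_mat) <-
      sprintf("gene_%03d_m%d", seq_len(G), truth)
    colnames(Y) <- colnames(mu_mat) <- spots$spot_ids
    structure(list(expression = Y, truth_labels = truth,
                   patterns = patterns, spots = spots, mu = mu_mat,
                   spatial_fraction = spatial_fraction),
              class = "sim_result")
  })
}

#' Randomly subsample spatial locations
#'
#' Emulates sparse spatial resolution by keeping a uniform random subset
#' of spots (columns) without replacement; deterministic under the seed.
#'
#' @param result a `sim_result`.
#' @param m number of spots to keep (3 <= m <= n).
#' @param seed RNG seed.
#' @return a `sim_result` restricted to the sampled spots.
#' @export
subsample_spots <- function(result, m, seed = 1L) {
  n <- ncol(result$expression)
  if (m > n) stop("m exceeds the number of spots")
  if (m < 3L) stop("at least 3 spots are required for a mesh")
  if (m == n) return(result)
  keep <- .with_seed(seed, sort(sample.int(n, m)))
  result$expression <- result$expression[, keep, drop = FALSE]
  result$mu <- result$mu[, keep, drop = FALSE]
  result$patterns <- result$patterns[, keep, drop = FALSE]
  result$spots <- spot_set(result$spots$coords[keep, , drop = FALSE],
                           result$spots$spot_ids[keep])
  result
}

#' Preset simulation scenarios
#'
#' Three stated scenarios with four pattern archetypes on a jittered
#' 30 x 30 grid: `balanced` (module sizes 25/25/25/25, 100 genes),
#' `imbalanced` (6/2/16/25, 49 genes), and `sparse` (the imbalanced gene
#' set with 260 randomly retained spots). All use `spatial_fraction = 1`
#' and negative-binomial counts.
#'
#' @param preset `"balanced"`, `"imbalanced"`, or `"sparse"`.
#' @param seed RNG seed driving grid jitter, pattern placement, counts,
#'   and (for `sparse`) the spot subsample.
#' @param nx,ny grid dimensions (default 30 x 30).
#' @return a `sim_result`.
#' @export
simulate_scenario <- function(preset = c("balanced", "imbalanced", "sparse"),
                              seed = 1L, nx = 30L, ny = 30L) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
                  balanced = c(25L, 25L, 25L, 25L),
                  imbalanced = c(6L, 2L, 16L, 25L),
                  sparse = c(6L, 2L, 16L, 25L))
  seed <- as.integer(seed)
  spots <- make_spot_grid(nx, ny, jitter = 0.3, seed = seed)
  pat <- make_patterns(spots, 4L, seed = seed + 1L)
  res <- simulate_genes(pat, sizes, spots, spatial_fraction = 1,
                        seed = seed + 2L)
  if (preset == "sparse") res <- subsample_spots(res, 260L, seed = seed + 3L)
  res
}
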