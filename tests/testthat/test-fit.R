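test_that("normal fit matches the dense closed-form solve and interpolates", {
  ss <- cloud_spots(12, 3)
  bs <- basis_system(ss)
  phi <- evaluate_basis(bs, ss$coords)
  set.seed(1)
  y <- rnorm(12)
  for (lam in c(1e-3, 0.1, 10)) {
    f <- fit_gene(y, bs, phi, lam)
    # independent dense oracle
    Pd <- as.matrix(bs$penalty); Phid <- as.matrix(phi)
    c_oracle <- solve(crossprod(Phid) + lam * Pd, crossprod(Phid, y))
    expect_equal(f$coefficients, drop(c_oracle), tolerance = 1e-8)
    expect_true(f$converged)
  }
  # lambda -> 0: interpolation (phi is the identity here)
  f0 <- fit_gene(y, bs, phi, 1e-12)
  expect_equal(f0$coefficients, y, tolerance = 1e-6)
  # lambda -> inf: constant field at the mean (projection onto null(P));
  # 1e8 stays within the numerically safe range of the penalized solve
  finf <- fit_gene(y, bs, phi, 1e8)
  expect_equal(finf$fitted_mean, rep(mean(y), 12), tolerance = 5e-3)
})

test_that("poisson PIRLS matches a generic-optimizer oracle on a 6-spot mesh", {
  ss <- cloud_spots(6, 8)
  bs <- basis_system(ss)
  phi <- evaluate_basis(bs, ss$coords)
  set.seed(2)
  y <- rpois(6, lambda = c(2, 5, 9, 3, 7, 4))
  lam <- 0.5
  f <- fit_gene(y, bs, phi, lam, fit_config("poisson"))
  Pd <- as.matrix(bs$penalty); Phid <- as.matrix(phi)
  obj <- function(cc) {             # penalized poisson deviance, brute force
    mu <- exp(drop(Phid %*% cc))
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu)) +
      lam * drop(cc %*% (Pd %*% cc))
  }
  o <- optim(f$coefficients + 0.3, obj, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-14))
  expect_equal(f$coefficients, o$par, tolerance = 1e-4)
  expect_true(all(f$fitted_mean > 0))
  # negative counts refuse
  expect_error(fit_gene(c(-1, y[-1]), bs, phi, lam, fit_config("poisson")),
               "nonnegative")
})

test_that("GCV reproduces the hand-computed identity-design case", {
  bs <- fake_basis(diag(2))
  phi <- Matrix::Diagonal(2)
  f <- fit_gene(c(2, 2), bs, phi, 1)
  # H = (I + I)^-1 = I/2, tr H = 1, RSS = 2 => GCV = 2*2/(2-1)^2 = 4
  expect_equal(f$edf, 1, tolerance = 1e-12)
  expect_equal(gcv_score(f, 2), 4, tolerance = 1e-12)
  expect_equal(f$gcv, 4, tolerance = 1e-12)
})

test_that("hat trace and roughness are monotone in lambda", {
  ss <- cloud_spots(15, 4)
  bs <- basis_system(ss)
  phi <- evaluate_basis(bs, ss$coords)
  set.seed(5)
  y <- rnorm(15)
  grid <- 10^seq(-4, 4, length.out = 9)
  fits <- lapply(grid, function(l) fit_gene(y, bs, phi, l))
  edf <- vapply(fits, `[[`, 0, "edf")
  rough <- vapply(fits, `[[`, 0, "penalty")
  expect_true(all(diff(edf) <= 1e-8))
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("small-noise normal data recovers the generating coefficients", {
  ss <- cloud_spots(25, 6)
  bs <- basis_system(ss)
  phi <- evaluate_basis(bs, ss$coords)
  set.seed(9)
  cstar <- sin(ss$coords[, 1] * 3) + ss$coords[, 2]
  err <- vapply(c(1e-2, 1e-4), function(sigma) {
    y <- drop(as.matrix(phi %*% cstar)) + rnorm(25, sd = sigma)
    max(abs(fit_gene(y, bs, phi, 1e-10)$coefficients - cstar))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 1e-3)
})

test_that("select_lambda minimizes the summed criterion on the grid", {
  ss <- cloud_spots(10, 10)
  bs <- basis_system(ss)
  phi <- evaluate_basis(bs, ss$coords)
  set.seed(11)
  Y <- matrix(rnorm(5 * 10, mean = rep(ss$coords[, 1], each = 5)), 5, 10)
  grid <- c(0.01, 1, 100)
  cfg <- fit_config(lambda_grid = grid)
  sel <- select_lambda(Y, bs, phi, cfg)
  # exhaustive oracle: per-gene dense GCV at each grid point
  Pd <- as.matrix(bs$penalty)
  gcv_oracle <- sapply(grid, function(l) {
    H <- solve(diag(10) + l * Pd)
    sapply(seq_len(5), function(g) {
      mu <- H %*% Y[g, ]
      10 * sum((Y[g, ] - mu)^2) / (10 - sum(diag(H)))^2
    })
  })
  expect_equal(unname(sel$per_gene_gcv), unname(gcv_oracle), tolerance = 1e-8)
  expect_equal(sel$lambda_opt, grid[which.min(colSums(gcv_oracle))])
  # single gene: the gene's own argmin; duplicated gene: unchanged argmin
  s1 <- select_lambda(Y[1, , drop = FALSE], bs, phi, cfg)
  expect_equal(s1$lambda_opt, grid[which.min(gcv_oracle[1, ])])
  s2 <- select_lambda(Y[c(1, 1), ], bs, phi, cfg)
  expect_equal(s2$lambda_opt, s1$lambda_opt)
})

test_that("fit_all assembles aligned coefficient rows deterministically", {
  ss <- cloud_spots(10, 12)
  bs <- basis_system(ss)
  set.seed(13)
  Y <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("a", "b", "c"), ss$spot_ids))
  cm <- fit_all(Y, bs)
  expect_identical(dim(cm$C), c(3L, 10L))
  expect_identical(cm$gene_ids, c("a", "b", "c"))
  # G = 1 equals fit_gene at the same lambda
  phi <- evaluate_basis(bs, ss$coords)
  f <- fit_gene(Y[1, ], bs, phi, cm$lambda_opt)
  cm1 <- fit_all(Y[1, , drop = FALSE], bs,
                 fit_config(lambda_grid = cm$lambda_opt))
  expect_equal(unname(cm1$C[1, ]), f$coefficients, tolerance = 1e-10)
  # permuting gene rows permutes coefficient rows identically
  cmp <- fit_all(Y[c(3, 1, 2), ], bs)
  expect_equal(cmp$C, cm$C[c(3, 1, 2), ], tolerance = 1e-12)
  # fast identity-phi path agrees with gene-by-gene solves
  C_slow <- t(vapply(1:3, function(g)
    fit_gene(Y[g, ], bs, phi, cm$lambda_opt)$coefficients, numeric(10)))
  expect_equal(unname(cm$C), C_slow, tolerance = 1e-8)
})
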