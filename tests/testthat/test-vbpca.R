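make_lowrank <- function(n, p, r, noise = 0.1, miss = 0, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * r), n, r)
  W <- matrix(rnorm(p * r), p, r)
  X <- Z %*% t(W) + if (noise > 0) matrix(rnorm(n * p, sd = noise), n, p) else 0
  Xm <- X
  if (miss > 0) {
    mask <- matrix(runif(n * p) < miss, n, p)
    # keep every row/column partly observed
    mask[cbind(seq_len(n), rep_len(seq_len(p), n))] <- FALSE
    Xm[mask] <- NA
  }
  list(X = X, Xm = Xm, miss = is.na(Xm))
}

test_that("a complete noiseless rank-1 matrix is reconstructed with one dominant eigenvalue", {
  set.seed(2)
  X <- outer(rnorm(30), rnorm(10))
  vb <- suppressWarnings(fit_vbpca(X, tol = 1e-9, seed = 1))
  recon <- impute(vb, centred = FALSE)
  expect_lt(max(abs(recon - X)), 1e-6)
  expect_gt(vb$eigenvalues[1] / (vb$eigenvalues[2] + 1e-300), 1e6)
})

test_that("free energy is non-decreasing and the same seed reproduces the fit", {
  lr <- make_lowrank(40, 12, 2, noise = 0.2, miss = 0.2, seed = 3)
  vb1 <- suppressWarnings(fit_vbpca(lr$Xm, tol = 1e-7, max_iter = 600, seed = 5))
  fe <- vb1$free_energy
  expect_true(all(diff(fe) >= -1e-8 * pmax(abs(fe[-1]), 1)))
  vb2 <- suppressWarnings(fit_vbpca(lr$Xm, tol = 1e-7, max_iter = 600, seed = 5))
  expect_identical(vb1$recon_mean, vb2$recon_mean)
})

test_that("held-out imputation beats the column-median baseline on rank-2 data", {
  lr <- make_lowrank(60, 15, 2, noise = 0.1, miss = 0.2, seed = 7)
  vb <- suppressWarnings(fit_vbpca(lr$Xm, tol = 1e-6, seed = 2))
  full <- impute(vb, centred = FALSE)
  rmse_vb <- sqrt(mean((full - lr$X)[lr$miss]^2))
  med <- apply(lr$Xm, 2, median, na.rm = TRUE)
  rmse_med <- sqrt(mean((matrix(med, nrow(lr$X), ncol(lr$X), byrow = TRUE) - lr$X)[lr$miss]^2))
  expect_lt(rmse_vb, rmse_med)
})

test_that("the imputed matrix is complete, centred, and near the classical PCA optimum", {
  lr <- make_lowrank(50, 14, 2, noise = 0.05, miss = 0, seed = 9)
  vb <- suppressWarnings(fit_vbpca(lr$X, tol = 1e-8, seed = 3))
  Xi <- impute(vb)
  expect_false(anyNA(Xi))
  # centred reconstruction of centred data: column means near zero
  expect_lt(max(abs(colMeans(Xi))), 1e-4)
  # oracle: classical truncated-SVD reconstruction at the model's rank
  Xc <- scale(lr$X, scale = FALSE)
  sv <- svd(Xc)
  d_used <- vb$d
  pca <- sv$u[, 1:d_used, drop = FALSE] %*% diag(sv$d[1:d_used], d_used) %*%
    t(sv$v[, 1:d_used, drop = FALSE])
  sse_vb <- sum((Xi - Xc)^2)
  sse_pca <- sum((pca - Xc)^2)
  expect_lt(sse_vb, sse_pca * 1.05 + 1e-6)
})

test_that("imputation is invariant to row permutation", {
  lr <- make_lowrank(30, 10, 2, noise = 0.1, miss = 0.15, seed = 11)
  vb <- suppressWarnings(fit_vbpca(lr$Xm, tol = 1e-8, seed = 4))
  perm <- sample(seq_len(30))
  vb_p <- suppressWarnings(fit_vbpca(lr$Xm[perm, ], tol = 1e-8, seed = 4))
  expect_lt(max(abs(vb_p$recon_mean - vb$recon_mean[perm, ])), 1e-4)
})

test_that("posterior samples have the reconstruction moments and are seed-reproducible", {
  lr <- make_lowrank(20, 8, 2, noise = 0.2, miss = 0.2, seed = 13)
  vb <- suppressWarnings(fit_vbpca(lr$Xm, tol = 1e-6, seed = 6))
  s1 <- sample_posterior(vb, 3, seed = 8)
  expect_length(s1, 3)
  expect_true(all(vapply(s1, function(m) !anyNA(m) && all(dim(m) == dim(lr$Xm)),
                         logical(1))))
  expect_identical(s1, sample_posterior(vb, 3, seed = 8))
  expect_error(sample_posterior(vb, 0), "N must be")
  # Monte-Carlo moment check at N = 500
  s <- sample_posterior(vb, 500, seed = 9)
  mn <- Reduce(`+`, s) / 500
  z <- (mn - vb$recon_mean) / sqrt(vb$recon_var / 500)
  expect_gt(mean(abs(z) < 4), 0.995)
  expect_lt(max(abs(z)), 6)
})

test_that("rows or columns with no observations are rejected", {
  m <- matrix(rnorm(20), 5, 4)
  m[, 2] <- NA
  expect_error(fit_vbpca(m), "no observed values")
  m2 <- matrix(rnorm(20), 5, 4)
  m2[3, ] <- NA
  expect_error(fit_vbpca(m2), "no observed values")
})

test_that("the eigenvalue resampling test finds no structure in i.i.d. noise", {
  ks <- vapply(1:25, function(s) {
    set.seed(s)
    X <- matrix(rnorm(35 * 12), 35, 12)
    vb <- suppressWarnings(fit_vbpca(X, d_max = 8, tol = 1e-5, max_iter = 200, seed = s))
    select_num_archetypes(vb, N = 40, seed = s)$k
  }, integer(1))
  expect_gte(mean(ks == 1), 0.95)
})

test_that("k tracks the number of significant eigenvalues plus one and is monotone in the level", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 30, B = 30, C = 30), p = 20,
                                  k = 3, noise_sd = 0.05, missing_rate = 0.1, seed = 31)
  vb <- suppressWarnings(fit_vbpca(ds$trait_matrix, d_max = 10, tol = 1e-5,
                                   max_iter = 300, seed = 7))
  sel <- select_num_archetypes(vb, N = 60, seed = 3)
  expect_equal(sel$k, sel$n_significant + 1L)
  expect_equal(sel$k, 3L)   # two significant eigenvalues from k = 3 archetypes
  sel_loose <- select_num_archetypes(vb, N = 60, sig_level = 0.2, seed = 3)
  expect_gte(sel_loose$k, sel$k)
  expect_error(select_num_archetypes(vb, N = 10), "N must be")
})
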