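#' Variational Bayesian PCA on an incomplete trait matrix
#'
#' Fits a probabilistic PCA model to the observed cells only, with
#' Gaussian variational posteriors over scores and loadings, automatic
#' relevance determination (ARD) priors on the loading columns (which
#' supplies the noise filtering: irrelevant components are shrunk away),
#' and a shared noise variance. The model reconstructs the complete
#' matrix, with a per-entry posterior mean and variance at every cell
#' including originally missing ones.
#'
#' Updates alternate exact coordinate maximisations of the variational
#' free energy (scores, loadings, ARD precisions, noise variance), so the
#' objective is non-decreasing; convergence is declared when its relative
#' change drops below `tol`.
#'
#' @param tm a [trait_matrix], or a plain numeric matrix with `NA`s.
#' @param d_max number of latent components; default
#'   `min(n, p) - 1` capped at 30.
#' @param tol relative free-energy change at convergence.
#' @param max_iter iteration cap; hitting it sets `converged = FALSE`
#'   (a warning flag on the model, not an error).
#' @param seed integer seed (initialisation is deterministic given it).
#' @return an object of class `vbpca_model` with fields `column_means`,
#'   `loadings_mean`, `loadings_var`, `scores_mean`, `scores_var`,
#'   `noise_variance`, `recon_mean`, `recon_var`, `eigenvalues`,
#'   `free_energy` (per-iteration trace), `converged`, `mask`, `values`.
#' @export
fit_vbpca <- function(tm, d_max = NULL, tol = 1e-6, max_iter = 2000, seed = 1) {
  X <- if (inherits(tm, "trait_matrix")) encode_traits(tm) else as.matrix(tm)
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  if (any(colSums(obs) == 0))
    stop("column(s) with no observed values; apply filter_by_coverage first")
  if (any(rowSums(obs) == 0)) stop("row(s) with no observed values")
  if (is.null(d_max)) d_max <- min(min(n, p) - 1L, 30L)
  d <- max(1L, min(d_max, min(n, p) - 1L))

  mu <- colSums(X * obs, na.rm = TRUE) / colSums(obs)
  Xc <- sweep(X, 2L, mu)
  Xc[!obs] <- 0
  omask <- obs * 1

  # deterministic SVD-based initialisation on mean-filled data
  sv <- svd(Xc, nu = d, nv = d)
  W <- sv$v %*% diag(sv$d[seq_len(d)] / sqrt(n), d, d)   # p x d
  Z <- sv$u * sqrt(n)                                    # n x d
  # second moments stored flat: each column is a vec(d x d) covariance
  Sz_flat <- matrix(rep(as.numeric(diag(1e-3, d)), n), d * d, n)
  Sw_flat <- matrix(rep(as.numeric(diag(1e-3, d)), p), d * d, p)
  sigma2 <- max(mean((Xc - Z %*% t(W))[obs]^2), 1e-8)
  ard <- rep(1, d)
  n_obs <- sum(obs)
  Id <- diag(1, d)

  free_energy <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # prune components ARD has shrunk away (their posteriors equal the
    # prior, so they contribute nothing to the fit or the free energy);
    # done at iteration start so every free-energy term below is computed
    # in the pruned dimension
    # a component is dead once its per-entry contribution 1/ard is far
    # below the noise floor; jumping to the ard -> Inf limit of the
    # coordinate-ascent path cannot decrease the free energy
    dead <- ard > pmax(1e5, 1e4 / sigma2)
    if (any(dead) && !all(dead)) {
      keep <- which(!dead)
      sub_idx <- as.numeric(outer(keep, (keep - 1L) * d, `+`))
      d <- length(keep)
      Id <- diag(1, d)
      W <- W[, keep, drop = FALSE]
      Z <- Z[, keep, drop = FALSE]
      Sw_flat <- Sw_flat[sub_idx, , drop = FALSE]
      Sz_flat <- Sz_flat[sub_idx, , drop = FALSE]
      ard <- ard[keep]
    }
    # q(Z): exact Gaussian update per row over its observed columns
    # E[w_j w_j^T] flat, then row-wise sums over observed columns via matmul
    WtW_flat <- vapply(seq_len(p), function(j) as.numeric(tcrossprod(W[j, ])),
                       numeric(d * d)) + Sw_flat            # (d*d) x p
    WtW_rows <- WtW_flat %*% t(omask)                       # (d*d) x n
    B_z <- (Xc * omask) %*% W                               # n x d
    logdet_z <- numeric(n)
    for (i in seq_len(n)) {
      A <- Id + matrix(WtW_rows[, i], d, d) / sigma2
      ch <- chol(A)
      Sz <- chol2inv(ch)
      Sz_flat[, i] <- as.numeric(Sz)
      Z[i, ] <- Sz %*% (B_z[i, ] / sigma2)
      logdet_z[i] <- -2 * sum(log(diag(ch)))                # log det Sz
    }
    # q(W): exact Gaussian update per column over its observed rows
    ZtZ_flat <- vapply(seq_len(n), function(i) as.numeric(tcrossprod(Z[i, ])),
                       numeric(d * d)) + Sz_flat            # (d*d) x n
    ZtZ_cols <- ZtZ_flat %*% omask                          # (d*d) x p
    B_w <- t(Xc * omask) %*% Z                              # p x d
    logdet_w <- numeric(p)
    for (j in seq_len(p)) {
      A <- diag(ard, d) + matrix(ZtZ_cols[, j], d, d) / sigma2
      ch <- chol(A)
      Sw <- chol2inv(ch)
      Sw_flat[, j] <- as.numeric(Sw)
      W[j, ] <- Sw %*% (B_w[j, ] / sigma2)
      logdet_w[j] <- -2 * sum(log(diag(ch)))
    }
    # ARD precisions (type-II maximisation of the free energy)
    diag_idx <- (seq_len(d) - 1L) * d + seq_len(d)
    w2 <- colSums(W^2) + rowSums(Sw_flat[diag_idx, , drop = FALSE])
    ard <- pmin(p / pmax(w2, 1e-12), 1e12)
    # expected squared error over observed cells
    M <- Z %*% t(W)
    se <- sum(((Xc - M) * omask)^2)
    EzzT <- vapply(seq_len(n), function(i) as.numeric(tcrossprod(Z[i, ])),
                   numeric(d * d)) + Sz_flat
    EwwT <- vapply(seq_len(p), function(j) as.numeric(tcrossprod(W[j, ])),
                   numeric(d * d)) + Sw_flat
    # E[(w'z)^2] - (w'z)^2 = tr(EzzT EwwT) - (Zw)^2 summed over observed cells
    cross <- crossprod(EzzT, EwwT)                          # n x p of traces
    se <- se + sum((cross - M^2) * omask)
    sigma2 <- max(se / n_obs, 1e-10)
    # variational free energy
    fe <- -0.5 * n_obs * log(2 * pi * sigma2) - 0.5 * se / sigma2
    tr_z <- colSums(Sz_flat[diag_idx, , drop = FALSE])
    kl_z <- 0.5 * sum(tr_z + rowSums(Z^2) - d - logdet_z)
    tr_w_ard <- as.numeric(ard %*% Sw_flat[diag_idx, , drop = FALSE])
    kl_w <- 0.5 * sum(tr_w_ard + as.numeric(W^2 %*% ard) - d -
                        sum(log(ard)) - logdet_w)
    fe <- fe - kl_z - kl_w
    free_energy <- c(free_energy, fe)
    if (it > 1) {
      delta <- abs(fe - free_energy[it - 1]) / (abs(fe) + 1e-12)
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("fit_vbpca: free energy did not converge within max_iter; model flagged")

  recon_mean <- Z %*% t(W)
  # predictive variance: subspace uncertainty + noise
  EzzT <- vapply(seq_len(n), function(i) as.numeric(tcrossprod(Z[i, ])),
                 numeric(d * d)) + Sz_flat
  EwwT <- vapply(seq_len(p), function(j) as.numeric(tcrossprod(W[j, ])),
                 numeric(d * d)) + Sw_flat
  recon_var <- crossprod(EzzT, EwwT) - recon_mean^2 + sigma2
  recon_var <- pmax(recon_var, 1e-12)
  dimnames(recon_mean) <- dimnames(X)
  dimnames(recon_var) <- dimnames(X)
  ev <- eigen(stats::cov(recon_mean), symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(pmax(ev, 0), decreasing = TRUE)

  structure(list(column_means = mu,
                 loadings_mean = W,
                 loadings_var = Sw_flat,
                 scores_mean = Z,
                 scores_var = Sz_flat,
                 noise_variance = sigma2,
                 recon_mean = recon_mean,
                 recon_var = recon_var,
                 eigenvalues = ev,
                 ard = ard,
                 free_energy = free_energy,
                 converged = converged,
                 d = d,
                 mask = obs,
                 values = X),
            class = "vbpca_model")
}

#' @export
print.vbpca_model <- function(x, ...) {
  cat(sprintf("vbpca_model: %d x %d, d = %d, noise variance %.4g, %s after %d iterations\n",
              nrow(x$recon_mean), ncol(x$recon_mean), x$d, x$noise_variance,
              if (x$converged) "converged" else "NOT converged",
              length(x$free_energy)))
  invisible(x)
}

#' Completed, mean-centred reconstruction
#'
#' Returns the posterior-mean completed matrix. The centred reconstruction
#' (default) is the denoised matrix handed to archetypal analysis; with
#' `centred = FALSE` the column means are added back for inspection on the
#' original code scale.
#'
#' @param model a `vbpca_model`.
#' @param centred return the mean-centred matrix (default) or the
#'   inverse-centred convenience view.
#' @return a complete numeric matrix (no missing entries).
#' @export
impute <- function(model, centred = TRUE) {
  out <- model$recon_mean
  if (!centred) out <- sweep(out, 2L, model$column_means, `+`)
  out
}

#' Sample completed matrices from the reconstruction posterior
#'
#' Draws `N` complete matrices with independent per-entry Gaussian draws
#' at the reconstruction moments (`recon_mean`, `recon_var`).
#'
#' @param model a `vbpca_model`.
#' @param N number of samples (>= 1).
#' @param seed integer seed; the same seed reproduces the sample set.
#' @return a list of `N` complete centred matrices.
#' @export
sample_posterior <- function(model, N, seed = 1) {
  if (N < 1) stop("N must be >= 1")
  n <- nrow(model$recon_mean); p <- ncol(model$recon_mean)
  sdm <- sqrt(model$recon_var)
  with_seed(derive_seed(seed, "posterior"), {
    lapply(seq_len(N), function(s)
      model$recon_mean + matrix(rnorm(n * p), n, p) * sdm)
  })
}

#' Select the number of archetypes by a resampling eigenvalue test
#'
#' Builds an empirical null for each leading eigenvalue of the
#' reconstructed data covariance: `N` posterior samples of the completed
#' matrix are drawn, each column of each sample is independently permuted
#' (destroying inter-trait covariance while preserving marginals), and the
#' eigen-spectra of the permuted samples form the null. An observed
#' eigenvalue is "large" when it exceeds the `1 - sig_level` quantile of
#' the corresponding null eigenvalue; counting stops at the first
#' non-significant eigenvalue. Because mean-centred data generated from
#' `k` archetypes span `k - 1` dimensions, the selected number of
#' archetypes is the number of large eigenvalues plus one.
#'
#' @param model a `vbpca_model`.
#' @param N number of posterior resamples (>= 20).
#' @param sig_level per-eigenvalue significance level.
#' @param seed integer seed.
#' @return list with `k`, `n_significant`, and a data frame `report`
#'   (eigenvalue, null quantile, significant flag) for the tested leading
#'   eigenvalues.
#' @export
select_num_archetypes <- function(model, N = 100, sig_level = 0.05, seed = 1) {
  if (N < 20) stop("N must be >= 20 for a stable empirical null")
  n <- nrow(model$recon_mean); p <- ncol(model$recon_mean)
  n_test <- min(model$d, p, n - 1L)
  samples <- sample_posterior(model, N, seed = derive_seed(seed, "eig_samples"))
  null_eigs <- with_seed(derive_seed(seed, "eig_perm"), {
    vapply(samples, function(S) {
      Sp <- apply(S, 2L, sample)
      ev <- eigen(stats::cov(Sp), symmetric = TRUE, only.values = TRUE)$values
      sort(pmax(ev, 0), decreasing = TRUE)[seq_len(n_test)]
    }, numeric(n_test))
  })
  null_eigs <- matrix(null_eigs, nrow = n_test)
  qs <- apply(null_eigs, 1L, quantile, probs = 1 - sig_level, names = FALSE)
  obs <- model$eigenvalues[seq_len(n_test)]
  sig <- obs > qs
  n_sig <- if (!sig[1]) 0L else (which(c(!sig, TRUE))[1] - 1L)
  list(k = n_sig + 1L,
       n_significant = n_sig,
       report = data.frame(component = seq_len(n_test),
                           eigenvalue = obs,
                           null_quantile = qs,
                           significant = seq_len(n_test) <= n_sig))
}
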