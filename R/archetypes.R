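#' Archetypal analysis by principal convex hull (PCHA) optimisation
#'
#' Approximates a complete, mean-centred data matrix `X` (`n x p`) as
#' `X ~ alpha %*% t(beta) %*% X`, where each row of `alpha` (`n x k`) lies
#' on the probability simplex (membership coefficients of each society in
#' each archetype) and each column of `beta` (`n x k`) lies on the simplex
#' (archetypes as convex combinations of societies). The archetype
#' profiles are `S = t(X) %*% beta` (`p x k`). Optimisation alternates
#' projected-gradient steps on `alpha` and `beta` with adaptive step sizes
#' (the sum of squared errors is non-increasing by construction);
#' `beta` support is initialised by furthest-sum seeding and the best of
#' `n_restarts` runs by SSE is kept. Archetype columns are canonicalised
#' by descending total membership mass.
#'
#' @param X complete numeric matrix (no `NA`), typically [impute()] output.
#' @param k number of archetypes (1 <= k <= n).
#' @param n_restarts number of restarts (different furthest-sum seeds).
#' @param tol relative SSE change at convergence.
#' @param max_iter iteration cap per restart.
#' @param seed integer seed.
#' @return an object of class `archetype_model` with fields `alpha`,
#'   `beta`, `profiles` (`S`), `sse`, `explained_variance`, `k`, `seed`.
#' @export
fit_archetypes <- function(X, k, n_restarts = 10, tol = 1e-8,
                           max_iter = 5000, seed = 1) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete; impute first")
  n <- nrow(X)
  if (k > n) stop("k must not exceed the number of rows")
  if (k < 1) stop("k must be >= 1")
  total_ss <- sum(X^2)

  if (k == 1) {
    # best single convex combination is the row mean (unconstrained optimum
    # of the profile lies at the centroid, which uniform beta attains)
    beta <- matrix(1 / n, n, 1)
    alpha <- matrix(1, n, 1)
    S <- crossprod(X, beta)
    sse <- sum((X - alpha %*% t(S))^2)
    return(new_archetype_model(X, alpha, beta, sse, total_ss, k, seed))
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    rseed <- derive_seed(seed, "pcha_restart", r)
    init_idx <- furthest_sum(X, k, seed = rseed)
    beta <- matrix(0, n, k)
    beta[cbind(init_idx, seq_len(k))] <- 1
    fit <- pcha_optimise(X, beta, tol, max_iter)
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  new_archetype_model(X, best$alpha, best$beta, best$sse, total_ss, k, seed)
}

new_archetype_model <- function(X, alpha, beta, sse, total_ss, k, seed) {
  ord <- order(colSums(alpha), decreasing = TRUE)
  alpha <- alpha[, ord, drop = FALSE]
  beta <- beta[, ord, drop = FALSE]
  S <- crossprod(X, beta)
  colnames(alpha) <- colnames(beta) <- colnames(S) <- paste0("A", seq_len(k))
  rownames(alpha) <- rownames(beta) <- rownames(X)
  rownames(S) <- colnames(X)
  structure(list(alpha = alpha, beta = beta, profiles = S,
                 sse = sse,
                 explained_variance = max(0, min(1, 1 - sse / total_ss)),
                 k = k, seed = seed),
            class = "archetype_model")
}

#' @export
print.archetype_model <- function(x, ...) {
  cat(sprintf("archetype_model: k = %d, SSE %.6g, explained variance %.1f%%\n",
              x$k, x$sse, 100 * x$explained_variance))
  invisible(x)
}

# Furthest-sum seeding: greedily pick points maximising the summed
# distance to the already-selected set (standard PCHA initialisation).
furthest_sum <- function(X, k, seed = 1) {
  n <- nrow(X)
  with_seed(seed, {
    idx <- sample.int(n, 1)
    if (k == 1) return(idx)
    sumd <- rep(0, n)
    for (j in seq_len(k - 1)) {
      last <- idx[length(idx)]
      sumd <- sumd + sqrt(rowSums(sweep(X, 2L, X[last, ])^2))
      cand <- setdiff(order(sumd, decreasing = TRUE), idx)
      idx <- c(idx, cand[1])
    }
    idx
  })
}

# Alternating projected-gradient PCHA with adaptive step sizes.
pcha_optimise <- function(X, beta, tol, max_iter) {
  n <- nrow(X); k <- ncol(beta)
  XtX_row <- NULL
  S <- crossprod(X, beta)                # p x k
  # initial alpha: uniform
  alpha <- matrix(1 / k, n, k)
  sse <- sum((X - alpha %*% t(S))^2)
  mu_a <- 1 / max(sum(S^2), 1e-12)
  mu_b <- 1
  for (it in seq_len(max_iter)) {
    sse_prev <- sse
    # alpha step: grad = -2 (X - alpha S') S
    E <- X - alpha %*% t(S)
    g_a <- -2 * E %*% S
    for (try in 1:12) {
      a_new <- project_rows_simplex(alpha - mu_a * g_a)
      sse_new <- sum((X - a_new %*% t(S))^2)
      if (sse_new <= sse) { alpha <- a_new; sse <- sse_new; mu_a <- mu_a * 1.2; break }
      mu_a <- mu_a / 2
    }
    # beta step: grad = -2 X E' alpha, with S = X' beta
    E <- X - alpha %*% t(S)
    g_b <- -2 * X %*% crossprod(E, alpha)
    for (try in 1:12) {
      b_new <- project_cols_simplex(beta - mu_b * g_b)
      S_new <- crossprod(X, b_new)
      sse_new <- sum((X - alpha %*% t(S_new))^2)
      if (sse_new <= sse) { beta <- b_new; S <- S_new; sse <- sse_new; mu_b <- mu_b * 1.2; break }
      mu_b <- mu_b / 2
    }
    if (abs(sse_prev - sse) <= tol * max(sse_prev, 1e-300)) break
  }
  list(alpha = alpha, beta = beta, sse = sse)
}

#' Match archetype columns between two fits
#'
#' Greedy maximum-correlation assignment of the columns of `S` to the
#' columns of `S_ref`; used to align archetypes across posterior samples
#' or against generator ground truth.
#'
#' @param S_ref,S `p x k` profile matrices.
#' @return integer permutation `perm` such that `S[, perm]` aligns with
#'   `S_ref`, with attribute `"correlations"` (the matched correlations).
#' @export
align_archetypes <- function(S_ref, S) {
  k <- ncol(S_ref)
  cc <- suppressWarnings(stats::cor(S_ref, S))
  cc[is.na(cc)] <- 0
  m <- cc
  perm <- integer(k); cors <- numeric(k)
  for (step in seq_len(k)) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    perm[ij[1]] <- ij[2]
    cors[ij[1]] <- cc[ij[1], ij[2]]
    m[ij[1], ] <- -Inf
    m[, ij[2]] <- -Inf
  }
  structure(perm, correlations = cors)
}

#' K-means cluster-count selection in the archetype space
#'
#' Scans candidate cluster counts around the number of archetypes
#' (`k - 2` to `k + 2`, floored at 2; for `k = 2` the scan is 2..4),
#' clusters the membership rows with K-means (50 restarts), and scores
#' each candidate with the silhouette score (higher better), the
#' variance-ratio (Calinski-Harabasz) criterion (higher better) and the
#' Davies-Bouldin index (lower better). The selected count is the
#' candidate optimising at least two of the three metrics; if the three
#' metrics prefer three different candidates, the number of archetypes
#' `k` is returned. Metric ties break toward the smaller count.
#'
#' @param am an `archetype_model`.
#' @param seed integer seed for the K-means restarts.
#' @return list of class `cluster_selection` with `n_clusters`, `labels`,
#'   `metrics` (one row per candidate) and `rule` (how the count was
#'   chosen).
#' @export
select_num_kmeans_clusters <- function(am, seed = 1) {
  if (am$k < 2) stop("cluster scan requires a model with k >= 2")
  A <- am$alpha
  n <- nrow(A)
  cand <- if (am$k == 2) 2:4 else seq(max(2, am$k - 2), am$k + 2)
  cand <- cand[cand <= n - 1]
  if (!length(cand)) {
    warning("too few societies for the cluster scan; using k")
    cand <- am$k
  }
  fits <- list()
  metrics <- data.frame(n_clusters = cand, silhouette = NA_real_,
                        variance_ratio = NA_real_, davies_bouldin = NA_real_)
  for (i in seq_along(cand)) {
    c_i <- cand[i]
    km <- with_seed(derive_seed(seed, "kmeans", c_i),
                    kmeans(A, centers = c_i, nstart = 50, iter.max = 100))
    fits[[i]] <- km
    metrics$silhouette[i] <- mean(cluster::silhouette(km$cluster, dist(A))[, 3])
    metrics$variance_ratio[i] <- calinski_harabasz(A, km$cluster)
    metrics$davies_bouldin[i] <- davies_bouldin(A, km$cluster)
  }
  pick <- choose_cluster_count(metrics, am$k)
  sel <- match(pick$n_clusters, cand)
  structure(list(n_clusters = pick$n_clusters,
                 labels = fits[[sel]]$cluster,
                 metrics = metrics,
                 rule = pick$rule),
            class = "cluster_selection")
}

# The "two or more metrics" selection rule, applied to a metric table.
choose_cluster_count <- function(metrics, k) {
  best_sil <- metrics$n_clusters[which.max(metrics$silhouette)]
  best_vr <- metrics$n_clusters[which.max(metrics$variance_ratio)]
  best_db <- metrics$n_clusters[which.min(metrics$davies_bouldin)]
  winners <- c(best_sil, best_vr, best_db)
  tab <- table(winners)
  top <- as.integer(names(tab)[tab >= 2])
  if (length(top)) {
    list(n_clusters = min(top), rule = "majority of metrics")
  } else if (k %in% metrics$n_clusters) {
    list(n_clusters = k, rule = "no majority; defaulted to number of archetypes")
  } else {
    list(n_clusters = min(winners), rule = "no majority; smallest winning candidate")
  }
}

# Variance-ratio criterion: between-cluster over within-cluster
# dispersion, scaled by degrees of freedom.
calinski_harabasz <- function(X, labels) {
  n <- nrow(X); cl <- unique(labels); c_n <- length(cl)
  if (c_n < 2) return(NA_real_)
  grand <- colMeans(X)
  Wss <- 0; Bss <- 0
  for (g in cl) {
    rows <- X[labels == g, , drop = FALSE]
    cen <- colMeans(rows)
    Wss <- Wss + sum(sweep(rows, 2L, cen)^2)
    Bss <- Bss + nrow(rows) * sum((cen - grand)^2)
  }
  (Bss / (c_n - 1)) / (Wss / (n - c_n))
}

# Davies-Bouldin index: average over clusters of the worst ratio of
# summed intra-cluster scatters to centroid separation.
davies_bouldin <- function(X, labels) {
  cl <- sort(unique(labels)); c_n <- length(cl)
  if (c_n < 2) return(NA_real_)
  cen <- t(vapply(cl, function(g) colMeans(X[labels == g, , drop = FALSE]),
                  numeric(ncol(X))))
  scatter <- vapply(seq_along(cl), function(gi) {
    rows <- X[labels == cl[gi], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2L, cen[gi, ])^2)))
  }, numeric(1))
  db <- 0
  for (i in seq_len(c_n)) {
    rij <- vapply(setdiff(seq_len(c_n), i), function(j) {
      (scatter[i] + scatter[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
    }, numeric(1))
    db <- db + max(rij)
  }
  db / c_n
}
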