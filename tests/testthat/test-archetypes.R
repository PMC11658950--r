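test_that("data that are k distinct repeated vertices are their own archetypes", {
  set.seed(3)
  V <- matrix(rnorm(3 * 8), 3, 8) * 3
  X <- V[rep(1:3, each = 6), ]
  am <- fit_archetypes(X, 3, n_restarts = 3, seed = 1)
  expect_lt(am$sse, 1e-10)
  # alpha is one-hot up to column permutation
  expect_true(all(abs(apply(am$alpha, 1, max) - 1) < 1e-5))
  expect_lt(max(abs(rowSums(am$alpha) - 1)), 1e-8)
  expect_lt(max(abs(colSums(am$beta) - 1)), 1e-8)
  expect_true(all(am$alpha >= -1e-12) && all(am$beta >= -1e-12))
  # S reproducible from X and beta
  expect_lt(max(abs(am$profiles - crossprod(X, am$beta))), 1e-8)
})

test_that("k = 1 matches the closed-form centroid solution and a simplex grid search", {
  set.seed(4)
  X <- matrix(rnorm(15), 5, 3)
  am <- fit_archetypes(X, 1, seed = 1)
  expect_equal(unname(am$alpha), matrix(1, 5, 1))
  sse_exact <- sum(sweep(X, 2, colMeans(X))^2)
  expect_equal(am$sse, sse_exact, tolerance = 1e-10)
  # grid over beta on the 5-simplex (step 0.1): fitted sse is the minimum
  grid <- as.matrix(expand.grid(rep(list(0:10), 4)))
  grid <- grid[rowSums(grid) <= 10, , drop = FALSE]
  grid <- cbind(grid, 10 - rowSums(grid)) / 10
  sse_grid <- min(apply(grid, 1, function(b) {
    s <- crossprod(X, b)
    sum((X - matrix(s, 5, 3, byrow = TRUE))^2)
  }))
  expect_lte(am$sse, sse_grid + 1e-10)
})

test_that("synthetic low-noise archetypes are recovered with r > 0.95 per profile", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 25, B = 25, C = 25), p = 20,
                                  k = 3, noise_sd = 0.01, missing_rate = 0, seed = 17,
                                  quantise = FALSE)
  X <- scale(ds$trait_matrix$values, scale = FALSE)
  am <- fit_archetypes(X, 3, n_restarts = 3, seed = 2)
  S_unc <- sweep(am$profiles, 1L, colMeans(ds$trait_matrix$values), `+`)
  perm <- align_archetypes(ds$truth$true_profiles, S_unc)
  expect_true(all(attr(perm, "correlations") > 0.95))
})

test_that("explained variance is a fraction and every row is its own archetype at k = n", {
  set.seed(6)
  X <- matrix(rnorm(5 * 4), 5, 4)
  am <- fit_archetypes(X, 2, n_restarts = 2, seed = 3)
  expect_gte(am$explained_variance, 0)
  expect_lte(am$explained_variance, 1)
  expect_equal(am$explained_variance, 1 - am$sse / sum(X^2), tolerance = 1e-12)
  am_n <- fit_archetypes(X, 5, n_restarts = 3, seed = 3)
  expect_lt(am_n$sse, 1e-8 * sum(X^2))
  expect_error(fit_archetypes(X, 6), "exceed")
})

test_that("the fit is equivariant to row permutation", {
  set.seed(7)
  ds <- generate_cultural_dataset(n_per_region = c(A = 15, B = 15), p = 10, k = 2,
                                  noise_sd = 0.05, missing_rate = 0, seed = 8,
                                  quantise = FALSE)
  X <- scale(ds$trait_matrix$values, scale = FALSE)
  am <- fit_archetypes(X, 2, n_restarts = 2, seed = 4)
  perm <- sample(nrow(X))
  am_p <- fit_archetypes(X[perm, ], 2, n_restarts = 2, seed = 4)
  # archetype columns are canonicalised, so profiles should agree closely
  pp <- align_archetypes(am$profiles, am_p$profiles)
  expect_true(all(attr(pp, "correlations") > 0.999))
  expect_equal(am_p$sse, am$sse, tolerance = 1e-4)
})

test_that("the cluster scan covers the documented candidate ranges", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 20, B = 20), p = 10, k = 2,
                                  noise_sd = 0.05, missing_rate = 0, seed = 12,
                                  quantise = FALSE)
  X <- scale(ds$trait_matrix$values, scale = FALSE)
  am2 <- fit_archetypes(X, 2, n_restarts = 2, seed = 5)
  cs2 <- select_num_kmeans_clusters(am2, seed = 1)
  expect_identical(cs2$metrics$n_clusters, 2:4)      # k = 2 scans 2..4
  am4 <- fit_archetypes(X, 4, n_restarts = 2, seed = 5)
  cs4 <- select_num_kmeans_clusters(am4, seed = 1)
  expect_identical(cs4$metrics$n_clusters, 2:6)      # k - 2 .. k + 2
  expect_true(all(cs2$labels %in% seq_len(cs2$n_clusters)))
})

test_that("the two-or-more-metrics selection rule and its fallback are applied", {
  choose <- cultarch:::choose_cluster_count
  tab <- data.frame(n_clusters = 2:6,
                    silhouette = c(0.2, 0.7, 0.3, 0.1, 0.1),
                    variance_ratio = c(10, 50, 20, 5, 5),
                    davies_bouldin = c(1.5, 1.2, 0.4, 1.9, 2.0))
  # silhouette and variance ratio optimal at 3, Davies-Bouldin at 4 -> 3
  expect_equal(choose(tab, k = 4)$n_clusters, 3)
  tab2 <- tab
  tab2$silhouette <- c(0.7, 0.1, 0.3, 0.1, 0.1)       # best at 2
  tab2$variance_ratio <- c(10, 50, 20, 5, 5)          # best at 3
  tab2$davies_bouldin <- c(1.5, 1.2, 0.4, 1.9, 2.0)   # best at 4
  # three different winners -> fall back to k
  expect_equal(choose(tab2, k = 5)$n_clusters, 5)
  # a clean three-way agreement
  tab3 <- tab
  tab3$davies_bouldin <- c(1.5, 0.2, 0.4, 1.9, 2.0)
  expect_equal(choose(tab3, k = 4)$n_clusters, 3)
})

test_that("three metrics pick the true cluster count on well-separated mixtures", {
  set.seed(9)
  A <- rbind(rdirichlet(20, c(30, 1, 1)), rdirichlet(20, c(1, 30, 1)),
             rdirichlet(20, c(1, 1, 30)))
  am <- structure(list(alpha = A, k = 3), class = "archetype_model")
  cs <- select_num_kmeans_clusters(am, seed = 2)
  expect_equal(cs$n_clusters, 3)
})
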