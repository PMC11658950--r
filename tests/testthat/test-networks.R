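test_that("archetype distances are plain Euclidean distances between membership rows", {
  a <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  rownames(a) <- paste0("s", 1:3)
  dm <- archetype_distances(a)
  expect_equal(dm$d["s1", "s2"], sqrt(2))
  expect_equal(dm$d["s3", "s3"], 0)
  set.seed(2)
  A <- rdirichlet(10, c(2, 3, 1))
  dm2 <- archetype_distances(A)
  # brute-force double loop oracle
  for (i in 1:10) for (j in 1:10)
    expect_lt(abs(dm2$d[i, j] - sqrt(sum((A[i, ] - A[j, ])^2))), 1e-12)
})

test_that("Neighbor-Net recovers tree splits and branch lengths on additive metrics", {
  for (s in c(1, 5)) {
    g <- generate_additive_tree_distances(6, seed = s)
    nn <- neighbor_net(g$distances)
    expect_lt(max(abs(splits_to_metric(nn) - g$distances$d)), 1e-6)
    expect_gt(nn$fit, 1 - 1e-9)
    # unrooted binary tree on 6 taxa has 2n - 3 = 9 splits
    expect_equal(length(nn$splits), 9)
    expect_true(all(nn$weights > 0))
  }
})

test_that("Neighbor-Net recovers a constructed circular split metric exactly", {
  splits <- list(c(2L, 3L), c(3L, 4L, 5L), c(2L, 3L, 4L, 5L), c(5L, 6L),
                 1L, 2L, 3L, 4L, 5L, 6L)
  w <- c(0.5, 1.2, 0.3, 0.9, rep(0.4, 6))
  dm <- metric_from_circular_splits(6, splits, w)
  nn <- neighbor_net(dm)
  expect_lt(max(abs(splits_to_metric(nn) - dm$d)), 1e-6)
  # every constructed split is recovered with its weight
  key <- function(I) paste(sort(if (1 %in% I) setdiff(1:6, I) else I), collapse = "-")
  got <- setNames(nn$weights, vapply(nn$splits, key, character(1)))
  for (s in seq_along(splits)) {
    expect_true(key(splits[[s]]) %in% names(got))
    expect_lt(abs(got[[key(splits[[s]])]] - w[s]), 1e-6)
  }
})

test_that("active-set split weights match a reference NNLS solver", {
  set.seed(12)
  g <- generate_additive_tree_distances(7, seed = 9)
  noisy <- g$distances$d + matrix(runif(49, 0, 0.2), 7, 7)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  dm <- distance_matrix(noisy, g$distances$taxa)
  nn <- neighbor_net(dm, weight_tol = 0)
  # rebuild the full circular-split design on the same cycle and solve
  # with an independent NNLS implementation
  cyc <- nn$cycle
  P <- dm$d[cyc, cyc]
  pair_i <- rep(1:6, times = 6:1)
  pair_j <- unlist(lapply(1:6, function(i) (i + 1):7))
  dvec <- P[cbind(pair_i, pair_j)]
  arcs <- cbind(rep(2:7, times = 7 - (2:7) + 1),
                unlist(lapply(2:7, function(a) a:7)))
  A <- apply(arcs, 1, function(ab) {
    ini <- pair_i >= ab[1] & pair_i <= ab[2]
    inj <- pair_j >= ab[1] & pair_j <= ab[2]
    as.numeric(xor(ini, inj))
  })
  ref <- pracma::lsqnonneg(A, dvec)
  expect_equal(sum((A %*% ref$x - dvec)^2),
               sum(dvec^2) * (1 - nn$fit), tolerance = 1e-6)
})

test_that("tiny taxon sets yield the trivial splits", {
  d3 <- distance_matrix(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3), c("a", "b", "c"))
  nn3 <- neighbor_net(d3)
  expect_equal(length(nn3$splits), 3)
  expect_true(all(lengths(nn3$splits) %in% c(1, 2)))
  expect_lt(max(abs(splits_to_metric(nn3) - d3$d)), 1e-9)
  d2 <- distance_matrix(matrix(c(0, 1.5, 1.5, 0), 2), c("a", "b"))
  expect_equal(neighbor_net(d2)$weights, 1.5)
  expect_error(neighbor_net(distance_matrix(matrix(0, 1, 1), "a")), "at least 2")
})

test_that("Neighbor-Net represents reticulate metrics at least as well as the NJ tree", {
  set.seed(8)
  g <- generate_additive_tree_distances(8, seed = 3)
  noisy <- g$distances$d + matrix(runif(64, 0, 0.3), 8, 8)
  noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
  dm <- distance_matrix(noisy, g$distances$taxa)
  nn <- neighbor_net(dm)
  nj <- ape::nj(as.dist(noisy))
  nj$edge.length <- pmax(nj$edge.length, 0)
  dnj <- ape::cophenetic.phylo(nj)[dm$taxa, dm$taxa]
  fit_nj <- 1 - sum((dnj - noisy)^2) / sum(noisy^2)
  expect_gte(nn$fit, fit_nj - 1e-9)
})

test_that("quartet delta and Q follow the ordered-sum formulas", {
  dm <- quartet_dm_10_8_6()
  expect_equal(delta_score(dm)$mean_delta, 0.5)
  expect_equal(q_residual(dm, normalise = FALSE)$mean_q_residual, 4)
  # all three sums equal -> 0 by the m1 = m3 convention
  deq <- matrix(1, 4, 4); diag(deq) <- 0
  dmeq <- distance_matrix(deq, paste0("t", 1:4))
  expect_equal(delta_score(dmeq)$mean_delta, 0)
  expect_equal(q_residual(dmeq)$mean_q_residual, 0)
})

test_that("delta agrees with the brute-force oracle and is scale invariant", {
  set.seed(4)
  m <- matrix(runif(64, 1, 4), 8, 8); m <- (m + t(m)) / 2; diag(m) <- 0
  dm <- distance_matrix(m)
  expect_equal(delta_score(dm)$mean_delta, delta_brute(m), tolerance = 1e-12)
  dm2 <- distance_matrix(3.7 * m)
  expect_equal(delta_score(dm2)$mean_delta, delta_score(dm)$mean_delta,
               tolerance = 1e-12)
  # normalised Q is scale invariant too
  expect_equal(q_residual(dm2)$mean_q_residual, q_residual(dm)$mean_q_residual,
               tolerance = 1e-12)
  expect_length(delta_score(dm)$per_taxon_delta, 8)
  expect_error(delta_score(distance_matrix(matrix(0, 3, 3))), "at least 4")
})

test_that("delta is zero exactly when the four-point condition holds", {
  for (s in 1:3) {
    g <- generate_additive_tree_distances(7, seed = s + 20)
    expect_true(four_point_holds(g$distances$d))
    expect_lt(delta_score(g$distances)$mean_delta, 1e-10)
    set.seed(s)
    noisy <- g$distances$d + matrix(runif(49, 0, 0.5), 7, 7)
    noisy <- (noisy + t(noisy)) / 2; diag(noisy) <- 0
    expect_false(four_point_holds(noisy))
    expect_gt(delta_score(distance_matrix(noisy))$mean_delta, 0)
  }
})

test_that("added noise increases expected tree-likeness scores", {
  g <- generate_additive_tree_distances(9, seed = 5)
  mean_delta_at <- function(noise, s) {
    set.seed(s)
    e <- matrix(runif(81, 0, noise), 9, 9); e <- (e + t(e)) / 2; diag(e) <- 0
    delta_score(distance_matrix(g$distances$d + e))$mean_delta
  }
  lo <- mean(vapply(1:5, function(s) mean_delta_at(0.1, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mean_delta_at(0.8, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("the sampled quartet path approximates the exhaustive statistic", {
  set.seed(6)
  m <- matrix(runif(144, 1, 3), 12, 12); m <- (m + t(m)) / 2; diag(m) <- 0
  dm <- distance_matrix(m)
  exact <- delta_score(dm)$mean_delta
  approxed <- delta_score(dm, max_exhaustive = 10, n_sample = 2e5, seed = 1)
  expect_lt(abs(approxed$mean_delta - exact), 5 * approxed$mc_se + 1e-3)
})

test_that("the dip statistic matches frozen exact values and the bisection oracle", {
  expect_equal(dip_statistic(c(0, 1)), 0.25)
  expect_equal(dip_statistic(c(0, 0, 0, 1, 1, 1)), 0.25)
  expect_equal(dip_statistic(1:10), 1 / 20)
  set.seed(7)
  for (r in 1:8) {
    x <- switch(1 + r %% 4,
                runif(15), rnorm(17), c(rnorm(8), rnorm(9, 5)), rbeta(12, 2, 1))
    expect_equal(dip_statistic(x), dip_oracle(x), tolerance = 1e-7)
  }
})

test_that("bimodality raises the dip and uniform data are not rejected", {
  set.seed(8)
  two_point <- rep(c(0, 1), each = 50) + rnorm(100, sd = 1e-3)
  unif <- runif(100)
  expect_gt(dip_statistic(two_point), dip_statistic(unif))
  ps <- vapply(1:20, function(s) {
    set.seed(s)
    dm <- distance_matrix({
      m <- matrix(0, 8, 8); m[upper.tri(m)] <- runif(28); m + t(m)
    })
    distance_distribution_stats(dm, dip_boot = 300, seed = s)$dip_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("skewness follows the adjusted moment formula and symmetric data give zero", {
  expect_equal(fisher_pearson_skew(c(0, 0, 0, 1, 1, 1)), 0)
  x <- c(1, 2, 3, 4, 100)
  n <- 5
  s <- sqrt(mean((x - mean(x))^2))
  g1 <- mean((x - mean(x))^3) / s^3
  expect_equal(fisher_pearson_skew(x), g1 * sqrt(n * (n - 1)) / (n - 2))
  expect_error(fisher_pearson_skew(rep(2, 10)), "constant")
  dmc <- distance_matrix(matrix(1, 4, 4) - diag(4))
  expect_error(distance_distribution_stats(dmc), "distinct")
})
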