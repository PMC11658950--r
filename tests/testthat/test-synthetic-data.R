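test_that("generated memberships lie on the simplex and regeneration is reproducible", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 10, B = 10), p = 12, k = 3,
                                  missing_rate = 0.2, seed = 11)
  a <- ds$truth$true_memberships
  expect_true(all(a >= 0))
  expect_lt(max(abs(rowSums(a) - 1)), 1e-12)
  ds2 <- generate_cultural_dataset(n_per_region = c(A = 10, B = 10), p = 12, k = 3,
                                   missing_rate = 0.2, seed = 11)
  expect_identical(ds$trait_matrix$values, ds2$trait_matrix$values)
  expect_identical(ds$truth$true_memberships, ds2$truth$true_memberships)
})

test_that("degenerate missing rate and low-rank limits behave as constructed", {
  ds0 <- generate_cultural_dataset(n_per_region = c(A = 8, B = 8), p = 10, k = 2,
                                   missing_rate = 0, seed = 3)
  expect_true(all(ds0$trait_matrix$mask))

  dsr <- generate_cultural_dataset(n_per_region = c(A = 15, B = 15), p = 10, k = 2,
                                   noise_sd = 0, missing_rate = 0, seed = 4,
                                   quantise = FALSE)
  sv <- svd(dsr$trait_matrix$values)$d
  expect_lt(sv[3] / sv[1], 1e-12)   # numerical rank <= 2

  expect_error(generate_cultural_dataset(n_per_region = c(A = 10), missing_rate = 1),
               "missing_rate")
  expect_error(generate_cultural_dataset(n_per_region = c(A = 0, B = 5)),
               "at least one society")
})

test_that("membership moments match Dirichlet theory (Monte-Carlo oracle)", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 300), p = 5, k = 3,
                                  region_params = list(A = c(5, 5, 5)),
                                  missing_rate = 0, seed = 21)
  cm <- colMeans(ds$truth$true_memberships)
  # component variance of Dirichlet(5,5,5): a(a0-a)/(a0^2 (a0+1))
  mc_se <- sqrt((5 * 10) / (15^2 * 16) / 300)
  expect_true(all(abs(cm - 1 / 3) < 3 * mc_se))
})

test_that("every society keeps at least one observation under heavy masking", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 12, B = 12), p = 8, k = 2,
                                  missing_rate = 0.5, seed = 6)
  expect_true(all(rowSums(ds$trait_matrix$mask) > 0))
  expect_lt(abs(mean(!ds$trait_matrix$mask) - 0.5), 0.08)
})

test_that("additive tree distances satisfy the four-point condition and known path sums", {
  for (n in c(5, 8, 12)) {
    g <- generate_additive_tree_distances(n, seed = n)
    expect_true(four_point_holds(g$distances$d))
    expect_equal(g$distances$d, t(g$distances$d))
    expect_true(all(diag(g$distances$d) == 0))
  }
  # hand path-count on the fixed balanced quartet with unit branches
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["a", "b"], 2)
  expect_equal(d["c", "d"], 2)
  expect_equal(d["a", "c"], 4)
  # the generator's metrics are exactly tree-like for the delta-score
  g <- generate_additive_tree_distances(7, seed = 2)
  expect_lt(delta_score(g$distances)$mean_delta, 1e-10)
  expect_error(generate_additive_tree_distances(1), "n_taxa")
})

test_that("outlier injection resamples only the listed societies from the donor region", {
  ds <- generate_cultural_dataset(n_per_region = c(Home = 10, Donor = 10), p = 8, k = 3,
                                  region_params = list(Home = c(8, 1, 1),
                                                       Donor = c(1, 1, 8)),
                                  missing_rate = 0.1, seed = 9)
  same <- inject_outliers(ds, character(0), "Donor")
  expect_identical(same$truth$true_memberships, ds$truth$true_memberships)

  out <- inject_outliers(ds, c("soc_002", "soc_005"), "Donor", seed = 13)
  a <- out$truth$true_memberships
  expect_lt(max(abs(rowSums(a) - 1)), 1e-12)
  expect_true(all(a >= 0))
  expect_setequal(out$truth$outlier_ids, c("soc_002", "soc_005"))
  # region label unchanged; non-target rows unchanged
  expect_identical(out$truth$region_of, ds$truth$region_of)
  untouched <- setdiff(rownames(a), c("soc_002", "soc_005"))
  expect_identical(a[untouched, ], ds$truth$true_memberships[untouched, ])
  # injected rows now look like the donor region (dominant third archetype)
  expect_true(all(a[c("soc_002", "soc_005"), 3] > 0.5))
  expect_error(inject_outliers(ds, "soc_001", "Nowhere"), "unknown donor region")
})

test_that("low-noise unquantised data let PCHA recover the generating profiles", {
  ds <- generate_cultural_dataset(n_per_region = c(A = 25, B = 25, C = 25), p = 20, k = 3,
                                  noise_sd = 0.01, missing_rate = 0, seed = 14,
                                  quantise = FALSE)
  X <- scale(ds$trait_matrix$values, scale = FALSE)
  am <- fit_archetypes(X, 3, n_restarts = 3, seed = 5)
  S_unc <- sweep(am$profiles, 1L, colMeans(ds$trait_matrix$values), `+`)
  perm <- align_archetypes(ds$truth$true_profiles, S_unc)
  expect_true(all(attr(perm, "correlations") > 0.95))
})
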