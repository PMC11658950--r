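#' Generate a synthetic cultural trait dataset with known archetypes
#'
#' Emulates the statistical structure assumed by archetypal analysis of
#' cross-cultural databases: each society's latent trait vector is a convex
#' combination of `k` archetype profiles, with membership weights drawn
#' from a region-specific Dirichlet distribution; Gaussian noise is added,
#' each trait is affinely mapped to its ordinal range and rounded to
#' integer codes, and entries are masked missing-completely-at-random.
#'
#' Defaults mirror the scale of the Austronesian cross-cultural databases
#' the pipeline is aimed at: about 130 societies in five geographic
#' regions, 40 ordinal variables on small integer scales, four archetypes,
#' each region dominated by one archetype, and a quarter of the entries
#' missing.
#'
#' @param n_per_region named integer vector: societies per region.
#' @param p number of trait variables.
#' @param k number of archetypes (>= 2).
#' @param region_params named list mapping each region to a length-`k`
#'   positive Dirichlet concentration vector. Default: base concentration
#'   0.5 with an extra 5 on a region-specific dominant archetype.
#' @param ordinal_levels integer (recycled) or length-`p` vector of ordinal
#'   scale sizes L; observed codes lie in `1..L`. Must be >= 2.
#' @param noise_sd standard deviation of the additive Gaussian noise on
#'   the latent trait values (profiles are drawn from a standard normal,
#'   so this is on the profile scale).
#' @param missing_rate expected fraction of cells masked MCAR, in `[0, 1)`.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param quantise if `FALSE`, skip the affine map and rounding and return
#'   the continuous latent values (useful for rank checks).
#' @return a list with fields `trait_matrix` (a [trait_matrix]) and
#'   `truth` (a `ground_truth` object holding `true_memberships`,
#'   `true_profiles`, `region_params`, `region_of`, `outlier_ids`, `seed`
#'   and the generation parameters needed to regenerate rows).
#' @export
generate_cultural_dataset <- function(n_per_region = c(Malesia = 40, Papuasia = 30,
                                                       OuterMelanesia = 15,
                                                       Micronesia = 15, Polynesia = 30),
                                      p = 40, k = 4,
                                      region_params = NULL,
                                      ordinal_levels = 4,
                                      noise_sd = 0.1,
                                      missing_rate = 0.25,
                                      seed = 1,
                                      quantise = TRUE) {
  stopifnot(k >= 2, p >= 1)
  if (missing_rate >= 1 || missing_rate < 0) stop("missing_rate must be in [0, 1)")
  if (any(n_per_region < 1)) stop("every region must have at least one society")
  regions <- names(n_per_region)
  if (is.null(regions)) stop("n_per_region must be named by region")
  if (is.null(region_params)) {
    region_params <- lapply(seq_along(regions), function(r) {
      a <- rep(0.5, k)
      a[((r - 1) %% k) + 1] <- a[((r - 1) %% k) + 1] + 5
      a
    })
    names(region_params) <- regions
  }
  stopifnot(all(regions %in% names(region_params)))
  if (any(vapply(region_params, function(a) any(a <= 0) || length(a) != k, logical(1))))
    stop("region_params must be positive length-k concentration vectors")
  levels_vec <- rep_len(as.integer(ordinal_levels), p)
  if (any(levels_vec < 2)) stop("ordinal_levels must be >= 2 for every trait")

  n <- sum(n_per_region)
  region_of <- rep(regions, times = n_per_region)
  ids <- sprintf("soc_%03d", seq_len(n))
  names(region_of) <- ids

  alpha <- with_seed(derive_seed(seed, "memberships"), {
    do.call(rbind, lapply(regions, function(r)
      rdirichlet(n_per_region[[r]], region_params[[r]])))
  })
  rownames(alpha) <- ids
  profiles <- with_seed(derive_seed(seed, "profiles"),
                        matrix(rnorm(p * k), p, k))
  colnames(profiles) <- paste0("A", seq_len(k))
  rownames(profiles) <- sprintf("var_%02d", seq_len(p))

  truth <- structure(list(true_memberships = alpha,
                          true_profiles = profiles,
                          region_params = region_params,
                          region_of = region_of,
                          outlier_ids = character(0),
                          seed = seed,
                          noise_sd = noise_sd,
                          ordinal_levels = levels_vec,
                          missing_rate = missing_rate,
                          quantise = quantise),
                     class = "ground_truth")
  build_trait_matrix_from_truth(truth)
}

# Materialise the trait matrix implied by a ground_truth object:
# latent = alpha %*% t(profiles) + noise, per-trait min-max map to [1, L],
# rounding, then MCAR masking redrawn until no row is fully missing.
build_trait_matrix_from_truth <- function(truth) {
  alpha <- truth$true_memberships
  profiles <- truth$true_profiles
  n <- nrow(alpha); p <- nrow(profiles)
  ids <- rownames(alpha)
  latent <- alpha %*% t(profiles)
  latent <- latent + with_seed(derive_seed(truth$seed, "noise"),
                               matrix(rnorm(n * p, sd = truth$noise_sd), n, p))
  if (truth$quantise) {
    vals <- latent
    lo <- apply(latent, 2, min); hi <- apply(latent, 2, max)
    for (j in seq_len(p)) {
      L <- truth$ordinal_levels[j]
      if (hi[j] - lo[j] < .Machine$double.eps) {
        vals[, j] <- 1
      } else {
        vals[, j] <- round(1 + (L - 1) * (latent[, j] - lo[j]) / (hi[j] - lo[j]))
      }
    }
    # per-trait affine maps, so ground-truth profiles can be expressed on
    # the ordinal data scale for recovery comparisons
    truth$affine_lo <- lo
    truth$affine_hi <- hi
  } else {
    vals <- latent
  }
  mask <- with_seed(derive_seed(truth$seed, "mask"), {
    repeat {
      m <- matrix(runif(n * p) >= truth$missing_rate, n, p)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
    }
    m
  })
  vals[!mask] <- NA
  trait_meta <- data.frame(name = rownames(profiles),
                           cultural_class = "synthetic",
                           kind = if (truth$quantise) "ordinal" else "continuous",
                           min_level = 1L,
                           max_level = truth$ordinal_levels,
                           stringsAsFactors = FALSE)
  society_meta <- data.frame(id = ids,
                             region = unname(truth$region_of[ids]),
                             language_group = unname(truth$region_of[ids]),
                             polynesian_outlier_flag = ids %in% truth$outlier_ids,
                             stringsAsFactors = FALSE)
  tm <- trait_matrix(vals, trait_meta, society_meta)
  list(trait_matrix = tm, truth = truth)
}

#' Ground-truth archetype profiles on the observed data scale
#'
#' Applies each trait's quantisation affine map to the latent generating
#' profiles, so they are directly comparable with profiles recovered from
#' the integer-coded data (per-trait scaling otherwise distorts
#' column-wise correlations).
#'
#' @param truth a `ground_truth` object.
#' @return a `p x k` profile matrix on the ordinal code scale (the latent
#'   profiles unchanged when quantisation was disabled).
#' @export
true_profiles_on_data_scale <- function(truth) {
  S <- truth$true_profiles
  if (!isTRUE(truth$quantise) || is.null(truth$affine_lo)) return(S)
  rng <- pmax(truth$affine_hi - truth$affine_lo, .Machine$double.eps)
  1 + (truth$ordinal_levels - 1) * (S - truth$affine_lo) / rng
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d societies, %d traits, k = %d archetypes, %d regions\n",
              nrow(x$true_memberships), nrow(x$true_profiles),
              ncol(x$true_memberships), length(x$region_params)))
  if (length(x$outlier_ids))
    cat("injected outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Inject cultural outliers into a synthetic dataset
#'
#' Resamples the membership rows of the listed societies from a donor
#' region's Dirichlet distribution while leaving their region label
#' unchanged, then regenerates their trait values. This creates the
#' detectable condition the outlier test targets: a society whose cultural
#' profile matches a foreign region rather than its geographic neighbours.
#'
#' @param dataset a list `(trait_matrix, truth)` from
#'   [generate_cultural_dataset()].
#' @param society_ids ids of societies to convert into outliers.
#' @param donor_region region whose Dirichlet distribution supplies the new
#'   membership rows; must differ from each society's home region to be
#'   meaningful.
#' @param seed integer seed for the resampling.
#' @return a list `(trait_matrix, truth)` with updated memberships, trait
#'   rows and `outlier_ids`.
#' @export
inject_outliers <- function(dataset, society_ids, donor_region, seed = 1) {
  truth <- dataset$truth
  if (!donor_region %in% names(truth$region_params))
    stop("unknown donor region: ", donor_region)
  if (!length(society_ids)) return(dataset)
  if (!all(society_ids %in% rownames(truth$true_memberships)))
    stop("unknown society id(s): ",
         paste(setdiff(society_ids, rownames(truth$true_memberships)), collapse = ", "))
  new_rows <- with_seed(derive_seed(seed, "inject"),
                        rdirichlet(length(society_ids),
                                   truth$region_params[[donor_region]]))
  truth$true_memberships[society_ids, ] <- new_rows
  truth$outlier_ids <- union(truth$outlier_ids, society_ids)
  build_trait_matrix_from_truth(truth)
}

#' Random additive-tree distance matrix
#'
#' Generates a random binary tree with positive branch lengths and returns
#' its path-length metric, which satisfies the four-point condition
#' exactly; used as the tree-like limit for delta-score, Q-residual and
#' Neighbor-Net consistency checks.
#'
#' @param n_taxa number of tips (>= 2; >= 4 for quartet-based statistics).
#' @param branch_length_law function(n) returning n positive branch
#'   lengths; defaults to `runif(n, 0.1, 1)`.
#' @param seed integer seed.
#' @return list with `distances` (a [distance_matrix]) and `newick` (the
#'   generating tree as a Newick string).
#' @export
generate_additive_tree_distances <- function(n_taxa,
                                             branch_length_law = function(n) runif(n, 0.1, 1),
                                             seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  tr <- with_seed(derive_seed(seed, "tree"), {
    tr <- ape::rtree(n_taxa, rooted = n_taxa < 4,
                     tip.label = paste0("t", seq_len(n_taxa)))
    tr$edge.length <- branch_length_law(nrow(tr$edge))
    tr
  })
  d <- ape::cophenetic.phylo(tr)
  ord <- paste0("t", seq_len(n_taxa))
  d <- d[ord, ord]
  list(distances = distance_matrix(d, ord),
       newick = ape::write.tree(tr))
}
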