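#' Archetype memberships over posterior reconstructions
#'
#' Draws `N` completed matrices from the VBPCA reconstruction posterior,
#' refits the archetypes on each (warm-started from the point-estimate
#' model, whose neighbourhood the posterior draws occupy) and aligns the
#' archetype columns to the reference fit by profile correlation. The
#' result feeds the posterior-resampled outlier test.
#'
#' @param model a `vbpca_model`.
#' @param am the reference `archetype_model` fitted on [impute()] output.
#' @param N number of posterior draws.
#' @param seed integer seed.
#' @param max_iter PCHA iteration cap per draw (warm start needs few).
#' @return list of `N` aligned membership matrices (rows named by society).
#' @export
sample_archetype_memberships <- function(model, am, N = 100, seed = 1,
                                         max_iter = 200) {
  draws <- sample_posterior(model, N, seed = derive_seed(seed, "memb_draws"))
  lapply(draws, function(Xs) {
    fit <- pcha_optimise(Xs, am$beta, tol = 1e-7, max_iter = max_iter)
    S <- crossprod(Xs, fit$beta)
    perm <- align_archetypes(am$profiles, S)
    a <- fit$alpha[, perm, drop = FALSE]
    dimnames(a) <- dimnames(am$alpha)
    a
  })
}

#' Run the full per-cultural-class analysis
#'
#' Orchestrates, for every cultural class in the configuration: coverage
#' filtering, VBPCA imputation, archetype-number selection, archetypal
#' analysis, K-means cluster-count selection, archetype-space distances,
#' Neighbor-Net splits (skipped with a note when the class has only two
#' archetypes, whose network degenerates to a two-branch tree),
#' delta-score / Q-residual tree-likeness, distance-distribution
#' statistics, regional Dirichlet fits, pairwise region tests, flagged
#' outlier tests against the reference region, and per-region normalised
#' Fst. All randomness derives from the single master seed in the
#' configuration, so a rerun with the same configuration is identical.
#'
#' @param config a list, or path to a YAML file, with fields `seed`,
#'   `out_dir`, `reference_region`, `n_posterior`, `sig_level`,
#'   `dip_boot`, and either `synthetic` (named list of per-class
#'   [generate_cultural_dataset()] argument lists, each optionally with an
#'   `outliers` block `list(ids=..., donor_region=...)`) or `files`
#'   (`values`, `trait_meta`, `society_meta` CSV paths).
#' @return a `report_bundle` list (also written to `out_dir` as
#'   `report.json`, `report.md` and per-class CSV/PHYLIP/NEXUS files).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("cultarch_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig <- config$sig_level %||% 0.05
  n_post <- config$n_posterior %||% 100L
  dip_boot <- config$dip_boot %||% 2000L
  ref_region <- config$reference_region %||% "Polynesia"

  classes <- load_class_data(config, seed)
  bundle <- list(provenance = list(config = config, seed = seed,
                                   version = as.character(utils::packageVersion("cultarch"))),
                 classes = list(), failures = list())

  for (cls in names(classes)) {
    res <- tryCatch(
      analyse_class(classes[[cls]], cls, out_dir,
                    seed = derive_seed(seed, "class", match(cls, names(classes))),
                    sig = sig, n_post = n_post, dip_boot = dip_boot,
                    ref_region = ref_region),
      error = function(e) structure(list(stage = attr(e, "stage") %||% "unknown",
                                         message = conditionMessage(e)),
                                    class = "class_failure"))
    if (inherits(res, "class_failure")) {
      bundle$failures[[cls]] <- unclass(res)
    } else {
      bundle$classes[[cls]] <- res
    }
  }
  write_report(bundle, out_dir)
  invisible(structure(bundle, class = "report_bundle", out_dir = out_dir))
}

load_class_data <- function(config, seed) {
  if (!is.null(config$synthetic)) {
    out <- list()
    for (i in seq_along(config$synthetic)) {
      cls <- names(config$synthetic)[i]
      args <- config$synthetic[[i]]
      outliers <- args$outliers
      args$outliers <- NULL
      if (!is.null(args$n_per_region)) args$n_per_region <- unlist(args$n_per_region)
      if (!is.null(args$region_params)) args$region_params <- lapply(args$region_params, unlist)
      args$seed <- args$seed %||% derive_seed(seed, "synthclass", i)
      ds <- do.call(generate_cultural_dataset, args)
      if (!is.null(outliers)) {
        ids <- outliers$ids %||% {
          # default: first societies of the donor-complement region list
          ro <- ds$truth$region_of
          names(ro)[ro != outliers$donor_region][seq_len(outliers$n %||% 1L)]
        }
        ds <- inject_outliers(ds, ids, outliers$donor_region,
                              seed = derive_seed(seed, "inject", i))
      }
      ds$trait_matrix$trait_meta$cultural_class <- cls
      out[[cls]] <- ds$trait_matrix
    }
    out
  } else if (!is.null(config$files)) {
    tm <- read_trait_table(config$files$values, config$files$trait_meta,
                           config$files$society_meta)
    split_by_class(tm)
  } else stop("config needs a 'synthetic' or 'files' block")
}

#' Split a trait matrix into per-class matrices
#'
#' One [trait_matrix] per `cultural_class` in the trait metadata;
#' societies with no observation in a class are dropped from that class
#' only (classes are analysed independently).
#'
#' @param tm a [trait_matrix].
#' @return named list of [trait_matrix] objects.
#' @export
split_by_class <- function(tm) {
  out <- list()
  for (cls in unique(tm$trait_meta$cultural_class)) {
    keep <- tm$trait_meta$cultural_class == cls
    vals <- tm$values[, keep, drop = FALSE]
    rows <- rowSums(!is.na(vals)) > 0
    out[[cls]] <- trait_matrix(vals[rows, , drop = FALSE],
                               tm$trait_meta[keep, , drop = FALSE],
                               tm$society_meta[rows, , drop = FALSE])
  }
  out
}

analyse_class <- function(tm, cls, out_dir, seed, sig, n_post, dip_boot,
                          ref_region) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      err <- simpleError(sprintf("[class %s, stage %s] %s", cls, name,
                                 conditionMessage(e)))
      attr(err, "stage") <- name
      stop(err)
    })
  }
  tmf <- stage("coverage_filter", filter_by_coverage(tm))
  vb <- stage("vbpca", fit_vbpca(tmf, seed = derive_seed(seed, "vbpca")))
  sel <- stage("select_k", select_num_archetypes(vb, N = max(20L, n_post),
                                                 sig_level = sig,
                                                 seed = derive_seed(seed, "selk")))
  k_use <- max(2L, sel$k)
  X <- impute(vb)
  am <- stage("archetypes", fit_archetypes(X, k_use,
                                           seed = derive_seed(seed, "pcha")))
  clus <- stage("kmeans", select_num_kmeans_clusters(am, seed = derive_seed(seed, "kmeans")))
  dm <- stage("distances", archetype_distances(am))
  utils::write.csv(data.frame(id = rownames(am$alpha), am$alpha, check.names = FALSE),
                   file.path(out_dir, sprintf("alpha_%s.csv", cls)), row.names = FALSE)
  utils::write.csv(data.frame(variable = rownames(am$profiles), am$profiles,
                              check.names = FALSE),
                   file.path(out_dir, sprintf("profiles_%s.csv", cls)), row.names = FALSE)
  utils::write.csv(data.frame(id = rownames(X), sweep(X, 2L, vb$column_means, `+`),
                              check.names = FALSE),
                   file.path(out_dir, sprintf("imputed_%s.csv", cls)), row.names = FALSE)
  write_distance_phylip(dm, file.path(out_dir, sprintf("distances_%s.phy", cls)))

  network_note <- NULL
  splits_path <- NULL
  nnet_fit <- NULL
  if (k_use > 2) {
    ss <- stage("neighbor_net", neighbor_net(dm))
    splits_path <- file.path(out_dir, sprintf("splits_%s.nex", cls))
    write_splits_nexus(ss, splits_path)
    nnet_fit <- ss$fit
  } else {
    network_note <- "k = 2: split network degenerates to a two-branch tree; Neighbor-Net skipped"
  }
  tl_delta <- stage("delta_score", delta_score(dm, seed = derive_seed(seed, "delta")))
  tl_q <- stage("q_residual", q_residual(dm, seed = derive_seed(seed, "qres")))
  dstats <- stage("distance_stats",
                  distance_distribution_stats(dm, dip_boot = dip_boot,
                                              seed = derive_seed(seed, "dip")))

  regions <- tm$society_meta$region[match(rownames(am$alpha), tm$society_meta$id)]
  names(regions) <- rownames(am$alpha)
  big_regions <- names(which(table(regions) >= k_use + 1))
  dir_fits <- lapply(big_regions, function(r)
    tryCatch(fit_dirichlet(am$alpha[regions == r, , drop = FALSE]),
             error = function(e) NULL))
  names(dir_fits) <- big_regions
  fst_by_region <- vapply(big_regions, function(r)
    normalized_fst(am$alpha[regions == r, , drop = FALSE]), numeric(1))

  rt <- matrix(NA_real_, length(big_regions), length(big_regions),
               dimnames = list(big_regions, big_regions))
  for (i in seq_along(big_regions)) for (j in seq_along(big_regions)) {
    if (i < j) {
      p <- tryCatch(region_test(am$alpha[regions == big_regions[i], , drop = FALSE],
                                am$alpha[regions == big_regions[j], , drop = FALSE],
                                sig = sig)$p_value,
                    error = function(e) NA_real_)
      rt[i, j] <- rt[j, i] <- p
    }
  }

  flagged_ids <- tm$society_meta$id[tm$society_meta$polynesian_outlier_flag]
  flagged_ids <- intersect(flagged_ids, rownames(am$alpha))
  outlier_tab <- NULL
  if (length(flagged_ids) && ref_region %in% big_regions) {
    post_memb <- stage("posterior_memberships",
                       sample_archetype_memberships(vb, am, N = n_post,
                                                    seed = derive_seed(seed, "post")))
    rows <- lapply(flagged_ids, function(id) {
      home <- regions[[id]]
      if (identical(home, ref_region) || !(home %in% big_regions))
        return(data.frame(society = id, home_region = home, statistic = NA,
                          p_value = NA, flagged = NA,
                          note = "home region is the reference or too small"))
      if (!isTRUE(rt[home, ref_region] < sig))
        return(data.frame(society = id, home_region = home, statistic = NA,
                          p_value = NA, flagged = NA,
                          note = "home region not significantly distinct from reference"))
      tt <- tryCatch(outlier_test(post_memb, id, home, ref_region, regions, sig = sig),
                     error = function(e) NULL)
      if (is.null(tt))
        return(data.frame(society = id, home_region = home, statistic = NA,
                          p_value = NA, flagged = NA, note = "test failed"))
      data.frame(society = id, home_region = home, statistic = tt$statistic,
                 p_value = tt$p_value, flagged = tt$flagged, note = "")
    })
    outlier_tab <- do.call(rbind, rows)
    utils::write.csv(outlier_tab,
                     file.path(out_dir, sprintf("outliers_%s.csv", cls)),
                     row.names = FALSE)
  }

  list(n_societies = nrow(am$alpha),
       retained_variables = colnames(tmf$values),
       k_selected = sel$k,
       k_used = k_use,
       eigenvalue_report = sel$report,
       vbpca = list(converged = vb$converged, noise_variance = vb$noise_variance,
                    d = vb$d, iterations = length(vb$free_energy)),
       archetypes = list(sse = am$sse, explained_variance = am$explained_variance),
       clusters = list(n_clusters = clus$n_clusters, rule = clus$rule,
                       metrics = clus$metrics),
       dirichlet_fits = lapply(dir_fits, function(f)
         if (is.null(f)) NULL else list(concentration = unname(f$concentration),
                                        loglik = f$loglik)),
       region_test_p = rt,
       normalized_fst = as.list(fst_by_region),
       outliers = outlier_tab,
       network = list(skipped = !is.null(network_note), note = network_note,
                      splits_file = splits_path, fit = nnet_fit),
       treelikeness = list(mean_delta = tl_delta$mean_delta,
                           mean_q_residual = tl_q$mean_q_residual),
       distance_stats = list(skew = dstats$skew,
                             dip_statistic = dstats$dip_statistic,
                             dip_p = dstats$dip_p))
}

write_report <- function(bundle, out_dir) {
  jsonlite::write_json(bundle, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       force = TRUE, na = "null")
  lines <- c("# cultarch pipeline report", "",
             sprintf("Master seed: %s", bundle$provenance$seed), "")
  for (cls in names(bundle$classes)) {
    r <- bundle$classes[[cls]]
    lines <- c(lines,
               sprintf("## %s", cls),
               sprintf("- societies: %d, retained variables: %d",
                       r$n_societies, length(r$retained_variables)),
               sprintf("- archetypes: selected k = %d (used %d); explained variance %.1f%%",
                       r$k_selected, r$k_used, 100 * r$archetypes$explained_variance),
               sprintf("- clusters: %d (%s)", r$clusters$n_clusters, r$clusters$rule),
               sprintf("- mean delta-score %.3f; mean Q-residual %.4g",
                       r$treelikeness$mean_delta, r$treelikeness$mean_q_residual),
               sprintf("- distance skew %.3f; dip %.4f (p = %.3f)",
                       r$distance_stats$skew, r$distance_stats$dip_statistic,
                       r$distance_stats$dip_p),
               if (!is.null(r$network$note)) sprintf("- network: %s", r$network$note)
               else sprintf("- network fit: %.2f%%", 100 * r$network$fit),
               if (!is.null(r$outliers))
                 sprintf("- outliers flagged: %d of %d tested",
                         sum(r$outliers$flagged %in% TRUE),
                         sum(!is.na(r$outliers$p_value)))
               else "- outliers: none tested",
               "")
  }
  for (cls in names(bundle$failures)) {
    f <- bundle$failures[[cls]]
    lines <- c(lines, sprintf("## %s (FAILED at %s)", cls, f$stage), f$message, "")
  }
  writeLines(lines, file.path(out_dir, "report.md"))
}
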