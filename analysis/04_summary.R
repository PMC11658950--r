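#!/usr/bin/env Rscript
# Cross-class summary of the pipeline run: how many archetypes each
# cultural class has, how tree-like its archetype-distance network is,
# how the distance distributions are shaped, and whether the injected
# Polynesian-style outliers were recovered. Writes results/summary.csv
# and prints the comparison table.

suppressPackageStartupMessages(library(cultarch))

report <- jsonlite::read_json("results/pipeline/report.json")
truth <- jsonlite::read_json("results/data/ground_truth.json")

rows <- lapply(names(report$classes), function(cls) {
  r <- report$classes[[cls]]
  ot <- tryCatch(utils::read.csv(sprintf("results/pipeline/outliers_%s.csv", cls)),
                 error = function(e) NULL)
  injected <- unlist(truth[[cls]]$outlier_ids)
  flagged <- if (!is.null(ot)) ot$society[ot$flagged %in% TRUE] else character(0)
  data.frame(
    class = cls,
    k_true = truth[[cls]]$k,
    k_selected = r$k_selected,
    n_clusters = r$clusters$n_clusters,
    explained_variance = round(r$archetypes$explained_variance, 3),
    mean_delta = round(r$treelikeness$mean_delta, 3),
    mean_q_residual = signif(r$treelikeness$mean_q_residual, 3),
    skew = round(r$distance_stats$skew, 3),
    dip = round(r$distance_stats$dip_statistic, 4),
    dip_p = round(r$distance_stats$dip_p, 3),
    outliers_injected = length(injected),
    outliers_recovered = sum(flagged %in% injected),
    false_outliers = sum(!flagged %in% injected))
})
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/summary.csv", row.names = FALSE)
print(tab, row.names = FALSE)

cat("\nReading the table: classes whose distance networks are more",
    "tree-like (lower mean delta) are the ones whose transmission the",
    "archetype geometry represents as more vertical; outlier recovery",
    "shows the posterior-resampled Mann-Whitney test finding the",
    "societies whose memberships were injected from Polynesia's",
    "Dirichlet distribution.\n")
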