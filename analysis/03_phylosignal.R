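#!/usr/bin/env Rscript
# Phylogenetic signal of individual traits over a language phylogeny.
# The study dataset has no real language tree, so this driver shows the
# check on simulated tip data: a random 130-tip phylogeny stands in for
# the language tree, one binary trait is evolved with strong vertical
# transmission (Brownian threshold), one is shuffled across tips (no
# signal), and one is a 50/50 blend. Writes results/phylosignal.csv.

suppressPackageStartupMessages(library(cultarch))

seed <- 20260929
set.seed(seed)
tree <- ape::rcoal(130, tip.label = sprintf("soc_%03d", 1:130))
ape::write.tree(tree, "results/language_tree.nwk")

bm <- as.numeric(ape::rTraitCont(tree, model = "BM"))
names(bm) <- tree$tip.label

traits <- list(
  vertical_binary = setNames(as.numeric(bm > median(bm)), names(bm)),
  shuffled        = setNames(bm, sample(names(bm))),
  half_shuffled   = {
    x <- bm; idx <- sample(130, 65); x[idx] <- x[sample(idx)]; x
  })

rows <- lapply(names(traits), function(nm) {
  r <- pagel_lambda(tree, traits[[nm]])
  data.frame(trait = nm, lambda = r$lambda_hat,
             loglik = r$loglik_at_hat, loglik0 = r$loglik_at_zero,
             p_value = r$p_value, n_tips = r$n_tips)
})
tab <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
utils::write.csv(tab, "results/phylosignal.csv", row.names = FALSE)
print(tab, digits = 3)
cat("\nStrongly vertically transmitted traits keep lambda near 1;",
    "shuffling destroys the signal (lambda near 0, large p).\n")
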