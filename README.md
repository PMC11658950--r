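# cultarch

Archetypal analysis of cross-cultural trait matrices, with imputation,
regional outlier tests and phylogenetic-network measures of cultural
transmission.

## The problem

Cross-cultural databases (D-PLACE exports of the Ethnographic Atlas,
Pulotu) describe each society by dozens of ordinal or categorical
variables coded as small integers, with 10–50% of the cells missing.
Researchers in cultural macroevolution want to know, per class of
variables (social organisation, subsistence, religion, cultural
interaction):

* what the major **archetypes** of variation are, and how strongly each
  society belongs to each — the cultural analogue of admixture
  proportions;
* whether regions differ in their archetype distributions, and which
  societies are **cultural outliers** better explained by a distant
  region (the "Polynesian outlier" situation: Polynesian-speaking
  societies far outside the Polynesian Triangle);
* how **vertical** the transmission of each cultural class was, read
  from the tree-likeness of phylogenetic networks built on distances in
  archetype space.

cultarch implements that chain end to end, for users of the real
databases and — via a bundled generator with known ground truth — for
anyone who wants to validate the methods before trusting them.

## The models in one paragraph each

**Imputation.** Variational Bayesian PCA (`fit_vbpca()`) fits
`x_ij = m_j + w_j' z_i + noise` to observed cells only, with ARD priors
that prune unsupported components. It returns a posterior mean and
variance for every cell, so downstream tests can resample whole
completed datasets (`sample_posterior()`) instead of conditioning on one
imputation.

**Archetypes.** PCHA archetypal analysis (`fit_archetypes()`)
approximates the completed centred matrix as `X ~ alpha beta' X` with
`alpha` rows and `beta` columns on the probability simplex;
`alpha[i, j]` is the membership of society `i` in archetype `j` and
`S = X' beta` are the archetype profiles. The number of archetypes is
chosen by a resampling eigenvalue test (`select_num_archetypes()`):
`k - 1` eigenvalues of the reconstruction covariance should exceed a
null built from column-permuted posterior samples.

**Regions and outliers.** Regional membership matrices are modelled as
Dirichlet samples (`fit_dirichlet()`, Newton MLE). `region_test()` is a
likelihood-ratio chi-square test of shared versus distinct regional
Dirichlets; `outlier_test()` asks, across `N` posterior datasets,
whether a reference region's Dirichlet explains a society better than
its home region (one-sided Mann–Whitney on the two log-likelihood
sets); `normalized_fst()` summarises regional differentiation on a 0–1
scale.

**Transmission.** Pairwise Euclidean distances between membership rows
(`archetype_distances()`) feed a Neighbor-Net split network
(`neighbor_net()`, written as NEXUS for SplitsTree), and tree-likeness
is scored by quartet delta-scores and Q-residuals (`delta_score()`,
`q_residual()`): both are exactly 0 on additive tree metrics, and higher
values indicate reticulation — non-vertical transmission. Distance
distributions are summarised by skewness and Hartigan's dip test
(`distance_distribution_stats()`), and per-trait phylogenetic signal
over a language phylogeny by Pagel's lambda (`pagel_lambda()`).

## Worked example

The `analysis/` scripts are the full workflow. `analysis/01_simulate.R`
builds a 130-society, 64-variable dataset over five Oceanian-style
regions and four cultural classes (5/4/4/2 generating archetypes, 25%
missing), injecting three societies whose social-organisation,
subsistence and religion memberships come from Polynesia's distribution
while they stay labelled Papuasia / Outer Melanesia.
`analysis/02_pipeline.R` runs `run_pipeline()` on the resulting CSVs;
`analysis/04_summary.R` compares the output with the generator's ground
truth and printed, on this run:

```
                class k_true k_selected n_clusters explained_variance
  social organisation      5          4          4              0.906
          subsistence      4          4          4              0.989
             religion      4          4          4              0.993
 cultural interaction      2          2          2              0.988
 mean_delta   skew    dip dip_p outliers_injected outliers_recovered false_outliers
      0.228 -0.402 0.0039 0.313                 3                  3              0
      0.212 -0.186 0.0273 0.001                 3                  3              0
      0.221 -0.064 0.0115 0.001                 3                  3              0
      0.000  0.241 0.0695 0.001                 0                  0              0
```

Reading it: three of the four classes recover their generating
archetype count exactly (for social organisation the fifth archetype's
eigenvalue does not clear the resampling null at this noise and
missingness, so the test conservatively returns 4); all nine injected
Polynesian-style outliers are flagged with no false positives; the
two-archetype cultural-interaction class has delta-score exactly 0 — its
"network" is a line between the two archetypes, which is why the
pipeline skips Neighbor-Net for it; and the three multi-archetype
classes show the moderate delta-scores (0.21–0.23) expected of data
that mix regional continuity with Dirichlet overlap.
`analysis/03_phylosignal.R` shows the lambda check: a Brownian binary
trait on a 130-tip tree gets `lambda = 1.00, p = 9e-48`, its shuffled
copy `lambda = 0.00, p = 1`.

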