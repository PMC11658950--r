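---
title: "Methods: archetypes, outliers and tree-likeness in cross-cultural trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: archetypes, outliers and tree-likeness in cross-cultural trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cultarch analyses society-by-variable tables of integer-coded cultural
traits — the kind of wide export one gets from cross-cultural databases
such as the Ethnographic Atlas or Pulotu via D-PLACE — and asks two
linked questions: what are the major *archetypes* of cultural variation
within a class of variables (social organisation, subsistence, religion,
cultural interaction), and how *vertically* were those cultural packages
transmitted along the expansion of the societies that carry them. This
vignette explains each model in the chain, the tunable parameters, what
the bundled synthetic-data generator does and does not emulate, and the
numerical choices that were genuinely open.

## 1. Imputation and denoising: VBPCA

Cross-cultural tables are sparse (10–50% missing is typical) and
variables are coded on short ordinal scales. We first drop variables
observed in fewer than half of the societies (`filter_by_coverage()`,
`min_fraction = 0.5`), then fit variational Bayesian PCA
(`fit_vbpca()`) to the observed cells only.

The model is `x_ij = m_j + w_j' z_i + noise`, with Gaussian variational
posteriors over the scores `z_i` and loadings `w_j`, a shared noise
variance, and per-component automatic relevance determination (ARD)
precisions on the loading columns. ARD is what supplies the "noise
filtering": components the data do not support are shrunk until their
per-entry contribution falls well below the noise floor, at which point
they are pruned (the jump to the infinite-precision limit of the
coordinate-ascent path cannot decrease the variational objective). All
updates are exact coordinate maximisations of the free energy, so the
objective is non-decreasing — the test suite asserts this per iteration
with a `1e-8` relative slack.

Parameters that matter:

* `d_max` (default `min(n, p) - 1` capped at 30): the latent dimension
  before ARD pruning. At the ~130 x 40–70 scale of these datasets the
  cap is not binding in practice; smaller values trade a little
  fidelity for speed.
* `tol` (default `1e-6` relative free-energy change): convergence. The
  imputation error is insensitive to the last order of magnitude; the
  repeated-fit simulations in the tests and the acceptance script use
  `1e-5` with an iteration cap so that 50-seed studies finish in
  minutes; single analyses use the default.

The model exposes a per-entry posterior mean and variance of the
completed matrix. `impute()` returns the mean-centred posterior mean —
this completed, centred, denoised matrix is exactly what archetypal
analysis consumes. `sample_posterior()` draws completed matrices
entry-wise at the reconstruction moments (subspace uncertainty plus
noise variance); these draws feed both the archetype-number test and the
outlier test, so every downstream significance statement propagates the
imputation uncertainty.

## 2. How many archetypes: a resampling eigenvalue test

Mean-centred data generated from `k` archetypes span `k - 1` dimensions
(the memberships live on a simplex, which loses one dimension under
centering). `select_num_archetypes()` therefore counts "large"
eigenvalues of the reconstructed data covariance and returns that count
plus one. "Large" is judged against an empirical null rather than a
theoretical eigenvalue law: each of `N` posterior draws of the completed
matrix has its columns independently permuted — destroying inter-trait
covariance while preserving every marginal — and the eigen-spectra of
the permuted draws form a per-rank null distribution. An observed
eigenvalue is significant when it exceeds the `1 - sig_level` null
quantile, counting stops at the first failure, and the monotonicity of
the construction means raising `sig_level` can never decrease `k`. The
column-permutation null is our concrete choice; it is documented and
tested here rather than inherited from any particular reference
implementation.

## 3. Archetypal analysis (PCHA)

`fit_archetypes()` approximates the completed centred matrix `X`
(`n x p`) as `X ~ alpha beta' X`, where rows of `alpha` (`n x k`) lie on
the probability simplex — `alpha[i, j]` is the membership coefficient of
society `i` in archetype `j`, exactly analogous to an admixture
proportion — and columns of `beta` (`n x k`) lie on the simplex, so each
archetype profile `S = X' beta` is a convex combination of observed
societies. Optimisation alternates projected-gradient steps on `alpha`
and `beta` with adaptive step sizes and exact simplex projection; the
sum of squared errors is non-increasing by construction. `beta` support
is seeded by furthest-sum, the best of `n_restarts` (default 10) runs is
kept, and sparsity in `beta` comes from the simplex projection itself —
no extra penalty. Archetype columns are canonicalised by descending
total membership mass so that repeated runs report archetypes in a
stable order. Restart counts and tolerances are our defaults; the
underlying relaxation is the standard principal-convex-hull form.

Clustering *within* the archetype space can be finer than the number of
archetypes (societies sharing a characteristic mixture form their own
cluster). `select_num_kmeans_clusters()` scans counts from `k - 2` to
`k + 2` (floored at 2; for `k = 2` the scan is 2–4), runs K-means with
50 restarts per candidate, and scores each candidate with the silhouette
(higher better), the Calinski–Harabasz variance ratio (higher better)
and the Davies–Bouldin index (lower better). The count optimising at
least two of the three wins; a three-way disagreement falls back to
`k`; metric ties break toward the smaller count (parsimony).

## 4. Regional structure and outliers: Dirichlet machinery

A region's membership rows are modelled as a Dirichlet sample — the
natural distribution on the simplex. `fit_dirichlet()` maximises the
likelihood by Newton iteration with the diagonal-plus-rank-one Hessian
inverted in closed form, falling back to the classical digamma
fixed-point when a step leaves the positive orthant. PCHA can emit exact
zeros, which have infinite negative Dirichlet density for concentrations
below one, so rows are clipped to `[1e-6, 1 - 1e-6]` and renormalised
before fitting. Non-convergence (e.g. identical rows, whose MLE
diverges) is an error, not a silent result.

`region_test()` compares a shared-Dirichlet null (`k` parameters)
against separate per-region Dirichlets (`2k` parameters) with a
likelihood-ratio statistic on `chi^2_k` — the degrees of freedom are the
parameter-count difference, which the source description of the test
leaves implicit. Simulation places its size at the nominal level
(the acceptance suite requires the empirical type-I rate in
`[0.02, 0.09]` at nominal 0.05 over 1000 replicates).

`outlier_test()` asks whether a *reference* region (Polynesia, in the
motivating analyses) explains a flagged society better than its own
geographic region. For each of `N` posterior membership samples,
Dirichlets are fitted to the reference and home regions and the
society's log-likelihood is computed under both; the two sets of `N`
log-likelihoods enter a one-sided Mann–Whitney U test (normal
approximation with tie correction at `N >= 20`, exact below) with the
alternative that the reference log-likelihoods are stochastically
dominant. Two choices here were open and are ours: the tested society is
excluded from both regional fits (avoiding self-inflation of the home
likelihood), and `N` defaults to 100. The pipeline only tests societies
whose home region is significantly distinct from the reference, mirroring
the logic that an "outlier" is only meaningful against a distinct
background.

Regional differentiation is summarised by a normalised Fst
(`normalized_fst()`): each archetype column is treated as an allele
frequency, columns contribute `var(q) / (qbar (1 - qbar))` weighted by
`qbar (1 - qbar)`, giving 0 for identical rows, 1 for pure simplex
vertices, and a value that decreases monotonically with the Dirichlet
concentration of the sample.

## 5. Distances, networks, tree-likeness

Cultural distance is the Euclidean distance between membership rows
(`archetype_distances()`): distances in archetype space respect the
covariance structure of traits in a way raw trait-space metrics do not.

`neighbor_net()` builds a split network from the distance matrix: the
agglomerative Neighbor-Net construction (neighbour-joining selection
applied twice, once over clusters and once over their linking nodes,
with joined triples reduced to weighted pairs) yields a circular
ordering of the societies; weights for all contiguous-arc splits of that
ordering are then estimated by non-negative least squares (Lawson–Hanson
active set, columns generated on demand, gradients over all candidate
splits via two-dimensional prefix sums) and splits below `1e-9` are
pruned. On an additive tree metric the recovered splits are exactly the
tree's edges with their branch lengths; on a circular (reticulate)
metric the generating splits are recovered with their weights — both are
enforced at `1e-6` in the acceptance suite. Networks are written as
NEXUS TAXA + SPLITS blocks (with the ordering as CYCLE) for viewers
such as SplitsTree. A class with only two archetypes is skipped: its
"network" is a line segment between the two archetypes and carries no
reticulation information.

Tree-likeness is quantified per quartet. Order the three pairwise-sum
quantities `m1 >= m2 >= m3`; the quartet delta-score is
`(m1 - m2) / (m1 - m3)` (defined 0 when `m1 = m3`) and the Q-residual is
`(m1 - m2)^2`. Both are zero exactly on additive (four-point) metrics;
delta is scale-free while Q is magnitude-sensitive, so Q is computed on
distances normalised to mean 1 by default. The headline score averages
over all `C(n, 4)` quartets (a per-taxon average over the quartets
containing each taxon is reported alongside — the averaging convention
is stated because either could be meant by a "mean" score). Enumeration
is exhaustive up to 200 taxa and switches to seeded quartet subsampling
with a reported Monte-Carlo standard error beyond.

Distance distributions are summarised by the adjusted Fisher–Pearson
skewness and Hartigan's dip statistic of unimodality. The dip is
computed from the band characterisation of unimodal cdf fits: a convex
minorant sweep over prefixes and a concave majorant sweep over suffixes
give, for every modal split, the minimal band width a unimodal cdf
needs; the dip is half the best value. The implementation is validated
against a bisection oracle built directly from that definition and
against exactly known values (`dip = 1/4` for two points or an equal
two-point mixture, `1/(2n)` for equally spaced samples). The dip
p-value is bootstrapped from the uniform null (`dip_boot` default 2000),
which is the classical calibration reference.

## 6. Phylogenetic signal

`pagel_lambda()` profiles the Brownian-motion Gaussian likelihood of a
tip trait with all off-diagonal covariances multiplied by `lambda`; the
ancestral mean and rate are maximised analytically and `lambda` by
bounded search on `[0, 1]`, with a `chi^2_1` likelihood-ratio p-value
against `lambda = 0`. Binary traits are analysed as 0/1 numeric under
the same continuous model — a documented stand-in, since a threshold or
discrete-state model is a different estimator; at the sample sizes here
the continuous `lambda` separates strongly transmitted from shuffled
binary traits cleanly (see `analysis/03_phylosignal.R`). Zero branch
lengths are floored at `1e-8`; a star phylogeny makes `lambda`
unidentifiable and is an explicit error.

## 7. What the synthetic generator emulates — and what it does not

`generate_cultural_dataset()` draws membership rows per region from
region-specific Dirichlet distributions (default: five regions of
40/30/15/15/30 societies, each region's concentration 0.5 everywhere
plus 5 on a region-dominant archetype), multiplies them with standard
normal archetype profiles, adds Gaussian noise (`noise_sd` default 0.1),
min–max maps each trait to `[1, L]` (default `L = 4`, matching codes
like a 1–4 conflict scale) and rounds, then masks cells
missing-completely-at-random (`missing_rate` default 0.25, within the
10–50% range of the real databases), redrawing the mask until no row or
column is entirely missing. `inject_outliers()` resamples chosen
societies' memberships from a donor region while leaving their region
label unchanged — the exact condition a "Polynesian outlier" presents.
`generate_additive_tree_distances()` supplies exactly tree-like metrics
for the tree-limit identities.

The generator deliberately does *not* emulate: informative
(non-random) missingness, mixed categorical/ordinal semantics of real
variables, spatial autocorrelation within regions, or any real
Austronesian trait content. Passing tests therefore demonstrate that the
chain of estimators recovers the structure it assumes, at realistic
sizes and noise — not that real coded ethnography satisfies those
assumptions. The Gaussian-then-round noise model in particular is a
stand-in; nothing is claimed about the error process of real coders.

## 8. Numerical choices and problem sizes

Reproducibility: every stochastic operation takes one integer seed, and
compound procedures derive per-stage child seeds from it
arithmetically; `run_pipeline()` expands a single master seed, so a
rerun with the same configuration is byte-identical. Ties in the
cluster-metric rule break toward smaller counts; quartets with
`m1 = m3` score zero; boundary memberships are clipped before Dirichlet
fits; rank-deficient NNLS candidates are dropped with a tiny ridge
guard.

The simulation studies in the tests and acceptance script use sizes
chosen to make 50–1000-replicate studies comfortable on one core while
staying at the scale the methods target: 150 x 40 matrices for
archetype recovery, 30–50 societies per region for the Dirichlet
operating characteristics, 64-tip balanced trees for `lambda`, and
`N = 50` posterior samples inside the repeated outlier simulations
(single analyses use the `N = 100` default). The full study-scale
drivers under `analysis/` run 130 societies x 64 variables across four
classes.

Known limitations: PCHA solves a non-convex problem — restarts make the
archetype basins stable in practice but global optimality is not
guaranteed; the eigenvalue test inherits the usual conservatism of
permutation nulls when signal eigenvalues are only marginally above
noise; Neighbor-Net's circular ordering is exact on circular metrics but
heuristic otherwise; and the continuous-lambda treatment of binary
traits is a pragmatic approximation, not a threshold model.
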