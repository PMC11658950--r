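#' Maximum-likelihood Dirichlet fit to membership rows
#'
#' Fits a Dirichlet distribution to simplex rows (archetype membership
#' coefficients of the societies in a region) by Minka's fixed-point
#' iteration on the log-likelihood. Rows containing exact 0/1 entries are
#' clipped to `[eps, 1 - eps]` and renormalised before fitting, because
#' boundary memberships (which PCHA can emit) have infinite negative
#' density under concentrations below one.
#'
#' @param memberships matrix whose rows lie on the simplex (>= 2 rows,
#'   >= 2 columns).
#' @param eps boundary clip.
#' @param tol fixed-point convergence tolerance on the concentrations.
#' @param max_iter iteration cap; non-convergence is an error (it signals
#'   a degenerate sample such as identical rows).
#' @return object of class `dirichlet_fit`: `concentration`, `loglik`,
#'   `n_obs`.
#' @export
fit_dirichlet <- function(memberships, eps = 1e-6, tol = 1e-10, max_iter = 10000) {
  m <- as.matrix(memberships)
  if (nrow(m) < 2) stop("need at least 2 membership rows")
  if (ncol(m) < 2) stop("need at least 2 archetype columns")
  m <- pmin(pmax(m, eps), 1 - eps)
  m <- m / rowSums(m)
  logp_bar <- colMeans(log(m))

  # moment-matched initialisation (first two moments of the first column)
  p_bar <- colMeans(m)
  v1 <- stats::var(m[, 1])
  a0 <- if (is.finite(v1) && v1 > 1e-12) {
    max((p_bar[1] * (1 - p_bar[1])) / v1 - 1, 1e-3)
  } else 1e6
  a <- pmax(p_bar * a0, 1e-8)
  ll_init <- dirichlet_loglik_sum(a, logp_bar, nrow(m))

  n <- nrow(m)
  for (it in seq_len(max_iter)) {
    # Newton step with the diagonal-plus-rank-one Hessian inverted in
    # closed form; falls back to the digamma fixed point when the step
    # leaves the positive orthant
    g <- n * (digamma(sum(a)) - digamma(a) + logp_bar)
    q <- -n * trigamma(a)
    z <- n * trigamma(sum(a))
    b <- sum(g / q) / (1 / z + sum(1 / q))
    a_new <- a - (g - b) / q
    if (any(!is.finite(a_new)) || any(a_new <= 0))
      a_new <- pmax(inv_digamma(digamma(sum(a)) + logp_bar), 1e-12)
    if (max(abs(a_new - a) / pmax(a, 1e-12)) < tol) {
      a <- a_new
      ll <- dirichlet_loglik_sum(a, logp_bar, n)
      return(structure(list(concentration = a, loglik = ll,
                            loglik_at_init = ll_init, n_obs = n),
                       class = "dirichlet_fit"))
    }
    a <- a_new
    if (any(!is.finite(a)) || sum(a) > 1e12)
      stop("Dirichlet MLE diverged: degenerate sample (e.g. identical rows)")
  }
  stop("Dirichlet MLE did not converge within ", max_iter, " iterations")
}

#' @export
print.dirichlet_fit <- function(x, ...) {
  cat("dirichlet_fit: concentration (",
      paste(sprintf("%.3f", x$concentration), collapse = ", "),
      "), loglik ", sprintf("%.4f", x$loglik), " on ", x$n_obs, " rows\n", sep = "")
  invisible(x)
}

# total log-likelihood of n rows given sufficient statistics mean log p
dirichlet_loglik_sum <- function(a, logp_bar, n) {
  n * (lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * logp_bar))
}

#' Log-density of simplex rows under a Dirichlet fit
#'
#' @param fit a `dirichlet_fit`.
#' @param x simplex vector or matrix of rows; boundary values are clipped
#'   as in [fit_dirichlet()].
#' @param eps boundary clip.
#' @return numeric vector of log-densities.
#' @export
dirichlet_loglik <- function(fit, x, eps = 1e-6) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  x <- pmin(pmax(x, eps), 1 - eps)
  x <- x / rowSums(x)
  a <- fit$concentration
  lgamma(sum(a)) - sum(lgamma(a)) + as.numeric(log(x) %*% (a - 1))
}

# Newton inversion of the digamma function (Minka's initialisation).
inv_digamma <- function(y, iters = 8) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in seq_len(iters)) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

#' Likelihood-ratio test for distinct regional archetype distributions
#'
#' Null model: both membership matrices are independent samples from one
#' shared Dirichlet distribution (`k` parameters). Alternative: each
#' region has its own Dirichlet (`2k` parameters). The statistic
#' `2 (l_M1 - l_M0)` is referred to a chi-square with `k` degrees of
#' freedom (the parameter-count difference); the two regions are declared
#' significantly distinct when `p < sig`.
#'
#' @param A,B membership matrices sharing the same number of columns.
#' @param sig significance level.
#' @return object of class `cultarch_test` (`kind = "lrt_chi2"`) with
#'   `statistic`, `df`, `p_value`, `reject`, `reject_at`.
#' @export
region_test <- function(A, B, sig = 0.05) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("membership matrices must share k columns")
  fa <- fit_dirichlet(A)
  fb <- fit_dirichlet(B)
  f0 <- fit_dirichlet(rbind(A, B))
  stat <- max(0, 2 * (fa$loglik + fb$loglik - f0$loglik))
  df <- ncol(A)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 reject = p < sig, reject_at = sig, kind = "lrt_chi2"),
            class = "cultarch_test")
}

#' @export
print.cultarch_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g%s, p = %.4g (%ssignificant at %g)\n",
              x$kind, x$statistic,
              if (!is.null(x$df)) sprintf(", df = %d", x$df) else "",
              x$p_value, if (x$reject) "" else "not ", x$reject_at))
  invisible(x)
}

#' Posterior-resampled Mann-Whitney cultural-outlier test
#'
#' For each of `N` posterior membership samples, Dirichlet distributions
#' are fitted to the reference region and to the society's home region
#' (the tested society is excluded from both fits), and the society's
#' membership log-likelihood is computed under each. The two sets of `N`
#' log-likelihoods are compared with a one-sided Mann-Whitney U test with
#' the alternative that the reference-region log-likelihoods are
#' stochastically dominant over the home-region log-likelihoods; the
#' society is flagged a cultural outlier when `p < sig`. A normal
#' approximation with tie correction is used for `N >= 20`, the exact
#' distribution below that.
#'
#' @param posterior_membership_samples list of `N` membership matrices
#'   (identical row names = society ids), e.g. archetype fits to
#'   [sample_posterior()] draws.
#' @param society_id id of the tested society.
#' @param home_region the society's geographic region.
#' @param reference_region the donor region hypothesised to explain the
#'   society better (e.g. Polynesia); must differ from `home_region`.
#' @param region_of named character vector mapping society id to region.
#' @param sig significance level.
#' @return object of class `cultarch_test` (`kind =
#'   "mann_whitney_one_sided"`) with `statistic` (U), `p_value`,
#'   `flagged`, and the two log-likelihood vectors.
#' @export
outlier_test <- function(posterior_membership_samples, society_id,
                         home_region, reference_region, region_of,
                         sig = 0.05) {
  N <- length(posterior_membership_samples)
  if (N < 2) stop("need at least 2 posterior samples")
  if (home_region == reference_region)
    stop("home and reference regions must differ")
  if (region_of[[society_id]] != home_region)
    stop("society '", society_id, "' is not in region '", home_region, "'")
  ids <- rownames(posterior_membership_samples[[1]])
  home_ids <- setdiff(ids[region_of[ids] == home_region], society_id)
  ref_ids <- setdiff(ids[region_of[ids] == reference_region], society_id)
  k <- ncol(posterior_membership_samples[[1]])
  if (length(home_ids) < k + 1 || length(ref_ids) < k + 1)
    stop("region smaller than k + 1 societies after excluding the tested society")
  ll_ref <- numeric(N); ll_home <- numeric(N)
  for (s in seq_len(N)) {
    m <- posterior_membership_samples[[s]]
    ll_ref[s] <- dirichlet_loglik(fit_dirichlet(m[ref_ids, , drop = FALSE]),
                                  m[society_id, ])
    ll_home[s] <- dirichlet_loglik(fit_dirichlet(m[home_ids, , drop = FALSE]),
                                   m[society_id, ])
  }
  wt <- suppressWarnings(stats::wilcox.test(ll_ref, ll_home,
                                            alternative = "greater",
                                            exact = N < 20, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), df = NULL,
                 p_value = wt$p.value, reject = wt$p.value < sig,
                 flagged = wt$p.value < sig, reject_at = sig,
                 kind = "mann_whitney_one_sided",
                 ll_reference = ll_ref, ll_home = ll_home),
            class = "cultarch_test")
}

#' Normalised Fst of membership coefficients
#'
#' Treats each archetype column as an allele frequency across societies
#' and computes the variance-based differentiation
#' `var(q) / (qbar (1 - qbar))` per column (population variance), then
#' aggregates by a `qbar (1 - qbar)`-weighted mean. The statistic is 0
#' when all rows are identical and 1 when every row is a simplex vertex;
#' it decreases with the Dirichlet concentration of the sample. Columns
#' with zero variance are excluded from the aggregation; if all are
#' excluded the statistic is 0.
#'
#' @param memberships matrix of simplex rows (>= 2 rows).
#' @return scalar in `[0, 1]`.
#' @export
normalized_fst <- function(memberships) {
  m <- as.matrix(memberships)
  if (nrow(m) < 2) stop("need at least 2 membership rows")
  n <- nrow(m)
  qbar <- colMeans(m)
  v <- colMeans(sweep(m, 2L, qbar)^2)   # population variance
  denom <- qbar * (1 - qbar)
  keep <- v > 1e-15 & denom > 1e-15
  if (!any(keep)) return(0)
  sum((v[keep] / denom[keep]) * denom[keep]) / sum(denom[keep])
}
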