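#' Pagel's lambda phylogenetic signal for a single trait
#'
#' Profiles the Brownian-motion Gaussian likelihood of tip values over a
#' phylogeny whose off-diagonal covariance entries are multiplied by
#' `lambda`: the ancestral mean and Brownian rate are maximised
#' analytically (GLS) and `lambda` by bounded univariate optimisation on
#' `bounds`. The likelihood-ratio p-value compares the fitted `lambda`
#' against `lambda = 0` (no signal: independent tips) on one chi-square
#' degree of freedom. Binary traits are accepted as 0/1 numeric values
#' under the same continuous model.
#'
#' @param tree an `ape` phylo object with branch lengths.
#' @param trait named numeric vector (names = tip labels); tips missing
#'   from the tree (or vice versa) are dropped with a warning. At least
#'   10 matched tips are required.
#' @param bounds search interval for lambda, default `c(0, 1)`.
#' @return object of class `phylo_signal_result`: `lambda_hat`,
#'   `loglik_at_hat`, `loglik_at_zero`, `p_value`, `trait_name`, `n_tips`.
#' @export
pagel_lambda <- function(tree, trait, bounds = c(0, 1)) {
  trait_name <- deparse(substitute(trait))
  if (is.null(names(trait))) stop("trait must be named by tip label")
  common <- intersect(tree$tip.label, names(trait))
  common <- common[!is.na(trait[common])]
  if (length(common) < length(tree$tip.label) || length(common) < length(trait))
    warning("dropping tips without matched trait values")
  if (length(common) < 10) stop("need trait values on at least 10 tips")
  tree <- ape::keep.tip(tree, common)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  x <- trait[tree$tip.label]
  C <- ape::vcv(tree)
  if (max(abs(C[upper.tri(C)])) < 1e-12)
    stop("star tree: lambda is unidentifiable (no shared branch lengths)")

  ll <- function(lambda) {
    Cl <- C * lambda
    diag(Cl) <- diag(C)
    ch <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(ch)) return(-1e300)
    n <- length(x)
    logdet <- 2 * sum(log(diag(ch)))
    Ci1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    Cix <- backsolve(ch, forwardsolve(t(ch), x))
    mu <- sum(Cix) / sum(Ci1)
    r <- x - mu
    Cir <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * Cir) / n
    if (s2 <= 0) return(-1e300)
    -0.5 * (n * log(2 * pi * s2) + logdet + n)
  }
  opt <- optimize(ll, interval = bounds, maximum = TRUE, tol = 1e-8)
  # guard the interval ends: optimize can miss boundary optima
  cand <- c(opt$maximum, bounds)
  lls <- vapply(cand, ll, numeric(1))
  lambda_hat <- cand[which.max(lls)]
  l_hat <- max(lls)
  l_zero <- ll(0)
  stat <- max(0, 2 * (l_hat - l_zero))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(lambda_hat = lambda_hat,
                 loglik_at_hat = l_hat,
                 loglik_at_zero = l_zero,
                 p_value = p,
                 trait_name = trait_name,
                 n_tips = length(x)),
            class = "phylo_signal_result")
}

#' @export
print.phylo_signal_result <- function(x, ...) {
  cat(sprintf("Pagel's lambda = %.3f (logL %.3f vs %.3f at lambda = 0), p = %.3g, %d tips\n",
              x$lambda_hat, x$loglik_at_hat, x$loglik_at_zero, x$p_value, x$n_tips))
  invisible(x)
}
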