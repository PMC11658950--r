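#' @useDynLib cultarch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rgamma var sd cov optimize pchisq
#'   wilcox.test kmeans quantile median dist rbinom
NULL

# Derive a reproducible child seed from a master seed and a stage label.
# Keeps results < 2^31 so set.seed() accepts them on 32-bit integers.
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw rows from a Dirichlet distribution
#'
#' Samples `n` vectors from a Dirichlet distribution with concentration
#' `alpha` via normalised gamma draws.
#'
#' @param n number of rows to draw.
#' @param alpha positive concentration vector of length `k`.
#' @return an `n x k` matrix whose rows lie on the probability simplex.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(n >= 1, all(alpha > 0))
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n), rate = 1), n, k)
  g / rowSums(g)
}

# Euclidean projection of each row of `m` onto the probability simplex
# (Duchi et al. 2008), vectorised over rows.
project_rows_simplex <- function(m) {
  n <- nrow(m); k <- ncol(m)
  srt <- matrix(apply(m, 1L, sort, decreasing = TRUE), k, n) # k x n
  css <- apply(srt, 2L, cumsum)
  j <- matrix(seq_len(k), k, n)
  cond <- srt - (css - 1) / j > 0
  rho <- apply(cond, 2L, function(z) max(which(z)))
  theta <- (css[cbind(rho, seq_len(n))] - 1) / rho
  out <- pmax(m - theta, 0)
  out / rowSums(out)
}

project_cols_simplex <- function(m) t(project_rows_simplex(t(m)))

`%||%` <- function(a, b) if (is.null(a)) b else a
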