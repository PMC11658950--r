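# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, bisection, grid search) so they share
# no code with the implementations they check.

# all-quartets four-point check: largest two of the three pairwise sums
# agree within tol for every quartet
four_point_holds <- function(d, tol = 1e-8) {
  n <- nrow(d)
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
    s <- sort(c(d[i, j] + d[k, l], d[i, k] + d[j, l], d[i, l] + d[j, k]),
              decreasing = TRUE)
    if (s[1] - s[2] > tol * max(s[1], 1)) return(FALSE)
  }
  TRUE
}

# naive quartet delta-score mean
delta_brute <- function(d) {
  n <- nrow(d)
  vals <- sapply(utils::combn(n, 4, simplify = FALSE), function(q) {
    i <- q[1]; j <- q[2]; k <- q[3]; l <- q[4]
    s <- sort(c(d[i, j] + d[k, l], d[i, k] + d[j, l], d[i, l] + d[j, k]),
              decreasing = TRUE)
    if (s[1] - s[3] <= 1e-12 * (abs(s[1]) + 1)) 0 else (s[1] - s[2]) / (s[1] - s[3])
  })
  mean(vals)
}

# greatest convex minorant of points (x, y) evaluated at each x (ties in
# x keep the lowest y); used by the dip bisection oracle
gcm_eval <- function(x, y) {
  ux <- sort(unique(x))
  uy <- vapply(ux, function(v) min(y[x == v]), numeric(1))
  m <- length(ux)
  if (m == 1) return(rep(uy, length(x)))
  hull <- 1L
  for (i in 2:m) {
    while (length(hull) >= 2) {
      h1 <- hull[length(hull)]; h2 <- hull[length(hull) - 1]
      cr <- (ux[i] - ux[h2]) * (uy[h1] - uy[h2]) -
        (ux[h1] - ux[h2]) * (uy[i] - uy[h2])
      if (cr >= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  stats::approx(ux[hull], uy[hull], xout = x, rule = 2)$y
}

# dip by bisection on the band half-width: a unimodal cdf within d of the
# empirical cdf exists iff some split admits a convex fit of the bands on
# the prefix and a concave fit on the suffix
dip_oracle <- function(xs, tol = 1e-9) {
  xs <- sort(xs); n <- length(xs)
  feasible <- function(d) {
    u <- (seq_len(n) - 1) / n + d
    l <- seq_len(n) / n - d
    conv_ok <- c(TRUE, vapply(seq_len(n), function(m)
      all(gcm_eval(xs[1:m], u[1:m]) >= l[1:m] - 1e-12), logical(1)))
    conc_ok <- c(vapply(seq_len(n), function(m)
      all(-gcm_eval(xs[m:n], -l[m:n]) <= u[m:n] + 1e-12), logical(1)), TRUE)
    any(conv_ok & conc_ok) # split m: convex on 1..m, concave on (m+1)..n
  }
  lo <- 1 / (2 * n) - tol; hi <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

# a 4-taxon distance matrix whose quartet sums are (10, 8, 6)
quartet_dm_10_8_6 <- function() {
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 5; d[3, 4] <- d[4, 3] <- 5  # sum 10
  d[1, 3] <- d[3, 1] <- 4; d[2, 4] <- d[4, 2] <- 4  # sum 8
  d[1, 4] <- d[4, 1] <- 3; d[2, 3] <- d[3, 2] <- 3  # sum 6
  distance_matrix(d, paste0("t", 1:4))
}

# metric assembled from an explicit circular split set (positions on the
# given cycle), used to test Neighbor-Net recovery on reticulate input
metric_from_circular_splits <- function(n, splits, weights) {
  d <- matrix(0, n, n)
  for (s in seq_along(splits)) {
    I <- splits[[s]]
    for (i in seq_len(n)) for (j in seq_len(n))
      if (xor(i %in% I, j %in% I)) d[i, j] <- d[i, j] + weights[s]
  }
  distance_matrix(d, paste0("t", seq_len(n)))
}

# distance matrix implied by a split system (for recovery checks)
splits_to_metric <- function(ss) {
  n <- length(ss$taxa)
  d <- matrix(0, n, n)
  for (s in seq_along(ss$splits)) {
    I <- ss$splits[[s]]
    for (i in seq_len(n)) for (j in seq_len(n))
      if (xor(i %in% I, j %in% I)) d[i, j] <- d[i, j] + ss$weights[s]
  }
  d
}

# small trait matrix fixture with two metadata classes
toy_trait_matrix <- function() {
  vals <- matrix(c(1, 2, 3, 4,
                   2, 2, NA, 3,
                   1, NA, NA, NA,
                   4, 1, 2, 2), 4, 4, byrow = TRUE)
  trait_meta <- data.frame(name = paste0("v", 1:4),
                           cultural_class = c("social organisation", "social organisation",
                                              "religion", "religion"),
                           kind = "ordinal", min_level = 1L, max_level = 4L,
                           stringsAsFactors = FALSE)
  society_meta <- data.frame(id = paste0("s", 1:4),
                             region = c("A", "A", "B", "B"),
                             language_group = "g1",
                             polynesian_outlier_flag = c(FALSE, TRUE, FALSE, FALSE),
                             stringsAsFactors = FALSE)
  trait_matrix(vals, trait_meta, society_meta)
}
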