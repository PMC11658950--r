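#' Pairwise Euclidean distances in the archetype space
#'
#' `d(i, j)` is the Euclidean norm of the difference between the
#' membership rows of societies `i` and `j`. Distances in the archetype
#' space account for covariance among cultural traits in a way that raw
#' trait-space distances do not.
#'
#' @param am an `archetype_model` (or a plain membership matrix).
#' @return a [distance_matrix] over the societies.
#' @export
archetype_distances <- function(am) {
  A <- if (inherits(am, "archetype_model")) am$alpha else as.matrix(am)
  d <- as.matrix(dist(A, method = "euclidean"))
  distance_matrix(d, rownames(A) %||% paste0("t", seq_len(nrow(A))))
}

#' Neighbor-Net split network from a distance matrix
#'
#' Implements the agglomerative Neighbor-Net construction: clusters are
#' joined by the neighbour-joining selection criterion applied twice (once
#' to pick the cluster pair, once to pick the linking nodes), with joined
#' node triples replaced by weighted pairs, until three nodes remain;
#' reversing the replacements yields a circular ordering of the taxa.
#' Split weights are then estimated by non-negative least squares of all
#' circular (contiguous-arc) split metrics against the input distances,
#' and splits with weight below `weight_tol` are dropped. On an additive
#' tree metric the recovered splits are exactly the tree's splits with
#' weights equal to branch lengths.
#'
#' @param dm a [distance_matrix].
#' @param weight_tol splits with smaller weight are pruned.
#' @return object of class `split_system`: `taxa`, `cycle` (circular
#'   ordering as indices into `taxa`), `splits` (list of integer taxon
#'   index sets, the side not containing the cycle's first taxon),
#'   `weights`, `fit` (fraction of distance variance represented).
#' @export
neighbor_net <- function(dm, weight_tol = 1e-9) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- length(dm$taxa)
  if (n == 1) stop("need at least 2 taxa")
  if (n == 2) {
    return(structure(list(taxa = dm$taxa, cycle = 1:2,
                          splits = list(2L), weights = dm$d[1, 2], fit = 1),
                     class = "split_system"))
  }
  cycle <- if (n == 3) 1:3 else nnet_circular_order(dm$d)
  est <- circular_split_weights(dm$d, cycle)
  keep <- est$weights > weight_tol
  structure(list(taxa = dm$taxa, cycle = cycle,
                 splits = est$splits[keep], weights = est$weights[keep],
                 fit = est$fit),
            class = "split_system")
}

#' @export
print.split_system <- function(x, ...) {
  ntriv <- sum(lengths(x$splits) == 1 | lengths(x$splits) == length(x$taxa) - 1)
  cat(sprintf("split_system: %d taxa, %d splits (%d non-trivial), fit %.2f%%\n",
              length(x$taxa), length(x$splits), length(x$splits) - ntriv,
              100 * x$fit))
  invisible(x)
}

# Neighbor-Net agglomeration: returns a circular ordering (permutation of
# 1..n) compatible with the circular split system underlying d.
nnet_circular_order <- function(d0) {
  n <- nrow(d0)
  # working distance matrix over nodes; original taxa are nodes 1..n and
  # each of the up to n - 3 triple reductions creates two new nodes
  d <- matrix(0, 3 * n + 2, 3 * n + 2)
  d[1:n, 1:n] <- d0
  next_id <- n + 1L
  clusters <- lapply(seq_len(n), identity)
  reductions <- list()

  cluster_dist <- function(A, B) mean(d[A, B, drop = FALSE])
  node_entity_dist <- function(x, E) mean(d[x, E])

  reduce_triple <- function(a, b, c) {
    u <- next_id; v <- next_id + 1L
    next_id <<- next_id + 2L
    others <- setdiff(unlist(clusters), c(a, b, c))
    d[u, others] <<- (2 / 3) * d[a, others] + (1 / 3) * d[b, others]
    d[others, u] <<- d[u, others]
    d[v, others] <<- (1 / 3) * d[b, others] + (2 / 3) * d[c, others]
    d[others, v] <<- d[v, others]
    duv <- (1 / 3) * (d[a, b] + d[b, c] + d[a, c])
    d[u, v] <<- duv; d[v, u] <<- duv
    reductions[[length(reductions) + 1L]] <<- c(u, v, a, b, c)
    c(u, v)
  }

  repeat {
    n_nodes <- sum(lengths(clusters))
    m <- length(clusters)
    if (n_nodes <= 3 || m < 2) break
    # cluster-pair selection (neighbour-joining criterion on clusters)
    Dc <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      Dc[i, j] <- Dc[j, i] <- cluster_dist(clusters[[i]], clusters[[j]])
    }
    Rs <- rowSums(Dc)
    Qc <- (m - 2) * Dc - outer(Rs, Rs, `+`)
    diag(Qc) <- Inf
    ij <- which(Qc == min(Qc), arr.ind = TRUE)[1, ]
    A <- clusters[[ij[1]]]; B <- clusters[[ij[2]]]

    if (length(A) == 1 && length(B) == 1) {
      merged <- c(A, B)
    } else {
      # node-pair selection: other clusters as wholes, nodes of A and B
      # as singleton entities
      other <- clusters[-c(ij[1], ij[2])]
      entities <- c(other, as.list(c(A, B)))
      ent_of <- c(rep(0L, length(other)), seq_along(c(A, B)))
      nodesAB <- c(A, B)
      mh <- length(entities)
      best <- NULL
      for (x in A) for (y in B) {
        sx <- sum(vapply(entities, function(E) node_entity_dist(x, E), numeric(1))[
          !vapply(entities, function(E) length(E) == 1 && E == x, logical(1))])
        sy <- sum(vapply(entities, function(E) node_entity_dist(y, E), numeric(1))[
          !vapply(entities, function(E) length(E) == 1 && E == y, logical(1))])
        q <- (mh - 2) * d[x, y] - sx - sy
        if (is.null(best) || q < best$q) best <- list(q = q, x = x, y = y)
      }
      orient <- function(chain, endpoint, at_start) {
        if (length(chain) == 1) return(chain)
        if (at_start && chain[1] != endpoint) rev(chain)
        else if (!at_start && chain[length(chain)] != endpoint) rev(chain)
        else chain
      }
      merged <- c(orient(A, best$x, at_start = FALSE),
                  orient(B, best$y, at_start = TRUE))
      while (length(merged) > 2) {
        uv <- reduce_triple(merged[1], merged[2], merged[3])
        merged <- c(uv, merged[-(1:3)])
      }
    }
    clusters <- c(clusters[-c(ij[1], ij[2])], list(merged))
  }

  # close the remaining nodes (<= 3) into a cycle, then expand
  ord <- unlist(clusters)
  for (r in rev(reductions)) {
    u <- r[1]; v <- r[2]; abc <- r[3:5]
    pu <- which(ord == u); pv <- which(ord == v)
    k <- length(ord)
    if ((pu %% k) + 1 == pv) {
      ord <- append(ord[-c(pu, pv)], abc, after = pu - 1)
    } else if ((pv %% k) + 1 == pu) {
      ord <- if (pv == k) c(rev(abc), ord[-c(pu, pv)]) else
        append(ord[-c(pu, pv)], rev(abc), after = pv - 1)
    } else stop("internal error: reduced pair not adjacent in cycle")
  }
  ord
}

# Non-negative least-squares estimation of circular split weights
# (Lawson-Hanson active set with columns generated on demand; the
# gradient over all splits is computed with 2-D prefix sums).
circular_split_weights <- function(d0, cycle, max_active = NULL, tol = NULL) {
  n <- length(cycle)
  P <- d0[cycle, cycle]
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  dvec <- P[cbind(pair_i, pair_j)]
  npair <- length(dvec)
  # candidate splits: arcs [a..b] of the cycle with 2 <= a <= b <= n
  arcs <- cbind(a = rep(2:n, times = n - (2:n) + 1),
                b = unlist(lapply(2:n, function(a) a:n)))
  if (is.null(tol)) tol <- 1e-8 * max(abs(dvec), 1)
  if (is.null(max_active)) max_active <- min(3L * n, nrow(arcs))

  split_col <- function(a, b) {
    ini <- pair_i >= a & pair_i <= b
    inj <- pair_j >= a & pair_j <= b
    as.numeric(xor(ini, inj))
  }
  # gradient of 0.5 ||d - Aw||^2 wrt every candidate split at once:
  # g_S = sum_{i in I, j notin I} rmat[i, j], via 2-D prefix sums
  grad_all <- function(rmat) {
    rs <- rowSums(rmat)
    cs_rs <- c(0, cumsum(rs))
    C2 <- rbind(0, apply(rmat, 2, cumsum))
    C2 <- cbind(0, t(apply(C2, 1, cumsum)))  # (n+1) x (n+1); C2[i+1, j+1] = sum rmat[1:i, 1:j]
    a <- arcs[, 1]; b <- arcs[, 2]
    rowblock <- cs_rs[b + 1] - cs_rs[a]
    within <- C2[cbind(b + 1, b + 1)] - C2[cbind(a, b + 1)] -
      C2[cbind(b + 1, a)] + C2[cbind(a, a)]
    rowblock - within
  }

  active <- integer(0)
  Xact <- matrix(0, npair, 0)
  w <- numeric(0)
  resid <- dvec
  for (outer_it in seq_len(4L * max_active)) {
    rmat <- matrix(0, n, n)
    rmat[cbind(pair_i, pair_j)] <- resid
    rmat <- rmat + t(rmat)
    g <- grad_all(rmat)
    g[active] <- -Inf
    jmax <- which.max(g)
    if (g[jmax] <= tol || length(active) >= max_active) break
    active <- c(active, jmax)
    Xact <- cbind(Xact, split_col(arcs[jmax, 1], arcs[jmax, 2]))
    ls_solve <- function(M) {
      G <- crossprod(M)
      tryCatch(solve(G + diag(1e-12 * max(diag(G)), ncol(G)),
                     crossprod(M, dvec))[, 1],
               error = function(e) NULL)
    }
    repeat {
      wls <- ls_solve(Xact)
      if (is.null(wls) || anyNA(wls)) { # rank deficiency: drop newest
        active <- active[-length(active)]
        Xact <- Xact[, -ncol(Xact), drop = FALSE]
        wls <- if (length(active)) ls_solve(Xact) else numeric(0)
        w <- wls
        break
      }
      if (all(wls >= -1e-12)) { w <- pmax(wls, 0); break }
      # step back along the segment to the feasible boundary
      neg <- which(wls < 0)
      wcur <- if (length(w) == length(wls)) w else c(w, 0)
      alpha <- min(wcur[neg] / (wcur[neg] - wls[neg]))
      wcur <- wcur + alpha * (wls - wcur)
      drop_idx <- which(wcur <= 1e-12)
      active <- active[-drop_idx]
      Xact <- Xact[, -drop_idx, drop = FALSE]
      w <- wcur[-drop_idx]
      if (!length(active)) break
    }
    resid <- dvec - if (length(w)) as.numeric(Xact %*% w) else 0
  }
  splits <- lapply(seq_along(active), function(s) {
    a <- arcs[active[s], 1]; b <- arcs[active[s], 2]
    sort(cycle[a:b])
  })
  fit <- 1 - sum(resid^2) / sum(dvec^2)
  list(splits = splits, weights = as.numeric(w), fit = fit,
       arcs = arcs[active, , drop = FALSE])
}

#' Delta-score tree-likeness of a distance matrix
#'
#' For every quartet the three pairwise-sum quantities are ordered
#' `m1 >= m2 >= m3` and the quartet delta is `(m1 - m2) / (m1 - m3)`
#' (0 when `m1 = m3`). The mean over all `C(n, 4)` quartets is the
#' headline score; per-taxon values average over the quartets containing
#' each taxon. The score is 0 exactly when every quartet satisfies the
#' four-point condition (an additive tree metric) and approaches 1 for
#' maximally box-like quartets; a low score indicates a tree-like network
#' mostly owing to vertical transmission. Quartets are enumerated
#' exhaustively up to `max_exhaustive` taxa and subsampled (seeded, with
#' reported Monte-Carlo error) beyond.
#'
#' @param dm a [distance_matrix] (n >= 4).
#' @param max_exhaustive largest n for exhaustive enumeration.
#' @param n_sample quartets drawn when subsampling.
#' @param seed seed for the subsampling path.
#' @return object of class `treelikeness_result` with `mean_delta`,
#'   `per_taxon_delta` and bookkeeping fields.
#' @export
delta_score <- function(dm, max_exhaustive = 200, n_sample = 2e6, seed = 1) {
  qs <- quartet_scores(dm, normalise_q = FALSE, max_exhaustive, n_sample, seed)
  structure(list(mean_delta = qs$mean_delta,
                 per_taxon_delta = qs$per_taxon_delta,
                 n_quartets = qs$n_quartets,
                 mc_se = qs$mc_se,
                 normalised = FALSE),
            class = "treelikeness_result")
}

#' Q-residual tree-likeness of a distance matrix
#'
#' The quartet Q-residual is the squared gap `(m1 - m2)^2` between the
#' two largest pairwise-sum quantities. Unlike the delta-score it is
#' sensitive to distance magnitudes, so by default distances are rescaled
#' to mean pairwise distance 1 before scoring, making values comparable
#' across cultural classes.
#'
#' @inheritParams delta_score
#' @param normalise rescale distances to mean 1 first.
#' @return object of class `treelikeness_result` with `mean_q_residual`,
#'   `per_taxon_q` and bookkeeping fields.
#' @export
q_residual <- function(dm, normalise = TRUE, max_exhaustive = 200,
                       n_sample = 2e6, seed = 1) {
  qs <- quartet_scores(dm, normalise_q = normalise, max_exhaustive, n_sample, seed)
  structure(list(mean_q_residual = qs$mean_q,
                 per_taxon_q = qs$per_taxon_q,
                 n_quartets = qs$n_quartets,
                 normalised = normalise),
            class = "treelikeness_result")
}

#' @export
print.treelikeness_result <- function(x, ...) {
  if (!is.null(x$mean_delta))
    cat(sprintf("mean delta-score: %.4f over %g quartets\n", x$mean_delta, x$n_quartets))
  if (!is.null(x$mean_q_residual))
    cat(sprintf("mean Q-residual: %.6g (%snormalised)\n", x$mean_q_residual,
                if (x$normalised) "" else "not "))
  invisible(x)
}

quartet_scores <- function(dm, normalise_q, max_exhaustive, n_sample, seed) {
  stopifnot(inherits(dm, "distance_matrix"))
  d <- dm$d
  n <- nrow(d)
  if (n < 4) stop("quartet statistics need at least 4 taxa")
  if (normalise_q) {
    mu <- mean(d[upper.tri(d)])
    if (mu > 0) d <- d / mu
  }
  if (n <= max_exhaustive) {
    out <- quartet_stats_exhaustive(d)
    out$mc_se <- 0
  } else {
    out <- quartet_stats_sampled(d, as.integer(n_sample),
                                 derive_seed(seed, "quartets"))
    out$mc_se <- out$mc_se_delta
  }
  names(out$per_taxon_delta) <- dm$taxa
  names(out$per_taxon_q) <- dm$taxa
  out
}

#' Distribution statistics of pairwise distances
#'
#' Summarises the upper-triangle distance distribution with the adjusted
#' Fisher-Pearson moment coefficient of skewness and Hartigan's dip
#' statistic of unimodality, with a dip p-value bootstrapped from the
#' uniform null (uniform samples of the same size).
#'
#' @param dm a [distance_matrix] with at least 4 distinct off-diagonal
#'   values.
#' @param dip_boot bootstrap replicates for the dip p-value.
#' @param seed integer seed for the bootstrap.
#' @return list with `skew`, `dip_statistic`, `dip_p`.
#' @export
distance_distribution_stats <- function(dm, dip_boot = 2000, seed = 1) {
  x <- dm$d[upper.tri(dm$d)]
  if (length(unique(x)) < 4)
    stop("need at least 4 distinct off-diagonal distances")
  structure(list(skew = fisher_pearson_skew(x),
                 dip_statistic = dip_statistic(x),
                 dip_p = dip_test_uniform_p(x, dip_boot, seed)),
            class = "distance_distribution_stats")
}

#' @export
print.distance_distribution_stats <- function(x, ...) {
  cat(sprintf("skew %.4f, dip statistic %.4f (uniform-null p = %.3f)\n",
              x$skew, x$dip_statistic, x$dip_p))
  invisible(x)
}

#' Adjusted Fisher-Pearson skewness coefficient
#'
#' The sample-size-adjusted moment coefficient
#' `g1 * sqrt(n (n-1)) / (n - 2)`.
#'
#' @param x numeric sample (n >= 3, non-constant).
#' @return scalar skewness.
#' @export
fisher_pearson_skew <- function(x) {
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  s <- sd(x) * sqrt((n - 1) / n)  # population sd for the moment coefficient
  if (s < .Machine$double.eps) stop("skew undefined for constant values")
  g1 <- mean((x - mean(x))^3) / s^3
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Hartigan dip statistic
#'
#' Sup-norm distance from the empirical cdf to the closest unimodal cdf,
#' computed by convex/concave minorant-majorant sweeps over every modal
#' split of the sorted sample.
#'
#' @param x numeric sample (n >= 2).
#' @return the dip statistic (>= `1/(2n)`).
#' @export
dip_statistic <- function(x) {
  dip_stat_sorted(sort(as.numeric(x)))
}

dip_test_uniform_p <- function(x, dip_boot, seed) {
  obs <- dip_statistic(x)
  n <- length(x)
  null <- with_seed(derive_seed(seed, "dipboot"), {
    vapply(seq_len(dip_boot), function(b) dip_stat_sorted(sort(runif(n))),
           numeric(1))
  })
  (1 + sum(null >= obs)) / (dip_boot + 1)
}
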