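#' Trait matrix container
#'
#' Bundles an integer-coded society-by-variable table with its
#' observed-entry mask and per-variable / per-society metadata. This is the
#' data matrix as it exists before centering and imputation: rows are
#' societies, columns are ordinal or categorical cultural variables coded
#' as small integers, and unobserved cells are `NA`.
#'
#' @param values numeric matrix (`n x p`), `NA` where unobserved. Row and
#'   column names are taken as society ids and variable names.
#' @param trait_meta data frame with one row per column of `values`:
#'   `name`, `cultural_class`, `kind` (`"ordinal"` or `"categorical"`),
#'   `min_level`, `max_level`.
#' @param society_meta data frame with one row per row of `values`: `id`,
#'   `region`, `language_group`, `polynesian_outlier_flag`.
#' @return an object of class `trait_matrix` with fields `values`, `mask`,
#'   `trait_meta`, `society_meta`.
#' @export
trait_matrix <- function(values, trait_meta, society_meta) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values); p <- ncol(values)
  stopifnot(nrow(trait_meta) == p, nrow(society_meta) == n)
  if (anyDuplicated(society_meta$id))
    stop("duplicate society id: ",
         paste(unique(society_meta$id[duplicated(society_meta$id)]), collapse = ", "))
  rownames(values) <- as.character(society_meta$id)
  colnames(values) <- as.character(trait_meta$name)
  mask <- !is.na(values)
  # observed ordinal codes must respect the declared range
  ord <- which(trait_meta$kind == "ordinal")
  for (j in ord) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < trait_meta$min_level[j] | v > trait_meta$max_level[j]))
    if (length(bad))
      stop(sprintf("value %g outside declared range [%d, %d] at society '%s', variable '%s'",
                   v[bad[1]], trait_meta$min_level[j], trait_meta$max_level[j],
                   rownames(values)[bad[1]], colnames(values)[j]))
  }
  structure(list(values = values, mask = mask,
                 trait_meta = as.data.frame(trait_meta),
                 society_meta = as.data.frame(society_meta)),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d societies x %d variables (%.1f%% observed)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  cat("classes:", paste(unique(x$trait_meta$cultural_class), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Distance matrix container
#'
#' A labelled symmetric pairwise distance matrix with zero diagonal
#' (archetype-space units unless stated otherwise).
#'
#' @param d square numeric matrix.
#' @param taxa character labels; defaults to the row names of `d`.
#' @return an object of class `distance_matrix` with fields `taxa` and `d`.
#' @export
distance_matrix <- function(d, taxa = rownames(d)) {
  d <- as.matrix(d)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(d)))
  stopifnot(nrow(d) == ncol(d), length(taxa) == nrow(d))
  if (any(abs(d - t(d)) > 1e-10)) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(taxa, taxa)
  structure(list(taxa = as.character(taxa), d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix over %d taxa (mean off-diagonal %.4g)\n",
              length(x$taxa), mean(x$d[upper.tri(x$d)])))
  invisible(x)
}
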