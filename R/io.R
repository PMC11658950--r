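#' Read a D-PLACE-style trait table with metadata
#'
#' Reads a wide CSV of integer-coded trait values (societies in rows,
#' variables in columns, first column the society id) together with
#' per-variable and per-society metadata tables, and joins them into a
#' [trait_matrix]. Empty cells and the missing sentinel become `NA`.
#'
#' @param values_path CSV of trait values; first column `id`.
#' @param trait_meta_path CSV with columns `name`, `cultural_class`,
#'   `kind`, `min_level`, `max_level`.
#' @param society_meta_path CSV with columns `id`, `region`,
#'   `language_group`, `polynesian_outlier_flag`.
#' @param na_sentinel string treated as missing in addition to empty cells.
#' @return a [trait_matrix].
#' @export
read_trait_table <- function(values_path, trait_meta_path, society_meta_path,
                             na_sentinel = "NA") {
  vals <- utils::read.csv(values_path, check.names = FALSE,
                          na.strings = c("", na_sentinel),
                          stringsAsFactors = FALSE)
  tm <- utils::read.csv(trait_meta_path, stringsAsFactors = FALSE)
  sm <- utils::read.csv(society_meta_path, stringsAsFactors = FALSE)
  ids <- as.character(vals[[1]])
  m <- as.matrix(vals[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  tm <- tm[match(colnames(m), tm$name), , drop = FALSE]
  if (anyNA(tm$name)) stop("trait metadata missing for some variables")
  sm <- sm[match(ids, as.character(sm$id)), , drop = FALSE]
  if (anyNA(sm$id)) stop("society metadata missing for some ids")
  if (is.character(sm$polynesian_outlier_flag))
    sm$polynesian_outlier_flag <- as.logical(sm$polynesian_outlier_flag)
  trait_matrix(m, tm, sm)
}

#' Write a trait table and its metadata as CSV
#'
#' Inverse of [read_trait_table()]; missing cells are written as the
#' sentinel so the round trip is exact.
#'
#' @param tm a [trait_matrix].
#' @param values_path,trait_meta_path,society_meta_path output CSV paths.
#' @param na_sentinel string written for missing cells.
#' @export
write_trait_table <- function(tm, values_path, trait_meta_path,
                              society_meta_path, na_sentinel = "NA") {
  df <- data.frame(id = rownames(tm$values), tm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, values_path, row.names = FALSE, na = na_sentinel)
  utils::write.csv(tm$trait_meta, trait_meta_path, row.names = FALSE)
  utils::write.csv(tm$society_meta, society_meta_path, row.names = FALSE)
  invisible(c(values_path, trait_meta_path, society_meta_path))
}

#' Drop variables with insufficient coverage
#'
#' Removes columns observed in fewer than `min_fraction` of the societies;
#' the retained columns are the ones later imputed. Idempotent and never
#' alters retained values.
#'
#' @param tm a [trait_matrix].
#' @param min_fraction minimum observed fraction a column must reach to be
#'   kept (default 0.5).
#' @return the filtered [trait_matrix].
#' @export
filter_by_coverage <- function(tm, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  keep <- colMeans(tm$mask) >= min_fraction
  if (!any(keep)) stop("coverage filter removed every column")
  trait_matrix(tm$values[, keep, drop = FALSE],
               tm$trait_meta[keep, , drop = FALSE],
               tm$society_meta)
}

#' Numeric encoding of a trait matrix for Euclidean analysis
#'
#' Ordinal variables are kept as numeric codes; categorical variables are
#' one-hot expanded (one indicator column per observed level), since the
#' Euclidean machinery downstream (VBPCA, PCHA) assumes interval-like
#' columns. Missingness propagates to all indicator columns of a variable.
#'
#' @param tm a [trait_matrix].
#' @return a numeric matrix with `NA` at unobserved cells.
#' @export
encode_traits <- function(tm) {
  cols <- list()
  for (j in seq_len(ncol(tm$values))) {
    v <- tm$values[, j]
    nm <- colnames(tm$values)[j]
    if (tm$trait_meta$kind[j] == "categorical") {
      lev <- sort(unique(v[!is.na(v)]))
      for (l in lev) {
        x <- as.numeric(v == l)
        x[is.na(v)] <- NA
        cols[[paste0(nm, "=", l)]] <- x
      }
    } else {
      cols[[nm]] <- v
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(tm$values)
  out
}

#' Write / read a square PHYLIP distance matrix
#'
#' Standard square PHYLIP format: a header line with the number of taxa,
#' then one row per taxon (label, then distances). Values are printed with
#' enough digits that write-then-read round-trips to 1e-9.
#'
#' @param dm a [distance_matrix].
#' @param path output file.
#' @export
write_distance_phylip <- function(dm, path) {
  n <- length(dm$taxa)
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i) {
               paste0(format(dm$taxa[i], width = 12),
                      paste(sprintf("%.10f", dm$d[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_distance_phylip
#' @export
read_distance_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1) stop("malformed PHYLIP distance file")
  taxa <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(toks) != n + 1) stop("ragged row in PHYLIP distance file: line ", i + 1)
    taxa[i] <- toks[1]
    d[i, ] <- as.numeric(toks[-1])
  }
  distance_matrix(d, taxa)
}

#' Write a split system as a NEXUS SPLITS block
#'
#' Emits TAXA and SPLITS blocks (with the circular ordering recorded as
#' CYCLE) readable by standard split-network viewers such as SplitsTree.
#'
#' @param ss a `split_system` as returned by [neighbor_net()].
#' @param path output file.
#' @export
write_splits_nexus <- function(ss, path) {
  n <- length(ss$taxa)
  nspl <- length(ss$splits)
  out <- c("#NEXUS", "",
           "BEGIN TAXA;",
           sprintf("DIMENSIONS NTAX=%d;", n),
           "TAXLABELS",
           sprintf("  [%d] '%s'", seq_len(n), ss$taxa),
           ";", "END;", "",
           "BEGIN SPLITS;",
           sprintf("DIMENSIONS NTAX=%d NSPLITS=%d;", n, nspl),
           sprintf("FORMAT LABELS=NO WEIGHTS=YES CONFIDENCES=NO;"),
           sprintf("PROPERTIES FIT=%.2f CYCLIC;", 100 * ss$fit),
           sprintf("CYCLE %s;", paste(ss$cycle, collapse = " ")),
           "MATRIX")
  rows <- vapply(seq_len(nspl), function(i) {
    sprintf("  [%d] %.10g \t %s,", i, ss$weights[i],
            paste(sort(ss$splits[[i]]), collapse = " "))
  }, character(1))
  out <- c(out, rows, ";", "END;")
  writeLines(out, path)
  invisible(path)
}

#' Read a Newick phylogeny
#'
#' Thin wrapper over [ape::read.tree()] returning a `phylo` object with
#' branch lengths.
#'
#' @param path Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}
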