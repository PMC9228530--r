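#' Construct a feature table
#'
#' The central container of the pipeline: a taxa-by-samples matrix of
#' non-negative integer counts, with one Greengenes-style 7-rank lineage
#' string per taxon (`"k__...;p__...;c__...;o__...;f__...;g__...;s__..."`;
#' ranks may be empty after their prefix).
#'
#' @param counts Numeric matrix, taxa in rows and samples in columns, with
#'   unique row and column names. All entries must be non-negative integers.
#' @param lineages Character vector of lineage strings, one per taxon. May be
#'   named by taxon id; unnamed vectors are matched by position. Defaults to
#'   empty lineages.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(counts, lineages = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have taxon row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("counts must be non-negative integers; offending cell: taxon '%s', sample '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "double"
  if (is.null(lineages)) {
    lineages <- rep("k__;p__;c__;o__;f__;g__;s__", nrow(counts))
    names(lineages) <- rownames(counts)
  }
  if (is.null(names(lineages))) {
    if (length(lineages) != nrow(counts)) {
      stop("`lineages` must have one entry per taxon")
    }
    names(lineages) <- rownames(counts)
  } else {
    missing <- setdiff(rownames(counts), names(lineages))
    if (length(missing) > 0) {
      stop("lineages missing for taxa: ", paste(missing, collapse = ", "))
    }
    lineages <- lineages[rownames(counts)]
  }
  structure(list(counts = counts, lineages = unname(lineages)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d taxa x %d samples, total reads %s\n",
              n_taxa(x), n_samples(x),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Accessors for feature tables
#'
#' @param x A `feature_table`.
#' @return `taxon_ids()`/`sample_ids()` return character vectors;
#'   `n_taxa()`/`n_samples()` integers; `lineages()` a named character
#'   vector; `sample_sums()` a named numeric vector of per-sample read
#'   totals; `rel_abundance()` the column-normalized counts matrix (a view,
#'   never written back to disk).
#' @name feature_table-accessors
NULL

#' @rdname feature_table-accessors
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname feature_table-accessors
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname feature_table-accessors
#' @export
n_taxa <- function(x) nrow(x$counts)

#' @rdname feature_table-accessors
#' @export
n_samples <- function(x) ncol(x$counts)

#' @rdname feature_table-accessors
#' @export
lineages <- function(x) stats::setNames(x$lineages, taxon_ids(x))

#' @rdname feature_table-accessors
#' @export
sample_sums <- function(x) colSums(x$counts)

#' @rdname feature_table-accessors
#' @export
rel_abundance <- function(x) {
  tot <- colSums(x$counts)
  if (any(tot == 0)) {
    stop("sample(s) with zero total: ",
         paste(colnames(x$counts)[tot == 0], collapse = ", "))
  }
  sweep(x$counts, 2, tot, "/")
}

#' Subset a feature table
#'
#' Order-stable subsetting by taxon and/or sample ids (or logical/integer
#' indices along the stored order).
#'
#' @param x A `feature_table`.
#' @param taxa,samples Ids or indices to keep; `NULL` keeps all.
#' @return A `feature_table`.
#' @export
ft_subset <- function(x, taxa = NULL, samples = NULL) {
  counts <- x$counts
  lin <- lineages(x)
  if (!is.null(taxa)) {
    counts <- counts[taxa, , drop = FALSE]
    lin <- lin[rownames(counts)]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  feature_table(counts, lin)
}

#' Convert a feature table to a tidy tibble
#'
#' @param x A `feature_table` object.
#' @param ... Unused.
#' @return A tibble with columns `taxon`, `sample`, `count`, `lineage`
#'   (one row per taxon-sample cell).
#' @export
tidy.feature_table <- function(x, ...) {
  tibble::tibble(
    taxon = rep(taxon_ids(x), times = n_samples(x)),
    sample = rep(sample_ids(x), each = n_taxa(x)),
    count = as.vector(x$counts),
    lineage = rep(x$lineages, times = n_samples(x))
  )
}

#' @export
glance.feature_table <- function(x, ...) {
  tot <- sample_sums(x)
  tibble::tibble(
    n_taxa = n_taxa(x), n_samples = n_samples(x),
    total_reads = sum(tot),
    min_depth = min(tot), median_depth = stats::median(tot), max_depth = max(tot),
    sparsity = mean(x$counts == 0)
  )
}

#' Read a feature table from TSV
#'
#' Expects a header row, identifiers in the first column and an optional
#' final taxonomy column (named `"taxonomy"` or `"Taxon"`, the two QIIME2
#' dialects, or any name passed via `taxonomy_col`).
#'
#' @param path Path to a tab-separated file.
#' @param orientation `"taxa"` if taxa are in rows (default), `"samples"`
#'   if samples are in rows; the returned object is always taxa x samples.
#' @param taxonomy_col Accepted names for the lineage column.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, orientation = c("taxa", "samples"),
                               taxonomy_col = c("taxonomy", "Taxon")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("feature table must have an id column and at least one data column")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate ids in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  df <- df[, -1, drop = FALSE]
  lin <- NULL
  tax_idx <- which(names(df) %in% taxonomy_col)
  if (length(tax_idx) > 0) {
    if (orientation == "samples") stop("taxonomy column requires taxa-in-rows orientation")
    lin <- df[[tax_idx[1]]]
    df <- df[, -tax_idx, drop = FALSE]
  }
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(df)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(df) > 0 && length(bad) > 0) {
    bad <- matrix(bad, ncol = 2)
    stop(sprintf("non-integer or negative count at row '%s', column '%s' (value '%s')",
                 ids[bad[1, 1]], colnames(df)[bad[1, 2]], df[bad[1, 1], bad[1, 2]]))
  }
  rownames(num) <- ids
  if (orientation == "samples") num <- t(num)
  if (!is.null(lin)) names(lin) <- ids
  feature_table(num, lin)
}

#' Write a feature table to TSV
#'
#' Taxa in rows, samples in columns, a leading `feature-id` column and a
#' trailing `taxonomy` column. `read_feature_table()` of the written file
#' returns an equal object.
#'
#' @param x A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(`feature-id` = taxon_ids(x), x$counts,
                   taxonomy = x$lineages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "feature-id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata (sample id -> group label)
#'
#' @param path TSV with a header; first column sample ids, second column the
#'   group label.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("metadata must have sample-id and group columns")
  out <- tibble::tibble(sample_id = df[[1]], group = df[[2]])
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample ids in metadata: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  }
  out
}

#' Write sample metadata
#' @param metadata Tibble with `sample_id` and `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(
    data.frame(`sample-id` = metadata$sample_id, group = metadata$group,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Checks metadata against a table: every sample labeled once, two levels for
# two-group operations. Returns the labels aligned to sample order.
align_groups <- function(x, metadata, require_two = TRUE) {
  ids <- if (inherits(x, "feature_table")) sample_ids(x) else x
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss) > 0) {
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  }
  g <- metadata$group[match(ids, metadata$sample_id)]
  if (require_two && length(unique(g)) != 2) {
    stop("exactly two group levels required, got: ",
         paste(unique(g), collapse = ", "))
  }
  factor(g)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Duplicate leaf names are rejected; missing branch lengths are set to 0
#' with a warning; negative branch lengths are rejected.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("could not parse Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf names: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  tr
}

#' Read / write a labeled square distance matrix (TSV)
#'
#' On read the matrix must be square with matching row/column labels; small
#' asymmetries (below `tol`) are symmetrized, larger ones are an error.
#'
#' @param path File path.
#' @param tol Largest tolerated asymmetry, default `1e-9`.
#' @return `read_distance_matrix()` returns a symmetric numeric matrix with
#'   sample ids as dimnames and zero diagonal.
#' @export
read_distance_matrix <- function(path, tol = 1e-9) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) {
    stop(sprintf("distance matrix must be square, got %d x %d", nrow(m), ncol(m)))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels differ")
  }
  as_distance_matrix(m, tol = tol)
}

#' @rdname read_distance_matrix
#' @param dm Symmetric matrix with dimnames.
#' @export
write_distance_matrix <- function(dm, path) {
  df <- data.frame(`sample-id` = rownames(dm), dm, check.names = FALSE)
  names(df)[1] <- "sample-id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Validate and canonicalize a distance matrix: symmetric within tol (then
# exactly symmetrized), zero diagonal, non-negative.
as_distance_matrix <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("distance matrix must carry sample ids")
  asym <- max(abs(m - t(m)))
  if (asym > tol) {
    stop(sprintf("asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  }
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (any(m < 0)) stop("negative dissimilarities are not allowed")
  m
}
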