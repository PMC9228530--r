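#' Remove contaminant taxa by lineage pattern
#'
#' Drops taxa whose lineage string case-insensitively contains any of the
#' given substrings. Defaults target mitochondrial and chloroplast reads,
#' the usual 16S contaminants.
#'
#' @param table A [feature_table()].
#' @param patterns Character vector of lineage substrings (matched as fixed
#'   strings, case-insensitively).
#' @return A list with `table` (filtered) and `report` (a `filter_report`).
#' @export
remove_contaminants <- function(table, patterns = c("mitochondri", "chloroplast")) {
  lin <- tolower(lineages(table))
  hit <- rep(FALSE, n_taxa(table))
  for (p in tolower(patterns)) hit <- hit | grepl(p, lin, fixed = TRUE)
  if (all(hit)) stop("all taxa match contaminant patterns; nothing left")
  out <- ft_subset(table, taxa = !hit)
  list(table = out,
       report = filter_report(contaminants = taxon_ids(table)[hit]))
}

#' Remove ultra-rare taxa
#'
#' A taxon is removed when its prevalence (number of samples with count
#' > 0) is below `min_samples` or its total count across samples is below
#' `min_total` (strict "less than"; a taxon in exactly `min_samples`
#' samples with exactly `min_total` reads is retained). `rule = "and"`
#' requires both conditions to remove.
#'
#' @param table A [feature_table()].
#' @param min_samples Minimum prevalence, default 5.
#' @param min_total Minimum total count across samples, default 20.
#' @param rule `"or"` (default: either condition removes) or `"and"`.
#' @return A list with `table` and `report`.
#' @export
remove_ultra_rare <- function(table, min_samples = 5, min_total = 20,
                              rule = c("or", "and")) {
  rule <- match.arg(rule)
  prev <- rowSums(table$counts > 0)
  tot <- rowSums(table$counts)
  low_prev <- prev < min_samples
  low_tot <- tot < min_total
  drop <- if (rule == "or") low_prev | low_tot else low_prev & low_tot
  if (all(drop)) {
    warning("all taxa removed as ultra-rare; returning empty table")
  }
  out <- ft_subset(table, taxa = !drop)
  list(table = out,
       report = filter_report(ultra_rare = taxon_ids(table)[drop]))
}

#' Rarefy a feature table to even depth
#'
#' Samples with fewer than `depth` total reads are excluded (and reported);
#' the rest are subsampled without replacement (multivariate
#' hypergeometric, QIIME2-style) to exactly `depth` reads.
#'
#' @param table A [feature_table()].
#' @param depth Target depth in reads, default 10000.
#' @param seed Integer seed; fixed seed gives a reproducible subsample.
#' @return A list with `table` and `report` (excluded samples and their
#'   totals in `report$excluded_samples`).
#' @export
rarefy <- function(table, depth = 10000, seed = 1L) {
  stopifnot(depth > 0)
  tot <- sample_sums(table)
  keep <- tot >= depth
  if (!any(keep)) stop("all samples have fewer than `depth` reads")
  kept <- ft_subset(table, samples = keep)
  counts <- withr::with_seed(as.integer(seed), {
    rrarefy_counts(kept$counts, depth)
  })
  ft <- feature_table(counts, lineages(kept))
  list(table = ft,
       report = filter_report(
         excluded_samples = tibble::tibble(
           sample_id = sample_ids(table)[!keep],
           total = unname(tot[!keep])),
         depth = depth))
}

#' Rarefaction curve of an alpha metric
#'
#' Mean of the metric over `replicates` random subsamples at each depth;
#' depths above a sample's total are reported as `NA` for that sample.
#'
#' @param table A [feature_table()].
#' @param depths Numeric vector of depths.
#' @param replicates Subsample replicates per depth, default 10.
#' @param metric Alpha metric name (see [alpha_diversity()]).
#' @param tree Tree, required for `faith_pd`.
#' @param seed Integer seed.
#' @return Tibble `sample_id`, `depth`, `value` (mean over replicates).
#' @export
rarefaction_curve <- function(table, depths, replicates = 10,
                              metric = "observed_features", tree = NULL,
                              seed = 1L) {
  tot <- sample_sums(table)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (d in depths) {
      ok <- tot >= d
      acc <- matrix(NA_real_, replicates, n_samples(table))
      if (any(ok)) {
        sub <- ft_subset(table, samples = ok)
        for (r in seq_len(replicates)) {
          rft <- feature_table(rrarefy_counts(sub$counts, d),
                               lineages(sub))
          a <- alpha_diversity(rft, metric = metric, tree = tree, warn_uneven = FALSE)
          acc[r, ok] <- a$value[match(sample_ids(sub), a$sample_id)]
        }
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sample_ids(table), depth = d, value = colMeans(acc))
    }
    dplyr::bind_rows(rows)
  })
}

# Subsample without replacement (vegan::rrarefy) on a taxa x samples
# matrix, preserving dimnames even in the one-taxon degenerate case.
rrarefy_counts <- function(counts, depth) {
  if (nrow(counts) == 1) {  # single taxon: all subsampled reads are it
    out <- matrix(pmin(depth, counts[1, ]), nrow = 1)
  } else {
    # inputs are pre-validated (integral counts, depth <= every total), so
    # vegan's advisory warnings are noise here
    out <- t(as.matrix(suppressWarnings(vegan::rrarefy(t(counts), depth))))
  }
  dimnames(out) <- dimnames(counts)
  storage.mode(out) <- "double"
  out
}

filter_report <- function(contaminants = character(0),
                          ultra_rare = character(0),
                          excluded_samples = tibble::tibble(
                            sample_id = character(0), total = numeric(0)),
                          depth = NA_real_) {
  structure(list(contaminants = contaminants, ultra_rare = ultra_rare,
                 excluded_samples = excluded_samples, depth = depth),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat("  contaminant taxa removed:", length(x$contaminants), "\n")
  cat("  ultra-rare taxa removed:", length(x$ultra_rare), "\n")
  if (nrow(x$excluded_samples) > 0 || !is.na(x$depth)) {
    cat(sprintf("  samples excluded at depth %s: %d\n",
                format(x$depth), nrow(x$excluded_samples)))
  }
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(kind = "contaminant", id = x$contaminants, total = NA_real_),
    tibble::tibble(kind = "ultra_rare", id = x$ultra_rare, total = NA_real_),
    tibble::tibble(kind = "excluded_sample", id = x$excluded_samples$sample_id,
                   total = x$excluded_samples$total))
}
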