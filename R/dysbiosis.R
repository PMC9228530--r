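#' Median Bray-Curtis distance dysbiosis test
#'
#' Each test sample is scored by its median Bray-Curtis distance to every
#' reference sample; the dysbiotic cutoff is the `quantile` (default 90%)
#' quantile of the reference-internal distribution. By default the
#' reference-internal distribution is the set of per-reference-sample
#' median distances to the other reference samples (leave-one-out), so the
#' cutoff and the test statistic are the same functional and ~10% of
#' reference samples exceed the cutoff by construction; the pooled
#' pairwise distribution is available via `cutoff_method = "pooled"`.
#' Quantiles use linear (type-7) interpolation.
#'
#' @param dm Symmetric distance matrix covering all ids.
#' @param reference_ids Reference (healthy) sample ids, at least 3.
#' @param test_ids Test sample ids; must be disjoint from the reference.
#' @param quantile Cutoff quantile, default 0.90.
#' @param cutoff_method `"loo_median"` (default) or `"pooled"`.
#' @return A `median_distance_result`: tibble `sample_id`,
#'   `median_distance`, `cutoff`, `dysbiotic`, with attribute `cutoff`.
#' @export
median_distance_test <- function(dm, reference_ids, test_ids,
                                 quantile = 0.90,
                                 cutoff_method = c("loo_median", "pooled")) {
  cutoff_method <- match.arg(cutoff_method)
  dm <- as_distance_matrix(dm, tol = 1e-8)
  if (length(reference_ids) < 3) stop("need at least 3 reference samples")
  overlap <- intersect(reference_ids, test_ids)
  if (length(overlap) > 0) {
    stop("test and reference ids overlap: ", paste(overlap, collapse = ", "))
  }
  miss <- setdiff(c(reference_ids, test_ids), rownames(dm))
  if (length(miss) > 0) stop("ids missing from distance matrix: ",
                             paste(miss, collapse = ", "))
  ref <- dm[reference_ids, reference_ids, drop = FALSE]
  ref_stat <- vapply(seq_along(reference_ids), function(i) {
    stats::median(ref[i, -i])
  }, numeric(1))
  cutoff <- if (cutoff_method == "loo_median") {
    stats::quantile(ref_stat, quantile, type = 7, names = FALSE)
  } else {
    stats::quantile(ref[upper.tri(ref)], quantile, type = 7, names = FALSE)
  }
  stat <- vapply(test_ids, function(id) {
    stats::median(dm[id, reference_ids])
  }, numeric(1))
  out <- tibble::tibble(sample_id = test_ids,
                        median_distance = unname(stat),
                        cutoff = cutoff,
                        dysbiotic = unname(stat) > cutoff)
  structure(out, class = c("median_distance_result", class(out)),
            cutoff = cutoff, reference_statistics = ref_stat)
}

# Pairwise overlap / dissimilarity for the DOC: overlap is the shared-taxa
# mass, dissimilarity the root Jensen-Shannon divergence (natural log) of
# the two compositions renormalized over the shared taxa.
doc_pair <- function(x, y) {
  s <- x > 0 & y > 0
  if (!any(s)) return(c(NA_real_, NA_real_))
  o <- 0.5 * sum(x[s] + y[s])
  xs <- x[s] / sum(x[s]); ys <- y[s] / sum(y[s])
  m <- (xs + ys) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  d <- sqrt(pmax(0, 0.5 * kl(xs, m) + 0.5 * kl(ys, m)))
  c(o, d)
}

#' Dissimilarity-overlap curve (DOC) analysis
#'
#' For every sample pair the overlap `O = ½ Σ_{i∈S}(xᵢ + yᵢ)` over the
#' shared taxon set S and the dissimilarity `D = rJSD` of the
#' renormalized shared compositions are computed; a LOWESS curve of D on O
#' is fitted, and within the high-overlap region (pairs above the median
#' overlap by default) the slope of a linear fit and the Spearman
#' correlation are reported, with a bootstrap over samples for confidence
#' bands. A negative high-overlap slope is the signature of universal
#' microbial dynamics; healthy reference cohorts typically show it.
#'
#' @param table A [feature_table()].
#' @param ids Sample ids to use (default all); at least 10 for a
#'   meaningful curve (warning below that).
#' @param lowess_frac LOWESS smoother span, default 0.3.
#' @param region Either `"median"` (pairs with overlap above the median)
#'   or a numeric overlap lower bound.
#' @param n_boot Bootstrap resamples of samples, default 100.
#' @param seed Integer seed.
#' @return A `doc_result`: list with `pairs` (tibble `sample_1`,
#'   `sample_2`, `overlap`, `dissimilarity`), `curve` (LOWESS fit),
#'   `region_bound`, `slope`, `spearman`, `boot` (per-resample slope and
#'   Spearman).
#' @export
doc_analysis <- function(table, ids = NULL, lowess_frac = 0.3,
                         region = "median", n_boot = 100, seed = 1L) {
  if (!is.null(ids)) table <- ft_subset(table, samples = ids)
  n <- n_samples(table)
  if (n < 3) stop("need at least 3 samples")
  if (n < 10) warning("fewer than 10 samples; the DOC will be noisy")
  p <- rel_abundance(table)
  sid <- sample_ids(table)
  pair_idx <- utils::combn(n, 2)
  od <- apply(pair_idx, 2, function(ij) doc_pair(p[, ij[1]], p[, ij[2]]))
  pairs <- tibble::tibble(sample_1 = sid[pair_idx[1, ]],
                          sample_2 = sid[pair_idx[2, ]],
                          overlap = od[1, ], dissimilarity = od[2, ])
  if (all(is.na(pairs$overlap))) stop("no sample pair shares any taxon")
  ok <- stats::complete.cases(pairs$overlap, pairs$dissimilarity)
  region_stats <- function(o, d, bound) {
    inr <- o > bound
    if (sum(inr) < 3 || stats::sd(o[inr]) == 0 || stats::sd(d[inr]) == 0) {
      return(c(slope = NA_real_, spearman = NA_real_))
    }
    c(slope = unname(stats::coef(stats::lm(d[inr] ~ o[inr]))[2]),
      spearman = suppressWarnings(
        stats::cor(o[inr], d[inr], method = "spearman")))
  }
  bound <- if (identical(region, "median")) {
    stats::median(pairs$overlap[ok])
  } else as.numeric(region)
  obs <- region_stats(pairs$overlap[ok], pairs$dissimilarity[ok], bound)
  lw <- stats::lowess(pairs$overlap[ok], pairs$dissimilarity[ok],
                      f = lowess_frac)
  boot <- withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_boot), function(b) {
      take <- sample(n, n, replace = TRUE)
      keep <- ok & pair_idx[1, ] %in% take & pair_idx[2, ] %in% take
      st <- region_stats(pairs$overlap[keep], pairs$dissimilarity[keep], bound)
      tibble::tibble(replicate = b, slope = st["slope"],
                     spearman = st["spearman"])
    })
  })
  structure(list(pairs = pairs,
                 curve = tibble::tibble(overlap = lw$x, dissimilarity = lw$y),
                 region_bound = bound,
                 slope = unname(obs["slope"]),
                 spearman = unname(obs["spearman"]),
                 boot = boot),
            class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  cat(sprintf("<doc_result> %d pairs; high-overlap (O > %.3f) slope %.3f, Spearman %.3f\n",
              nrow(x$pairs), x$region_bound, x$slope, x$spearman))
  invisible(x)
}

#' @export
glance.doc_result <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), region_bound = x$region_bound,
                 slope = x$slope, spearman = x$spearman,
                 spearman_lo = stats::quantile(x$boot$spearman, 0.025,
                                               na.rm = TRUE, names = FALSE),
                 spearman_hi = stats::quantile(x$boot$spearman, 0.975,
                                               na.rm = TRUE, names = FALSE))
}

#' @export
tidy.doc_result <- function(x, ...) x$pairs

#' DOC plot
#' @param object A `doc_result`.
#' @param ... Unused.
#' @return A ggplot of the dissimilarity-overlap cloud and LOWESS curve.
#' @export
autoplot.doc_result <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$overlap, .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_line(data = object$curve, colour = "red") +
    ggplot2::geom_vline(xintercept = object$region_bound,
                        linetype = "dashed") +
    ggplot2::labs(x = "overlap", y = "dissimilarity (rJSD)") +
    ggplot2::theme_minimal()
}

# Mean distance from row `i` of `d` to its k nearest of the columns `js`.
knn_diameter <- function(d, i, js, k) {
  v <- sort(d[i, js])[seq_len(k)]
  mean(v)
}

cloud_r <- function(dm, subset_ids, id, k) {
  own <- knn_diameter(dm, id, subset_ids, k)
  ref <- vapply(subset_ids, function(s) {
    knn_diameter(dm, s, setdiff(subset_ids, s), k)
  }, numeric(1))
  denom <- mean(ref)
  if (denom == 0) return(1)
  own / denom
}

#' CLOUD nonparametric outlier (dysbiosis) test
#'
#' The r statistic is the ratio of the test sample's k-nearest-neighbour
#' neighbourhood diameter (mean distance to its k nearest members of a
#' random reference subset) to the average leave-one-out neighbourhood
#' diameter of the subset members; `r = 3` means the sample's
#' neighbourhood is three times wider than a typical healthy one. The
#' reported r is the mean over `n_draws` random subsets of the chosen
#' reference fraction; the empirical p-value is the +1-corrected fraction
#' of reference samples whose own (leave-one-out) r is at least the test
#' sample's.
#'
#' @param dm Symmetric distance matrix.
#' @param reference_ids Reference sample ids.
#' @param test_ids Test sample ids (disjoint from the reference).
#' @param ref_fraction Fraction of the reference used per subset draw,
#'   typically 0.05, 0.15 or 0.30 (1 uses the whole reference set in a
#'   single deterministic draw).
#' @param k Neighbourhood size; default `max(3, ceiling(0.05 *
#'   n_reference))`, capped at subset size − 1.
#' @param n_draws Random subset draws, default 100.
#' @param seed Integer seed.
#' @return A `cloud_result` tibble: `sample_id`, `r`, `p_value`, `k`,
#'   `ref_fraction`.
#' @export
cloud_test <- function(dm, reference_ids, test_ids, ref_fraction = 0.30,
                       k = NULL, n_draws = 100, seed = 1L) {
  dm <- as_distance_matrix(dm, tol = 1e-8)
  overlap <- intersect(reference_ids, test_ids)
  if (length(overlap) > 0) {
    stop("test and reference ids overlap: ", paste(overlap, collapse = ", "))
  }
  nref <- length(reference_ids)
  ssize <- ceiling(ref_fraction * nref)
  if (is.null(k)) k <- max(3L, ceiling(0.05 * nref))
  k <- as.integer(k)
  if (ssize - 1 < k) {
    stop(sprintf("subset size %d too small for k = %d neighbours", ssize, k))
  }
  deterministic <- ssize >= nref
  if (deterministic) n_draws <- 1L
  score_sample <- function(id, pool) {
    # mean r over subset draws from `pool` (the reference minus the sample
    # itself when scoring a reference sample)
    rs <- vapply(seq_len(n_draws), function(b) {
      sub <- if (deterministic) pool else sample(pool, min(ssize, length(pool)))
      cloud_r(dm, sub, id, min(k, length(sub) - 1))
    }, numeric(1))
    mean(rs)
  }
  withr::with_seed(as.integer(seed), {
    ref_scores <- vapply(reference_ids, function(id) {
      score_sample(id, setdiff(reference_ids, id))
    }, numeric(1))
    test_scores <- vapply(test_ids, function(id) {
      score_sample(id, reference_ids)
    }, numeric(1))
  })
  p <- vapply(test_scores, function(r) {
    (1 + sum(ref_scores >= r)) / (1 + nref)
  }, numeric(1))
  out <- tibble::tibble(sample_id = test_ids, r = unname(test_scores),
                        p_value = p, k = k, ref_fraction = ref_fraction)
  structure(out, class = c("cloud_result", class(out)),
            reference_scores = ref_scores, n_draws = n_draws)
}

#' Combined three-test dysbiosis report
#'
#' Computes a Bray-Curtis distance matrix, then runs the median-distance
#' quantile test and the CLOUD test (at each requested reference fraction)
#' for every test sample against the reference group, and DOC analyses for
#' the reference set and (when large enough) the test set.
#'
#' @param table A [feature_table()] (rarefied recommended).
#' @param metadata Metadata tibble.
#' @param reference_group The group label to use as healthy reference.
#' @param quantile Median-distance cutoff quantile, default 0.90.
#' @param ref_fractions CLOUD reference fractions, default
#'   `c(0.05, 0.15, 0.30)`.
#' @param k CLOUD neighbourhood size (`NULL` for the default rule).
#' @param n_draws CLOUD subset draws, default 100.
#' @param n_boot DOC bootstrap resamples, default 100.
#' @param alpha CLOUD significance level used for the flag, default 0.05.
#' @param seed Integer seed.
#' @return A `dysbiosis_report`: list with `median_distance`, `cloud`
#'   (tibble over fractions), `doc_reference`, `doc_test`, `flags`
#'   (per-sample summary tibble).
#' @export
dysbiosis_report <- function(table, metadata, reference_group,
                             quantile = 0.90,
                             ref_fractions = c(0.05, 0.15, 0.30),
                             k = NULL, n_draws = 100, n_boot = 100,
                             alpha = 0.05, seed = 1L) {
  g <- align_groups(table, metadata, require_two = FALSE)
  ids <- sample_ids(table)
  reference_ids <- ids[g == reference_group]
  test_ids <- setdiff(ids, reference_ids)
  if (length(reference_ids) < 4) stop("reference group too small")
  dm <- beta_matrix(table, "bray_curtis")
  md <- median_distance_test(dm, reference_ids, test_ids, quantile = quantile)
  cl <- purrr::map_dfr(ref_fractions, function(fr) {
    ssize <- ceiling(fr * length(reference_ids))
    kk <- if (is.null(k)) max(3L, ceiling(0.05 * length(reference_ids))) else k
    if (ssize - 1 < kk) {
      # fraction too small for the neighbourhood rule on this cohort
      return(tibble::tibble(sample_id = character(0), r = numeric(0),
                            p_value = numeric(0), k = integer(0),
                            ref_fraction = numeric(0)))
    }
    tibble::as_tibble(cloud_test(dm, reference_ids, test_ids,
                                 ref_fraction = fr, k = kk,
                                 n_draws = n_draws, seed = seed))
  })
  doc_ref <- doc_analysis(table, ids = reference_ids, n_boot = n_boot,
                          seed = seed)
  doc_test <- if (length(test_ids) >= 10) {
    doc_analysis(table, ids = test_ids, n_boot = n_boot, seed = seed)
  } else NULL
  cloud_flag <- if (nrow(cl) > 0) {
    cl |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(cloud_r_max = max(.data$r),
                       cloud_dysbiotic = any(.data$r > 1 &
                                               .data$p_value < alpha),
                       .groups = "drop")
  } else {
    tibble::tibble(sample_id = character(0), cloud_r_max = numeric(0),
                   cloud_dysbiotic = logical(0))
  }
  flags <- tibble::tibble(sample_id = test_ids) |>
    dplyr::left_join(tibble::as_tibble(md)[, c("sample_id", "median_distance",
                                               "dysbiotic")],
                     by = "sample_id") |>
    dplyr::rename(median_dysbiotic = "dysbiotic") |>
    dplyr::left_join(cloud_flag, by = "sample_id")
  structure(list(median_distance = md, cloud = cl,
                 doc_reference = doc_ref, doc_test = doc_test,
                 flags = flags,
                 parameters = list(reference_group = reference_group,
                                   quantile = quantile,
                                   ref_fractions = ref_fractions,
                                   n_draws = n_draws, n_boot = n_boot,
                                   alpha = alpha, seed = seed)),
            class = "dysbiosis_report")
}

#' @export
print.dysbiosis_report <- function(x, ...) {
  cat("<dysbiosis_report>\n")
  cat(sprintf("  median-distance cutoff: %.4f; flagged: %d / %d\n",
              attr(x$median_distance, "cutoff"),
              sum(x$median_distance$dysbiotic), nrow(x$median_distance)))
  if (nrow(x$cloud) > 0) {
    cat(sprintf("  CLOUD flagged (any fraction): %d\n",
                sum(x$flags$cloud_dysbiotic, na.rm = TRUE)))
  }
  cat(sprintf("  reference DOC high-overlap Spearman: %.3f\n",
              x$doc_reference$spearman))
  invisible(x)
}

#' @export
tidy.dysbiosis_report <- function(x, ...) x$flags
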