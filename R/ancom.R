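# Centered log-ratio transform of a counts matrix (features x samples),
# after adding `pseudocount` and closing each sample to 1.
clr_transform <- function(counts, pseudocount = 1) {
  x <- counts + pseudocount
  x <- sweep(x, 2, colSums(x), "/")
  lx <- log(x)
  sweep(lx, 2, colMeans(lx), "-")
}

#' ANCOM: analysis of composition of microbiomes
#'
#' For every ordered pair of taxa (i, j) the group difference of the
#' additive log-ratio `log((cᵢ + pc) / (cⱼ + pc))` is tested with a
#' Mann-Whitney test; p-values are BH-adjusted within each taxon i's family
#' of m−1 tests, and Wᵢ counts the rejections at `alpha`. A taxon is
#' flagged as differentially abundant when `Wᵢ ≥ threshold_frac × (m−1)`
#' (the usual 0.7 heuristic; the raw W is always reported). The direction
#' of enrichment is the group with the higher mean CLR abundance.
#'
#' @param table A [feature_table()], already contaminant- and
#'   ultra-rare-filtered.
#' @param metadata Metadata tibble with two group levels.
#' @param alpha Per-family rejection level, default 0.05.
#' @param pseudocount Added before log-ratio formation, default 1.
#' @param threshold_frac Detection threshold as a fraction of m−1,
#'   default 0.7.
#' @return An `ancom_result`: tibble `taxon`, `W`, `detected`, `direction`,
#'   `clr_diff`, with attributes `threshold` and `groups`.
#' @export
ancom <- function(table, metadata, alpha = 0.05, pseudocount = 1,
                  threshold_frac = 0.7) {
  m <- n_taxa(table)
  if (m < 3) stop("ANCOM needs at least 3 taxa")
  g <- align_groups(table, metadata)
  lev <- levels(g)
  lc <- log(table$counts + pseudocount)
  i1 <- which(g == lev[1])
  i2 <- which(g == lev[2])
  # p-value matrix of the pairwise log-ratio tests (symmetric in i, j)
  pmat <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      lr <- lc[i, ] - lc[j, ]
      p <- suppressWarnings(
        stats::wilcox.test(lr[i1], lr[i2], exact = FALSE)$p.value)
      if (is.nan(p)) p <- 1  # constant log-ratio in both groups
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  W <- vapply(seq_len(m), function(i) {
    q <- stats::p.adjust(pmat[i, -i], method = "BH")
    sum(q < alpha)
  }, integer(1))
  clr <- clr_transform(table$counts, pseudocount)
  clr_diff <- unname(rowMeans(clr[, i1, drop = FALSE]) -
                       rowMeans(clr[, i2, drop = FALSE]))
  threshold <- threshold_frac * (m - 1)
  out <- tibble::tibble(
    taxon = taxon_ids(table),
    W = W,
    detected = W >= threshold,
    direction = ifelse(clr_diff >= 0, lev[1], lev[2]),
    clr_diff = clr_diff)
  structure(out, class = c("ancom_result", class(out)),
            threshold = threshold, groups = lev, alpha = alpha)
}

#' @export
print.ancom_result <- function(x, ...) {
  cat(sprintf("<ancom_result> %d taxa, detection threshold W >= %.1f, %d detected\n",
              nrow(x), attr(x, "threshold"), sum(x$detected)))
  NextMethod()
}

#' ANCOM W plot
#' @param object An `ancom_result`.
#' @param ... Unused.
#' @return A ggplot of W against the mean CLR group difference.
#' @export
autoplot.ancom_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$clr_diff, .data$W,
                                   colour = .data$detected)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean CLR difference", y = "W") +
    ggplot2::theme_minimal()
}
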