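# Balance statistic of a two-part partition (numerator/denominator taxon
# sets) on log counts: sqrt(kn*kd/(kn+kd)) * (mean log N - mean log D),
# i.e. a normalized log-contrast of geometric means. Scale-invariant:
# multiplying a sample's counts by a constant shifts both means equally.
balance_values <- function(lc, num, den) {
  kn <- length(num); kd <- length(den)
  mn <- if (kn == 1) lc[num, ] else colMeans(lc[num, , drop = FALSE])
  md <- if (kd == 1) lc[den, ] else colMeans(lc[den, , drop = FALSE])
  sqrt(kn * kd / (kn + kd)) * (mn - md)
}

# Cross-validated AUC of a fixed univariate balance: orientation is learned
# on the training folds, held-out signed scores are pooled and ranked.
cv_auc_balance <- function(b, y, fold) {
  pred <- numeric(length(b))
  pos <- y == levels(y)[2]
  for (f in unique(fold)) {
    tr <- fold != f
    s <- if (mean(b[tr & pos]) >= mean(b[tr & !pos])) 1 else -1
    pred[!tr] <- s * b[!tr]
  }
  rank_auc(pred, y)
}

#' Selbal-style greedy balance selection
#'
#' Forward search over two-part balances: the best discriminating
#' (numerator, denominator) taxon pair initializes the balance, then taxa
#' are greedily added to either side while the cross-validated AUC of the
#' balance improves, stopping at `max_taxa` total taxa. Ties are broken by
#' the lowest taxon index (numerator side first) for determinism. The
#' final balance is oriented so that its mean is higher in the second
#' group level; numerator taxa are therefore enriched in that group.
#'
#' @inheritParams clr_lasso
#' @return A `selection_result` with `role` = `"numerator"` /
#'   `"denominator"`.
#' @export
selbal <- function(table, metadata, max_taxa = 20, cv_folds = 5,
                   pseudocount = 1, seed = 1L) {
  counts <- get_counts(table)
  m <- nrow(counts)
  if (m < 2) stop("selbal needs at least 2 taxa")
  g <- align_groups(colnames(counts), metadata)
  lev <- levels(g)
  lc <- log(counts + pseudocount)
  withr::with_seed(as.integer(seed), {
    fold <- make_folds(g, cv_folds)
    best <- list(score = -Inf, num = NULL, den = NULL)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        sc <- cv_auc_balance(balance_values(lc, i, j), g, fold)
        if (!is.na(sc) && sc > best$score) best <- list(score = sc, num = i, den = j)
      }
    }
    num <- best$num; den <- best$den; score <- best$score
    repeat {
      if (length(num) + length(den) >= max_taxa) break
      cand <- setdiff(seq_len(m), c(num, den))
      if (length(cand) == 0) break
      step_best <- list(score = score, num = num, den = den, improved = FALSE)
      for (t in cand) {
        for (side in c("num", "den")) {
          nn <- if (side == "num") c(num, t) else num
          dd <- if (side == "den") c(den, t) else den
          sc <- cv_auc_balance(balance_values(lc, nn, dd), g, fold)
          if (!is.na(sc) && sc > step_best$score) {
            step_best <- list(score = sc, num = nn, den = dd, improved = TRUE)
          }
        }
      }
      if (!step_best$improved) break
      num <- step_best$num; den <- step_best$den; score <- step_best$score
    }
    # orient the balance toward the second group level
    b <- balance_values(lc, num, den)
    if (mean(b[g == lev[2]]) < mean(b[g == lev[1]])) {
      tmp <- num; num <- den; den <- tmp
    }
    taxa_idx <- c(num, den)
    selection_result("selbal",
                     taxa = rownames(counts)[taxa_idx],
                     coefficient = rep(NA_real_, length(taxa_idx)),
                     role = rep(c("numerator", "denominator"),
                                c(length(num), length(den))),
                     direction = rep(c(lev[2], lev[1]),
                                     c(length(num), length(den))),
                     score = score, groups = lev)
  })
}

#' Cross-method consensus of differential-abundance selections
#'
#' Tallies, per taxon, which methods selected it and its direction of
#' enrichment, with optional collapsing of taxa that share a lineage
#' prefix at a given rank (1 = kingdom ... 7 = species) when counting
#' distinct taxonomies.
#'
#' @param ancom Optional [ancom()] result (its detected taxa count as a
#'   selection by method `"ancom"`).
#' @param selections List of `selection_result` objects.
#' @param lineage Optional named lineage vector (as from [lineages()]) used
#'   for taxonomy collapsing.
#' @param collapse_rank Rank depth at which taxa sharing a lineage prefix
#'   collapse to one taxonomy; `NULL` disables collapsing.
#' @return A `consensus_report`: list with `table` (tibble `taxon`,
#'   `methods`, `n_methods`, `direction`, `taxonomy`) and `summary`
#'   (per-direction taxa and distinct-taxonomy counts).
#' @export
da_consensus <- function(ancom = NULL, selections = list(), lineage = NULL,
                         collapse_rank = NULL) {
  rows <- list()
  if (!is.null(ancom)) {
    det <- ancom[ancom$detected, ]
    if (nrow(det) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = det$taxon, method = "ancom", direction = det$direction)
    }
  }
  for (s in selections) {
    if (nrow(s) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        taxon = s$taxon, method = attr(s, "method"), direction = s$direction)
    }
  }
  long <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble::tibble(taxon = character(0), method = character(0),
                   direction = character(0))
  tab <- long |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      methods = paste(sort(unique(.data$method)), collapse = ","),
      n_methods = dplyr::n_distinct(.data$method),
      direction = if (dplyr::n_distinct(.data$direction) == 1)
        .data$direction[1] else "conflicting",
      .groups = "drop")
  tab$taxonomy <- if (!is.null(lineage)) {
    lin <- lineage[tab$taxon]
    if (!is.null(collapse_rank)) collapse_lineage(lin, collapse_rank) else unname(lin)
  } else tab$taxon
  summary <- tab |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(n_taxa = dplyr::n(),
                     n_taxonomies = dplyr::n_distinct(.data$taxonomy),
                     .groups = "drop")
  structure(list(table = tab, summary = summary,
                 collapse_rank = collapse_rank),
            class = "consensus_report")
}

# First `rank` fields of a semicolon-separated lineage string, trimmed.
collapse_lineage <- function(lineage, rank) {
  vapply(strsplit(lineage, ";"), function(parts) {
    parts <- trimws(parts)
    paste(parts[seq_len(min(rank, length(parts)))], collapse = ";")
  }, character(1))
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("<consensus_report>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.consensus_report <- function(x, ...) x$table

#' @export
glance.consensus_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "direction",
                     values_from = c("n_taxa", "n_taxonomies"))
}
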