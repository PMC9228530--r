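#' ALDEx2-style CLR effect sizes for a two-group count table
#'
#' For each of `n_mc` Monte-Carlo instances a per-sample composition is
#' drawn from `Dirichlet(counts + prior)` and CLR-transformed; per feature
#' and instance, `min(n1, n2)` random cross-group pairings give
#' between-group CLR differences (`diff.btw`, sign convention: second
#' group level minus first, declared in the output attribute) and random
#' within-group pairings give within-group differences whose per-pairing
#' maximum of the two groups' absolute values is the dispersion
#' (`diff.win`). The effect is the median of `diff.btw / diff.win` over all
#' instances and pairings. Features with all-zero counts in both groups
#' are excluded with a warning.
#'
#' @param counts Feature-by-sample count matrix (or [feature_table()]),
#'   e.g. an unstratified MetaCyc pathway table.
#' @param metadata Metadata tibble with two group levels.
#' @param n_mc Number of Dirichlet Monte-Carlo instances, default 128.
#' @param prior Dirichlet prior added to every count, default 0.5.
#' @param seed Integer seed; fixed seed gives an identical table.
#' @return An `effect_table`: tibble `feature`, `clr_median_1`,
#'   `clr_median_2`, `diff_btw`, `diff_win`, `effect`, with attribute
#'   `groups` (effect sign is `groups[2] - groups[1]`).
#' @export
aldex_effect <- function(counts, metadata, n_mc = 128, prior = 0.5,
                         seed = 1L) {
  counts <- get_counts(counts)
  g <- align_groups(colnames(counts), metadata)
  lev <- levels(g)
  if (any(table(g) < 2)) stop("each group needs at least 2 samples")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " feature(s) with all-zero counts")
    counts <- counts[!zero, , drop = FALSE]
  }
  m <- nrow(counts); n <- ncol(counts)
  i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
  npair <- min(length(i1), length(i2))
  withr::with_seed(as.integer(seed), {
    ratios <- matrix(NA_real_, m, n_mc * npair)
    btw <- matrix(NA_real_, m, n_mc * npair)
    win <- matrix(NA_real_, m, n_mc * npair)
    sum1 <- matrix(0, m, n_mc); sum2 <- matrix(0, m, n_mc)
    for (k in seq_len(n_mc)) {
      # Dirichlet draw per sample, then CLR
      gmat <- matrix(stats::rgamma(m * n, shape = counts + prior, rate = 1),
                     m, n)
      lx <- log(gmat)  # CLR of g/sum(g): log g - mean log g (sums cancel)
      clr <- sweep(lx, 2, colMeans(lx), "-")
      sum1[, k] <- apply(clr[, i1, drop = FALSE], 1, stats::median)
      sum2[, k] <- apply(clr[, i2, drop = FALSE], 1, stats::median)
      # one global permutation induces both groups' orders, so swapping
      # the group labels mirrors the pairings and negates the effect
      # exactly
      perm <- sample.int(n)
      p1 <- perm[perm %in% i1]
      p2 <- perm[perm %in% i2]
      a1 <- p1[seq_len(npair)]; a2 <- p2[seq_len(npair)]
      # within-group pairs from a cyclic shift: never self-paired
      w1a <- p1[seq_len(npair)]
      w1b <- p1[c(seq_along(p1)[-1], 1)][seq_len(npair)]
      w2a <- p2[seq_len(npair)]
      w2b <- p2[c(seq_along(p2)[-1], 1)][seq_len(npair)]
      cols <- (k - 1) * npair + seq_len(npair)
      b <- clr[, a2, drop = FALSE] - clr[, a1, drop = FALSE]
      wmax <- pmax(abs(clr[, w1a, drop = FALSE] - clr[, w1b, drop = FALSE]),
                   abs(clr[, w2a, drop = FALSE] - clr[, w2b, drop = FALSE]))
      wmax[wmax == 0] <- .Machine$double.eps
      btw[, cols] <- b
      win[, cols] <- wmax
      ratios[, cols] <- b / wmax
    }
    out <- tibble::tibble(
      feature = rownames(counts),
      clr_median_1 = apply(sum1, 1, stats::median),
      clr_median_2 = apply(sum2, 1, stats::median),
      diff_btw = apply(btw, 1, stats::median),
      diff_win = apply(win, 1, stats::median),
      effect = apply(ratios, 1, stats::median))
    structure(out, class = c("effect_table", class(out)), groups = lev,
              n_mc = n_mc, prior = prior)
  })
}

#' @export
print.effect_table <- function(x, ...) {
  lev <- attr(x, "groups")
  cat(sprintf("<effect_table> %d features; effect sign = %s minus %s\n",
              nrow(x), lev[2], lev[1]))
  NextMethod()
}

#' Threshold ladder over an effect table
#'
#' Features passing each absolute-effect cutoff, signed by direction.
#' Cutoff classes are nested by construction (1.5 ⊆ 1 ⊆ 0.5).
#'
#' @param effects An `effect_table` from [aldex_effect()].
#' @param cutoffs Absolute-effect cutoffs, default `c(0.5, 1, 1.5)`.
#' @return Tibble `cutoff`, `feature`, `effect`, `direction`.
#' @export
threshold_report <- function(effects, cutoffs = c(0.5, 1, 1.5)) {
  lev <- attr(effects, "groups")
  if (is.null(lev)) lev <- c("group1", "group2")
  rows <- lapply(sort(cutoffs), function(ct) {
    hit <- effects[abs(effects$effect) >= ct, ]
    tibble::tibble(cutoff = rep(ct, nrow(hit)),
                   feature = hit$feature, effect = hit$effect,
                   direction = as.character(ifelse(hit$effect >= 0,
                                                   lev[2], lev[1])))
  })
  dplyr::bind_rows(rows)
}

#' Effect-size plot
#' @param object An `effect_table`.
#' @param cutoffs Cutoffs to mark, default `c(0.5, 1, 1.5)`.
#' @param ... Unused.
#' @return A ggplot of effect against within-group dispersion.
#' @export
autoplot.effect_table <- function(object, cutoffs = c(0.5, 1, 1.5), ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$diff_win, .data$effect)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = c(-cutoffs, cutoffs),
                        linetype = "dotted") +
    ggplot2::labs(x = "within-group dispersion (diff.win)",
                  y = "effect") +
    ggplot2::theme_minimal()
}
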