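# Edge-by-tip incidence: M[e, t] = 1 if tip t descends through edge e.
# Shared machinery for Faith's PD and both UniFrac variants.
edge_tip_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  M <- matrix(0, nn, ntip)
  M[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    M[po$edge[k, 1], ] <- M[po$edge[k, 1], ] + M[po$edge[k, 2], ]
  }
  M <- M[tree$edge[, 2], , drop = FALSE]
  M[M > 1] <- 1
  colnames(M) <- tree$tip.label
  M
}

check_tree_coverage <- function(table, tree) {
  miss <- setdiff(taxon_ids(table), tree$tip.label)
  if (length(miss) > 0) {
    stop("taxa missing from tree: ", paste(miss, collapse = ", "))
  }
}

#' Per-sample alpha diversity
#'
#' Shannon entropy (log base 2 by default, QIIME2 convention), Pielou's
#' evenness (same base; `NA` when fewer than 2 taxa observed), observed
#' features, or Faith's phylogenetic diversity (total branch length of the
#' union of root-to-leaf paths of observed taxa, root path included).
#'
#' @param table A [feature_table()]; a rarefied table is recommended (a
#'   warning is issued when sample depths are unequal).
#' @param metric One of `"shannon"`, `"pielou"`, `"observed_features"`,
#'   `"faith_pd"`.
#' @param tree Rooted [ape::phylo] tree, required for `faith_pd`.
#' @param base Log base for Shannon/Pielou, default 2.
#' @param warn_uneven Warn when sample totals differ.
#' @return Tibble with columns `sample_id`, `metric`, `value`.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "pielou",
                                              "observed_features", "faith_pd"),
                            tree = NULL, base = 2, warn_uneven = TRUE) {
  metric <- match.arg(metric)
  tot <- sample_sums(table)
  if (warn_uneven && length(unique(tot)) > 1) {
    warning("sample depths are unequal; alpha diversity is depth-sensitive ",
            "(consider rarefy())")
  }
  obs <- colSums(table$counts > 0)
  value <- switch(metric,
    observed_features = as.numeric(obs),
    shannon = shannon_entropy(table, base),
    pielou = {
      h <- shannon_entropy(table, base)
      ifelse(obs >= 2, h / log(obs, base = base), NA_real_)
    },
    faith_pd = {
      if (is.null(tree)) stop("faith_pd requires a tree")
      check_tree_coverage(table, tree)
      M <- edge_tip_matrix(tree)[, taxon_ids(table), drop = FALSE]
      pres <- (table$counts > 0) * 1
      on_edge <- M %*% pres > 0
      as.numeric(crossprod(on_edge, tree$edge.length))
    })
  tibble::tibble(sample_id = sample_ids(table), metric = metric,
                 value = unname(value))
}

shannon_entropy <- function(table, base = 2) {
  p <- rel_abundance(table)
  apply(p, 2, function(col) {
    col <- col[col > 0]
    -sum(col * log(col, base = base))
  })
}

#' Pairwise beta diversity matrix
#'
#' Jaccard (1 - |A∩B|/|A∪B| on presence/absence), Bray-Curtis
#' (Σ|x−y| / Σ(x+y) on counts), unweighted UniFrac (unique / total observed
#' branch length) or weighted UniFrac (Σ bᵢ|pᵢᴬ−pᵢᴮ| over branches with
#' subtree relative abundances; unnormalized by default, the QIIME2
#' `weighted_unifrac` convention).
#'
#' @param table A [feature_table()] with at least 2 samples.
#' @param metric One of `"jaccard"`, `"bray_curtis"`,
#'   `"unweighted_unifrac"`, `"weighted_unifrac"`.
#' @param tree Rooted tree covering all taxa; required for UniFrac.
#' @param normalized Normalize weighted UniFrac by Σ bᵢ(pᵢᴬ+pᵢᴮ)?
#'   Default `FALSE`.
#' @return Symmetric distance matrix with sample ids as dimnames.
#' @export
beta_matrix <- function(table, metric = c("jaccard", "bray_curtis",
                                          "unweighted_unifrac",
                                          "weighted_unifrac"),
                        tree = NULL, normalized = FALSE) {
  metric <- match.arg(metric)
  if (n_samples(table) < 2) stop("need at least 2 samples")
  if (any(sample_sums(table) == 0)) {
    stop("sample(s) with zero total: ",
         paste(sample_ids(table)[sample_sums(table) == 0], collapse = ", "))
  }
  if (metric %in% c("unweighted_unifrac", "weighted_unifrac")) {
    if (is.null(tree)) stop(metric, " requires a tree")
    check_tree_coverage(table, tree)
  }
  m <- switch(metric,
    jaccard = as.matrix(vegan::vegdist(t(table$counts), method = "jaccard",
                                       binary = TRUE)),
    bray_curtis = as.matrix(vegan::vegdist(t(table$counts), method = "bray")),
    unweighted_unifrac = unifrac_matrix(table, tree, weighted = FALSE),
    weighted_unifrac = unifrac_matrix(table, tree, weighted = TRUE,
                                      normalized = normalized))
  as_distance_matrix(m, tol = 1e-8)
}

unifrac_matrix <- function(table, tree, weighted, normalized = FALSE) {
  M <- edge_tip_matrix(tree)[, taxon_ids(table), drop = FALSE]
  len <- tree$edge.length
  n <- n_samples(table)
  d <- matrix(0, n, n, dimnames = list(sample_ids(table), sample_ids(table)))
  if (weighted) {
    W <- M %*% rel_abundance(table)  # edge x sample subtree abundance
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      num <- sum(len * abs(W[, i] - W[, j]))
      d[i, j] <- d[j, i] <- if (normalized) {
        den <- sum(len * (W[, i] + W[, j]))
        if (den == 0) 0 else num / den
      } else num
    }
  } else {
    E <- (M %*% (table$counts > 0)) > 0  # edge x sample branch presence
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      either <- E[, i] | E[, j]
      uniq <- xor(E[, i], E[, j])
      den <- sum(len[either])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else sum(len[uniq]) / den
    }
  }
  d
}

#' Kruskal-Wallis group tests on alpha diversity
#'
#' One rank-based Kruskal-Wallis test (with tie correction) per metric,
#' with Benjamini-Hochberg adjustment across the declared family of
#' metrics.
#'
#' @param alpha Tibble as returned by [alpha_diversity()] (rows for several
#'   metrics may be bound together).
#' @param metadata Metadata tibble (`sample_id`, `group`).
#' @param family Metrics forming the BH family; default, all metrics
#'   present in `alpha`.
#' @return Tibble `metric`, `statistic`, `df`, `p_value`, `q_value`, `n`.
#' @export
kruskal_wallis_alpha <- function(alpha, metadata, family = NULL) {
  if (is.null(family)) family <- unique(alpha$metric)
  alpha <- alpha[alpha$metric %in% family, ]
  res <- lapply(split(alpha, alpha$metric), function(a) {
    g <- align_groups(a$sample_id, metadata)
    kw <- stats::kruskal.test(a$value, g)
    tibble::tibble(metric = a$metric[1],
                   statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value, n = length(g))
  })
  out <- dplyr::bind_rows(res)[match(intersect(family, alpha$metric),
                                     names(res)), ]
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::relocate(out, "q_value", .after = "p_value")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance of squared
#' dissimilarities against the two-group label, via [vegan::adonis2()].
#' The permutation p-value carries the +1 correction, so the minimum
#' attainable p is `1 / (n_permutations + 1)`.
#'
#' @param dm Symmetric distance matrix (sample ids as dimnames).
#' @param metadata Metadata tibble.
#' @param n_permutations Number of label permutations, default 999.
#' @param seed Integer seed for the permutation stream.
#' @param metric Optional metric name carried into the output.
#' @return One-row tibble `metric`, `statistic` (pseudo-F), `r2`,
#'   `p_value`, `permutations`.
#' @export
permanova <- function(dm, metadata, n_permutations = 999, seed = 1L,
                      metric = NA_character_) {
  dm <- as_distance_matrix(dm, tol = 1e-8)
  g <- align_groups(rownames(dm), metadata)
  if (any(table(g) < 2)) stop("each group needs at least 2 samples")
  df <- data.frame(group = g)
  fit <- withr::with_seed(as.integer(seed), {
    vegan::adonis2(stats::as.dist(dm) ~ group, data = df,
                   permutations = n_permutations)
  })
  tibble::tibble(metric = metric,
                 statistic = fit$F[1], r2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 permutations = n_permutations)
}

#' PERMANOVA across a family of beta metrics with BH correction
#'
#' @param dms Named list of distance matrices (names are metric labels).
#' @inheritParams permanova
#' @return Tibble with one row per metric plus a BH `q_value` over the
#'   family.
#' @export
permanova_family <- function(dms, metadata, n_permutations = 999, seed = 1L) {
  out <- purrr::imap(dms, function(dm, nm) {
    permanova(dm, metadata, n_permutations = n_permutations,
              seed = seed, metric = nm)
  })
  out <- dplyr::bind_rows(out)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  dplyr::relocate(out, "q_value", .after = "p_value")
}

#' Principal coordinates analysis
#'
#' Classical (Gower-centred) metric scaling of a dissimilarity matrix.
#' Negative eigenvalues are reported but excluded from the
#' proportion-explained denominator; no correction is applied by default
#' (`correction = "cailliez"` applies the Cailliez constant).
#'
#' @param dm Symmetric distance matrix.
#' @param k Number of axes to keep (default: all positive-eigenvalue axes).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return An `ordination_result`: list with `points` (tibble `sample_id`,
#'   `PC1`, ...), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(dm, k = NULL, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  dm <- as_distance_matrix(dm, tol = 1e-8)
  d <- stats::as.dist(dm)
  n <- nrow(dm)
  fit <- suppressWarnings(
    stats::cmdscale(d, k = n - 1, eig = TRUE,
                    add = correction == "cailliez"))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = rownames(dm)),
                              tibble::as_tibble(coords)),
    eigenvalues = eig,
    proportion_explained = eig[seq_len(k)] / sum(eig[pos])),
    class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d axes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$points), ncol(x$points) - 1,
              100 * x$proportion_explained[1],
              if (length(x$proportion_explained) > 1)
                100 * x$proportion_explained[2] else NA))
  invisible(x)
}

#' @export
tidy.ordination_result <- function(x, ...) x$points

#' @export
glance.ordination_result <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$points) - 1,
                 prop_pc1 = x$proportion_explained[1],
                 prop_pc2 = if (length(x$proportion_explained) > 1)
                   x$proportion_explained[2] else NA_real_,
                 n_negative_eig = sum(x$eigenvalues < 0))
}

#' Ordination plot
#'
#' @param object An `ordination_result`.
#' @param metadata Optional metadata tibble for coloring by group.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ordination_result <- function(object, metadata = NULL, ...) {
  pts <- object$points
  pe <- object$proportion_explained
  p <- if (!is.null(metadata)) {
    pts$group <- metadata$group[match(pts$sample_id, metadata$sample_id)]
    ggplot2::ggplot(pts, ggplot2::aes(.data$PC1, .data$PC2,
                                      colour = .data$group))
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * pe[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * pe[2])) +
    ggplot2::theme_minimal()
}
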