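# Small in-code fixtures shared across the suite.

make_table <- function(counts, lineage = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("T%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  }
  feature_table(counts, lineage)
}

make_metadata <- function(table, groups) {
  tibble::tibble(sample_id = sample_ids(table), group = groups)
}

# Two-group table with a given per-group composition, multinomial counts.
sample_two_groups <- function(p1, p2, n1, n2, depth, seed) {
  withr::with_seed(seed, {
    counts <- cbind(
      stats::rmultinom(n1, depth, p1),
      stats::rmultinom(n2, depth, p2))
    colnames(counts) <- sprintf("S%03d", seq_len(n1 + n2))
    tab <- make_table(counts)
    list(table = tab,
         metadata = make_metadata(tab, rep(c("A", "B"), c(n1, n2))))
  })
}

# Brute-force UniFrac oracle: descendant tip sets per edge come from
# phangorn::Descendants (an independent traversal of the tree), and the
# per-branch terms are accumulated in a plain loop.
oracle_unifrac <- function(tree, xa, xb, weighted) {
  pa <- xa / sum(xa)
  pb <- xb / sum(xb)
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    tips <- tree$tip.label[phangorn::Descendants(tree, child, "tips")[[1]]]
    wa <- sum(pa[tips]); wb <- sum(pb[tips])
    len <- tree$edge.length[k]
    if (weighted) {
      num <- num + len * abs(wa - wb)
    } else {
      in_a <- wa > 0; in_b <- wb > 0
      if (xor(in_a, in_b)) num <- num + len
      if (in_a || in_b) den <- den + len
    }
  }
  if (weighted) num else if (den == 0) 0 else num / den
}
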