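test_that("alpha metrics match closed forms", {
  counts <- matrix(c(25, 25, 25, 25,   # uniform over 4 taxa
                     100, 0, 0, 0),    # single taxon
                   nrow = 4,
                   dimnames = list(paste0("t", 1:4), c("u", "single")))
  ft <- feature_table(counts)
  sh <- alpha_diversity(ft, "shannon", warn_uneven = FALSE)
  expect_equal(sh$value, c(2, 0))
  pi <- alpha_diversity(ft, "pielou", warn_uneven = FALSE)
  expect_equal(pi$value[1], 1)
  expect_true(is.na(pi$value[2]))  # evenness undefined for a single taxon
  ob <- alpha_diversity(ft, "observed_features", warn_uneven = FALSE)
  expect_equal(ob$value, c(4, 1))
})

test_that("Faith's PD spans the whole tree when every leaf is observed", {
  tr <- simulate_tree(12, seed = 6)
  counts <- matrix(1, 12, 1, dimnames = list(tr$tip.label, "all"))
  ft <- feature_table(counts)
  pd <- alpha_diversity(ft, "faith_pd", tree = tr, warn_uneven = FALSE)
  expect_equal(pd$value, sum(tr$edge.length))
  # cross-check against an independent implementation
  skip_if_not_installed("picante")
  withr::with_seed(3, {
    counts2 <- matrix(rpois(36, 2), 12, 3,
                      dimnames = list(tr$tip.label, c("a", "b", "c")))
  })
  counts2[1, ] <- pmax(counts2[1, ], 1)  # keep every sample non-empty
  ft2 <- feature_table(counts2)
  mine <- alpha_diversity(ft2, "faith_pd", tree = tr, warn_uneven = FALSE)
  ref <- picante::pd(t(counts2), tr, include.root = TRUE)
  expect_equal(mine$value, ref$PD, tolerance = 1e-9)
  # taxa missing from the tree are an error naming them
  bad <- feature_table(matrix(1, 2, 2,
                              dimnames = list(c("zz1", "zz2"),
                                              c("a", "b"))))
  expect_error(alpha_diversity(bad, "faith_pd", tree = tr,
                               warn_uneven = FALSE),
               "zz1")
})

test_that("beta metrics honor identity, disjointness and symmetry", {
  star <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")
  counts <- matrix(c(10, 10, 0, 0,
                     10, 10, 0, 0,
                     0, 0, 5, 5), nrow = 4,
                   dimnames = list(paste0("t", 1:4), c("a", "a2", "b")))
  ft <- feature_table(counts)
  for (m in c("jaccard", "bray_curtis", "unweighted_unifrac",
              "weighted_unifrac")) {
    d <- beta_matrix(ft, m, tree = star)
    expect_equal(d["a", "a2"], 0, info = m)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
  expect_equal(beta_matrix(ft, "jaccard")["a", "b"], 1)
  expect_equal(beta_matrix(ft, "bray_curtis")["a", "b"], 1)
  expect_equal(beta_matrix(ft, "unweighted_unifrac", tree = star)["a", "b"], 1)
})

test_that("weighted UniFrac on a two-leaf star equals the closed form", {
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  counts <- matrix(c(30, 70, 60, 40), 2,
                   dimnames = list(c("t1", "t2"), c("a", "b")))
  ft <- feature_table(counts)
  d <- beta_matrix(ft, "weighted_unifrac", tree = tr)
  expect_equal(d["a", "b"], abs(.3 - .6) + abs(.7 - .4))
})

test_that("both UniFrac variants agree with the per-branch oracle", {
  skip_if_not_installed("phangorn")
  withr::with_seed(99, {
    for (case in 1:50) {
      n <- sample(3:8, 1)
      tr <- ape::rtree(n, rooted = TRUE, br = stats::rexp)
      tr$tip.label <- paste0("t", seq_len(n))
      counts <- matrix(rpois(2 * n, 3), n, 2,
                       dimnames = list(tr$tip.label, c("a", "b")))
      counts[cbind(sample(n, 2, replace = TRUE), 1:2)] <- 5  # non-empty
      ft <- feature_table(counts)
      uu <- beta_matrix(ft, "unweighted_unifrac", tree = tr)["a", "b"]
      wu <- beta_matrix(ft, "weighted_unifrac", tree = tr)["a", "b"]
      expect_equal(uu, oracle_unifrac(tr, counts[, 1], counts[, 2], FALSE),
                   tolerance = 1e-9)
      expect_equal(wu, oracle_unifrac(tr, counts[, 1], counts[, 2], TRUE),
                   tolerance = 1e-9)
    }
  })
})

test_that("Kruskal-Wallis separates disjoint groups and respects the BH family", {
  withr::with_seed(1, {
    vals <- c(runif(10, 0, 1), runif(10, 2, 3))  # disjoint ranges
  })
  a <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                      metric = "shannon", value = vals)
  md <- tibble::tibble(sample_id = a$sample_id,
                       group = rep(c("CD", "HC"), each = 10))
  res <- kruskal_wallis_alpha(a, md)
  expect_lt(res$p_value, 0.001)
  # permuting the labels leaves the statistic distribution unchanged
  md2 <- md; md2$group <- rev(md2$group)
  expect_equal(kruskal_wallis_alpha(a, md2)$statistic, res$statistic)
  # BH across a declared 2-metric family
  b <- dplyr::mutate(a, metric = "pielou",
                     value = sample(vals))
  fam <- kruskal_wallis_alpha(dplyr::bind_rows(a, b), md)
  expect_equal(nrow(fam), 2)
  expect_equal(fam$q_value,
               stats::p.adjust(fam$p_value, "BH"))
})

test_that("PERMANOVA attains its minimal p on separated clusters and is seeded", {
  withr::with_seed(3, {
    pts <- rbind(matrix(rnorm(20, 0, .1), ncol = 2),
                 matrix(rnorm(20, 5, .1), ncol = 2))
  })
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(sprintf("s%02d", 1:20), sprintf("s%02d", 1:20))
  md <- tibble::tibble(sample_id = rownames(dm),
                       group = rep(c("A", "B"), each = 10))
  res <- permanova(dm, md, n_permutations = 999, seed = 1)
  expect_equal(res$p_value, 0.001)  # 1 / (999 + 1)
  expect_equal(res$p_value,
               permanova(dm, md, n_permutations = 999, seed = 1)$p_value)
  one <- md; one$group <- c("A", rep("B", 19))
  expect_error(permanova(dm, one), "at least 2")
})

test_that("PCoA recovers planar configurations and orders axes", {
  withr::with_seed(8, {
    pts <- matrix(rnorm(24), ncol = 2)
  })
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(sprintf("s%02d", 1:12), sprintf("s%02d", 1:12))
  ord <- pcoa(dm)
  rec <- as.matrix(ord$points[, -1])
  expect_equal(as.matrix(stats::dist(rec[, 1:2])), unname(dm),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(ord$eigenvalues[seq_len(2)]) <= 0))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # three equidistant samples: two equal positive eigenvalues
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(c("a", "b", "c"), c("a", "b", "c"))
  orde <- pcoa(eq)
  expect_equal(orde$eigenvalues[1], orde$eigenvalues[2])
  # Bray-Curtis reconstruction from all positive axes stays within 10%
  withr::with_seed(9, {
    ft <- make_table(matrix(rpois(200, 12), nrow = 20))
  })
  bc <- beta_matrix(ft, "bray_curtis")
  o2 <- pcoa(bc)
  rec2 <- as.matrix(stats::dist(as.matrix(o2$points[, -1])))
  off <- upper.tri(bc)
  expect_lt(max(abs(rec2[off] - bc[off]) / bc[off]), 0.10)
})
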