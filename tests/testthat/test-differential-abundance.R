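# One shared cohort with a strongly planted taxon keeps this file fast.
planted_sim <- simulate_cohort(
  cohort_spec(n_group1 = 30, n_group2 = 30, n_taxa = 20,
              planted_taxa = list(list(taxon = 5, lfc = 3, group = 1)),
              seed = 101))

test_that("ANCOM assigns maximal W to a strongly planted taxon", {
  res <- ancom(planted_sim$table, planted_sim$metadata)
  expect_equal(res$W[res$taxon == "T0005"], 19)
  expect_true(res$detected[res$taxon == "T0005"])
  expect_equal(res$direction[res$taxon == "T0005"], "CD")
  expect_true(all(res$W >= 0 & res$W <= 19))
  expect_error(ancom(ft_subset(planted_sim$table, taxa = 1:2),
                     planted_sim$metadata),
               "at least 3")
})

test_that("ANCOM W is invariant to per-sample count rescaling", {
  # compositional scale invariance on the (near) pseudocount-free path:
  # with no zero counts and a negligible pseudocount, multiplying one
  # sample's counts by a constant leaves every log-ratio unchanged
  dense <- feature_table(planted_sim$table$counts + 1,
                         lineages(planted_sim$table))
  scaled <- dense$counts
  scaled[, 3] <- scaled[, 3] * 10
  ft2 <- feature_table(scaled, lineages(dense))
  w1 <- ancom(dense, planted_sim$metadata, pseudocount = 1e-9)$W
  w2 <- ancom(ft2, planted_sim$metadata, pseudocount = 1e-9)$W
  expect_equal(w1, w2)
})

test_that("ANCOM median W never falls as the planted dose rises", {
  meds <- vapply(c(1, 2, 3), function(lfc) {
    sim <- simulate_cohort(
      cohort_spec(n_group1 = 20, n_group2 = 20, n_taxa = 15,
                  planted_taxa = list(list(taxon = 4, lfc = lfc, group = 1)),
                  seed = 77))
    stats::median(vapply(1:3, function(r) {
      ancom(sim$table, sim$metadata)$W[4]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("CLR-lasso recovers the planted taxon and obeys the cap", {
  res <- clr_lasso(planted_sim$table, planted_sim$metadata, seed = 1)
  expect_true("T0005" %in% res$taxon)
  expect_lte(nrow(res), 20)
  expect_equal(res$direction[res$taxon == "T0005"], "CD")
  one <- clr_lasso(planted_sim$table, planted_sim$metadata, max_taxa = 1,
                   seed = 1)
  expect_lte(nrow(one), 1)
  # degenerate single-group input errors
  md1 <- planted_sim$metadata
  md1$group <- "CD"
  expect_error(clr_lasso(planted_sim$table, md1), "two group")
})

test_that("CLR-lasso CV AUC is near chance on label-permuted data", {
  aucs <- vapply(1:5, function(r) {
    md <- planted_sim$metadata
    md$group <- withr::with_seed(r, sample(md$group))
    attr(clr_lasso(planted_sim$table, md, seed = r), "score")
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("coda-lasso respects the zero-sum log-contrast constraint", {
  res <- coda_lasso(planted_sim$table, planted_sim$metadata, seed = 1)
  expect_lt(abs(sum(res$coefficient)), 1e-8)
  expect_lte(nrow(res), 20)
  expect_true("T0005" %in% res$taxon)
})

test_that("coda-lasso recovers a planted taxon across replicate cohorts", {
  hits <- vapply(1:10, function(r) {
    sim <- simulate_cohort(
      cohort_spec(n_group1 = 30, n_group2 = 30, n_taxa = 20,
                  planted_taxa = list(list(taxon = 5, lfc = 3, group = 1)),
                  seed = 1000 + r))
    "T0005" %in% coda_lasso(sim$table, sim$metadata, seed = r)$taxon
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("selbal finds a perfectly separating two-taxon balance", {
  # ratio t1/t2 cleanly separates the groups
  withr::with_seed(4, {
    n <- 20
    base <- matrix(rpois(5 * 2 * n, 50) + 1, nrow = 5)
    base[1, 1:n] <- base[1, 1:n] * 9
    base[2, (n + 1):(2 * n)] <- base[2, (n + 1):(2 * n)] * 9
  })
  ft <- make_table(base)
  md <- make_metadata(ft, rep(c("CD", "HC"), each = n))
  res <- selbal(ft, md, seed = 1)
  expect_true(all(c("T0001", "T0002") %in% res$taxon[1:2]))
  expect_equal(attr(res, "score"), 1)
})

test_that("selbal balances are invariant to sample-wise count rescaling", {
  lc1 <- log(planted_sim$table$counts + 1)
  b1 <- dysbiome:::balance_values(lc1, c(1, 3), c(2, 5))
  # rescaling a sample (with the pseudocount at matched scale) adds the
  # same constant to the numerator and denominator log means
  scaled <- planted_sim$table$counts
  scaled[, 4] <- scaled[, 4] * 7
  pc <- rep(1, ncol(scaled)); pc[4] <- 7
  b2 <- dysbiome:::balance_values(log(sweep(scaled, 2, pc, "+")), c(1, 3),
                                  c(2, 5))
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("selbal stops early on signal-free data", {
  # greedy selection overfits somewhat on noise, so judge the stop rule
  # and score over replicate null cohorts rather than one draw
  stats <- vapply(1:5, function(r) {
    sim <- simulate_cohort(cohort_spec(n_group1 = 25, n_group2 = 25,
                                       n_taxa = 20, seed = 50 + r))
    res <- selbal(sim$table, sim$metadata, seed = r)
    c(n = nrow(res), score = attr(res, "score"))
  }, numeric(2))
  expect_true(all(stats["n", ] < 20))
  expect_lt(mean(stats["score", ]), 0.8)
  expect_true(all(stats["score", ] < 0.9))
})

test_that("selbal includes the planted taxon", {
  res <- selbal(planted_sim$table, planted_sim$metadata, seed = 3)
  expect_true("T0005" %in% res$taxon)
  expect_equal(res$direction[res$taxon == "T0005"], "CD")
})

test_that("consensus tallies unions, intersections and lineage collapse", {
  mk_sel <- function(method, taxa, dir) {
    dysbiome:::selection_result(method, taxa,
                                coefficient = rep(1, length(taxa)),
                                direction = rep(dir, length(taxa)),
                                groups = c("CD", "HC"))
  }
  s1 <- mk_sel("clr_lasso", c("t1", "t2"), "HC")
  s2 <- mk_sel("coda_lasso", c("t3", "t4"), "HC")
  disjoint <- da_consensus(selections = list(s1, s2))
  expect_equal(nrow(disjoint$table), 4)
  expect_true(all(disjoint$table$n_methods == 1))

  s3 <- mk_sel("selbal", c("t1", "t2"), "HC")
  same <- da_consensus(selections = list(s1, s3))
  expect_equal(nrow(same$table), 2)
  expect_true(all(same$table$n_methods == 2))

  lin <- c(t1 = "k__B;p__F;c__C;o__O;f__L;g__Coprococcus;s__eutactus",
           t2 = "k__B;p__F;c__C;o__O;f__L;g__Coprococcus;s__catus",
           t3 = "k__B;p__F;c__C;o__O;f__L;g__Blautia;s__")
  s4 <- mk_sel("clr_lasso", c("t1", "t2", "t3"), "HC")
  col <- da_consensus(selections = list(s4), lineage = lin,
                      collapse_rank = 6)
  expect_equal(col$summary$n_taxa, 3)
  expect_equal(col$summary$n_taxonomies, 2)  # the two Coprococcus collapse
})
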