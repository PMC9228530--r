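# A labeled distance matrix from clustered planar points: reference
# samples near the origin, with controllable test points.
ref_cloud_dm <- function(n_ref = 30, test_offsets = numeric(0), seed = 1) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(2 * n_ref, 0, 0.1), ncol = 2)
  })
  ids <- sprintf("R%02d", seq_len(n_ref))
  if (length(test_offsets) > 0) {
    pts <- rbind(pts, cbind(test_offsets, 0))
    ids <- c(ids, sprintf("X%02d", seq_along(test_offsets)))
  }
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(ids, ids)
  dm
}

test_that("median-distance test flags outliers, not in-distribution samples", {
  dm <- ref_cloud_dm(30, test_offsets = c(0.01, 5))
  res <- median_distance_test(dm, sprintf("R%02d", 1:30), c("X01", "X02"))
  expect_false(res$dysbiotic[1])
  expect_true(res$dysbiotic[2])
  expect_true(all(res$median_distance >= 0))
  expect_error(median_distance_test(dm, sprintf("R%02d", 1:30),
                                    c("R01", "X01")),
               "overlap")
  expect_error(median_distance_test(dm, c("R01", "R02"), "X01"),
               "at least 3")
})

test_that("~10% of a 30-sample reference exceeds its own 90% cutoff", {
  dm <- ref_cloud_dm(30, test_offsets = 0.01)
  res <- median_distance_test(dm, sprintf("R%02d", 1:30), "X01")
  ref_stat <- attr(res, "reference_statistics")
  # type-7 quantile of 30 distinct values leaves exactly 3 above
  expect_equal(sum(ref_stat > attr(res, "cutoff")), 3)
})

test_that("median-distance flags survive reordering and reference duplication", {
  dm <- ref_cloud_dm(20, test_offsets = c(0.3, 2))
  refs <- sprintf("R%02d", 1:20)
  res <- median_distance_test(dm, refs, c("X01", "X02"))
  perm <- withr::with_seed(3, sample(nrow(dm)))
  res2 <- median_distance_test(dm[perm, perm], refs, c("X01", "X02"))
  expect_equal(res$dysbiotic, res2$dysbiotic)
  # duplicating a reference sample moves the cutoff only by interpolation
  dm3 <- rbind(cbind(dm, dup = dm[, "R01"]), dup = c(dm["R01", ], 0))
  rownames(dm3)[nrow(dm3)] <- colnames(dm3)[ncol(dm3)] <- "Rdup"
  res3 <- median_distance_test(dm3, c(refs, "Rdup"), c("X01", "X02"))
  expect_equal(attr(res3, "cutoff"), attr(res, "cutoff"), tolerance = 0.05)
  expect_equal(res$dysbiotic, res3$dysbiotic)
})

test_that("DOC returns O = 1, D = 0 for identical samples and errors on none shared", {
  counts <- matrix(rep(c(5, 3, 2, 0), 4), 4,
                   dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  ft <- feature_table(counts)
  d <- suppressWarnings(doc_analysis(ft, n_boot = 0, seed = 1))
  expect_true(all(d$pairs$overlap == 1))
  expect_true(all(d$pairs$dissimilarity == 0))
  disjoint <- feature_table(matrix(c(5, 2, 0, 0, 0, 0,
                                     0, 0, 3, 1, 0, 0,
                                     0, 0, 0, 0, 2, 2), 6,
                                   dimnames = list(paste0("t", 1:6),
                                                   c("a", "b", "c"))))
  expect_error(suppressWarnings(doc_analysis(disjoint, n_boot = 0)),
               "shares")
})

test_that("DOC dissimilarity respects the rJSD range and symmetry", {
  u <- simulate_universal_dynamics(n_samples = 15, n_taxa = 60, seed = 4)
  d <- doc_analysis(u, n_boot = 0, seed = 1)
  expect_true(all(d$pairs$dissimilarity >= 0))
  expect_true(all(d$pairs$dissimilarity <= sqrt(log(2)) + 1e-12))
  expect_true(all(d$pairs$overlap >= 0 & d$pairs$overlap <= 1 + 1e-12))
  # symmetric in the pair
  p <- rel_abundance(u)
  expect_equal(dysbiome:::doc_pair(p[, 1], p[, 2]),
               dysbiome:::doc_pair(p[, 2], p[, 1]))
})

test_that("CLOUD r matches the worked ratio on a constructed matrix", {
  # 5 reference samples pairwise 0.2 apart; the test sample 0.6 from each:
  # with k = 3 the test diameter is 0.6 and every LOO diameter 0.2
  ids <- c(paste0("R", 1:5), "X")
  dm <- matrix(0.2, 6, 6, dimnames = list(ids, ids))
  dm["X", ] <- dm[, "X"] <- 0.6
  diag(dm) <- 0
  res <- cloud_test(dm, paste0("R", 1:5), "X", ref_fraction = 1, k = 3)
  expect_equal(res$r, 3.0)
  expect_lte(res$p_value, 1 / 6 + 1e-12)
  # identical distances everywhere: r is exactly 1
  flat <- matrix(0.4, 6, 6, dimnames = list(ids, ids)); diag(flat) <- 0
  expect_equal(cloud_test(flat, paste0("R", 1:5), "X", ref_fraction = 1,
                          k = 3)$r, 1)
})

test_that("CLOUD scores in-distribution samples near r = 1 with large p", {
  # 30 reference plus 5 test samples all drawn from the same cloud, and
  # one genuine outlier far outside it
  withr::with_seed(7, {
    pts <- matrix(rnorm(70, 0, 0.1), ncol = 2)
  })
  pts <- rbind(pts, c(3, 0))
  ids <- c(sprintf("R%02d", 1:30), sprintf("X%02d", 1:6))
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(ids, ids)
  res <- cloud_test(dm, sprintf("R%02d", 1:30), sprintf("X%02d", 1:6),
                    ref_fraction = 0.30, n_draws = 50, seed = 2)
  expect_gt(stats::median(res$r[1:5]), 0.8)
  expect_lt(stats::median(res$r[1:5]), 1.25)
  expect_gt(stats::median(res$p_value[1:5]), 0.05)
  expect_gt(res$r[6], 2)
  expect_lte(res$p_value[6], 1 / 31 + 1e-12)
  # leave-one-out reference scores average to ~1
  expect_lt(abs(mean(attr(res, "reference_scores")) - 1), 0.15)
  expect_error(cloud_test(dm, sprintf("R%02d", 1:30), "X01",
                          ref_fraction = 0.05, k = 3),
               "too small")
})

test_that("the combined report flags a planted outlier by both distance tests", {
  sim <- simulate_cohort(cohort_spec(n_group1 = 6, n_group2 = 30,
                                     n_taxa = 60, seed = 13))
  pert <- plant_dysbiotic_samples(sim$table, "CD002", strength = 6, seed = 2)
  rep <- dysbiosis_report(pert, sim$metadata, reference_group = "HC",
                          n_draws = 30, n_boot = 0, seed = 1)
  flag <- rep$flags[rep$flags$sample_id == "CD002", ]
  expect_true(flag$median_dysbiotic)
  expect_true(flag$cloud_dysbiotic)
  # empty test set still yields a reference-only report
  hc_only <- ft_subset(sim$table,
                       samples = sim$metadata$sample_id[
                         sim$metadata$group == "HC"])
  rep0 <- dysbiosis_report(hc_only, sim$metadata, reference_group = "HC",
                           n_draws = 10, n_boot = 0, seed = 1)
  expect_equal(nrow(rep0$flags), 0)
  expect_false(is.null(rep0$doc_reference))
})
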