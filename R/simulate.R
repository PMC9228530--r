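#' Specify a synthetic two-group cohort
#'
#' Defaults emulate the study design the package targets: 46 test (CD) and
#' 30 reference (HC) stool microbiomes, sparse overdispersed
#' Dirichlet-multinomial compositions, and per-sample read totals drawn
#' from a log-normal law with median 16,841 and IQR 13,210--23,273, so that
#' a realistic fraction of samples falls below a 10,000-read rarefaction
#' depth.
#'
#' @param n_group1,n_group2 Sample counts for the two groups (group 1 is the
#'   test group, group 2 the reference group).
#' @param n_taxa Number of taxa.
#' @param base_concentration Dirichlet concentration vector (length
#'   `n_taxa`, all positive). The default draws a skewed vector (few
#'   dominant taxa, a long sparse tail) from a gamma law and is itself
#'   seeded, so a fixed `seed` fixes the whole cohort; under the default,
#'   planted taxa are reset to the median background concentration before
#'   the fold-change is applied, so a planted effect always acts on a
#'   taxon that is present.
#' @param depth_meanlog,depth_sdlog Parameters of the log-normal read-total
#'   law. Defaults reproduce median 16,841 and IQR 13,210--23,273.
#' @param planted_taxa List of `list(taxon = index, lfc = log2 fold-change,
#'   group = 1 or 2)` entries; the taxon's concentration is multiplied by
#'   `2^lfc` in the enriched group.
#' @param n_outliers Number of dysbiotic samples to plant (drawn from the
#'   test group), via [plant_dysbiotic_samples()].
#' @param outlier_strength Concentration-perturbation exponent for planted
#'   outliers (>1 means strongly perturbed).
#' @param group_labels Labels for the two groups.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_group1 = 46, n_group2 = 30, n_taxa = 100,
                        base_concentration = NULL,
                        depth_meanlog = log(16841),
                        depth_sdlog = log(23273 / 13210) / (2 * stats::qnorm(0.75)),
                        planted_taxa = list(),
                        n_outliers = 0, outlier_strength = 3,
                        group_labels = c("CD", "HC"),
                        seed = 1L) {
  stopifnot(n_taxa >= 2, n_group1 >= 1, n_group2 >= 1, outlier_strength > 0)
  if (!is.null(base_concentration)) {
    stopifnot(length(base_concentration) == n_taxa, all(base_concentration > 0))
  }
  for (p in planted_taxa) {
    stopifnot(is.finite(p$lfc), p$taxon >= 1, p$taxon <= n_taxa, p$group %in% 1:2)
  }
  structure(list(n_group1 = n_group1, n_group2 = n_group2, n_taxa = n_taxa,
                 base_concentration = base_concentration,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 planted_taxa = planted_taxa,
                 n_outliers = n_outliers, outlier_strength = outlier_strength,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "cohort_spec")
}

taxon_names <- function(n) sprintf("T%04d", seq_len(n))

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate guard for tiny alphas
  g / sum(g)
}

# Default skewed concentration: few abundant taxa over a sparse tail, total
# concentration ~ n_taxa * 0.35 so zeros are common at 10^4 reads.
default_concentration <- function(n_taxa) {
  a <- stats::rgamma(n_taxa, shape = 0.35, rate = 1)
  pmax(a, 1e-3)
}

#' Simulate a two-group Dirichlet-multinomial cohort
#'
#' Per sample: a read total is drawn from the spec's log-normal depth law, a
#' composition from a Dirichlet whose concentration is the base vector
#' modified by the planted fold-changes of the sample's group, and counts
#' from a multinomial at that depth. Optionally, `n_outliers` test-group
#' samples are redrawn as dysbiotic outliers.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `table` (a [feature_table()]), `metadata` (tibble
#'   `sample_id`, `group`) and `truth` (planted taxa, outlier ids, drawn
#'   depths, concentration used).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n_taxa <- spec$n_taxa
    conc <- spec$base_concentration
    if (is.null(conc)) {
      conc <- default_concentration(n_taxa)
      # planted taxa start from the median background concentration so the
      # planted fold-change acts on a taxon that is actually present
      for (p in spec$planted_taxa) conc[p$taxon] <- stats::median(conc)
    }
    conc_g <- list(conc, conc)
    for (p in spec$planted_taxa) {
      conc_g[[p$group]][p$taxon] <- conc_g[[p$group]][p$taxon] * 2^p$lfc
    }
    n <- spec$n_group1 + spec$n_group2
    grp <- rep(1:2, c(spec$n_group1, spec$n_group2))
    ids <- c(sprintf("%s%03d", spec$group_labels[1], seq_len(spec$n_group1)),
             sprintf("%s%03d", spec$group_labels[2], seq_len(spec$n_group2)))
    depths <- round(stats::rlnorm(n, spec$depth_meanlog, spec$depth_sdlog))
    counts <- matrix(0, n_taxa, n, dimnames = list(taxon_names(n_taxa), ids))
    for (i in seq_len(n)) {
      p <- rdirichlet1(conc_g[[grp[i]]])
      counts[, i] <- stats::rmultinom(1, depths[i], p)
    }
    tab <- feature_table(counts)
    metadata <- tibble::tibble(sample_id = ids,
                               group = spec$group_labels[grp])
    outlier_ids <- character(0)
    if (spec$n_outliers > 0) {
      outlier_ids <- sample(ids[grp == 1], spec$n_outliers)
      tab <- plant_dysbiotic_samples(tab, outlier_ids,
                                     strength = spec$outlier_strength,
                                     seed = spec$seed + 1L)
    }
    list(table = tab, metadata = metadata,
         truth = list(planted_taxa = spec$planted_taxa,
                      planted_ids = taxon_names(n_taxa)[
                        vapply(spec$planted_taxa, function(p) as.integer(p$taxon), integer(1))],
                      outlier_ids = outlier_ids,
                      depths = stats::setNames(depths, ids),
                      concentration = conc))
  })
}

#' Simulate a random rooted bifurcating tree over the cohort's taxa
#'
#' Exponential branch lengths (rate 1); leaves are named to match
#' [simulate_cohort()] taxa.
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] rooted bifurcating tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2) stop("n_taxa must be at least 2")
  withr::with_seed(as.integer(seed), {
    tr <- ape::rtree(n_taxa, rooted = TRUE, br = stats::rexp)
    tr$tip.label <- taxon_names(n_taxa)
    tr
  })
}

#' Replace samples by dysbiotic outliers
#'
#' Listed samples are redrawn from a perturbed composition: the sample's
#' own (pseudocounted) relative abundances are permuted across taxa and
#' sharpened by raising to the power `strength`, then counts are redrawn
#' multinomially at the sample's original depth. `strength = 1` with
#' `permute = FALSE` is an exact identity.
#'
#' @param table A [feature_table()].
#' @param ids Sample ids to perturb (may be empty).
#' @param strength Perturbation exponent; larger is more dysbiotic.
#' @param seed Integer seed.
#' @param permute Permute taxon weights before sharpening (default TRUE).
#' @return A `feature_table` with the listed samples replaced.
#' @export
plant_dysbiotic_samples <- function(table, ids, strength = 3, seed = 1L,
                                    permute = TRUE) {
  stopifnot(inherits(table, "feature_table"), strength > 0)
  if (length(ids) == 0) return(table)
  miss <- setdiff(ids, sample_ids(table))
  if (length(miss) > 0) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  if (!permute && strength == 1) return(table)
  counts <- table$counts
  withr::with_seed(as.integer(seed), {
    for (id in ids) {
      x <- counts[, id]
      depth <- sum(x)
      w <- (x + 0.5) / sum(x + 0.5)
      if (permute) w <- w[sample.int(length(w))]
      w <- w^strength
      w <- w / sum(w)
      counts[, id] <- stats::rmultinom(1, depth, w)
    }
  })
  feature_table(counts, lineages(table))
}

#' Simulate samples obeying (or violating) universal microbial dynamics
#'
#' Under universality (`universal = TRUE`) all samples share one
#' steady-state abundance profile; each sample carries a uniformly random
#' subset of taxa whose size is drawn from `presence_gradient` (as
#' fractions of `n_taxa`), with multiplicative log-normal noise around the
#' shared profile whose scale grows as the subset shrinks
#' (`noise_sd * 2 * (n_taxa/k - 1)`, zero for a complete community):
#' samples hosting nearly the full community sit at the shared attractor,
#' samples missing many taxa deviate from it. That is the signature a
#' dissimilarity-overlap curve detects as a negative slope at high
#' overlap. With `universal = FALSE` every sample gets its own
#' independent steady state with constant noise `noise_sd`, and the curve
#' flattens. Counts are deterministic largest-remainder quantizations of
#' the composition at `depth` reads, so `noise_sd = 0` with identical
#' subsets gives exactly zero pairwise dissimilarity.
#'
#' @param n_samples,n_taxa Dimensions.
#' @param presence_gradient Range of the per-sample fraction of taxa
#'   present, e.g. `c(0.4, 1)`.
#' @param noise_sd Baseline log-normal noise sd (natural-log scale).
#' @param depth Read total per sample.
#' @param universal Share one steady state across samples?
#' @param seed Integer seed.
#' @return A [feature_table()].
#' @export
simulate_universal_dynamics <- function(n_samples = 50, n_taxa = 200,
                                        presence_gradient = c(0.4, 1),
                                        noise_sd = 0.3, depth = 10000,
                                        universal = TRUE, seed = 1L) {
  stopifnot(n_taxa >= 2, n_samples >= 2,
            presence_gradient[1] > 0, presence_gradient[2] <= 1)
  withr::with_seed(as.integer(seed), {
    steady <- stats::rlnorm(n_taxa, 0, 0.8)
    counts <- matrix(0, n_taxa, n_samples,
                     dimnames = list(taxon_names(n_taxa),
                                     sprintf("S%03d", seq_len(n_samples))))
    for (i in seq_len(n_samples)) {
      frac <- stats::runif(1, presence_gradient[1], presence_gradient[2])
      k <- max(2L, round(frac * n_taxa))
      present <- if (k < n_taxa) sort(sample.int(n_taxa, k)) else seq_len(n_taxa)
      a <- if (universal) steady else stats::rlnorm(n_taxa, 0, 0.8)
      sd_i <- if (universal) noise_sd * 2 * (n_taxa / k - 1) else noise_sd
      x <- a[present] * exp(stats::rnorm(k, 0, sd_i))
      p <- numeric(n_taxa)
      p[present] <- x / sum(x)
      counts[, i] <- quantize_counts(p, depth)
    }
    feature_table(counts)
  })
}

# Largest-remainder quantization of a composition to integer counts
# summing exactly to `depth`; deterministic (stable order() tie-break).
quantize_counts <- function(p, depth) {
  x <- floor(p * depth)
  r <- depth - sum(x)
  if (r > 0) {
    idx <- order(p * depth - x, decreasing = TRUE)[seq_len(r)]
    x[idx] <- x[idx] + 1
  }
  x
}

#' Simulate a pathway count table with planted CLR-scale effects
#'
#' Pathway base abundances are log-normal; per-sample log abundances add
#' within-group normal noise of sd `sigma_within`; `planted_effects` shift
#' the named pathway's log abundance in group 2 by `shift` within-group
#' standard deviations (a CLR-scale shift, since one pathway among many
#' leaves the sample log-mean nearly unchanged). Counts are multinomial at
#' `depth` reads.
#'
#' @param n_pathways,n_per_group Dimensions (two equal-size groups).
#' @param planted_effects List of `list(pathway = index, shift = numeric)`.
#' @param sigma_within Within-group sd on the natural-log scale.
#' @param depth Multinomial total per sample.
#' @param group_labels Labels for the two groups.
#' @param seed Integer seed.
#' @return List with `table` (pathway x sample count matrix, MetaCyc-style
#'   row names), `metadata` tibble and `truth`.
#' @export
simulate_pathway_table <- function(n_pathways = 200, n_per_group = 20,
                                   planted_effects = list(),
                                   sigma_within = 1, depth = 50000,
                                   group_labels = c("CD", "HC"),
                                   seed = 1L) {
  stopifnot(n_pathways >= 2, n_per_group >= 2)
  withr::with_seed(as.integer(seed), {
    mu <- stats::rnorm(n_pathways, 0, 1.5)
    n <- 2 * n_per_group
    grp <- rep(1:2, each = n_per_group)
    ids <- paste0(rep(group_labels, each = n_per_group),
                  sprintf("%03d", c(seq_len(n_per_group), seq_len(n_per_group))))
    shift <- numeric(n_pathways)
    for (p in planted_effects) shift[p$pathway] <- p$shift * sigma_within
    counts <- matrix(0, n_pathways, n,
                     dimnames = list(sprintf("PWY-%04d", seq_len(n_pathways)), ids))
    for (i in seq_len(n)) {
      lx <- mu + stats::rnorm(n_pathways, 0, sigma_within)
      if (grp[i] == 2) lx <- lx + shift
      p <- exp(lx - max(lx))
      counts[, i] <- stats::rmultinom(1, depth, p / sum(p))
    }
    list(table = counts,
         metadata = tibble::tibble(sample_id = ids, group = group_labels[grp]),
         truth = list(planted = planted_effects,
                      planted_ids = rownames(counts)[
                        vapply(planted_effects, function(p) as.integer(p$pathway), integer(1))]))
  })
}
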