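#' Configure a pipeline run
#'
#' Exactly one of `input` (paths to on-disk artifacts) or `cohort`
#' (a [cohort_spec()] for a synthetic run) must be given. Defaults follow
#' the study design the package targets: rarefaction depth 10,000 reads,
#' 999 PERMANOVA permutations, a 20-taxon cap per selector, a 0.90
#' median-distance quantile and CLOUD reference fractions 5/15/30%.
#'
#' @param input `NULL`, or a list with elements `table`, `metadata` and
#'   optionally `tree`, `pathway_table` (file paths).
#' @param cohort `NULL`, or a [cohort_spec()].
#' @param out_dir Output directory for artifacts (created if missing);
#'   `NULL` disables artifact writing.
#' @param depth Rarefaction depth, default 10000.
#' @param n_permutations PERMANOVA permutations, default 999.
#' @param max_taxa Selector cap, default 20.
#' @param beta_metrics Beta metrics to run; UniFrac variants require a
#'   tree (validated here, before execution).
#' @param reference_group Reference group label for dysbiosis (default:
#'   second group level encountered).
#' @param quantile,ref_fractions,n_draws,n_boot Dysbiosis parameters
#'   (see [dysbiosis_report()]).
#' @param seed Global seed; per-stage seeds are derived by fixed offsets.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, cohort = NULL, out_dir = NULL,
                       depth = 10000, n_permutations = 999, max_taxa = 20,
                       beta_metrics = NULL, reference_group = NULL,
                       quantile = 0.90, ref_fractions = c(0.05, 0.15, 0.30),
                       n_draws = 100, n_boot = 100, seed = 1L) {
  if (is.null(input) == is.null(cohort)) {
    stop("exactly one of `input` or `cohort` must be given")
  }
  has_tree <- (!is.null(input) && !is.null(input$tree)) || !is.null(cohort)
  if (is.null(beta_metrics)) {
    beta_metrics <- if (has_tree) {
      c("jaccard", "bray_curtis", "unweighted_unifrac", "weighted_unifrac")
    } else c("jaccard", "bray_curtis")
  }
  if (any(grepl("unifrac", beta_metrics)) && !has_tree) {
    stop("UniFrac metrics requested but no tree available")
  }
  structure(list(input = input, cohort = cohort, out_dir = out_dir,
                 depth = depth, n_permutations = n_permutations,
                 max_taxa = max_taxa, beta_metrics = beta_metrics,
                 reference_group = reference_group, quantile = quantile,
                 ref_fractions = ref_fractions, n_draws = n_draws,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Stage order: load/simulate inputs, contaminant filter, ultra-rare
#' filter, rarefaction, alpha diversity + Kruskal-Wallis (BH over the
#' 4-metric family), beta diversity + PERMANOVA (BH over the metric
#' family) + PCoA, ANCOM + CLR-lasso + coda-lasso + selbal + consensus,
#' ALDEx2-style pathway effects (when a pathway table is present), and
#' the three dysbiosis tests. A failed stage is recorded and its
#' dependent stages are skipped. The same config and seed produce an
#' identical report.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list (also written as `report.json`, with
#'   TSV artifacts, when `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  report <- list(
    schema = "dysbiome-report/1",
    package_version = as.character(utils::packageVersion("dysbiome")),
    seed = seed,
    stage_seeds = list(rarefy = seed + 101L, tests = seed + 202L,
                       selectors = seed + 303L, effects = seed + 404L,
                       dysbiosis = seed + 505L),
    parameters = config[c("depth", "n_permutations", "max_taxa",
                          "beta_metrics", "quantile", "ref_fractions",
                          "n_draws", "n_boot")],
    stages = list())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  failed <- FALSE
  stage <- function(name, deps_ok, fn) {
    if (!deps_ok) {
      report$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      failed <<- TRUE
      NULL
    })
    if (!is.null(res) || is.null(report$stages[[name]])) {
      report$stages[[name]] <<- list(status = "ok")
      message(sprintf("[dysbiome] stage %-12s ok (%.1fs)", name,
                      proc.time()[["elapsed"]] - t0))
    }
    res
  }

  inputs <- stage("inputs", TRUE, function() {
    if (!is.null(config$cohort)) {
      sim <- simulate_cohort(config$cohort)
      tree <- simulate_tree(config$cohort$n_taxa, seed = config$cohort$seed)
      list(table = sim$table, metadata = sim$metadata, tree = tree,
           pathway = NULL, truth = sim$truth)
    } else {
      inp <- config$input
      list(table = read_feature_table(inp$table),
           metadata = read_metadata(inp$metadata),
           tree = if (!is.null(inp$tree)) read_tree(inp$tree) else NULL,
           pathway = if (!is.null(inp$pathway_table))
             get_counts(read_feature_table(inp$pathway_table)) else NULL,
           truth = NULL)
    }
  })

  filtered <- stage("filter", !is.null(inputs), function() {
    fc <- remove_contaminants(inputs$table)
    fr <- remove_ultra_rare(fc$table)
    list(table = fr$table,
         report = list(contaminants = fc$report$contaminants,
                       ultra_rare = fr$report$ultra_rare))
  })
  if (!is.null(filtered)) report$filter <- filtered$report

  rarefied <- stage("rarefy", !is.null(filtered), function() {
    rarefy(filtered$table, depth = config$depth,
           seed = report$stage_seeds$rarefy)
  })
  if (!is.null(rarefied)) {
    report$rarefaction <- list(depth = config$depth,
                               excluded = rarefied$report$excluded_samples)
  }

  md <- if (!is.null(inputs)) inputs$metadata else NULL
  tree <- if (!is.null(inputs)) inputs$tree else NULL

  alpha_res <- stage("alpha", !is.null(rarefied), function() {
    metrics <- c("shannon", "pielou", "observed_features")
    if (!is.null(tree)) metrics <- c(metrics, "faith_pd")
    a <- dplyr::bind_rows(lapply(metrics, function(mtr) {
      alpha_diversity(rarefied$table, metric = mtr, tree = tree,
                      warn_uneven = FALSE)
    }))
    list(values = a, tests = kruskal_wallis_alpha(a, md, family = metrics))
  })
  if (!is.null(alpha_res)) report$alpha_tests <- alpha_res$tests

  beta_res <- stage("beta", !is.null(rarefied), function() {
    dms <- lapply(stats::setNames(config$beta_metrics, config$beta_metrics),
                  function(mtr) beta_matrix(rarefied$table, mtr, tree = tree))
    tests <- permanova_family(dms, md,
                              n_permutations = config$n_permutations,
                              seed = report$stage_seeds$tests)
    ords <- lapply(dms, pcoa)
    list(dms = dms, tests = tests, ordinations = ords)
  })
  if (!is.null(beta_res)) {
    report$beta_tests <- beta_res$tests
    report$pcoa <- lapply(beta_res$ordinations, function(o) {
      list(proportion_explained = o$proportion_explained[
        seq_len(min(3, length(o$proportion_explained)))])
    })
  }

  da_res <- stage("diffabund", !is.null(filtered), function() {
    s3 <- report$stage_seeds$selectors
    an <- ancom(filtered$table, md)
    cl <- clr_lasso(filtered$table, md, max_taxa = config$max_taxa, seed = s3)
    co <- coda_lasso(filtered$table, md, max_taxa = config$max_taxa, seed = s3)
    sb <- selbal(filtered$table, md, max_taxa = config$max_taxa, seed = s3)
    cons <- da_consensus(ancom = an, selections = list(cl, co, sb),
                         lineage = lineages(filtered$table))
    list(ancom = an, clr_lasso = cl, coda_lasso = co, selbal = sb,
         consensus = cons)
  })
  if (!is.null(da_res)) {
    report$differential_abundance <- list(
      ancom_detected = da_res$ancom$taxon[da_res$ancom$detected],
      ancom_max_w = max(da_res$ancom$W),
      clr_lasso = da_res$clr_lasso$taxon,
      coda_lasso = da_res$coda_lasso$taxon,
      selbal = da_res$selbal$taxon,
      consensus = da_res$consensus$summary)
  }

  eff_res <- stage("effects",
                   !is.null(inputs) && !is.null(inputs$pathway), function() {
    eff <- aldex_effect(inputs$pathway, md, seed = report$stage_seeds$effects)
    list(effects = eff, thresholds = threshold_report(eff))
  })
  if (!is.null(eff_res)) {
    report$effects <- list(
      n_features = nrow(eff_res$effects),
      passing = eff_res$thresholds |>
        dplyr::group_by(.data$cutoff) |>
        dplyr::summarise(n = dplyr::n(), .groups = "drop"))
  }
  if (!is.null(inputs) && is.null(inputs$pathway)) {
    report$stages$effects <- list(status = "skipped")
  }

  dys_res <- stage("dysbiosis", !is.null(rarefied), function() {
    refg <- config$reference_group
    if (is.null(refg)) refg <- sort(unique(md$group))[2]
    dysbiosis_report(rarefied$table, md, reference_group = refg,
                     quantile = config$quantile,
                     ref_fractions = config$ref_fractions,
                     n_draws = config$n_draws, n_boot = config$n_boot,
                     seed = report$stage_seeds$dysbiosis)
  })
  if (!is.null(dys_res)) {
    report$dysbiosis <- list(
      flags = dys_res$flags,
      median_cutoff = attr(dys_res$median_distance, "cutoff"),
      doc_reference_spearman = dys_res$doc_reference$spearman,
      doc_test_spearman = if (!is.null(dys_res$doc_test))
        dys_res$doc_test$spearman else NULL)
  }

  report$status <- if (failed) "failed" else "ok"
  if (!is.null(out_dir)) {
    if (!is.null(rarefied)) {
      write_feature_table(rarefied$table,
                          file.path(out_dir, "rarefied_table.tsv"))
    }
    if (!is.null(inputs)) {
      write_metadata(inputs$metadata, file.path(out_dir, "metadata.tsv"))
      if (!is.null(inputs$tree)) {
        ape::write.tree(inputs$tree, file.path(out_dir, "tree.nwk"))
      }
    }
    if (!is.null(beta_res)) {
      for (mtr in names(beta_res$dms)) {
        write_distance_matrix(beta_res$dms[[mtr]],
                              file.path(out_dir, paste0(mtr, ".tsv")))
      }
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> status:", x$status, "\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %s\n", nm, x$stages[[nm]]$status))
  }
  invisible(x)
}
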