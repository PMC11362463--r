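#' Build a validated run configuration
#'
#' Collects the knobs shared by the four workflows. Thresholds are validated
#' against their documented ranges and a seed is mandatory for any workflow
#' with a stochastic step. A YAML file may supply or override fields via
#' [read_run_config()].
#'
#' @param workflow One of "simulate", "discovery", "enrichment", "biomarker".
#' @param out_dir Output directory for all written artifacts.
#' @param seed Integer seed.
#' @param inputs Named list of input paths (workflow-specific; see
#'   [run_workflow()]).
#' @param stage_levels Ordered stage ladder for discovery.
#' @param alpha,fc_threshold,span_min,tolerance,weight,n_perm,margin
#'   Analysis thresholds with the package defaults.
#' @param simulate Named list of generator overrides for the simulate
#'   workflow (passed to the generators).
#' @return A `run_config` list.
#' @export
run_config <- function(workflow = c("simulate", "discovery", "enrichment",
                                    "biomarker"),
                       out_dir, seed, inputs = list(),
                       stage_levels = hcc_stage_ladder(),
                       alpha = 0.05, fc_threshold = 1.5,
                       span_min = log2(1.5), tolerance = 0.1,
                       weight = 1, n_perm = 1000, margin = 0,
                       simulate = list()) {
  workflow <- match.arg(workflow)
  seed <- check_seed(seed)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  check_number(fc_threshold, "fc_threshold", lower = 0, allow_lower = FALSE)
  check_number(span_min, "span_min", lower = 0)
  check_number(tolerance, "tolerance", lower = 0)
  check_number(weight, "weight", lower = 0)
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  check_number(margin, "margin", lower = 0, upper = 1)
  if (workflow == "discovery" && length(stage_levels) < 3) {
    abort_hcc("The discovery stage ladder needs >= 3 unique labels.",
              "hccdriver_error_bad_argument")
  }
  structure(
    list(workflow = workflow, out_dir = out_dir, seed = seed,
         inputs = inputs, stage_levels = as.character(stage_levels),
         alpha = alpha, fc_threshold = fc_threshold, span_min = span_min,
         tolerance = tolerance, weight = weight, n_perm = n_perm,
         margin = margin, simulate = simulate),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @param ... Overrides applied on top of the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(run_config, raw)
}

#' Execute a named workflow end to end
#'
#' Runs one of the four pipelines and writes every intermediate table, plus a
#' provenance file echoing the configuration, the package version and the
#' seed, into `config$out_dir`. Identical configuration and seed produce
#' byte-identical output trees.
#'
#' Workflows and their `inputs` entries:
#' \describe{
#'   \item{simulate}{no inputs; writes generated fixture families
#'     (staged cohorts, single-cell counts, methylation, survival, Ct).}
#'   \item{discovery}{`tier_a`, `tier_b`: lists with `matrix`/`metadata`
#'     paths per cohort. Runs [run_cascade()].}
#'   \item{enrichment}{`sc_dir` (from [write_sc_counts()]), `gmt`,
#'     `focal_gene`. Aggregate, stratify, DE, rank, preranked GSEA, ssGSEA
#'     and group comparison.}
#'   \item{biomarker}{`methylation` (TSV), optional `expression` (TSV:
#'     patient, expression), optional `survival` (TSV). Differential
#'     methylation, hypomethylation call, ROC, correlation, KM/log-rank/Cox.}
#' }
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of computed results and written paths.
#' @export
run_workflow <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(config$workflow,
    simulate = workflow_simulate(config),
    discovery = workflow_discovery(config),
    enrichment = workflow_enrichment(config),
    biomarker = workflow_biomarker(config)
  )
  write_provenance(config)
  invisible(res)
}

write_provenance <- function(config) {
  prov <- list(
    package = "hccdriver",
    version = as.character(packageVersion("hccdriver")),
    workflow = config$workflow,
    seed = config$seed,
    thresholds = config[c("alpha", "fc_threshold", "span_min", "tolerance",
                          "weight", "n_perm", "margin")],
    stage_levels = config$stage_levels,
    inputs = config$inputs
  )
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

write_table <- function(tb, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_tsv(tb, path, progress = FALSE)
  path
}

workflow_simulate <- function(config) {
  out <- config$out_dir
  seeds <- child_seeds(config$seed, 5L)
  sim_args <- config$simulate

  gen <- do.call(generate_multistage_cohorts,
                 c(list(seed = seeds[1]), sim_args$cohorts %||% list()))
  for (co in gen$cohorts) {
    write_expression_matrix(
      co,
      file.path(out, sprintf("%s_expression.tsv", co$cohort_id)),
      file.path(out, sprintf("%s_metadata.tsv", co$cohort_id))
    )
  }
  write_table(tibble::tibble(gene = gen$truth$driver_genes), out,
              "truth_drivers.tsv")

  sc <- do.call(generate_sc_counts,
                c(list(seed = seeds[2]), sim_args$sc %||% list()))
  write_sc_counts(sc$counts, sc$cells, file.path(out, "sc"))

  meth <- do.call(generate_methylation_expression,
                  c(list(seed = seeds[3]), sim_args$methylation %||% list()))
  write_table(meth$methylation, out, "methylation.tsv")
  write_table(meth$expression, out, "expression_paired.tsv")

  surv <- do.call(generate_survival,
                  c(list(seed = seeds[4]), sim_args$survival %||% list()))
  write_table(surv, out, "survival.tsv")

  ct <- do.call(generate_ct_table,
                c(list(seed = seeds[5]),
                  sim_args$ct %||% list(
                    true_fold_changes = c(ref = 1, s1 = 2, s2 = 4, s3 = 0.5),
                    reference_sample = "ref"
                  )))
  write_table(ct, out, "ct.tsv")

  invisible(list(cohorts = gen, sc = sc, methylation = meth,
                 survival = surv, ct = ct))
}

read_cohort_list <- function(specs, stage_levels) {
  lapply(specs, function(s) {
    read_expression_matrix(s$matrix, s$metadata,
                           cohort_id = s$cohort_id %||% basename(s$matrix),
                           stage_levels = stage_levels)
  })
}

workflow_discovery <- function(config) {
  ins <- config$inputs
  if (is.null(ins$tier_a) || is.null(ins$tier_b)) {
    abort_hcc("The discovery workflow needs `tier_a` and `tier_b` cohort inputs.",
              "hccdriver_error_bad_config")
  }
  cohorts_a <- read_cohort_list(ins$tier_a, config$stage_levels)
  cohorts_b <- read_cohort_list(ins$tier_b, config$stage_levels)
  cascade <- run_cascade(
    cohorts_a, cohorts_b,
    fc_threshold = config$fc_threshold, alpha = config$alpha,
    span_min = config$span_min, tolerance = config$tolerance
  )
  out <- config$out_dir
  for (nm in names(cascade$deg_tables)) {
    write_table(cascade$deg_tables[[nm]], out, sprintf("deg_%s.tsv", nm))
  }
  for (nm in names(cascade$trend_a %||% list())) {
    write_table(flatten_trend(cascade$trend_a[[nm]]), out,
                sprintf("trend_a_%s.tsv", nm))
  }
  for (nm in names(cascade$trend_b %||% list())) {
    write_table(flatten_trend(cascade$trend_b[[nm]]), out,
                sprintf("trend_b_%s.tsv", nm))
  }
  write_table(tibble::tibble(gene = cascade$consensus_deg_genes), out,
              "consensus_degs.tsv")
  write_table(cascade$trend_a_consensus, out, "trend_consensus_a.tsv")
  write_table(cascade$final, out, "final_gene_list.tsv")

  if (!is.null(ins$truth)) {
    truth_genes <- readr::read_tsv(ins$truth, show_col_types = FALSE,
                                   progress = FALSE)$gene
    universe <- rownames(cohorts_a[[1]]$expression)
    truth <- structure(list(genes = universe, driver_genes = truth_genes),
                       class = "ground_truth")
    write_table(score_recovery(cascade$final$gene, truth), out,
                "recovery_report.tsv")
  }
  invisible(cascade)
}

# serialise the stage-means list-column for TSV output
flatten_trend <- function(trend_tb) {
  dplyr::mutate(
    trend_tb,
    stage_means = vapply(
      .data$stage_means,
      function(m) paste(sprintf("%s=%.6g", names(m), m), collapse = ";"),
      character(1)
    )
  )
}

workflow_enrichment <- function(config) {
  ins <- config$inputs
  if (is.null(ins$sc_dir) || is.null(ins$gmt) || is.null(ins$focal_gene)) {
    abort_hcc("The enrichment workflow needs `sc_dir`, `gmt` and `focal_gene` inputs.",
              "hccdriver_error_bad_config")
  }
  sc <- read_sc_counts(file.path(ins$sc_dir, "counts.mtx"),
                       file.path(ins$sc_dir, "cells.tsv"),
                       features_path = file.path(ins$sc_dir, "features.txt"),
                       barcodes_path = file.path(ins$sc_dir, "barcodes.txt"))
  collection <- read_gmt(ins$gmt)
  if (!ins$focal_gene %in% colnames(sc$counts)) {
    abort_hcc(sprintf("Focal gene '%s' is absent from the counts.",
                      ins$focal_gene),
              "hccdriver_error_unknown_gene")
  }

  agg <- aggregate_expression(sc$counts, sc$cells)
  strata <- stratify_quartiles(agg[, ins$focal_gene])
  log_expr <- t(log2(aggregate_expression(sc$counts, sc$cells,
                                          normalize = "cpm") + 1))
  lab <- stats::setNames(as.character(strata$stratum), strata$sample)
  de <- compute_de(log_expr, group_a = "high", group_b = "low",
                   groups = lab[colnames(log_expr)],
                   fc_threshold = config$fc_threshold, alpha = config$alpha)
  ranking <- rank_genes_by_log2fc(de)
  gsea <- purrr::map_dfr(names(collection), function(nm) {
    r <- preranked_gsea(ranking, collection[[nm]], weight = config$weight,
                        n_perm = config$n_perm, seed = config$seed)
    tibble::tibble(set = nm, es = r$es, nes = r$nes, p_value = r$p_value,
                   n_hits = r$n_hits,
                   leading_edge = paste(r$leading_edge[[1]], collapse = ";"))
  })
  scores <- ssgsea_scores(log_expr, collection)
  tests <- compare_ssgsea_groups(scores, strata)

  out <- config$out_dir
  write_table(strata, out, "strata.tsv")
  write_table(de, out, "pseudobulk_de.tsv")
  write_table(ranking, out, "ranking.tsv")
  write_table(gsea, out, "gsea.tsv")
  write_table(scores, out, "ssgsea_scores.tsv")
  write_table(tests, out, "ssgsea_tests.tsv")
  invisible(list(strata = strata, de = de, ranking = ranking, gsea = gsea,
                 ssgsea = scores, tests = tests))
}

workflow_biomarker <- function(config) {
  ins <- config$inputs
  if (is.null(ins$methylation)) {
    abort_hcc("The biomarker workflow needs a `methylation` input.",
              "hccdriver_error_bad_config")
  }
  meth <- read_methylation_table(ins$methylation)
  dm <- differential_methylation(meth)
  top_cpg <- ins$cpg %||% dm$cpg[order(dm$q, dm$delta_beta)][1]
  hypo <- call_hypomethylation(meth, top_cpg, margin = config$margin)

  df <- dplyr::filter(meth, .data$cpg == top_cpg)
  roc_scores <- c(df$beta_nt, df$beta_t)
  roc_labels <- rep(c("non-tumor", "tumor"), each = nrow(df))
  roc <- roc_auc(roc_scores, roc_labels, positive = "tumor",
                 lower_is_positive = TRUE)
  curve <- roc_curve(roc_scores, roc_labels, positive = "tumor",
                     lower_is_positive = TRUE)

  out <- config$out_dir
  write_table(dm, out, "differential_methylation.tsv")
  write_table(hypo$calls, out, "hypomethylation_calls.tsv")
  write_table(tibble::tibble(cpg = top_cpg, fraction = hypo$fraction,
                             margin = config$margin),
              out, "hypomethylation_summary.tsv")
  write_table(roc, out, "roc_summary.tsv")
  write_table(curve, out, "roc_curve.tsv")

  assoc <- NULL
  if (!is.null(ins$expression)) {
    expr <- readr::read_tsv(ins$expression, show_col_types = FALSE,
                            progress = FALSE)
    joined <- dplyr::inner_join(df, expr, by = "patient")
    assoc <- methylation_expression_association(joined$beta_t,
                                                joined$expression)
    write_table(assoc, out, "methylation_expression_correlation.tsv")
  }

  survfit_out <- NULL
  if (!is.null(ins$survival)) {
    surv <- read_survival_table(ins$survival)
    if (!"group" %in% names(surv)) {
      values <- stats::setNames(df$beta_t, df$patient)[surv$patient]
      if (anyNA(values)) {
        abort_hcc("Survival patients without a tumor beta at the focal CpG.",
                  "hccdriver_error_mismatched_samples")
      }
      surv$group <- dichotomize(values, rule = "median")
    }
    if (length(unique(as.character(surv$group))) < 2) {
      abort_hcc("Survival analysis needs two groups.",
                "hccdriver_error_single_group")
    }
    km <- km_estimate(surv)
    fit <- cox_binary_hr(surv)
    write_table(km, out, "km_curves.tsv")
    write_table(generics::glance(fit), out, "survival_fit.tsv")
    survfit_out <- list(km = km, fit = fit)
  }
  invisible(list(differential = dm, hypomethylation = hypo, roc = roc,
                 association = assoc, survival = survfit_out))
}
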