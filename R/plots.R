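#' Stage-profile plot for selected genes
#'
#' Per-stage expression distributions for a handful of genes in one cohort -
#' the standard view for judging a monotone "serial pattern".
#'
#' @param dataset A [stage_dataset()].
#' @param genes Genes to display.
#' @return A ggplot object (boxplots by stage, facetted by gene, with the
#'   stage-mean trend line overlaid).
#' @export
plot_stage_trend <- function(dataset, genes) {
  stopifnot(inherits(dataset, "stage_dataset"))
  missing_g <- setdiff(genes, rownames(dataset$expression))
  if (length(missing_g)) {
    abort_hcc(sprintf("Genes absent from the cohort: %s.",
                      paste(head(missing_g, 5), collapse = ", ")),
              "hccdriver_error_unknown_gene")
  }
  df <- tibble::as_tibble(t(dataset$expression[genes, , drop = FALSE]),
                          rownames = "sample") %>%
    dplyr::left_join(dataset$samples, by = "sample") %>%
    tidyr::pivot_longer(dplyr::all_of(genes), names_to = "gene",
                        values_to = "expression")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$expression)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          ggplot2::aes(group = 1), colour = "firebrick") +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "log2 expression",
                  title = dataset$cohort_id)
}

#' @describeIn plot_stage_trend autoplot method showing the top final genes
#'   of a cascade in a chosen cohort.
#' @param object A `driver_cascade`.
#' @param dataset Cohort to display the profiles in.
#' @param n_genes Number of top genes.
#' @param ... Unused.
#' @export
autoplot.driver_cascade <- function(object, dataset, n_genes = 4, ...) {
  genes <- head(object$final$gene, n_genes)
  if (!length(genes)) {
    abort_hcc("The cascade final list is empty; nothing to plot.",
              "hccdriver_error_empty_input")
  }
  plot_stage_trend(dataset, genes)
}

#' Kaplan-Meier step plot
#'
#' @param object An `hcc_km` table from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcc_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = NULL)
}

#' ROC curve plot
#'
#' @param object An `hcc_roc_curve` table from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object (sensitivity against 1 - specificity).
#' @export
autoplot.hcc_roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}

#' Enrichment running-sum plot
#'
#' @param object An `hcc_gsea` result from [preranked_gsea()].
#' @param ... Unused.
#' @return A ggplot object of the running enrichment score.
#' @export
autoplot.hcc_gsea <- function(object, ...) {
  rs <- attr(object, "running_sum")
  df <- tibble::tibble(position = seq_along(rs), running_sum = rs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "rank position", y = "running enrichment score")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
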