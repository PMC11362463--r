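#' Per-gene differential expression between two sample groups
#'
#' Welch t-test on log2 expression for every gene, BH adjustment across
#' genes, and the standard DEG gate: a gene is flagged when `p_adj < alpha`
#' and `|log2fc| >= log2(fc_threshold)`.
#'
#' @param dataset A [stage_dataset()] (groups are selected by stage label) or
#'   a plain genes-by-samples log2 matrix (groups are selected by a `groups`
#'   label vector aligned with the columns).
#' @param group_a,group_b Stage labels (for a `stage_dataset`) or group labels
#'   (for a matrix) defining the numerator and denominator groups. For the
#'   cascade, `group_a` is the tumor tier (default `c("eHCC", "aHCC")`) and
#'   `group_b` the non-tumor tier.
#' @param groups Optional per-sample label vector when `dataset` is a matrix.
#' @param fc_threshold Linear fold-change gate (default 1.5, i.e. the gate is
#'   `|log2fc| >= log2(1.5)`).
#' @param alpha Adjusted-p significance gate.
#' @return Tibble with one row per gene: `gene`, `log2fc` (mean a - mean b),
#'   `p`, `p_adj`, `direction` ("up"/"down"), `deg` (logical flag).
#' @export
compute_de <- function(dataset, group_a = c("eHCC", "aHCC"),
                       group_b = c("NL", "CH", "LC"),
                       groups = NULL, fc_threshold = 1.5, alpha = 0.05) {
  check_number(fc_threshold, "fc_threshold", lower = 0, allow_lower = FALSE)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  if (inherits(dataset, "stage_dataset")) {
    expr <- dataset$expression
    labels <- as.character(dataset$samples$stage)
  } else if (is.matrix(dataset)) {
    if (is.null(groups) || length(groups) != ncol(dataset)) {
      abort_hcc("A matrix input needs a `groups` label per column.",
                "hccdriver_error_bad_argument")
    }
    expr <- dataset
    labels <- as.character(groups)
  } else {
    abort_hcc("`dataset` must be a stage_dataset or a numeric matrix.",
              "hccdriver_error_bad_argument")
  }
  idx_a <- labels %in% group_a
  idx_b <- labels %in% group_b
  if (sum(idx_a) < 2 || sum(idx_b) < 2) {
    abort_hcc("Both groups need >= 2 samples.", "hccdriver_error_small_group")
  }

  a <- expr[, idx_a, drop = FALSE]
  b <- expr[, idx_b, drop = FALSE]
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  log2fc <- ma - mb
  stat <- ifelse(se2 > 0, log2fc / sqrt(se2), ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.finite(stat), 2 * pt(-abs(stat), df), 0)
  p[se2 == 0 & log2fc == 0] <- 1
  log2fc <- unname(log2fc)
  p <- unname(p)
  p_adj <- bh_adjust(p)
  tibble::tibble(
    gene = rownames(expr),
    log2fc = log2fc,
    p = p,
    p_adj = p_adj,
    direction = ifelse(log2fc > 0, "up", "down"),
    deg = p_adj < alpha & abs(log2fc) >= log2(fc_threshold)
  )
}

#' Cross-cohort consensus of differentially expressed genes
#'
#' Genes flagged as DEGs in every cohort with the same direction in all
#' cohorts - the intersection step of the cascade.
#'
#' @param per_cohort List of DEG tibbles from [compute_de()].
#' @return Character vector of consensus genes (sorted).
#' @export
consensus_degs <- function(per_cohort) {
  if (!is.list(per_cohort) || !length(per_cohort)) {
    abort_hcc("`per_cohort` must be a non-empty list of DEG tables.",
              "hccdriver_error_empty_input")
  }
  flagged <- lapply(per_cohort, function(tb) dplyr::filter(tb, .data$deg))
  common <- Reduce(intersect, lapply(flagged, function(tb) tb$gene))
  if (!length(common)) return(character(0))
  dirs <- vapply(flagged, function(tb) {
    stats::setNames(tb$direction, tb$gene)[common]
  }, character(length(common)))
  dirs <- matrix(dirs, nrow = length(common))
  consistent <- apply(dirs, 1, function(d) length(unique(d)) == 1)
  sort(common[consistent])
}

#' Ordered-stage monotone trend scoring per gene
#'
#' The serial-pattern selection criterion of the cascade: for each gene, a
#' one-sided increasing Jonckheere-Terpstra test across the cohort's ordered
#' stages (exact permutation enumeration when total n <= `exact_n_max`,
#' otherwise tie-corrected normal approximation), BH adjustment across the
#' scored genes, and two deterministic gates - stage means must be
#' non-decreasing up to a dip allowance of `tolerance` times the gene's
#' observed rise (last minus first stage mean, floored at zero), and the
#' last-minus-first stage-mean span must reach `span_min` log2 units.
#' `monotone_pass` holds only when all three conditions are met. Scaling the
#' dip allowance by the gene's own rise keeps the gate scale-free: a gene
#' climbing 2.5 log2 units may dip 0.25 between adjacent stages at the
#' default, while a flat gene gets no allowance at all.
#'
#' @param dataset A [stage_dataset()] with >= 3 represented stages.
#' @param genes Genes to score (default: all genes in the dataset).
#' @param span_min Minimum last-minus-first stage-mean difference (log2).
#' @param tolerance Allowed backward step between consecutive stage means, as
#'   a fraction of the gene's overall stage-mean rise.
#' @param alpha FDR level applied to the BH-adjusted trend p-values.
#' @param exact_n_max Exact-enumeration threshold passed to the trend test.
#' @return Tibble with one row per gene: `gene`, `cohort_id`, `jt_statistic`,
#'   `jt_z`, `p`, `q`, `stage_means` (list-column of named per-stage means),
#'   `span`, `monotone_pass`.
#' @export
trend_score <- function(dataset, genes = NULL, span_min = log2(1.5),
                        tolerance = 0.1, alpha = 0.05, exact_n_max = 12) {
  stopifnot(inherits(dataset, "stage_dataset"))
  check_number(span_min, "span_min", lower = 0)
  check_number(tolerance, "tolerance", lower = 0)
  check_number(alpha, "alpha", lower = 0, upper = 1)
  expr <- dataset$expression
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(expr))
    if (length(missing_g)) {
      abort_hcc(sprintf("Genes absent from cohort '%s': %s.",
                        dataset$cohort_id,
                        paste(head(missing_g, 5), collapse = ", ")),
                "hccdriver_error_unknown_gene")
    }
    expr <- expr[genes, , drop = FALSE]
  }
  stage <- droplevels(dataset$samples$stage)
  if (nlevels(stage) < 3) {
    abort_hcc("Trend scoring needs >= 3 represented stages.",
              "hccdriver_error_bad_argument")
  }

  jt <- jt_batch(expr, stage, exact_n_max = exact_n_max)

  stage_list <- split(seq_len(ncol(expr)), stage)
  means_mat <- vapply(stage_list,
                      function(idx) rowMeans(expr[, idx, drop = FALSE]),
                      numeric(nrow(expr)))
  if (nrow(expr) == 1L) means_mat <- matrix(means_mat, nrow = 1,
                                            dimnames = list(rownames(expr),
                                                            names(stage_list)))
  diffs <- means_mat[, -1, drop = FALSE] - means_mat[, -ncol(means_mat), drop = FALSE]
  span <- unname(means_mat[, ncol(means_mat)] - means_mat[, 1])
  dip_allowance <- tolerance * pmax(span, 0)
  nondecreasing <- apply(diffs >= -dip_allowance, 1, all)

  q <- bh_adjust(jt$p_value)
  tibble::tibble(
    gene = jt$gene,
    cohort_id = dataset$cohort_id,
    jt_statistic = jt$statistic,
    jt_z = jt$z,
    p = jt$p_value,
    q = q,
    stage_means = lapply(seq_len(nrow(means_mat)),
                         function(i) means_mat[i, ]),
    span = span,
    monotone_pass = q < alpha & nondecreasing & span >= span_min
  )
}

#' Cross-cohort consensus of monotone-trend genes
#'
#' Genes whose `monotone_pass` flag holds in all cohorts (`require_all`) or
#' in at least `quorum` cohorts, ordered by decreasing mean Jonckheere
#' z-score with lexicographic gene-id tie-breaking.
#'
#' @param per_cohort_trends List of trend tibbles from [trend_score()].
#' @param require_all Require a pass in every cohort (default).
#' @param quorum Minimum number of passing cohorts when `require_all` is
#'   `FALSE`.
#' @return Tibble: `gene`, `n_pass`, `mean_z`, ordered as described.
#' @export
consensus_trend <- function(per_cohort_trends, require_all = TRUE,
                            quorum = NULL) {
  if (!is.list(per_cohort_trends) || !length(per_cohort_trends)) {
    abort_hcc("`per_cohort_trends` must be a non-empty list.",
              "hccdriver_error_empty_input")
  }
  n_cohorts <- length(per_cohort_trends)
  need <- if (require_all) n_cohorts else check_count(quorum %||% n_cohorts, "quorum")
  all_tb <- dplyr::bind_rows(per_cohort_trends)
  out <- all_tb %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_pass = sum(.data$monotone_pass),
      n_scored = dplyr::n(),
      mean_z = mean(.data$jt_z),
      .groups = "drop"
    ) %>%
    dplyr::filter(.data$n_scored == n_cohorts, .data$n_pass >= need) %>%
    dplyr::arrange(dplyr::desc(.data$mean_z), .data$gene) %>%
    dplyr::select("gene", "n_pass", "mean_z")
  out
}

#' Run the full driver-discovery cascade
#'
#' Reproduces the multi-cohort discovery logic: (1) per-cohort differential
#' expression tumor vs non-tumor in the tier-A cohorts and direction-
#' consistent consensus; (2) monotone trend scoring of the consensus DEGs in
#' every tier-A cohort and all-cohort trend consensus; (3) validation of the
#' surviving genes by trend scoring in every tier-B cohort (require-all); the
#' final list is ordered by mean tier-B trend z-score.
#'
#' @param cohorts_a List of tier-A [stage_dataset()] cohorts (discovery).
#' @param cohorts_b List of tier-B cohorts (validation); may equal
#'   `cohorts_a`.
#' @param tumor_stages,nontumor_stages Stage labels forming the DE contrast.
#' @param fc_threshold,alpha Differential-expression gates (see
#'   [compute_de()]).
#' @param span_min,tolerance Trend gates (see [trend_score()]).
#' @return A `driver_cascade` object: list with `deg_tables`,
#'   `consensus_deg_genes`, `trend_a`, `trend_a_consensus`, `trend_b`,
#'   `final` (ordered tibble), and `params`. Use [generics::tidy()] for the
#'   final table and [generics::glance()] for per-step counts.
#' @export
run_cascade <- function(cohorts_a, cohorts_b,
                        tumor_stages = c("eHCC", "aHCC"),
                        nontumor_stages = c("NL", "CH", "LC"),
                        fc_threshold = 1.5, alpha = 0.05,
                        span_min = log2(1.5), tolerance = 0.1) {
  if (!length(cohorts_a) || !length(cohorts_b)) {
    abort_hcc("Both cohort tiers must be non-empty.",
              "hccdriver_error_empty_input")
  }
  deg_tables <- lapply(cohorts_a, compute_de, group_a = tumor_stages,
                       group_b = nontumor_stages, fc_threshold = fc_threshold,
                       alpha = alpha)
  names(deg_tables) <- vapply(cohorts_a, `[[`, character(1), "cohort_id")
  consensus_genes <- consensus_degs(deg_tables)

  empty_final <- tibble::tibble(gene = character(0), n_pass = integer(0),
                                mean_z = numeric(0))
  trend_a <- trend_a_cons <- trend_b <- NULL
  final <- empty_final
  if (length(consensus_genes)) {
    trend_a <- lapply(cohorts_a, trend_score, genes = consensus_genes,
                      span_min = span_min, tolerance = tolerance,
                      alpha = alpha)
    names(trend_a) <- names(deg_tables)
    trend_a_cons <- consensus_trend(trend_a, require_all = TRUE)
    if (nrow(trend_a_cons)) {
      trend_b <- lapply(cohorts_b, trend_score, genes = trend_a_cons$gene,
                        span_min = span_min, tolerance = tolerance,
                        alpha = alpha)
      names(trend_b) <- vapply(cohorts_b, `[[`, character(1), "cohort_id")
      final <- consensus_trend(trend_b, require_all = TRUE)
    }
  }

  structure(
    list(
      deg_tables = deg_tables,
      consensus_deg_genes = consensus_genes,
      trend_a = trend_a,
      trend_a_consensus = trend_a_cons %||% empty_final,
      trend_b = trend_b,
      final = final,
      params = list(
        tumor_stages = tumor_stages, nontumor_stages = nontumor_stages,
        fc_threshold = fc_threshold, alpha = alpha,
        span_min = span_min, tolerance = tolerance,
        n_cohorts_a = length(cohorts_a), n_cohorts_b = length(cohorts_b)
      )
    ),
    class = "driver_cascade"
  )
}

#' @export
print.driver_cascade <- function(x, ...) {
  cat("<driver_cascade>\n")
  cat(sprintf("  tier-A cohorts: %d, tier-B cohorts: %d\n",
              x$params$n_cohorts_a, x$params$n_cohorts_b))
  cat(sprintf("  consensus DEGs: %d\n", length(x$consensus_deg_genes)))
  cat(sprintf("  tier-A trend consensus: %d genes\n", nrow(x$trend_a_consensus)))
  cat(sprintf("  final list: %d genes\n", nrow(x$final)))
  invisible(x)
}
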