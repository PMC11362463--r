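#' Pseudo-bulk aggregation of single-cell counts
#'
#' Sums raw counts over the cells of each sample, yielding a samples-by-genes
#' matrix. Total counts are conserved. An optional counts-per-million
#' normalisation serves the ssGSEA input path.
#'
#' @param counts Cells-by-genes count matrix (base matrix or sparse
#'   `dgCMatrix`), non-negative integers, cell rownames.
#' @param cells Tibble with `cell`, `sample` (and optionally `phenotype`)
#'   covering every row of `counts`.
#' @param normalize "none" (raw sums, default) or "cpm".
#' @return Samples-by-genes numeric matrix.
#' @export
aggregate_expression <- function(counts, cells, normalize = c("none", "cpm")) {
  normalize <- match.arg(normalize)
  validate_cell_matrix(counts, cells)
  sample_of <- stats::setNames(cells$sample, cells$cell)[rownames(counts)]
  agg <- rowsum(as.matrix(counts), group = sample_of, reorder = TRUE)
  if (normalize == "cpm") {
    lib <- rowSums(agg)
    if (any(lib == 0)) {
      abort_hcc("A sample has zero total counts; CPM is undefined.",
                "hccdriver_error_zero_library")
    }
    agg <- agg / lib * 1e6
  }
  agg
}

validate_cell_matrix <- function(counts, cells) {
  if (is.null(rownames(counts))) {
    abort_hcc("`counts` must carry cell rownames.",
              "hccdriver_error_bad_argument")
  }
  if (any(counts < 0)) {
    abort_hcc("Counts must be non-negative.", "hccdriver_error_bad_argument")
  }
  missing_cells <- setdiff(rownames(counts), cells$cell)
  if (length(missing_cells)) {
    abort_hcc(sprintf("Cells without metadata: %s.",
                      paste(head(missing_cells, 5), collapse = ", ")),
              "hccdriver_error_mismatched_samples")
  }
  invisible(TRUE)
}

#' Quartile stratification of samples by a focal-gene value
#'
#' Samples are sorted by value in descending order (stable in input order for
#' ties); the top `ceiling(n/4)` become the "high" stratum, the bottom
#' `floor(n/4)` the "low" stratum, and the remainder "mid". High therefore
#' means highest aggregated expression. The three strata always partition the
#' sample set.
#'
#' @param values Named numeric vector: one aggregated focal-gene value per
#'   sample (n >= 4).
#' @return Tibble: `sample`, `stratum` (factor high/mid/low),
#'   `aggregated_value`.
#' @export
stratify_quartiles <- function(values) {
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    abort_hcc("`values` must be uniquely named by sample.",
              "hccdriver_error_bad_argument")
  }
  n <- length(values)
  if (n < 4) {
    abort_hcc("Quartile stratification needs >= 4 samples.",
              "hccdriver_error_small_group")
  }
  ord <- order(-values)                  # stable: ties keep input order
  n_high <- ceiling(n / 4)
  n_low <- floor(n / 4)
  stratum <- rep("mid", n)
  stratum[ord[seq_len(n_high)]] <- "high"
  stratum[ord[(n - n_low + 1):n]] <- "low"
  tibble::tibble(
    sample = names(values),
    stratum = factor(stratum, levels = c("high", "mid", "low")),
    aggregated_value = unname(values)
  )
}

#' Positivity proportion of a gene per phenotype
#'
#' A cell is positive for the gene when its count is at least 1 and negative
#' when the count is 0; the proportion divides positive cells by all cells of
#' each phenotype.
#'
#' @param counts Cells-by-genes count matrix with gene colnames.
#' @param cells Tibble with `cell` and `phenotype` labels.
#' @param gene Gene identifier (must be a column of `counts`).
#' @return Tibble: `phenotype`, `n_cells`, `n_positive`, `proportion`.
#' @export
positivity_proportion <- function(counts, cells, gene) {
  validate_cell_matrix(counts, cells)
  if (!gene %in% colnames(counts)) {
    abort_hcc(sprintf("Unknown gene '%s'.", gene),
              "hccdriver_error_unknown_gene")
  }
  phen <- stats::setNames(cells$phenotype, cells$cell)[rownames(counts)]
  pos <- as.numeric(counts[, gene]) >= 1
  tibble::tibble(phenotype = phen, positive = pos) %>%
    dplyr::group_by(.data$phenotype) %>%
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_positive = sum(.data$positive),
      proportion = mean(.data$positive),
      .groups = "drop"
    )
}
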