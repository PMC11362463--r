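#' The ordered liver-disease stage ladder
#'
#' Default ordering of disease states used throughout the discovery cascade:
#' normal liver (NL), chronic hepatitis (CH), liver cirrhosis (LC), dysplastic
#' nodule (DN), early hepatocellular carcinoma (eHCC) and advanced HCC (aHCC).
#' Cohorts may carry any subset of at least three of these stages.
#'
#' @return Character vector of stage labels, ordered from benign to advanced.
#' @export
#' @examples
#' hcc_stage_ladder()
hcc_stage_ladder <- function() {
  c("NL", "CH", "LC", "DN", "eHCC", "aHCC")
}

#' Construct a stage-labelled expression dataset
#'
#' Bundles a genes-by-samples log2 expression matrix with per-sample stage
#' labels drawn from an ordered stage ladder. This is the unit of input for
#' the discovery cascade; one `stage_dataset` corresponds to one cohort.
#'
#' @param expression Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), log2 scale, no missing values.
#' @param stage Character or factor vector of stage labels, one per column of
#'   `expression`, or a data frame with columns `sample` and `stage`.
#' @param cohort_id Single label identifying the cohort.
#' @param stage_levels Ordered stage ladder the labels are drawn from.
#' @return An object of class `stage_dataset`: a list with elements
#'   `expression` (matrix), `samples` (tibble with `sample` and ordered-factor
#'   `stage`) and `cohort_id`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' stage_dataset(m, rep(c("NL", "LC", "aHCC"), each = 2), "demo")
stage_dataset <- function(expression, stage, cohort_id,
                          stage_levels = hcc_stage_ladder()) {
  if (!is.matrix(expression) || !is.numeric(expression)) {
    abort_hcc("`expression` must be a numeric matrix (genes x samples).",
              "hccdriver_error_bad_expression")
  }
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    abort_hcc("`expression` must have gene rownames and sample colnames.",
              "hccdriver_error_bad_expression")
  }
  if (anyNA(expression)) {
    abort_hcc("`expression` contains missing values.",
              "hccdriver_error_missing_values")
  }
  if (anyDuplicated(rownames(expression))) {
    dup <- unique(rownames(expression)[duplicated(rownames(expression))])
    abort_hcc(
      sprintf("Duplicate gene identifiers: %s.",
              paste(head(dup, 5), collapse = ", ")),
      "hccdriver_error_duplicate_genes"
    )
  }
  if (is.data.frame(stage)) {
    if (!all(c("sample", "stage") %in% names(stage))) {
      abort_hcc("Stage metadata needs `sample` and `stage` columns.",
                "hccdriver_error_bad_metadata")
    }
    missing_meta <- setdiff(colnames(expression), stage$sample)
    missing_expr <- setdiff(stage$sample, colnames(expression))
    if (length(missing_meta) || length(missing_expr)) {
      abort_hcc(
        sprintf(
          "Samples in matrix and metadata do not match (matrix-only: %s; metadata-only: %s).",
          paste(head(missing_meta, 5), collapse = ", ") %|e|% "none",
          paste(head(missing_expr, 5), collapse = ", ") %|e|% "none"
        ),
        "hccdriver_error_mismatched_samples"
      )
    }
    stage <- stage$stage[match(colnames(expression), stage$sample)]
  }
  stage <- as.character(stage)
  if (length(stage) != ncol(expression)) {
    abort_hcc("One stage label per sample is required.",
              "hccdriver_error_bad_metadata")
  }
  bad <- setdiff(unique(stage), stage_levels)
  if (length(bad)) {
    abort_hcc(
      sprintf("Stage labels outside the declared ladder: %s.",
              paste(bad, collapse = ", ")),
      "hccdriver_error_unknown_stage"
    )
  }
  tab <- table(stage)
  if (any(tab < 2)) {
    abort_hcc(
      sprintf("Every represented stage needs >= 2 samples; offending: %s.",
              paste(names(tab)[tab < 2], collapse = ", ")),
      "hccdriver_error_small_stage"
    )
  }
  structure(
    list(
      expression = expression,
      samples = tibble::tibble(
        sample = colnames(expression),
        stage = factor(stage, levels = stage_levels, ordered = TRUE)
      ),
      cohort_id = as.character(cohort_id)[1]
    ),
    class = "stage_dataset"
  )
}

# empty-string helper for error messages
`%|e|%` <- function(a, b) if (!nzchar(a)) b else a

#' @export
print.stage_dataset <- function(x, ...) {
  tab <- table(as.character(x$samples$stage))
  cat(sprintf("<stage_dataset> cohort '%s': %d genes x %d samples\n",
              x$cohort_id, nrow(x$expression), ncol(x$expression)))
  cat("stages:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stages present in a stage dataset, in ladder order
#' @param dataset A `stage_dataset`.
#' @return Character vector of represented stages.
#' @export
stages_present <- function(dataset) {
  stopifnot(inherits(dataset, "stage_dataset"))
  lv <- levels(dataset$samples$stage)
  lv[lv %in% as.character(dataset$samples$stage)]
}
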