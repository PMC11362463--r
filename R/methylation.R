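#' Paired differential methylation per CpG
#'
#' Paired t-test of tumor minus non-tumor beta values for each CpG, with BH
#' adjustment across CpGs. Negative `delta_beta` means tumor hypomethylation.
#'
#' @param records Tibble with `cpg`, `patient`, `beta_nt`, `beta_t` (one row
#'   per CpG-patient pair; betas in [0, 1]).
#' @param cpgs CpGs to test (default all present).
#' @return Tibble: `cpg`, `n`, `delta_beta`, `statistic`, `p`, `q`.
#' @export
differential_methylation <- function(records, cpgs = NULL) {
  validate_methylation(records)
  if (!is.null(cpgs)) records <- dplyr::filter(records, .data$cpg %in% cpgs)
  res <- records %>%
    dplyr::group_by(.data$cpg) %>%
    dplyr::group_modify(function(df, key) {
      d <- df$beta_t - df$beta_nt
      if (length(d) < 3) {
        abort_hcc(sprintf("CpG '%s' has fewer than 3 pairs.", key$cpg),
                  "hccdriver_error_small_group")
      }
      if (sd(d) == 0) {
        # identical pairs: no evidence of change, by convention
        return(tibble::tibble(n = length(d), delta_beta = mean(d),
                              statistic = 0, p = 1))
      }
      tt <- t.test(d)
      tibble::tibble(n = length(d), delta_beta = mean(d),
                     statistic = unname(tt$statistic), p = tt$p.value)
    }) %>%
    dplyr::ungroup()
  dplyr::mutate(res, q = bh_adjust(.data$p))
}

validate_methylation <- function(records) {
  need <- c("cpg", "patient", "beta_nt", "beta_t")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort_hcc(sprintf("Methylation records need columns: %s.",
                      paste(miss, collapse = ", ")),
              "hccdriver_error_bad_argument")
  }
  if (anyNA(records$beta_nt) || anyNA(records$beta_t)) {
    abort_hcc("Missing beta values: every (cpg, patient) needs a complete NT/T pair.",
              "hccdriver_error_missing_pair")
  }
  if (any(records$beta_nt < 0 | records$beta_nt > 1 |
            records$beta_t < 0 | records$beta_t > 1)) {
    abort_hcc("Beta values must lie in [0, 1].", "hccdriver_error_bad_argument")
  }
  if (anyDuplicated(records[c("cpg", "patient")])) {
    abort_hcc("One record per (cpg, patient) is required.",
              "hccdriver_error_duplicate_records")
  }
  invisible(TRUE)
}

#' Per-patient hypomethylation call at one CpG
#'
#' A patient is called hypomethylated when the tumor beta falls below the
#' paired non-tumor beta by more than `margin`; the cohort fraction is the
#' share of called patients.
#'
#' @param records Paired methylation tibble (see
#'   [differential_methylation()]).
#' @param cpg CpG to call.
#' @param margin Required beta decrease (default 0: strict inequality).
#' @return List of class `hypomethylation_call`: `calls` (tibble `patient`,
#'   `beta_nt`, `beta_t`, `hypomethylated`), `fraction`, `cpg`, `margin`.
#' @export
call_hypomethylation <- function(records, cpg, margin = 0) {
  validate_methylation(records)
  check_number(margin, "margin", lower = 0, upper = 1)
  df <- dplyr::filter(records, .data$cpg == !!cpg)
  if (!nrow(df)) {
    abort_hcc(sprintf("No records for CpG '%s'.", cpg),
              "hccdriver_error_unknown_cpg")
  }
  calls <- df %>%
    dplyr::transmute(
      patient = .data$patient,
      beta_nt = .data$beta_nt,
      beta_t = .data$beta_t,
      hypomethylated = .data$beta_t < .data$beta_nt - margin
    )
  structure(
    list(calls = calls, fraction = mean(calls$hypomethylated),
         cpg = cpg, margin = margin),
    class = "hypomethylation_call"
  )
}

#' @export
print.hypomethylation_call <- function(x, ...) {
  cat(sprintf("<hypomethylation_call> %s: %d/%d patients (%.1f%%) at margin %g\n",
              x$cpg, sum(x$calls$hypomethylated), nrow(x$calls),
              100 * x$fraction, x$margin))
  invisible(x)
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC via the Mann-Whitney identity (concordant-pair fraction with half
#' credit for ties) and a 95% DeLong interval, computed with the pROC
#' package. The `lower_is_positive` orientation flag makes a tumor-
#' hypomethylated marker (low beta = positive class) explicit instead of
#' silently reporting `1 - AUC`.
#'
#' @param scores Numeric vector of marker values.
#' @param labels Class labels aligned with `scores`.
#' @param positive Label of the positive class (default "tumor").
#' @param lower_is_positive If `TRUE`, lower scores indicate the positive
#'   class.
#' @return One-row tibble of class `hcc_roc`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = "tumor",
                    lower_is_positive = FALSE) {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2 || !positive %in% classes) {
    abort_hcc("`labels` must contain exactly two classes including the positive one.",
              "hccdriver_error_single_class")
  }
  negative <- setdiff(classes, positive)
  roc <- pROC::roc(
    response = labels, predictor = scores,
    levels = c(negative, positive),
    direction = if (lower_is_positive) ">" else "<",
    quiet = TRUE
  )
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(roc, method = "delong")))
  out <- tibble::tibble(
    auc = as.numeric(pROC::auc(roc)),
    ci_low = max(0, ci[1]),
    ci_high = min(1, ci[3]),
    n_pos = sum(labels == positive),
    n_neg = sum(labels == negative)
  )
  class(out) <- c("hcc_roc", class(out))
  out
}

#' Full ROC coordinate table
#'
#' @inheritParams roc_auc
#' @return Tibble of class `hcc_roc_curve`: `threshold`, `sensitivity`,
#'   `specificity` over all cutoffs.
#' @export
roc_curve <- function(scores, labels, positive = "tumor",
                      lower_is_positive = FALSE) {
  labels <- as.character(labels)
  negative <- setdiff(unique(labels), positive)
  if (length(negative) != 1) {
    abort_hcc("`labels` must contain exactly two classes including the positive one.",
              "hccdriver_error_single_class")
  }
  roc <- pROC::roc(
    response = labels, predictor = scores,
    levels = c(negative, positive),
    direction = if (lower_is_positive) ">" else "<",
    quiet = TRUE
  )
  co <- pROC::coords(roc, "all", ret = c("threshold", "sensitivity",
                                         "specificity"), transpose = FALSE)
  out <- tibble::as_tibble(co)
  class(out) <- c("hcc_roc_curve", class(out))
  out
}

#' Methylation-expression association
#'
#' Pearson correlation (sign reported as-is) between a CpG's beta values and
#' paired expression, via [pearson_corr()].
#'
#' @param beta,expression Paired numeric vectors, n >= 3.
#' @return One-row tibble: `r`, `p_value`, `n`, `method`.
#' @export
methylation_expression_association <- function(beta, expression) {
  pearson_corr(beta, expression)
}
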