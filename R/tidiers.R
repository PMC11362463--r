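#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the final gene list of a driver cascade
#'
#' @param x A `driver_cascade` from [run_cascade()].
#' @param ... Unused.
#' @return The ordered final tibble (`gene`, `n_pass`, `mean_z`).
#' @export
tidy.driver_cascade <- function(x, ...) {
  x$final
}

#' One-row summary of a driver cascade
#'
#' @param x A `driver_cascade`.
#' @param ... Unused.
#' @return Tibble with per-step gene counts and the main thresholds.
#' @export
glance.driver_cascade <- function(x, ...) {
  tibble::tibble(
    n_consensus_degs = length(x$consensus_deg_genes),
    n_trend_consensus_a = nrow(x$trend_a_consensus),
    n_final = nrow(x$final),
    fc_threshold = x$params$fc_threshold,
    alpha = x$params$alpha,
    span_min = x$params$span_min
  )
}

#' Coefficient table of a binary Cox fit
#'
#' @param x An `hcc_coxfit` from [cox_binary_hr()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log hazard), `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.hcc_coxfit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "coef"],
    std_error = sm[, "se(coef)"],
    statistic = sm[, "z"],
    p_value = sm[, "Pr(>|z|)"]
  )
}

#' One-row summary of a binary Cox fit
#'
#' @param x An `hcc_coxfit`.
#' @param ... Unused.
#' @return Tibble: `hr`, `ci_low`, `ci_high`, `logrank_chi2`, `logrank_p`,
#'   `n`, `n_events`.
#' @export
glance.hcc_coxfit <- function(x, ...) {
  tibble::tibble(
    hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high,
    logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p,
    n = x$n, n_events = x$n_events
  )
}
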