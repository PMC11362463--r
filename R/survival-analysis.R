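#' Dichotomize patients into high/low groups
#'
#' Deterministic splits for survival analysis. The median rule sends values
#' at or below the median to "low" (ties at the median go low); the quartile
#' rule labels the top quartile "high", the bottom quartile "low" and leaves
#' the middle `NA`; the threshold rule labels values strictly above
#' `threshold` "high".
#'
#' @param values Numeric vector (n >= 4).
#' @param rule "median", "quartile" or "threshold".
#' @param threshold Cut point for the threshold rule.
#' @return Factor with levels low/high (possibly `NA` under the quartile
#'   rule), invariant to positive affine rescaling of `values` for the
#'   median and quartile rules.
#' @export
dichotomize <- function(values, rule = c("median", "quartile", "threshold"),
                        threshold = NULL) {
  rule <- match.arg(rule)
  if (length(values) < 4) {
    abort_hcc("Dichotomization needs n >= 4.", "hccdriver_error_small_group")
  }
  lab <- switch(
    rule,
    median = {
      if (max(values) == min(values)) {
        abort_hcc("All values identical: the median split is degenerate.",
                  "hccdriver_error_degenerate_split")
      }
      ifelse(values > median(values), "high", "low")
    },
    quartile = {
      q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
      ifelse(values >= q[2], "high", ifelse(values <= q[1], "low", NA))
    },
    threshold = {
      if (is.null(threshold)) {
        abort_hcc("The threshold rule needs `threshold`.",
                  "hccdriver_error_bad_argument")
      }
      ifelse(values > threshold, "high", "low")
    }
  )
  factor(lab, levels = c("low", "high"))
}

validate_survival <- function(records) {
  need <- c("time", "event", "group")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort_hcc(sprintf("Survival records need columns: %s.",
                      paste(miss, collapse = ", ")),
              "hccdriver_error_bad_argument")
  }
  if (any(records$time < 0) || anyNA(records$time)) {
    abort_hcc("Times must be non-negative.", "hccdriver_error_bad_argument")
  }
  if (!all(records$event %in% c(0, 1))) {
    abort_hcc("`event` must be 0 (censored) or 1 (event).",
              "hccdriver_error_bad_argument")
  }
  invisible(TRUE)
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator via [survival::survfit()], returned as a tidy step
#' table (one row per distinct time per group, preceded by the time-zero
#' anchor at survival 1).
#'
#' @param records Tibble with `time`, `event`, `group`.
#' @return Tibble of class `hcc_km`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(records) {
  validate_survival(records)
  if (sum(records$event) < 1) {
    # no events: the estimator never drops
    groups <- unique(as.character(records$group))
    out <- tibble::tibble(group = groups, time = 0, n_risk = NA_integer_,
                          n_event = 0L, n_censor = 0L, surv = 1)
    class(out) <- c("hcc_km", class(out))
    return(out)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           data = records)
  strata_names <- if (is.null(fit$strata)) {
    rep(unique(as.character(records$group)), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  steps <- tibble::tibble(
    group = strata_names,
    time = fit$time,
    n_risk = as.integer(fit$n.risk),
    n_event = as.integer(fit$n.event),
    n_censor = as.integer(fit$n.censor),
    surv = fit$surv
  )
  anchors <- steps %>%
    dplyr::distinct(.data$group) %>%
    dplyr::mutate(time = 0, n_risk = NA_integer_, n_event = 0L,
                  n_censor = 0L, surv = 1)
  out <- dplyr::bind_rows(anchors, steps) %>%
    dplyr::arrange(.data$group, .data$time)
  class(out) <- c("hcc_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times, via [survival::survdiff()]; chi-square p with
#' 1 degree of freedom. Identical groups give statistic 0.
#'
#' @param records Tibble with `time`, `event`, `group` (exactly two groups).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records) {
  validate_survival(records)
  groups <- unique(as.character(records$group))
  if (length(groups) != 2) {
    abort_hcc("The log-rank test needs exactly two groups.",
              "hccdriver_error_single_group")
  }
  if (sum(records$event) < 1) {
    abort_hcc("At least one event is required.", "hccdriver_error_no_events")
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  tibble::tibble(
    statistic = sd$chisq,
    df = 1L,
    p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Binary-covariate Cox hazard ratio
#'
#' Univariate Cox proportional-hazards fit of the high-vs-low group indicator
#' with Breslow tie handling (Efron behind a flag), Newton-Raphson iterated
#' to a 1e-9 tolerance, and a Wald 95% interval on the log-hazard scale. A
#' log-rank summary is attached. Complete separation (all events in one
#' group) is a hard error.
#'
#' @param records Tibble with `time`, `event`, `group` (levels low/high; the
#'   reported hazard ratio is high vs low).
#' @param ties "breslow" (default) or "efron".
#' @return Object of class `hcc_coxfit`; use [generics::glance()] for the
#'   one-row summary (`hr`, `ci_low`, `ci_high`, `logrank_chi2`,
#'   `logrank_p`) and [generics::tidy()] for the coefficient table.
#' @export
cox_binary_hr <- function(records, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  validate_survival(records)
  records$group <- factor(as.character(records$group),
                          levels = c("low", "high"))
  if (any(is.na(records$group))) {
    abort_hcc("Groups must be labelled 'low' and 'high'.",
              "hccdriver_error_bad_argument")
  }
  ev <- tapply(records$event, records$group, sum)
  if (sum(records$event) < 2) {
    abort_hcc("At least two events are required.", "hccdriver_error_no_events")
  }
  if (any(ev == 0)) {
    abort_hcc("All events fall in one group: the hazard ratio is not identified (complete separation).",
              "hccdriver_error_separation")
  }
  fit <- survival::coxph(
    survival::Surv(time, event) ~ group, data = records, ties = ties,
    control = survival::coxph.control(eps = 1e-9, iter.max = 50)
  )
  sm <- summary(fit)
  lr <- logrank_test(records)
  structure(
    list(
      fit = fit,
      hr = unname(exp(stats::coef(fit))),
      ci_low = unname(sm$conf.int[1, "lower .95"]),
      ci_high = unname(sm$conf.int[1, "upper .95"]),
      se = unname(sm$coefficients[1, "se(coef)"]),
      logrank_chi2 = lr$statistic,
      logrank_p = lr$p_value,
      n = nrow(records),
      n_events = sum(records$event),
      ties = ties
    ),
    class = "hcc_coxfit"
  )
}

#' @export
print.hcc_coxfit <- function(x, ...) {
  cat(sprintf("<hcc_coxfit> HR (high vs low) = %.3f [%.3f, %.3f], log-rank chi2 = %.3f (p = %.3g), n = %d (%d events)\n",
              x$hr, x$ci_low, x$ci_high, x$logrank_chi2, x$logrank_p,
              x$n, x$n_events))
  invisible(x)
}
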