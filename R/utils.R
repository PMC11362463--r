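# internal validation and seeding helpers

abort_hcc <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "hccdriver_error"), ...)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort_hcc(
      sprintf("`%s` must be a single integer >= %d (got %s).", name, min, deparse(x)),
      "hccdriver_error_bad_argument"
    )
  }
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_lower) x >= lower else x > lower) &&
    (if (allow_upper) x <= upper else x < upper)
  if (!ok) {
    abort_hcc(
      sprintf("`%s` must be a single finite number in %s%s, %s%s (got %s).",
              name, if (allow_lower) "[" else "(", format(lower),
              format(upper), if (allow_upper) "]" else ")", deparse(x)),
      "hccdriver_error_bad_argument"
    )
  }
  as.numeric(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) {
    abort_hcc("A `seed` is required for every stochastic generator.",
              "hccdriver_error_missing_seed")
  }
  check_count(seed, "seed", min = 0L)
}

# Deterministic child seeds so each cohort/table has its own reproducible
# sub-stream. Kept below .Machine$integer.max.
child_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(2147483646L, n))
}

# clamp values into the open unit interval (beta-value support)
clamp_unit <- function(x, eps = 1e-4) pmin(pmax(x, eps), 1 - eps)
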