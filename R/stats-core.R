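#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. A thin, validated wrapper around
#' [stats::p.adjust()] so every module shares one multiple-testing route.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, capped at 1, same order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort_hcc("All p-values must be numeric and within [0, 1].",
              "hccdriver_error_bad_pvalues")
  }
  p.adjust(p, method = "BH")
}

#' Pearson or Spearman correlation with a two-sided test
#'
#' Sample correlation with the two-sided p-value from the t transformation.
#' Constant input is a hard error rather than a silent `NA`.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, each non-constant.
#' @param method "pearson" (default) or "spearman".
#' @return One-row tibble: `r`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' pearson_corr(1:10, (1:10) + rnorm(10))
pearson_corr <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) != length(y) || length(x) < 3) {
    abort_hcc("`x` and `y` must be equal-length with n >= 3 finite pairs.",
              "hccdriver_error_bad_argument")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort_hcc("Correlation is undefined for a constant vector.",
              "hccdriver_error_constant_input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(x),
    method = method
  )
}

#' Wilcoxon rank-sum test with an explicit exact/approximate switch
#'
#' Uses exact enumeration of the rank-sum distribution when the smaller
#' sample has at most `exact_below` observations and there are no ties;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction). Delegates to [stats::wilcox.test()].
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact_below Exact p-values when `min(length(a), length(b))` is at
#'   or below this and the pooled sample is tie-free.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return One-row tibble: `statistic` (Mann-Whitney U of `a`), `p_value`,
#'   `method` ("exact" or "normal-approx"), `n_a`, `n_b`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_below = 8,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b)) {
    abort_hcc("Both samples must be non-empty.", "hccdriver_error_empty_sample")
  }
  if (sd(c(a, b)) == 0) {
    # no variation at all: no evidence of a shift, by convention
    return(tibble::tibble(statistic = length(a) * length(b) / 2,
                          p_value = 1, method = "degenerate-constant",
                          n_a = length(a), n_b = length(b)))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= exact_below && !ties
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = !exact)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    method = if (exact) "exact" else "normal-approx",
    n_a = length(a),
    n_b = length(b)
  )
}

#' Normality-gated group comparison
#'
#' Implements the test-selection policy used throughout the bulk analyses:
#' each group is screened with the Shapiro-Wilk test; if every group looks
#' normal the parametric branch is taken (Welch t for two unpaired groups,
#' paired t for paired data, one-way ANOVA with Tukey post-hoc for more than
#' two groups), otherwise the rank branch (Wilcoxon for two groups - signed
#' rank when paired - or Kruskal-Wallis with Dunn's post-hoc, BH-adjusted).
#'
#' @param groups Named list of numeric vectors, each with n >= 3.
#' @param paired Treat two groups as paired (requires equal sizes).
#' @param alpha_normality Shapiro-Wilk significance level for the branch
#'   decision (conventional 0.05 default).
#' @return A `group_test` list: `test` (one-row tibble with `method`,
#'   `statistic`, `p_value`), `posthoc` (tibble or `NULL`), `normality`
#'   (per-group Shapiro results), `branch` ("parametric"/"nonparametric").
#' @export
choose_and_run_group_test <- function(groups, paired = FALSE,
                                      alpha_normality = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_hcc("`groups` must be a list of >= 2 numeric vectors.",
              "hccdriver_error_bad_argument")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes < 3)) {
    abort_hcc("Every group needs n >= 3.", "hccdriver_error_small_group")
  }
  if (paired && length(groups) != 2) {
    abort_hcc("`paired = TRUE` requires exactly two groups.",
              "hccdriver_error_bad_argument")
  }
  if (paired && sizes[1] != sizes[2]) {
    abort_hcc("Paired comparison requires equal group sizes.",
              "hccdriver_error_unequal_pairs")
  }

  shapiro_p <- vapply(groups, function(g) {
    if (sd(g) == 0) return(0)          # constant: treat as non-normal
    shapiro.test(g)$p.value
  }, numeric(1))
  normality <- tibble::tibble(group = names(groups), n = as.integer(sizes),
                              shapiro_p = shapiro_p)
  all_normal <- all(shapiro_p > alpha_normality)

  pooled <- unlist(groups, use.names = FALSE)
  if (sd(pooled) == 0) {
    # no variation anywhere: no evidence of any difference, by convention
    res <- list(
      test = tibble::tibble(method = "degenerate-constant", statistic = 0,
                            p_value = 1),
      posthoc = NULL, normality = normality, branch = "degenerate",
      sizes = sizes
    )
    return(structure(res, class = "group_test"))
  }

  posthoc <- NULL
  if (all_normal) {
    branch <- "parametric"
    if (length(groups) == 2) {
      tt <- t.test(groups[[1]], groups[[2]], paired = paired, var.equal = FALSE)
      test <- tibble::tibble(
        method = if (paired) "paired-t" else "welch-t",
        statistic = unname(tt$statistic), p_value = tt$p.value
      )
    } else {
      df <- data.frame(
        value = pooled,
        group = factor(rep(names(groups), times = sizes))
      )
      fit <- aov(value ~ group, data = df)
      an <- summary(fit)[[1]]
      test <- tibble::tibble(method = "anova",
                             statistic = an[["F value"]][1],
                             p_value = an[["Pr(>F)"]][1])
      tk <- TukeyHSD(fit)$group
      posthoc <- tibble::tibble(
        comparison = rownames(tk),
        diff = tk[, "diff"], ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
    }
  } else {
    branch <- "nonparametric"
    if (length(groups) == 2) {
      if (paired) {
        wt <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]], paired = TRUE))
        test <- tibble::tibble(method = "wilcoxon-signed-rank",
                               statistic = unname(wt$statistic),
                               p_value = wt$p.value)
      } else {
        wr <- wilcoxon_rank_sum(groups[[1]], groups[[2]])
        test <- tibble::tibble(method = "wilcoxon-rank-sum",
                               statistic = wr$statistic, p_value = wr$p_value)
      }
    } else {
      kw <- kruskal.test(groups)
      test <- tibble::tibble(method = "kruskal-wallis",
                             statistic = unname(kw$statistic),
                             p_value = kw$p.value)
      posthoc <- dunn_posthoc(groups)
    }
  }
  structure(
    list(test = test, posthoc = posthoc, normality = normality,
         branch = branch, sizes = sizes),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s branch: %s, statistic = %.4g, p = %.4g\n",
              x$branch, x$test$method, x$test$statistic, x$test$p_value))
  if (!is.null(x$posthoc)) {
    cat(sprintf("post-hoc: %d pairwise comparisons\n", nrow(x$posthoc)))
  }
  invisible(x)
}

# Dunn's z post-hoc on midranks with tie correction; BH-adjusted.
dunn_posthoc <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), times = lengths(groups)),
              levels = names(groups))
  r <- rank(pooled)
  n_tot <- length(pooled)
  mean_rank <- tapply(r, g, mean)
  n_i <- tapply(r, g, length)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- combn(names(groups), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / n_i[[i]] + 1 / n_i[[j]]))
    z[k] <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  tibble::tibble(
    comparison = paste(pairs[1, ], pairs[2, ], sep = "-"),
    z = z, p_value = p_raw, p_adj = bh_adjust(p_raw)
  )
}
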