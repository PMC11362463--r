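# Jonckheere-Terpstra trend test against an ordered alternative.
#
# The statistic is the sum over ordered group pairs (i < j) of Mann-Whitney
# counts U_ij = #\{x in group i, y in group j : x < y\} + 0.5 * #ties.
# Large values support means increasing along the group order.

jt_statistic <- function(values, group_idx) {
  k <- length(group_idx)
  J <- 0
  for (i in seq_len(k - 1)) {
    vi <- values[group_idx[[i]]]
    for (j in (i + 1):k) {
      vj <- values[group_idx[[j]]]
      cmp <- outer(vi, vj, "<")
      tie <- outer(vi, vj, "==")
      J <- J + sum(cmp) + 0.5 * sum(tie)
    }
  }
  J
}

# Null mean and tie-corrected variance (Hollander & Wolfe).
jt_null_moments <- function(values, sizes) {
  n_tot <- sum(sizes)
  mu <- (n_tot^2 - sum(sizes^2)) / 4
  t_j <- as.numeric(table(values))
  A <- n_tot * (n_tot - 1) * (2 * n_tot + 5) -
    sum(sizes * (sizes - 1) * (2 * sizes + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  B <- sum(sizes * (sizes - 1) * (sizes - 2)) *
    sum(t_j * (t_j - 1) * (t_j - 2))
  C <- sum(sizes * (sizes - 1)) * sum(t_j * (t_j - 1))
  v <- A / 72 +
    B / (36 * n_tot * (n_tot - 1) * (n_tot - 2)) +
    C / (8 * n_tot * (n_tot - 1))
  list(mean = mu, var = v)
}

# All distinct assignments of `items` into ordered groups of given sizes.
enumerate_assignments <- function(items, sizes) {
  if (length(sizes) == 1L) {
    return(list(list(items)))
  }
  out <- list()
  for (f in combn(items, sizes[1], simplify = FALSE)) {
    rest <- enumerate_assignments(setdiff(items, f), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(list(f), r)))
  }
  out
}

#' Jonckheere-Terpstra test for an increasing ordered trend
#'
#' One-sided test of the null of exchangeable groups against the alternative
#' that location increases along the given group order. Uses exhaustive
#' permutation enumeration when the total sample size is at most
#' `exact_n_max`, otherwise the normal approximation with tie-corrected
#' variance.
#'
#' @param values Numeric vector of observations.
#' @param groups Ordered factor (or vector coercible to one) giving each
#'   observation's group; factor level order defines the trend direction.
#' @param exact_n_max Exact enumeration threshold on the total n.
#' @return One-row tibble: `statistic`, `z`, `p_value`, `method`
#'   ("exact-permutation" or "normal-approx"), `n`.
#' @export
#' @examples
#' jonckheere_test(c(1, 2, 4, 5, 8, 9), rep(c("a", "b", "c"), each = 2))
jonckheere_test <- function(values, groups, exact_n_max = 12) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 3) {
    abort_hcc("At least 3 ordered groups are required for the trend test.",
              "hccdriver_error_bad_argument")
  }
  if (length(values) != length(groups) || anyNA(values)) {
    abort_hcc("`values` must align with `groups` and contain no NAs.",
              "hccdriver_error_bad_argument")
  }
  group_idx <- split(seq_along(values), groups)
  sizes <- lengths(group_idx)
  n_tot <- length(values)
  J <- jt_statistic(values, group_idx)
  mom <- jt_null_moments(values, sizes)
  z <- if (mom$var > 0) (J - mom$mean) / sqrt(mom$var) else 0

  if (n_tot <= exact_n_max) {
    assigns <- enumerate_assignments(seq_len(n_tot), sizes)
    J_all <- vapply(assigns, function(a) jt_statistic(values, a), numeric(1))
    p <- mean(J_all >= J - 1e-9)
    method <- "exact-permutation"
  } else {
    p <- if (mom$var > 0) pnorm(z, lower.tail = FALSE) else 1
    method <- "normal-approx"
  }
  tibble::tibble(statistic = J, z = z, p_value = p, method = method,
                 n = n_tot)
}

# Batch JT over the rows of a genes-x-samples matrix sharing one stage
# layout. Returns J, z and p per gene; exact enumeration is applied
# uniformly when total n <= exact_n_max.
jt_batch <- function(expr, groups, exact_n_max = 12) {
  groups <- droplevels(as.factor(groups))
  group_idx <- split(seq_len(ncol(expr)), groups)
  sizes <- lengths(group_idx)
  n_tot <- ncol(expr)
  k <- length(group_idx)
  n_genes <- nrow(expr)

  J <- numeric(n_genes)
  for (i in seq_len(k - 1)) {
    A <- expr[, group_idx[[i]], drop = FALSE]
    for (j in (i + 1):k) {
      B <- expr[, group_idx[[j]], drop = FALSE]
      for (a in seq_len(ncol(A))) {
        va <- A[, a]
        for (b in seq_len(ncol(B))) {
          vb <- B[, b]
          J <- J + (va < vb) + 0.5 * (va == vb)
        }
      }
    }
  }

  # tie-free moments; genes with ties get corrected individually
  mu <- (n_tot^2 - sum(sizes^2)) / 4
  var0 <- (n_tot^2 * (2 * n_tot + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
  vars <- rep(var0, n_genes)
  has_ties <- apply(expr, 1, anyDuplicated) > 0
  for (g in which(has_ties)) {
    vars[g] <- jt_null_moments(expr[g, ], sizes)$var
  }
  J <- unname(J)
  z <- ifelse(vars > 0, (J - mu) / sqrt(vars), 0)

  if (n_tot <= exact_n_max) {
    assigns <- enumerate_assignments(seq_len(n_tot), sizes)
    p <- vapply(seq_len(n_genes), function(g) {
      J_all <- vapply(assigns, function(a) jt_statistic(expr[g, ], a),
                      numeric(1))
      mean(J_all >= J[g] - 1e-9)
    }, numeric(1))
  } else {
    p <- ifelse(vars > 0, pnorm(z, lower.tail = FALSE), 1)
  }
  tibble::tibble(gene = rownames(expr), statistic = J, z = z, p_value = p)
}
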