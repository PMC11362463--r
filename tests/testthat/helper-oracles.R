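# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition, without touching the package internals.

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (perm in all_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(perm, n, after = pos - 1L)
    }
  }
  out
}

# Jonckheere-Terpstra statistic straight from the definition
oracle_jt_stat <- function(values, group_sizes) {
  ends <- cumsum(group_sizes)
  starts <- c(1, head(ends, -1) + 1)
  J <- 0
  for (i in seq_along(group_sizes)) {
    for (j in seq_along(group_sizes)) {
      if (i >= j) next
      for (a in starts[i]:ends[i]) {
        for (b in starts[j]:ends[j]) {
          if (values[a] < values[b]) J <- J + 1
          if (values[a] == values[b]) J <- J + 0.5
        }
      }
    }
  }
  J
}

# exact one-sided (increasing) JT p by exhaustive permutation of the values
oracle_jt_exact_p <- function(values, group_sizes) {
  obs <- oracle_jt_stat(values, group_sizes)
  perms <- all_permutations(length(values))
  js <- vapply(perms, function(p) oracle_jt_stat(values[p], group_sizes),
               numeric(1))
  mean(js >= obs - 1e-9)
}

# exact two-sided Wilcoxon rank-sum p by enumeration of all assignments
oracle_wilcox_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(idx_a) {
    xa <- pooled[idx_a]
    xb <- pooled[-idx_a]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  us <- vapply(combn(n, na, simplify = FALSE), u_of, numeric(1))
  p_ge <- mean(us >= u_obs - 1e-9)
  p_le <- mean(us <= u_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# AUC as the concordant-pair fraction (half credit for ties)
oracle_auc <- function(scores, labels, positive, lower_is_positive = FALSE) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (lower_is_positive) {
    conc <- sum(outer(pos, neg, "<")) + 0.5 * sum(outer(pos, neg, "=="))
  } else {
    conc <- sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))
  }
  conc / (length(pos) * length(neg))
}

# weighted running-sum enrichment score, re-derived step by step
oracle_gsea_es <- function(genes, scores, gene_set, weight) {
  n <- length(genes)
  hit <- genes %in% gene_set
  nr <- sum(abs(scores[hit])^weight)
  steps <- numeric(n)
  for (i in seq_len(n)) {
    steps[i] <- if (hit[i]) {
      if (nr == 0) 1 / sum(hit) else abs(scores[i])^weight / nr
    } else {
      -1 / (n - sum(hit))
    }
  }
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

# ssGSEA score, re-derived: weighted in-set ECDF minus uniform out-of-set
oracle_ssgsea <- function(profile, gene_set, weight) {
  ord <- order(-profile, names(profile))
  genes <- names(profile)[ord]
  n <- length(genes)
  rank_val <- n:1
  hit <- genes %in% gene_set
  denom <- sum(rank_val[hit]^weight)
  n_out <- n - sum(hit)
  total <- 0
  acc_in <- 0
  acc_out <- 0
  for (i in seq_len(n)) {
    if (hit[i]) acc_in <- acc_in + rank_val[i]^weight else acc_out <- acc_out + 1
    total <- total + acc_in / denom - acc_out / n_out
  }
  total
}

# two-group log-rank chi-square from the risk table at each event time
oracle_logrank_chi2 <- function(time, event, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2)
  event_times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == groups[1])
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == groups[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# convenience: a tiny deterministic staged cohort with one planted trend gene
tiny_trend_cohort <- function(noise = 0, seed = 42) {
  withr::with_seed(seed, {
    stages <- c("NL", "LC", "aHCC")
    stage_vec <- rep(stages, each = 3)
    flat <- rep(5, 9)
    rising <- rep(c(4, 6, 8), each = 3)
    falling <- rep(c(8, 6, 4), each = 3)
    expr <- rbind(
      rising = rising + rnorm(9, 0, noise),
      flat = flat + rnorm(9, 0, noise),
      falling = falling + rnorm(9, 0, noise)
    )
    colnames(expr) <- sprintf("s%d", 1:9)
    stage_dataset(expr, stage_vec, "tiny", stage_levels = stages)
  })
}
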