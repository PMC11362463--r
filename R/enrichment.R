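#' Order genes by descending log2 fold change
#'
#' The ranking step feeding preranked GSEA: genes sorted by decreasing
#' `log2fc`, ties broken lexicographically by gene identifier (stable and
#' input-order invariant).
#'
#' @param de_table Tibble with `gene` and `log2fc` columns (one row per
#'   gene), e.g. from [compute_de()].
#' @return Tibble `gene`, `score` ordered as described.
#' @export
rank_genes_by_log2fc <- function(de_table) {
  if (anyDuplicated(de_table$gene)) {
    abort_hcc("Duplicate gene entries in the DE table.",
              "hccdriver_error_duplicate_genes")
  }
  if (anyNA(de_table$log2fc)) {
    abort_hcc("`log2fc` must be present for every gene.",
              "hccdriver_error_missing_values")
  }
  de_table %>%
    dplyr::transmute(gene = .data$gene, score = .data$log2fc) %>%
    dplyr::arrange(dplyr::desc(.data$score), .data$gene)
}

# Weighted Kolmogorov-Smirnov running sum for an ordered scored ranking.
# Hit steps are |score|^weight normalised to sum 1; miss steps are
# 1/(N - n_hits). Returns the running sum, signed extremum and its position.
gsea_running_sum <- function(scores, is_hit, weight) {
  n <- length(scores)
  n_hit <- sum(is_hit)
  hit_w <- abs(scores)^weight * is_hit
  denom <- sum(hit_w)
  if (denom == 0) hit_w[is_hit] <- 1 / n_hit else hit_w <- hit_w / denom
  miss_w <- (!is_hit) / (n - n_hit)
  rs <- cumsum(hit_w - miss_w)
  pos <- which.max(abs(rs))
  list(running_sum = rs, es = rs[pos], pos = pos)
}

#' Preranked gene-set enrichment (weighted running-sum ES)
#'
#' Classic weighted Kolmogorov-Smirnov enrichment of a gene set in a ranked,
#' scored gene list. The p-value comes from seeded gene-label permutations
#' (random sets of the same size); the normalised ES divides by the mean
#' |permuted ES| of matching sign and is `NA` when fewer than 10 matching-
#' sign permutations exist.
#'
#' @param ranking Tibble `gene`, `score` from [rank_genes_by_log2fc()] (must
#'   already be ordered).
#' @param gene_set Character vector of gene identifiers.
#' @param weight Score-weighting exponent (canonical 1).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed for the permutations.
#' @return One-row `hcc_gsea` tibble: `es`, `nes`, `p_value`, `n_hits`,
#'   `leading_edge` (list-column). The running sum is attached as attribute
#'   `running_sum` for plotting.
#' @export
preranked_gsea <- function(ranking, gene_set, weight = 1, n_perm = 1000,
                           seed) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  check_number(weight, "weight", lower = 0)
  seed <- check_seed(seed)
  genes <- ranking$gene
  scores <- ranking$score
  is_hit <- genes %in% gene_set
  n_hit <- sum(is_hit)
  if (n_hit == 0) {
    abort_hcc("The gene set does not overlap the ranking.",
              "hccdriver_error_empty_overlap")
  }
  if (n_hit == length(genes)) {
    abort_hcc("The gene set equals the whole ranking; enrichment is undefined.",
              "hccdriver_error_degenerate_set")
  }

  obs <- gsea_running_sum(scores, is_hit, weight)
  es <- obs$es

  perm_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      hit_i <- logical(length(genes))
      hit_i[sample.int(length(genes), n_hit)] <- TRUE
      gsea_running_sum(scores, hit_i, weight)$es
    }, numeric(1))
  })
  same_sign <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  p <- if (length(same_sign)) {
    extreme <- if (es >= 0) sum(same_sign >= es) else sum(same_sign <= es)
    (1 + extreme) / (1 + length(same_sign))
  } else {
    1 / (1 + n_perm)
  }
  nes <- if (length(same_sign) >= 10) es / mean(abs(same_sign)) else NA_real_

  leading <- if (es >= 0) {
    genes[seq_len(obs$pos)][is_hit[seq_len(obs$pos)]]
  } else {
    idx <- obs$pos:length(genes)
    genes[idx][is_hit[idx]]
  }
  out <- tibble::tibble(
    es = es, nes = nes, p_value = p, n_hits = n_hit,
    leading_edge = list(leading)
  )
  attr(out, "running_sum") <- obs$running_sum
  class(out) <- c("hcc_gsea", class(out))
  out
}

#' Single-sample GSEA score of a gene set in one expression profile
#'
#' Rank-based ssGSEA: genes are ranked by expression (descending; ties broken
#' by gene name), in-set positions contribute `rank^weight` to a weighted
#' empirical CDF, out-of-set positions contribute uniformly, and the score is
#' the sum of the CDF difference over all positions. Deterministic and
#' invariant under strictly monotone transforms of the profile.
#'
#' @param profile Named numeric vector of one sample's expression.
#' @param gene_set Character vector of gene identifiers.
#' @param weight Rank-weighting exponent (canonical ssGSEA value 0.25).
#' @return A single numeric score.
#' @export
ssgsea_score <- function(profile, gene_set, weight = 0.25) {
  if (is.null(names(profile)) || anyNA(profile)) {
    abort_hcc("`profile` must be a named numeric vector without NAs.",
              "hccdriver_error_bad_argument")
  }
  ord <- order(-profile, names(profile))
  genes <- names(profile)[ord]
  n <- length(genes)
  is_hit <- genes %in% gene_set
  if (!any(is_hit)) {
    abort_hcc("The gene set does not overlap the profile.",
              "hccdriver_error_empty_overlap")
  }
  rank_val <- n - seq_len(n) + 1          # top gene carries the largest rank
  hit_w <- rank_val^weight * is_hit
  p_in <- cumsum(hit_w) / sum(hit_w)
  n_out <- n - sum(is_hit)
  p_out <- if (n_out > 0) cumsum(!is_hit) / n_out else rep(0, n)
  sum(p_in - p_out)
}

#' ssGSEA scores for a collection of sets across samples
#'
#' @param expr Genes-by-samples numeric matrix.
#' @param collection Named list of gene-identifier vectors (see
#'   [read_gmt()]).
#' @param weight Rank-weighting exponent.
#' @param normalize Rescale all scores by the range across the whole
#'   matrix of scores (the usual cross-sample normalisation); default off,
#'   reporting raw scores.
#' @return Tibble `set`, `sample`, `score`.
#' @export
ssgsea_scores <- function(expr, collection, weight = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  res <- purrr::map_dfr(names(collection), function(set_name) {
    tibble::tibble(
      set = set_name,
      sample = colnames(expr),
      score = vapply(seq_len(ncol(expr)), function(j) {
        ssgsea_score(stats::setNames(expr[, j], rownames(expr)),
                     collection[[set_name]], weight = weight)
      }, numeric(1))
    )
  })
  if (normalize && nrow(res)) {
    rng <- diff(range(res$score))
    if (rng > 0) res$score <- res$score / rng
  }
  res
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail probability of observing at least the seen overlap
#' between a hit list and a gene set inside a finite universe.
#'
#' @param hit_list Character vector of hits (must lie inside `universe`).
#' @param gene_set Character vector; only its intersection with `universe`
#'   counts.
#' @param universe Character vector of all assayed genes.
#' @return One-row tibble: `overlap`, `n_hits`, `n_set`, `n_universe`,
#'   `p_value`.
#' @export
ora_hypergeometric <- function(hit_list, gene_set, universe) {
  hit_list <- unique(hit_list)
  universe <- unique(universe)
  outside <- setdiff(hit_list, universe)
  if (length(outside)) {
    abort_hcc(sprintf("Hits outside the universe: %s.",
                      paste(head(outside, 5), collapse = ", ")),
              "hccdriver_error_outside_universe")
  }
  set_in <- intersect(unique(gene_set), universe)
  if (!length(set_in)) {
    abort_hcc("The gene set does not intersect the universe.",
              "hccdriver_error_empty_overlap")
  }
  k <- length(intersect(hit_list, set_in))
  tibble::tibble(
    overlap = k,
    n_hits = length(hit_list),
    n_set = length(set_in),
    n_universe = length(universe),
    p_value = phyper(k - 1, length(set_in),
                     length(universe) - length(set_in),
                     length(hit_list), lower.tail = FALSE)
  )
}

#' Over-representation across a gene-set collection, BH-adjusted
#'
#' @inheritParams ora_hypergeometric
#' @param collection Named list of gene sets.
#' @return Tibble with one row per set plus a BH `q_value` column.
#' @export
ora_collection <- function(hit_list, collection, universe) {
  res <- purrr::map_dfr(names(collection), function(nm) {
    dplyr::mutate(ora_hypergeometric(hit_list, collection[[nm]], universe),
                  set = nm, .before = 1)
  })
  dplyr::mutate(res, q_value = bh_adjust(.data$p_value))
}

#' Compare ssGSEA scores between stratified sample groups
#'
#' Wilcoxon rank-sum test of each set's scores between the high and low
#' strata (mid samples are ignored), BH-adjusted across sets.
#'
#' @param scores Tibble `set`, `sample`, `score` from [ssgsea_scores()].
#' @param strata Tibble `sample`, `stratum` (e.g. from
#'   [stratify_quartiles()]) or a named stratum vector.
#' @param high,low Stratum labels to compare.
#' @return Tibble: `set`, `statistic`, `p_value`, `q_value`, `n_high`,
#'   `n_low`.
#' @export
compare_ssgsea_groups <- function(scores, strata, high = "high", low = "low") {
  if (is.data.frame(strata)) {
    strata <- stats::setNames(as.character(strata$stratum), strata$sample)
  }
  lab <- strata[scores$sample]
  if (anyNA(lab)) {
    abort_hcc("Every scored sample needs a stratum label.",
              "hccdriver_error_missing_group")
  }
  scores <- dplyr::mutate(scores, stratum = unname(lab))
  if (!any(scores$stratum == high) || !any(scores$stratum == low)) {
    abort_hcc("Both compared strata must be present.",
              "hccdriver_error_missing_group")
  }
  res <- scores %>%
    dplyr::filter(.data$stratum %in% c(high, low)) %>%
    dplyr::group_by(.data$set) %>%
    dplyr::group_modify(function(df, key) {
      a <- df$score[df$stratum == high]
      b <- df$score[df$stratum == low]
      if (length(a) < 2 || length(b) < 2) {
        abort_hcc("Each compared stratum needs >= 2 samples per set.",
                  "hccdriver_error_small_group")
      }
      wr <- wilcoxon_rank_sum(a, b)
      tibble::tibble(statistic = wr$statistic, p_value = wr$p_value,
                     n_high = length(a), n_low = length(b))
    }) %>%
    dplyr::ungroup()
  dplyr::mutate(res, q_value = bh_adjust(.data$p_value))
}
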