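test_that("log2fc ranking sorts descending with lexicographic ties", {
  de <- tibble::tibble(gene = c("b", "a", "c", "d"),
                       log2fc = c(2, 3, 2, -1))
  rk <- rank_genes_by_log2fc(de)
  expect_equal(rk$gene, c("a", "b", "c", "d"))
  expect_equal(rank_genes_by_log2fc(de[4:1, ]), rk)   # order invariance
  expect_error(rank_genes_by_log2fc(tibble::tibble(gene = c("a", "a"),
                                                   log2fc = c(1, 2))),
               class = "hccdriver_error_duplicate_genes")
})

test_that("preranked ES matches hand-enumerated running sums", {
  # 4 genes, equal scores, weight 0, set at the top:
  # steps +1/2, +1/2, -1/2, -1/2 -> extremum 1 at position 2
  rk <- tibble::tibble(gene = c("a", "b", "c", "d"), score = c(1, 1, 1, 1))
  res <- preranked_gsea(rk, c("a", "b"), weight = 0, n_perm = 100, seed = 1)
  expect_equal(res$es, 1)
  expect_equal(res$leading_edge[[1]], c("a", "b"))

  withr::with_seed(2, {
    for (i in 1:20) {
      n <- sample(5:10, 1)
      genes <- paste0("g", seq_len(n))
      scores <- sort(round(rnorm(n, 0, 2), 4), decreasing = TRUE)
      set <- sample(genes, sample(1:(n - 1), 1))
      w <- sample(c(0, 0.5, 1, 1.5), 1)
      got <- preranked_gsea(tibble::tibble(gene = genes, score = scores),
                            set, weight = w, n_perm = 100, seed = i)
      expect_equal(got$es, oracle_gsea_es(genes, scores, set, w),
                   tolerance = 1e-12)
      expect_lte(abs(got$es), 1)
    }
  })
})

test_that("ES of the complement mirrors the set on equal-weight rankings", {
  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(4:8, 1)
      genes <- paste0("g", seq_len(n))
      scores <- rep(1, n)
      k <- sample(1:(n - 1), 1)
      set <- sample(genes, k)
      rk <- tibble::tibble(gene = genes, score = scores)
      es_set <- preranked_gsea(rk, set, weight = 0, n_perm = 100, seed = 1)$es
      es_comp <- preranked_gsea(rk, setdiff(genes, set), weight = 0,
                                n_perm = 100, seed = 1)$es
      expect_equal(es_comp, -es_set, tolerance = 1e-12)
    }
  })
})

test_that("a top-ranked singleton set outscores a bottom-ranked one", {
  rk <- tibble::tibble(gene = paste0("g", 1:10), score = 10:1)
  top <- preranked_gsea(rk, "g1", n_perm = 100, seed = 1)$es
  bottom <- preranked_gsea(rk, "g10", n_perm = 100, seed = 1)$es
  expect_gt(top, bottom)
  expect_error(preranked_gsea(rk, "absent", n_perm = 100, seed = 1),
               class = "hccdriver_error_empty_overlap")
  expect_error(preranked_gsea(rk, rk$gene, n_perm = 100, seed = 1),
               class = "hccdriver_error_degenerate_set")
})

test_that("permutation p-values are reproducible and null-calibrated", {
  rk <- tibble::tibble(gene = paste0("g", 1:40),
                       score = withr::with_seed(4, rnorm(40)))
  a <- preranked_gsea(rk, paste0("g", 1:5), n_perm = 200, seed = 7)
  b <- preranked_gsea(rk, paste0("g", 1:5), n_perm = 200, seed = 7)
  expect_identical(a$p_value, b$p_value)

  withr::with_seed(5, {
    ps <- replicate(100, {
      set <- sample(rk$gene, 6)
      preranked_gsea(rk, set, n_perm = 100,
                     seed = sample.int(1e6, 1))$p_value
    })
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("ssGSEA matches the hand-evaluated running sum and is rank-based", {
  profile <- c(a = 5, b = 4, c = 3, d = 2, e = 1)
  set <- c("a", "c")
  expect_equal(ssgsea_score(profile, set, weight = 0.25),
               oracle_ssgsea(profile, set, 0.25), tolerance = 1e-12)

  withr::with_seed(6, {
    for (i in 1:10) {
      n <- sample(5:10, 1)
      prof <- setNames(round(rnorm(n), 4), paste0("g", seq_len(n)))
      st <- sample(names(prof), sample(1:(n - 1), 1))
      w <- sample(c(0.25, 1), 1)
      expect_equal(ssgsea_score(prof, st, w), oracle_ssgsea(prof, st, w),
                   tolerance = 1e-12)
      # invariance under a strictly monotone transform
      expect_equal(ssgsea_score(exp(prof), st, w), ssgsea_score(prof, st, w))
    }
  })

  # joint relabeling of profile and set leaves the score unchanged
  perm <- c(a = "x", b = "y", c = "z", d = "u", e = "v")
  prof2 <- setNames(profile, perm[names(profile)])
  expect_equal(ssgsea_score(prof2, perm[set], 0.25),
               ssgsea_score(profile, set, 0.25))
  # the top gene beats the bottom gene as a singleton set
  expect_gt(ssgsea_score(profile, "a"), ssgsea_score(profile, "e"))
  expect_error(ssgsea_score(profile, "zz"),
               class = "hccdriver_error_empty_overlap")
})

test_that("hypergeometric over-representation matches combinatorics", {
  u <- paste0("g", 1:10)
  expect_equal(ora_hypergeometric(u[1:5], u[1:5], u)$p_value, 1 / choose(10, 5))
  expect_equal(ora_hypergeometric(u[1:3], u[4:6], u)$p_value, 1)
  expect_equal(ora_hypergeometric(u[1:4], u, u)$p_value, 1)
  expect_error(ora_hypergeometric(c("zz"), u[1:2], u),
               class = "hccdriver_error_outside_universe")
  coll <- ora_collection(u[1:3], list(s1 = u[1:3], s2 = u[8:10]), u)
  expect_true(all(coll$q_value >= coll$p_value))
})

test_that("ssGSEA group comparison flags planted sets and respects the null", {
  withr::with_seed(7, {
    genes <- paste0("g", 1:60)
    planted <- genes[1:10]
    samples <- paste0("s", 1:16)
    strata <- tibble::tibble(
      sample = samples,
      stratum = rep(c("high", "mid", "low"), c(6, 4, 6))
    )
    expr <- matrix(rnorm(60 * 16), 60, 16, dimnames = list(genes, samples))
    expr[planted, strata$stratum == "high"] <-
      expr[planted, strata$stratum == "high"] + 3
    scores <- ssgsea_scores(expr, list(planted = planted,
                                       null = genes[40:50]))
    res <- compare_ssgsea_groups(scores, strata)
    expect_lt(res$q_value[res$set == "planted"], 0.05)
    expect_gt(res$p_value[res$set == "null"], 0.05)

    # identical score vectors: nothing is significant
    flat <- dplyr::mutate(scores, score = 1)
    res_flat <- compare_ssgsea_groups(flat, strata)
    expect_true(all(res_flat$p_value == 1))
  })
  expect_error(
    compare_ssgsea_groups(
      tibble::tibble(set = "s", sample = c("a", "b"), score = 1:2),
      tibble::tibble(sample = c("a", "b"), stratum = c("mid", "mid"))
    ),
    class = "hccdriver_error_missing_group"
  )
})
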