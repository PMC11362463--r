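test_that("exact Jonckheere p equals exhaustive permutation of the values", {
  withr::with_seed(21, {
    cases <- list(
      list(sizes = c(2L, 2L, 2L), values = round(rnorm(6), 4)),
      list(sizes = c(2L, 2L, 2L), values = c(1, 1, 2, 2, 3, 3)),   # ties
      list(sizes = c(3L, 2L, 2L), values = round(rnorm(7, 1:7 / 3), 4)),
      list(sizes = c(2L, 3L, 2L), values = round(rexp(7), 4))
    )
  })
  for (cs in cases) {
    groups <- factor(rep(seq_along(cs$sizes), times = cs$sizes))
    got <- jonckheere_test(cs$values, groups)
    expect_equal(got$method, "exact-permutation")
    expect_equal(got$statistic, oracle_jt_stat(cs$values, cs$sizes))
    expect_equal(got$p_value, oracle_jt_exact_p(cs$values, cs$sizes),
                 tolerance = 1e-12)
  }
})

test_that("the batch trend scorer agrees with the scalar test", {
  withr::with_seed(22, {
    expr <- matrix(rnorm(5 * 15), 5, 15,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:15)))
    groups <- factor(rep(c("A", "B", "C"), each = 5),
                     levels = c("A", "B", "C"), ordered = TRUE)
    batch <- hccdriver:::jt_batch(expr, groups)
    for (g in 1:5) {
      single <- jonckheere_test(expr[g, ], groups)
      expect_equal(batch$statistic[g], single$statistic)
      expect_equal(batch$p_value[g], single$p_value, tolerance = 1e-12)
    }
  })
})

test_that("trend gates pass a clean ladder and reject flat or falling genes", {
  co <- tiny_trend_cohort(noise = 0.05)
  tr <- trend_score(co)
  tr <- tr[match(c("rising", "flat", "falling"), tr$gene), ]
  expect_true(tr$monotone_pass[1])
  expect_lt(tr$p[1], 0.01)
  expect_false(tr$monotone_pass[2])     # span gate
  expect_false(tr$monotone_pass[3])     # wrong direction
  expect_gte(tr$p[3], 0.5)
  expect_error(trend_score(co, genes = "absent"),
               class = "hccdriver_error_unknown_gene")
})

test_that("differential expression applies both the FDR and fold-change gates", {
  withr::with_seed(23, {
    expr <- matrix(rnorm(100 * 20, 5, 0.3), 100, 20,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:20)))
    groups <- rep(c("T", "N"), each = 10)
    # identical distributions: no DEGs expected
    de_null <- compute_de(expr, group_a = "T", group_b = "N", groups = groups)
    expect_equal(sum(de_null$deg), 0)

    # planted 1-log2 shift is recovered
    expr_sig <- expr
    expr_sig["g001", groups == "T"] <- expr_sig["g001", groups == "T"] + 1
    de <- compute_de(expr_sig, group_a = "T", group_b = "N", groups = groups)
    expect_true(de$deg[de$gene == "g001"])
    expect_equal(unname(de$direction[de$gene == "g001"]), "up")
    expect_true(all(de$p_adj >= de$p))
  })

  # a fold change below the gate is never flagged, however significant
  base <- matrix(rep(c(5, 5 + log2(1.4)), each = 8), nrow = 1)
  expr2 <- base + matrix(rnorm(16, 0, 1e-4), 1, 16)
  dimnames(expr2) <- list("g1", paste0("s", 1:16))
  de2 <- compute_de(expr2, group_a = "T", group_b = "N",
                    groups = rep(c("N", "T"), each = 8))
  expect_lt(de2$p_adj, 1e-9)
  expect_false(de2$deg)
  expect_true(compute_de(expr2, group_a = "T", group_b = "N",
                         groups = rep(c("N", "T"), each = 8),
                         fc_threshold = 1.3)$deg)
})

test_that("DEG sets are monotone in the gates", {
  withr::with_seed(24, {
    sim <- generate_multistage_cohorts(n_cohorts = 1, n_genes = 300,
                                       n_drivers = 30, samples_per_stage = 5,
                                       seed = 99)
    co <- sim$cohorts[[1]]
    strict <- compute_de(co, fc_threshold = 2, alpha = 0.01)
    loose <- compute_de(co, fc_threshold = 1.2, alpha = 0.1)
    expect_true(all(strict$gene[strict$deg] %in% loose$gene[loose$deg]))
  })
})

test_that("DEG consensus requires joint significance and direction agreement", {
  tb <- function(genes, dirs, deg = TRUE) {
    tibble::tibble(gene = genes, log2fc = ifelse(dirs == "up", 1, -1),
                   p = 0.001, p_adj = 0.01, direction = dirs, deg = deg)
  }
  one <- tb(c("a", "b"), c("up", "down"))
  expect_equal(consensus_degs(list(one)), c("a", "b"))
  expect_equal(consensus_degs(list(tb("a", "up"), tb("b", "up"))), character(0))
  expect_equal(consensus_degs(list(tb("a", "up"), tb("a", "down"))),
               character(0))
  expect_equal(consensus_degs(list(tb(c("a", "b"), c("up", "up")),
                                   tb(c("b", "a"), c("up", "up")))),
               c("a", "b"))
  expect_error(consensus_degs(list()), class = "hccdriver_error_empty_input")
})

test_that("trend consensus honours the quorum and ordering rules", {
  mk <- function(gene, pass, z, cohort) {
    tibble::tibble(gene = gene, cohort_id = cohort, jt_statistic = 1,
                   jt_z = z, p = 0.01, q = 0.01,
                   stage_means = list(c(a = 1)), span = 1,
                   monotone_pass = pass)
  }
  t1 <- dplyr::bind_rows(mk("a", TRUE, 3, "c1"), mk("b", TRUE, 2, "c1"))
  t2 <- dplyr::bind_rows(mk("a", TRUE, 2, "c2"), mk("b", FALSE, 2, "c2"))
  t3 <- dplyr::bind_rows(mk("a", TRUE, 4, "c3"), mk("b", TRUE, 2, "c3"))

  solo <- consensus_trend(list(t1))
  expect_equal(solo$gene, c("a", "b"))
  all3 <- consensus_trend(list(t1, t2, t3))
  expect_equal(all3$gene, "a")                 # b passes only 2 of 3
  quorum <- consensus_trend(list(t1, t2, t3), require_all = FALSE, quorum = 2)
  expect_equal(quorum$gene, c("a", "b"))
  # tie on mean z breaks lexicographically
  t4 <- dplyr::bind_rows(mk("z", TRUE, 3, "c1"), mk("y", TRUE, 3, "c1"))
  expect_equal(consensus_trend(list(t4))$gene, c("y", "z"))
  expect_error(consensus_trend(list()), class = "hccdriver_error_empty_input")
})

test_that("the cascade is invariant to row/column order and idempotent", {
  sim <- generate_multistage_cohorts(n_cohorts = 2, n_genes = 120,
                                     n_drivers = 8, samples_per_stage = 5,
                                     seed = 31)
  base <- run_cascade(sim$cohorts, sim$cohorts)
  expect_identical(base$final$gene, base$trend_a_consensus$gene)

  withr::with_seed(32, {
    shuffled <- lapply(sim$cohorts, function(co) {
      gi <- sample(nrow(co$expression))
      si <- sample(ncol(co$expression))
      stage_dataset(co$expression[gi, si],
                    as.character(co$samples$stage)[si],
                    co$cohort_id)
    })
  })
  shuf <- run_cascade(shuffled, shuffled)
  expect_equal(shuf$final, base$final)
  expect_equal(sort(shuf$consensus_deg_genes), sort(base$consensus_deg_genes))
})

test_that("a null configuration yields an empty final list", {
  sim0 <- generate_multistage_cohorts(n_cohorts = 3, n_genes = 400,
                                      n_drivers = 0, per_stage_shift = 0,
                                      samples_per_stage = 5, seed = 33)
  cas <- run_cascade(sim0$cohorts, sim0$cohorts)
  expect_equal(nrow(cas$final), 0)
  gl <- generics::glance(cas)
  expect_equal(gl$n_final, 0)
})
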