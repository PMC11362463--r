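make_cells <- function(counts, samples) {
  tibble::tibble(cell = rownames(counts), sample = samples,
                 phenotype = rep("x", nrow(counts)))
}

test_that("pseudo-bulk aggregation sums counts and conserves the total", {
  counts <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                   dimnames = list(c("c1", "c2", "c3"), c("gA", "gB")))
  cells <- make_cells(counts, c("s1", "s1", "s2"))
  agg <- aggregate_expression(counts, cells)
  expect_equal(agg["s1", ], c(gA = 4, gB = 6))
  expect_equal(agg["s2", ], c(gA = 5, gB = 6))
  expect_equal(sum(agg), sum(counts))

  # one cell per sample: identity
  solo <- make_cells(counts, c("a", "b", "c"))
  agg1 <- aggregate_expression(counts, solo)
  expect_equal(agg1[c("a", "b", "c"), ], unname(counts), ignore_attr = TRUE)

  # additivity over arbitrary splits of a sample's cells
  sc <- generate_sc_counts(n_samples = 3, cells_per_sample = 10,
                           n_genes = 8, seed = 41)
  whole <- aggregate_expression(sc$counts, sc$cells)
  half1 <- sc$cells[1:15, ]
  half2 <- sc$cells[16:30, ]
  part <- aggregate_expression(sc$counts[half1$cell, ], half1)
  part2 <- aggregate_expression(sc$counts[half2$cell, ], half2)
  merged <- part
  for (s in rownames(part2)) {
    if (s %in% rownames(merged)) merged[s, ] <- merged[s, ] + part2[s, ]
    else merged <- rbind(merged, part2[s, , drop = FALSE])
  }
  expect_equal(merged[rownames(whole), ], whole)

  cpm <- aggregate_expression(sc$counts, sc$cells, normalize = "cpm")
  expect_equal(unname(rowSums(cpm)), rep(1e6, 3))
  expect_error(aggregate_expression(counts, make_cells(counts, "s1")[1:2, ]),
               class = "hccdriver_error_mismatched_samples")
})

test_that("quartile stratification partitions samples with the top quartile high", {
  v <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), paste0("s", 1:8))
  st <- stratify_quartiles(v)
  expect_equal(as.character(st$stratum),
               c("high", "high", "mid", "mid", "mid", "mid", "low", "low"))
  # scale invariance
  expect_equal(stratify_quartiles(v * 10)$stratum, st$stratum)
  # partition property across sizes, including ties
  for (n in 4:13) {
    vv <- setNames(rep(1, n), paste0("s", seq_len(n)))
    stt <- stratify_quartiles(vv)
    expect_equal(sum(stt$stratum == "high"), ceiling(n / 4))
    expect_equal(sum(stt$stratum == "low"), floor(n / 4))
    expect_equal(nrow(stt), n)
  }
  # ties keep input order: first samples take the high slots
  tied <- stratify_quartiles(setNames(rep(5, 8), paste0("s", 1:8)))
  expect_equal(as.character(tied$stratum[1:2]), c("high", "high"))
  expect_error(stratify_quartiles(setNames(1:3, c("a", "b", "c"))),
               class = "hccdriver_error_small_group")
})

test_that("positivity counts cells with at least one transcript", {
  counts <- matrix(c(0, 0, 0, 1, 5, 0, 2, 0, 0, 0), ncol = 1,
                   dimnames = list(paste0("c", 1:10), "gX"))
  cells <- tibble::tibble(cell = rownames(counts),
                          sample = "s1",
                          phenotype = rep(c("malignant", "normal"), each = 5))
  pp <- positivity_proportion(counts, cells, "gX")
  expect_equal(pp$proportion[pp$phenotype == "malignant"], 2 / 5)
  expect_equal(pp$proportion[pp$phenotype == "normal"], 1 / 5)

  # threshold invariance: any positive count behaves like count 1
  big <- counts
  big[big > 0] <- 100
  expect_equal(positivity_proportion(big, cells, "gX")$proportion,
               pp$proportion)

  zero <- matrix(0L, 4, 1, dimnames = list(paste0("c", 1:4), "gX"))
  zc <- tibble::tibble(cell = rownames(zero), sample = "s", phenotype = "m")
  expect_equal(positivity_proportion(zero, zc, "gX")$proportion, 0)
  expect_error(positivity_proportion(counts, cells, "nope"),
               class = "hccdriver_error_unknown_gene")
})

test_that("the stratified-enrichment pipeline recovers a planted module", {
  hits <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    sc <- generate_sc_counts(n_samples = 12, cells_per_sample = 60,
                             n_genes = 200, phenotype_effect = 2.5,
                             module_size = 15, module_effect = 2,
                             seed = 100 + r)
    agg <- aggregate_expression(sc$counts, sc$cells)
    strata <- stratify_quartiles(agg[, sc$truth$focal_gene])
    log_expr <- t(log2(aggregate_expression(sc$counts, sc$cells,
                                            normalize = "cpm") + 1))
    lab <- setNames(as.character(strata$stratum), strata$sample)
    de <- compute_de(log_expr, group_a = "high", group_b = "low",
                     groups = lab[colnames(log_expr)])
    rk <- rank_genes_by_log2fc(de)
    withr::with_seed(200 + r, {
      decoy <- sample(setdiff(rk$gene, c(sc$truth$module_genes,
                                         sc$truth$focal_gene)), 15)
    })
    es_mod <- preranked_gsea(rk, sc$truth$module_genes, n_perm = 100,
                             seed = r)$es
    es_dec <- preranked_gsea(rk, decoy, n_perm = 100, seed = r)$es
    if (es_mod > es_dec && es_mod > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
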