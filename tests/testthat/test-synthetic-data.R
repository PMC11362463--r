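test_that("every generator is a pure function of its arguments and seed", {
  g1 <- generate_multistage_cohorts(n_cohorts = 2, n_genes = 60, n_drivers = 5,
                                    samples_per_stage = 3, seed = 7)
  g2 <- generate_multistage_cohorts(n_cohorts = 2, n_genes = 60, n_drivers = 5,
                                    samples_per_stage = 3, seed = 7)
  expect_identical(g1$cohorts[[1]]$expression, g2$cohorts[[1]]$expression)
  expect_identical(g1$truth$driver_genes, g2$truth$driver_genes)

  s1 <- generate_sc_counts(n_samples = 4, cells_per_sample = 20, n_genes = 30,
                           seed = 7)
  s2 <- generate_sc_counts(n_samples = 4, cells_per_sample = 20, n_genes = 30,
                           seed = 7)
  expect_identical(s1$counts, s2$counts)

  m1 <- generate_methylation_expression(n_pairs = 20, null_cpgs = 2, seed = 7)
  m2 <- generate_methylation_expression(n_pairs = 20, null_cpgs = 2, seed = 7)
  expect_identical(m1$methylation, m2$methylation)
  expect_identical(m1$expression, m2$expression)

  v1 <- generate_survival(n_per_group = 15, seed = 7)
  expect_identical(v1, generate_survival(n_per_group = 15, seed = 7))

  c1 <- generate_ct_table(c(r = 1, a = 2), "r", seed = 7)
  expect_identical(c1, generate_ct_table(c(r = 1, a = 2), "r", seed = 7))
})

test_that("planted drivers follow the programmed stage ladder within 3 SEM", {
  sim <- generate_multistage_cohorts(seed = 1)
  truth <- sim$truth
  co <- sim$cohorts[[1]]
  drivers <- truth$driver_genes
  stage <- as.character(co$samples$stage)
  for (s in seq_along(truth$stages)) {
    idx <- stage == truth$stages[s]
    programmed <- truth$baseline[drivers] +
      truth$cohort_batch_shifts[[co$cohort_id]] +
      (s - 1) * truth$per_stage_shift
    observed <- rowMeans(co$expression[drivers, idx, drop = FALSE])
    dev <- mean(observed - programmed)
    sem <- truth$noise_sd / sqrt(length(drivers) * sum(idx))
    expect_lt(abs(dev), 3 * sem)
  }
})

test_that("with zero per-stage shift drivers and nulls are indistinguishable", {
  sim <- generate_multistage_cohorts(n_cohorts = 1, n_genes = 400,
                                     n_drivers = 100, per_stage_shift = 0,
                                     samples_per_stage = 5, seed = 2)
  co <- sim$cohorts[[1]]
  stage <- as.character(co$samples$stage)
  last <- stage == tail(sim$truth$stages, 1)
  driver_means <- rowMeans(co$expression[sim$truth$driver_genes, last]) -
    sim$truth$baseline[sim$truth$driver_genes]
  nulls <- setdiff(sim$truth$genes, sim$truth$driver_genes)
  null_means <- rowMeans(co$expression[nulls, last]) -
    sim$truth$baseline[nulls]
  expect_gt(suppressWarnings(stats::ks.test(driver_means, null_means))$p.value,
            0.01)
})

test_that("single-cell counts behave at the null and in the Poisson limit", {
  sc0 <- generate_sc_counts(n_samples = 8, cells_per_sample = 150,
                            n_genes = 40, phenotype_effect = 0, seed = 3)
  pp <- positivity_proportion(sc0$counts, sc0$cells, sc0$truth$focal_gene)
  pt <- stats::prop.test(pp$n_positive, pp$n_cells)
  expect_gt(pt$p.value, 0.005)

  # huge dispersion and unit size factors: variance/mean near 1
  scp <- generate_sc_counts(n_samples = 4, cells_per_sample = 500,
                            n_genes = 60, phenotype_effect = 0,
                            dispersion = 1e6, size_factor_sd = 0, seed = 4)
  mu <- colMeans(scp$counts)
  vr <- apply(scp$counts, 2, var)
  keep <- mu > 0.5
  ratio <- vr[keep] / mu[keep]
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("methylation generator hits its programmed drop and correlation", {
  null_sim <- generate_methylation_expression(n_pairs = 300, marker_cpgs = 1,
                                              null_cpgs = 3,
                                              tumor_beta_drop = 0,
                                              target_r = 0, seed = 5)
  expect_true(all(null_sim$methylation$beta_nt > 0 &
                    null_sim$methylation$beta_nt < 1))
  expect_true(all(null_sim$methylation$beta_t > 0 &
                    null_sim$methylation$beta_t < 1))
  marker <- dplyr::filter(null_sim$methylation, cpg == "cgM0001")
  r_null <- pearson_corr(marker$beta_t, null_sim$expression$expression)
  expect_lt(abs(r_null$r), 0.15)
  # null drop: marker deltas indistinguishable from zero-centred
  expect_gt(t.test(marker$beta_t - marker$beta_nt)$p.value, 0.01)

  sim <- generate_methylation_expression(n_pairs = 300, target_r = -0.5,
                                         seed = 6)
  marker <- dplyr::filter(sim$methylation, cpg == "cgM0001")
  r_hat <- pearson_corr(marker$beta_t, sim$expression$expression)$r
  expect_lt(abs(r_hat - (-0.5)), 0.1)
  expect_lt(abs(mean(marker$beta_t - marker$beta_nt) - (-0.2)), 0.03)
  expect_error(generate_methylation_expression(target_r = 0.3, seed = 1),
               class = "hccdriver_error_bad_argument")
})

test_that("survival generator honours censoring and event construction", {
  no_cens <- generate_survival(n_per_group = 40, censor_rate = 0, seed = 8)
  expect_true(all(no_cens$event == 1))
  some <- generate_survival(n_per_group = 200, censor_rate = 0.1, seed = 9)
  expect_true(any(some$event == 0))
  expect_true(all(some$time >= 0))
  expect_error(generate_survival(n_per_group = 0, seed = 1),
               class = "hccdriver_error_bad_argument")
})

test_that("Ct construction inverts exactly through 2^-ddCt when noiseless", {
  folds <- c(ref = 1, up2 = 2, up4 = 4, down = 0.5)
  ct <- generate_ct_table(folds, "ref", ct_noise_sd = 0, seed = 10)
  res <- ddct_fold_change(ct, "ref")
  expect_equal(setNames(res$fold_change, res$sample)[names(folds)], folds)

  ones <- generate_ct_table(c(a = 1, b = 1, r = 1), "r", ct_noise_sd = 0,
                            seed = 11)
  res1 <- ddct_fold_change(ones, "r")
  expect_equal(res1$ddct, rep(0, 3))
  expect_error(generate_ct_table(c(a = 1), "zz", seed = 1),
               class = "hccdriver_error_unknown_sample")
})
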