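#' Generate staged expression cohorts with planted driver genes
#'
#' Simulates several cohorts of log2-scale expression over an ordered disease
#' ladder. A set of planted driver genes gains `per_stage_shift` log2 units of
#' mean expression per stage step; all other genes are stage-constant. Cohorts
#' share driver identities but differ by an additive batch shift and by noise
#' realisation, emulating the structure of independent staged liver cohorts.
#'
#' Noise is Gaussian on the log2 scale (log-normal intensities), matching the
#' microarray-style data the discovery cascade consumes.
#'
#' @param n_cohorts Number of cohorts to generate.
#' @param stages Ordered stage labels (>= 3).
#' @param n_genes Number of genes.
#' @param n_drivers Number of planted driver genes (<= `n_genes`).
#' @param per_stage_shift Log2 mean increment per stage step for drivers
#'   (>= 0; 0 gives a pure null configuration).
#' @param noise_sd Residual log2 standard deviation.
#' @param samples_per_stage Samples per stage per cohort (>= 2).
#' @param cohort_batch_sd SD of the per-cohort additive log2 batch shift.
#' @param baseline_mean,baseline_sd Distribution of gene baseline log2 means,
#'   shared across cohorts.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A list with `cohorts` (named list of [stage_dataset()] objects) and
#'   `truth`, a `ground_truth` list recording `driver_genes`,
#'   `per_stage_shift`, `cohort_batch_shifts`, `noise_sd`, `stages` and the
#'   full `genes` universe - sufficient to score recovery without re-reading
#'   generator internals.
#' @export
#' @examples
#' sim <- generate_multistage_cohorts(n_cohorts = 2, n_genes = 100,
#'                                    n_drivers = 5, seed = 1)
#' sim$cohorts[[1]]
generate_multistage_cohorts <- function(n_cohorts = 3,
                                        stages = hcc_stage_ladder(),
                                        n_genes = 2000,
                                        n_drivers = 50,
                                        per_stage_shift = 0.5,
                                        noise_sd = 0.5,
                                        samples_per_stage = 10,
                                        cohort_batch_sd = 0.3,
                                        baseline_mean = 7,
                                        baseline_sd = 1,
                                        seed) {
  n_cohorts <- check_count(n_cohorts, "n_cohorts")
  n_genes <- check_count(n_genes, "n_genes")
  n_drivers <- check_count(n_drivers, "n_drivers", min = 0L)
  samples_per_stage <- check_count(samples_per_stage, "samples_per_stage", min = 2L)
  check_number(per_stage_shift, "per_stage_shift", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  seed <- check_seed(seed)
  stages <- as.character(stages)
  if (length(stages) < 3) {
    abort_hcc("At least 3 ordered stages are required.",
              "hccdriver_error_bad_argument")
  }
  if (n_drivers > n_genes) {
    abort_hcc("`n_drivers` cannot exceed `n_genes`.",
              "hccdriver_error_bad_argument")
  }

  genes <- sprintf("g%05d", seq_len(n_genes))
  seeds <- child_seeds(seed, n_cohorts + 1L)

  shared <- withr::with_seed(seeds[1], {
    list(
      baseline = stats::setNames(rnorm(n_genes, baseline_mean, baseline_sd), genes),
      drivers = sort(sample(genes, n_drivers)),
      batch = rnorm(n_cohorts, 0, cohort_batch_sd)
    )
  })
  driver_idx <- genes %in% shared$drivers
  step <- seq_along(stages) - 1L

  cohorts <- lapply(seq_len(n_cohorts), function(ci) {
    withr::with_seed(seeds[ci + 1L], {
      stage_vec <- rep(stages, each = samples_per_stage)
      n_samp <- length(stage_vec)
      mu <- matrix(shared$baseline + shared$batch[ci], n_genes, n_samp)
      shift_per_sample <- rep(step * per_stage_shift, each = samples_per_stage)
      mu[driver_idx, ] <- sweep(mu[driver_idx, , drop = FALSE], 2,
                                shift_per_sample, "+")
      expr <- mu + matrix(rnorm(n_genes * n_samp, 0, noise_sd), n_genes, n_samp)
      dimnames(expr) <- list(
        genes,
        sprintf("c%02d_%s_%02d", ci, stage_vec,
                rep(seq_len(samples_per_stage), times = length(stages)))
      )
      stage_dataset(expr, stage_vec, cohort_id = sprintf("cohort%02d", ci),
                    stage_levels = stages)
    })
  })
  names(cohorts) <- vapply(cohorts, `[[`, character(1), "cohort_id")

  truth <- structure(
    list(
      genes = genes,
      driver_genes = shared$drivers,
      per_stage_shift = per_stage_shift,
      cohort_batch_shifts = stats::setNames(shared$batch, names(cohorts)),
      noise_sd = noise_sd,
      stages = stages,
      baseline = shared$baseline
    ),
    class = "ground_truth"
  )
  list(cohorts = cohorts, truth = truth)
}

#' Score driver recovery of a discovered gene list against ground truth
#'
#' @param genes Character vector of discovered genes (for example
#'   `tidy(cascade)$gene`).
#' @param truth `ground_truth` object from [generate_multistage_cohorts()].
#' @return One-row tibble with sensitivity (fraction of planted drivers
#'   recovered), the null pass rate (fraction of non-driver genes in the
#'   list), and the underlying counts.
#' @export
score_recovery <- function(genes, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  drivers <- truth$driver_genes
  nulls <- setdiff(truth$genes, drivers)
  tibble::tibble(
    n_listed = length(genes),
    n_drivers = length(drivers),
    n_true_positive = sum(genes %in% drivers),
    n_false_positive = sum(genes %in% nulls),
    sensitivity = if (length(drivers)) sum(genes %in% drivers) / length(drivers) else NA_real_,
    null_pass_rate = if (length(nulls)) sum(genes %in% nulls) / length(nulls) else NA_real_
  )
}

#' Generate overdispersed single-cell counts with a focal gene effect
#'
#' Counts are negative binomial with log-normal per-cell library-size factors,
#' giving realistic overdispersion and dropout. The focal gene's mean is
#' multiplied by `2^phenotype_effect` in cells of the first (malignant)
#' phenotype; an optional planted gene module shares a `module_effect` in the
#' same cells, so stratified enrichment can be validated end to end.
#'
#' @param n_samples Number of samples (split evenly across the two phenotypes).
#' @param cells_per_sample Cells per sample.
#' @param n_genes Number of genes.
#' @param focal_gene Identifier of the focal gene; must be one of the
#'   generated gene names `g00001 ...`.
#' @param phenotype_effect Log2-fold effect of the malignant phenotype on the
#'   focal gene mean.
#' @param dispersion Negative binomial size parameter (> 0); larger values
#'   approach the Poisson limit.
#' @param module_size,module_effect Size and log2-fold effect of a planted
#'   co-regulated module (0 disables it).
#' @param phenotypes Two phenotype labels; the first receives the effect.
#' @param base_log_mean,base_log_sd Log-normal distribution of per-gene base
#'   mean counts.
#' @param size_factor_sd SD of log-normal per-cell size factors.
#' @param seed Integer seed.
#' @return List with `counts` (integer matrix, cells x genes), `cells`
#'   (tibble: `cell`, `sample`, `phenotype`) and `truth` (focal gene, module
#'   genes, effects).
#' @export
generate_sc_counts <- function(n_samples = 12,
                               cells_per_sample = 100,
                               n_genes = 500,
                               focal_gene = "g00001",
                               phenotype_effect = 1,
                               dispersion = 2,
                               module_size = 0,
                               module_effect = 0,
                               phenotypes = c("malignant", "non_malignant"),
                               base_log_mean = log(0.5),
                               base_log_sd = 1,
                               size_factor_sd = 0.3,
                               seed) {
  n_samples <- check_count(n_samples, "n_samples", min = 2L)
  cells_per_sample <- check_count(cells_per_sample, "cells_per_sample")
  n_genes <- check_count(n_genes, "n_genes")
  module_size <- check_count(module_size, "module_size", min = 0L)
  check_number(dispersion, "dispersion", lower = 0, allow_lower = FALSE)
  seed <- check_seed(seed)
  stopifnot(length(phenotypes) == 2)

  genes <- sprintf("g%05d", seq_len(n_genes))
  if (!focal_gene %in% genes) {
    abort_hcc(sprintf("Unknown focal gene '%s'.", focal_gene),
              "hccdriver_error_unknown_gene")
  }

  withr::with_seed(seed, {
    base_mu <- exp(rnorm(n_genes, base_log_mean, base_log_sd))
    names(base_mu) <- genes
    module_genes <- if (module_size > 0) {
      sort(sample(setdiff(genes, focal_gene), module_size))
    } else {
      character(0)
    }
    samples <- sprintf("s%03d", seq_len(n_samples))
    sample_phen <- rep(phenotypes, length.out = n_samples)
    cells <- tibble::tibble(
      cell = sprintf("cell%05d", seq_len(n_samples * cells_per_sample)),
      sample = rep(samples, each = cells_per_sample),
      phenotype = rep(sample_phen, each = cells_per_sample)
    )
    n_cells <- nrow(cells)
    sf <- exp(rnorm(n_cells, 0, size_factor_sd))
    effect <- stats::setNames(numeric(n_genes), genes)
    effect[focal_gene] <- phenotype_effect
    effect[module_genes] <- module_effect
    affected <- cells$phenotype == phenotypes[1]
    # mu[cell, gene] = sf_cell * base_g * 2^(effect_g * affected_cell)
    mu <- outer(sf, base_mu) * 2^(outer(as.numeric(affected), effect))
    counts <- matrix(rnbinom(length(mu), size = dispersion, mu = mu),
                     n_cells, n_genes, dimnames = list(cells$cell, genes))
    list(
      counts = counts,
      cells = cells,
      truth = list(focal_gene = focal_gene, phenotype_effect = phenotype_effect,
                   module_genes = module_genes, module_effect = module_effect,
                   affected_phenotype = phenotypes[1])
    )
  })
}

#' Generate paired tumor/non-tumor methylation with coupled expression
#'
#' Marker CpGs lose `tumor_beta_drop` beta units on average in the tumor
#' member of each pair; null CpGs are exchangeable between tumor and
#' non-tumor. Beta values are truncated-Gaussian on the beta scale with noise
#' SD `noise_sd`, so the hypomethylation fraction at margin 0 has the closed
#' form `pnorm(tumor_beta_drop / (noise_sd * sqrt(2)))`. A paired tumor
#' expression value is coupled to the first marker CpG's tumor beta so the
#' achieved Pearson correlation approximates `target_r` (inverse coupling;
#' positive targets are rejected).
#'
#' @param n_pairs Number of patients (tumor/non-tumor pairs).
#' @param marker_cpgs Number of tumor-hypomethylated marker CpGs (>= 1).
#' @param null_cpgs Number of null CpGs.
#' @param tumor_beta_drop Mean beta decrease in tumor at marker CpGs, in
#'   [0, 1).
#' @param target_r Target Pearson correlation between marker beta and
#'   expression, in [-1, 0].
#' @param noise_sd Beta-scale noise SD per measurement.
#' @param nt_mean Mean non-tumor beta at every CpG.
#' @param seed Integer seed.
#' @return List with `methylation` (tibble: `cpg`, `patient`, `beta_nt`,
#'   `beta_t`, `is_marker`), `expression` (tibble: `patient`, `expression`),
#'   and `truth` (marker ids, programmed drop and target correlation).
#' @export
generate_methylation_expression <- function(n_pairs = 300,
                                            marker_cpgs = 1,
                                            null_cpgs = 20,
                                            tumor_beta_drop = 0.2,
                                            target_r = -0.5,
                                            noise_sd = 0.1,
                                            nt_mean = 0.7,
                                            seed) {
  n_pairs <- check_count(n_pairs, "n_pairs", min = 3L)
  marker_cpgs <- check_count(marker_cpgs, "marker_cpgs")
  null_cpgs <- check_count(null_cpgs, "null_cpgs", min = 0L)
  check_number(tumor_beta_drop, "tumor_beta_drop", lower = 0, upper = 1,
               allow_upper = FALSE)
  if (!is.numeric(target_r) || length(target_r) != 1L || is.na(target_r) ||
      target_r > 0 || target_r < -1) {
    abort_hcc("`target_r` must lie in [-1, 0]: the emulated methylation-expression signal is inverse.",
              "hccdriver_error_bad_argument")
  }
  check_number(noise_sd, "noise_sd", lower = 0, allow_lower = FALSE)
  seed <- check_seed(seed)

  cpgs <- c(sprintf("cgM%04d", seq_len(marker_cpgs)),
            if (null_cpgs > 0) sprintf("cgN%04d", seq_len(null_cpgs)))
  is_marker <- c(rep(TRUE, marker_cpgs), rep(FALSE, null_cpgs))
  patients <- sprintf("p%04d", seq_len(n_pairs))

  withr::with_seed(seed, {
    meth <- purrr::map2_dfr(cpgs, is_marker, function(cg, mk) {
      drop <- if (mk) tumor_beta_drop else 0
      tibble::tibble(
        cpg = cg,
        patient = patients,
        beta_nt = clamp_unit(rnorm(n_pairs, nt_mean, noise_sd)),
        beta_t = clamp_unit(rnorm(n_pairs, nt_mean - drop, noise_sd)),
        is_marker = mk
      )
    })
    anchor <- meth$beta_t[meth$cpg == cpgs[1]]
    z <- as.numeric(scale(anchor))
    expr <- target_r * z + sqrt(1 - target_r^2) * rnorm(n_pairs)
    list(
      methylation = meth,
      expression = tibble::tibble(patient = patients, expression = expr),
      truth = list(marker_cpgs = cpgs[is_marker], tumor_beta_drop = tumor_beta_drop,
                   target_r = target_r, noise_sd = noise_sd)
    )
  })
}

#' Generate two-group survival data with a known hazard ratio
#'
#' Event times are exponential with hazard `baseline_hazard` in the low group
#' and `baseline_hazard * true_hr` in the high group; censoring is independent
#' exponential with rate `censor_rate` (0 disables censoring).
#'
#' @param n_per_group Patients per group.
#' @param true_hr True hazard ratio (high vs low, > 0).
#' @param baseline_hazard Event hazard in the low group (> 0).
#' @param censor_rate Censoring hazard (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `patient`, `group` (factor low/high), `time`, `event`.
#' @export
generate_survival <- function(n_per_group = 100,
                              true_hr = 2,
                              baseline_hazard = 0.1,
                              censor_rate = 0.05,
                              seed) {
  n_per_group <- check_count(n_per_group, "n_per_group")
  check_number(true_hr, "true_hr", lower = 0, allow_lower = FALSE)
  check_number(baseline_hazard, "baseline_hazard", lower = 0, allow_lower = FALSE)
  check_number(censor_rate, "censor_rate", lower = 0)
  seed <- check_seed(seed)

  n <- 2L * n_per_group
  group <- factor(rep(c("low", "high"), each = n_per_group),
                  levels = c("low", "high"))
  hazard <- baseline_hazard * ifelse(group == "high", true_hr, 1)
  withr::with_seed(seed, {
    t_event <- rexp(n, rate = hazard)
    t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    tibble::tibble(
      patient = sprintf("p%04d", seq_len(n)),
      group = group,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Constructs target and housekeeping Ct values so that the noiseless
#' delta-delta-Ct computation recovers `true_fold_changes` (relative to
#' `reference_sample`) exactly; Gaussian cycle noise is added per replicate.
#'
#' @param true_fold_changes Named positive vector of per-sample fold changes
#'   relative to the reference sample (names are sample ids).
#' @param reference_sample Which sample is the calibrator; must be a name of
#'   `true_fold_changes`.
#' @param ct_noise_sd Cycle noise SD (0 for exact recovery).
#' @param n_replicates Technical replicates per (sample, assay).
#' @param housekeeping_ct Mean housekeeping Ct.
#' @param base_delta_ct Target-minus-housekeeping Ct offset at fold 1.
#' @param seed Integer seed.
#' @return Long tibble: `sample`, `assay` ("target"/"housekeeping"),
#'   `replicate`, `ct`.
#' @export
generate_ct_table <- function(true_fold_changes,
                              reference_sample,
                              ct_noise_sd = 0.2,
                              n_replicates = 3,
                              housekeeping_ct = 20,
                              base_delta_ct = 5,
                              seed) {
  if (is.null(names(true_fold_changes)) || anyDuplicated(names(true_fold_changes))) {
    abort_hcc("`true_fold_changes` must be a uniquely named vector.",
              "hccdriver_error_bad_argument")
  }
  if (any(!is.finite(true_fold_changes)) || any(true_fold_changes <= 0)) {
    abort_hcc("All fold changes must be finite and > 0.",
              "hccdriver_error_bad_argument")
  }
  if (!reference_sample %in% names(true_fold_changes)) {
    abort_hcc(sprintf("Reference sample '%s' is not among the samples.",
                      reference_sample),
              "hccdriver_error_unknown_sample")
  }
  check_number(ct_noise_sd, "ct_noise_sd", lower = 0)
  n_replicates <- check_count(n_replicates, "n_replicates")
  seed <- check_seed(seed)

  samples <- names(true_fold_changes)
  grid <- tidyr::expand_grid(
    sample = samples,
    assay = c("target", "housekeeping"),
    replicate = seq_len(n_replicates)
  )
  # delta-Ct per sample: base - log2(fold); ddCt vs reference = -log2(fold/fold_ref)
  target_mu <- housekeeping_ct + base_delta_ct -
    log2(true_fold_changes[grid$sample[grid$assay == "target"]])
  withr::with_seed(seed, {
    noise <- rnorm(nrow(grid), 0, ct_noise_sd)
    ct <- ifelse(grid$assay == "housekeeping", housekeeping_ct, NA_real_)
    ct[grid$assay == "target"] <- target_mu
    dplyr::mutate(grid, ct = ct + noise)
  })
}
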