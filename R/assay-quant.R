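#' Relative expression by the 2^-ddCt method
#'
#' Technical-replicate Ct values are averaged per (sample, assay) on the Ct
#' scale; `dCt = mean target Ct - mean housekeeping Ct`; `ddCt` subtracts the
#' reference sample's dCt; the fold change is `2^-ddCt`. The reference sample
#' itself always reports fold 1.
#'
#' @param ct Long Ct tibble: `sample`, `assay` ("target"/"housekeeping"),
#'   `replicate`, `ct` (finite positive cycles).
#' @param reference_sample The calibrator sample.
#' @return Tibble: `sample`, `delta_ct`, `ddct`, `fold_change`.
#' @export
#' @examples
#' ct <- generate_ct_table(c(ref = 1, s1 = 4), "ref", ct_noise_sd = 0, seed = 1)
#' ddct_fold_change(ct, "ref")
ddct_fold_change <- function(ct, reference_sample) {
  need <- c("sample", "assay", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    abort_hcc(sprintf("Ct table needs columns: %s.", paste(miss, collapse = ", ")),
              "hccdriver_error_bad_argument")
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    abort_hcc("Ct values must be finite and positive.",
              "hccdriver_error_bad_argument")
  }
  wide <- ct %>%
    dplyr::group_by(.data$sample, .data$assay) %>%
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "ct")
  if (!all(c("target", "housekeeping") %in% names(wide)) ||
        anyNA(wide$target) || anyNA(wide$housekeeping)) {
    abort_hcc("Every sample needs both target and housekeeping records.",
              "hccdriver_error_missing_housekeeping")
  }
  if (!reference_sample %in% wide$sample) {
    abort_hcc(sprintf("Reference sample '%s' is absent.", reference_sample),
              "hccdriver_error_unknown_sample")
  }
  wide <- dplyr::mutate(wide, delta_ct = .data$target - .data$housekeeping)
  ref_dct <- wide$delta_ct[wide$sample == reference_sample]
  wide %>%
    dplyr::transmute(
      sample = .data$sample,
      delta_ct = .data$delta_ct,
      ddct = .data$delta_ct - ref_dct,
      fold_change = 2^-(.data$delta_ct - ref_dct)
    )
}

#' qMSP relative methylation from methylated/unmethylated Ct values
#'
#' The assay's primary quantity is the Ct difference between the methylated-
#' and unmethylated-specific amplicons. A derived two-species fraction
#' `2^-ctM / (2^-ctM + 2^-ctU) = 1 / (1 + 2^delta_ct)` is also reported,
#' clearly labelled as a derived convenience: it is strictly decreasing in
#' `delta_ct` and equals 0.5 at `delta_ct = 0`.
#'
#' @param ct_methylated,ct_unmethylated Finite Ct values (vectorised).
#' @return Tibble: `delta_ct` (methylated minus unmethylated),
#'   `methylated_fraction` in (0, 1).
#' @export
#' @examples
#' qmsp_relative_methylation(24, 26)
qmsp_relative_methylation <- function(ct_methylated, ct_unmethylated) {
  if (any(!is.finite(ct_methylated)) || any(!is.finite(ct_unmethylated))) {
    abort_hcc("Ct values must be finite.", "hccdriver_error_bad_argument")
  }
  if (length(ct_methylated) != length(ct_unmethylated)) {
    abort_hcc("Ct vectors must have equal length.",
              "hccdriver_error_bad_argument")
  }
  delta <- ct_methylated - ct_unmethylated
  tibble::tibble(
    delta_ct = delta,
    methylated_fraction = 1 / (1 + 2^delta)
  )
}

#' Xenograft tumor volume from caliper measurements
#'
#' `volume = 0.52 * length * width^2`, the standard ellipsoid approximation
#' for subcutaneous tumors, in cubic millimetres. If `width > length` the
#' inputs are swapped with a warning (the convention is length >= width).
#'
#' @param length,width Caliper measurements in mm (vectorised,
#'   non-negative).
#' @return Numeric volume(s) in mm^3.
#' @export
#' @examples
#' tumor_volume(10, 5)
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) {
    abort_hcc("Measurements must be non-negative.",
              "hccdriver_error_bad_argument")
  }
  swap <- width > length
  if (any(swap)) {
    warning("`width` exceeds `length` for some measurements; swapping per the length >= width convention.",
            call. = FALSE)
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  0.52 * length * width^2
}
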