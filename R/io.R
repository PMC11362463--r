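#' Read a stage-labelled expression matrix
#'
#' Expects a TSV matrix whose first column holds gene identifiers and whose
#' remaining columns are samples, plus a metadata TSV with `sample` and
#' `stage` columns. Samples in the two files must match exactly; duplicate
#' genes and non-numeric cells are distinct, named errors.
#'
#' @param path Expression matrix TSV.
#' @param metadata_path Sample metadata TSV.
#' @param cohort_id Cohort label (default: the matrix file name).
#' @param stage_levels Ordered stage ladder.
#' @return A [stage_dataset()].
#' @export
read_expression_matrix <- function(path, metadata_path,
                                   cohort_id = NULL,
                                   stage_levels = hcc_stage_ladder()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) {
    abort_hcc("The matrix needs a gene column plus >= 1 sample column.",
              "hccdriver_error_bad_expression")
  }
  genes <- as.character(raw[[1]])
  mat_cols <- raw[-1]
  non_numeric <- names(mat_cols)[!vapply(mat_cols, is.numeric, logical(1))]
  if (length(non_numeric)) {
    abort_hcc(sprintf("Non-numeric expression columns: %s.",
                      paste(head(non_numeric, 5), collapse = ", ")),
              "hccdriver_error_non_numeric")
  }
  expr <- as.matrix(mat_cols)
  rownames(expr) <- genes
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  stage_dataset(expr, as.data.frame(meta),
                cohort_id = cohort_id %||% basename(path),
                stage_levels = stage_levels)
}

#' Write a stage dataset as matrix + metadata TSVs
#'
#' @param dataset A [stage_dataset()].
#' @param path,metadata_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_matrix <- function(dataset, path, metadata_path) {
  stopifnot(inherits(dataset, "stage_dataset"))
  tb <- tibble::as_tibble(dataset$expression, rownames = "gene")
  readr::write_tsv(tb, path, progress = FALSE)
  meta <- dplyr::mutate(dataset$samples, stage = as.character(.data$stage))
  readr::write_tsv(meta, metadata_path, progress = FALSE)
  invisible(c(path, metadata_path))
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated dialect: set name, description, then gene
#' identifiers. Duplicate genes within a set are dropped with a warning;
#' an empty file yields an empty collection.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(list(), descriptions = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) {
    abort_hcc(sprintf("GMT line(s) with fewer than 3 fields: %s.",
                      paste(head(which(short), 5), collapse = ", ")),
              "hccdriver_error_bad_gmt")
  }
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("Duplicate genes in set '%s' were dropped.", p[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), names(sets)
  )
  sets
}

#' Write a gene-set collection as GMT
#' @param collection Named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  desc <- descriptions %||% attr(collection, "descriptions") %||%
    stats::setNames(rep("na", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read single-cell counts (MTX triplet or dense TSV) with cell metadata
#'
#' @param path Either an `.mtx` MatrixMarket file (with `features_path` and
#'   `barcodes_path` text files) or a dense TSV (cells in rows, first column
#'   `cell`).
#' @param metadata_path Cell metadata TSV with `cell`, `sample`, `phenotype`.
#' @param features_path,barcodes_path Companion files for the MTX route
#'   (genes-by-cells triplet, as conventionally distributed).
#' @return List with `counts` (cells-by-genes matrix) and `cells` (tibble).
#' @export
read_sc_counts <- function(path, metadata_path, features_path = NULL,
                           barcodes_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(features_path) || is.null(barcodes_path)) {
      abort_hcc("The MTX route needs `features_path` and `barcodes_path`.",
                "hccdriver_error_bad_argument")
    }
    m <- Matrix::readMM(path)           # genes x cells triplet convention
    genes <- readLines(features_path)
    cells_ids <- readLines(barcodes_path)
    counts <- t(as.matrix(m))
    dimnames(counts) <- list(cells_ids, genes)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    counts <- as.matrix(raw[-1])
    rownames(counts) <- as.character(raw[[1]])
  }
  cells <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("cell", "sample", "phenotype")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    abort_hcc(sprintf("Cell metadata needs columns: %s.",
                      paste(miss, collapse = ", ")),
              "hccdriver_error_bad_metadata")
  }
  validate_cell_matrix(counts, cells)
  list(counts = counts, cells = cells)
}

#' Write single-cell counts as MTX triplet + features/barcodes + metadata
#'
#' @param counts Cells-by-genes count matrix.
#' @param cells Cell metadata tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_sc_counts <- function(counts, cells, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(methods::as(methods::as(t(counts), "CsparseMatrix"),
                              "generalMatrix"), mtx)
  writeLines(colnames(counts), file.path(dir, "features.txt"))
  writeLines(rownames(counts), file.path(dir, "barcodes.txt"))
  readr::write_tsv(cells, file.path(dir, "cells.tsv"), progress = FALSE)
  invisible(file.path(dir, c("counts.mtx", "features.txt", "barcodes.txt",
                             "cells.tsv")))
}

#' Read a paired methylation beta table
#' @param path TSV with `cpg`, `patient`, `beta_nt`, `beta_t`.
#' @return Validated tibble.
#' @export
read_methylation_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_methylation(tb)
  tb
}

#' Read a survival table
#' @param path TSV with `patient`, `time`, `event` and either `group` or a
#'   numeric `value` to dichotomize downstream.
#' @return Tibble.
#' @export
read_survival_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("patient", "time", "event"), names(tb))
  if (length(miss)) {
    abort_hcc(sprintf("Survival table needs columns: %s.",
                      paste(miss, collapse = ", ")),
              "hccdriver_error_bad_argument")
  }
  tb
}

#' Read a long-format Ct table
#' @param path TSV with `sample`, `assay`, `replicate`, `ct`.
#' @return Tibble.
#' @export
read_ct_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("sample", "assay", "ct"), names(tb))
  if (length(miss)) {
    abort_hcc(sprintf("Ct table needs columns: %s.",
                      paste(miss, collapse = ", ")),
              "hccdriver_error_bad_argument")
  }
  tb
}
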