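#' Write a synthetic cohort to standard on-disk formats
#'
#' Serializes each generated component to the field's plain-text formats:
#' an AIRR-style rearrangement TSV, a Matrix Market count matrix with
#' `cells.tsv`/`genes.tsv` companions, one CSV per spatial map, a survival
#' CSV, and the planted truth as JSON.
#'
#' @param cohort a `ct_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ct_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort$clonotypes)) {
    readr::write_tsv(cohort$clonotypes, file.path(dir, "clonotypes.tsv"))
  }
  if (!is.null(cohort$expression)) {
    Matrix::writeMM(Matrix::Matrix(cohort$expression$counts, sparse = TRUE),
                    file.path(dir, "counts.mtx"))
    readr::write_tsv(cohort$expression$cells, file.path(dir, "cells.tsv"))
    readr::write_tsv(cohort$expression$genes, file.path(dir, "genes.tsv"))
  }
  if (!is.null(cohort$spatial)) {
    for (sp in cohort$spatial) {
      readr::write_csv(sp$cells,
                       file.path(dir, paste0("spatial_", sp$sample_id, ".csv")))
    }
  }
  if (!is.null(cohort$survival)) {
    readr::write_csv(cohort$survival, file.path(dir, "survival.csv"))
  }
  truth <- cohort$truth
  truth$usage <- NULL # large and reproducible from the seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an AIRR-style rearrangement TSV
#'
#' Expects at least `cell_id`, `sample_id`, `locus`, `v_call`, `junction`;
#' `junction_aa`, `duplicate_count`, `patient_id`, and `timepoint` are kept
#' when present and extra columns are ignored. Loci outside
#' TRA/TRB/IGH/IGK/IGL raise a parse error naming the offending rows.
#'
#' @param path TSV file path.
#' @return a tibble of clonotype records.
#' @export
read_airr <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "sample_id", "locus", "v_call", "junction")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    abort(paste0("AIRR table lacks required column(s): ",
                 paste(missing, collapse = ", ")), class = "ct_parse_error")
  }
  validate_clonotypes(tb)
}

#' Validate a clonotype record table
#' @param records tibble of clonotype records.
#' @return the validated tibble (with `duplicate_count` defaulted to 1).
#' @export
validate_clonotypes <- function(records) {
  allowed <- c("TRA", "TRB", "IGH", "IGK", "IGL")
  bad <- which(!records$locus %in% allowed)
  if (length(bad)) {
    abort(paste0("Unknown locus in row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 " (allowed: ", paste(allowed, collapse = "/"), ")."),
          class = "ct_parse_error")
  }
  if (!"duplicate_count" %in% names(records)) records$duplicate_count <- 1L
  if (any(records$duplicate_count < 1, na.rm = TRUE)) {
    abort("`duplicate_count` must be >= 1.", class = "ct_parse_error")
  }
  empty <- which(is.na(records$junction) | records$junction == "")
  if (length(empty)) {
    abort(paste0("Empty junction in row(s) ",
                 paste(head(empty, 5), collapse = ", "), "."),
          class = "ct_parse_error")
  }
  tibble::as_tibble(records)
}

#' Read a spatial cell CSV written by [write_cohort()]
#' @param path CSV path.
#' @return tibble of spatial cells.
#' @export
read_spatial_cells <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "x_um", "y_um", "cell_type")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    abort(paste0("Spatial table lacks required column(s): ",
                 paste(missing, collapse = ", ")), class = "ct_parse_error")
  }
  tb
}

#' Read a survival CSV (patient_id, time_days, event, group)
#' @param path CSV path.
#' @return tibble of survival records.
#' @export
read_survival <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("patient_id", "time_days", "event", "group")
  missing <- setdiff(required, names(tb))
  if (length(missing)) {
    abort(paste0("Survival table lacks required column(s): ",
                 paste(missing, collapse = ", ")), class = "ct_parse_error")
  }
  tb
}

#' Read a Matrix Market expression directory
#'
#' Expects `counts.mtx`, `cells.tsv`, `genes.tsv` as written by
#' [write_cohort()].
#'
#' @param dir directory path.
#' @return list with `counts` (dense integer matrix, cells x genes),
#'   `cells`, `genes`.
#' @export
read_expression <- function(dir) {
  mtx <- file.path(dir, "counts.mtx")
  if (!file.exists(mtx)) {
    abort(paste0("No counts.mtx under ", dir, "."), class = "ct_parse_error")
  }
  counts <- as.matrix(Matrix::readMM(mtx))
  cells <- readr::read_tsv(file.path(dir, "cells.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  genes <- readr::read_tsv(file.path(dir, "genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  rownames(counts) <- cells$cell_id
  colnames(counts) <- genes$gene
  storage.mode(counts) <- "integer"
  list(counts = counts, cells = cells, genes = genes)
}
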