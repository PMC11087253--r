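# Readers and writers for the plain-text interchange formats: TSV matrices
# (probes/genes as rows, samples as columns), CSV sample sheets, TSV
# annotation tables.

#' Read a methylation dataset from TSV/CSV files
#'
#' @param beta_path TSV of beta-values, first column probe ids, one column
#'   per sample.
#' @param detp_path TSV of detection p-values with the same layout.
#' @param samples_path CSV sample sheet with `sample_id`, `model`,
#'   `condition`.
#' @param model_label Model label; defaults to the sheet's single model.
#' @return A [methyl_dataset()].
#' @export
read_methyl_dataset <- function(beta_path, detp_path, samples_path,
                                model_label = NULL) {
  beta <- read_matrix_tsv(beta_path)
  detp <- read_matrix_tsv(detp_path)
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  if (!identical(rownames(beta), rownames(detp))) {
    abort("beta and detection-p matrices must share probe rows")
  }
  beta <- beta[, samples$sample_id, drop = FALSE]
  detp <- detp[, samples$sample_id, drop = FALSE]
  if (is.null(model_label)) model_label <- unique(samples$model)[1]
  methyl_dataset(beta, detp, samples, model_label)
}

#' Read a numeric matrix from TSV (first column = row ids)
#' @param path File path.
#' @return Numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- as.character(d[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a numeric matrix to TSV (rownames in the first column)
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  d <- as_tibble(m, rownames = id_col)
  readr::write_tsv(d, path)
  invisible(path)
}

#' Write DMRs as BED-like TSV plus a JSON member sidecar
#'
#' The TSV uses 0-based starts in BED convention; member probe ids go to
#' `<path>.members.json`.
#'
#' @param dmrs Tibble from [dmr_significance()].
#' @param path Output TSV path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  bed <- tibble(chrom = dmrs$chrom, start = dmrs$start - 1L, end = dmrs$end,
                n_dm = dmrs$n_dm, n_nondm = dmrs$n_nondm,
                p_combined = dmrs$p_combined %||% NA_real_,
                q = dmrs$q %||% NA_real_)
  readr::write_tsv(bed, path)
  members <- setNames(dmrs$probe_ids,
                      sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end))
  jsonlite::write_json(members, paste0(path, ".members.json"))
  invisible(path)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the interchange files for one simulated study: per-model beta and
#' detection-p TSVs and sample-sheet CSVs, the probe annotation TSV, the
#' count matrix TSV with its sample sheet, and the truth set as JSON.
#'
#' @param sim Output of [simulate_methylation()].
#' @param expr Output of [simulate_expression()] (optional).
#' @param annotation The probe annotation used for the simulation.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, expr = NULL, annotation = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(sim$datasets)) {
    ds <- sim$datasets[[mod]]
    write_matrix_tsv(ds$beta, file.path(dir, sprintf("beta_%s.tsv", mod)))
    write_matrix_tsv(ds$detp, file.path(dir, sprintf("detp_%s.tsv", mod)))
    readr::write_csv(ds$samples, file.path(dir, sprintf("samples_%s.csv", mod)))
  }
  if (!is.null(annotation)) {
    readr::write_tsv(annotation, file.path(dir, "annotation.tsv"))
  }
  if (!is.null(expr)) {
    write_matrix_tsv(expr$counts, file.path(dir, "counts.tsv"), id_col = "gene")
    readr::write_csv(expr$samples, file.path(dir, "counts_samples.csv"))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(dm = truth$dm, snp_like = truth$snp_like,
         failing_cells = truth$failing_cells,
         planted_dmrs = dplyr::select(truth$planted_dmrs, -dplyr::any_of("probe_ids")),
         planted_dmr_members = truth$planted_dmrs$probe_ids,
         linked_genes = truth$linked_genes),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
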