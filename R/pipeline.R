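# End-to-end orchestration: simulate (or load) -> QC per model -> per-model
# moderated-t differential methylation -> random-effects meta-analysis ->
# DMR scan -> chromatin-state enrichment -> expression integration
# (ML-tCpGs), with a machine-readable run summary.

#' Default pipeline configuration
#'
#' Thresholds default to the analysis' canonical values: methylation FDR
#' 0.01, expression FDR 0.05, detection p 0.01, DMR rule 3 DM CpGs / < 1 kb
#' / at most 3 non-DM CpGs.
#'
#' @param seed Integer seed driving all simulation randomness.
#' @param design,effects Lists of overrides for [study_design()] /
#'   [effect_spec()] (simulation mode), or `NULL` with `inputs` set.
#' @param inputs Optional named list of file paths for user-supplied data:
#'   `beta_<model>`, `detp_<model>`, `samples_<model>` for each of
#'   `spherical`/`cylindrical`, plus `annotation`, `counts`, `counts_samples`.
#' @param dm_fdr,expr_fdr,detection_p Thresholds in (0, 1).
#' @param dmr List with `min_dm`, `max_gap_bp`, `max_nondm`.
#' @param scale Analysis scale for methylation, `"beta"` or `"m"`.
#' @param blacklist Optional probe blacklist (vector or file).
#' @param external_tcpgs Optional external tCpG gene list (vector, data
#'   frame or file) for the overlap stage.
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(seed = 1, design = list(), effects = list(),
                            inputs = NULL, dm_fdr = 0.01, expr_fdr = 0.05,
                            detection_p = 0.01,
                            dmr = list(min_dm = 3, max_gap_bp = 1000, max_nondm = 3),
                            scale = "beta", blacklist = NULL,
                            external_tcpgs = NULL) {
  check_prob(dm_fdr, "dm_fdr")
  check_prob(expr_fdr, "expr_fdr")
  check_prob(detection_p, "detection_p")
  if (!scale %in% c("beta", "m")) abort("`scale` must be 'beta' or 'm'")
  if (!is.null(inputs) && length(design)) {
    abort("give either simulation settings or input paths, not both")
  }
  structure(list(seed = as.integer(seed), design = design, effects = effects,
                 inputs = inputs, dm_fdr = dm_fdr, expr_fdr = expr_fdr,
                 detection_p = detection_p, dmr = dmr, scale = scale,
                 blacklist = blacklist, external_tcpgs = external_tcpgs),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A validated `run_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full loading-methylation pipeline
#'
#' Executes every stage on simulated or user-supplied data and returns all
#' stage outputs with a run summary. Identical configuration and seed give
#' identical results. When `out_dir` is given, stage outputs are written as
#' TSV/BED/JSON files sufficient to re-run any downstream stage in
#' isolation.
#'
#' @param config A `run_config` from [pipeline_config()] or
#'   [read_pipeline_config()], or a list of arguments for
#'   [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with `summary` (stage counts), `qc_reports`, `dm` (per-model
#'   tables), `meta`, `dmrs`, `enrichment`, `pairs`, `de`, `tcpgs`,
#'   `category_summary`, `overlap`, and (simulation mode) `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- do.call(pipeline_config, config)

  # --- inputs
  truth <- NULL
  if (is.null(config$inputs)) {
    design <- do.call(study_design, config$design)
    effects <- do.call(effect_spec, config$effects)
    annotation <- simulate_probe_annotation(design, seed = config$seed)
    sim <- simulate_methylation(design, effects, annotation, seed = config$seed + 1L)
    expr <- simulate_expression(design, effects, annotation, sim$truth,
                                seed = config$seed + 2L)
    datasets <- sim$datasets
    truth <- sim$truth
    counts <- expr$counts
    count_samples <- expr$samples
  } else {
    inp <- config$inputs
    annotation <- readr::read_tsv(inp$annotation, show_col_types = FALSE)
    datasets <- list(
      spherical = read_methyl_dataset(inp$beta_spherical, inp$detp_spherical,
                                      inp$samples_spherical, "spherical"),
      cylindrical = read_methyl_dataset(inp$beta_cylindrical, inp$detp_cylindrical,
                                        inp$samples_cylindrical, "cylindrical")
    )
    counts <- read_matrix_tsv(inp$counts)
    count_samples <- readr::read_csv(inp$counts_samples, show_col_types = FALSE)
  }

  # --- QC and per-model differential methylation
  qc <- purrr::map(datasets, run_qc, detection_p = config$detection_p,
                   blacklist = config$blacklist)
  dm <- purrr::map(qc, function(q) dm_analyze(q$dataset, scale = config$scale))

  # --- meta-analysis, DMRs, enrichment
  meta <- meta_ewas(dm$spherical, dm$cylindrical, fdr_threshold = config$dm_fdr)
  dmrs <- do.call(scan_dmrs, c(list(meta = meta, annotation = annotation), config$dmr))
  dmrs <- dmr_significance(dmrs, meta)
  enrichment <- enrichment_by_state(meta, annotation)

  # --- expression integration
  pairs <- map_cpgs_to_genes(meta, annotation)
  de <- differential_expression(counts, count_samples)
  tcpgs <- prioritize_tcpgs(pairs, de, expr_fdr = config$expr_fdr)
  category_summary <- region_category_summary(tcpgs)
  overlap <- NULL
  if (!is.null(config$external_tcpgs)) {
    overlap <- overlap_tcpg_sets(tcpgs, config$external_tcpgs)
  }

  summary <- list(
    seed = config$seed,
    n_probes_retained = vapply(qc, function(q) q$report$n_retained, integer(1)),
    n_meta_probes = nrow(meta),
    n_dm_cpgs = sum(meta$dm_flag),
    n_dmrs = nrow(dmrs),
    n_enrichment_states = sum(!is.na(enrichment$p)),
    n_cpg_gene_pairs = nrow(pairs),
    n_tcpg_pairs = attr(tcpgs, "n_pairs"),
    n_tcpg_genes = attr(tcpgs, "n_genes"),
    n_overlap_genes = if (is.null(overlap)) NA_integer_ else overlap$n_overlap_genes,
    thresholds = list(dm_fdr = config$dm_fdr, expr_fdr = config$expr_fdr,
                      detection_p = config$detection_p),
    scale = config$scale
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mod in names(qc)) {
      write_matrix_tsv(qc[[mod]]$dataset$beta,
                       file.path(out_dir, sprintf("beta_qc_%s.tsv", mod)))
      readr::write_tsv(dm[[mod]], file.path(out_dir, sprintf("dm_%s.tsv", mod)))
    }
    readr::write_tsv(meta, file.path(out_dir, "meta.tsv"))
    write_dmr_bed(dmrs, file.path(out_dir, "dmrs.bed"))
    readr::write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    readr::write_tsv(dplyr::select(tcpgs, -dplyr::any_of("probe_ids")),
                     file.path(out_dir, "tcpgs.tsv"))
    readr::write_tsv(de, file.path(out_dir, "de.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(summary = summary, qc_reports = dplyr::bind_rows(purrr::map(qc, "report")),
       dm = dm, meta = meta, dmrs = dmrs, enrichment = enrichment,
       pairs = pairs, de = de, tcpgs = tcpgs,
       category_summary = category_summary, overlap = overlap, truth = truth,
       annotation = annotation)
}
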