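# Positional integration of differential methylation with differential
# expression: DM CpGs are mapped to genes through promoter/UTR/exon
# categories, mapped genes are tested for differential expression, and
# CpG-gene pairs whose gene passes a restricted FDR become transcriptionally
# active CpGs (ML-tCpGs).

TCPG_CATEGORIES <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "ExonBnd", "3'UTR")

#' Map DM CpGs to genes by positional category
#'
#' Explodes the semicolon-separated gene/category annotation of each DM CpG
#' into (probe, gene, category) triples, keeps the qualifying categories
#' (TSS200, TSS1500, 5'UTR, 1stExon, ExonBnd, 3'UTR; gene-body mappings are
#' excluded), and collapses duplicate (probe, gene) pairs, concatenating
#' their categories.
#'
#' @param meta Meta-analysis tibble with `probe_id`, `dm_flag`, `b_meta`, `q`.
#' @param annotation Probe annotation with semicolon-separated parallel
#'   `gene` and `category` columns.
#' @param categories Qualifying categories (default the six above).
#' @return Tibble with one row per (DM CpG, gene) pair: `probe_id`, `gene`,
#'   `category` (semicolon-joined when a pair maps through several),
#'   `meth_effect`, `meth_q`.
#' @export
map_cpgs_to_genes <- function(meta, annotation, categories = TCPG_CATEGORIES) {
  dm <- meta[meta$dm_flag, , drop = FALSE]
  empty <- tibble(probe_id = character(), gene = character(),
                  category = character(), meth_effect = numeric(),
                  meth_q = numeric())
  if (!nrow(dm)) return(empty)
  ann <- annotation[match(dm$probe_id, annotation$probe_id), ]
  has_map <- !is.na(ann$gene)
  if (!any(has_map)) return(empty)
  long <- tibble(probe_id = dm$probe_id[has_map],
                 gene = ann$gene[has_map],
                 category = ann$category[has_map],
                 meth_effect = dm$b_meta[has_map],
                 meth_q = dm$q[has_map])
  long <- tidyr::separate_longer_delim(long, c("gene", "category"), delim = ";")
  long <- long[long$category %in% categories, , drop = FALSE]
  if (!nrow(long)) return(empty)
  long |>
    dplyr::group_by(.data$probe_id, .data$gene) |>
    dplyr::summarise(category = paste(unique(.data$category), collapse = ";"),
                     meth_effect = .data$meth_effect[1],
                     meth_q = .data$meth_q[1], .groups = "drop") |>
    dplyr::arrange(.data$probe_id, .data$gene)
}

#' Differential expression on log2-CPM with moderated t-statistics
#'
#' Counts are library-size normalized to counts per million, transformed to
#' `log2(CPM + 0.5)`, and fed through the same two-group moderated-t engine
#' used for methylation. Genes with all-zero counts are dropped with a
#' message. By default the organoid model is included as a covariate
#' (design `~ loading + model`) so both models contribute jointly; set
#' `adjust_model = FALSE` for the plain two-group fit.
#'
#' @param counts Gene x sample non-negative integer matrix.
#' @param samples Sample sheet with `sample_id`, `condition` and (if
#'   `adjust_model`) `model`; rows match the count columns.
#' @param adjust_model Include the organoid model as a covariate (default
#'   TRUE when the sheet has more than one model).
#' @return Tibble with `gene`, `log2fc` (loaded minus control), `se`, `t`,
#'   `p.value`, `q.value`.
#' @export
differential_expression <- function(counts, samples, adjust_model = NULL) {
  if (!is.matrix(counts) || any(counts < 0)) {
    abort("`counts` must be a non-negative matrix")
  }
  samples <- as_tibble(samples)
  if (nrow(samples) != ncol(counts)) abort("sample sheet must match count columns")
  n1 <- sum(samples$condition == "loaded")
  n0 <- sum(samples$condition == "control")
  if (n1 < 2 || n0 < 2) abort("each group needs at least 2 samples")
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    inform(sprintf("differential_expression: dropping %d all-zero gene(s)", sum(zero)))
    counts <- counts[!zero, , drop = FALSE]
  }
  cpm <- t(t(counts) / colSums(counts)) * 1e6
  y <- log2(cpm + 0.5)
  if (is.null(adjust_model)) {
    adjust_model <- "model" %in% names(samples) &&
      length(unique(samples$model)) > 1
  }
  if (adjust_model) {
    fit <- fit_design(y, cbind(
      intercept = 1,
      loaded = as.numeric(samples$condition == "loaded"),
      model = as.numeric(factor(samples$model)) - 1
    ), coef = "loaded")
  } else {
    fit <- fit_linear_model(y, samples$condition)
  }
  mod <- ebayes_moderate(fit)
  out <- tidy(mod)
  tibble(gene = out$probe_id, log2fc = out$b, se = out$se, t = out$t,
         p.value = out$p.value, q.value = out$q.value)
}

# internal: rowwise least squares against a shared design matrix, returning
# the named coefficient in fit_linear_model() layout
fit_design <- function(values, design, coef) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) abort("design matrix is singular")
  xtx_inv <- chol2inv(chol(crossprod(design)))
  betas <- values %*% design %*% xtx_inv
  fitted <- betas %*% t(design)
  df <- ncol(values) - ncol(design)
  rss <- rowSums((values - fitted)^2)
  j <- match(coef, colnames(design))
  tibble(
    probe_id = rownames(values) %||% as.character(seq_len(nrow(values))),
    b = unname(betas[, j]),
    v = xtx_inv[j, j],
    s2 = unname(rss / df),
    df_residual = df
  )
}

#' Prioritize transcriptionally active CpG-gene pairs (ML-tCpGs)
#'
#' Restricts the differential-expression p-values to the unique genes that
#' carry at least one mapped DM CpG, applies BH within that restricted
#' family only, and retains pairs whose gene passes `expr_fdr`. Pair genes
#' absent from the DE results are dropped with a message.
#'
#' @param pairs CpG-gene pairs from [map_cpgs_to_genes()].
#' @param de Differential-expression tibble from
#'   [differential_expression()].
#' @param expr_fdr Gene-level FDR threshold within the restricted family
#'   (default 0.05).
#' @return Tibble of retained pairs with `expr_log2fc`, `expr_p` and
#'   `expr_q_restricted` added. Attributes `n_pairs` and `n_genes` hold the
#'   retained pair and unique-gene counts; `n_mapped_genes` the size of the
#'   restricted family.
#' @export
prioritize_tcpgs <- function(pairs, de, expr_fdr = 0.05) {
  check_prob(expr_fdr, "expr_fdr")
  empty <- tibble(probe_id = character(), gene = character(),
                  category = character(), meth_effect = numeric(),
                  meth_q = numeric(), expr_log2fc = numeric(),
                  expr_p = numeric(), expr_q_restricted = numeric())
  if (!nrow(pairs)) {
    attr(empty, "n_pairs") <- 0L; attr(empty, "n_genes") <- 0L
    attr(empty, "n_mapped_genes") <- 0L
    return(empty)
  }
  genes <- unique(pairs$gene)
  known <- genes[genes %in% de$gene]
  if (length(known) < length(genes)) {
    inform(sprintf("prioritize_tcpgs: %d mapped gene(s) missing from DE results",
                   length(genes) - length(known)))
  }
  if (!length(known)) {
    attr(empty, "n_pairs") <- 0L; attr(empty, "n_genes") <- 0L
    attr(empty, "n_mapped_genes") <- 0L
    return(empty)
  }
  sub <- de[match(known, de$gene), ]
  sub$expr_q_restricted <- adjust_bh(sub$p.value)
  keep_genes <- sub$gene[sub$expr_q_restricted < expr_fdr]
  out <- pairs[pairs$gene %in% keep_genes, , drop = FALSE]
  i <- match(out$gene, sub$gene)
  out$expr_log2fc <- sub$log2fc[i]
  out$expr_p <- sub$p.value[i]
  out$expr_q_restricted <- sub$expr_q_restricted[i]
  out <- dplyr::arrange(out, .data$probe_id, .data$gene)
  attr(out, "n_pairs") <- nrow(out)
  attr(out, "n_genes") <- length(unique(out$gene))
  attr(out, "n_mapped_genes") <- length(known)
  out
}

#' Category composition of tCpG pairs
#'
#' Fraction of pairs per positional category. Pairs mapping through several
#' concatenated categories contribute one count per category occurrence;
#' fractions are normalized by total occurrences and sum to one.
#'
#' @param tcpgs Pair tibble with a `category` column (possibly
#'   semicolon-joined).
#' @return Tibble with `category` and `fraction`; empty input gives an
#'   empty summary.
#' @export
region_category_summary <- function(tcpgs) {
  if (!nrow(tcpgs)) return(tibble(category = character(), fraction = numeric()))
  cats <- unlist(strsplit(tcpgs$category, ";", fixed = TRUE))
  tab <- table(cats)
  tibble(category = names(tab), fraction = as.numeric(tab) / length(cats)) |>
    dplyr::arrange(dplyr::desc(.data$fraction))
}

#' Overlap of ML-tCpG pairs with an external tCpG catalog
#'
#' Intersects by case-normalized gene symbol, and additionally by exact
#' (probe, gene) pair when both sides carry probe ids.
#'
#' @param ml ML-tCpG pair tibble (needs `gene`, optionally `probe_id`).
#' @param external Character vector of gene symbols, a data frame with a
#'   `gene` column (optionally `probe_id`), or a path to a text file with
#'   one gene (or `probe_id,gene`) per line.
#' @return List with `n_overlap_genes`, `genes` (sorted overlapping
#'   symbols), and `n_overlap_pairs` (NA when either side lacks probe ids).
#' @export
overlap_tcpg_sets <- function(ml, external) {
  if (is.character(external) && length(external) == 1 && file.exists(external)) {
    lines <- readr::read_lines(external)
    lines <- lines[nzchar(lines)]
    if (any(grepl(",", lines, fixed = TRUE))) {
      parts <- strsplit(lines, ",", fixed = TRUE)
      external <- tibble(probe_id = vapply(parts, `[`, "", 1),
                         gene = vapply(parts, `[`, "", 2))
    } else {
      external <- lines
    }
  }
  if (is.character(external)) external <- tibble(gene = external)
  external <- as_tibble(external)
  if (!nrow(external)) {
    warn("overlap_tcpg_sets: empty external list")
    return(list(n_overlap_genes = 0L, genes = character(0), n_overlap_pairs = NA_integer_))
  }
  g_ml <- unique(toupper(ml$gene))
  g_ext <- unique(toupper(external$gene))
  genes <- sort(intersect(g_ml, g_ext))
  n_pairs <- NA_integer_
  if ("probe_id" %in% names(ml) && "probe_id" %in% names(external)) {
    key_ml <- unique(paste(ml$probe_id, toupper(ml$gene)))
    key_ext <- unique(paste(external$probe_id, toupper(external$gene)))
    n_pairs <- length(intersect(key_ml, key_ext))
  }
  list(n_overlap_genes = length(genes), genes = genes, n_overlap_pairs = n_pairs)
}
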