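# Probe-level quality control and normalization for one organoid model.

#' Methylation dataset container
#'
#' Bundles a probe-by-sample beta-value matrix with its detection p-values
#' and sample sheet for one organoid model. Betas must lie in (0, 1) and
#' detection p-values in \[0, 1\]; the two matrices share dimensions and
#' sample ids must be unique.
#'
#' @param beta Numeric probe x sample matrix of beta-values, rownames =
#'   probe ids, colnames = sample ids.
#' @param detp Numeric matrix of detection p-values, same dimensions.
#' @param samples Data frame with at least `sample_id` and `condition`
#'   (loaded/control); rows match the matrix columns.
#' @param model_label Model this dataset comes from ("spherical" or
#'   "cylindrical").
#' @return A `methyl_dataset` object.
#' @export
methyl_dataset <- function(beta, detp, samples, model_label = "spherical") {
  if (!is.matrix(beta) || !is.matrix(detp)) abort("`beta` and `detp` must be matrices")
  if (!identical(dim(beta), dim(detp))) abort("`beta` and `detp` must share dimensions")
  samples <- as_tibble(samples)
  if (nrow(samples) != ncol(beta)) abort("sample sheet rows must match matrix columns")
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique")
  if (nrow(beta) > 0) {
    if (min(beta) <= 0 || max(beta) >= 1) abort("beta-values must lie strictly in (0, 1)")
    if (min(detp) < 0 || max(detp) > 1) abort("detection p-values must lie in [0, 1]")
  }
  if (nrow(beta) > 0 && is.null(rownames(beta))) abort("`beta` needs probe ids as rownames")
  structure(list(beta = beta, detp = detp, samples = samples,
                 model_label = model_label),
            class = "methyl_dataset")
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat(sprintf("<methyl_dataset> %s model: %d probes x %d samples (%d loaded / %d control)\n",
              x$model_label, nrow(x$beta), ncol(x$beta),
              sum(x$samples$condition == "loaded"),
              sum(x$samples$condition == "control")))
  invisible(x)
}

# internal: subset a methyl_dataset to a set of probe ids (kept order)
subset_probes <- function(ds, keep) {
  methyl_dataset(ds$beta[keep, , drop = FALSE], ds$detp[keep, , drop = FALSE],
                 ds$samples, ds$model_label)
}

#' Remove probes failing detection in any sample
#'
#' A probe is removed if its detection p-value exceeds `p_thresh` in one or
#' more samples; the retained matrix contains no failed measurement.
#'
#' @param ds A [methyl_dataset()].
#' @param p_thresh Detection p-value threshold (default 0.01).
#' @return List with `dataset` (filtered [methyl_dataset()]) and `removed`
#'   (character vector of removed probe ids).
#' @export
filter_detection <- function(ds, p_thresh = 0.01) {
  stopifnot(inherits(ds, "methyl_dataset"))
  if (nrow(ds$beta) == 0) abort("empty dataset: no probes to filter")
  check_prob(p_thresh, "p_thresh")
  failed <- rowSums(ds$detp > p_thresh) > 0
  list(dataset = subset_probes(ds, !failed),
       removed = rownames(ds$beta)[failed])
}

#' Quantile normalization across samples
#'
#' Forces every column to share the same empirical distribution: each
#' column's sorted values are replaced by the row-wise mean of the columns'
#' order statistics, ties receiving the average of the tied reference
#' values. Idempotent, and a no-op (with a warning) on a single column.
#'
#' @param x Numeric matrix, samples in columns; no missing values.
#' @return Normalized matrix with the same dimensions and dimnames.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix")
  if (anyNA(x)) abort("`x` must not contain missing values")
  if (ncol(x) < 2) {
    warn("quantile_normalize: fewer than 2 columns, returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Regress control-probe principal components out of a value matrix
#'
#' A simplified functional-normalization step: technical variation shared
#' with control probes is removed by projecting each probe row off the top
#' `k` principal components of the column-standardized control matrix.
#' Constant (zero-variance) control probes carry no technical signal and are
#' dropped; if none remain, or `k = 0`, the input is returned unchanged.
#'
#' @param values Probe x sample numeric matrix.
#' @param controls Control-probe x sample numeric matrix over the same
#'   sample columns.
#' @param k Number of control principal components to remove (default 2);
#'   must satisfy `k < n_samples`.
#' @return Matrix of the same shape with the control components regressed
#'   out of each row (row means preserved).
#' @export
control_probe_normalize <- function(values, controls, k = 2) {
  if (!is.matrix(values) || !is.matrix(controls)) abort("inputs must be matrices")
  if (ncol(values) != ncol(controls)) abort("`values` and `controls` must share sample columns")
  if (k < 0 || k != round(k)) abort("`k` must be a non-negative integer")
  if (k == 0) return(values)
  if (k >= ncol(values)) abort("`k` must be smaller than the number of samples")
  ctrl_sd <- apply(controls, 1, sd)
  controls <- controls[ctrl_sd > 0, , drop = FALSE]
  if (nrow(controls) == 0) return(values)
  cs <- scale(t(controls))           # samples x controls, standardized
  pc <- stats::prcomp(cs, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  s <- pc$x[, seq_len(k), drop = FALSE]
  s <- scale(s, center = TRUE, scale = FALSE)
  # project each row of `values` off span(s); row means are untouched
  proj <- s %*% solve(crossprod(s), t(s))
  centered <- values - rowMeans(values)
  values - centered %*% proj
}

#' Flag probes with SNP-like trimodal beta patterns
#'
#' A probe whose beta-values split into genotype-like clusters (near 0, 0.5
#' and 1) usually reflects an underlying SNP rather than methylation. Samples
#' are binned into three bands (`beta < gap_low`, middle, `beta > gap_high`);
#' a band qualifies when it holds at least `min_cluster_frac` of samples
#' (and no fewer than two), has within-band SD below `max_band_sd`, and its
#' mean lies within `max_center_dist` of the canonical genotype cluster for
#' that band (0.05 homozygous unmethylated-like, 0.5 heterozygous, 0.95
#' homozygous). Probes with two or more qualifying bands are flagged;
#' isolated samples outside the qualifying bands are treated as outliers
#' and do not disqualify a probe. The centre condition keeps probes whose
#' betas merely straddle a band boundary, or split into two moderately
#' separated group clusters, from being flagged: genotype clusters sit
#' tight on the canonical pattern, band-straddlers and group effects do
#' not. The confidence score is `1 - mean(qualifying band SD) /
#' max_band_sd`, clipped to \[0, 1\]; tighter clusters score closer to 1.
#'
#' @param ds A [methyl_dataset()].
#' @param gap_low,gap_high Band boundaries (defaults 0.25 / 0.75).
#' @param min_cluster_frac Minimum fraction of samples per qualifying band.
#' @param max_band_sd Maximum within-band SD for a qualifying band.
#' @param max_center_dist Maximum distance of a qualifying band's mean from
#'   its canonical genotype centre (default 0.1).
#' @return Tibble with `probe_id`, `flagged`, `confidence` and
#'   `n_bands` (number of qualifying bands).
#' @export
flag_snp_like <- function(ds, gap_low = 0.25, gap_high = 0.75,
                          min_cluster_frac = 0.05, max_band_sd = 0.1,
                          max_center_dist = 0.1) {
  stopifnot(inherits(ds, "methyl_dataset"))
  ns <- ncol(ds$beta)
  if (ns < 10) warn("flag_snp_like: fewer than 10 samples; flags will be unstable")
  min_n <- max(2L, ceiling(min_cluster_frac * ns))
  band <- matrix(findInterval(ds$beta, c(gap_low, gap_high)) + 1L,
                 nrow = nrow(ds$beta))
  centers <- c(0.05, 0.5, 0.95)
  res <- purrr::map(seq_len(nrow(ds$beta)), function(i) {
    b <- ds$beta[i, ]
    g <- band[i, ]
    stats_by_band <- vapply(1:3, function(k) {
      v <- b[g == k]
      c(n = length(v),
        s = if (length(v) >= 2) sd(v) else NA_real_,
        m = if (length(v)) mean(v) else NA_real_)
    }, numeric(3))
    qual <- stats_by_band["n", ] >= min_n &
      !is.na(stats_by_band["s", ]) & stats_by_band["s", ] < max_band_sd &
      abs(stats_by_band["m", ] - centers) <= max_center_dist
    if (sum(qual) >= 2) {
      conf <- 1 - mean(stats_by_band["s", qual]) / max_band_sd
      c(1, min(max(conf, 0), 1), sum(qual))
    } else {
      c(0, 0, sum(qual))
    }
  })
  res <- do.call(rbind, res)
  tibble(probe_id = rownames(ds$beta), flagged = res[, 1] == 1,
         confidence = res[, 2], n_bands = as.integer(res[, 3]))
}

#' Remove blacklisted probes
#'
#' Drops probes named in a blacklist (cross-reactive probes, probes
#' overlapping rare SNPs, ...). Blacklist ids absent from the dataset are
#' ignored with a message.
#'
#' @param ds A [methyl_dataset()].
#' @param blacklist Character vector of probe ids, or path to a text file
#'   with one probe id per line.
#' @return The filtered [methyl_dataset()].
#' @export
remove_blacklisted <- function(ds, blacklist) {
  stopifnot(inherits(ds, "methyl_dataset"))
  if (is.character(blacklist) && length(blacklist) == 1 && file.exists(blacklist)) {
    blacklist <- readr::read_lines(blacklist)
    blacklist <- blacklist[nzchar(blacklist)]
  }
  present <- intersect(blacklist, rownames(ds$beta))
  absent <- setdiff(blacklist, present)
  if (length(absent)) {
    inform(sprintf("remove_blacklisted: %d blacklist id(s) not in dataset", length(absent)))
  }
  keep <- setdiff(rownames(ds$beta), present)
  if (!length(keep)) warn("remove_blacklisted: all probes removed")
  subset_probes(ds, keep)
}

#' Run the full probe-level QC chain for one model
#'
#' Default order: detection filter, quantile normalization across samples,
#' optional control-probe normalization, SNP-like flag removal, blacklist
#' removal. Probes with any missing beta after normalization are dropped.
#'
#' @param ds A [methyl_dataset()].
#' @param detection_p Detection p-value threshold.
#' @param blacklist Optional probe-id blacklist (vector or file path).
#' @param controls Optional control-probe matrix for
#'   [control_probe_normalize()].
#' @param k Control principal components to remove when `controls` given.
#' @param snp_args Named list of overrides for [flag_snp_like()].
#' @return List with `dataset` (clean [methyl_dataset()]) and `report`, a
#'   one-row tibble of QC counts (`n_input_probes`, `n_failed_detection`,
#'   `n_snp_like`, `n_blacklisted`, `n_retained`); `n_retained` equals the
#'   input count minus the union of the removed sets.
#' @export
run_qc <- function(ds, detection_p = 0.01, blacklist = NULL, controls = NULL,
                   k = 2, snp_args = list()) {
  stopifnot(inherits(ds, "methyl_dataset"))
  n_input <- nrow(ds$beta)
  det <- filter_detection(ds, detection_p)
  ds2 <- det$dataset

  beta_n <- quantile_normalize(ds2$beta)
  # quantile targets are means of order statistics of values in (0,1): stays in (0,1)
  if (!is.null(controls)) {
    beta_n <- control_probe_normalize(beta_n, controls[, colnames(beta_n), drop = FALSE], k)
    beta_n <- pmin(pmax(beta_n, 1e-6), 1 - 1e-6)
  }
  miss <- rowSums(is.na(beta_n)) > 0
  if (any(miss)) {
    inform(sprintf("run_qc: dropping %d probe(s) with missing values", sum(miss)))
    beta_n <- beta_n[!miss, , drop = FALSE]
  }
  ds2 <- methyl_dataset(beta_n, ds2$detp[rownames(beta_n), , drop = FALSE],
                        ds2$samples, ds2$model_label)

  snp <- do.call(flag_snp_like, c(list(ds = ds2), snp_args))
  snp_ids <- snp$probe_id[snp$flagged]
  ds3 <- subset_probes(ds2, setdiff(rownames(ds2$beta), snp_ids))

  n_black <- 0L
  if (!is.null(blacklist)) {
    before <- nrow(ds3$beta)
    ds3 <- remove_blacklisted(ds3, blacklist)
    n_black <- before - nrow(ds3$beta)
  }
  report <- tibble(
    model = ds$model_label,
    n_input_probes = n_input,
    n_failed_detection = length(det$removed),
    n_missing = sum(miss),
    n_snp_like = length(snp_ids),
    n_blacklisted = n_black,
    n_retained = nrow(ds3$beta)
  )
  list(dataset = ds3, report = report, snp_flags = snp)
}
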