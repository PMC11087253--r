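# Shared fixtures and independent oracles used across test files.

# tiny methyl_dataset built from a beta matrix (clean detection p-values)
make_dataset <- function(beta, condition = NULL, detp = NULL, model = "spherical") {
  if (is.null(rownames(beta))) rownames(beta) <- sprintf("p%03d", seq_len(nrow(beta)))
  if (is.null(colnames(beta))) colnames(beta) <- sprintf("s%02d", seq_len(ncol(beta)))
  if (is.null(detp)) detp <- matrix(0, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  if (is.null(condition)) {
    condition <- rep(c("loaded", "control"), length.out = ncol(beta))
  }
  methyl_dataset(beta, detp,
                 tibble::tibble(sample_id = colnames(beta), model = model,
                                condition = condition),
                 model_label = model)
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    js <- which(p[o] >= p[o][i])
    q[o][i] <- min(1, min(n * p[o][js] / js))
  }
  q
}

# brute-force DMR enumeration: all contiguous windows, validity check,
# containment filter, then greedy left-to-right non-overlap selection
dmr_oracle <- function(pos, dm, min_dm = 3, max_gap_bp = 1000, max_nondm = 3) {
  n <- length(pos)
  valid <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      idx <- i:j
      if (!dm[i] || !dm[j]) next
      if (sum(dm[idx]) < min_dm || sum(!dm[idx]) > max_nondm) next
      if (j > i && any(diff(pos[idx]) >= max_gap_bp)) next
      valid[[length(valid) + 1]] <- c(i, j)
    }
  }
  if (!length(valid)) return(NULL)
  w <- do.call(rbind, valid)
  maximal <- sapply(seq_len(nrow(w)), function(r) {
    !any(w[, 1] <= w[r, 1] & w[, 2] >= w[r, 2] &
           (w[, 1] != w[r, 1] | w[, 2] != w[r, 2]))
  })
  w <- w[maximal, , drop = FALSE]
  w <- w[order(w[, 1]), , drop = FALSE]
  sel <- NULL
  last_end <- -1L
  for (r in seq_len(nrow(w))) {
    if (w[r, 1] > last_end) {
      sel <- rbind(sel, w[r, ])
      last_end <- w[r, 2]
    }
  }
  sel
}

# random CpG layout on one chromosome for DMR tests
random_layout <- function(n_cpg, dm_rate = 0.5) {
  pos <- sort(sample(1:20000, n_cpg))
  tibble::tibble(
    probe_id = sprintf("cg%03d", seq_len(n_cpg)),
    chrom = "chr1", pos = pos,
    dm = stats::runif(n_cpg) < dm_rate
  )
}

# run scan_dmrs on a layout tibble
scan_layout <- function(layout, ...) {
  meta <- tibble::tibble(probe_id = layout$probe_id, dm_flag = layout$dm)
  ann <- tibble::tibble(probe_id = layout$probe_id, chrom = layout$chrom,
                        pos = layout$pos)
  scan_dmrs(meta, ann, ...)
}
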