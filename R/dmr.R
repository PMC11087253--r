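# Scanning positionally sorted meta-analysis results for differentially
# methylated regions (DMRs).
#
# A candidate region is a run of consecutive CpGs (DM or not) on one
# chromosome that starts and ends at a DM CpG, has every consecutive pair of
# member CpGs closer than `max_gap_bp`, contains at least `min_dm` DM CpGs
# and at most `max_nondm` non-DM CpGs. Reported regions are maximal (not
# contained in any other candidate) and mutually non-overlapping, selected
# greedily left to right.

#' Call DMRs from meta-analysis results
#'
#' Implements the region rule of three or more DM CpGs with inter-CpG
#' distance below 1 kb, allowing up to three interspersed non-DM CpGs.
#' By default the distance constraint applies between consecutive member
#' CpGs whether DM or not (`gap_between = "members"`); the looser
#' `"dm_only"` variant constrains only consecutive DM CpGs.
#'
#' @param meta Meta-analysis tibble from [meta_ewas()] (needs `probe_id`,
#'   `dm_flag`).
#' @param annotation Probe annotation with `probe_id`, `chrom`, `pos`
#'   covering every probe in `meta`.
#' @param min_dm Minimum DM CpGs per region (default 3).
#' @param max_gap_bp Maximum distance between consecutive CpGs (default 1000,
#'   i.e. gaps must be < 1 kb).
#' @param max_nondm Maximum interspersed non-DM CpGs (default 3).
#' @param gap_between Which consecutive pairs the gap rule binds:
#'   `"members"` (default) or `"dm_only"`.
#' @return Tibble with one row per DMR: `chrom`, `start`, `end` (positions of
#'   the first/last DM CpG), `n_dm`, `n_nondm`, and a `probe_ids`
#'   list-column of ordered member probes.
#' @export
scan_dmrs <- function(meta, annotation, min_dm = 3, max_gap_bp = 1000,
                      max_nondm = 3, gap_between = c("members", "dm_only")) {
  gap_between <- match.arg(gap_between)
  if (!all(c("probe_id", "dm_flag") %in% names(meta))) {
    abort("`meta` needs columns probe_id and dm_flag")
  }
  missing <- setdiff(meta$probe_id, annotation$probe_id)
  if (length(missing)) {
    abort(sprintf("probes missing from annotation: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  n_dm = integer(), n_nondm = integer(), probe_ids = list())
  ann <- annotation[match(meta$probe_id, annotation$probe_id), c("chrom", "pos")]
  d <- tibble(probe_id = meta$probe_id, chrom = ann$chrom, pos = ann$pos,
              dm = meta$dm_flag)
  d <- dplyr::arrange(d, .data$chrom, .data$pos)
  if (!any(d$dm)) return(empty)

  res <- lapply(split(d, d$chrom), function(ch) {
    scan_chrom(ch, min_dm, max_gap_bp, max_nondm, gap_between)
  })
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) empty else dplyr::arrange(out, .data$chrom, .data$start)
}

# one chromosome, rows sorted by pos
scan_chrom <- function(ch, min_dm, max_gap_bp, max_nondm, gap_between) {
  n <- nrow(ch)
  dm <- ch$dm
  pos <- ch$pos

  # right-maximal end R(i) for each DM start i: walk right while the gap and
  # non-DM budgets allow, recording the farthest DM index with >= min_dm DM
  # members in the window
  right_end <- function(i) {
    ndm <- 0L; nnon <- 0L; best <- NA_integer_
    last_dm_pos <- NA_real_
    for (j in i:n) {
      if (j > i) {
        gap <- if (gap_between == "members") {
          pos[j] - pos[j - 1]
        } else if (dm[j]) {
          if (is.na(last_dm_pos)) Inf else pos[j] - last_dm_pos
        } else 0
        if (gap >= max_gap_bp) break
      }
      if (dm[j]) ndm <- ndm + 1L else nnon <- nnon + 1L
      if (nnon > max_nondm) break
      if (dm[j]) {
        last_dm_pos <- pos[j]
        if (ndm >= min_dm) best <- j
      }
    }
    best
  }

  starts <- which(dm)
  ends <- vapply(starts, right_end, integer(1))
  ok <- !is.na(ends)
  starts <- starts[ok]; ends <- ends[ok]
  if (!length(starts)) return(NULL)

  # maximality: [i, R(i)] is contained in an earlier candidate iff some
  # earlier valid start reaches at least as far
  keep <- ends > cummax(c(-1L, head(ends, -1)))
  starts <- starts[keep]; ends <- ends[keep]

  # greedy left-to-right non-overlapping selection
  sel_s <- integer(0); sel_e <- integer(0); last_end <- -1L
  for (k in seq_along(starts)) {
    if (starts[k] > last_end) {
      sel_s <- c(sel_s, starts[k]); sel_e <- c(sel_e, ends[k])
      last_end <- ends[k]
    }
  }
  dplyr::bind_rows(purrr::map2(sel_s, sel_e, function(i, j) {
    idx <- i:j
    tibble(chrom = ch$chrom[1], start = pos[i], end = pos[j],
           n_dm = sum(dm[idx]), n_nondm = sum(!dm[idx]),
           probe_ids = list(ch$probe_id[idx]))
  }))
}

#' Region-level significance for called DMRs
#'
#' Combines the member DM CpGs' signed meta-analysis z-scores per region.
#' With Stouffer's method (default) the combined z is `sum(z) / sqrt(m)`
#' over the m DM members, giving a two-sided p; Fisher's method combines the
#' members' two-sided p-values as `-2 sum log p ~ chi^2(2m)`. Region
#' p-values are BH-adjusted across all called DMRs.
#'
#' @param dmrs Output of [scan_dmrs()].
#' @param meta Meta-analysis tibble providing `z` and `p` per probe.
#' @param method `"stouffer"` (default) or `"fisher"`.
#' @return `dmrs` with `z_combined` (Stouffer only), `p_combined` and `q`.
#' @export
dmr_significance <- function(dmrs, meta, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  if (!nrow(dmrs)) {
    return(dplyr::mutate(dmrs, z_combined = numeric(0), p_combined = numeric(0),
                         q = numeric(0)))
  }
  dm_ids <- meta$probe_id[meta$dm_flag]
  stats <- purrr::map(dmrs$probe_ids, function(ids) {
    members <- intersect(ids, dm_ids)
    if (!length(members)) abort("DMR without DM member probes")
    i <- match(members, meta$probe_id)
    if (anyNA(i)) abort("DMR member probe missing from meta table")
    if (method == "stouffer") {
      zc <- sum(meta$z[i]) / sqrt(length(i))
      c(z = zc, p = 2 * pnorm(-abs(zc)))
    } else {
      stat <- -2 * sum(log(meta$p[i]))
      c(z = NA_real_, p = pchisq(stat, df = 2 * length(i), lower.tail = FALSE))
    }
  })
  stats <- do.call(rbind, stats)
  out <- dplyr::mutate(dmrs, z_combined = as.numeric(stats[, "z"]),
                       p_combined = as.numeric(stats[, "p"]))
  out$q <- adjust_bh(out$p_combined)
  out
}
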