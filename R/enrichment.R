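# Enrichment / depletion of DM CpGs across the 15 ChromHMM chromatin states.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Direct hypergeometric summation: conditioning on the table margins, the
#' p-value sums the probabilities of all tables as or less likely than the
#' observed one (the conventional tolerance factor 1 + 1e-7 guards the
#' comparison against floating-point ties).
#'
#' @param a,b,c,d Non-negative integer cell counts: `a` = DM in state,
#'   `b` = DM not in state, `c` = non-DM in state, `d` = non-DM not in state.
#' @return Two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  m <- a + c        # in-state total
  n <- b + d        # not-in-state total
  k <- a + b        # DM total
  x <- max(0, k - n):min(k, m)
  dens <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Chromatin-state enrichment of DM CpGs
#'
#' For each of the 15 ChromHMM states, tests whether DM CpGs are over- or
#' under-represented relative to the background of all meta-analysed probes
#' with a two-sided Fisher exact test; odds ratios are the sample
#' cross-product `(a d) / (b c)`. BH adjustment is applied across the
#' states that hold at least one tested probe; states with no probes are
#' reported with null counts and excluded from the adjustment.
#'
#' @param meta Meta-analysis tibble with `probe_id` and `dm_flag`.
#' @param annotation Probe annotation with `probe_id` and a single
#'   `chromatin_state` per probe.
#' @return Tibble with one row per state: `state`, cell counts `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p`, `q`.
#' @export
enrichment_by_state <- function(meta, annotation) {
  if (!all(c("probe_id", "dm_flag") %in% names(meta))) {
    abort("`meta` needs columns probe_id and dm_flag")
  }
  st <- annotation$chromatin_state[match(meta$probe_id, annotation$probe_id)]
  if (anyNA(st)) abort("every tested probe needs a chromatin state")
  dm <- meta$dm_flag
  n_dm <- sum(dm)
  n_tot <- length(dm)
  rows <- purrr::map(CHROMATIN_STATES, function(s) {
    in_state <- st == s
    a <- sum(dm & in_state)
    b <- n_dm - a
    c <- sum(!dm & in_state)
    d <- (n_tot - n_dm) - c
    if (a + c == 0) {
      inform(sprintf("enrichment_by_state: no tested probes in state %s", s))
      return(tibble(state = s, a = a, b = b, c = c, d = d,
                    odds_ratio = NA_real_, p = NA_real_))
    }
    or <- if (b > 0 && c > 0) (a * d) / (b * c) else if (a == 0) 0 else Inf
    tibble(state = s, a = a, b = b, c = c, d = d, odds_ratio = or,
           p = fisher_exact_p(a, b, c, d))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- adjust_bh(out$p[tested])
  out
}
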