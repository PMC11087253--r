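# Random-effects meta-analysis combining the per-model differential
# methylation results (DerSimonian-Laird between-study variance).

#' DerSimonian-Laird random-effects combination
#'
#' Combines k >= 2 study estimates with the method-of-moments between-study
#' variance: with fixed-effect weights `w_i = 1/se_i^2`,
#' `Q = sum w_i (b_i - b_FE)^2` and
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random-effects
#' weights are `1 / (se_i^2 + tau^2)`, giving the combined effect, its
#' standard error, `z = b/se` and a two-sided normal p-value.
#'
#' @param b Numeric vector of study effects (length k >= 2).
#' @param se Positive study standard errors, same length.
#' @return One-row tibble with `b_meta`, `se_meta`, `tau_sq`, `Q`, `z`, `p`.
#' @examples
#' random_effects_combine(c(0.1, 0.3), c(0.1, 0.1))
#' @export
random_effects_combine <- function(b, se) {
  if (length(b) < 2) abort("need at least 2 studies")
  if (length(se) != length(b)) abort("`b` and `se` must have equal length")
  if (any(!is.finite(se)) || any(se <= 0)) abort("all standard errors must be > 0")
  w <- 1 / se^2
  b_fe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - b_fe)^2)
  k <- length(b)
  tau_sq <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau_sq)
  b_meta <- sum(ws * b) / sum(ws)
  se_meta <- 1 / sqrt(sum(ws))
  z <- b_meta / se_meta
  tibble(b_meta = b_meta, se_meta = se_meta, tau_sq = tau_sq, Q = Q,
         z = z, p = 2 * pnorm(-abs(z)))
}

#' Epigenome-wide meta-analysis of the two organoid models
#'
#' Probes present in both per-model tables are combined with the
#' DerSimonian-Laird random-effects model; BH FDR is computed across all
#' combined probes and the DM flag set at `q < fdr_threshold`. Probes seen
#' in only one model are excluded (a random-effects estimate needs k >= 2)
#' and reported through the `excluded` attribute.
#'
#' @param dm_spherical,dm_cylindrical Per-model result tibbles from
#'   [dm_analyze()] (need `probe_id`, `b`, `se`).
#' @param fdr_threshold DM call threshold on the BH q-value (default 0.01).
#' @return Tibble with one row per shared probe: `probe_id`, `b_meta`,
#'   `se_meta`, `tau_sq`, `Q`, `z`, `p`, `q`, `dm_flag`. Attribute
#'   `excluded` holds the probe ids seen in only one model.
#' @export
meta_ewas <- function(dm_spherical, dm_cylindrical, fdr_threshold = 0.01) {
  check_prob(fdr_threshold, "fdr_threshold")
  for (d in list(dm_spherical, dm_cylindrical)) {
    if (!all(c("probe_id", "b", "se") %in% names(d))) {
      abort("per-model tables need columns probe_id, b, se")
    }
  }
  shared <- intersect(dm_spherical$probe_id, dm_cylindrical$probe_id)
  if (!length(shared)) abort("no probes shared between the two models")
  only <- c(setdiff(dm_spherical$probe_id, shared),
            setdiff(dm_cylindrical$probe_id, shared))
  if (length(only)) {
    inform(sprintf("meta_ewas: %d probe(s) present in only one model excluded", length(only)))
  }
  a <- dm_spherical[match(shared, dm_spherical$probe_id), ]
  b <- dm_cylindrical[match(shared, dm_cylindrical$probe_id), ]

  # vectorized two-study DerSimonian-Laird (same algebra as
  # random_effects_combine, k = 2)
  w1 <- 1 / a$se^2; w2 <- 1 / b$se^2
  sw <- w1 + w2
  b_fe <- (w1 * a$b + w2 * b$b) / sw
  Q <- w1 * (a$b - b_fe)^2 + w2 * (b$b - b_fe)^2
  tau_sq <- pmax(0, (Q - 1) / (sw - (w1^2 + w2^2) / sw))
  ws1 <- 1 / (a$se^2 + tau_sq); ws2 <- 1 / (b$se^2 + tau_sq)
  b_meta <- (ws1 * a$b + ws2 * b$b) / (ws1 + ws2)
  se_meta <- 1 / sqrt(ws1 + ws2)
  z <- b_meta / se_meta
  p <- 2 * pnorm(-abs(z))
  out <- tibble(
    probe_id = shared, b_meta = b_meta, se_meta = se_meta, tau_sq = tau_sq,
    Q = Q, z = z, p = p, q = adjust_bh(p)
  )
  out$dm_flag <- out$q < fdr_threshold
  attr(out, "excluded") <- only
  out
}
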