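# Two-group differential analysis with empirical-Bayes moderated
# t-statistics, implemented from the closed-form shrinkage equations.
#
# Per probe g the two-group fit gives the difference b_g with unscaled
# variance factor v_g = 1/n1 + 1/n0, residual variance s_g^2 on d_g = n - 2
# df. The s_g^2 are shrunk toward a prior (d_0, s_0^2) estimated by matching
# moments of log s_g^2: for s_g^2 ~ s0^2 * F(d_g, d_0),
#   E[log s_g^2]   = log s0^2 + digamma(d_g/2) - log(d_g/2)
#                              - digamma(d_0/2) + log(d_0/2)
#   Var[log s_g^2] = trigamma(d_g/2) + trigamma(d_0/2)
# so trigamma(d_0/2) = var(log s^2) - trigamma(d_g/2), solved by monotone
# bisection. The posterior variance is the df-weighted mix
#   s_post^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)
# and t_mod = b_g / sqrt(s_post^2 v_g) is referred to a t distribution on
# d_0 + d_g df. d_0 = 0 recovers the ordinary pooled t; d_0 = Inf fixes
# every variance at s_0^2.

#' Per-probe two-group linear fit
#'
#' Ordinary least squares of each probe (row) on the loading indicator:
#' `b = mean(loaded) - mean(control)`, `v = 1/n_loaded + 1/n_control`,
#' pooled residual variance on `n - 2` degrees of freedom. Vectorized over
#' probes.
#'
#' @param values Probe x sample numeric matrix (beta- or M-values).
#' @param condition Per-sample condition, values "loaded"/"control" (order
#'   matches columns). Each group needs >= 2 samples.
#' @return Tibble with `probe_id`, `b` (group difference), `v` (unscaled
#'   variance factor), `s2` (residual variance), `df_residual`.
#' @export
fit_linear_model <- function(values, condition) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) abort("`condition` must match the sample columns")
  bad <- setdiff(unique(condition), c("loaded", "control"))
  if (length(bad)) abort("`condition` values must be 'loaded' or 'control'")
  n1 <- sum(condition == "loaded")
  n0 <- sum(condition == "control")
  if (n1 < 2 || n0 < 2) abort("each group needs at least 2 samples")
  yl <- values[, condition == "loaded", drop = FALSE]
  yc <- values[, condition == "control", drop = FALSE]
  ml <- rowMeans(yl)
  mc <- rowMeans(yc)
  rss <- rowSums((yl - ml)^2) + rowSums((yc - mc)^2)
  df <- n1 + n0 - 2L
  tibble(
    probe_id = rownames(values) %||% as.character(seq_len(nrow(values))),
    b = unname(ml - mc),
    v = 1 / n1 + 1 / n0,
    s2 = unname(rss / df),
    df_residual = df
  )
}

# internal: solve trigamma(x) = y for x > 0 by bisection (trigamma is
# strictly decreasing); y must be positive
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  lo <- 1e-8
  hi <- 1
  while (trigamma(hi) > y) hi <- hi * 2     # expand until trigamma(hi) <= y
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < 1e-12 * max(1, hi)) break
  }
  (lo + hi) / 2
}

#' Empirical-Bayes moderation of per-probe variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq`
#' from the spread of the log residual variances (method of moments with
#' digamma/trigamma corrections, see the source header), shrinks each
#' probe's variance toward the prior, and forms moderated t-statistics with
#' `d0 + df_residual` degrees of freedom. When the observed log-variance
#' spread does not exceed what sampling alone implies, `d0` is infinite and
#' every posterior variance equals `s0_sq`. Probes with zero residual
#' variance are excluded from hyperparameter estimation (their log-variance
#' is undefined) but still receive moderated statistics.
#'
#' @param fits Tibble from [fit_linear_model()] (all probes must share
#'   `df_residual`).
#' @param d0 Optional forced prior degrees of freedom: `0` gives the
#'   ordinary pooled t, `Inf` fully pooled variances. Default `NULL`
#'   estimates d0 from the data.
#' @param s0_sq Optional forced prior variance; default `NULL` estimates it
#'   from the data. In the degenerate case of identical residual variances
#'   the prior variance is that common value.
#' @return A `moderated_fit` object: list with `table` (tibble of
#'   `probe_id`, `b`, `se`, `t`, `df_total`, `p.value`, `q.value`), `d0`,
#'   `s0_sq`, `df_residual`, `n_probes`.
#' @export
ebayes_moderate <- function(fits, d0 = NULL, s0_sq = NULL) {
  req <- c("probe_id", "b", "v", "s2", "df_residual")
  if (!all(req %in% names(fits))) abort("`fits` must come from fit_linear_model()")
  dg <- unique(fits$df_residual)
  if (length(dg) != 1) abort("all probes must share the residual degrees of freedom")
  s2 <- fits$s2
  pos <- s2 > 0
  if (!any(pos)) abort("degenerate input: all residual variances are zero")

  z <- log(s2[pos])
  vz <- var(z)
  if (is.null(d0)) {
    if (sum(pos) < 10) abort("need >= 10 probes with positive residual variance")
    excess <- vz - trigamma(dg / 2)
    d0 <- if (excess <= 0) Inf else 2 * trigamma_inverse(excess)
  } else if (d0 < 0) {
    abort("`d0` must be >= 0")
  }
  if (is.null(s0_sq)) {
    s0_sq <- if (vz < 1e-10) {
      # no scatter at all: the common residual variance is the prior
      exp(mean(z))
    } else if (is.infinite(d0)) {
      exp(mean(z) - digamma(dg / 2) + log(dg / 2))
    } else if (d0 == 0) {
      NA_real_
    } else {
      exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
            digamma(d0 / 2) - log(d0 / 2))
    }
  }

  if (is.infinite(d0)) {
    s_post <- rep(s0_sq, nrow(fits))
    df_total <- Inf
  } else if (d0 == 0) {
    s_post <- s2
    df_total <- dg
  } else {
    s_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  se <- sqrt(s_post * fits$v)
  t <- fits$b / se
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t)) else 2 * pt(-abs(t), df_total)
  tab <- tibble(
    probe_id = fits$probe_id, b = fits$b, se = se, t = t,
    df_total = df_total, p.value = p, q.value = adjust_bh(p)
  )
  structure(list(table = tab, d0 = d0, s0_sq = s0_sq, df_residual = dg,
                 n_probes = nrow(fits)),
            class = "moderated_fit")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %d probes, d0 = %s, s0_sq = %s, df = %d + d0\n",
              x$n_probes, format(x$d0, digits = 4),
              format(x$s0_sq, digits = 4), x$df_residual))
  invisible(x)
}

#' @rdname ebayes_moderate
#' @param x A `moderated_fit` object.
#' @param ... Unused.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname ebayes_moderate
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, df_residual = x$df_residual,
         n_probes = x$n_probes)
}

#' Differential methylation for one model
#'
#' Two-group moderated-t analysis of a QC'd dataset under the design
#' `~ loading`. The default analysis scale is the beta-value, so effect
#' sizes are methylation-fraction differences; `scale = "m"` analyses
#' M-values instead.
#'
#' @param ds A [methyl_dataset()].
#' @param scale `"beta"` (default) or `"m"`.
#' @return Tibble with `probe_id`, `b`, `se`, `t`, `df_total`, `p.value`,
#'   `q.value`, plus a `model` column.
#' @export
dm_analyze <- function(ds, scale = c("beta", "m")) {
  stopifnot(inherits(ds, "methyl_dataset"))
  scale <- match.arg(scale)
  values <- if (scale == "m") beta_to_m(ds$beta) else ds$beta
  fit <- fit_linear_model(values, ds$samples$condition)
  mod <- ebayes_moderate(fit)
  dplyr::mutate(tidy(mod), model = ds$model_label)
}
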