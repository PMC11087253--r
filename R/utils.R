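# Small shared numerical helpers used across the pipeline.

#' Convert beta-values to M-values and back
#'
#' M-values are the log2-logit transform of methylation beta-values,
#' `M = log2(beta / (1 - beta))`, the variance-stabilised scale commonly used
#' for linear modelling of array methylation data. Values are clipped to
#' `[eps, 1 - eps]` before the transform so boundary betas do not map to
#' infinities; clipping is reported via a message.
#'
#' @param beta Numeric vector or matrix of beta-values in (0, 1).
#' @param m Numeric vector or matrix of M-values.
#' @param eps Clipping bound applied to `beta` before the logit (default 1e-6).
#' @return `beta_to_m()` returns M-values; `m_to_beta()` returns beta-values.
#'   Dimensions and names are preserved.
#' @examples
#' beta_to_m(0.8) # log2(4) = 2
#' m_to_beta(beta_to_m(0.37))
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(is.numeric(beta))
  n_clip <- sum(beta < eps | beta > 1 - eps, na.rm = TRUE)
  if (n_clip > 0) {
    inform(sprintf("beta_to_m: clipped %d value(s) to [%g, %g]", n_clip, eps, 1 - eps))
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  out
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  stopifnot(is.numeric(m))
  1 / (1 + 2^(-m))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Input order is preserved and the
#' output satisfies `q >= p` elementwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted q-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  if (length(p) && (min(p, na.rm = TRUE) < 0 || max(p, na.rm = TRUE) > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Bonferroni significance threshold
#'
#' The family-wise threshold `alpha / n_tests`. For an epigenome-wide analysis
#' of 800,883 probes at alpha = 0.05 this is 6.243109e-08.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests; must be >= 1.
#' @return The per-test significance threshold.
#' @examples
#' bonferroni_threshold(0.05, 800883)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(n_tests) || length(n_tests) != 1 || n_tests < 1) {
    abort("`n_tests` must be a single count >= 1")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  alpha / n_tests
}

# internal: validate a probability-like scalar
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single value in (0, 1)", name))
  }
  invisible(x)
}
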