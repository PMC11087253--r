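# Clinical severity association for selected CpGs and the targeted RT-qPCR
# statistics (delta-Ct, fold change, loading-effect model).

#' Association of CpG methylation with radiographic OA severity
#'
#' Ordinary least squares of the CpG's methylation on the Kellgren-Lawrence
#' grade with BMI and age as covariates, returning the KL coefficient. The
#' default models the beta-value directly (so the slope is a methylation
#' fraction per KL grade); `scale = "logit"` models the natural-logit of
#' the beta instead, matching the scale the synthetic cohort generator
#' plants its slope on. `direction = "kl_on_meth"` swaps response and
#' predictor (KL regressed on methylation, BMI, age).
#'
#' @param clinical Tibble with `kl_score`, `bmi`, `age` and one beta column
#'   per CpG; at least 10 complete rows.
#' @param cpg Name of the CpG column to test.
#' @param scale `"beta"` (default) or `"logit"`.
#' @param direction `"meth_on_kl"` (default) or `"kl_on_meth"`.
#' @param covariates Adjustment columns (default BMI and age).
#' @return One-row tibble with `cpg`, `slope`, `se`, `p`, `n`.
#' @export
correlate_with_severity <- function(clinical, cpg,
                                    scale = c("beta", "logit"),
                                    direction = c("meth_on_kl", "kl_on_meth"),
                                    covariates = c("bmi", "age")) {
  scale <- match.arg(scale)
  direction <- match.arg(direction)
  need <- unique(c(cpg, "kl_score", covariates))
  if (!all(need %in% names(clinical))) {
    abort(sprintf("clinical table needs columns: %s", paste(need, collapse = ", ")))
  }
  d <- clinical[complete.cases(clinical[, need]), need]
  if (nrow(d) < 10) abort("need at least 10 complete patients")
  meth <- if (scale == "logit") qlogis(pmin(pmax(d[[cpg]], 1e-6), 1 - 1e-6)) else d[[cpg]]
  covs <- as.matrix(d[, covariates, drop = FALSE])
  if (direction == "meth_on_kl") {
    X <- cbind(1, d$kl_score, covs)
    yv <- meth
    term <- 2L
  } else {
    X <- cbind(1, meth, covs)
    yv <- d$kl_score
    term <- 2L
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X) || kappa(X, exact = TRUE) > 1e10) {
    abort("singular or near-singular design (collinear covariates)")
  }
  fit <- lm.fit(X, yv)
  df <- nrow(X) - ncol(X)
  s2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(s2 * xtx_inv[term, term])
  slope <- fit$coefficients[term]
  tibble(cpg = cpg, slope = unname(slope), se = se,
         p = 2 * pt(-abs(slope / se), df), n = nrow(X))
}

#' Delta-Ct against the mean of housekeeping genes
#'
#' `deltaCt = Ct(gene of interest) - mean(Ct(housekeeping genes))`.
#'
#' @param ct_goi Ct of the gene of interest (cycles).
#' @param ct_housekeeping Numeric vector of housekeeping Cts (>= 1 value).
#' @return The delta-Ct in cycles.
#' @examples
#' delta_ct(22, c(18, 20)) # 3
#' @export
delta_ct <- function(ct_goi, ct_housekeeping) {
  if (!length(ct_housekeeping)) abort("need at least one housekeeping Ct")
  ct_goi - mean(ct_housekeeping)
}

#' Fold change by the 2^-ddCt method
#'
#' `fc = 2^-(deltaCt_treated - deltaCt_control)`.
#'
#' @param dct_treated,dct_control Finite delta-Ct values.
#' @return The expression fold change.
#' @examples
#' fold_change(2, 3) # ddCt = -1, fc = 2
#' @export
fold_change <- function(dct_treated, dct_control) {
  2^(-(dct_treated - dct_control))
}

#' Loading effect on -deltaCt expression levels
#'
#' Gaussian linear model of `-deltaCt` on the loading indicator (loaded = 1)
#' for one gene: the coefficient is the loading-induced shift in relative
#' expression (cycles), with a two-sided t-test p-value.
#'
#' @param records qPCR tibble with `condition`, `gene`, `ct_goi` and
#'   housekeeping columns `ct_gapdh`, `ct_sdha` (or a precomputed
#'   `minus_delta_ct` column).
#' @param gene Gene to test.
#' @return One-row tibble with `gene`, `estimate`, `se`, `p`, `n_loaded`,
#'   `n_control`.
#' @export
loading_effect_glm <- function(records, gene) {
  d <- records[records$gene == gene, , drop = FALSE]
  if (!nrow(d)) abort(sprintf("no records for gene %s", gene))
  if (!"minus_delta_ct" %in% names(d)) {
    hk <- (d$ct_gapdh + d$ct_sdha) / 2
    d$minus_delta_ct <- -(d$ct_goi - hk)
  }
  n1 <- sum(d$condition == "loaded")
  n0 <- sum(d$condition == "control")
  if (n1 < 2 || n0 < 2) abort("need at least 2 samples per condition")
  fit <- lm(minus_delta_ct ~ I(condition == "loaded"), data = d)
  sm <- summary(fit)$coefficients
  tibble(gene = gene, estimate = sm[2, 1], se = sm[2, 2], p = sm[2, 4],
         n_loaded = n1, n_control = n0)
}
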