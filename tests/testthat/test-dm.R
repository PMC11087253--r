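test_that("two-group fit matches an independent least-squares oracle", {
  set.seed(1)
  y <- matrix(rnorm(50 * 14), 50, 14)
  cond <- rep(c("loaded", "control"), c(6, 8))
  fit <- fit_linear_model(y, cond)
  for (i in seq_len(nrow(y))) {
    lmfit <- lm(y[i, ] ~ I(cond == "loaded"))
    expect_equal(fit$b[i], unname(coef(lmfit)[2]), tolerance = 1e-10)
    expect_equal(fit$s2[i], summary(lmfit)$sigma^2, tolerance = 1e-10)
  }
  expect_equal(fit$v, rep(1 / 6 + 1 / 8, 50))
  expect_equal(fit$df_residual, rep(12L, 50))

  # null and degenerate cases
  y0 <- cbind(y[, 1:4], y[, 1:4])
  f0 <- fit_linear_model(y0, rep(c("loaded", "control"), each = 4))
  expect_equal(f0$b, rep(0, 50))
  yc <- matrix(rep(c(1, 2), each = 4), 5, 8, byrow = TRUE)
  fc <- fit_linear_model(yc, rep(c("loaded", "control"), each = 4))
  expect_equal(fc$s2, rep(0, 5))
  expect_error(fit_linear_model(y[, 1:3], c("loaded", "control", "control")),
               "at least 2")
})

test_that("moderation limits recover the pooled t and the fully shrunk statistic", {
  set.seed(2)
  y <- matrix(rnorm(200 * 12, sd = runif(200, 0.5, 2)), 200, 12)
  cond <- rep(c("loaded", "control"), each = 6)
  fit <- fit_linear_model(y, cond)

  # d0 = 0: ordinary pooled two-sample t
  m0 <- ebayes_moderate(fit, d0 = 0)
  t_pool <- fit$b / sqrt(fit$s2 * fit$v)
  expect_lt(max(abs(m0$table$t - t_pool)), 1e-10)
  expect_equal(m0$table$df_total, rep(10, 200))

  # equal variances: d0 estimated infinite, s_post = s0 = common s2
  yeq <- matrix(rnorm(50 * 12), 50, 12)
  feq <- fit_linear_model(yeq, cond)
  feq$s2 <- rep(1.7, 50)
  meq <- ebayes_moderate(feq)
  expect_equal(meq$d0, Inf)
  expect_equal(meq$s0_sq, 1.7, tolerance = 1e-12)
  expect_equal(unique(meq$table$se), sqrt(1.7 * feq$v[1]))

  # shrinkage is monotone in d0 toward the fully pooled statistic (fixed prior)
  s0 <- median(fit$s2)
  t_inf <- fit$b / sqrt(s0 * fit$v)
  ts <- sapply(c(0, 1, 5, 50, 5000), function(d) {
    ebayes_moderate(fit, d0 = d, s0_sq = s0)$table$t
  })
  gaps <- abs(ts - t_inf)
  expect_true(all(diff(t(gaps)) <= 1e-8))

  expect_error(ebayes_moderate(dplyr::mutate(fit, s2 = 0)), "degenerate")
})

test_that("estimated hyperparameters and statistics match limma's empirical Bayes", {
  set.seed(3)
  sigma <- sqrt(0.01 * 4 / stats::rchisq(300, 4))
  y <- matrix(rnorm(300 * 16, sd = rep(sigma, 16)), 300, 16)
  cond <- rep(c("loaded", "control"), each = 8)
  mine <- ebayes_moderate(fit_linear_model(y, cond))
  lf <- limma::eBayes(limma::lmFit(y, cbind(1, cond == "loaded")))
  expect_equal(mine$d0, lf$df.prior, tolerance = 1e-9)
  expect_equal(mine$s0_sq, lf$s2.prior, tolerance = 1e-9)
  expect_equal(mine$table$t, unname(lf$t[, 2]), tolerance = 1e-9)
  expect_equal(mine$table$p.value, unname(lf$p.value[, 2]), tolerance = 1e-9)
})

test_that("per-model p-values are uniform under the simulated global null", {
  d <- study_design(n_probes = 2000, n_genes = 100)
  ks <- sapply(1:5, function(s) {
    ann <- simulate_probe_annotation(d, seed = s)
    sim <- simulate_methylation(d, effect_spec(frac_dm = 0, tau_model = 0,
                                               frac_snp_like = 0, frac_fail = 0),
                                ann, seed = s)
    p <- dm_analyze(sim$datasets$spherical)$p.value
    suppressWarnings(stats::ks.test(p, "punif")$statistic)
  })
  expect_true(all(ks < 0.05))
})

test_that("tidy/glance/autoplot expose the moderated fit", {
  set.seed(4)
  y <- matrix(rnorm(30 * 8), 30, 8)
  m <- ebayes_moderate(fit_linear_model(y, rep(c("loaded", "control"), each = 4)))
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("probe_id", "b", "se", "t", "df_total", "p.value", "q.value"))
  gl <- glance(m)
  expect_equal(gl$n_probes, 30)
  expect_s3_class(ggplot2::autoplot(m), "ggplot")
})
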