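test_that("detection filter removes exactly the probes failing in any sample", {
  set.seed(1)
  beta <- matrix(runif(200, 0.2, 0.8), 20, 10)
  ds <- make_dataset(beta)
  expect_equal(filter_detection(ds)$removed, character(0))

  detp <- matrix(0, 20, 10, dimnames = dimnames(ds$beta))
  detp[3, 7] <- 0.02
  ds2 <- make_dataset(beta, detp = detp)
  expect_equal(filter_detection(ds2)$removed, "p003")

  # random detection matrix vs an exhaustive per-cell scan
  detp3 <- matrix(sample(c(0, 0.005, 0.02, 0.5), 200, replace = TRUE, prob = c(.7, .1, .1, .1)),
                  20, 10, dimnames = dimnames(ds$beta))
  ds3 <- make_dataset(beta, detp = detp3)
  removed <- filter_detection(ds3, p_thresh = 0.01)$removed
  oracle <- rownames(detp3)[apply(detp3, 1, function(r) any(r > 0.01))]
  expect_setequal(removed, oracle)
})

test_that("quantile normalization equalizes column distributions", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(x)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  y <- matrix(rep(c(0.1, 0.5, 0.9), 4), 3, 4)
  expect_equal(quantile_normalize(y), y)

  set.seed(3)
  z <- matrix(rnorm(600), 60, 10)
  zn <- quantile_normalize(z)
  sorted <- apply(zn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  expect_equal(quantile_normalize(zn), zn, tolerance = 1e-12)
  expect_warning(quantile_normalize(z[, 1, drop = FALSE]), "fewer than 2")
})

test_that("control-probe normalization removes exactly the control components", {
  set.seed(4)
  n_s <- 12
  controls <- matrix(rnorm(5 * n_s), 5, n_s)
  values <- matrix(rnorm(30 * n_s), 30, n_s)
  expect_equal(control_probe_normalize(values, controls, k = 0), values)
  expect_error(control_probe_normalize(values, controls, k = 12), "smaller")

  const <- matrix(1, 4, n_s)
  expect_equal(control_probe_normalize(values, const, k = 2), values)

  # rows constructed as mean + c * PC1(controls) must come back flat
  cs <- scale(t(controls))
  pc1 <- stats::prcomp(cs, center = FALSE)$x[, 1]
  built <- outer(seq(0.1, 1, length.out = 15), pc1) + 0.5
  out <- control_probe_normalize(built, controls, k = 2)
  expect_lt(max(abs(out - rowMeans(built))), 1e-8)
})

test_that("SNP-like flagging separates trimodal probes from unimodal ones", {
  set.seed(5)
  ns <- 26
  uni <- matrix(pmin(pmax(rnorm(40 * ns, 0.5, 0.03), 0.01), 0.99), 40, ns)
  ds_uni <- make_dataset(uni)
  expect_false(any(flag_snp_like(ds_uni)$flagged))

  # planted trimodal probe at the canonical genotype pattern
  geno <- rbinom(ns, 2, 0.5)
  tri <- plogis(qlogis(c(0.05, 0.5, 0.95)[geno + 1]) + rnorm(ns, 0, 0.1))
  dst <- make_dataset(rbind(uni, tri))
  flags <- flag_snp_like(dst)
  expect_true(flags$flagged[41])
  expect_gt(flags$confidence[41], 0.5)
})

test_that("SNP-like flagging hits the sensitivity/specificity targets on planted data", {
  d <- study_design(n_probes = 1000, n_genes = 100)
  ann <- simulate_probe_annotation(d, seed = 6)
  sim <- simulate_methylation(d, effect_spec(frac_dm = 0, tau_model = 0,
                                             frac_snp_like = 0.05, frac_fail = 0),
                              ann, seed = 6)
  ds <- sim$datasets$spherical
  flags <- flag_snp_like(ds)
  truth_snp <- flags$probe_id %in% sim$truth$snp_like
  sens <- mean(flags$flagged[truth_snp])
  spec <- mean(!flags$flagged[!truth_snp])
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.95)
})

test_that("blacklist removal is an exact set difference", {
  set.seed(7)
  ds <- make_dataset(matrix(runif(100, 0.2, 0.8), 20, 5))
  expect_equal(rownames(remove_blacklisted(ds, character(0))$beta), rownames(ds$beta))
  expect_message(
    out <- remove_blacklisted(ds, c("p001", "p005", "p009", "nope1", "nope2")),
    "2 blacklist id"
  )
  expect_equal(nrow(out$beta), 17)
  expect_false(any(c("p001", "p005", "p009") %in% rownames(out$beta)))
  expect_warning(remove_blacklisted(ds, rownames(ds$beta)), "all probes")

  bl_file <- withr::local_tempfile(lines = c("p002", "p004"))
  expect_equal(nrow(remove_blacklisted(ds, bl_file)$beta), 18)
})

test_that("QC filters commute and the report reconciles with the sets", {
  d <- study_design(n_probes = 500, n_genes = 50)
  ann <- simulate_probe_annotation(d, seed = 8)
  sim <- simulate_methylation(d, effect_spec(frac_snp_like = 0.04, frac_fail = 0.002),
                              ann, seed = 8)
  ds <- sim$datasets$spherical
  bl <- sample(rownames(ds$beta), 20)

  # order-insensitivity of the retained set (no normalization in between)
  det <- filter_detection(ds)$dataset
  snp_first <- flag_snp_like(ds)
  a <- remove_blacklisted(
    mechamethyl:::subset_probes(det, setdiff(rownames(det$beta),
                                             snp_first$probe_id[snp_first$flagged])), bl)
  b1 <- remove_blacklisted(ds, bl)
  snp_b <- flag_snp_like(b1)
  b2 <- filter_detection(
    mechamethyl:::subset_probes(b1, setdiff(rownames(b1$beta),
                                            snp_b$probe_id[snp_b$flagged])))$dataset
  expect_setequal(rownames(a$beta), rownames(b2$beta))

  qc <- run_qc(ds, blacklist = bl)
  r <- qc$report
  expect_equal(r$n_retained,
               r$n_input_probes - r$n_failed_detection - r$n_missing -
                 r$n_snp_like - r$n_blacklisted)
  expect_equal(r$n_retained, nrow(qc$dataset$beta))
})
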