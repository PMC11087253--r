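test_that("study design validation enforces arm sizes and probe/gene counts", {
  expect_error(study_design(n_loaded_spherical = 1), "invalid design")
  expect_error(study_design(n_probes = 10, n_genes = 20), "invalid design")
  d <- study_design()
  sheet <- design_sample_sheet(d)
  expect_equal(nrow(sheet), 53)
  expect_equal(sum(sheet$condition == "loaded"), 26)
  expect_equal(sum(sheet$condition == "control"), 27)
})

test_that("probe annotation is deterministic, complete and positionally sound", {
  d <- study_design(n_probes = 5000, n_genes = 500)
  ann <- simulate_probe_annotation(d, seed = 11)
  expect_identical(ann, simulate_probe_annotation(d, seed = 11))
  expect_equal(nrow(ann), 5000)
  # all 15 chromatin states present
  expect_setequal(unique(ann$chromatin_state), mechamethyl:::CHROMATIN_STATES)
  # exhaustive per-chromosome scan: strictly increasing, unique positions
  for (ch in unique(ann$chrom)) {
    pos <- ann$pos[ann$chrom == ch]
    expect_true(all(diff(pos) > 0))
    expect_equal(anyDuplicated(pos), 0)
  }
  # categories drawn from the known vocabulary
  cats <- unlist(strsplit(stats::na.omit(ann$category), ";"))
  expect_true(all(cats %in% mechamethyl:::GENE_CATEGORIES))
  # empty case
  empty <- simulate_probe_annotation(study_design(n_probes = 0, n_genes = 0))
  expect_equal(nrow(empty), 0)
})

test_that("methylation generator plants recoverable effects and respects ranges", {
  d <- study_design(n_probes = 400, n_genes = 40)
  ann <- simulate_probe_annotation(d, seed = 3)
  eff <- effect_spec(frac_dm = 0.1, frac_snp_like = 0.02, frac_fail = 0.001)
  sim <- simulate_methylation(d, eff, ann, seed = 3)
  sim2 <- simulate_methylation(d, eff, ann, seed = 3)
  expect_identical(sim$datasets$spherical$beta, sim2$datasets$spherical$beta)
  for (ds in sim$datasets) {
    expect_true(all(ds$beta > 0 & ds$beta < 1))
    expect_true(all(ds$detp >= 0 & ds$detp <= 1))
    expect_equal(dim(ds$beta), c(400, nrow(ds$samples)))
  }
  # truth-set consistency: planted DMRs hold >= 3 DM probes with gaps < 1 kb
  truth <- sim$truth
  expect_true(all(truth$dm$probe_id %in% ann$probe_id))
  for (i in seq_len(nrow(truth$planted_dmrs))) {
    ids <- truth$planted_dmrs$probe_ids[[i]]
    expect_gte(sum(ids %in% truth$dm$probe_id), 3)
    pos <- ann$pos[match(ids, ann$probe_id)]
    expect_true(all(diff(pos) < 1000))
  }
  # DM and SNP-like sets are disjoint
  expect_length(intersect(truth$dm$probe_id, truth$snp_like), 0)
})

test_that("null effect spec gives no group difference beyond noise", {
  d <- study_design(n_probes = 300, n_genes = 30)
  ann <- simulate_probe_annotation(d, seed = 5)
  sim <- simulate_methylation(d, effect_spec(frac_dm = 0, tau_model = 0,
                                             frac_snp_like = 0), ann, seed = 5)
  ds <- sim$datasets$spherical
  m <- qlogis(ds$beta)
  diff <- rowMeans(m[, ds$samples$condition == "loaded"]) -
    rowMeans(m[, ds$samples$condition == "control"])
  # mean over probes of the group difference: SE = noise_sd * sqrt(v / n_probes)
  se <- 0.5 * sqrt((1 / 13 + 1 / 13) / nrow(m))
  expect_lt(abs(mean(diff)), 3 * se)
})

test_that("planted logit shift is recovered at Monte-Carlo scale", {
  d <- study_design(100, 100, 2, 2, n_probes = 300, n_genes = 30)
  ann <- simulate_probe_annotation(d, seed = 6)
  eff <- effect_spec(frac_dm = 0.3, delta_m = 1, tau_model = 0,
                     frac_snp_like = 0, frac_fail = 0)
  sim <- simulate_methylation(d, eff, ann, seed = 6)
  ds <- sim$datasets$spherical
  m <- qlogis(ds$beta)
  diff <- rowMeans(m[, ds$samples$condition == "loaded"]) -
    rowMeans(m[, ds$samples$condition == "control"])
  dm <- sim$truth$dm
  est <- mean(diff[match(dm$probe_id, rownames(m))] * sign(dm$delta))
  expect_equal(est, 1, tolerance = 0.05)
})

test_that("expression counts are integer, linked genes shifted by 2^lfc", {
  d <- study_design(50, 50, 2, 2, n_probes = 500, n_genes = 100)
  ann <- simulate_probe_annotation(d, seed = 7)
  eff <- effect_spec(frac_dm = 0.3, frac_linked_genes = 0.8, expr_lfc = 1)
  sim <- simulate_methylation(d, eff, ann, seed = 7)
  expr <- simulate_expression(d, eff, ann, sim$truth, seed = 7)
  expect_true(all(expr$counts >= 0))
  expect_true(all(expr$counts == round(expr$counts)))
  expect_equal(dim(expr$counts), c(100, 104))
  # library-size-corrected mean ratio at linked genes ~ 2^|lfc|
  sf <- colSums(expr$counts)
  cpm <- t(t(expr$counts) / sf)
  loaded <- expr$samples$condition == "loaded"
  linked <- sim$truth$linked_genes
  skip_if(nrow(linked) < 5)
  ratio <- rowMeans(cpm[linked$gene, loaded]) / rowMeans(cpm[linked$gene, !loaded])
  est <- mean(log2(ratio) * sign(linked$lfc))
  expect_equal(est, 1, tolerance = 0.2)
  # null linkage: no planted fold change
  sim0 <- simulate_methylation(d, effect_spec(frac_linked_genes = 0), ann, seed = 8)
  expect_equal(nrow(sim0$truth$linked_genes), 0)
})

test_that("clinical cohort covariates and KL grades are in range", {
  cl <- simulate_clinical(n_patients = 200, cpgs = c("cgA", "cgB"),
                          slopes = c(0, -0.1), seed = 9)
  expect_true(all(cl$kl_score %in% 1:4))
  expect_true(all(cl$cgA > 0 & cl$cgA < 1))
  expect_error(simulate_clinical(n_patients = 5), ">= 10")
  # zero slope: fitted KL coefficient indistinguishable from zero
  fit <- correlate_with_severity(cl, "cgA", scale = "logit")
  expect_lt(abs(fit$slope), 3 * fit$se)
})
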