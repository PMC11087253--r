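mk_meta <- function(ids, flag = TRUE) {
  tibble::tibble(probe_id = ids, dm_flag = flag,
                 b_meta = 0.05, q = 0.001)
}

test_that("CpG-gene mapping explodes annotations and excludes gene bodies", {
  ann <- tibble::tibble(
    probe_id = c("c1", "c2", "c3"),
    chrom = "chr1", pos = c(1L, 2L, 3L),
    gene = c("GeneA", "GeneA;GeneB", "GeneC"),
    category = c("TSS200", "TSS1500;5'UTR", "Body"),
    chromatin_state = "TssA"
  )
  pairs <- map_cpgs_to_genes(mk_meta(c("c1", "c2", "c3")), ann)
  expect_equal(nrow(pairs), 3)   # c3 is Body-only
  expect_setequal(pairs$gene[pairs$probe_id == "c2"], c("GeneA", "GeneB"))
  expect_false("c3" %in% pairs$probe_id)
  # non-DM probes never map
  expect_equal(nrow(map_cpgs_to_genes(mk_meta("c1", flag = FALSE), ann)), 0)
})

test_that("mapping totals match an explode-and-count oracle on random annotations", {
  set.seed(1)
  genes <- sprintf("G%02d", 1:20)
  cats <- mechamethyl:::GENE_CATEGORIES
  n <- 1000
  k <- sample(0:3, n, replace = TRUE)
  gene_col <- vapply(k, function(m) {
    if (m == 0) NA_character_ else paste(sample(genes, m), collapse = ";")
  }, "")
  cat_col <- vapply(k, function(m) {
    if (m == 0) NA_character_ else paste(sample(cats, m, replace = TRUE), collapse = ";")
  }, "")
  ann <- tibble::tibble(probe_id = sprintf("cg%04d", 1:n), chrom = "chr1",
                        pos = seq_len(n), gene = gene_col, category = cat_col,
                        chromatin_state = "TssA")
  pairs <- map_cpgs_to_genes(mk_meta(ann$probe_id), ann)
  # oracle: explode every annotation, filter categories, unique probe-gene
  oracle <- 0L
  for (i in seq_len(n)) {
    if (is.na(gene_col[i])) next
    g <- strsplit(gene_col[i], ";")[[1]]
    cc <- strsplit(cat_col[i], ";")[[1]]
    keep <- cc %in% setdiff(cats, "Body")
    oracle <- oracle + length(unique(g[keep]))
  }
  expect_equal(nrow(pairs), oracle)
})

test_that("differential expression is null-safe and library-size invariant", {
  set.seed(2)
  counts <- matrix(rnbinom(50 * 12, mu = 100, size = 10), 50, 12,
                   dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  samples <- tibble::tibble(sample_id = colnames(counts),
                            condition = rep(c("loaded", "control"), each = 6))
  # identical columns in both arms: log2 fold changes exactly zero
  sym <- cbind(counts[, 1:6], counts[, 1:6])
  colnames(sym) <- colnames(counts)
  de0 <- differential_expression(sym, samples)
  expect_equal(de0$log2fc, rep(0, nrow(de0)))

  # doubling one library leaves CPM-based fold changes unchanged
  de1 <- differential_expression(counts, samples)
  counts2 <- counts
  counts2[, 3] <- counts2[, 3] * 2L
  de2 <- differential_expression(counts2, samples)
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-6)

  # all-zero genes are dropped with a message
  counts3 <- rbind(counts, zero = 0L)
  expect_message(de3 <- differential_expression(counts3, samples), "all-zero")
  expect_false("zero" %in% de3$gene)
})

test_that("restricted-FDR prioritization reproduces the hand-worked example", {
  pairs <- tibble::tibble(
    probe_id = sprintf("c%d", 1:4), gene = sprintf("G%d", 1:4),
    category = "TSS200", meth_effect = 0.05, meth_q = 0.001
  )
  de <- tibble::tibble(gene = sprintf("G%d", 1:10),
                       log2fc = 1, se = 0.1, t = 5,
                       p.value = c(0.001, 0.01, 0.2, 0.9, runif(6)),
                       q.value = NA_real_)
  got <- prioritize_tcpgs(pairs, de, expr_fdr = 0.05)
  # BH within the 4 mapped genes: q = (0.004, 0.02, 0.267, 0.9)
  expect_setequal(got$gene, c("G1", "G2"))
  expect_equal(sort(unique(got$expr_q_restricted)), c(0.004, 0.02))
  expect_equal(attr(got, "n_mapped_genes"), 4L)
  expect_equal(attr(got, "n_genes"), 2L)

  # gene over the threshold loses all its pairs
  expect_false("G3" %in% got$gene)
  # empty pair list
  empty <- prioritize_tcpgs(pairs[0, ], de)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "n_genes"), 0L)
})

test_that("category summary and external overlap behave as tallies", {
  tc <- tibble::tibble(category = c("TSS200", "TSS200", "3'UTR", "3'UTR"))
  s <- region_category_summary(tc)
  expect_equal(sort(s$fraction), c(0.5, 0.5))
  s1 <- region_category_summary(tibble::tibble(category = rep("TSS200", 3)))
  expect_equal(s1$fraction, 1)
  # concatenated categories count once per occurrence and still sum to 1
  s2 <- region_category_summary(tibble::tibble(category = c("TSS200;5'UTR", "3'UTR")))
  expect_equal(sum(s2$fraction), 1, tolerance = 1e-12)
  expect_equal(nrow(region_category_summary(tc[0, ])), 0)

  ml <- tibble::tibble(probe_id = sprintf("c%d", 1:5), gene = sprintf("G%d", 1:5))
  expect_equal(overlap_tcpg_sets(ml, c("X1", "X2"))$n_overlap_genes, 0)
  expect_equal(overlap_tcpg_sets(ml, sprintf("g%d", 1:5))$n_overlap_genes, 5)
  set.seed(4)
  for (i in 1:10) {
    ext <- sample(sprintf("G%d", 1:10), 6)
    got <- overlap_tcpg_sets(ml, ext)
    expect_equal(got$n_overlap_genes, length(intersect(toupper(ml$gene), toupper(ext))))
  }
  both <- overlap_tcpg_sets(ml, tibble::tibble(probe_id = c("c1", "c9"),
                                               gene = c("G1", "G9")))
  expect_equal(both$n_overlap_pairs, 1)
  expect_warning(overlap_tcpg_sets(ml, character(0)), "empty")
})
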