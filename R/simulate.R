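# Synthetic-data generators. These plant known loading effects in paired
# methylation / expression / clinical datasets so that every downstream stage
# of the pipeline can be verified against a recorded truth set.

CHROMATIN_STATES <- c(
  "TssA", "TssAFlnk", "TxFlnk", "Tx", "TxWk", "Enh", "EnhG", "ZNF/Rpts",
  "Het", "TssBiv", "BivFlnk", "EnhBiv", "ReprPC", "ReprPCWk", "Quies"
)

GENE_CATEGORIES <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "ExonBnd", "3'UTR", "Body")

#' Study design for the two-organoid-model loading experiment
#'
#' Describes the sample layout of the loading experiment: two organoid models
#' (spherical neo-cartilage constructs and cylindrical agarose-embedded
#' constructs), each with a loaded and an unloaded control arm. The defaults
#' mirror the experiment's totals of 26 loaded and 27 control samples, split
#' 13/13 (spherical) and 13/14 (cylindrical); only the totals are fixed by the
#' experiment, the per-model split is configurable.
#'
#' @param n_loaded_spherical,n_control_spherical Samples per arm, spherical model.
#' @param n_loaded_cylindrical,n_control_cylindrical Samples per arm, cylindrical model.
#' @param n_probes Number of CpG probes in the synthetic array.
#' @param n_genes Number of genes in the synthetic transcriptome; must not
#'   exceed `n_probes`.
#' @return A `study_design` object (list).
#' @export
study_design <- function(n_loaded_spherical = 13, n_control_spherical = 13,
                         n_loaded_cylindrical = 13, n_control_cylindrical = 14,
                         n_probes = 5000, n_genes = 500) {
  arms <- c(n_loaded_spherical, n_control_spherical,
            n_loaded_cylindrical, n_control_cylindrical)
  if (any(!is.finite(arms)) || any(arms < 2) || any(arms != round(arms))) {
    abort("invalid design: every arm of every model needs an integer count >= 2")
  }
  if (!is.finite(n_probes) || n_probes < 0 || n_genes < 0 || n_probes < n_genes) {
    abort("invalid design: need n_probes >= n_genes >= 0")
  }
  structure(
    list(
      n_loaded_spherical = as.integer(n_loaded_spherical),
      n_control_spherical = as.integer(n_control_spherical),
      n_loaded_cylindrical = as.integer(n_loaded_cylindrical),
      n_control_cylindrical = as.integer(n_control_cylindrical),
      n_probes = as.integer(n_probes),
      n_genes = as.integer(n_genes)
    ),
    class = "study_design"
  )
}

#' Planted-effect specification for the synthetic generator
#'
#' Controls the structure planted into synthetic data. Loading effects are
#' planted additively on the natural-logit scale of the beta-value, where
#' Gaussian noise keeps betas inside (0, 1).
#'
#' Default magnitudes reflect the conditions the recovery analyses are run
#' under: a planted logit-scale shift of 1.0 at differentially methylated
#' (DM) probes, residual logit SD of 0.5 (equivalent to a within-group
#' beta-value SD of roughly 0.03-0.12 depending on the methylation level,
#' the noisy end of what Infinium arrays show), mild between-model
#' heterogeneity of the loading effect, and a planted expression log2
#' fold change of 1 at genes linked to DM probes.
#'
#' @param frac_dm Fraction of probes given a true loading effect.
#' @param delta_m Loading effect magnitude on the logit(beta) scale; each DM
#'   probe receives `+delta_m` or `-delta_m`.
#' @param tau_model SD of the between-model heterogeneity of the loading
#'   effect at DM probes (logit scale).
#' @param frac_dmr_clustered Fraction of DM probes placed in positional runs
#'   of five adjacent CpGs (planted DMRs).
#' @param frac_linked_genes Fraction of genes mapped to a DM probe (through a
#'   TSS/UTR/exon category) that receive a true expression fold change.
#' @param expr_lfc Planted expression log2 fold change magnitude.
#' @param frac_snp_like Fraction of probes given a SNP-like trimodal pattern.
#' @param frac_fail Fraction of probe-sample cells with a failed detection
#'   p-value.
#' @param noise_sd_m Residual SD on the logit(beta) scale.
#' @return An `effect_spec` object (list).
#' @export
effect_spec <- function(frac_dm = 0.05, delta_m = 1, tau_model = 0.2,
                        frac_dmr_clustered = 0.4, frac_linked_genes = 0.5,
                        expr_lfc = 1, frac_snp_like = 0.02, frac_fail = 5e-4,
                        noise_sd_m = 0.5) {
  fracs <- c(frac_dm = frac_dm, tau_model = NA, frac_dmr_clustered = frac_dmr_clustered,
             frac_linked_genes = frac_linked_genes, frac_snp_like = frac_snp_like,
             frac_fail = frac_fail)
  fr <- fracs[!is.na(fracs)]
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (!is.finite(noise_sd_m) || noise_sd_m <= 0) abort("`noise_sd_m` must be > 0")
  if (tau_model < 0) abort("`tau_model` must be >= 0")
  structure(
    list(frac_dm = frac_dm, delta_m = delta_m, tau_model = tau_model,
         frac_dmr_clustered = frac_dmr_clustered,
         frac_linked_genes = frac_linked_genes, expr_lfc = expr_lfc,
         frac_snp_like = frac_snp_like, frac_fail = frac_fail,
         noise_sd_m = noise_sd_m),
    class = "effect_spec"
  )
}

#' Sample sheet implied by a study design
#'
#' @param design A [study_design()].
#' @return Tibble with `sample_id`, `model` (spherical/cylindrical) and
#'   `condition` (loaded/control), one row per sample.
#' @export
design_sample_sheet <- function(design) {
  stopifnot(inherits(design, "study_design"))
  mk <- function(prefix, arm, n) sprintf("%s_%s%02d", prefix, arm, seq_len(n))
  tibble(
    sample_id = c(
      mk("sph", "L", design$n_loaded_spherical),
      mk("sph", "C", design$n_control_spherical),
      mk("cyl", "L", design$n_loaded_cylindrical),
      mk("cyl", "C", design$n_control_cylindrical)
    ),
    model = rep(c("spherical", "cylindrical"),
                c(design$n_loaded_spherical + design$n_control_spherical,
                  design$n_loaded_cylindrical + design$n_control_cylindrical)),
    condition = c(
      rep(c("loaded", "control"),
          c(design$n_loaded_spherical, design$n_control_spherical)),
      rep(c("loaded", "control"),
          c(design$n_loaded_cylindrical, design$n_control_cylindrical))
    )
  )
}

#' Simulate a probe annotation table
#'
#' Builds a synthetic array manifest over four chromosomes. Probes are laid
#' out in CpG-island-like clusters (3-8 probes, 50-400 bp apart) separated by
#' 2-20 kb gaps, so that positional DMR structure is representable. Each
#' probe carries one of the 15 ChromHMM chromatin-state labels and zero or
#' more gene mappings, each labelled with an Illumina-style region category
#' (TSS200, TSS1500, 5'UTR, 1stExon, ExonBnd, 3'UTR, Body); multiple
#' mappings are semicolon-separated in parallel `gene` / `category` columns,
#' as in real array manifests.
#'
#' @param design A [study_design()].
#' @param seed Integer seed; identical seeds give identical annotations.
#' @return Tibble with columns `probe_id`, `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `gene`, `category`, `chromatin_state`.
#' @export
simulate_probe_annotation <- function(design, seed = 1) {
  stopifnot(inherits(design, "study_design"))
  n <- design$n_probes
  empty <- tibble(probe_id = character(), chrom = character(), pos = integer(),
                  gene = character(), category = character(),
                  chromatin_state = character())
  if (n == 0) return(empty)

  withr::with_seed(seed, {
    chroms <- paste0("chr", 1:4)
    alloc <- diff(floor(seq(0, n, length.out = 5)))
    state_w <- c(0.07, 0.06, 0.02, 0.10, 0.12, 0.09, 0.03, 0.02, 0.05,
                 0.02, 0.015, 0.02, 0.04, 0.06, 0.285)
    cat_w <- c(0.12, 0.18, 0.12, 0.05, 0.04, 0.09, 0.40)

    per_chrom <- purrr::map2(chroms, alloc, function(ch, nc) {
      if (nc == 0) return(NULL)
      # island layout: sizes 3-8 with small intra-island gaps
      sizes <- integer(0)
      while (sum(sizes) < nc) sizes <- c(sizes, sample(3:8, 1))
      island <- rep(seq_along(sizes), sizes)[seq_len(nc)]
      new_island <- c(TRUE, diff(island) != 0)
      gaps <- ifelse(new_island, sample(2000:20000, nc, replace = TRUE),
                     sample(50:400, nc, replace = TRUE))
      pos <- 10000L + cumsum(as.integer(gaps))
      tibble(chrom = ch, pos = pos)
    })
    ann <- dplyr::bind_rows(per_chrom)
    ann$probe_id <- sprintf("cg%08d", seq_len(nrow(ann)))

    # genes: uniform TSS positions within each chromosome's probe span
    ng <- design$n_genes
    genes <- NULL
    if (ng > 0) {
      galloc <- diff(floor(seq(0, ng, length.out = 5)))
      genes <- dplyr::bind_rows(purrr::map2(chroms, galloc, function(ch, k) {
        if (k == 0) return(NULL)
        span <- range(ann$pos[ann$chrom == ch])
        tibble(chrom = ch, tss = as.integer(round(runif(k, span[1], span[2]))))
      }))
      genes$gene <- sprintf("g%04d", seq_len(nrow(genes)))
    }

    n_map <- sample(0:2, nrow(ann), replace = TRUE, prob = c(0.25, 0.60, 0.15))
    gene_col <- rep(NA_character_, nrow(ann))
    cat_col <- rep(NA_character_, nrow(ann))
    if (!is.null(genes)) {
      for (ch in chroms) {
        idx <- which(ann$chrom == ch)
        gch <- genes[genes$chrom == ch, ]
        if (!length(idx) || !nrow(gch)) next
        d <- abs(outer(ann$pos[idx], gch$tss, "-"))
        ord1 <- apply(d, 1, which.min)
        nearest <- gch$gene[ord1]
        second <- if (nrow(gch) >= 2) {
          gch$gene[apply(d, 1, function(r) order(r)[2])]
        } else nearest
        k <- n_map[idx]
        cats1 <- sample(GENE_CATEGORIES, length(idx), replace = TRUE, prob = cat_w)
        cats2 <- sample(GENE_CATEGORIES, length(idx), replace = TRUE, prob = cat_w)
        gene_col[idx] <- dplyr::case_when(
          k == 0 ~ NA_character_,
          k == 1 ~ nearest,
          TRUE ~ paste(nearest, second, sep = ";")
        )
        cat_col[idx] <- dplyr::case_when(
          k == 0 ~ NA_character_,
          k == 1 ~ cats1,
          TRUE ~ paste(cats1, cats2, sep = ";")
        )
      }
    }
    ann$gene <- gene_col
    ann$category <- cat_col
    ann$chromatin_state <- sample(CHROMATIN_STATES, nrow(ann),
                                  replace = TRUE, prob = state_w)
    ann[, c("probe_id", "chrom", "pos", "gene", "category", "chromatin_state")]
  })
}

# internal: island id per probe (runs of consecutive probes < gap_bp apart)
probe_islands <- function(annotation, gap_bp = 1000) {
  new_block <- c(TRUE, annotation$chrom[-1] != annotation$chrom[-nrow(annotation)] |
                   diff(annotation$pos) >= gap_bp)
  cumsum(new_block)
}

#' Simulate the two-model methylation experiment
#'
#' Draws logit-scale methylation values `mu_probe + (delta + model_shift) *
#' loaded + N(0, noise_sd_m)` per probe and sample, where `delta` is the
#' planted signed effect (zero at non-DM probes) and `model_shift ~ N(0,
#' tau_model)` is an independent per-probe, per-model perturbation of the
#' loading effect at DM probes, representing between-model heterogeneity.
#' Betas are the inverse logit, hence strictly in (0, 1). A fraction of
#' probes get SNP-like trimodal patterns (Hardy-Weinberg cluster weights with
#' allele frequency drawn U(0.2, 0.8), betas near 0.05/0.5/0.95), and a
#' fraction of probe-sample cells get failing detection p-values (U(0.02, 1)
#' instead of U(0, 0.005)). A share of DM probes is placed in runs of five
#' adjacent CpGs inside probe islands, forming planted DMRs.
#'
#' @param design A [study_design()].
#' @param effects An [effect_spec()].
#' @param annotation Output of [simulate_probe_annotation()] for `design`.
#' @param seed Integer seed.
#' @return List with `datasets` (named list of [methyl_dataset()] objects,
#'   `spherical` and `cylindrical`) and `truth` (class `ml_truth`: `dm` tibble
#'   of probe_id/delta, `snp_like` probe ids, `failing_cells` tibble,
#'   `planted_dmrs` tibble with member probe ids, `linked_genes` tibble of
#'   gene/lfc).
#' @export
simulate_methylation <- function(design, effects, annotation, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_spec"))
  if (nrow(annotation) != design$n_probes) {
    abort("`annotation` must cover exactly design$n_probes probes")
  }
  n <- design$n_probes
  probes <- annotation$probe_id

  withr::with_seed(seed, {
    snp_like <- sort(sample(probes, round(effects$frac_snp_like * n)))
    eligible <- setdiff(probes, snp_like)

    # --- plant DM probes: clustered runs first, then scattered singles
    n_dm <- round(effects$frac_dm * n)
    run_len <- 5L
    n_runs <- floor(effects$frac_dmr_clustered * n_dm / run_len)
    run_probes <- character(0)
    planted_dmrs <- tibble(chrom = character(), start = integer(),
                           end = integer(), probe_ids = list())
    if (n_runs > 0 && n > 0) {
      isl <- probe_islands(annotation)
      ok <- !(probes %in% snp_like)
      cand <- lapply(split(seq_len(n), isl), function(ix) {
        if (length(ix) < run_len) return(NULL)
        # first window of run_len consecutive non-SNP probes in this island
        for (s in seq_len(length(ix) - run_len + 1)) {
          w <- ix[s:(s + run_len - 1)]
          if (all(ok[w])) return(w)
        }
        NULL
      })
      cand <- cand[!vapply(cand, is.null, logical(1))]
      if (length(cand) < n_runs) {
        warn(sprintf("only %d island(s) can host a planted DMR (requested %d)",
                     length(cand), n_runs))
        n_runs <- length(cand)
      }
      chosen <- sample(cand, n_runs)
      run_probes <- unlist(lapply(chosen, function(w) probes[w]))
      planted_dmrs <- dplyr::bind_rows(lapply(chosen, function(w) {
        tibble(chrom = annotation$chrom[w[1]],
               start = annotation$pos[w[1]],
               end = annotation$pos[w[length(w)]],
               probe_ids = list(probes[w]))
      }))
    }
    scattered <- sample(setdiff(eligible, run_probes),
                        max(0, n_dm - length(run_probes)))
    run_signs <- if (n_runs > 0) {
      rep(sample(c(-1, 1), n_runs, replace = TRUE), each = run_len)
    } else numeric(0)
    dm <- tibble(
      probe_id = c(run_probes, scattered),
      delta = effects$delta_m * c(run_signs,
                                  sample(c(-1, 1), length(scattered), replace = TRUE))
    )

    # --- linked genes: genes reached from DM probes through a TSS/UTR/exon category
    qualifying <- setdiff(GENE_CATEGORIES, "Body")
    ann_dm <- annotation[annotation$probe_id %in% dm$probe_id & !is.na(annotation$gene), ]
    mapped_genes <- character(0)
    if (nrow(ann_dm)) {
      gs <- strsplit(ann_dm$gene, ";", fixed = TRUE)
      cs <- strsplit(ann_dm$category, ";", fixed = TRUE)
      keep <- unlist(purrr::map2(gs, cs, function(g, c) g[c %in% qualifying]))
      mapped_genes <- sort(unique(keep))
    }
    n_linked <- round(effects$frac_linked_genes * length(mapped_genes))
    linked <- sort(sample(mapped_genes, n_linked))
    linked_genes <- tibble(
      gene = linked,
      lfc = effects$expr_lfc * sample(c(-1, 1), length(linked), replace = TRUE)
    )

    # --- per-probe baselines: bimodal methylation landscape on the logit scale
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.45, 0.40, 0.15))
    mu <- c(rnorm(n, -2.2, 0.6), rnorm(n, 2.2, 0.6), rnorm(n, 0, 0.8))[
      (comp - 1) * n + seq_len(n)]
    delta_vec <- setNames(rep(0, n), probes)
    delta_vec[dm$probe_id] <- dm$delta
    snp_maf <- runif(length(snp_like), 0.2, 0.8)

    sheet <- design_sample_sheet(design)
    failing <- list()
    datasets <- list()
    for (mod in c("spherical", "cylindrical")) {
      sh <- sheet[sheet$model == mod, ]
      ns <- nrow(sh)
      loaded <- as.numeric(sh$condition == "loaded")
      shift <- rep(0, n)
      is_dm <- probes %in% dm$probe_id
      shift[is_dm] <- rnorm(sum(is_dm), 0, effects$tau_model)
      lin <- matrix(mu, n, ns) +
        outer(delta_vec + shift, loaded) +
        matrix(rnorm(n * ns, 0, effects$noise_sd_m), n, ns)
      beta <- plogis(lin)
      # SNP-like probes: Hardy-Weinberg genotype clusters near 0.05/0.5/0.95
      if (length(snp_like)) {
        centers <- c(0.05, 0.5, 0.95)
        rows <- match(snp_like, probes)
        for (j in seq_along(rows)) {
          geno <- rbinom(ns, 2, snp_maf[j])
          beta[rows[j], ] <- plogis(qlogis(centers[geno + 1]) + rnorm(ns, 0, 0.12))
        }
      }
      detp <- matrix(runif(n * ns, 0, 0.005), n, ns)
      n_fail <- round(effects$frac_fail * n * ns)
      if (n_fail > 0) {
        cells <- sample(n * ns, n_fail)
        detp[cells] <- runif(n_fail, 0.02, 1)
        failing[[mod]] <- tibble(
          model = mod,
          probe_id = probes[(cells - 1) %% n + 1],
          sample_id = sh$sample_id[(cells - 1) %/% n + 1]
        )
      }
      dimnames(beta) <- dimnames(detp) <- list(probes, sh$sample_id)
      datasets[[mod]] <- methyl_dataset(beta, detp, sh, model_label = mod)
    }

    truth <- structure(
      list(dm = dplyr::arrange(dm, .data$probe_id),
           snp_like = snp_like,
           failing_cells = dplyr::bind_rows(failing),
           planted_dmrs = planted_dmrs,
           linked_genes = linked_genes,
           effects = effects),
      class = "ml_truth"
    )
    list(datasets = datasets, truth = truth)
  })
}

#' Simulate RNA-seq counts linked to the methylation truth set
#'
#' Negative-binomial counts (dispersion `dispersion`) for all samples of both
#' models. Genes in `truth$linked_genes` have their mean multiplied by
#' `2^lfc` in loaded samples; library sizes vary by +/-30%.
#'
#' @param design A [study_design()].
#' @param effects An [effect_spec()].
#' @param annotation Probe annotation (defines the gene universe).
#' @param truth Truth set from [simulate_methylation()].
#' @param seed Integer seed.
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @return List with `counts` (gene x sample integer matrix) and `samples`
#'   (the combined sample sheet).
#' @export
simulate_expression <- function(design, effects, annotation, truth, seed = 1,
                                dispersion = 0.1) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ml_truth"))
  genes <- sprintf("g%04d", seq_len(design$n_genes))
  if (!all(truth$linked_genes$gene %in% genes)) {
    abort("truth$linked_genes contains genes outside the design's gene universe")
  }
  withr::with_seed(seed, {
    sheet <- design_sample_sheet(design)
    ns <- nrow(sheet)
    base <- 2^rnorm(length(genes), 6, 1.5)
    sf <- runif(ns, 0.7, 1.3)
    mu <- outer(base, sf)
    lfc <- setNames(rep(0, length(genes)), genes)
    lfc[truth$linked_genes$gene] <- truth$linked_genes$lfc
    loaded <- sheet$condition == "loaded"
    mu[, loaded] <- mu[, loaded] * 2^lfc
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = length(genes),
                     dimnames = list(genes, sheet$sample_id))
    list(counts = counts, samples = sheet)
  })
}

#' Simulate a clinical cartilage cohort
#'
#' Patients carry a Kellgren-Lawrence (KL) radiographic severity grade in
#' 1-4, BMI ~ N(27, 4) and age ~ N(65, 8). Methylation at each requested CpG
#' is generated on the natural-logit scale as `intercept + slope * KL +
#' b_bmi * BMI + b_age * age + N(0, noise_sd)` and returned as a beta-value.
#'
#' @param n_patients Number of patients (>= 10).
#' @param cpgs Character vector of CpG column names.
#' @param slopes Per-CpG true KL coefficient on the logit scale (recycled).
#' @param seed Integer seed.
#' @param intercept,b_bmi,b_age Baseline logit and covariate coefficients.
#' @param noise_sd Residual SD on the logit scale.
#' @return Tibble with `patient_id`, `kl_score`, `bmi`, `age` and one
#'   beta-value column per CpG.
#' @export
simulate_clinical <- function(n_patients = 500, cpgs = "cg_test",
                              slopes = -0.1, seed = 1, intercept = -0.5,
                              b_bmi = 0.02, b_age = -0.01, noise_sd = 0.4) {
  if (n_patients < 10) abort("`n_patients` must be >= 10")
  slopes <- rep_len(slopes, length(cpgs))
  withr::with_seed(seed, {
    kl <- sample(1:4, n_patients, replace = TRUE)
    bmi <- rnorm(n_patients, 27, 4)
    age <- rnorm(n_patients, 65, 8)
    out <- tibble(patient_id = sprintf("pt%04d", seq_len(n_patients)),
                  kl_score = kl, bmi = bmi, age = age)
    for (i in seq_along(cpgs)) {
      lin <- intercept + slopes[i] * kl + b_bmi * bmi + b_age * age +
        rnorm(n_patients, 0, noise_sd)
      out[[cpgs[i]]] <- plogis(lin)
    }
    out
  })
}

#' Simulate RT-qPCR records with a planted loading effect
#'
#' Housekeeping Cts (GAPDH, SDHA) are stable; the gene of interest's Ct is
#' shifted so that the -deltaCt of loaded samples exceeds that of controls by
#' `shift` cycles on average.
#'
#' @param gene Gene label.
#' @param shift Planted difference in -deltaCt (loaded minus control).
#' @param n_loaded,n_control Samples per arm.
#' @param noise_sd Residual SD of the gene-of-interest Ct.
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `condition`, `gene`, `ct_goi`,
#'   `ct_gapdh`, `ct_sdha`.
#' @export
simulate_qpcr <- function(gene = "GENE", shift = 0.5, n_loaded = 6,
                          n_control = 6, noise_sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    n <- n_loaded + n_control
    condition <- rep(c("loaded", "control"), c(n_loaded, n_control))
    ct_gapdh <- rnorm(n, 18, 0.05)
    ct_sdha <- rnorm(n, 20, 0.05)
    hk <- (ct_gapdh + ct_sdha) / 2
    # -dCt = hk - ct_goi; baseline -dCt of -4, plus `shift` when loaded
    ct_goi <- hk + 4 - shift * (condition == "loaded") + rnorm(n, 0, noise_sd)
    tibble(sample_id = sprintf("qs%02d", seq_len(n)), condition = condition,
           gene = gene, ct_goi = ct_goi, ct_gapdh = ct_gapdh, ct_sdha = ct_sdha)
  })
}
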