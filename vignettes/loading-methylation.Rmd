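---
title: "Methods: differential methylation under mechanical loading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation under mechanical loading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechamethyl)
```

This vignette is the package's account of its statistical machinery: the
models, the assumptions behind them, the defaults and why they are what
they are, and what the synthetic-data tests do and do not establish about
real data.

## The scientific setting

Articular chondrocytes are post-mitotic and lean on CpG methylation to hold
their phenotypic set points. Hyper-physiological mechanical loading — the
kind of insult associated with post-traumatic osteoarthritis — may push
those set points around. The design analysed here exposes chondrocyte
organoids to a single loading episode in two model systems (spherical
neo-cartilage constructs and cylindrical agarose-embedded constructs; 26
loaded and 27 control samples in total) and profiles methylation and
expression 12 h later. The analysis asks three nested questions: which
CpGs move (differential methylation), whether movement clusters positionally
(DMRs) and by chromatin context (state enrichment), and which movements
plausibly matter for transcription (tCpG integration with differential
expression, clinical severity association).

## Per-model differential methylation

Each model is analysed as a two-group comparison under the design
`~ loading`. For probe $g$, the group difference $b_g$ has unscaled
variance factor $v_g = 1/n_1 + 1/n_0$ and pooled residual variance $s_g^2$
on $d_g = n - 2$ degrees of freedom. Variances are moderated with the
standard empirical-Bayes hierarchy, implemented from the closed-form
equations rather than called from a library: assuming
$s_g^2 \sim s_0^2 F(d_g, d_0)$,

$$\mathrm{E}[\log s_g^2] = \log s_0^2 + \psi(d_g/2) - \log(d_g/2)
                              - \psi(d_0/2) + \log(d_0/2), \qquad
\mathrm{Var}[\log s_g^2] = \psi'(d_g/2) + \psi'(d_0/2),$$

so $d_0$ solves $\psi'(d_0/2) = \mathrm{var}(\log s^2) - \psi'(d_g/2)$,
found by monotone bisection of the (strictly decreasing) trigamma; the
posterior variance is the df-weighted mix and the moderated t gains $d_0$
degrees of freedom. Numerical choices:

* the bisection brackets $[10^{-8}, \infty)$ and stops at a relative width
  of $10^{-12}$;
* probes with $s_g = 0$ are excluded from hyperparameter estimation (their
  log-variance is undefined) but still receive moderated statistics;
* when the observed log-variance spread does not exceed pure sampling
  scatter, $d_0 = \infty$ and every posterior variance is $s_0^2$; in the
  fully degenerate case of *identical* residual variances the prior is that
  common value itself (no chi-square bias correction, which would otherwise
  inflate it);
* $d_0 = 0$ reproduces the ordinary pooled two-sample t exactly, which the
  tests assert at $10^{-10}$, and the estimated fit is cross-checked
  against an independent implementation at the same tolerance.

**Analysis scale.** The default analyses beta-values directly, so effect
sizes are methylation-fraction differences — the scale on which effect
sizes in this literature are quoted. M-value analysis (`scale = "m"`) is a
flag away and is statistically preferable when baselines sit near 0 or 1;
the recovery tests pass on both.

## Meta-analysis across the two models

The per-model estimates are combined per probe with the DerSimonian–Laird
random-effects estimator (fixed-effect weights $w_i = 1/se_i^2$, moment
estimator $\tau^2$ floored at zero, random-effects weights
$1/(se_i^2 + \tau^2)$, $p = 2\Phi(-|z|)$). DM CpGs are called at BH
FDR < 0.01 across all meta-analysed probes (one family, not
per-chromosome). Probes surviving QC in only one model are excluded — a
random-effects estimate needs $k \ge 2$ — and reported separately. The
package also computes the epigenome-wide Bonferroni threshold
($0.05 / 800{,}883 = 6.243109 \times 10^{-8}$ at the real array's tested
probe count) for reference, but the DM flag follows the FDR rule, which is
what the downstream stages key on.

Two calibration properties of this estimator at $k = 2$ deserve honesty,
and the test suite measures both under the global synthetic null:

* **Conservative middle.** With two studies, $Q \sim \chi^2_1$ under
  homogeneity and $\tau^2 = (Q-1)\,se^2$ whenever $Q > 1$, which deflates
  $|z|$ on about a third of probes. Mid-range p-values are therefore
  conservative, and the Kolmogorov–Smirnov distance of the null p-value
  distribution from uniform sits around 0.05 — real, but harmless for
  error control.
* **Heavy extremes.** $p = 2\Phi(-|z|)$ treats the combined statistic as
  normal while the per-model moderated statistics carry roughly
  $d_0 + d_g$ degrees of freedom. At 26/27 samples the normal reference
  understates extreme-tail mass, so over many null runs an occasional
  probe clears even the q < 0.01 bar. BH's average FDR guarantee is not
  violated, but a run's realized false-discovery proportion under a global
  null is 0 or 1, so small averages over few runs are fragile.

## DMR scanning

A candidate region is a run of consecutive CpGs on one chromosome that
starts and ends at a DM CpG, has every consecutive pair of member CpGs
(DM or not) closer than 1 kb, contains at least 3 DM CpGs and at most 3
interspersed non-DM CpGs. The scanner reports maximal candidates (not
contained in any other candidate) chosen greedily left-to-right without
overlap — a deterministic rule that an exhaustive window enumeration can
verify, and does, on randomized layouts. Reading the 1 kb rule as binding
*all* consecutive members is the stricter of the two possible readings;
`gap_between = "dm_only"` gives the looser one. Region significance is a
design gap in the source analysis: the package uses Stouffer combination
of the member DM CpGs' signed z-scores by default (Fisher's method as an
alternative), documented as a stand-in rather than a claim about the
original analysis. Signed combination means a region of opposing effects
is *not* rewarded — regions are interesting here when they move coherently.

## Chromatin-state enrichment

For each of the 15 ChromHMM states a 2×2 table of DM status against state
membership is tested with a two-sided Fisher exact test, implemented by
direct hypergeometric summation (all tables with probability at most that
of the observed one, with the conventional $1 + 10^{-7}$ tolerance factor
guarding floating-point ties). Odds ratios are the sample cross-product
$(ad)/(bc)$. The background is the tested universe — probes surviving QC
and meta-analysis — not the full array manifest: enrichment should be
relative to what could have been called. BH runs across the 15 states
only. States with no tested probes are reported but excluded from the
adjustment.

## Expression integration (ML-tCpGs)

DM CpGs are mapped to genes through the promoter-proximal and
transcript-structure categories (TSS200, TSS1500, 5'UTR, 1stExon, ExonBnd,
3'UTR); gene-body-only mappings are excluded. Semicolon-separated
multi-gene/multi-category annotations are exploded into pairs and
duplicate (probe, gene) pairs collapse with concatenated categories.
Differential expression uses library-size-normalized log2(CPM + 0.5)
through the same moderated-t engine, with the organoid model as a
covariate by default (`~ loading + model`) since both models' samples
enter jointly. The FDR correction "for the number of genes overlapping
with mapped CpGs" is read literally: BH within the restricted family of
unique genes carrying at least one mapped DM CpG, at 0.05. One caution:
restricted BH is *usually*, but not provably always, more generous than a
genome-wide adjustment for the same genes — step-up q-values depend on
within-family ranks, so pathological p-value configurations can invert the
relationship. The package therefore oracle-tests the restricted
computation itself instead of asserting the folklore monotonicity.

## Clinical association and RT-qPCR

Methylation of selected CpGs is regressed on the Kellgren–Lawrence grade
with BMI and age as covariates (OLS; the KL coefficient, its SE and a
two-sided t-test are returned). The source phrasing does not pin down
response versus predictor; methylation-on-KL is the default and
`direction = "kl_on_meth"` the alternative. The fit scale is a second
genuinely open choice: `scale = "beta"` matches how such coefficients are
reported, `scale = "logit"` matches the generative model of the synthetic
cohort and is what the recovery tests use — a slope planted on the logit
scale is not numerically equal to a beta-scale slope, so tests must fit on
the planted scale. Designs are checked for (near-)singularity via rank and
condition number before fitting.

RT-qPCR analysis follows ΔCt = Ct(gene) − mean(Ct of GAPDH, SDHA), fold
change $2^{-\Delta\Delta Ct}$, and a Gaussian linear model of −ΔCt on the
loading indicator — the only GLM consistent with a continuous, signed
response.

## The synthetic-data generator

The generator is the package's test bed, emulating the study conditions:

* **Design**: 26 loaded / 27 control total, split 13/13 (spherical) and
  13/14 (cylindrical). The source reports only totals; the near-even split
  is an assumption, exposed as configuration.
* **Methylation**: logit-scale values
  $\mu_g + (\delta_g + u_{g,\text{model}})\,\text{loaded} + \varepsilon$,
  with a bimodal baseline landscape (hypo/hyper components at logit
  $\mp 2.2$ plus an intermediate component), planted effects
  $\delta_g = \pm 1.0$ on the natural-logit scale at 5% of probes, residual
  SD 0.5 and between-model heterogeneity SD 0.2 at DM probes. A logit SD
  of 0.5 corresponds to within-group beta-value SDs of roughly 0.03–0.12
  depending on the methylation level — the noisy end of what Infinium
  arrays show, chosen deliberately conservative. Heterogeneity attaches to
  the *loading effect of DM probes only*: attaching it to all probes would
  make a "no effects" configuration not actually null.
* **Structure**: probes are laid out in CpG-island-like clusters so 40% of
  DM probes can be planted as runs of five adjacent CpGs (< 1 kb gaps) —
  the planted DMRs; 2% of probes get SNP-like trimodal patterns
  (Hardy–Weinberg cluster weights, allele frequency U(0.2, 0.8), clusters
  near 0.05/0.5/0.95); 0.05% of probe-sample cells fail detection.
* **Expression**: negative-binomial counts (dispersion 0.1), library sizes
  ±30%; half of the genes reachable from DM probes through qualifying
  categories get a planted log2 fold change of ±1.
* **Clinical**: KL grades 1–4, BMI ~ N(27, 4), age ~ N(65, 8), CpG betas
  generated on the logit scale with a planted KL slope.

Default problem sizes for the test suite and the acceptance script are
5,000 probes and 500 genes — large enough for stable FDR behaviour and
positional structure, small enough to run the whole battery in minutes.

**What passing tests do and do not show.** The generator draws Gaussian
logit-scale noise with independent probes, a clean two-arm design and
annotation-faithful gene mappings. Real arrays add correlated probes,
batch and position effects, dye/chemistry biases (the Infinium I/II
distinction is deliberately not simulated — QC consumes betas, not
intensities), cell-type mixture and annotation error. Recovery rates
measured here are therefore upper bounds on real-data performance; what
the tests *do* establish is that each stage computes exactly its stated
statistic (oracle equivalence at $10^{-10}$), that error rates are
controlled where the statistics promise control, and that planted signal
of realistic size survives the full chain.

## SNP-like probe flagging

Probes sitting on common SNPs show genotype clusters rather than
methylation. Samples are binned at 0.25/0.75; a band qualifies when it
holds ≥ 5% of samples (at least two), its SD is below 0.1, and its mean
lies within 0.1 of the canonical genotype pattern (0.05/0.5/0.95); two or
more qualifying bands flag the probe, and stray samples outside qualifying
bands are tolerated as outliers. The band-centre condition is the one
addition to a plain three-band rule, and it earns its place twice over:
without it, unimodal probes whose methylation level happens to straddle a
band boundary are flagged wholesale (~30% of probes in simulation), and a
genuine two-group loading effect of moderate size masquerades as a
two-cluster genotype pattern, silently deleting true positives. Genotype
clusters hug the canonical centres; straddlers and group effects do not.
The confidence score (1 − mean band SD / 0.1) mirrors the idea of scoring
closeness to the canonical SNP pattern.

QC order — detection filter, quantile normalization, optional
control-probe regression, SNP/blacklist removal — is configurable; the
default normalizes before pattern-based flagging so that flags are made on
the same values the analysis will use. The retained probe *set* is
order-insensitive for the pure filters, which the tests assert.

## Known limitations

* DL at $k = 2$ has the calibration quirks described above; a
  Knapp–Hartung adjustment or REML $\tau^2$ would trade them for others
  and is out of scope.
* DMR significance is a documented stand-in (Stouffer), not a permutation
  null.
* Gene symbols are case-normalized but not alias-resolved; external tCpG
  catalogs must use matching symbols.
* The clinical model treats the KL grade as numeric; an ordinal model
  would be the next refinement.
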