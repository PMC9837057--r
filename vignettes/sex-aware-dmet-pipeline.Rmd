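---
title: "Detecting sex-differentiated genetic effects from summary statistics"
author: "sexgwas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-differentiated genetic effects from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexgwas)
```

## The problem

Most genome-wide association studies (GWAS) analyze males and females
together, which can mask genetic effects that differ between the sexes.
Sex-differentiated regulation is particularly plausible for drug
metabolism enzyme and transporter (DMET) genes, whose products process
both medications and endogenous serum biomarkers and whose activity is
known to differ between men and women.  `sexgwas` implements a complete
sex-aware analysis chain over *summary statistics* — no individual-level
genotypes are required for the analytic stages — together with a
seedable synthetic-data generator so that every stage can be exercised
and validated without access to restricted cohort or expression data.

The pipeline stages are:

1. **Input and harmonization** (`read_sumstats()`, `align_pair()`):
   validated summary-statistics tables per trait and stratum
   (sex-combined, male, female), paired across sexes on variant identity
   with allele harmonization.
2. **Regions and trait filters** (`build_regions()`,
   `map_snps_to_regions()`, `filter_traits()`): cis gene regions of
   ±1 Mb around each gene's transcription start site, and the
   case-count/prevalence filters that define an analyzable binary trait.
3. **Sex-difference tests and SDE calling** (`sex_difference_z()`,
   `rg_vs_one_t()`, `call_sdes()`).
4. **eQTL classification** (`two_step_correction()`,
   `classify_eqtls()`).
5. **Colocalization** (`coloc_abf()`, `sex_stratified_gwas_coloc()`,
   `classify_sex_specific_coloc()`).
6. **Mendelian randomization** (`mr_egger()`, `run_mr_grid()`,
   `call_sex_specific_mr()`, `restrict_to_dmet()`).
7. **Region enrichment** (`region_enrichment()`).

## Core statistics

### Sex-difference z test

For any statistic estimated separately in the two sexes — a trait
heritability, a per-variant GWAS effect, an eQTL effect — with standard
errors, the sex difference is tested with

$$z = \frac{\hat\theta_{\mathrm{F}} - \hat\theta_{\mathrm{M}}}
          {\sqrt{\mathrm{SE}_{\mathrm{F}}^2 + \mathrm{SE}_{\mathrm{M}}^2}},$$

with a two-sided p-value from the standard normal.  The sign convention
is female minus male throughout.  Whether the male-female genetic
*correlation* departs from its null value of 1 is tested with the Wald
statistic $t = (\hat r_g - 1)/\mathrm{SE}_{r_g}$, also referred to the
standard normal: summary-level estimates carry no usable degrees of
freedom, so a t reference with arbitrary df would be a pretense of
precision.  Multiple testing is controlled by Benjamini–Hochberg FDR in
both cases.

### SDE calling

A variant has a *sex-differentiated effect* (SDE) for a trait when

* the sex-difference z test on its per-sex GWAS effects is
  FDR-significant (q < 0.05 within the trait), **and**
* the variant is genome-wide significant (p < 5×10⁻⁸) in at least one
  sex.

The second condition restricts claims of heterogeneity to variants that
are actually associated with the trait somewhere.  The FDR scope is
within-trait across all region-mapped variants; a caller wanting a
global cross-trait FDR can concatenate paired tables before
`call_sdes()`.

### Two-step eQTL correction and classification

Region-scoped cis-eQTL scans test many correlated variants per gene and
many genes.  The two-step correction first Bonferroni-scales each
gene's minimum variant p-value by the number of *independent* variants
in its region (greedy LD partition at r² < 0.8, `count_independent()`),
then BH-adjusts the resulting gene-level p-values across genes.  A gene
is a significant eQTL in a sex at gene-level q < 0.1.

Genes are then labeled:

* **sex-differentiated** — the sex-difference z test on the per-sex
  effect sizes at the gene's lead variant is BH-significant (q < 0.1
  across tested genes);
* **male-/female-specific** — gene-level q < 0.1 in exactly one sex and
  > 0.1 in the other;
* a gene meeting both definitions is labeled `sex_differentiated`,
  since effect-size heterogeneity is the stronger claim; both raw flags
  are retained in the output.

The shared lead variant for the z test is the variant minimizing
min(p_male, p_female), ties broken by position — a symmetric choice
that does not privilege either sex.

### Colocalization

`coloc_abf()` is a from-scratch implementation of approximate-Bayes-
factor colocalization under one causal variant per trait.  Per variant
and trait, the Wakefield log approximate Bayes factor is

$$\log\mathrm{ABF} = \tfrac12\!\left[\log(1 - r) + r z^2\right],
\qquad r = \frac{W}{V + W},$$

with $V$ the squared standard error, $W$ the squared prior effect SD
and $z$ the Wald ratio.  Prior effect SDs follow the field convention:
0.2 on the log-odds scale for case-control traits and $0.15\,s_Y$ for
quantitative traits, with $s_Y$ estimated from the summary statistics
($s_Y^2 \approx \mathrm{median}\, \mathrm{SE}^2 \cdot 2f(1-f)\,n$
across the locus) because the measurement scale of the phenotype is
usually not recorded; an explicit `sdY` override exists.  Hypothesis
weights (H0 none, H1 trait-1 only, H2 trait-2 only, H3 both-distinct,
H4 shared) are accumulated entirely in log space with a stable
log-difference for H3; when rounding drives the H3 argument nonpositive
the posterior is clamped to 0 and flagged.  Default priors are
p1 = p2 = 10⁻⁴ and p12 = 10⁻⁵ per variant.

Applied to the male and female statistics of the *same* trait around a
tagging SDE (±200 kb, `sex_stratified_gwas_coloc()`), PPH1 reads "males
only have an association", PPH2 "females only", PPH4 "the sexes share a
causal variant".  Applied to a sex-combined GWAS against one sex's
eQTL over a gene's ±1 Mb region, the same machinery plus
`classify_sex_specific_coloc()` (PPH4 > 0.5 in exactly one sex, strict
inequality) yields sex-specific regulatory colocalizations.  A
single-variant locus has PPH3 = 0 by construction; the wrapper warns on
such loci rather than refusing them, because zero-width windows are a
legitimate boundary case.

### MR-Egger

`mr_egger()` regresses outcome effects on exposure effects with a free
intercept, weights $1/\mathrm{SE}_{by}^2$, after orienting every
instrument to a non-negative exposure effect.  The slope estimates the
causal effect; the intercept absorbs directional pleiotropy.  Standard
errors use multiplicative residual overdispersion floored at 1 and
p-values come from the t distribution with (number of instruments − 2)
degrees of freedom, the conventional implementation for this estimator.
Instruments are exposure variants at p < 5×10⁻⁸, clumped at r² < 0.001
(`select_instruments()`).  A *sex-specific* MR relationship is one
whose slope is significant in exactly one sex and in neither the other
sex nor the sex-combined model, at the Bonferroni threshold
0.05/(186·29) matching a 29-exposure × 186-outcome screening grid; the
decision is made on the slope p-value, since the causal effect (not the
pleiotropy test) is the claim being screened.  `restrict_to_dmet()`
re-runs a relationship using only instruments inside the DMET gene
regions, reporting "underpowered" below three surviving instruments
rather than fitting an unidentified model.

### Region enrichment

`region_enrichment()` asks whether significant variants concentrate in
the target regions beyond chance.  Each permutation redraws every
target region at a uniformly random start *on its own chromosome* with
its own length, because region length and chromosome identity drive
variant density; overlaps between drawn regions are allowed (the
simplest well-defined null) and a variant inside several drawn regions
counts once.  The p-value is add-one corrected,
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, hence never zero.
Counting is per variant by default; a per-locus mode collapses
significant variants onto tagging loci (r² < 0.2) first, mitigating
inflation from clumped signals.

## The synthetic-data generator

The generator stands in for cohort-scale GWAS and expression resources
and defines the conditions under which the pipeline is validated.

* **Genotypes** (`simulate_genotypes()`): dosages arise from two
  independent latent Gaussian draws per individual, correlated within
  LD blocks as an AR(1) with parameter `ld_rho` and thresholded at the
  per-variant MAF cutpoint.  This one-parameter model yields
  Hardy-Weinberg margins and monotone LD decay — enough structure to
  exercise tagging, clumping and colocalization — but makes no claim to
  reproduce human LD maps, demographic history, or genome-wide scale;
  loci of at most a few thousand variants are intended.  Variant keys
  use non-palindromic allele pairs so harmonization never silently
  drops a planted variant.
* **Phenotypes** (`simulate_sex_stratified_gwas()`): per-sex additive
  effects plus Gaussian noise; binary traits threshold the liability at
  the configured prevalence but are summarized with per-variant
  logistic fits (log-odds betas), reflecting how case-control summary
  statistics are actually produced.  Covariates are explicit matrices;
  no surrogate-variable machinery is emulated.  For eQTL-like scenarios
  equal per-sex sample sizes mirror the down-sampling convention that
  equalizes discovery power between sexes.
* **MR scenarios** (`simulate_mr_scenario()`): true instrument effects
  are half-normal, i.e. oriented to the exposure-increasing allele — a
  directional pleiotropy mean is only meaningful relative to a fixed
  orientation.  Defaults: `gamma_sd = 0.1`, `se_x = 0.005`,
  `se_y = 0.01`, `alpha_sd = 0.01`, `alpha_mean = 0.05`, 50
  instruments — effect and noise scales typical of well-powered
  biomarker GWAS instruments.
* **Colocalization scenarios** (`simulate_coloc_scenario()`): two
  cohorts of n = 5,000 over a 50-variant locus (blocks of 10,
  `ld_rho = 0.8`, MAF 0.1–0.5), causal variant explaining 1% of
  phenotypic variance; modes plant a shared causal variant, distinct
  causal variants in different blocks, a trait-A-only variant, or
  nothing.
* All generators are pure functions of their arguments and a single
  integer master seed, with per-component streams at fixed offsets;
  repeated calls are bit-identical.

What passing tests on these simulations *do* show: the statistics are
implemented correctly (oracle equivalence), calibrated under their
nulls, and powered to recover planted effects at realistic sample
sizes.  What they do *not* show: robustness to real-data pathologies —
population stratification, imputation error, long-range LD, winner's
curse in instrument selection — which no locus-scale simulation can
establish.

## Numerical and design choices

* P-values are clamped below at 10⁻³⁰⁰ (flagged, never zero) so
  downstream log and FDR arithmetic stays finite.
* Positions are 1-based throughout; BED input is converted at the
  reader boundary; `chr` prefixes are stripped.  Region intervals are
  closed on both ends — "±1 Mb" naturally includes both bounds — and
  clamped at position 1; upper clamping is not applied because
  chromosome lengths are not part of region construction (the
  enrichment module, which needs them, takes a `chrom.sizes` table).
* Palindromic (A/T, C/G) variants are dropped during harmonization when
  both MAFs fall in (0.42, 0.5], mirroring standard two-sample
  harmonization defaults.
* Greedy tagging selects index variants by ascending p-value, ties by
  position then key; this index-by-significance convention is standard
  for clumping, and makes the partition deterministic.
* Malformed summary-statistics rows never abort a load; they are
  dropped and counted per reason in a load report, because consortium
  files routinely contain such rows.
* The binary-trait prevalence filter keeps a trait when
  |prev_M − prev_F| / max(prev) > 0.02; the rule is exposed as a
  pluggable predicate since reasonable variants exist.
* The heritable-trait filter retains traits strictly above the median
  sex-combined heritability, making tie behavior deterministic.

## Problem sizes used in the shipped checks

The package's validation suite uses: 20,000 trait pairs for null
calibration of the heritability test; 100 replicates at n = 20,000 per
sex (12-variant loci, planted β_M = 0.4 at MAF 0.3) for SDE recovery;
20 runs of 20,000 analytically simulated paired variants for realized
FDR under a shared-effect null; 200 random loci (m ≤ 12) for
enumeration-oracle equivalence of the colocalization posteriors plus 50
replicates per scenario mode for behavioral recovery; 200 replicates
for MR-Egger slope and intercept recovery; 500 random instances for the
tagging-rule oracle; 1,000 random instances for the region-mapping
oracle; and 200 runs at B = 99 permutations for enrichment null
calibration.  These sizes give Monte-Carlo error comfortably inside
each check's tolerance while keeping a full run in the low minutes on
one CPU.

## Known limitations

* Heritability and genetic correlation are *consumed*, not estimated;
  the package tests externally produced estimates.
* Colocalization assumes a single causal variant per trait per locus;
  no multi-causal (SuSiE-style) extension is provided.
* MR is MR-Egger only (with IVW as a diagnostic); no weighted-median,
  mode-based or outlier-removal estimators, no Steiger filtering.
* LD is computed from supplied dosage panels (composite LD) or read
  from files; no external reference-panel service is contacted.
* Enrichment permutes regions, not variants; no MAF- or LD-matched
  variant resampling.
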