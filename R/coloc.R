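# Approximate-Bayes-factor colocalization of two association signals over
# a locus, under the single-causal-variant assumption per trait, with
# sex-stratified wrappers and the single-sex classification rule.

#' Colocalization priors
#'
#' Per-variant prior probabilities that a variant is causal for trait 1
#' only (`p1`), trait 2 only (`p2`), or both (`p12`).  Defaults match the
#' standard values used with this class of analysis.
#'
#' @param p1,p2,p12 priors; must satisfy `0 < p12 <= p1, p2 < 1`.
#' @return List of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p12 > 0, p12 <= p1, p12 <= p2, p1 < 1, p2 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimate `beta` with standard error `se` and a Gaussian prior
#' with standard deviation `prior_sd` on the true effect, the asymptotic
#' Bayes factor against the null is
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)` with `V = se^2`,
#' `W = prior_sd^2`, `r = W / (V + W)`, `z = beta / se`.
#' Vectorized.
#'
#' @param beta,se estimate and standard error (`se > 0`).
#' @param prior_sd prior effect standard deviation (`>= 0`; 0 gives
#'   log ABF = 0).
#' @return Numeric vector of log Bayes factors.
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(prior_sd < 0)) stop("prior_sd must be non-negative")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

#' Effective prior effect standard deviation for a locus
#'
#' Binary (case-control) traits use the fixed log-odds-scale prior 0.2.
#' For quantitative traits the prior is `0.15 * sdY`, with the phenotype
#' standard deviation `sdY` estimated from the summary statistics via
#' `sdY^2 ~ median(se^2 * 2 * maf * (1 - maf) * n)` across the locus
#' variants, since the trait's measurement scale is usually unavailable.
#' An explicit `sdY` overrides the estimate.
#'
#' @param table a [sumstats] object for the locus.
#' @param sdY optional known phenotype standard deviation.
#' @return A single prior standard deviation.
#' @export
effective_prior_sd <- function(table, sdY = NULL) {
  if (attr(table, "trait_type") == "binary") return(0.2)
  if (!is.null(sdY)) {
    stopifnot(sdY > 0)
    return(0.15 * sdY)
  }
  est2 <- median(table$se^2 * 2 * table$maf * (1 - table$maf) * table$n)
  if (!is.finite(est2) || est2 <= 0) {
    stop("cannot estimate sdY from (maf, n, se); supply sdY explicitly")
  }
  0.15 * sqrt(est2)
}

#' Approximate-Bayes-factor colocalization of two traits over one locus
#'
#' Computes per-variant log approximate Bayes factors for both traits and
#' the posterior probabilities of the five causal configurations under a
#' single causal variant per trait: H0 no association, H1 trait-1 only,
#' H2 trait-2 only, H3 both traits with different causal variants, H4 a
#' shared causal variant.  All hypothesis arithmetic is in log space; the
#' H3 term uses a stable log-difference and is clamped to zero (with a
#' diagnostic) if rounding makes its argument nonpositive.  A
#' single-variant locus has PPH3 = 0 by construction.
#'
#' @param stats_a,stats_b [sumstats] objects over the same harmonized
#'   variant set (identical keys, same effect alleles).
#' @param priors a [coloc_priors()] object.
#' @param sdY_a,sdY_b optional phenotype standard deviations for
#'   quantitative traits (see [effective_prior_sd()]).
#' @param prior_sd_a,prior_sd_b explicit prior effect standard
#'   deviations; override the per-trait defaults entirely.
#' @return A list of class `coloc_result`: `pph` (named numeric,
#'   PPH0..PPH4, summing to 1), `labf_a`, `labf_b`, `h4_weights`
#'   (per-variant posterior weight under H4), `nsnps`, `priors`.
#' @export
coloc_abf <- function(stats_a, stats_b, priors = coloc_priors(),
                      sdY_a = NULL, sdY_b = NULL,
                      prior_sd_a = NULL, prior_sd_b = NULL) {
  ka <- variant_key(stats_a)
  kb <- variant_key(stats_b)
  if (!identical(ka, kb)) {
    stop("coloc_abf() requires identical harmonized variant sets")
  }
  m <- length(ka)
  stopifnot(m >= 1)
  if (m * (priors$p1 + priors$p2 + priors$p12) >= 1) {
    warning("locus size times total per-variant prior is >= 1; ",
            "priors are implausibly large for this locus")
  }
  wa <- prior_sd_a %||% effective_prior_sd(stats_a, sdY = sdY_a)
  wb <- prior_sd_b %||% effective_prior_sd(stats_b, sdY = sdY_b)
  la <- log_abf(stats_a$beta, stats_a$se, wa)
  lb <- log_abf(stats_b$beta, stats_b$se, wb)

  sa <- logsumexp(la)
  sb <- logsumexp(lb)
  sab <- logsumexp(la + lb)
  L <- c(
    H0 = 0,
    H1 = log(priors$p1) + sa,
    H2 = log(priors$p2) + sb,
    H3 = if (m > 1) {
      log(priors$p1) + log(priors$p2) + logdiffexp(sa + sb, sab)
    } else {
      -Inf
    },
    H4 = log(priors$p12) + sab)
  h3_clamped <- m > 1 && !is.finite(L["H3"])
  pph <- exp(L - logsumexp(L))
  pph <- pph / sum(pph)
  names(pph) <- paste0("PPH", 0:4)

  structure(
    list(pph = pph, labf_a = la, labf_b = lb,
         h4_weights = exp(la + lb - sab),
         keys = ka, nsnps = m, priors = priors,
         prior_sd = c(a = wa, b = wb),
         h3_clamped = h3_clamped),
    class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants\n", x$nsnps))
  print(round(x$pph, 4))
  cat(sprintf("Modal hypothesis: %s\n", names(which.max(x$pph))))
  if (isTRUE(x$h3_clamped)) cat("note: PPH3 clamped to 0 (log-diff underflow)\n")
  invisible(x)
}

#' Sex-stratified colocalization around a tagging variant
#'
#' Restricts the male and female summary statistics of one trait to the
#' window around a tagging variant (typically a tagging SDE), harmonizes
#' the two tables, and colocalizes with trait 1 = male, trait 2 = female.
#' PPH1 then reads "male-only association", PPH2 "female-only", PPH4
#' "shared causal variant".
#'
#' @param male,female [sumstats] objects for the same trait.
#' @param tag the tagging variant: a list/row with `chrom` and `pos`, or
#'   a `"chrom:pos"` string.
#' @param window half-width of the locus in bases (default 200,000).
#' @param priors,... passed to [coloc_abf()].
#' @return A `coloc_result`.
#' @export
sex_stratified_gwas_coloc <- function(male, female, tag, window = 2e5,
                                      priors = coloc_priors(), ...) {
  if (is.character(tag)) {
    parts <- strsplit(tag, ":")[[1]]
    tag <- list(chrom = parts[1], pos = as.numeric(parts[2]))
  }
  tag$chrom <- normalize_chrom(tag$chrom)
  in_window <- function(s) {
    s[s$chrom == tag$chrom & s$pos >= tag$pos - window &
        s$pos <= tag$pos + window, , drop = FALSE]
  }
  sub_m <- in_window(male)
  sub_f <- in_window(female)
  keep_attrs <- function(sub, orig) {
    sumstats(sub, trait_id = attr(orig, "trait_id"),
             stratum = attr(orig, "stratum"),
             trait_type = attr(orig, "trait_type"))
  }
  paired <- align_pair(keep_attrs(sub_m, male), keep_attrs(sub_f, female))
  if (nrow(paired) == 0L) {
    stop("no harmonized variants in the window around the tagging variant")
  }
  if (nrow(paired) == 1L) {
    warning("single-variant locus: PPH3 is 0 by construction")
  }
  strat <- function(which) {
    cols <- paste0(c("beta_", "se_", "pval_", "maf_", "n_"), which)
    df <- data.frame(
      rsid = paired$rsid, chrom = paired$chrom, pos = paired$pos,
      effect_allele = paired$effect_allele,
      other_allele = paired$other_allele,
      beta = paired[[cols[1]]], se = paired[[cols[2]]],
      pval = paired[[cols[3]]], maf = paired[[cols[4]]],
      n = paired[[cols[5]]], stringsAsFactors = FALSE)
    sumstats(df, trait_id = attr(male, "trait_id"),
             stratum = if (which == "m") "male" else "female",
             trait_type = attr(male, "trait_type"))
  }
  coloc_abf(strat("m"), strat("f"), priors = priors, ...)
}

#' Classify single-sex colocalization
#'
#' A locus colocalizes sex-specifically when the posterior probability of
#' a shared causal variant (PPH4) exceeds the threshold in one sex but
#' not the other (strict `>` at the threshold).
#'
#' @param result_male,result_female `coloc_result` objects or bare PPH4
#'   values.
#' @param threshold PPH4 cutoff (default 0.5).
#' @return One of `"male_specific"`, `"female_specific"`, `"both"`,
#'   `"neither"`.
#' @export
classify_sex_specific_coloc <- function(result_male, result_female,
                                        threshold = 0.5) {
  pph4 <- function(x) {
    if (inherits(x, "coloc_result")) unname(x$pph["PPH4"]) else as.numeric(x)
  }
  m <- pph4(result_male) > threshold
  f <- pph4(result_female) > threshold
  if (m && !f) "male_specific"
  else if (f && !m) "female_specific"
  else if (m && f) "both"
  else "neither"
}
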