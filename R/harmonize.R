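# Allele harmonization of variant records between two summary-statistics
# tables, and pairwise alignment of male/female tables.

#' Harmonize the alleles of two records at the same position
#'
#' Two-sample analyses (male/female effect comparison, Mendelian
#' randomization) require both records' effect sizes to refer to the same
#' effect allele.  If record `b`'s alleles are swapped relative to `a`,
#' `b`'s beta sign is inverted and the alleles relabeled (`action =
#' "flip"`).  Palindromic variants (A/T or C/G) whose minor allele
#' frequencies both fall in the strand-ambiguity band are dropped, as are
#' incompatible allele sets (`action = "drop"`).
#'
#' @param a,b single-row data frames (or lists) with fields `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `maf`.
#' @param ambiguity_band MAF interval `(low, high]` within which a
#'   palindromic variant is considered strand-ambiguous; default
#'   `c(0.42, 0.5)`, mirroring standard two-sample harmonization defaults.
#' @return A list with elements `a`, `b` (possibly modified) and `action`,
#'   one of `"keep"`, `"flip"`, `"drop"`.  Harmonization is idempotent:
#'   applying it to its own output returns `action = "keep"` (or the same
#'   `"drop"`).
#' @export
harmonize_alleles <- function(a, b, ambiguity_band = c(0.42, 0.5)) {
  if (a$chrom != b$chrom || a$pos != b$pos) {
    stop("harmonize_alleles() requires records at the same chrom and pos")
  }
  pal <- is_palindromic(a$effect_allele, a$other_allele)
  ambiguous <- function(maf) maf > ambiguity_band[1] & maf <= ambiguity_band[2]
  if (pal && ambiguous(a$maf) && ambiguous(b$maf)) {
    return(list(a = a, b = b, action = "drop"))
  }
  same <- b$effect_allele == a$effect_allele &&
    b$other_allele == a$other_allele
  swapped <- b$effect_allele == a$other_allele &&
    b$other_allele == a$effect_allele
  if (same) {
    list(a = a, b = b, action = "keep")
  } else if (swapped) {
    b$beta <- -b$beta
    ea <- b$effect_allele
    b$effect_allele <- b$other_allele
    b$other_allele <- ea
    list(a = a, b = b, action = "flip")
  } else {
    list(a = a, b = b, action = "drop")
  }
}

#' Align male and female summary statistics for one trait
#'
#' Intersects two tables on variant identity (after allele harmonization)
#' and returns one row per shared variant with both strata's statistics,
#' the female record sign-flipped where its alleles were swapped relative
#' to the male record.  The sex-difference tests consume this pairing.
#'
#' @param male,female [sumstats] objects for the same trait.
#' @param key matching key: `"position"` (chrom:pos:alleles, default) or
#'   `"rsid"`.
#' @param ambiguity_band passed to the palindromic-variant rule; see
#'   [harmonize_alleles()].
#' @return A data frame of class `paired_sumstats` with the shared variant
#'   keys and columns `beta_m`, `se_m`, `pval_m`, `maf_m`, `n_m`,
#'   `beta_f`, `se_f`, `pval_f`, `maf_f`, `n_f`.  Attribute `drop_report`
#'   counts variants not paired, by reason.  An empty intersection yields
#'   zero rows with a warning, not an error.
#' @export
align_pair <- function(male, female, key = c("position", "rsid"),
                       ambiguity_band = c(0.42, 0.5)) {
  key <- match.arg(key)
  stopifnot(inherits(male, "sumstats"), inherits(female, "sumstats"))
  km <- switch(key,
    position = canonical_key(male$chrom, male$pos,
                             male$effect_allele, male$other_allele),
    rsid = male$rsid)
  kf <- switch(key,
    position = canonical_key(female$chrom, female$pos,
                             female$effect_allele, female$other_allele),
    rsid = female$rsid)
  im <- match(kf, km)
  jf <- which(!is.na(im))
  jm <- im[jf]

  report <- c(unmatched_male = nrow(male) - length(jm),
              unmatched_female = nrow(female) - length(jf))

  m <- male[jm, , drop = FALSE]
  f <- female[jf, , drop = FALSE]

  same <- f$effect_allele == m$effect_allele & f$other_allele == m$other_allele
  swapped <- f$effect_allele == m$other_allele & f$other_allele == m$effect_allele
  compatible <- same | swapped
  pal <- is_palindromic(m$effect_allele, m$other_allele)
  amb <- function(maf) maf > ambiguity_band[1] & maf <= ambiguity_band[2]
  drop_pal <- pal & amb(m$maf) & amb(f$maf)
  keep <- compatible & !drop_pal

  report["incompatible_alleles"] <- sum(!compatible)
  report["ambiguous_palindrome"] <- sum(compatible & drop_pal)

  m <- m[keep, , drop = FALSE]
  f <- f[keep, , drop = FALSE]
  flip <- swapped[keep]
  f$beta[flip] <- -f$beta[flip]

  out <- data.frame(
    rsid = m$rsid, chrom = m$chrom, pos = m$pos,
    effect_allele = m$effect_allele, other_allele = m$other_allele,
    beta_m = m$beta, se_m = m$se, pval_m = m$pval, maf_m = m$maf, n_m = m$n,
    beta_f = f$beta, se_f = f$se, pval_f = f$pval, maf_f = f$maf, n_f = f$n,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("align_pair(): no shared variants after harmonization")
  }
  structure(out,
    class = c("paired_sumstats", "data.frame"),
    trait_id = attr(male, "trait_id"),
    trait_type = attr(male, "trait_type"),
    drop_report = report)
}
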