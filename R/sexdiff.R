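# Sex-difference statistics: the heterogeneity z test on paired per-sex
# estimates, the genetic-correlation-vs-one test, BH-FDR, SDE calling,
# the two-step eQTL multiple-testing correction, and the
# sex-differentiated / sex-specific eQTL classifier.

#' Sex-difference z test on paired estimates
#'
#' For a statistic estimated separately in females and males (a
#' heritability, a GWAS effect size, an eQTL effect size) with standard
#' errors, computes
#' `z = (stat_f - stat_m) / sqrt(se_f^2 + se_m^2)` and a two-sided p-value
#' from the standard normal.  The sign convention is female minus male.
#' Vectorized over all arguments.
#'
#' @param stat_f,se_f female estimate and its standard error (> 0).
#' @param stat_m,se_m male estimate and its standard error (> 0).
#' @return List with numeric vectors `z` and `pval`.
#' @examples
#' sex_difference_z(0.5, 0.1, 0.9, 0.1)  # z = -2.8284
#' @export
sex_difference_z <- function(stat_f, se_f, stat_m, se_m) {
  if (any(se_f <= 0) || any(se_m <= 0)) {
    stop("standard errors must be positive")
  }
  z <- (stat_f - stat_m) / sqrt(se_f^2 + se_m^2)
  list(z = z, pval = clamp_p(2 * pnorm(-abs(z))))
}

#' Test whether a male-female genetic correlation differs from 1
#'
#' Computes `t = (rg - 1) / se_rg` with a two-sided p-value from the
#' standard normal reference (a Wald test on the summary-level estimate;
#' no degrees of freedom are available for summary statistics).
#'
#' @param rg estimated genetic correlation.
#' @param se_rg its standard error (> 0).
#' @return List with `t` and `pval`.
#' @export
rg_vs_one_t <- function(rg, se_rg) {
  if (any(se_rg <= 0)) stop("standard errors must be positive")
  t <- (rg - 1) / se_rg
  list(t = t, pval = clamp_p(2 * pnorm(-abs(t))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input.  Input
#' p-values must lie in (0, 1].
#'
#' @param pvals numeric vector of p-values.
#' @return Numeric vector of q-values, `q >= p` elementwise.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Call variants with sex-differentiated effects (SDEs)
#'
#' Applies the sex-difference z test to every harmonized male/female pair
#' of GWAS effect sizes, adjusts the resulting p-values by BH-FDR within
#' the trait, and flags a variant as an SDE when the sex difference is
#' FDR-significant and the variant is genome-wide significant in at least
#' one sex:
#' `is_sde == (qval < fdr_alpha) & (min(p_male, p_female) < gwas_alpha)`.
#'
#' @param paired an [align_pair()] result.
#' @param fdr_alpha FDR threshold for the sex-difference test (0.05).
#' @param gwas_alpha per-sex genome-wide significance threshold (5e-8).
#' @param scope `"trait"` adjusts across all variants of this table (the
#'   default); supplied for symmetry with cross-trait workflows where the
#'   caller concatenates tables before adjustment.
#' @return Data frame of class `sde_calls` with the pair columns plus
#'   `z`, `pval`, `qval`, `is_sde`.
#' @export
call_sdes <- function(paired, fdr_alpha = 0.05, gwas_alpha = 5e-8,
                      scope = "trait") {
  stopifnot(inherits(paired, "paired_sumstats") || is.data.frame(paired))
  zt <- sex_difference_z(paired$beta_f, paired$se_f,
                         paired$beta_m, paired$se_m)
  out <- as.data.frame(paired)
  out$z <- zt$z
  out$pval <- zt$pval
  out$qval <- bh_fdr(zt$pval)
  out$is_sde <- out$qval < fdr_alpha &
    pmin(out$pval_m, out$pval_f) < gwas_alpha
  structure(out,
    class = c("sde_calls", "data.frame"),
    trait_id = attr(paired, "trait_id"),
    fdr_alpha = fdr_alpha, gwas_alpha = gwas_alpha)
}

#' @export
print.sde_calls <- function(x, ...) {
  cat(sprintf(
    "SDE calls: trait '%s', %d variant pairs, %d SDEs (FDR < %g, per-sex P < %g)\n",
    attr(x, "trait_id") %||% "?", nrow(x), sum(x$is_sde),
    attr(x, "fdr_alpha"), attr(x, "gwas_alpha")))
  invisible(x)
}

#' Two-step multiple-testing correction for region-scoped association
#'
#' Per gene, the minimum variant p-value is Bonferroni-corrected by the
#' number of independent variants in the gene's region
#' (`p_gene = min(1, M * min_p)`), and gene-level p-values are then
#' BH-FDR adjusted across genes.  The lead variant is the argmin p (ties
#' broken by position).
#'
#' @param snp_stats data frame with columns `gene_id`, `pval` and
#'   optionally `pos` and a key column (`rsid` or `key`).
#' @param m_independent named integer vector: independent-variant count
#'   `M >= 1` per gene (e.g. from [count_independent()]).
#' @return Data frame with one row per gene: `gene_id`, `lead`, `p_lead`,
#'   `m_independent`, `p_gene`, `qval`.
#' @export
two_step_correction <- function(snp_stats, m_independent) {
  stopifnot(all(c("gene_id", "pval") %in% names(snp_stats)),
            !is.null(names(m_independent)))
  genes <- unique(snp_stats$gene_id)
  missing_m <- setdiff(genes, names(m_independent))
  if (length(missing_m)) {
    stop("no independent-variant count for gene(s): ",
         paste(missing_m, collapse = ", "))
  }
  if (any(m_independent[genes] < 1)) stop("m_independent must be >= 1")
  key_col <- intersect(c("key", "rsid"), names(snp_stats))[1]
  rows <- lapply(genes, function(g) {
    sub <- snp_stats[snp_stats$gene_id == g, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    ord <- order(sub$pval, if ("pos" %in% names(sub)) sub$pos else
      seq_len(nrow(sub)))
    lead <- ord[1]
    m <- as.numeric(m_independent[[g]])
    data.frame(
      gene_id = g,
      lead = if (!is.na(key_col)) as.character(sub[[key_col]][lead]) else
        as.character(lead),
      p_lead = sub$pval[lead],
      m_independent = m,
      p_gene = min(1, m * sub$pval[lead]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- bh_fdr(out$p_gene)
  rownames(out) <- NULL
  out
}

#' Classify sex-differentiated and sex-specific eQTLs
#'
#' Implements the region-scoped eQTL comparison between sexes:
#' \enumerate{
#'   \item per sex, gene-level significance via the two-step correction
#'     ([two_step_correction()]);
#'   \item sex-differentiated eQTLs: the sex-difference z test on the
#'     per-sex effect sizes of each gene's lead variant, BH-FDR adjusted
#'     across genes, significant at `fdr`;
#'   \item sex-specific eQTLs: gene-level q below `fdr` in exactly one
#'     sex and above it in the other.
#' }
#' A gene meeting both definitions is labeled `sex_differentiated`
#' (effect-size heterogeneity is the stronger claim); both raw flags are
#' retained.  The lead variant for the z test is the variant minimizing
#' `min(p_male, p_female)` (ties by position).
#'
#' @param male,female data frames of per-variant eQTL statistics with
#'   columns `gene_id`, `rsid` (or `key`), `pos`, `beta`, `se`, `pval`;
#'   same gene set in both sexes.
#' @param m_independent named vector of independent-variant counts per
#'   gene; if `NULL`, computed from `ld`, a named list of per-gene
#'   `ld_matrix` objects.
#' @param ld optional named list of per-gene LD matrices (keys must match
#'   the eQTL tables' `rsid`/`key` column).
#' @param fdr significance threshold for both rules (default 0.1).
#' @return Data frame with one row per gene: per-sex gene-level q, lead
#'   variant and per-sex statistics at the shared lead, `z`, `pval_z`,
#'   `qval_z`, logical flags `sex_differentiated`, `sex_specific`, the
#'   specific sex, and the final `label` (one of `sex_differentiated`,
#'   `male_specific`, `female_specific`, `shared`, `none`).
#' @export
classify_eqtls <- function(male, female, m_independent = NULL, ld = NULL,
                           fdr = 0.1) {
  if (is.null(male) || is.null(female)) stop("both sexes are required")
  genes <- sort(unique(male$gene_id))
  if (!identical(genes, sort(unique(female$gene_id)))) {
    stop("male and female tables must cover the same gene set")
  }
  key_col <- intersect(c("key", "rsid"), names(male))[1]
  if (is.null(m_independent)) {
    if (is.null(ld)) stop("supply m_independent or per-gene ld matrices")
    m_independent <- vapply(ld, count_independent, numeric(1))
  }
  gm <- two_step_correction(male, m_independent)
  gf <- two_step_correction(female, m_independent)
  gm <- gm[match(genes, gm$gene_id), ]
  gf <- gf[match(genes, gf$gene_id), ]

  # shared lead variant per gene: argmin of min(p_male, p_female)
  lead_stats <- lapply(genes, function(g) {
    sm <- male[male$gene_id == g, , drop = FALSE]
    sf <- female[female$gene_id == g, , drop = FALSE]
    shared <- intersect(sm[[key_col]], sf[[key_col]])
    if (!length(shared)) {
      stop("gene ", g, " has no variant shared between sexes")
    }
    sm <- sm[match(shared, sm[[key_col]]), ]
    sf <- sf[match(shared, sf[[key_col]]), ]
    best <- pmin(sm$pval, sf$pval)
    ord <- order(best, if ("pos" %in% names(sm)) sm$pos else
      seq_along(shared))
    i <- ord[1]
    data.frame(gene_id = g, lead = shared[i],
               beta_m = sm$beta[i], se_m = sm$se[i], pval_m = sm$pval[i],
               beta_f = sf$beta[i], se_f = sf$se[i], pval_f = sf$pval[i],
               stringsAsFactors = FALSE)
  })
  lead_stats <- do.call(rbind, lead_stats)
  zt <- sex_difference_z(lead_stats$beta_f, lead_stats$se_f,
                         lead_stats$beta_m, lead_stats$se_m)
  qz <- bh_fdr(zt$pval)

  sig_m <- gm$qval < fdr
  sig_f <- gf$qval < fdr
  sexdiff <- qz < fdr
  specific <- xor(sig_m, sig_f)
  specific_sex <- ifelse(!specific, NA_character_,
                         ifelse(sig_m, "male", "female"))
  label <- ifelse(sexdiff, "sex_differentiated",
            ifelse(specific & specific_sex == "male", "male_specific",
             ifelse(specific & specific_sex == "female", "female_specific",
              ifelse(sig_m & sig_f, "shared", "none"))))
  label[is.na(label)] <- "none"

  data.frame(
    gene_id = genes,
    lead = lead_stats$lead,
    beta_m = lead_stats$beta_m, se_m = lead_stats$se_m,
    pval_m = lead_stats$pval_m,
    beta_f = lead_stats$beta_f, se_f = lead_stats$se_f,
    pval_f = lead_stats$pval_f,
    qval_gene_m = gm$qval, qval_gene_f = gf$qval,
    z = zt$z, pval_z = zt$pval, qval_z = qz,
    sex_differentiated = sexdiff,
    sex_specific = specific,
    specific_sex = specific_sex,
    label = label,
    stringsAsFactors = FALSE)
}
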