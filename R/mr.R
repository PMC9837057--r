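# Two-sample Mendelian randomization with MR-Egger regression,
# sex-combined vs sex-stratified grids, the sex-specific relationship
# decision rule, and gene-region-restricted instrument re-runs.

#' Select and clump genetic instruments from an exposure GWAS
#'
#' Keeps variants below the significance threshold and greedily clumps
#' them at `clump_r2` by ascending p-value (via [greedy_tag()]), returning
#' the index variants of the resulting loci.
#'
#' @param exposure a [sumstats] object.
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param ld an `ld_matrix` covering (at least) the exposure's variants,
#'   keyed as `chrom:pos:ea:oa`; `NULL` skips clumping.
#' @param clump_r2 clumping threshold (default 0.001).
#' @return Character vector of selected variant keys (possibly empty).
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8, ld = NULL,
                               clump_r2 = 0.001) {
  sig <- exposure[exposure$pval < p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(character(0))
  keys <- variant_key(sig)
  if (is.null(ld)) return(keys)
  present <- keys %in% rownames(ld)
  sig <- sig[present, , drop = FALSE]
  keys <- keys[present]
  if (!nrow(sig)) return(character(0))
  sub <- ld[keys, keys, drop = FALSE]
  names(greedy_tag(sub, priority = sig$pval, threshold = clump_r2,
                   pos = sig$pos))
}

#' Build a harmonized instrument set from exposure and outcome tables
#'
#' Subsets both tables to the selected instruments, harmonizes alleles
#' (flipping the outcome beta where its alleles are swapped relative to
#' the exposure), and returns the `(bx, bx_se, by, by_se)` rows that
#' [mr_egger()] consumes.
#'
#' @param exposure,outcome [sumstats] objects.
#' @param keys instrument variant keys from [select_instruments()];
#'   `NULL` uses all shared variants.
#' @param exposure_id,outcome_id,stratum metadata carried on the result.
#' @return Data frame of class `instrument_set`.
#' @export
make_instruments <- function(exposure, outcome, keys = NULL,
                             exposure_id = attr(exposure, "trait_id"),
                             outcome_id = attr(outcome, "trait_id"),
                             stratum = attr(exposure, "stratum")) {
  paired <- align_pair(
    structure(exposure, class = class(exposure)),
    structure(outcome, class = class(outcome)))
  if (!is.null(keys)) {
    pk <- paste(paired$chrom, paired$pos, paired$effect_allele,
                paired$other_allele, sep = ":")
    canon <- function(k) {
      parts <- strsplit(k, ":")
      vapply(parts, function(p) canonical_key(p[1], p[2], p[3], p[4]),
             character(1))
    }
    paired <- paired[canon(pk) %in% canon(keys), , drop = FALSE]
  }
  out <- data.frame(
    rsid = paired$rsid, chrom = paired$chrom, pos = paired$pos,
    effect_allele = paired$effect_allele,
    other_allele = paired$other_allele,
    bx = paired$beta_m, bx_se = paired$se_m,
    by = paired$beta_f, by_se = paired$se_f,
    stringsAsFactors = FALSE)
  structure(out, class = c("instrument_set", "data.frame"),
            exposure_id = exposure_id, outcome_id = outcome_id,
            stratum = stratum)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept, weights `1 / by_se^2`.  Each instrument is
#' first oriented so its exposure effect is non-negative (flipping both
#' signs when `bx < 0`), which the intercept requires.  The slope is the
#' causal estimate; the intercept captures directional pleiotropy.
#' Standard errors are scaled by the residual overdispersion floored at 1
#' (multiplicative random-effects policy) and p-values come from the t
#' reference with `n_inst - 2` degrees of freedom.
#'
#' @param inst an `instrument_set` or data frame with columns `bx`,
#'   `bx_se`, `by`, `by_se`; at least 3 rows.
#' @return List of class `mr_result`: `slope`, `slope_se`, `slope_p`,
#'   `intercept`, `intercept_se`, `intercept_p`, `n_inst`, `sigma`
#'   (overdispersion used), `stratum`.
#' @export
mr_egger <- function(inst) {
  stopifnot(all(c("bx", "by", "by_se") %in% names(inst)))
  if (nrow(inst) < 3) stop("MR-Egger needs at least 3 instruments")
  if (any(inst$by_se <= 0)) stop("outcome standard errors must be positive")
  if (all(inst$bx == 0)) stop("all exposure effects are zero; no identification")
  flip <- sign(inst$bx)
  flip[flip == 0] <- 1
  bx <- inst$bx * flip
  by <- inst$by * flip
  w <- 1 / inst$by_se^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * sqrt(w))
  coefs <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coefs
  n <- nrow(inst)
  sigma2 <- max(1, sum(w * resid^2) / (n - 2))
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  tval <- coefs / se
  p <- clamp_p(2 * pt(-abs(tval), n - 2))
  structure(
    list(slope = coefs[2], slope_se = se[2], slope_p = p[2],
         intercept = coefs[1], intercept_se = se[1], intercept_p = p[1],
         n_inst = n, sigma = sqrt(sigma2),
         exposure_id = attr(inst, "exposure_id"),
         outcome_id = attr(inst, "outcome_id"),
         stratum = attr(inst, "stratum") %||% NA_character_),
    class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR-Egger (%d instruments%s)\n", x$n_inst,
              if (!is.na(x$stratum)) paste0(", stratum ", x$stratum) else ""))
  cat(sprintf("  slope     % .4f (SE %.4f, p = %.3g)\n",
              x$slope, x$slope_se, x$slope_p))
  cat(sprintf("  intercept % .4f (SE %.4f, p = %.3g)\n",
              x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Inverse-variance-weighted MR (diagnostic)
#'
#' No-intercept weighted regression of outcome on exposure effects;
#' reported alongside MR-Egger as a consistency diagnostic only.
#'
#' @inheritParams mr_egger
#' @return List with `slope`, `slope_se`, `slope_p`, `n_inst`.
#' @export
mr_ivw <- function(inst) {
  if (nrow(inst) < 2) stop("IVW needs at least 2 instruments")
  w <- 1 / inst$by_se^2
  sxx <- sum(w * inst$bx^2)
  slope <- sum(w * inst$bx * inst$by) / sxx
  n <- nrow(inst)
  sigma2 <- max(1, sum(w * (inst$by - slope * inst$bx)^2) / (n - 1))
  se <- sqrt(sigma2 / sxx)
  list(slope = slope, slope_se = se,
       slope_p = clamp_p(2 * pt(-abs(slope / se), n - 1)), n_inst = n)
}

#' Run MR over an exposure-by-outcome-by-stratum grid
#'
#' For each (exposure, outcome, stratum) cell: select instruments from
#' that stratum's exposure statistics, harmonize against the outcome, and
#' fit MR-Egger.  Cell failures (no instruments, too few after
#' harmonization) are recorded in the `status` column; the grid always
#' completes.
#'
#' @param exposures,outcomes lists of [sumstats] objects; each element
#'   carries its `trait_id` and `stratum` attributes.
#' @param strata strata to run (default all three).
#' @param ld optional `ld_matrix` for clumping.
#' @param p_threshold,clump_r2 see [select_instruments()].
#' @return Data frame with one row per cell: ids, stratum, `status`
#'   (`"ok"`, `"no_instruments"`, `"too_few_instruments"`, `"error"`),
#'   `n_inst`, slope/intercept estimates, SEs and p-values.
#' @export
run_mr_grid <- function(exposures, outcomes,
                        strata = c("combined", "male", "female"),
                        ld = NULL, p_threshold = 5e-8, clump_r2 = 0.001) {
  pick <- function(lst, id, stratum) {
    for (s in lst) {
      if (identical(attr(s, "trait_id"), id) &&
          identical(attr(s, "stratum"), stratum)) return(s)
    }
    NULL
  }
  exp_ids <- unique(vapply(exposures, attr, "", "trait_id"))
  out_ids <- unique(vapply(outcomes, attr, "", "trait_id"))
  rows <- list()
  for (e in exp_ids) for (o in out_ids) for (s in strata) {
    ex <- pick(exposures, e, s)
    ou <- pick(outcomes, o, s)
    row <- data.frame(exposure_id = e, outcome_id = o, stratum = s,
                      status = "ok", n_inst = NA_integer_,
                      slope = NA_real_, slope_se = NA_real_,
                      slope_p = NA_real_, intercept = NA_real_,
                      intercept_se = NA_real_, intercept_p = NA_real_,
                      stringsAsFactors = FALSE)
    if (is.null(ex) || is.null(ou)) {
      row$status <- "missing_stratum"
    } else {
      res <- tryCatch({
        keys <- select_instruments(ex, p_threshold = p_threshold, ld = ld,
                                   clump_r2 = clump_r2)
        if (!length(keys)) {
          row$status <- "no_instruments"
          NULL
        } else {
          inst <- make_instruments(ex, ou, keys = keys, exposure_id = e,
                                   outcome_id = o, stratum = s)
          if (nrow(inst) < 3) {
            row$status <- "too_few_instruments"
            NULL
          } else {
            mr_egger(inst)
          }
        }
      }, error = function(err) {
        row$status <<- "error"
        NULL
      }, warning = function(w) {
        row$status <<- "no_instruments"
        NULL
      })
      if (!is.null(res)) {
        row$n_inst <- res$n_inst
        row$slope <- res$slope
        row$slope_se <- res$slope_se
        row$slope_p <- res$slope_p
        row$intercept <- res$intercept
        row$intercept_se <- res$intercept_se
        row$intercept_p <- res$intercept_p
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Decide whether an MR relationship is sex-specific
#'
#' A relationship is sex-specific when it is significant (on the Egger
#' slope p-value) in exactly one sex and significant in neither the other
#' sex nor the sex-combined model, at a Bonferroni threshold over the
#' grid (default `0.05 / (186 * 29)`).  Missing results count as
#' non-significant.
#'
#' @param combined,male,female `mr_result` objects, bare slope p-values,
#'   or `NA` for absent cells.
#' @param alpha significance threshold.
#' @return One of `"male_specific"`, `"female_specific"`,
#'   `"not_sex_specific"`, `"none"`.
#' @export
call_sex_specific_mr <- function(combined, male, female,
                                 alpha = 0.05 / (186 * 29)) {
  pv <- function(x) {
    if (inherits(x, "mr_result")) x$slope_p else as.numeric(x)
  }
  sig <- function(p) !is.na(p) & p < alpha
  pc <- pv(combined); pm <- pv(male); pf <- pv(female)
  if (sig(pm) && !sig(pf) && !sig(pc)) "male_specific"
  else if (sig(pf) && !sig(pm) && !sig(pc)) "female_specific"
  else if (sig(pc) || (sig(pm) && sig(pf))) "not_sex_specific"
  else "none"
}

#' Restrict an instrument set to gene regions
#'
#' Keeps instruments whose variant maps into at least one of the supplied
#' regions (typically the DMET gene regions).  If fewer than three
#' instruments survive, the restriction is reported as underpowered (the
#' `status` attribute) and MR should not be re-estimated.
#'
#' @param inst an `instrument_set`.
#' @param regions a [build_regions()] data frame.
#' @return The filtered `instrument_set`; `attr(, "status")` is `"ok"` or
#'   `"underpowered"`.
#' @export
restrict_to_dmet <- function(inst, regions) {
  keep <- snp_in_regions(inst, regions)
  out <- inst[keep, , drop = FALSE]
  attr(out, "exposure_id") <- attr(inst, "exposure_id")
  attr(out, "outcome_id") <- attr(inst, "outcome_id")
  attr(out, "stratum") <- attr(inst, "stratum")
  attr(out, "status") <- if (nrow(out) >= 3) "ok" else "underpowered"
  class(out) <- class(inst)
  out
}
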