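# Synthetic-data generators: LD-aware genotype panels, sex-stratified
# phenotypes with planted shared or sex-differentiated effects,
# heritability-estimate pairs, MR scenarios and colocalization loci.
#
# All generators are pure functions of (arguments, seed): the master seed
# is a single integer and per-component streams are derived by fixed
# offsets (keys/MAFs: +0, first panel: +1, second panel: +2, phenotype
# noise: +3/+4).

#' Simulation configuration for sex-stratified GWAS scenarios
#'
#' @param n_male,n_female individuals per sex.
#' @param m number of variants in the locus.
#' @param maf_range minor-allele-frequency sampling range, in (0, 0.5].
#' @param ld_rho latent adjacent-variant correlation within an LD block,
#'   in \[0, 1).
#' @param block_size variants per LD block (independence across blocks).
#' @param causal data frame with columns `index`, `beta_male`,
#'   `beta_female`: the planted per-sex allelic effects.
#' @param noise_sd residual standard deviation of the phenotype (or
#'   liability, for binary traits).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param prevalence case fraction for binary traits.
#' @param seed master integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_male = 1000, n_female = 1000, m = 50,
                       maf_range = c(0.05, 0.5), ld_rho = 0,
                       block_size = 25,
                       causal = data.frame(index = integer(),
                                           beta_male = numeric(),
                                           beta_female = numeric()),
                       noise_sd = 1,
                       trait_type = c("quantitative", "binary"),
                       prevalence = 0.1, seed = 1) {
  trait_type <- match.arg(trait_type)
  stopifnot(
    n_male >= 1, n_female >= 1, m >= 1,
    length(maf_range) == 2, maf_range[1] > 0,
    maf_range[1] <= maf_range[2], maf_range[2] <= 0.5,
    ld_rho >= 0, ld_rho < 1, block_size >= 1,
    noise_sd >= 0, all(causal$index >= 1), all(causal$index <= m)
  )
  if (trait_type == "binary") stopifnot(prevalence > 0, prevalence < 1)
  structure(
    list(n_male = n_male, n_female = n_female, m = m,
         maf_range = maf_range, ld_rho = ld_rho, block_size = block_size,
         causal = causal, noise_sd = noise_sd, trait_type = trait_type,
         prevalence = prevalence, seed = as.integer(seed)),
    class = "sim_config")
}

# Variant keys for a simulated locus: one chromosome, evenly spaced
# positions, non-palindromic allele pairs by default so that two-sample
# harmonization is lossless for planted variants.
simulate_variant_keys <- function(m, chrom = "1", pos_start = 1e6,
                                  pos_step = 1000, palindromes = FALSE) {
  pairs <- expand.grid(effect_allele = c("A", "C", "G", "T"),
                       other_allele = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$effect_allele != pairs$other_allele, ]
  if (!palindromes) {
    pairs <- pairs[!is_palindromic(pairs$effect_allele, pairs$other_allele), ]
  }
  pick <- sample.int(nrow(pairs), m, replace = TRUE)
  data.frame(
    rsid = sprintf("rs%06d", seq_len(m)),
    chrom = chrom,
    pos = pos_start + pos_step * (seq_len(m) - 1L),
    effect_allele = pairs$effect_allele[pick],
    other_allele = pairs$other_allele[pick],
    stringsAsFactors = FALSE)
}

#' Simulate a genotype dosage panel with block LD
#'
#' Dosages are drawn by thresholding a latent Gaussian with within-block
#' AR(1) correlation `ld_rho` at per-variant MAF-determined cutpoints; two
#' independent latent draws per individual are summed, giving dosages in
#' \{0, 1, 2\} with Hardy-Weinberg margins and monotone LD decay inside a
#' block.  Blocks are mutually independent.  Deterministic given `seed`.
#'
#' @param n individuals.
#' @param m variants.
#' @param maf per-variant allele frequencies; if `NULL`, sampled uniformly
#'   from `maf_range`.
#' @param keys optional variant key data frame (as produced internally);
#'   generated when `NULL`.
#' @inheritParams sim_config
#' @param seed integer seed.
#' @return A list of class `genotype_panel` with elements `dosage`
#'   (n x m matrix), `keys`, `maf` (target) and `maf_real` (realized,
#'   folded to the minor allele).
#' @export
simulate_genotypes <- function(n, m, maf = NULL, maf_range = c(0.05, 0.5),
                               ld_rho = 0, block_size = 25,
                               keys = NULL, seed = 1) {
  stopifnot(n >= 1, m >= 1, ld_rho >= 0, ld_rho < 1)
  with_seed(seed, {
    if (is.null(maf)) maf <- runif(m, maf_range[1], maf_range[2])
    stopifnot(length(maf) == m, all(maf > 0), all(maf <= 0.5))
    if (is.null(keys)) keys <- simulate_variant_keys(m)
    cut <- qnorm(1 - maf)  # P(z > cut) = maf
    latent <- function() {
      e <- matrix(rnorm(n * m), n, m)
      z <- e
      if (ld_rho > 0) {
        for (j in 2:m) {
          if ((j - 1L) %% block_size == 0L) next  # new block boundary
          z[, j] <- ld_rho * z[, j - 1L] + sqrt(1 - ld_rho^2) * e[, j]
        }
      }
      z
    }
    g <- (sweep(latent(), 2, cut, ">") + sweep(latent(), 2, cut, ">"))
    storage.mode(g) <- "integer"
    freq <- colMeans(g) / 2
    structure(
      list(dosage = g, keys = keys, maf = maf,
           maf_real = pmin(freq, 1 - freq)),
      class = "genotype_panel")
  })
}

#' Per-variant marginal association scan
#'
#' Fits, for each variant separately, the single-variant linear model
#' `y ~ intercept + dosage + covariates` by ordinary least squares and
#' returns the slope, its standard error and a two-sided p-value from the
#' t reference with `n - k - 2` degrees of freedom (`k` covariates).
#' Variants with (residual) zero dosage variance are excluded and counted
#' in the load report.
#'
#' @param y numeric phenotype vector.
#' @param panel a [simulate_genotypes()] panel, or a dosage matrix.
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is always added).
#' @param trait_id,stratum metadata for the returned table.
#' @return A [sumstats] table with one row per retained variant; realized
#'   MAF and `n` are filled from the panel.
#' @export
marginal_association <- function(y, panel, covariates = NULL,
                                 trait_id = "sim_trait",
                                 stratum = "combined") {
  G <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  keys <- if (inherits(panel, "genotype_panel")) panel$keys else NULL
  n <- length(y)
  stopifnot(nrow(G) == n)
  if (is.null(keys)) keys <- simulate_variant_keys(ncol(G))
  X <- cbind(rep(1, n), covariates)
  k <- ncol(X) - 1L
  df <- n - k - 2L
  stopifnot(df >= 1)
  qrX <- qr(X)
  ry <- qr.resid(qrX, y)
  RG <- qr.resid(qrX, G)
  sxx <- colSums(RG^2)
  keep <- sxx > n * 1e-12
  n_dropped <- sum(!keep)

  sxy <- colSums(RG * ry)[keep]
  sxx <- sxx[keep]
  slope <- sxy / sxx
  rss <- pmax(sum(ry^2) - slope^2 * sxx, 0)
  se <- pmax(sqrt(rss / df / sxx), .P_FLOOR)
  pval <- clamp_p(2 * pt(-abs(slope / se), df))

  freq <- colMeans(G[, keep, drop = FALSE]) / 2
  out <- data.frame(
    keys[keep, , drop = FALSE],
    beta = slope, se = se, pval = pval,
    maf = pmin(pmax(freq, 1e-12), 1 - freq), n = n,
    stringsAsFactors = FALSE)
  tab <- sumstats(out, trait_id = trait_id, stratum = stratum,
                  trait_type = "quantitative")
  rep <- attr(tab, "load_report")
  rep["zero_variance"] <- n_dropped
  attr(tab, "load_report") <- rep
  tab
}

# Per-variant logistic fits for binary traits (log-odds scale betas).
logistic_association <- function(case, panel, trait_id = "sim_trait",
                                 stratum = "combined") {
  G <- panel$dosage
  n <- length(case)
  res <- lapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    if (var(g) < 1e-12) return(NULL)
    fit <- glm.fit(cbind(1, g), case, family = binomial())
    cov <- chol2inv(chol(crossprod(sqrt(fit$weights) * cbind(1, g))))
    beta <- fit$coefficients[2]
    se <- sqrt(cov[2, 2])
    z <- beta / se
    data.frame(j = j, beta = beta, se = se,
               pval = clamp_p(2 * pnorm(-abs(z))))
  })
  res <- do.call(rbind, res)
  freq <- colMeans(G[, res$j, drop = FALSE]) / 2
  out <- data.frame(
    panel$keys[res$j, , drop = FALSE],
    beta = res$beta, se = res$se, pval = res$pval,
    maf = pmin(pmax(freq, 1e-12), 1 - freq),
    n = n, n_cases = sum(case),
    stringsAsFactors = FALSE)
  sumstats(out, trait_id = trait_id, stratum = stratum, trait_type = "binary")
}

#' Simulate sex-stratified GWAS summary statistics
#'
#' Generates one genotype panel per sex (shared variant keys and MAFs),
#' phenotypes `y = sum(beta_sex * g) + e`, and runs the per-variant
#' marginal scan in each sex.  Binary traits are generated by thresholding
#' the liability at the configured prevalence and summarized with
#' per-variant logistic fits (log-odds scale betas).
#'
#' @param config a [sim_config()].
#' @return A list with [sumstats] elements `male` and `female` and a
#'   `truth` list carrying the planted per-variant `beta_male` /
#'   `beta_female` vectors, realized per-sex heritability of the planted
#'   effects, and the variant keys.
#' @export
simulate_sex_stratified_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  meta <- with_seed(cf$seed, {
    list(maf = runif(cf$m, cf$maf_range[1], cf$maf_range[2]),
         keys = simulate_variant_keys(cf$m))
  })
  beta <- list(male = numeric(cf$m), female = numeric(cf$m))
  beta$male[cf$causal$index] <- cf$causal$beta_male
  beta$female[cf$causal$index] <- cf$causal$beta_female

  one_sex <- function(sex, n, panel_seed, noise_seed) {
    panel <- simulate_genotypes(n, cf$m, maf = meta$maf, ld_rho = cf$ld_rho,
                                block_size = cf$block_size, keys = meta$keys,
                                seed = panel_seed)
    genetic <- drop(panel$dosage %*% beta[[sex]])
    y <- genetic + with_seed(noise_seed, rnorm(n, 0, cf$noise_sd))
    if (cf$trait_type == "quantitative") {
      tab <- marginal_association(y, panel, trait_id = "sim_trait",
                                  stratum = sex)
    } else {
      thr <- quantile(y, 1 - cf$prevalence, names = FALSE)
      case <- as.numeric(y > thr)
      if (sum(case) < 10) {
        stop("binary trait simulation produced fewer than 10 cases")
      }
      tab <- logistic_association(case, panel, trait_id = "sim_trait",
                                  stratum = sex)
    }
    list(tab = tab, h2 = var(genetic) / max(var(y), .Machine$double.eps))
  }
  male <- one_sex("male", cf$n_male, cf$seed + 1L, cf$seed + 3L)
  female <- one_sex("female", cf$n_female, cf$seed + 2L, cf$seed + 4L)
  list(male = male$tab, female = female$tab,
       truth = list(beta_male = beta$male, beta_female = beta$female,
                    h2_male = male$h2, h2_female = female$h2,
                    keys = meta$keys, maf = meta$maf))
}

#' Simulate pairs of per-sex heritability estimates
#'
#' Gaussian perturbations of the true per-sex heritabilities, clamped to
#' \[0, 1\], with the generating standard errors attached; feeds the
#' heritability sex-difference z test.
#'
#' @param h2 length-2 numeric `(male, female)` true heritabilities in
#'   \[0, 1\].
#' @param se length-2 numeric `(male, female)` standard errors (> 0).
#' @param n_traits number of trait pairs to draw.
#' @param seed integer seed.
#' @return Data frame with columns `trait_id`, `h2_male`, `se_male`,
#'   `h2_female`, `se_female`.
#' @export
simulate_h2_estimates <- function(h2, se, n_traits, seed = 1) {
  stopifnot(length(h2) == 2, length(se) == 2,
            all(h2 >= 0), all(h2 <= 1), all(se >= 0), n_traits >= 1)
  with_seed(seed, {
    data.frame(
      trait_id = sprintf("trait%05d", seq_len(n_traits)),
      h2_male = pmin(pmax(rnorm(n_traits, h2[1], se[1]), 0), 1),
      se_male = se[1],
      h2_female = pmin(pmax(rnorm(n_traits, h2[2], se[2]), 0), 1),
      se_female = se[2],
      stringsAsFactors = FALSE)
  })
}

#' Simulate a two-sample MR scenario
#'
#' Instruments are generated on the exposure-increasing allele (the usual
#' orientation convention for instrument sets), so the true effects are
#' half-normal, `gamma_j ~ |N(0, gamma_sd^2)|`.  Outcome effects are
#' `theta * gamma_j + alpha_j` plus sampling noise, where the pleiotropic
#' effects `alpha_j` are zero (`"none"`), zero-mean Gaussian
#' (`"balanced"`) or mean-shifted Gaussian (`"directional"`); a
#' directional mean is only identifiable relative to a fixed allele
#' orientation, which the half-normal convention provides.  Observed
#' exposure betas are `gamma_j` plus noise at `se_x`.
#'
#' @param theta true causal effect of exposure on outcome.
#' @param gamma_sd spread of true instrument-exposure effects.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param alpha_sd spread of pleiotropic effects.
#' @param alpha_mean mean pleiotropic effect under `"directional"`.
#' @param n_inst number of instruments (>= 3; the Egger regression needs
#'   at least three).
#' @param se_x,se_y sampling standard errors of the exposure and outcome
#'   betas.
#' @param seed integer seed.
#' @return A list with `instruments` (data frame ready for [mr_egger()]),
#'   `exposure` and `outcome` [sumstats] tables, and a `truth` list with
#'   `theta`, `gamma` and `alpha`.
#' @export
simulate_mr_scenario <- function(theta, gamma_sd = 0.1,
                                 pleiotropy_mode = c("none", "balanced",
                                                     "directional"),
                                 alpha_sd = 0.01, alpha_mean = 0.05,
                                 n_inst = 50, se_x = 0.005, se_y = 0.01,
                                 seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (n_inst < 3) stop("MR-Egger needs at least 3 instruments")
  with_seed(seed, {
    gamma <- abs(rnorm(n_inst, 0, gamma_sd))
    alpha <- switch(pleiotropy_mode,
      none = numeric(n_inst),
      balanced = rnorm(n_inst, 0, alpha_sd),
      directional = rnorm(n_inst, alpha_mean, alpha_sd))
    bx <- gamma + rnorm(n_inst, 0, se_x)
    by <- theta * gamma + alpha + rnorm(n_inst, 0, se_y)
    keys <- simulate_variant_keys(n_inst, pos_step = 1e6)
    maf <- runif(n_inst, 0.1, 0.5)
    bx_se <- rep(max(se_x, 1e-12), n_inst)
    by_se <- rep(max(se_y, 1e-12), n_inst)
    mk <- function(beta, se) {
      sumstats(
        data.frame(keys, beta = beta, se = se,
                   pval = clamp_p(2 * pnorm(-abs(beta / se))),
                   maf = maf, n = 1e5, stringsAsFactors = FALSE),
        trait_id = "exposure", stratum = "combined")
    }
    inst <- data.frame(keys,
                       bx = bx, bx_se = bx_se, by = by, by_se = by_se,
                       stringsAsFactors = FALSE)
    list(instruments = inst,
         exposure = mk(bx, bx_se), outcome = mk(by, by_se),
         truth = list(theta = theta, gamma = gamma, alpha = alpha))
  })
}

#' Simulate a colocalization locus for two traits
#'
#' Generates two cohorts genotyped at the same locus (shared keys, MAFs
#' and LD structure) and quantitative phenotypes according to `mode`:
#' `"shared"` plants the same causal variant for both traits, `"distinct"`
#' plants causal variants in different LD blocks (latent correlation 0),
#' `"single_stratum"` plants a causal variant for trait A only, `"null"`
#' plants none.  The causal variant explains `pve` of phenotypic variance.
#'
#' @param mode scenario type.
#' @param n individuals per cohort.
#' @param m variants (>= 10).
#' @param pve phenotypic variance explained by the causal variant.
#' @param maf_range,ld_rho,block_size locus structure; see
#'   [simulate_genotypes()].
#' @param seed integer seed.
#' @return A list with [sumstats] elements `stats_a`, `stats_b` and a
#'   `truth` list (`mode`, causal indices `index_a`, `index_b`).
#' @export
simulate_coloc_scenario <- function(mode = c("shared", "distinct",
                                             "single_stratum", "null"),
                                    n = 5000, m = 50, pve = 0.01,
                                    maf_range = c(0.1, 0.5), ld_rho = 0.8,
                                    block_size = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(m >= 10, pve > 0, pve < 1)
  meta <- with_seed(seed, {
    list(maf = runif(m, maf_range[1], maf_range[2]),
         keys = simulate_variant_keys(m))
  })
  n_blocks <- ceiling(m / block_size)
  block_mid <- function(b) min(m, (b - 1L) * block_size + ceiling(block_size / 2))
  idx_a <- block_mid(1L)
  idx_b <- if (mode == "distinct") block_mid(min(2L, n_blocks)) else idx_a
  if (mode == "distinct" && n_blocks < 2) {
    stop("distinct mode needs at least two LD blocks")
  }
  causal_a <- mode %in% c("shared", "distinct", "single_stratum")
  causal_b <- mode %in% c("shared", "distinct")

  one_trait <- function(idx, causal, panel_seed, noise_seed, trait_id) {
    panel <- simulate_genotypes(n, m, maf = meta$maf, ld_rho = ld_rho,
                                block_size = block_size, keys = meta$keys,
                                seed = panel_seed)
    y <- with_seed(noise_seed, rnorm(n, 0, sqrt(1 - pve)))
    if (causal) {
      f <- meta$maf[idx]
      beta <- sqrt(pve / (2 * f * (1 - f)))
      y <- y + beta * panel$dosage[, idx]
    }
    marginal_association(y, panel, trait_id = trait_id)
  }
  list(
    stats_a = one_trait(idx_a, causal_a, seed + 1L, seed + 3L, "trait_a"),
    stats_b = one_trait(idx_b, causal_b, seed + 2L, seed + 4L, "trait_b"),
    truth = list(mode = mode,
                 index_a = if (causal_a) idx_a else NA_integer_,
                 index_b = if (causal_b) idx_b else NA_integer_))
}
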