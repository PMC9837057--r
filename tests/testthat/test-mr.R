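# Instrument selection, MR-Egger estimation, the grid runner, the
# sex-specific relationship rule, and gene-region restriction.

make_inst <- function(bx, by, by_se = rep(0.05, length(bx)),
                      bx_se = rep(0.01, length(bx)), chrom = "1") {
  structure(
    data.frame(rsid = paste0("rs", seq_along(bx)), chrom = chrom,
               pos = seq_along(bx) * 1e6,
               effect_allele = "A", other_allele = "G",
               bx = bx, bx_se = bx_se, by = by, by_se = by_se,
               stringsAsFactors = FALSE),
    class = c("instrument_set", "data.frame"))
}

test_that("MR-Egger recovers exact linear relationships", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  fit <- mr_egger(make_inst(bx, 0.5 * bx))
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)

  fit2 <- mr_egger(make_inst(bx, 0.1 + 0.5 * bx))
  expect_equal(fit2$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit2$sigma, 1)  # overdispersion floored at 1
})

test_that("MR-Egger equals the closed-form weighted normal equations", {
  bx <- c(0.12, 0.25, 0.31)
  by <- c(0.07, 0.11, 0.18)
  by_se <- c(0.02, 0.05, 0.03)
  fit <- mr_egger(make_inst(bx, by, by_se = by_se))
  want <- wls_oracle(bx, by, 1 / by_se^2)
  expect_equal(fit$slope, unname(want["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(want["intercept"]), tolerance = 1e-10)
})

test_that("MR-Egger is scale-equivariant and orientation-invariant", {
  set.seed(61)
  bx <- runif(8, 0.05, 0.3)
  by <- 0.05 + 0.4 * bx + rnorm(8, 0, 0.02)
  by_se <- runif(8, 0.02, 0.08)
  base <- mr_egger(make_inst(bx, by, by_se = by_se))

  k <- 3.7
  scaled <- mr_egger(make_inst(bx, k * by, by_se = k * by_se))
  expect_equal(scaled$slope, k * base$slope, tolerance = 1e-10)
  expect_equal(scaled$intercept, k * base$intercept, tolerance = 1e-10)
  expect_equal(scaled$slope_se, k * base$slope_se, tolerance = 1e-10)
  expect_equal(scaled$slope_p, base$slope_p, tolerance = 1e-10)

  # flipping the reported allele of one instrument changes nothing
  bx2 <- bx; by2 <- by
  bx2[3] <- -bx2[3]; by2[3] <- -by2[3]
  flipped <- mr_egger(make_inst(bx2, by2, by_se = by_se))
  expect_equal(flipped$slope, base$slope, tolerance = 1e-12)
  expect_equal(flipped$intercept, base$intercept, tolerance = 1e-12)
})

test_that("MR-Egger rejects degenerate instrument sets", {
  expect_error(mr_egger(make_inst(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
  expect_error(mr_egger(make_inst(rep(0, 4), rep(0.1, 4))),
               "no identification")
})

test_that("instrument selection applies the p threshold and clumping", {
  df <- rand_sumstats_df(4)
  df$pval <- c(1e-9, 1e-7, 1e-10, 0.2)
  tab <- sumstats(df)
  keys <- select_instruments(tab, p_threshold = 5e-8)
  expect_length(keys, 2)  # 1e-9 and 1e-10 pass, 1e-7 does not

  # two significant variants in near-perfect LD collapse to the smaller p
  sig <- tab[tab$pval < 5e-8, ]
  kk <- variant_key(sig)
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(kk, kk))
  clumped <- select_instruments(tab, p_threshold = 5e-8, ld = r2,
                                clump_r2 = 0.001)
  expect_equal(clumped, kk[which.min(sig$pval)])

  none <- sumstats(transform(rand_sumstats_df(3), pval = 0.5))
  expect_length(select_instruments(none, p_threshold = 5e-8), 0)
})

test_that("the MR grid completes with per-cell failure records", {
  strong <- function(id, stratum, seed, theta = 0.3) {
    sc <- simulate_mr_scenario(theta, n_inst = 20, seed = seed)
    ex <- sumstats(as.data.frame(sc$exposure), trait_id = id,
                   stratum = stratum)
    out <- sumstats(as.data.frame(sc$outcome), trait_id = paste0("o_", id),
                    stratum = stratum)
    list(ex = ex, out = out)
  }
  cells <- list(
    strong("e1", "combined", 1), strong("e1", "male", 2),
    strong("e1", "female", 3),
    strong("e2", "combined", 4), strong("e2", "male", 5),
    strong("e2", "female", 6))
  exposures <- lapply(cells, `[[`, "ex")
  outcomes <- lapply(cells, `[[`, "out")
  # weak exposure with no significant instruments
  weak <- sumstats(transform(rand_sumstats_df(10), pval = 0.5),
                   trait_id = "e_weak", stratum = "combined")
  grid <- run_mr_grid(c(exposures, list(weak)), outcomes)
  expect_equal(nrow(grid), 3 * 2 * 3)  # 3 exposures x 2 outcomes x 3 strata
  ok <- grid[grid$exposure_id %in% c("e1", "e2") &
               grid$outcome_id == paste0("o_", grid$exposure_id), ]
  expect_true(all(ok$status == "ok"))
  expect_true(all(grid$status[grid$exposure_id == "e_weak" &
                                grid$stratum == "combined"] ==
                    "no_instruments"))
  expect_true(all(grid$status[grid$exposure_id == "e_weak" &
                                grid$stratum != "combined"] ==
                    "missing_stratum"))
})

test_that("sex-specific MR relationships follow the decision rule", {
  alpha <- 0.05 / (186 * 29)  # about 9.27e-6
  expect_equal(call_sex_specific_mr(0.2, 1e-7, 0.3), "male_specific")
  expect_equal(call_sex_specific_mr(0.2, 0.3, 1e-7), "female_specific")
  expect_equal(call_sex_specific_mr(1e-8, 1e-8, 1e-8), "not_sex_specific")
  expect_equal(call_sex_specific_mr(0.2, 0.5, 0.5), "none")
  # combined significance vetoes sex-specificity
  expect_equal(call_sex_specific_mr(1e-8, 1e-7, 0.3), "not_sex_specific")
  # boundary: p just above the threshold is not significant
  expect_equal(call_sex_specific_mr(0.2, alpha * 1.01, 0.3), "none")
  expect_equal(call_sex_specific_mr(NA, 1e-7, NA), "male_specific")
})

test_that("gene-region restriction filters instruments like the oracle", {
  regions <- build_regions(
    data.frame(gene_id = c("g1", "g2"), chrom = c("1", "2"),
               strand = "+", tss = c(5e6, 8e6)), flank = 1e6)
  inst <- make_inst(bx = runif(6, 0.1, 0.3), by = runif(6, 0, 0.2),
                    chrom = c("1", "1", "2", "2", "3", "1"))
  inst$pos <- c(4.5e6, 7.5e6, 8.2e6, 1e6, 5e6, 5.9e6)
  kept <- restrict_to_dmet(inst, regions)
  want <- vapply(seq_len(nrow(inst)), function(i) {
    any(inst$chrom[i] == regions$chrom &
          inst$pos[i] >= regions$start &
          inst$pos[i] <= regions$end)
  }, logical(1))
  expect_equal(kept$rsid, inst$rsid[want])
  expect_equal(attr(kept, "status"), "ok")

  # all inside: identical set; none inside: underpowered
  all_in <- restrict_to_dmet(inst[want, ], regions)
  expect_equal(nrow(all_in), sum(want))
  none_in <- inst
  none_in$chrom <- "9"
  expect_equal(attr(restrict_to_dmet(none_in, regions), "status"),
               "underpowered")
})

test_that("selected instruments flow through harmonization to estimation", {
  sc <- simulate_mr_scenario(0.5, n_inst = 30, seed = 91)
  keys <- select_instruments(sc$exposure, p_threshold = 5e-8)
  expect_gt(length(keys), 3)
  inst <- make_instruments(sc$exposure, sc$outcome, keys = keys)
  fit <- mr_egger(inst)
  expect_equal(fit$slope, 0.5, tolerance = 0.15)
})
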