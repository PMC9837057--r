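# Sex-difference z test, genetic-correlation test, BH-FDR, SDE calling,
# two-step eQTL correction and eQTL classification.

test_that("the sex-difference z statistic follows its closed form", {
  r <- sex_difference_z(1, 1, 1, 1)
  expect_equal(r$z, 0)
  expect_equal(r$pval, 1)

  r2 <- sex_difference_z(0.5, 0.1, 0.9, 0.1)
  expect_equal(r2$z, -0.4 / sqrt(0.02), tolerance = 1e-12)  # -2.8284

  # antisymmetric under sex swap, p unchanged
  a <- sex_difference_z(0.3, 0.05, 0.7, 0.08)
  b <- sex_difference_z(0.7, 0.08, 0.3, 0.05)
  expect_equal(a$z, -b$z)
  expect_equal(a$pval, b$pval)

  expect_error(sex_difference_z(1, 0, 1, 1), "positive")
})

test_that("the genetic-correlation-vs-one test is a normal Wald test", {
  r <- rg_vs_one_t(1, 0.1)
  expect_equal(r$t, 0)
  expect_equal(r$pval, 1)
  r5 <- rg_vs_one_t(0.5, 0.1)
  expect_equal(r5$t, -5)
  expect_equal(r5$pval, 2 * pnorm(-5), tolerance = 1e-12)  # 5.73e-7
  expect_error(rg_vs_one_t(0.5, 0), "positive")
})

test_that("BH adjustment matches hand step-up computation", {
  expect_equal(bh_fdr(c(0.001, 0.008, 0.039, 0.041)),
               c(0.004, 0.016, 0.041, 0.041), tolerance = 1e-12)
  expect_equal(bh_fdr(0.03), 0.03)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("BH q-values satisfy order preservation and q >= p", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
  }
})

make_paired <- function(beta_m, se_m, pval_m, beta_f, se_f, pval_f) {
  m <- length(beta_m)
  structure(
    data.frame(rsid = paste0("rs", seq_len(m)), chrom = "1",
               pos = seq_len(m) * 100, effect_allele = "A",
               other_allele = "G",
               beta_m = beta_m, se_m = se_m, pval_m = pval_m,
               maf_m = 0.3, n_m = 1e4,
               beta_f = beta_f, se_f = se_f, pval_f = pval_f,
               maf_f = 0.3, n_f = 1e4, stringsAsFactors = FALSE),
    class = c("paired_sumstats", "data.frame"), trait_id = "t")
}

test_that("SDE calling needs both FDR and per-sex GWAS significance", {
  # variant 1: huge sex difference AND genome-wide significant in males
  # variant 2: huge sex difference but only modest per-sex p-values
  # variants 3-10: null
  paired <- make_paired(
    beta_m = c(1, 1, rep(0.01, 8)), se_m = 0.1,
    pval_m = c(1e-20, 1e-3, rep(0.5, 8)),
    beta_f = c(0, 0, rep(0.01, 8)), se_f = 0.1,
    pval_f = c(0.9, 1e-3, rep(0.5, 8)))
  calls <- call_sdes(paired)
  expect_true(calls$is_sde[1])
  expect_lt(calls$qval[2], 0.05)   # FDR-significant difference...
  expect_false(calls$is_sde[2])    # ...but not GWAS-significant in any sex
  expect_false(any(calls$is_sde[3:10]))
  expect_true(all(calls$qval >= calls$pval))
})

test_that("the SDE pipeline flags a planted sex-differentiated variant", {
  cf <- sim_config(n_male = 20000, n_female = 20000, m = 12,
                   maf_range = c(0.3, 0.3),
                   causal = data.frame(index = 6, beta_male = 0.4,
                                       beta_female = 0),
                   seed = 301)
  sim <- simulate_sex_stratified_gwas(cf)
  calls <- call_sdes(align_pair(sim$male, sim$female))
  planted <- which(calls$pos == sim$truth$keys$pos[6])
  expect_true(calls$is_sde[planted])
  expect_false(any(calls$is_sde[-planted]))
})

test_that("two-step correction Bonferroni-scales then FDR-adjusts", {
  snp <- data.frame(gene_id = c("g1", "g2", "g2", "g3"),
                    rsid = c("a", "b", "c", "d"),
                    pos = c(10, 20, 30, 40),
                    pval = c(0.01, 0.001, 0.5, 0.05))
  m <- c(g1 = 1, g2 = 20, g3 = 1)
  res <- two_step_correction(snp, m)
  expect_equal(res$p_gene[res$gene_id == "g1"], 0.01)
  expect_equal(res$p_gene[res$gene_id == "g2"], 0.02)  # 20 * 0.001
  expect_equal(res$lead[res$gene_id == "g2"], "b")
  expect_equal(res$qval, bh_fdr(res$p_gene))

  # Bonferroni caps at 1
  res2 <- two_step_correction(
    data.frame(gene_id = "g", rsid = "x", pos = 1, pval = 0.2),
    c(g = 50))
  expect_equal(res2$p_gene, 1)

  expect_error(two_step_correction(snp, c(g1 = 1)), "g2")
})

test_that("with M = 1 the two-step correction is BH over per-gene minima", {
  set.seed(31)
  snp <- data.frame(gene_id = rep(paste0("g", 1:6), each = 4),
                    rsid = paste0("v", 1:24), pos = 1:24,
                    pval = runif(24))
  m <- setNames(rep(1, 6), paste0("g", 1:6))
  res <- two_step_correction(snp, m)
  minp <- as.vector(tapply(snp$pval, snp$gene_id, min)[res$gene_id])
  expect_equal(res$p_gene, minp)
  expect_equal(res$qval, bh_fdr(minp))
})

make_eqtl_table <- function(genes_spec) {
  # genes_spec: list of gene -> data.frame(rsid, pos, beta, se, pval)
  do.call(rbind, lapply(names(genes_spec), function(g) {
    cbind(gene_id = g, genes_spec[[g]], stringsAsFactors = FALSE)
  }))
}

test_that("an eQTL significant only in males is labeled male_specific", {
  # geneA lead: strong in males, null in females, similar effect scale so
  # the heterogeneity z is small; geneB/geneC null in both sexes
  male <- make_eqtl_table(list(
    geneA = data.frame(rsid = c("v1", "v2"), pos = c(10, 20),
                       beta = c(0.5, 0.05), se = c(0.1, 0.1),
                       pval = c(1e-6, 0.6)),
    geneB = data.frame(rsid = "v3", pos = 30, beta = 0.02, se = 0.1,
                       pval = 0.8),
    geneC = data.frame(rsid = "v4", pos = 40, beta = 0.01, se = 0.1,
                       pval = 0.9)))
  female <- make_eqtl_table(list(
    geneA = data.frame(rsid = c("v1", "v2"), pos = c(10, 20),
                       beta = c(0.40, 0.02), se = c(0.25, 0.1),
                       pval = c(0.4, 0.7)),
    geneB = data.frame(rsid = "v3", pos = 30, beta = 0.01, se = 0.1,
                       pval = 0.7),
    geneC = data.frame(rsid = "v4", pos = 40, beta = 0.03, se = 0.1,
                       pval = 0.5)))
  m_ind <- c(geneA = 2, geneB = 1, geneC = 1)
  res <- classify_eqtls(male, female, m_independent = m_ind)
  a <- res[res$gene_id == "geneA", ]
  expect_lt(a$qval_gene_m, 0.1)
  expect_gt(a$qval_gene_f, 0.1)
  expect_equal(a$label, "male_specific")
  expect_false(a$sex_differentiated)
  expect_equal(res$label[res$gene_id != "geneA"], c("none", "none"))
})

test_that("identical per-sex tables produce no sex-dependent labels", {
  tab <- make_eqtl_table(list(
    geneA = data.frame(rsid = "v1", pos = 10, beta = 0.5, se = 0.1,
                       pval = 1e-6),
    geneB = data.frame(rsid = "v2", pos = 20, beta = 0.1, se = 0.1,
                       pval = 0.3)))
  res <- classify_eqtls(tab, tab, m_independent = c(geneA = 1, geneB = 1))
  expect_false(any(res$sex_differentiated))
  expect_false(any(res$sex_specific))
  expect_equal(res$label[res$gene_id == "geneA"], "shared")
  expect_equal(res$label[res$gene_id == "geneB"], "none")
})

test_that("a strong planted effect-size difference is labeled sex_differentiated", {
  male <- make_eqtl_table(list(
    geneA = data.frame(rsid = "v1", pos = 10, beta = 0.8, se = 0.05,
                       pval = 1e-20),
    geneB = data.frame(rsid = "v2", pos = 20, beta = 0.0, se = 0.1,
                       pval = 0.9)))
  female <- make_eqtl_table(list(
    geneA = data.frame(rsid = "v1", pos = 10, beta = 0.2, se = 0.05,
                       pval = 1e-4),
    geneB = data.frame(rsid = "v2", pos = 20, beta = 0.0, se = 0.1,
                       pval = 0.8)))
  res <- classify_eqtls(male, female, m_independent = c(geneA = 1, geneB = 1))
  a <- res[res$gene_id == "geneA", ]
  expect_true(a$sex_differentiated)
  expect_equal(a$label, "sex_differentiated")
})

test_that("the simulated eQTL pipeline recovers a planted male-only effect", {
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    cf <- sim_config(n_male = 100, n_female = 100, m = 6,
                     maf_range = c(0.2, 0.4),
                     causal = data.frame(index = 3, beta_male = 0.8,
                                         beta_female = 0),
                     seed = 5000 + s)
    sim <- simulate_sex_stratified_gwas(cf)  # equal n per sex by design
    mk <- function(tab) {
      data.frame(gene_id = "gene1", rsid = tab$rsid, pos = tab$pos,
                 beta = tab$beta, se = tab$se, pval = tab$pval,
                 stringsAsFactors = FALSE)
    }
    res <- classify_eqtls(mk(sim$male), mk(sim$female),
                          m_independent = c(gene1 = 6))
    if (res$label %in% c("male_specific", "sex_differentiated")) {
      hits <- hits + 1L
    }
  }
  expect_gt(hits, n_rep / 2)
})
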