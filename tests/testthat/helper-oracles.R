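# Independent oracles and fixture builders shared across tests.  Each
# oracle is a literal, brute-force restatement of the rule it checks and
# stays independent of the package's implementation path.

# A random, valid summary-statistics data frame over one chromosome.
rand_sumstats_df <- function(m, chrom = "1", pos = NULL, n = 5000,
                             beta_sd = 0.3) {
  data.frame(
    rsid = sprintf("rs%04d", seq_len(m)),
    chrom = chrom,
    pos = pos %||% (seq_len(m) * 100),
    effect_allele = "A", other_allele = "G",
    beta = rnorm(m, 0, beta_sd),
    se = runif(m, 0.02, 0.2),
    pval = runif(m),
    maf = runif(m, 0.05, 0.5),
    n = n,
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Colocalization oracle: enumerate every per-variant causal configuration
# explicitly, collect its log prior-weighted Bayes factor, and normalize
# with a common max subtraction so huge Bayes factors cannot overflow.
coloc_enum_oracle <- function(labf_a, labf_b, p1 = 1e-4, p2 = 1e-4,
                              p12 = 1e-5) {
  m <- length(labf_a)
  logw <- c(0)          # H0: the empty configuration
  hyp <- c("H0")
  for (i in seq_len(m)) {
    logw <- c(logw, log(p1) + labf_a[i]); hyp <- c(hyp, "H1")
    logw <- c(logw, log(p2) + labf_b[i]); hyp <- c(hyp, "H2")
    logw <- c(logw, log(p12) + labf_a[i] + labf_b[i]); hyp <- c(hyp, "H4")
    for (j in seq_len(m)) {
      if (i != j) {
        logw <- c(logw, log(p1) + log(p2) + labf_a[i] + labf_b[j])
        hyp <- c(hyp, "H3")
      }
    }
  }
  w <- exp(logw - max(logw))
  totals <- vapply(c("H0", "H1", "H2", "H3", "H4"),
                   function(h) sum(w[hyp == h]), numeric(1))
  unname(totals / sum(totals))
}

# Greedy tagging oracle: a direct re-execution of the stated rule with
# explicit set bookkeeping.
greedy_tag_oracle <- function(r2, pvals, pos, threshold) {
  m <- nrow(r2)
  unassigned <- seq_len(m)
  loci <- list()
  while (length(unassigned)) {
    best <- unassigned[order(pvals[unassigned], pos[unassigned])][1]
    members <- unassigned[r2[best, unassigned] >= threshold]
    members <- sort(unique(c(best, members)))
    loci[[as.character(best)]] <- members
    unassigned <- setdiff(unassigned, members)
  }
  loci
}

# All-pairs interval containment (closed intervals, matching chromosome).
map_snps_oracle <- function(snps, regions) {
  lapply(seq_len(nrow(snps)), function(i) {
    hits <- character(0)
    for (j in seq_len(nrow(regions))) {
      if (snps$chrom[i] == regions$chrom[j] &&
          snps$pos[i] >= regions$start[j] &&
          snps$pos[i] <= regions$end[j]) {
        hits <- c(hits, regions$gene_id[j])
      }
    }
    hits
  })
}

# Closed-form weighted least squares of y on (1, x) with weights w:
# explicit 2x2 normal equations.
wls_oracle <- function(x, y, w) {
  s0 <- sum(w); s1 <- sum(w * x); s2 <- sum(w * x^2)
  t0 <- sum(w * y); t1 <- sum(w * x * y)
  det <- s0 * s2 - s1^2
  c(intercept = (s2 * t0 - s1 * t1) / det,
    slope = (s0 * t1 - s1 * t0) / det)
}

# BH step-up oracle: sort, scale, enforce monotonicity from the top.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  scaled <- p[ord] * n / seq_len(n)
  q <- rev(cummin(rev(scaled)))
  out <- numeric(n)
  out[ord] <- pmin(q, 1)
  out
}
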