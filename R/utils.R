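# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic generators route
# through this so they are pure functions of their arguments.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows or
# a <= b (caller treats that as a zero probability).
logdiffexp <- function(a, b) {
  if (!is.finite(a) || a <= b) return(-Inf)
  a + log1p(-exp(b - a))
}

# Smallest p-value retained; values below are clamped (never zero) so that
# downstream log/FDR arithmetic stays finite.
.P_FLOOR <- 1e-300

clamp_p <- function(p) pmin(pmax(p, .P_FLOOR), 1)

# Chromosome sort key: numeric chromosomes first in numeric order, then
# X, Y, MT, then anything else alphabetically.
chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  rank <- ifelse(!is.na(num), num,
    ifelse(chrom == "X", 100,
      ifelse(chrom == "Y", 101,
        ifelse(chrom %in% c("M", "MT"), 102, 103))))
  # stable within the "other" bucket
  rank + match(chrom, sort(unique(chrom))) * 1e-6
}

normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# Canonical variant key: alleles order-free so swapped records match.
canonical_key <- function(chrom, pos, a1, a2) {
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  paste(chrom, pos, lo, hi, sep = ":")
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$effect_allele, x$other_allele, sep = ":")
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) {
  vapply(strsplit(a, ""), function(ch) {
    paste(rev(unname(DNA_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

is_palindromic <- function(a1, a2) {
  single <- nchar(a1) == 1L & nchar(a2) == 1L
  comp <- unname(DNA_COMPLEMENT[a1])
  single & !is.na(comp) & comp == a2
}
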