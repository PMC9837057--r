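# Permutation test for enrichment of significant variants in target gene
# regions versus random same-length regions on the same chromosomes.

#' Read a two-column chromosome-sizes file
#'
#' Standard `chrom.sizes` format: name and length, tab-separated, no
#' header.
#'
#' @param path file path.
#' @return Data frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = c("character", "numeric"))
  data.frame(chrom = normalize_chrom(raw[[1]]), length = raw[[2]],
             stringsAsFactors = FALSE)
}

#' Region enrichment of significant variants by permutation
#'
#' Tests whether variants significant at `p_threshold` fall inside the
#' target regions more often than inside randomly placed regions of the
#' same lengths on the same chromosomes.  Each permutation redraws every
#' target region at a uniform random start on its own chromosome (clamped
#' to fit; overlap among drawn regions is permitted) and recounts; a
#' variant inside several drawn regions counts once.  The p-value is
#' add-one corrected, `(1 + #\{null >= observed\}) / (1 + B)`, so it is
#' never zero.
#'
#' @param snps a [sumstats] object.
#' @param target a [build_regions()] data frame.
#' @param genome chromosome-length table (`chrom`, `length`), covering
#'   every target region's chromosome.
#' @param p_threshold significance threshold for counting a variant.
#' @param B number of permutations (>= 1).
#' @param seed integer seed; the test is deterministic given
#'   (inputs, B, seed).
#' @param unit counting unit: `"variant"` (default) or `"locus"`, which
#'   collapses significant variants onto tagging loci first.
#' @param ld `ld_matrix` over the significant variants, required for
#'   `unit = "locus"`.
#' @param tag_r2 tagging threshold for the locus unit (default 0.2).
#' @return List of class `enrichment_result`: `observed_count`,
#'   `observed_prop` (fraction of significant units in targets),
#'   `null_counts` (length `B`), `empirical_p`, `B`, `seed`.
#' @export
region_enrichment <- function(snps, target, genome, p_threshold = 5e-8,
                              B = 1000, seed = 1,
                              unit = c("variant", "locus"), ld = NULL,
                              tag_r2 = 0.2) {
  unit <- match.arg(unit)
  stopifnot(B >= 1)
  glen <- setNames(genome$length, normalize_chrom(genome$chrom))
  missing_chr <- setdiff(unique(target$chrom), names(glen))
  if (length(missing_chr)) {
    stop("genome table lacks chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  len <- target$end - target$start + 1
  if (any(len > glen[target$chrom])) {
    stop("target region longer than its chromosome")
  }

  sig <- snps[snps$pval < p_threshold, , drop = FALSE]
  if (unit == "locus" && nrow(sig) > 1) {
    if (is.null(ld)) stop("unit = 'locus' requires an ld matrix")
    keys <- variant_key(sig)
    tags <- names(greedy_tag(ld[keys, keys, drop = FALSE],
                             priority = sig$pval, threshold = tag_r2,
                             pos = sig$pos))
    sig <- sig[keys %in% tags, , drop = FALSE]
  }
  n_sig <- nrow(sig)

  count_in <- function(starts, ends, chroms) {
    total <- 0L
    for (ch in unique(chroms)) {
      p <- sig$pos[sig$chrom == ch]
      if (!length(p)) next
      idx <- which(chroms == ch)
      inside <- rep(FALSE, length(p))
      for (k in idx) {
        inside <- inside | (p >= starts[k] & p <= ends[k])
      }
      total <- total + sum(inside)
    }
    total
  }

  observed <- count_in(target$start, target$end, target$chrom)
  null_counts <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      max_start <- glen[target$chrom] - len + 1
      starts <- floor(runif(length(len), 1, max_start + 1))
      starts <- pmin(starts, max_start)  # guard the open upper bound
      count_in(starts, starts + len - 1, target$chrom)
    }, numeric(1))
  })
  structure(
    list(observed_count = observed,
         observed_prop = if (n_sig > 0) observed / n_sig else NA_real_,
         n_significant = n_sig,
         null_counts = null_counts,
         empirical_p = (1 + sum(null_counts >= observed)) / (1 + B),
         B = B, seed = seed, unit = unit),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Region enrichment: %d of %d significant %ss in targets (prop %.3f)\n",
    x$observed_count, x$n_significant, x$unit,
    x$observed_prop %||% NA_real_))
  cat(sprintf("Empirical p = %.4g over B = %d permutations (seed %d)\n",
              x$empirical_p, x$B, x$seed))
  invisible(x)
}
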