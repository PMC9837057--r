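# Gene regions: strand-aware TSS extraction, flanked region construction,
# variant-to-region assignment, and trait-selection filters.

#' Load gene annotations with strand-aware transcription start sites
#'
#' Reads BED6 (0-based half-open; converted to 1-based at this boundary)
#' or minimal GTF gene lines (1-based closed).  The TSS is the feature
#' start for "+" strand genes and the feature end for "-" strand genes.
#' Rows with an unknown strand symbol are rejected and counted.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gtf"`.
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `tss`
#'   and an attribute `load_report`.
#' @export
load_gene_annotations <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    raw <- read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character")
    if (ncol(raw) < 6) stop("BED6 input requires 6 columns")
    out <- data.frame(
      gene_id = raw[[4]],
      chrom = normalize_chrom(raw[[1]]),
      strand = raw[[6]],
      start1 = as.numeric(raw[[2]]) + 1,  # 0-based -> 1-based
      end1 = as.numeric(raw[[3]]),
      stringsAsFactors = FALSE)
  } else {
    raw <- read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                      colClasses = "character")
    if (ncol(raw) < 9) stop("GTF input requires 9 columns")
    raw <- raw[raw[[3]] == "gene", , drop = FALSE]
    gene_id <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", raw[[9]])
    out <- data.frame(
      gene_id = gene_id,
      chrom = normalize_chrom(raw[[1]]),
      strand = raw[[7]],
      start1 = as.numeric(raw[[4]]),
      end1 = as.numeric(raw[[5]]),
      stringsAsFactors = FALSE)
  }
  ok <- out$strand %in% c("+", "-")
  report <- c(n_input = nrow(out), bad_strand = sum(!ok), n_kept = sum(ok))
  out <- out[ok, , drop = FALSE]
  out$tss <- ifelse(out$strand == "+", out$start1, out$end1)
  out <- out[, c("gene_id", "chrom", "strand", "tss")]
  rownames(out) <- NULL
  structure(out, load_report = report)
}

#' Build flanked gene regions around transcription start sites
#'
#' Each gene's region is the closed 1-based interval
#' `[max(1, tss - flank), tss + flank]`; the default 1 Mb flank is the
#' conventional cis window around a gene's TSS.
#'
#' @param genes data frame with `gene_id`, `chrom`, `strand`, `tss`
#'   (as from [load_gene_annotations()]).
#' @param flank flank size in bases (default 1,000,000).
#' @return Data frame of class `gene_regions` with added `start`, `end`,
#'   `flank` columns.
#' @export
build_regions <- function(genes, flank = 1e6) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)),
            flank >= 0, all(genes$tss >= 1))
  out <- genes
  out$start <- pmax(1, out$tss - flank)
  out$end <- out$tss + flank
  out$flank <- flank
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_regions", "data.frame")
  out
}

#' Map variants into gene regions
#'
#' Assigns each variant the gene regions containing it, by closed-interval
#' containment on the matching chromosome, using an interval index.  A
#' variant may map to several overlapping regions.
#'
#' @param table a [sumstats] object (or data frame with `chrom`, `pos`).
#' @param regions a [build_regions()] data frame.
#' @return A list, one character vector of `gene_id`s per variant (in
#'   `table` row order); empty vector where a variant maps nowhere.
#' @export
map_snps_to_regions <- function(table, regions) {
  res <- rep(list(character(0)), nrow(table))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    si <- which(table$chrom == ch)
    if (!length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = table$pos[si], width = 1L),
      IRanges::IRanges(start = regions$start[ri], end = regions$end[ri]))
    if (!length(hits)) next
    by_query <- split(regions$gene_id[ri][S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits))
    for (q in names(by_query)) {
      res[[si[as.integer(q)]]] <- unname(by_query[[q]])
    }
  }
  res
}

# TRUE for variants mapping into at least one region.
snp_in_regions <- function(table, regions) {
  lengths(map_snps_to_regions(table, regions)) > 0
}

#' Filter binary traits on per-sex case counts and prevalence difference
#'
#' Binary traits are excluded when either sex has fewer than `min_cases`
#' cases, or when the sexes show no material difference in prevalence.
#' The prevalence rule is pluggable; the default keeps a trait when
#' `|prev_male - prev_female| / max(prev) > 0.02`.  Quantitative traits
#' pass vacuously.  Binary traits with missing case counts are excluded
#' with reason `"incomplete_metadata"`.
#'
#' @param meta data frame with columns `trait_id`, `trait_type`,
#'   `n_male`, `n_female`, `n_cases_male`, `n_cases_female`.
#' @param min_cases minimum per-sex case count (default 300).
#' @param prevalence_predicate function of `(prev_male, prev_female)`
#'   returning `TRUE` when the trait shows a sex difference in prevalence.
#' @return Data frame with `trait_id`, `kept`, `reason` (`""` when kept).
#' @export
filter_traits <- function(meta, min_cases = 300,
                          prevalence_predicate = function(pm, pf) {
                            abs(pm - pf) / pmax(pm, pf) > 0.02
                          }) {
  out <- data.frame(trait_id = meta$trait_id,
                    kept = TRUE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    if (meta$trait_type[i] != "binary") next
    cm <- meta$n_cases_male[i]
    cf <- meta$n_cases_female[i]
    if (is.na(cm) || is.na(cf)) {
      out$kept[i] <- FALSE
      out$reason[i] <- "incomplete_metadata"
    } else if (min(cm, cf) < min_cases) {
      out$kept[i] <- FALSE
      out$reason[i] <- "case_count"
    } else if (!isTRUE(prevalence_predicate(cm / meta$n_male[i],
                                            cf / meta$n_female[i]))) {
      out$kept[i] <- FALSE
      out$reason[i] <- "no_sex_difference_in_prevalence"
    }
  }
  out
}

#' Select traits with above-median heritability
#'
#' Retains traits whose sex-combined heritability estimate is strictly
#' greater than the sample median across all traits; strictness makes the
#' behavior deterministic on ties.
#'
#' @param h2 named numeric vector of per-trait heritability estimates.
#' @return Character vector of retained trait names.
#' @export
select_heritable_traits <- function(h2) {
  stopifnot(length(h2) >= 2, !is.null(names(h2)))
  names(h2)[h2 > median(h2)]
}
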