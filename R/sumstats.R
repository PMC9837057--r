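# Summary-statistics tables: construction, validation, reading, writing.

.SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                    "beta", "se", "pval", "maf", "n", "n_cases")

#' Construct a validated summary-statistics table
#'
#' A `sumstats` object is a data frame of per-variant association records
#' for one trait in one population stratum (sex-combined, male, or female).
#' Rows violating the record invariants (`se > 0`, `pval` in (0, 1], `maf`
#' in (0, 0.5], `pos >= 1`, valid distinct alleles, `n >= 1`, and for binary
#' traits `0 < n_cases < n`) are dropped, never fatal; the counts per
#' rejection reason are attached as the load report.  Rows are sorted by
#' (chromosome, position) and variant keys are made unique.
#'
#' @param x data frame with columns `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `maf`, `n`, and optionally
#'   `rsid` and `n_cases`.
#' @param trait_id trait identifier.
#' @param stratum one of `"combined"`, `"male"`, `"female"`.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return A data frame of class `sumstats` with attributes `trait_id`,
#'   `stratum`, `trait_type` and `load_report`.
#' @examples
#' df <- data.frame(chrom = "1", pos = c(300, 100), effect_allele = "A",
#'                  other_allele = "G", beta = c(0.1, -0.2), se = 0.05,
#'                  pval = c(0.04, 1e-4), maf = 0.3, n = 1000)
#' s <- sumstats(df, trait_id = "trait1")
#' load_report(s)
#' @export
sumstats <- function(x, trait_id = "trait", stratum = "combined",
                     trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  stratum <- match.arg(stratum, c("combined", "male", "female"))
  x <- as.data.frame(x, stringsAsFactors = FALSE)

  required <- setdiff(.SUMSTATS_COLS, c("rsid", "n_cases"))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"rsid" %in% names(x)) x$rsid <- rep(NA_character_, nrow(x))
  if (!"n_cases" %in% names(x)) x$n_cases <- rep(NA_real_, nrow(x))

  x$chrom <- normalize_chrom(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "beta", "se", "pval", "maf", "n", "n_cases")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }

  report <- c(n_input = nrow(x))
  drop_reason <- function(bad, reason) {
    bad[is.na(bad)] <- TRUE
    report[reason] <<- sum(bad & keep)
    keep <<- keep & !bad
  }
  keep <- rep(TRUE, nrow(x))
  drop_reason(!(x$pos >= 1), "bad_pos")
  ok_allele <- grepl("^[ACGT]+$", x$effect_allele) &
    grepl("^[ACGT]+$", x$other_allele) &
    x$effect_allele != x$other_allele
  drop_reason(!ok_allele, "bad_allele")
  drop_reason(!(x$se > 0), "bad_se")
  drop_reason(!(x$pval > 0 & x$pval <= 1), "bad_pval")
  drop_reason(!(x$maf > 0 & x$maf <= 0.5), "bad_maf")
  drop_reason(!(x$n >= 1), "bad_n")
  if (trait_type == "binary") {
    drop_reason(!(x$n_cases > 0 & x$n_cases < x$n), "bad_n_cases")
  }
  x <- x[keep, , drop = FALSE]

  key <- variant_key(x)
  dup <- duplicated(key)
  report["duplicate_key"] <- sum(dup)
  x <- x[!dup, , drop = FALSE]

  ord <- order(chrom_rank(x$chrom), x$pos)
  x <- x[ord, .SUMSTATS_COLS, drop = FALSE]
  rownames(x) <- NULL
  report["n_kept"] <- nrow(x)

  structure(x,
    class = c("sumstats", "data.frame"),
    trait_id = trait_id, stratum = stratum, trait_type = trait_type,
    load_report = report)
}

#' @rdname sumstats
#' @param s a `sumstats` object.
#' @export
load_report <- function(s) attr(s, "load_report")

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("Summary statistics: trait '%s', stratum %s (%s), %d variants\n",
              attr(x, "trait_id"), attr(x, "stratum"),
              attr(x, "trait_type"), nrow(x)))
  rep <- load_report(x)
  rejected <- rep[!names(rep) %in% c("n_input", "n_kept")]
  rejected <- rejected[rejected > 0]
  if (length(rejected)) {
    cat("Rejected rows:",
        paste(sprintf("%s=%d", names(rejected), rejected), collapse = ", "),
        "\n")
  }
  print(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a summary-statistics file
#'
#' Reads a tab-separated summary-statistics file with columns `variant_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`,
#' `maf`, `n` and optionally `n_cases`.  Other column names are accepted
#' via `dialect`, a named character vector mapping the standard names to
#' the file's column names.  Malformed rows are dropped and counted in the
#' load report rather than aborting the load.
#'
#' @param path file path.
#' @param dialect named character vector, e.g.
#'   `c(pval = "p_value", chrom = "chromosome")`.
#' @inheritParams sumstats
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, dialect = NULL, trait_id = NULL,
                          stratum = "combined",
                          trait_type = c("quantitative", "binary")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
  for (std in names(dialect)) {
    if (!dialect[[std]] %in% names(raw)) {
      stop("dialect column '", dialect[[std]], "' not present in ", path)
    }
    names(raw)[names(raw) == dialect[[std]]] <- std
  }
  if ("variant_id" %in% names(raw) && !"rsid" %in% names(raw)) {
    names(raw)[names(raw) == "variant_id"] <- "rsid"
  }
  required <- c("chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval", "maf", "n")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  sumstats(raw, trait_id = trait_id %||% basename(path),
           stratum = stratum, trait_type = trait_type)
}

#' Write a summary-statistics table
#'
#' Writes a tab-separated file that [read_sumstats()] reads back
#' field-for-field identically; numeric fields are serialized at 17
#' significant digits so the round trip is lossless at double precision.
#'
#' @param table a [sumstats] object.
#' @param path output file path.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  out <- as.data.frame(table)
  names(out)[names(out) == "rsid"] <- "variant_id"
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  for (col in c("pos", "beta", "se", "pval", "maf", "n", "n_cases")) {
    out[[col]] <- fmt(out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
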