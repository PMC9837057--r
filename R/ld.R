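# Linkage disequilibrium: pairwise r-squared, greedy tagging/clumping,
# independent-SNP counting, and LD-matrix file I/O.

#' Pairwise r-squared from a genotype panel
#'
#' Composite LD: `r2[i, j]` is the squared Pearson correlation of the two
#' dosage columns.  Symmetric, unit diagonal, entries in \[0, 1\].
#'
#' @param panel a [simulate_genotypes()] panel or a dosage matrix with
#'   variant keys as column names.
#' @return A symmetric matrix of class `ld_matrix`, dimnames set to the
#'   variant keys.
#' @export
ld_from_genotypes <- function(panel) {
  G <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  keys <- if (inherits(panel, "genotype_panel")) {
    variant_key(panel$keys)
  } else {
    colnames(G) %||% as.character(seq_len(ncol(G)))
  }
  v <- apply(G, 2, var)
  if (any(v < 1e-12)) {
    stop("zero dosage variance for variant(s): ",
         paste(keys[v < 1e-12], collapse = ", "))
  }
  r2 <- cor(G)^2
  dimnames(r2) <- list(keys, keys)
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Greedy tagging of variants into LD loci
#'
#' Iteratively selects the unassigned variant with the best priority
#' (smallest p-value; ties broken by genomic position, then key), makes it
#' the tag of a new locus, and assigns to that locus every unassigned
#' variant with `r2 >= threshold` against the tag.  Repeats until all
#' variants are assigned: the output is a partition.  With the default
#' threshold 0.2 this reproduces the convention of collapsing correlated
#' association signals onto tagging loci; at 0.001 it is instrument
#' clumping.
#'
#' @param ld an `ld_matrix` (or plain symmetric matrix with dimnames).
#' @param priority per-variant priorities (typically p-values), aligned
#'   with the matrix rows; `NULL` means position (row) order.
#' @param threshold r-squared at or above which a variant joins the
#'   current tag's locus.
#' @param pos optional per-variant genomic positions used for
#'   tie-breaking; row order is used when absent.
#' @return Named list mapping each tag's key to the character vector of
#'   member keys (tag included).  `attr(, "assignment")` gives each
#'   variant's tag.
#' @export
greedy_tag <- function(ld, priority = NULL, threshold = 0.2, pos = NULL) {
  keys <- rownames(ld) %||% as.character(seq_len(nrow(ld)))
  m <- nrow(ld)
  priority <- priority %||% seq_len(m)
  pos <- pos %||% seq_len(m)
  stopifnot(length(priority) == m, length(pos) == m)
  ord <- order(priority, pos, keys)
  assigned <- rep(NA_character_, m)
  loci <- list()
  for (i in ord) {
    if (!is.na(assigned[i])) next
    members <- which(is.na(assigned) & ld[i, ] >= threshold)
    members <- union(i, members)
    assigned[members] <- keys[i]
    loci[[keys[i]]] <- keys[members]
  }
  names(assigned) <- keys
  structure(loci, assignment = assigned)
}

#' Count independent variants in a region
#'
#' Number of loci produced by [greedy_tag()] at the given r-squared
#' threshold (default 0.8); used as the Bonferroni denominator of the
#' two-step eQTL multiple-testing correction.
#'
#' @inheritParams greedy_tag
#' @return Integer count of independent loci.
#' @export
count_independent <- function(ld, threshold = 0.8, priority = NULL,
                              pos = NULL) {
  length(greedy_tag(ld, priority = priority, threshold = threshold,
                    pos = pos))
}

#' Read or write an LD matrix file
#'
#' TSV with a header row and first column of variant keys and a symmetric
#' numeric body; symmetry is checked on load to tolerance `1e-8`.
#'
#' @param path file path.
#' @return For `read_ld_matrix`, an `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8) {
    stop("LD matrix file is not symmetric (tolerance 1e-8): ", path)
  }
  m <- (m + t(m)) / 2
  class(m) <- c("ld_matrix", class(m))
  m
}

#' @rdname read_ld_matrix
#' @param ld the matrix to write.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- data.frame(key = rownames(ld), ld, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
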