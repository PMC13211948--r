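# Readers and writers for the tab-delimited summary-statistics dialect:
# columns `variant_id chrom pos effect_allele other_allele eaf beta se
# pvalue n` (1-based positions, as in GWAS-SSF); meta-analyzed tables add
# `n_studies q_stat q_p`.  Extra columns are tolerated; gzip is transparent.

SUMMARY_STATS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                           "other_allele", "eaf", "beta", "se", "pvalue",
                           "n")

#' Read a summary-statistics table
#'
#' Validates each row; rows failing the invariants (non-finite beta,
#' non-positive or non-finite se, p outside (0, 1], eaf outside (0, 1),
#' position < 1, bad or identical alleles) are quarantined with a reason and
#' returned in the `rejects` attribute (and optionally written to
#' `rejects_path`).
#'
#' @param path TSV file, optionally gzipped.
#' @param rejects_path optional path for the quarantined rows.
#' @return a `summary_stats` data frame (an `estimable` column is added if
#'   absent); attribute `rejects` holds the quarantined rows.
#' @export
read_summary_stats <- function(path, rejects_path = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(SUMMARY_STATS_COLUMNS, names(x))
  if (length(miss) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }
  est <- x$estimable %||% rep(TRUE, nrow(x))
  flag(!is.finite(x$beta), "non-finite beta")
  flag(est & (!is.finite(x$se) | x$se <= 0), "non-positive se")
  flag(est & (!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1),
       "p outside (0,1]")
  flag(!is.finite(x$eaf) | x$eaf <= 0 | x$eaf >= 1, "eaf outside (0,1)")
  flag(!is.finite(x$pos) | x$pos < 1, "position < 1")
  alleles_ok <- x$effect_allele %in% c("A", "C", "G", "T") &
    x$other_allele %in% c("A", "C", "G", "T") &
    x$effect_allele != x$other_allele
  flag(!alleles_ok, "bad alleles")
  rejects <- cbind(x[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  x <- x[is.na(reason), , drop = FALSE]
  if (nrow(x) == 0) stop("no valid rows in summary-statistics file")
  if (is.null(x$estimable)) x$estimable <- TRUE
  if (!is.null(rejects_path) && nrow(rejects) > 0)
    write.table(rejects, rejects_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  rownames(x) <- NULL
  attr(x, "rejects") <- rejects
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Write a summary-statistics table
#'
#' @param x `summary_stats` data frame.
#' @param path output path; a `.gz` suffix compresses.
#' @export
write_summary_stats <- function(x, path) {
  miss <- setdiff(SUMMARY_STATS_COLUMNS, names(x))
  if (length(miss) > 0)
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
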