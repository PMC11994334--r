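#' Per-read methylation fraction
#'
#' The fraction of methylated CpGs among the CpGs observed on one read
#' (mC/C). Reads without CpGs carry no methylation information: they yield
#' `NA`, never 0.
#'
#' @param n_cpg integer vector of CpG counts per read.
#' @param n_meth integer vector of methylated-CpG counts per read.
#' @return Numeric vector in \[0, 1\] with `NA` where `n_cpg == 0`.
#' @examples
#' per_read_fraction(c(4, 3, 0), c(2, 0, 0))  # 0.5, 0, NA
#' @export
per_read_fraction <- function(n_cpg, n_meth) {
  if (any(n_meth > n_cpg, na.rm = TRUE)) {
    stop("n_meth must not exceed n_cpg", call. = FALSE)
  }
  ifelse(n_cpg >= 1, n_meth / n_cpg, NA_real_)
}

#' Read-level methylation profile of a sample
#'
#' Summarizes a sample by its read-level methylation trichotomy - the
#' fractions of CpG-containing reads with per-read methylation exactly 0
#' (`f_zero`), strictly between 0 and 1 (`f_partial`), and exactly 1
#' (`f_full`) - together with the CpG-count histogram over all reads
#' (fractions of reads carrying 0, 1, 2, 3, or more than 3 CpGs).
#'
#' The trichotomy is the discriminating signature between blastocyst DNA
#' (demethylated; large `f_zero`) and somatic contaminants such as cumulus
#' cells (hypermethylated; large `f_full`), and is therefore the basis of
#' the decontamination filter.
#'
#' @param reads a [read_set()] with at least one CpG-containing read.
#' @return An object of class `methylation_profile`: a list with
#'   `n_total_reads`, `n_cpg_containing`, `cpg_histogram` (named fractions
#'   for "0","1","2","3",">3"), `f_zero`, `f_partial`, `f_full` and
#'   `sample_id`.
#' @export
profile_sample <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  n_total <- nrow(reads)
  if (n_total == 0L) stop("empty read set", call. = FALSE)
  n_cpg <- reads$n_cpg
  n_meth <- reads$n_meth
  cpg_class <- cut(n_cpg, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, Inf),
                   labels = c("0", "1", "2", "3", ">3"))
  cpg_histogram <- as.numeric(table(cpg_class)) / n_total
  names(cpg_histogram) <- c("0", "1", "2", "3", ">3")
  informative <- n_cpg >= 1
  n_inf <- sum(informative)
  if (n_inf == 0L) {
    stop("no CpG-containing reads; methylation distribution undefined",
         call. = FALSE)
  }
  frac <- n_meth[informative] / n_cpg[informative]
  structure(list(
    n_total_reads = n_total,
    n_cpg_containing = n_inf,
    cpg_histogram = cpg_histogram,
    f_zero = sum(frac == 0) / n_inf,
    f_partial = sum(frac > 0 & frac < 1) / n_inf,
    f_full = sum(frac == 1) / n_inf,
    sample_id = attr(reads, "sample_id")
  ), class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat(sprintf("<methylation_profile> sample '%s'\n", x$sample_id))
  cat(sprintf("  reads: %d total, %d CpG-containing (%.1f%%)\n",
              x$n_total_reads, x$n_cpg_containing,
              100 * x$n_cpg_containing / x$n_total_reads))
  cat(sprintf("  trichotomy of CpG-containing reads: 0%%: %.3f  (0,1): %.3f  100%%: %.3f\n",
              x$f_zero, x$f_partial, x$f_full))
  cat("  CpG-count histogram:",
      paste(sprintf("%s: %.3f", names(x$cpg_histogram), x$cpg_histogram),
            collapse = "  "), "\n")
  invisible(x)
}

#' Enrichment factor between two cell types
#'
#' The expected enrichment of target over contaminant DNA achieved by
#' selecting unmethylated reads: the ratio of the two cell types'
#' unmethylated-read fractions. For blastocyst (`f_zero` 0.47) over cumulus
#' cells (0.12) this is ~3.9, reported as a factor of approximately 4.
#'
#' @param f_zero_target unmethylated-read fraction of the cell type to be
#'   enriched, in (0, 1\].
#' @param f_zero_contaminant unmethylated-read fraction of the contaminant,
#'   in (0, 1\].
#' @return The ratio `f_zero_target / f_zero_contaminant`.
#' @examples
#' enrichment_factor(0.47, 0.12)  # ~ 4
#' enrichment_factor(0.47, 0.38)  # ~ 1.2
#' @export
enrichment_factor <- function(f_zero_target, f_zero_contaminant) {
  if (f_zero_contaminant <= 0) {
    stop("contaminant unmethylated-read fraction must be positive; ",
         "enrichment factor undefined", call. = FALSE)
  }
  if (f_zero_target <= 0 || f_zero_target > 1 || f_zero_contaminant > 1) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  f_zero_target / f_zero_contaminant
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.5 -> 1), the convention used for
#' reported percentages and enrichment factors, as opposed to R's
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # pre-round far below the reporting precision so decimal ties that are
  # not binary-representable (0.165 * 100 = 16.4999...) still round up
  sign(x) * floor(round(abs(x) * p, 9) + 0.5) / p
}
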