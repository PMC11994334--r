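#' Decontamination filter policy
#'
#' The selection rule that defines the decontamination operation: retain
#' reads carrying at least `min_cpg` CpGs whose per-read methylation does
#' not exceed `max_fraction`. The defaults (`min_cpg = 2`,
#' `max_fraction = 0`) implement the published rule - reads with more than
#' one CpG and average methylation exactly zero - which exploits the global
#' demethylation wave: blastocyst DNA is far more likely than somatic
#' contaminant DNA to produce fully unmethylated multi-CpG reads.
#'
#' Note the deliberate asymmetry with [profile_sample()]: read-level
#' profiling (and the enrichment-factor arithmetic built on it) counts all
#' reads with >= 1 CpG, whereas the filter demands >= 2 by default. Both
#' conventions are honored as stated; `min_cpg = 1` reproduces the
#' profiling universe.
#'
#' @param min_cpg minimum CpG count per retained read (>= 1).
#' @param max_fraction inclusive per-read methylation ceiling in \[0, 1).
#'   0 keeps only fully unmethylated reads; values such as 0.99 select
#'   hypomethylated reads more loosely.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(min_cpg = 2L, max_fraction = 0) {
  if (!is.numeric(min_cpg) || length(min_cpg) != 1L || min_cpg < 1) {
    stop("'min_cpg' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(max_fraction) || length(max_fraction) != 1L ||
      max_fraction < 0 || max_fraction >= 1) {
    stop("'max_fraction' must lie in [0, 1)", call. = FALSE)
  }
  structure(list(min_cpg = as.integer(min_cpg),
                 max_fraction = as.numeric(max_fraction)),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf("<filter_policy> keep reads with n_cpg >= %d and methylation <= %g\n",
              x$min_cpg, x$max_fraction))
  invisible(x)
}

#' Decontaminate a read set by unmethylated-read selection
#'
#' Applies a [filter_policy()] to a read set: keeps records with
#' `n_cpg >= min_cpg` whose per-read methylation fraction is at most
#' `max_fraction`, preserving the original record order. The methylation
#' comparison is exact in integer arithmetic (`n_meth <= max_fraction *
#' n_cpg`, and `n_meth == 0` when `max_fraction` is 0), so no read is kept
#' or dropped by floating-point accident.
#'
#' An empty result is not an error - downstream copy-number calling must
#' see it - but it is flagged: a warning is emitted and the attribute
#' `empty` is set. The retention fraction is stored in attribute
#' `retention`.
#'
#' @param reads a [read_set()].
#' @param policy a [filter_policy()]; defaults to the published rule.
#' @return The filtered [read_set()] with attributes `retention` (kept /
#'   input) and `empty` (logical).
#' @export
decontaminate <- function(reads, policy = filter_policy()) {
  stopifnot(inherits(reads, "read_set"), inherits(policy, "filter_policy"))
  # exact rational comparison: n_meth/n_cpg <= max_fraction
  # <=> n_meth <= max_fraction * n_cpg, with integer n_meth
  keep <- reads$n_cpg >= policy$min_cpg &
    (if (policy$max_fraction == 0) reads$n_meth == 0
     else reads$n_meth <= policy$max_fraction * reads$n_cpg)
  out <- subset_read_set(reads, which(keep))
  retention <- if (nrow(reads)) nrow(out) / nrow(reads) else NA_real_
  attr(out, "retention") <- retention
  attr(out, "empty") <- nrow(out) == 0L
  if (nrow(out) == 0L) {
    warning("decontamination removed every read; downstream calls will be undetermined",
            call. = FALSE)
  }
  out
}
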