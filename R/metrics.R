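#' Concordance table between SECM calls and TE-biopsy truth
#'
#' Joint classification counts of samples by the SECM call and the
#' trophectoderm-biopsy result: ploidy counts `n_ee` (both euploid),
#' `n_ea` (SECM euploid, TE aneuploid), `n_ae`, `n_aa`, and sex counts
#' `n_ff`, `n_fm` (SECM female, TE male), `n_mf`, `n_mm`.
#'
#' @param n_ee,n_ea,n_ae,n_aa ploidy 2x2 counts (>= 0).
#' @param n_ff,n_fm,n_mf,n_mm sex 2x2 counts (>= 0).
#' @return An object of class `concordance_table`.
#' @export
concordance_table <- function(n_ee = 0, n_ea = 0, n_ae = 0, n_aa = 0,
                              n_ff = 0, n_fm = 0, n_mf = 0, n_mm = 0) {
  counts <- c(n_ee = n_ee, n_ea = n_ea, n_ae = n_ae, n_aa = n_aa,
              n_ff = n_ff, n_fm = n_fm, n_mf = n_mf, n_mm = n_mm)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(as.list(counts), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("<concordance_table>\n")
  cat(sprintf("  ploidy: ee=%g ea=%g ae=%g aa=%g\n",
              x$n_ee, x$n_ea, x$n_ae, x$n_aa))
  cat(sprintf("  sex:    ff=%g fm=%g mf=%g mm=%g\n",
              x$n_ff, x$n_fm, x$n_mf, x$n_mm))
  invisible(x)
}

#' General concordance rate
#'
#' Fraction of samples concordant in ploidy between SECM and TE:
#' `(n_ee + n_aa) / (n_ee + n_ea + n_ae + n_aa)`.
#'
#' @param t a [concordance_table()].
#' @return Fraction in \[0, 1\].
#' @export
gcr <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  total <- t$n_ee + t$n_ea + t$n_ae + t$n_aa
  if (total <= 0) stop("GCR undefined: no classified samples", call. = FALSE)
  (t$n_ee + t$n_aa) / total
}

#' False-negative rate
#'
#' Among TE-aneuploid samples, the fraction called euploid by SECM:
#' `n_ea / (n_ea + n_aa)`.
#'
#' @param t a [concordance_table()].
#' @return Fraction in \[0, 1\].
#' @export
fnr <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  denom <- t$n_ea + t$n_aa
  if (denom <= 0) stop("FNR undefined: no TE-aneuploid samples", call. = FALSE)
  t$n_ea / denom
}

#' False-positive rate
#'
#' Among SECM-aneuploid-or-concordant-euploid samples, the fraction
#' called aneuploid by SECM but euploid by TE: `n_ae / (n_ae + n_ee)`.
#'
#' @param t a [concordance_table()].
#' @return Fraction in \[0, 1\].
#' @export
fpr <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  denom <- t$n_ae + t$n_ee
  if (denom <= 0) stop("FPR undefined: no TE-euploid samples with SECM calls",
                       call. = FALSE)
  t$n_ae / denom
}

#' Sex discordance rate
#'
#' Among TE-male samples, the fraction called female by SECM (the
#' signature of maternal contamination): `n_fm / (n_fm + n_mm)`.
#'
#' @param t a [concordance_table()].
#' @return Fraction in \[0, 1\].
#' @export
sdr <- function(t) {
  stopifnot(inherits(t, "concordance_table"))
  denom <- t$n_fm + t$n_mm
  if (denom <= 0) stop("SDR undefined: no TE-male samples", call. = FALSE)
  t$n_fm / denom
}

#' Sensitivity and specificity of aneuploidy detection
#'
#' Compares predicted against true karyotypes sample by sample. A truly
#' aneuploid sample counts as detected only when every truly aberrant
#' chromosome is called with the matching direction (chromosome and
#' loss/gain must both agree); a truly euploid sample counts as a false
#' positive when any autosome is called non-neutral.
#'
#' @param truth list of named character vectors giving each sample's true
#'   aberrations, e.g. `c(chr18 = "gain")`; an empty vector (or `NULL`
#'   entry) means euploid.
#' @param predicted list (same length/order) of predicted aberrations in
#'   the same form; `aberrations` fields of [call_karyotype()] /
#'   [integrated_call()] results can be passed directly.
#' @return List with `sensitivity`, `specificity` (either `NA` when its
#'   class is empty) and the counts `tp`, `fn`, `tn`, `fp`.
#' @export
sens_spec <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  as_ab <- function(x) {
    if (is.null(x) || length(x) == 0L) return(character(0))
    stats::setNames(as.character(x), names(x))
  }
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(truth)) {
    tr <- as_ab(truth[[i]])
    pr <- as_ab(predicted[[i]])
    if (length(tr) == 0L) {
      if (length(pr) == 0L) tn <- tn + 1L else fp <- fp + 1L
    } else {
      hit <- all(names(tr) %in% names(pr)) &&
        all(pr[names(tr)] == tr)
      if (hit) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Binomial proportion confidence interval (Wald, clipped)
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)` clipped to
#' \[0, 1\] - the form that reproduces the published intervals at
#' whole-percent rounding (e.g. 7/14 -> 24%-76%, 11/65 -> 8%-26%,
#' 2/5 -> 0%-83%).
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param conf confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, conf = 0.95) {
  if (n < 1) stop("CI undefined for n = 0", call. = FALSE)
  stopifnot(k >= 0, k <= n)
  p <- k / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(lower = max(0, p - half), upper = min(1, p + half))
}
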