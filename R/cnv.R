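#' Lowess GC-bias correction of bin counts
#'
#' Fits a robust lowess curve of count versus per-bin GC fraction
#' (span 0.3, 3 robustifying iterations) and divides each count by its
#' fitted value, rescaled so the mean count over usable bins is preserved.
#' Bins where the fit is non-positive are flagged unusable rather than
#' divided.
#'
#' @param counts per-bin counts from [bin_counts()] (numeric, with
#'   optional `usable` attribute).
#' @param bins the matching `bin_scheme`.
#' @param span lowess span.
#' @param iter lowess robustifying iterations.
#' @return Corrected counts, same shape as `counts`, with updated
#'   `usable` attribute.
#' @export
gc_correct <- function(counts, bins, span = 0.3, iter = 3L) {
  stopifnot(inherits(bins, "bin_scheme"), length(counts) == nrow(bins))
  usable <- attr(counts, "usable")
  if (is.null(usable)) usable <- !bins$blacklist
  if (sum(usable) < 20L) {
    stop("GC correction needs at least 20 usable bins", call. = FALSE)
  }
  lw <- stats::lowess(bins$gc[usable], counts[usable], f = span, iter = iter)
  fit <- stats::approx(lw$x, lw$y, xout = bins$gc, rule = 2, ties = mean)$y
  bad <- usable & fit <= 0
  usable <- usable & fit > 0
  if (!any(usable)) {
    warning("GC fit non-positive everywhere (near-empty counts); all bins flagged unusable",
            call. = FALSE)
    out <- numeric(length(counts))
    attr(out, "usable") <- usable
    return(out)
  }
  corrected <- as.numeric(counts)
  corrected[usable] <- counts[usable] * mean(fit[usable]) / fit[usable]
  # preserve the mean count over usable bins exactly
  m0 <- mean(counts[usable])
  m1 <- mean(corrected[usable])
  if (m1 > 0) corrected[usable] <- corrected[usable] * m0 / m1
  corrected[!usable] <- 0
  attr(corrected, "usable") <- usable
  if (any(bad)) {
    message(sprintf("gc_correct: %d bin(s) flagged unusable (non-positive fit)",
                    sum(bad)))
  }
  corrected
}

#' Normalize bin counts to a diploid reference
#'
#' Converts per-bin counts to copy-number values against a diploid
#' reference profile: `cn_i = 2 * (s_i / S) / (r_i / R)`, where `S` and
#' `R` are the sample and reference totals over usable autosomal bins.
#' Sex chromosomes are scaled by the same autosomal factor, so their
#' dosage (2 for XX-like, 1 for XY-like) is read directly off the result.
#' Bins with zero reference count are flagged unusable.
#'
#' @param sample_counts per-bin counts for the sample.
#' @param reference_counts per-bin counts for the diploid reference (same
#'   bin scheme).
#' @param bins the shared `bin_scheme`.
#' @return An object of class `cnv_profile`: data.frame with columns
#'   `chrom`, `start`, `end`, `cn`, `usable`, plus attributes
#'   `n_reads_used` and `low_coverage` (flag set when usable bins average
#'   fewer than one read).
#' @export
normalize_to_reference <- function(sample_counts, reference_counts, bins) {
  stopifnot(inherits(bins, "bin_scheme"),
            length(sample_counts) == nrow(bins),
            length(reference_counts) == nrow(bins))
  u_s <- attr(sample_counts, "usable")
  u_r <- attr(reference_counts, "usable")
  usable <- !bins$blacklist
  if (!is.null(u_s)) usable <- usable & u_s
  if (!is.null(u_r)) usable <- usable & u_r
  usable <- usable & reference_counts > 0
  auto <- is_autosome(bins$chrom)
  S <- sum(sample_counts[usable & auto])
  R <- sum(reference_counts[usable & auto])
  cn <- rep(NA_real_, nrow(bins))
  if (R <= 0) {
    # nothing to normalize against: an all-undefined profile, so the
    # karyotype caller reports the sample as too low-quality to call
    usable[] <- FALSE
  } else if (S > 0) {
    cn[usable] <- 2 * (sample_counts[usable] / S) /
      (reference_counts[usable] / R)
  }
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    cn = cn, usable = usable & !is.na(cn),
                    stringsAsFactors = FALSE)
  n_used <- sum(sample_counts[usable])
  structure(out,
            n_reads_used = n_used,
            low_coverage = n_used < sum(usable),
            class = c("cnv_profile", "data.frame"))
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d bins (%d usable), %.0f reads used%s\n",
              nrow(x), sum(x$usable), attr(x, "n_reads_used"),
              if (isTRUE(attr(x, "low_coverage"))) " [low coverage]" else ""))
  print(chromosome_summary(x))
  invisible(x)
}

#' @export
summary.cnv_profile <- function(object, ...) {
  chromosome_summary(object, ...)
}

#' Plot a copy-number profile
#'
#' Base-graphics line plot of per-bin copy number along the genome with
#' chromosome boundaries and the diploid baseline.
#'
#' @param x a `cnv_profile`.
#' @param thresholds optional [threshold_pair()] drawn as dashed lines.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cnv_profile <- function(x, thresholds = NULL, main = "CNV profile", ...) {
  df <- x[x$usable, , drop = FALSE]
  idx <- seq_len(nrow(df))
  graphics::plot(idx, df$cn, type = "p", pch = 16, cex = 0.3,
                 col = "grey40", xlab = "bin (genome order)",
                 ylab = "copy number", ylim = c(0, 4), main = main, ...)
  graphics::abline(h = 2, col = "steelblue")
  if (!is.null(thresholds)) {
    graphics::abline(h = c(thresholds$loss, thresholds$gain),
                     lty = 2, col = "firebrick")
  }
  bounds <- cumsum(table(factor(df$chrom, levels = unique(df$chrom))))
  graphics::abline(v = bounds + 0.5, col = "grey85")
  med <- tapply(df$cn, factor(df$chrom, levels = unique(df$chrom)),
                stats::median)
  centers <- bounds - diff(c(0, bounds)) / 2
  graphics::segments(c(0, bounds[-length(bounds)]) + 0.5, med,
                     bounds + 0.5, med, col = "firebrick", lwd = 2)
  graphics::mtext(sub("^chr", "", names(bounds)), side = 3, at = centers,
                  cex = 0.6, line = 0.1)
  invisible(x)
}

#' Per-chromosome copy-number summary
#'
#' Summarizes a copy-number profile per chromosome as the median of its
#' usable bin values - a robust whole-chromosome statistic standing in for
#' segmentation, adequate for the whole-chromosome aneuploidy endpoint.
#' Chromosomes with fewer than `min_bins` usable bins are undefined (`NA`).
#'
#' @param profile a `cnv_profile`.
#' @param min_bins minimum usable bins per chromosome.
#' @return Named numeric vector of per-chromosome copy numbers.
#' @export
chromosome_summary <- function(profile, min_bins = 5L) {
  stopifnot(inherits(profile, "cnv_profile"))
  chroms <- unique(profile$chrom)
  vapply(chroms, function(ch) {
    v <- profile$cn[profile$chrom == ch & profile$usable]
    v <- v[is.finite(v)]
    if (length(v) < min_bins) NA_real_ else stats::median(v)
  }, numeric(1))
}

#' Copy-number call thresholds
#'
#' A loss/gain threshold pair written `L&G` in the field's shorthand: a
#' chromosome is called a loss when its summary copy number is at or below
#' `loss` and a gain at or above `gain` (inclusive, so the printed boundary
#' values act as detection limits). The full-CNV pair is 1.5&2.5; the
#' mosaic-level pre-decontamination pair is 1.8&2.2.
#'
#' @param loss loss threshold, in (0, 2).
#' @param gain gain threshold, > 2.
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(loss = 1.5, gain = 2.5) {
  if (!(loss > 0 && loss < 2 && gain > 2)) {
    stop("need 0 < loss < 2 < gain", call. = FALSE)
  }
  structure(list(loss = loss, gain = gain), class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> %g&%g\n", x$loss, x$gain))
  invisible(x)
}

#' Call a karyotype from a copy-number profile
#'
#' Applies a [threshold_pair()] to the per-chromosome summaries: each
#' autosome is called `loss` (summary <= loss), `gain` (summary >= gain)
#' or `neutral`; chromosomes without a defined summary are `undetermined`.
#' Sex is `XY` when the chrY summary is at least 0.5 with chrX in
#' \[0.5, 1.5\], `XX` when chrY is below 0.5 with chrX at least 1.5, and
#' `undetermined` otherwise. The sample is `aneuploid` when at least one
#' autosome is non-neutral or the sex-chromosome dosage fits neither
#' pattern despite defined summaries.
#'
#' @param profile a `cnv_profile`.
#' @param thresholds a [threshold_pair()].
#' @param min_bins minimum usable bins per chromosome (see
#'   [chromosome_summary()]).
#' @param min_autosomes minimum number of callable autosomes; below this
#'   the sample is refused as low-quality. The default 20 suits a full
#'   human genome; lower it for reduced test genomes.
#' @return An object of class `karyotype_call`: list with `summary`
#'   (named copy numbers), `state` (named states), `sex`, `ploidy`,
#'   `aberrations` (non-neutral autosomes), `thresholds`, and flags
#'   carried over from the profile.
#' @export
call_karyotype <- function(profile, thresholds = threshold_pair(1.5, 2.5),
                           min_bins = 5L, min_autosomes = 20L) {
  stopifnot(inherits(profile, "cnv_profile"),
            inherits(thresholds, "threshold_pair"))
  summ <- chromosome_summary(profile, min_bins = min_bins)
  auto <- is_autosome(names(summ))
  n_callable <- sum(auto & !is.na(summ))
  if (n_callable < min_autosomes) {
    stop(sprintf("only %d callable autosomes (< %d); sample too low-quality to call",
                 n_callable, min_autosomes), call. = FALSE)
  }
  state <- ifelse(is.na(summ), "undetermined",
           ifelse(summ <= thresholds$loss, "loss",
           ifelse(summ >= thresholds$gain, "gain", "neutral")))
  names(state) <- names(summ)

  sx <- if ("chrX" %in% names(summ)) summ[["chrX"]] else NA_real_
  sy <- if ("chrY" %in% names(summ)) summ[["chrY"]] else NA_real_
  sex <- "undetermined"
  if (!is.na(sx)) {
    y_val <- if (is.na(sy)) 0 else sy
    if (y_val >= 0.5 && sx >= 0.5 && sx <= 1.5) sex <- "XY"
    else if (y_val < 0.5 && sx >= 1.5) sex <- "XX"
  }
  sex_anomaly <- sex == "undetermined" && !is.na(sx)

  aberr <- state[auto & state %in% c("loss", "gain")]
  ploidy <- if (length(aberr) > 0 || sex_anomaly) "aneuploid" else "euploid"
  structure(list(summary = summ, state = state, sex = sex, ploidy = ploidy,
                 aberrations = aberr, thresholds = thresholds,
                 n_callable_autosomes = n_callable,
                 low_coverage = isTRUE(attr(profile, "low_coverage"))),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  ab <- if (length(x$aberrations)) {
    paste(sprintf("%s%s", ifelse(x$aberrations == "gain", "+", "-"),
                  sub("^chr", "", names(x$aberrations))), collapse = ",")
  } else "none"
  cat(sprintf("<karyotype_call> %s, sex %s (thresholds %g&%g)\n",
              x$ploidy, x$sex, x$thresholds$loss, x$thresholds$gain))
  cat(sprintf("  aberrant autosomes: %s\n", ab))
  if (x$low_coverage) cat("  flag: low coverage\n")
  invisible(x)
}
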