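#' Configuration of the two-stage decision rule
#'
#' Bundles the parameters of the integrated caller: the mosaic-level
#' pre-decontamination thresholds (default 1.8&2.2), the full-CNV
#' post-decontamination thresholds (default 1.5&2.5), the decontamination
#' [filter_policy()], and the mode:
#'
#' * `"integrated"` (default): a chromosome is called non-neutral only
#'   when it crosses the pre-thresholds before decontamination AND the
#'   post-thresholds after decontamination, in the same direction.
#' * `"decon_only"`: the post-decontamination stage alone.
#' * `"pre_only"`: the raw (pre-decontamination) stage alone.
#'
#' @param pre_thresholds a [threshold_pair()] for the raw data.
#' @param post_thresholds a [threshold_pair()] for the decontaminated data.
#' @param filter_policy a [filter_policy()].
#' @param mode one of `"integrated"`, `"decon_only"`, `"pre_only"`.
#' @param min_post_reads floor on the post-filter read count below which
#'   the call is flagged low-confidence (never suppressed silently).
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(pre_thresholds = threshold_pair(1.8, 2.2),
                            post_thresholds = threshold_pair(1.5, 2.5),
                            filter_policy = secmdecon::filter_policy(),
                            mode = c("integrated", "decon_only", "pre_only"),
                            min_post_reads = 1e4) {
  stopifnot(inherits(pre_thresholds, "threshold_pair"),
            inherits(post_thresholds, "threshold_pair"),
            inherits(filter_policy, "filter_policy"))
  mode <- match.arg(mode)
  structure(list(pre_thresholds = pre_thresholds,
                 post_thresholds = post_thresholds,
                 filter_policy = filter_policy,
                 mode = mode,
                 min_post_reads = min_post_reads),
            class = "decision_config")
}

#' Read a decision configuration from a YAML file
#'
#' Reads the `decision` section of a YAML config with keys `pre_loss`,
#' `pre_gain`, `post_loss`, `post_gain`, `min_cpg`, `max_fraction`,
#' `mode`, `min_post_reads`; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [decision_config()].
#' @export
read_decision_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  d <- if (!is.null(cfg$decision)) cfg$decision else cfg
  default <- decision_config()
  grab <- function(key, fallback) if (!is.null(d[[key]])) d[[key]] else fallback
  decision_config(
    pre_thresholds = threshold_pair(grab("pre_loss", default$pre_thresholds$loss),
                                    grab("pre_gain", default$pre_thresholds$gain)),
    post_thresholds = threshold_pair(grab("post_loss", default$post_thresholds$loss),
                                     grab("post_gain", default$post_thresholds$gain)),
    filter_policy = filter_policy(grab("min_cpg", default$filter_policy$min_cpg),
                                  grab("max_fraction", default$filter_policy$max_fraction)),
    mode = grab("mode", default$mode),
    min_post_reads = grab("min_post_reads", default$min_post_reads))
}

#' Expected chromosome copy number in a contaminated mixture
#'
#' The closed-form dilution model behind all threshold arithmetic. A
#' chromosome with embryonic copy number `cn_embryo` diluted by a diploid
#' contaminant making up read fraction `c` has expected summary copy
#' number
#' \deqn{\frac{(1-c)\,s_e\,cn_e + c\,s_c\,2}{(1-c)\,s_e + c\,s_c}}
#' where `s_embryo` and `s_contaminant` are the probabilities that an
#' embryonic and a contaminant read survive the selection step. With no
#' selection (both 1), 50% contamination halves an aneuploidy signal of
#' 1&3 to 1.5&2.5; with unmethylated-read selection (0.47 vs 0.12 for
#' blastocyst vs cumulus) the same mixture yields 1.2&2.8.
#'
#' @param cn_embryo embryonic copy number of the chromosome.
#' @param c contamination fraction in \[0, 1\].
#' @param s_embryo,s_contaminant selection probabilities in (0, 1\].
#' @return Expected copy number.
#' @examples
#' expected_mixture_cn(1, 0.5)                  # 1.5
#' expected_mixture_cn(3, 0.5, 0.47, 0.12)      # ~2.80
#' @export
expected_mixture_cn <- function(cn_embryo, c, s_embryo = 1, s_contaminant = 1) {
  stopifnot(c >= 0, c <= 1,
            s_embryo > 0, s_embryo <= 1,
            s_contaminant > 0, s_contaminant <= 1)
  denom <- (1 - c) * s_embryo + c * s_contaminant
  if (denom <= 0) stop("degenerate mixture: zero selected mass", call. = FALSE)
  ((1 - c) * s_embryo * cn_embryo + c * s_contaminant * 2) / denom
}

# The AND rule of the integrated mode: a chromosome is non-neutral only
# when both stages cross their thresholds in the SAME direction. A
# direction contradiction (pre gain, post loss) is never called. A stage
# that cannot be assessed propagates "undetermined".
combine_states <- function(pre_state, post_state, mode) {
  switch(mode,
    pre_only = pre_state,
    decon_only = post_state,
    integrated = {
      s <- ifelse(pre_state == post_state & pre_state %in% c("loss", "gain"),
                  pre_state,
                  ifelse(pre_state == "undetermined" |
                           post_state == "undetermined",
                         "undetermined", "neutral"))
      stats::setNames(s, names(pre_state))
    },
    stop("unknown mode: ", mode, call. = FALSE))
}

stage_call <- function(reads, bins, reference, thresholds,
                       gc_correction, min_bins, min_autosomes) {
  counts <- bin_counts(reads, bins)
  if (gc_correction) counts <- gc_correct(counts, bins)
  profile <- normalize_to_reference(counts, reference, bins)
  call <- call_karyotype(profile, thresholds,
                         min_bins = min_bins, min_autosomes = min_autosomes)
  list(profile = profile, call = call)
}

#' Integrated two-stage aneuploidy call
#'
#' The package's main entry point: runs the full decision algorithm on a
#' raw SECM read set. The raw reads are binned, GC-corrected and
#' normalized against the diploid reference, and called at the mosaic
#' pre-decontamination thresholds; the reads are then decontaminated with
#' the unmethylated-read filter and called again at the full
#' post-decontamination thresholds. In `integrated` mode a chromosome is
#' reported as a loss or gain only when both stages cross their
#' thresholds in the same direction - genuine aneuploidy diluted by
#' contamination must already show as a mosaic signal before filtering,
#' which suppresses the false positives that filtering alone introduces.
#'
#' @param reads raw [read_set()] for the sample.
#' @param bins a `bin_scheme` (see [make_bins()]).
#' @param reference diploid reference bin counts (see [make_reference()]).
#' @param config a [decision_config()].
#' @param gc_correction apply [gc_correct()] in both stages.
#' @param min_bins,min_autosomes passed to [call_karyotype()].
#' @param enforce_qc require the sample to pass [sample_qc()] first.
#' @param min_unique_reads QC threshold when `enforce_qc` is `TRUE`.
#' @return An object of class `nipgt_call`: list with `state` (final
#'   per-chromosome states), `aberrations`, `ploidy`, `sex` (from the
#'   decontaminated stage), `pre`/`post` stage results (each a
#'   `karyotype_call` plus its `cnv_profile`), `retention`, `flags`, an
#'   `audit` table with the per-chromosome rationale, and the `config`.
#' @export
integrated_call <- function(reads, bins, reference,
                            config = decision_config(),
                            gc_correction = TRUE,
                            min_bins = 5L, min_autosomes = 20L,
                            enforce_qc = FALSE, min_unique_reads = 1e6) {
  stopifnot(inherits(reads, "read_set"), inherits(config, "decision_config"))
  if (enforce_qc) {
    qc <- sample_qc(reads, min_unique_reads)
    if (!qc$pass) {
      stop(sprintf("sample fails read-count QC (%d <= %g)", qc$n_reads,
                   min_unique_reads), call. = FALSE)
    }
  }
  flags <- character(0)

  pre <- stage_call(reads, bins, reference, config$pre_thresholds,
                    gc_correction, min_bins, min_autosomes)

  filtered <- decontaminate(reads, config$filter_policy)
  retention <- attr(filtered, "retention")
  if (nrow(filtered) < config$min_post_reads) {
    flags <- c(flags, "low_confidence_post_filter")
  }
  post <- if (nrow(filtered) > 0L) {
    stage_call(filtered, bins, reference, config$post_thresholds,
               gc_correction, min_bins, min_autosomes)
  } else NULL
  if (is.null(post)) flags <- c(flags, "empty_post_filter")

  chroms <- names(pre$call$state)
  pre_state <- pre$call$state
  post_state <- if (!is.null(post)) post$call$state[chroms] else
    stats::setNames(rep("undetermined", length(chroms)), chroms)

  final_state <- combine_states(pre_state, post_state, config$mode)

  auto <- is_autosome(chroms)
  aberr <- final_state[auto & final_state %in% c("loss", "gain")]
  sex <- switch(config$mode,
                pre_only = pre$call$sex,
                if (!is.null(post)) post$call$sex else "undetermined")
  sex_anomaly <- switch(config$mode,
    pre_only = pre$call$sex == "undetermined" &&
      !is.na(pre$call$summary["chrX"]),
    integrated = pre$call$sex == "undetermined" && !is.null(post) &&
      post$call$sex == "undetermined" && !is.na(pre$call$summary["chrX"]),
    decon_only = !is.null(post) && post$call$sex == "undetermined" &&
      !is.na(post$call$summary["chrX"]))
  ploidy <- if (length(aberr) > 0 || isTRUE(sex_anomaly)) "aneuploid"
            else "euploid"

  audit <- data.frame(
    chrom = chroms,
    pre_cn = round(pre$call$summary[chroms], 4),
    pre_state = pre_state,
    post_cn = if (!is.null(post)) round(post$call$summary[chroms], 4)
              else NA_real_,
    post_state = post_state,
    final_state = final_state,
    stringsAsFactors = FALSE, row.names = NULL)
  audit$rationale <- with(audit, ifelse(
    final_state %in% c("loss", "gain"),
    sprintf("pre %s and post %s cross in the same direction",
            pre_state, post_state),
    ifelse(pre_state %in% c("loss", "gain") & post_state == "neutral",
           "mosaic signal before filtering not confirmed after",
           ifelse(pre_state == "neutral" & post_state %in% c("loss", "gain"),
                  "post-filter signal without mosaic evidence before",
                  "no threshold crossing"))))

  structure(list(state = final_state, aberrations = aberr,
                 ploidy = ploidy, sex = sex,
                 pre = pre, post = post,
                 retention = retention, flags = flags,
                 audit = audit, config = config,
                 sample_id = attr(reads, "sample_id")),
            class = "nipgt_call")
}

#' @export
print.nipgt_call <- function(x, ...) {
  ab <- if (length(x$aberrations)) {
    paste(sprintf("%s%s", ifelse(x$aberrations == "gain", "+", "-"),
                  sub("^chr", "", names(x$aberrations))), collapse = ",")
  } else "none"
  cat(sprintf("<nipgt_call> sample '%s' (mode %s)\n",
              x$sample_id, x$config$mode))
  cat(sprintf("  verdict: %s, sex %s; aberrant autosomes: %s\n",
              x$ploidy, x$sex, ab))
  cat(sprintf("  decontamination retained %.1f%% of reads\n",
              100 * x$retention))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.nipgt_call <- function(object, ...) {
  cat(sprintf("Two-stage aneuploidy call for sample '%s'\n", object$sample_id))
  cat(sprintf("mode: %s; pre %g&%g, post %g&%g; filter: n_cpg >= %d, methylation <= %g\n",
              object$config$mode,
              object$config$pre_thresholds$loss, object$config$pre_thresholds$gain,
              object$config$post_thresholds$loss, object$config$post_thresholds$gain,
              object$config$filter_policy$min_cpg,
              object$config$filter_policy$max_fraction))
  cat(sprintf("verdict: %s, sex %s; retention %.1f%%\n\n",
              object$ploidy, object$sex, 100 * object$retention))
  print(object$audit, row.names = FALSE)
  invisible(object$audit)
}

#' Plot a two-stage call as before/after copy-number panels
#'
#' @param x a `nipgt_call`.
#' @param ... passed to [plot.cnv_profile()].
#' @export
plot.nipgt_call <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$pre$profile, thresholds = x$config$pre_thresholds,
       main = sprintf("%s: raw", x$sample_id), ...)
  if (!is.null(x$post)) {
    plot(x$post$profile, thresholds = x$config$post_thresholds,
         main = sprintf("%s: decontaminated", x$sample_id), ...)
  }
  invisible(x)
}

#' Serialize a call's audit record to JSON
#'
#' @param x a `nipgt_call`.
#' @param path output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
audit_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "nipgt_call"))
  obj <- list(sample_id = x$sample_id,
              mode = x$config$mode,
              ploidy = x$ploidy, sex = x$sex,
              aberrations = as.list(x$aberrations),
              retention = x$retention,
              flags = x$flags,
              chromosomes = x$audit)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
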