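#' Cell-type methylation signatures
#'
#' A cell-type signature holds the generative parameters the simulator uses
#' for one cell type: the read-level methylation trichotomy (`f_zero`,
#' `f_partial`, `f_full` over CpG-containing reads), the CpG-count
#' histogram over all reads, the shape of the within-(0,1) methylation
#' distribution for partially methylated reads, and the expected
#' genome-wide methylation level.
#'
#' @param name signature name.
#' @param f_zero,f_partial,f_full trichotomy fractions; must sum to 1.
#' @param cpg_histogram named fractions of reads with "0","1","2","3",">3"
#'   CpGs; renormalized to sum to 1.
#' @param partial_shape length-2 Beta shape parameters for the per-read
#'   methylation of partially methylated reads. The default Beta(0.5, 0.5)
#'   reflects the bimodal per-read methylation landscape.
#' @param genome_level expected genome-wide methylation level in \[0, 1\].
#' @return An object of class `cell_signature`.
#' @export
cell_signature <- function(name, f_zero, f_partial, f_full,
                           cpg_histogram,
                           partial_shape = c(0.5, 0.5),
                           genome_level = NA_real_) {
  tri <- c(f_zero, f_partial, f_full)
  if (any(tri < 0) || abs(sum(tri) - 1) > 1e-6) {
    stop("trichotomy fractions must be nonnegative and sum to 1", call. = FALSE)
  }
  if (length(cpg_histogram) != 5L || any(cpg_histogram < 0)) {
    stop("cpg_histogram must be 5 nonnegative fractions (0,1,2,3,>3 CpGs)",
         call. = FALSE)
  }
  cpg_histogram <- cpg_histogram / sum(cpg_histogram)
  names(cpg_histogram) <- c("0", "1", "2", "3", ">3")
  if (!is.na(genome_level) && (genome_level < 0 || genome_level > 1)) {
    stop("genome_level must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name,
                 f_zero = f_zero, f_partial = f_partial, f_full = f_full,
                 cpg_histogram = cpg_histogram,
                 partial_shape = partial_shape,
                 genome_level = genome_level),
            class = "cell_signature")
}

#' @export
print.cell_signature <- function(x, ...) {
  cat(sprintf("<cell_signature> '%s': trichotomy %.2f/%.2f/%.2f, genome level %s\n",
              x$name, x$f_zero, x$f_partial, x$f_full,
              ifelse(is.na(x$genome_level), "NA",
                     sprintf("%.2f", x$genome_level))))
  invisible(x)
}

#' Built-in cell-type signatures
#'
#' The registry of signatures for the cell types relevant to SECM
#' contamination, parameterized by the published read-level statistics:
#'
#' * `blastocyst`: trichotomy 0.47/0.11/0.42 (the SECM-column values; the
#'   ICM and TE variants differ by 1-3 points and are provided as the
#'   presets `icm` and `te`), genome level 0.29.
#' * `cumulus`: 0.12/0.14/0.74, genome level 0.71 - the dominant maternal
#'   contaminant, hypermethylated.
#' * `sperm`: 0.20/0.08/0.72 with its own CpG histogram
#'   (0.35/0.23/0.14/0.08/0.20), genome level 0.82.
#' * `mii_oocyte`: proxy for polar-body DNA. Only `f_zero` = 0.38 is
#'   reported; the remainder is split 0.14/0.48 so that the oocyte sits
#'   between blastocyst and cumulus in overall methylation (a documented
#'   assumption), genome level 0.50.
#'
#' The shared CpG histogram for non-sperm types is 0.30/0.24/0.15/0.09/0.19
#' for 0/1/2/3/>3 CpGs (renormalized), i.e. ~70% of reads carry at least
#' one CpG.
#'
#' @return Named list of [cell_signature()] objects.
#' @examples
#' builtin_signatures()$cumulus
#' @export
builtin_signatures <- function() {
  hist_default <- c(0.30, 0.24, 0.15, 0.09, 0.19)
  hist_sperm <- c(0.35, 0.23, 0.14, 0.08, 0.20)
  list(
    blastocyst = cell_signature("blastocyst", 0.47, 0.11, 0.42,
                                hist_default, genome_level = 0.29),
    icm = cell_signature("icm", 0.50 / 1.01, 0.12 / 1.01, 0.39 / 1.01,
                         hist_default, genome_level = 0.24),
    te = cell_signature("te", 0.50 / 0.99, 0.11 / 0.99, 0.38 / 0.99,
                        hist_default, genome_level = 0.24),
    cumulus = cell_signature("cumulus", 0.12, 0.14, 0.74,
                             hist_default, genome_level = 0.71),
    sperm = cell_signature("sperm", 0.20, 0.08, 0.72,
                           hist_sperm, genome_level = 0.82),
    mii_oocyte = cell_signature("mii_oocyte", 0.38, 0.14, 0.48,
                                hist_default, genome_level = 0.50)
  )
}

#' Karyotypes
#'
#' Per-chromosome integer copy numbers plus a sex designation. Autosomes
#' default to copy number 2; the sex chromosomes are set from `sex` (XX: X
#' = 2, Y = 0; XY: X = 1, Y = 1). Aberrations are given in the conventional
#' `"+22"` / `"-16,+18"` grammar: `+chr` adds one copy, `-chr` removes one.
#'
#' @param aberrations character scalar such as `"+22"`, `"-16,+18"`, or
#'   `""`/`NULL` for euploid. Chromosome tokens may carry or omit the
#'   `chr` prefix.
#' @param sex `"XX"` or `"XY"`.
#' @param genome a [chromosome_set()] naming the chromosomes.
#' @return An object of class `karyotype`: list with `cn` (named integer
#'   vector over the genome's chromosomes) and `sex`.
#' @examples
#' k <- karyotype("+18", sex = "XY")
#' k$cn[c("chr18", "chrX", "chrY")]
#' @export
karyotype <- function(aberrations = NULL, sex = c("XX", "XY"),
                      genome = scaled_hg19_genome()) {
  sex <- match.arg(sex)
  cn <- rep(2L, nrow(genome))
  names(cn) <- genome$chrom
  if ("chrX" %in% names(cn)) cn["chrX"] <- if (sex == "XX") 2L else 1L
  if ("chrY" %in% names(cn)) cn["chrY"] <- if (sex == "XX") 0L else 1L
  if (!is.null(aberrations) && nzchar(aberrations)) {
    tokens <- trimws(strsplit(aberrations, ",")[[1]])
    tokens <- tokens[nzchar(tokens)]
    for (tok in tokens) {
      if (!grepl("^[+-]", tok)) {
        stop("karyotype token must start with '+' or '-': ", tok,
             call. = FALSE)
      }
      delta <- if (substr(tok, 1, 1) == "+") 1L else -1L
      ch <- sub("^[+-]", "", tok)
      if (!grepl("^chr", ch)) ch <- paste0("chr", ch)
      if (!ch %in% names(cn)) {
        stop("karyotype names chromosome absent from genome: ", ch,
             call. = FALSE)
      }
      cn[ch] <- cn[ch] + delta
    }
  }
  if (any(cn < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  if (all(cn == 0)) stop("at least one chromosome must have CN > 0",
                         call. = FALSE)
  structure(list(cn = cn, sex = sex), class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  ab <- x$cn[is_autosome(names(x$cn)) & x$cn != 2L]
  desc <- if (length(ab)) {
    paste(sprintf("%s%s", ifelse(ab > 2, "+", "-"),
                  sub("^chr", "", names(ab))), collapse = ",")
  } else "euploid"
  cat(sprintf("<karyotype> %s, %s\n", desc, x$sex))
  invisible(x)
}
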