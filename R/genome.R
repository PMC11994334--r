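#' Chromosome sets
#'
#' A chromosome set names the chromosomes of the active genome and their
#' lengths. Every read set, bin scheme and karyotype refers to one, so that
#' chromosome membership and coordinate bounds can be validated at the
#' boundaries of the pipeline.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer/numeric vector of chromosome lengths in bp (> 0).
#' @return An object of class `chromosome_set`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' chromosome_set(c("chr1", "chr2", "chrX"), c(2e6, 1.5e6, 1e6))
#' @export
chromosome_set <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) {
    stop("duplicated chromosome names in chromosome set", call. = FALSE)
  }
  length <- as.numeric(length)
  if (length(chrom) != length(length) || length(chrom) == 0L) {
    stop("'chrom' and 'length' must be nonempty vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive and finite", call. = FALSE)
  }
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("chromosome_set", "data.frame"))
}

# hg19 chromosome lengths (bp), chr1..chr22, chrX, chrY
.hg19_lengths <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566
)

#' Scaled human genome for desk-scale simulation
#'
#' The default simulation genome: 22 autosomes plus X and Y with lengths
#' proportional to hg19, divided by `scale`. At the default 1/50 scale the
#' genome is ~62 Mb (haploid), so simulations with millions of reads and
#' ~20 kb bins (the scaled analogue of ~1 Mb bins) run in seconds while
#' preserving the relative chromosome sizes that determine read allocation
#' and copy-number dilution arithmetic.
#'
#' @param scale positive divisor applied to the hg19 lengths.
#' @return A [chromosome_set()].
#' @export
scaled_hg19_genome <- function(scale = 50) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  chromosome_set(names(.hg19_lengths), floor(.hg19_lengths / scale))
}

#' @export
print.chromosome_set <- function(x, ...) {
  cat(sprintf("<chromosome_set> %d chromosomes, total %.4g bp\n",
              nrow(x), sum(x$length)))
  print.data.frame(x, ...)
  invisible(x)
}

# autosome predicate used by normalization and karyotype calling
is_autosome <- function(chrom) {
  !(chrom %in% c("chrX", "chrY", "X", "Y"))
}
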