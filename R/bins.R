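#' Genomic bin schemes
#'
#' Copy-number calling counts reads in a fixed set of non-overlapping,
#' sorted genomic bins, each annotated with its GC fraction and an optional
#' blacklist flag for aberrant regions.
#'
#' `make_bins()` tiles a genome with fixed-width bins. Because the package
#' has no sequence to compute GC from, per-bin GC is simulated as a smooth
#' along-chromosome gradient plus noise - enough structure for the GC
#' correction to have signal to remove when a bias is injected. Real
#' variable-width schemes (e.g. the ~1 Mb variable bins used with hg19)
#' can be loaded with [read_bins_bed()].
#'
#' @param genome a [chromosome_set()].
#' @param bin_size bin width in bp. The default 20 kb is the 1/50-scaled
#'   analogue of ~1 Mb bins on hg19.
#' @param seed seed for the simulated GC noise.
#' @param gc_base,gc_amp,gc_noise mean, gradient amplitude and noise SD of
#'   the simulated per-bin GC fraction.
#' @return An object of class `bin_scheme`: data.frame with columns
#'   `chrom`, `start`, `end`, `gc`, `blacklist`.
#' @export
make_bins <- function(genome, bin_size = 2e4, seed = 1L,
                      gc_base = 0.41, gc_amp = 0.08, gc_noise = 0.015) {
  stopifnot(inherits(genome, "chromosome_set"), bin_size > 0)
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome$chrom[i],
               start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  with_seed(seed, {
    rel <- (bins$start + bins$end) / 2 /
      genome$length[match(bins$chrom, genome$chrom)]
    gc <- gc_base + gc_amp * sin(2 * pi * rel) +
      stats::rnorm(nrow(bins), 0, gc_noise)
    bins$gc <- pmin(pmax(gc, 0.2), 0.65)
  })
  bins$blacklist <- FALSE
  rownames(bins) <- NULL
  validate_bins(bins)
}

validate_bins <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(bins)))
  if (is.null(bins$blacklist)) bins$blacklist <- FALSE
  if (any(bins$gc < 0 | bins$gc > 1)) {
    stop("gc fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(bins$start >= bins$end)) {
    stop("bins must have start < end", call. = FALSE)
  }
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE) ||
        any(b$start[-1] < b$end[-nrow(b)])) {
      stop("bins must be sorted and non-overlapping within chromosomes",
           call. = FALSE)
    }
  }
  structure(bins, class = c("bin_scheme", "data.frame"))
}

#' Load a bin scheme from a BED file
#'
#' Reads bins from a BED-like file: columns chrom, start, end, and
#' optionally gc (4th) and blacklist (5th, 0/1). Bins must be sorted and
#' non-overlapping within chromosomes.
#'
#' @param path BED path (optionally gzip-compressed).
#' @return A `bin_scheme`.
#' @export
read_bins_bed <- function(path) {
  con <- open_maybe_gz(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  names(tab)[1:3] <- c("chrom", "start", "end")
  tab$gc <- if (ncol(tab) >= 4) as.numeric(tab[[4]]) else 0.5
  tab$blacklist <- if (ncol(tab) >= 5) as.logical(as.integer(tab[[5]])) else FALSE
  validate_bins(tab[, c("chrom", "start", "end", "gc", "blacklist")])
}

#' Count reads per bin
#'
#' Assigns each read to the bin whose half-open interval `[start, end)`
#' contains the read's start coordinate. Reads starting outside every bin
#' are left unassigned, so the total assigned count never exceeds the
#' number of reads. Blacklisted bins receive no count and are marked
#' unusable.
#'
#' @param reads a [read_set()] or a data.frame with `chrom` and `start`.
#' @param bins a `bin_scheme` on the same genome.
#' @return Numeric vector of per-bin counts with attribute `usable`
#'   (logical; `FALSE` for blacklisted bins).
#' @export
bin_counts <- function(reads, bins) {
  stopifnot(inherits(bins, "bin_scheme"))
  unknown <- setdiff(unique(reads$chrom), unique(bins$chrom))
  if (length(unknown)) {
    stop("reads on chromosome(s) absent from the bin scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- numeric(nrow(bins))
  for (ch in unique(reads$chrom)) {
    bi <- which(bins$chrom == ch)
    starts <- reads$start[reads$chrom == ch]
    idx <- findInterval(starts, bins$start[bi])
    ok <- idx >= 1L
    ok[ok] <- starts[ok] < bins$end[bi][idx[ok]]
    tab <- tabulate(idx[ok], nbins = length(bi))
    counts[bi] <- counts[bi] + tab
  }
  usable <- !bins$blacklist
  counts[!usable] <- 0
  attr(counts, "usable") <- usable
  counts
}
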