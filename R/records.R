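#' Per-read methylation record sets
#'
#' The atomic unit of the whole pipeline is one sequencing read's genomic
#' interval together with its CpG counts: `n_cpg` informative CpG sites and
#' `n_meth` methylated ones, plus (optionally) the number of unmethylated CH
#' cytosines used for the bisulfite-conversion filter. A read set bundles a
#' table of such records with a sample id and the active genome.
#'
#' Coordinates are 0-based half-open (`[start, end)`), the BED convention,
#' both in memory and in every file read or written by this package.
#'
#' @param records data.frame with columns `read_id`, `chrom`, `start`,
#'   `end`, `n_cpg`, `n_meth` and optionally `n_unmeth_ch` (defaults to 0
#'   when absent, so pre-filtered data flow through unchanged).
#' @param sample_id character scalar naming the sample.
#' @param genome a [chromosome_set()] or `NULL`. When supplied, records must
#'   lie on chromosomes of the genome and within their bounds.
#' @return An object of class `read_set`: the validated record data.frame
#'   with attributes `sample_id` and `genome`.
#' @export
read_set <- function(records, sample_id = "sample", genome = NULL) {
  required <- c("read_id", "chrom", "start", "end", "n_cpg", "n_meth")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("per-read table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$n_unmeth_ch)) records$n_unmeth_ch <- 0L
  records$read_id <- as.character(records$read_id)
  records$chrom <- as.character(records$chrom)
  for (col in c("start", "end", "n_cpg", "n_meth", "n_unmeth_ch")) {
    v <- records[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(v <- as.numeric(as.character(v)))
    }
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("column '%s' has non-numeric/missing values at row(s) %s",
                   col, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    records[[col]] <- v
  }
  validate_records(records, genome)
  keep <- c(required, "n_unmeth_ch",
            intersect("origin", names(records)))
  records <- records[, keep, drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            sample_id = as.character(sample_id)[1L],
            genome = genome,
            class = c("read_set", "data.frame"))
}

validate_records <- function(records, genome = NULL) {
  bad <- which(records$n_meth > records$n_cpg)
  if (length(bad)) {
    stop(sprintf("n_meth > n_cpg for read(s): %s",
                 paste(utils::head(records$read_id[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (any(records$n_cpg < 0) || any(records$n_meth < 0) ||
      any(records$n_unmeth_ch < 0)) {
    stop("CpG/CH counts must be nonnegative", call. = FALSE)
  }
  bad <- which(records$start >= records$end)
  if (length(bad)) {
    stop(sprintf("start >= end for read(s): %s",
                 paste(utils::head(records$read_id[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (any(records$start < 0)) {
    stop("negative start coordinate", call. = FALSE)
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(records$chrom), genome$chrom)
    if (length(unknown)) {
      stop("records on chromosome(s) absent from the genome: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    len <- genome$length[match(records$chrom, genome$chrom)]
    if (any(records$end > len)) {
      stop("record end coordinate exceeds chromosome length", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> sample '%s': %d reads on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more reads\n", nrow(x) - 6L))
  invisible(x)
}

# fast-path constructor for frames already known to satisfy the record
# invariants (simulator output, subsets of validated sets); skips the
# O(n) validation passes that read_set() performs on user input
new_read_set <- function(records, sample_id, genome = NULL) {
  rownames(records) <- NULL
  structure(records,
            sample_id = as.character(sample_id)[1L],
            genome = genome,
            class = c("read_set", "data.frame"))
}

# rebuild a read_set after row subsetting, preserving metadata;
# column-wise indexing avoids data.frame row-name materialization on
# multi-million-row sets
subset_read_set <- function(x, idx) {
  cols <- lapply(unclass(x)[names(x)], function(col) col[idx])
  out <- structure(cols,
                   row.names = c(NA_integer_, -length(idx)),
                   class = "data.frame")
  new_read_set(out, sample_id = attr(x, "sample_id"),
               genome = attr(x, "genome"))
}

open_maybe_gz <- function(path, mode = "r") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a per-read methylation table
#'
#' Reads the canonical tab-separated per-read table with header
#' `read_id chrom start end n_cpg n_meth n_unmeth_ch` (the last column is
#' optional). `#`-prefixed comment lines are skipped and `.gz` files are
#' decompressed transparently. The table models the per-read output of a
#' read-level methylation extractor run on PBAT bisulfite alignments.
#'
#' @param path path to the TSV (optionally gzip-compressed).
#' @param sample_id sample name; defaults to the file name.
#' @param genome optional [chromosome_set()] used for validation.
#' @return A [read_set()].
#' @export
read_per_read_table <- function(path, sample_id = NULL, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  }
  con <- open_maybe_gz(path)
  on.exit(close(con))
  tab <- utils::read.delim(con, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  read_set(tab, sample_id = sample_id, genome = genome)
}

#' Write a per-read methylation table
#'
#' Inverse of [read_per_read_table()]; the round trip is lossless.
#'
#' @param reads a [read_set()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_per_read_table <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- open_maybe_gz(path, "w")
  on.exit(close(con))
  cols <- intersect(c("read_id", "chrom", "start", "end",
                      "n_cpg", "n_meth", "n_unmeth_ch", "origin"),
                    names(reads))
  utils::write.table(as.data.frame(reads)[, cols, drop = FALSE], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export read intervals as BED4
#'
#' Writes a standard 4-column BED file (chrom, start, end, read_id),
#' 0-based half-open, sorted by chromosome then start. Chromosome order
#' follows the read set's genome when present, otherwise lexicographic
#' order.
#'
#' @param reads a [read_set()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_bed <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  genome <- attr(reads, "genome")
  df <- as.data.frame(reads)
  chrom_rank <- if (!is.null(genome)) {
    match(df$chrom, genome$chrom)
  } else {
    match(df$chrom, sort(unique(df$chrom)))
  }
  ord <- order(chrom_rank, df$start)
  con <- open_maybe_gz(path, "w")
  on.exit(close(con))
  if (nrow(df)) {
    utils::write.table(
      df[ord, c("chrom", "start", "end", "read_id"), drop = FALSE], con,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Bisulfite-conversion filter
#'
#' Discards reads whose mate carries more than `max_unmeth_ch` unmethylated
#' CH cytosines, the standard evidence of incomplete bisulfite conversion.
#' The default (3) keeps reads with up to three unmethylated CHs and drops
#' reads with four or more. Records lacking CH information (n_unmeth_ch 0,
#' the default at ingestion) always pass.
#'
#' Because the per-read table is single-record (the R1/R2 pairing of the
#' original library is not representable), the filter is applied per record
#' rather than per pair.
#'
#' @param reads a [read_set()].
#' @param max_unmeth_ch maximum tolerated unmethylated CH count (>= 0).
#' @return The filtered [read_set()]; the number of removed records is
#'   reported via `message()` and stored in attribute `n_removed`.
#' @export
conversion_filter <- function(reads, max_unmeth_ch = 3L) {
  stopifnot(inherits(reads, "read_set"))
  if (!is.numeric(max_unmeth_ch) || length(max_unmeth_ch) != 1L ||
      max_unmeth_ch < 0) {
    stop("'max_unmeth_ch' must be a nonnegative number", call. = FALSE)
  }
  keep <- reads$n_unmeth_ch <= max_unmeth_ch
  out <- subset_read_set(reads, which(keep))
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("conversion_filter: removed %d of %d reads (> %g unmethylated CHs)",
                    n_removed, nrow(reads), max_unmeth_ch))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Sample-level read-count QC
#'
#' A sample is retained when it has strictly more than `min_unique_reads`
#' uniquely mapped reads (default one million).
#'
#' @param reads a [read_set()].
#' @param min_unique_reads strict lower bound on the read count.
#' @return A list of class `sample_qc` with elements `pass`, `n_reads`,
#'   `min_unique_reads` and `sample_id`.
#' @export
sample_qc <- function(reads, min_unique_reads = 1e6) {
  stopifnot(inherits(reads, "read_set"))
  n <- nrow(reads)
  structure(list(pass = n > min_unique_reads,
                 n_reads = n,
                 min_unique_reads = min_unique_reads,
                 sample_id = attr(reads, "sample_id")),
            class = "sample_qc")
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf("<sample_qc> '%s': %d reads, threshold > %g: %s\n",
              x$sample_id, x$n_reads, x$min_unique_reads,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Genome-wide methylation level from a per-site table
#'
#' Computes the genome-wide CpG methylation level as the ratio of
#' methylated read observations to all read observations, over CpG sites
#' covered by at least `min_cov` reads (the "more than three reads" rule,
#' i.e. coverage >= 4 by default).
#'
#' @param site_table data.frame with columns `coverage` (total reads per
#'   CpG site) and `methylated` (methylated reads per site).
#' @param min_cov minimum per-site coverage for inclusion.
#' @return The methylation level in \[0, 1\].
#' @export
site_methylation_level <- function(site_table, min_cov = 4L) {
  if (!all(c("coverage", "methylated") %in% names(site_table))) {
    stop("site table needs columns 'coverage' and 'methylated'", call. = FALSE)
  }
  cov <- site_table$coverage
  meth <- site_table$methylated
  if (any(cov < 0) || any(meth < 0) || any(meth > cov)) {
    stop("per-site counts must satisfy 0 <= methylated <= coverage",
         call. = FALSE)
  }
  keep <- cov >= min_cov
  if (!any(keep)) {
    stop(sprintf("no CpG site reaches coverage %d; methylation level undefined",
                 min_cov), call. = FALSE)
  }
  sum(meth[keep]) / sum(cov[keep])
}
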