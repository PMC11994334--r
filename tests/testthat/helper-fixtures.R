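# shared fixtures, built once per test session on first use

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a small 3-autosome genome for cheap pipeline tests
tiny_genome <- function() {
  chromosome_set(c("chr1", "chr2", "chr3"), c(2e6, 1.5e6, 1e6))
}

tiny_bins <- function() {
  fixture("tiny_bins", function() make_bins(tiny_genome(), bin_size = 2e4))
}

tiny_reference <- function() {
  fixture("tiny_reference", function() {
    make_reference(tiny_genome(), tiny_bins(), n = 5e5, seed = 4242)
  })
}

# full scaled genome fixtures shared by the cnv/decision tests
scaled_genome <- function() fixture("scaled_genome", scaled_hg19_genome)

scaled_bins <- function() {
  fixture("scaled_bins", function() make_bins(scaled_genome()))
}

scaled_reference <- function() {
  fixture("scaled_reference", function() {
    make_reference(scaled_genome(), scaled_bins(), n = 2e6, seed = 4242)
  })
}

# strip class and bookkeeping attributes for content comparisons
plain <- function(x) {
  df <- as.data.frame(x)
  attrs <- attributes(df)
  attributes(df) <- attrs[intersect(c("names", "row.names"), names(attrs))]
  class(df) <- "data.frame"
  rownames(df) <- NULL
  df
}

# build a read_set from parallel vectors, with defaults for the
# coordinate fields, recycling scalars
make_reads <- function(n_cpg, n_meth, n_unmeth_ch = 0L,
                       chrom = "chr1", start = NULL, end = NULL,
                       genome = NULL, sample_id = "test") {
  n <- max(length(n_cpg), length(n_meth),
           if (length(chrom) > 1) length(chrom) else 0,
           if (length(n_unmeth_ch) > 1) length(n_unmeth_ch) else 0)
  if (is.null(start)) start <- seq(0, by = 200, length.out = n)
  if (is.null(end)) end <- start + 100
  read_set(data.frame(read_id = sprintf("r%03d", seq_len(n)),
                      chrom = rep_len(chrom, n),
                      start = start, end = end,
                      n_cpg = rep_len(n_cpg, n),
                      n_meth = rep_len(n_meth, n),
                      n_unmeth_ch = rep_len(n_unmeth_ch, n),
                      stringsAsFactors = FALSE),
           sample_id = sample_id, genome = genome)
}

# construct a cnv_profile with a given per-chromosome bin-value layout:
# cn_by_chrom is a named list of numeric bin values
fake_profile <- function(cn_by_chrom) {
  chroms <- names(cn_by_chrom)
  df <- do.call(rbind, lapply(chroms, function(ch) {
    v <- cn_by_chrom[[ch]]
    data.frame(chrom = ch,
               start = seq(0, by = 1e4, length.out = length(v)),
               end = seq(1e4, by = 1e4, length.out = length(v)),
               cn = v, usable = TRUE, stringsAsFactors = FALSE)
  }))
  structure(df, n_reads_used = 1e6, low_coverage = FALSE,
            class = c("cnv_profile", "data.frame"))
}

# per-chromosome layout for a whole genome with constant bin values,
# defaulting every chromosome to diploid
genome_layout <- function(..., sex = c("XX", "XY"), n_bins = 10L) {
  sex <- match.arg(sex)
  overrides <- list(...)
  chroms <- scaled_hg19_genome()$chrom
  vals <- stats::setNames(rep(2, length(chroms)), chroms)
  vals["chrX"] <- if (sex == "XX") 2 else 1
  vals["chrY"] <- if (sex == "XX") 0 else 1
  for (ch in names(overrides)) vals[ch] <- overrides[[ch]]
  lapply(stats::setNames(as.list(vals), names(vals)),
         function(v) rep(v, n_bins))
}
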