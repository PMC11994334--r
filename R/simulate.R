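# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# truncated geometric over 4..12 for the ">3 CpGs" histogram bucket
draw_cpg_tail <- function(n, p = 0.35, max_cpg = 12L) {
  support <- 4:max_cpg
  w <- p * (1 - p)^(support - 4L)
  sample(support, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate a per-read methylation sample
#'
#' Generates `n` per-read records for one cell type and karyotype. Reads
#' are placed uniformly within chromosomes, with chromosomes sampled in
#' proportion to length x copy number, so aneuploid chromosomes receive
#' proportionally more (or fewer) reads. Each read draws its CpG count
#' from the signature's histogram (the ">3" bucket from a truncated
#' geometric over 4..12) and its methylation state from the trichotomy:
#' unmethylated reads get `n_meth = 0`, fully methylated reads
#' `n_meth = n_cpg`, and partially methylated reads draw a Beta
#' methylation level discretized by a binomial over their CpGs, clamped to
#' the open interval. A partially methylated state needs at least two CpGs
#' to be representable, so partial reads that drew a single CpG redraw
#' their CpG count from the >= 2 classes of the histogram; this keeps the
#' realized trichotomy exact at the cost of a slight CpG-histogram shift.
#'
#' Output is deterministic for a fixed `(signature, karyotype, n, seed)`.
#'
#' @param signature a [cell_signature()].
#' @param karyotype a [karyotype()]; defaults to euploid XX.
#' @param n number of reads (>= 1).
#' @param genome a [chromosome_set()].
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param read_length fixed read length in bp.
#' @param gc_bias optional GC count-bias hook: a list
#'   `list(bins = <bin_scheme>, slope = <numeric>)`. Reads are thinned by
#'   rejection with acceptance probability proportional to
#'   `1 + slope * (gc - mean(gc))` of their bin, injecting a linear GC
#'   bias for [gc_correct()] to remove. Thinning returns fewer than `n`
#'   reads.
#' @param sample_id sample name stored in the result.
#' @return A [read_set()] with an `origin` column naming the signature
#'   (the provenance label used by mixture oracles).
#' @export
generate_reads <- function(signature, karyotype = NULL, n,
                           genome = scaled_hg19_genome(), seed = NULL,
                           read_length = 100L, gc_bias = NULL,
                           sample_id = signature$name) {
  stopifnot(inherits(signature, "cell_signature"), n >= 1)
  if (is.null(karyotype)) karyotype <- karyotype(NULL, "XX", genome)
  stopifnot(inherits(karyotype, "karyotype"))
  unknown <- setdiff(names(karyotype$cn), genome$chrom)
  if (length(unknown)) {
    stop("karyotype names chromosome(s) absent from genome: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cn <- karyotype$cn[genome$chrom]
  cn[is.na(cn)] <- 2L
  with_seed(seed, {
    n <- as.integer(n)
    w <- genome$length * cn
    chrom_idx <- sample.int(nrow(genome), n, replace = TRUE, prob = w)
    max_start <- pmax(genome$length[chrom_idx] - read_length, 1)
    start <- floor(stats::runif(n, 0, max_start))
    end <- pmin(start + read_length, genome$length[chrom_idx])

    # CpG counts from the histogram; class 5 is the >3 tail
    cls <- sample.int(5L, n, replace = TRUE, prob = signature$cpg_histogram)
    n_cpg <- c(0L, 1L, 2L, 3L, NA_integer_)[cls]
    tail_i <- which(cls == 5L)
    if (length(tail_i)) n_cpg[tail_i] <- draw_cpg_tail(length(tail_i))

    # methylation state for CpG-containing reads
    state <- integer(n)  # 0 = no CpG, 1 = zero, 2 = partial, 3 = full
    inf_i <- which(n_cpg >= 1L)
    tri <- c(signature$f_zero, signature$f_partial, signature$f_full)
    state[inf_i] <- sample.int(3L, length(inf_i), replace = TRUE, prob = tri)

    # partial state needs n_cpg >= 2: redraw CpG count from the >=2 classes
    fix_i <- which(state == 2L & n_cpg == 1L)
    if (length(fix_i)) {
      p_multi <- signature$cpg_histogram[c("2", "3", ">3")]
      cls2 <- sample.int(3L, length(fix_i), replace = TRUE, prob = p_multi)
      n_cpg[fix_i] <- c(2L, 3L, NA_integer_)[cls2]
      t2 <- which(is.na(n_cpg[fix_i]))
      if (length(t2)) n_cpg[fix_i][t2] <- draw_cpg_tail(length(t2))
    }

    n_meth <- integer(n)
    n_meth[state == 3L] <- n_cpg[state == 3L]
    part_i <- which(state == 2L)
    if (length(part_i)) {
      p <- stats::rbeta(length(part_i), signature$partial_shape[1],
                        signature$partial_shape[2])
      k <- stats::rbinom(length(part_i), n_cpg[part_i], p)
      n_meth[part_i] <- pmin(pmax(k, 1L), n_cpg[part_i] - 1L)
    }

    df <- data.frame(
      read_id = paste0(sample_id, "_r", seq_len(n)),
      chrom = genome$chrom[chrom_idx],
      start = start, end = end,
      n_cpg = n_cpg, n_meth = n_meth, n_unmeth_ch = 0L,
      origin = signature$name,
      stringsAsFactors = FALSE)

    if (!is.null(gc_bias)) {
      stopifnot(inherits(gc_bias$bins, "bin_scheme"),
                is.numeric(gc_bias$slope))
      bins <- gc_bias$bins
      gc <- rep(NA_real_, n)
      for (ch in unique(df$chrom)) {
        bi <- which(bins$chrom == ch)
        ri <- which(df$chrom == ch)
        if (!length(bi)) next
        idx <- findInterval(df$start[ri], bins$start[bi])
        ok <- idx >= 1L & df$start[ri] < bins$end[bi][pmax(idx, 1L)]
        gc[ri[ok]] <- bins$gc[bi[idx[ok]]]
      }
      mult <- 1 + gc_bias$slope * (gc - mean(bins$gc, na.rm = TRUE))
      mult[is.na(mult)] <- 0
      mult <- pmax(mult, 0)
      keep <- stats::runif(n) < mult / max(mult)
      df <- df[keep, , drop = FALSE]
    }

    new_read_set(df, sample_id = sample_id, genome = genome)
  })
}

#' Mix two read sets at a stated contamination fraction
#'
#' Emulates the in-silico contamination protocol: a simple random sample
#' without replacement of `round((1 - c) * n_total)` reads from `a` and
#' `round(c * n_total)` reads from `b`, concatenated. The `origin` label of
#' each record is retained so test oracles can count true provenance after
#' filtering.
#'
#' To reproduce the published mixing protocol - all reads of the embryo
#' sample kept and contaminant reads added on top until they make up
#' fraction `c` - call with `n_total = nrow(a) / (1 - c)`.
#'
#' @param a embryonic [read_set()].
#' @param b contaminant [read_set()].
#' @param c contamination fraction in \[0, 1\]: the fraction of the mixture
#'   drawn from `b`.
#' @param n_total total reads in the mixture.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [read_set()] of `n_total` reads with attribute
#'   `contamination` = `c`.
#' @export
mix_samples <- function(a, b, c, n_total, seed = NULL) {
  stopifnot(inherits(a, "read_set"), inherits(b, "read_set"),
            is.numeric(c), length(c) == 1L, c >= 0, c <= 1, n_total >= 1)
  n_b <- round(c * n_total)
  n_a <- round(n_total) - n_b
  if (nrow(a) < n_a) {
    stop(sprintf("embryo source has %d reads but %d are required", nrow(a), n_a),
         call. = FALSE)
  }
  if (nrow(b) < n_b) {
    stop(sprintf("contaminant source has %d reads but %d are required",
                 nrow(b), n_b), call. = FALSE)
  }
  with_seed(seed, {
    da <- unclass(a)
    db <- unclass(b)
    if (is.null(da$origin)) da$origin <- rep(attr(a, "sample_id"), nrow(a))
    if (is.null(db$origin)) db$origin <- rep(attr(b, "sample_id"), nrow(b))
    idx_a <- sample.int(nrow(a), n_a)
    idx_b <- sample.int(nrow(b), n_b)
    cols <- c("read_id", "chrom", "start", "end",
              "n_cpg", "n_meth", "n_unmeth_ch", "origin")
    out <- structure(
      lapply(stats::setNames(cols, cols),
             function(cl) c(da[[cl]][idx_a], db[[cl]][idx_b])),
      row.names = c(NA_integer_, -(n_a + n_b)),
      class = "data.frame")
    # sources were validated at construction; subsetting preserves validity
    out <- new_read_set(out,
                        sample_id = sprintf("%s+%.0f%%%s", attr(a, "sample_id"),
                                            100 * c, attr(b, "sample_id")),
                        genome = attr(a, "genome"))
    attr(out, "contamination") <- c
    out
  })
}

#' Synthesize a diploid reference count profile
#'
#' Generates a euploid sample and aggregates its reads per bin, giving the
#' diploid reference profile against which samples are normalized. A deep
#' reference (the default 1e7 reads) keeps reference-side sampling noise
#' negligible relative to the sample being called.
#'
#' The sex chromosomes of the reference are rescaled to the diploid
#' (2-copy) scale: the reference is generated as a euploid XY sample
#' (one copy each of X and Y) and its X and Y bin counts are doubled, so
#' that normalized samples read out absolute sex-chromosome dosage
#' (chrX ~ 2 / chrY ~ 0 for XX material, 1/1 for XY).
#'
#' @param genome a [chromosome_set()].
#' @param bins a [make_bins()] bin scheme on the same genome.
#' @param n number of reference reads.
#' @param seed integer seed.
#' @param signature signature used for the reference reads; methylation
#'   content is irrelevant for counting, so any signature works.
#' @return Numeric per-bin counts with attribute `usable` (see
#'   [bin_counts()]).
#' @export
make_reference <- function(genome, bins, n = 1e7, seed = NULL,
                           signature = builtin_signatures()$blastocyst) {
  stopifnot(inherits(bins, "bin_scheme"))
  if (nrow(bins) == 0L) stop("empty bin scheme", call. = FALSE)
  has_y <- "chrY" %in% genome$chrom
  sex <- if (has_y) "XY" else "XX"
  reads <- generate_reads(signature, karyotype(NULL, sex, genome), n,
                          genome = genome, seed = seed,
                          sample_id = "reference")
  counts <- bin_counts(reads, bins)
  if (has_y) {
    sexbin <- bins$chrom %in% c("chrX", "chrY")
    u <- attr(counts, "usable")
    counts[sexbin] <- counts[sexbin] * 2
    attr(counts, "usable") <- u
  }
  counts
}
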