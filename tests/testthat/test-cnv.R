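test_that("reads are assigned to the bin containing their start", {
  g <- tiny_genome()
  bins <- tiny_bins()
  reads <- make_reads(n_cpg = rep(2, 10), n_meth = 0,
                      start = rep(41000, 10), genome = g)  # inside bin 3 of chr1
  counts <- bin_counts(reads, bins)
  i <- which(bins$chrom == "chr1" & bins$start == 40000)
  expect_equal(unname(counts[i]), 10)
  expect_equal(sum(counts), 10)

  # a start exactly at a boundary belongs to the bin it opens
  edge <- make_reads(n_cpg = 2, n_meth = 0, start = 20000, genome = g)
  counts2 <- bin_counts(edge, bins)
  expect_equal(unname(counts2[bins$chrom == "chr1" & bins$start == 20000]), 1)

  bad <- make_reads(n_cpg = 2, n_meth = 0, chrom = "chrZ")
  expect_error(bin_counts(bad, bins), "chrZ")
})

test_that("blacklisted bins receive no counts and are unusable", {
  g <- tiny_genome()
  bins <- tiny_bins()
  bins$blacklist[3] <- TRUE
  reads <- make_reads(n_cpg = rep(2, 5), n_meth = 0,
                      start = bins$start[3] + 5, genome = g)
  counts <- bin_counts(reads, bins)
  expect_equal(unname(counts[3]), 0)
  expect_false(attr(counts, "usable")[3])
})

test_that("euploid bin counts are proportional to bin length", {
  # multinomial oracle at 1e6 simulated reads, equal-width bins
  bins <- tiny_bins()
  ref <- tiny_reference()
  inner <- bins$end - bins$start == 20000  # drop ragged terminal bins
  m <- mean(ref[inner])
  p <- 1 / sum(inner)
  se <- sqrt(sum(ref) * p * (1 - p))
  dev <- abs(ref[inner] - m)
  expect_lt(mean(dev > 3 * se), 0.01)  # ~0.27% expected beyond 3 SE
})

test_that("GC correction leaves unbiased counts alone and preserves the mean", {
  g <- tiny_genome()
  bins <- tiny_bins()
  flat <- rep(100, nrow(bins))
  corr <- gc_correct(flat, bins)
  expect_equal(as.numeric(corr), flat, tolerance = 1e-9)

  set.seed(9)
  noisy <- rpois(nrow(bins), 200)
  corr2 <- gc_correct(noisy, bins)
  u <- attr(corr2, "usable")
  expect_lt(abs(mean(corr2[u]) / mean(noisy[u]) - 1), 1e-6)
  expect_error(gc_correct(flat[1:10], bins[1:10, ]), "20 usable")
})

test_that("GC correction removes an injected linear GC bias", {
  # regression oracle: slope/correlation with GC vanish after correction
  g <- chromosome_set("chr1", 1e7)  # 500 bins of 20 kb
  bins <- make_bins(g, bin_size = 2e4, gc_noise = 0.03)
  set.seed(10)
  base <- 400
  lambda <- base * (1 + 2.5 * (bins$gc - mean(bins$gc)))
  counts <- rpois(nrow(bins), pmax(lambda, 1))
  expect_gt(cor(counts, bins$gc), 0.5)  # bias really is there
  corr <- gc_correct(counts, bins)
  u <- attr(corr, "usable")
  expect_lt(abs(cor(corr[u], bins$gc[u])), 0.05)
})

test_that("the simulator's GC-bias hook produces correctable counts", {
  g <- tiny_genome()
  bins <- tiny_bins()
  sig <- builtin_signatures()$blastocyst
  biased <- generate_reads(sig, n = 3e5, genome = g, seed = 77,
                           gc_bias = list(bins = bins, slope = 2))
  counts <- bin_counts(biased, bins)
  inner <- bins$end - bins$start == 20000
  expect_gt(cor(counts[inner], bins$gc[inner]), 0.3)
  corr <- gc_correct(counts, bins)
  u <- attr(corr, "usable") & inner
  expect_lt(abs(cor(corr[u], bins$gc[u])), 0.05)
})

test_that("normalization against the reference recovers copy number", {
  bins <- tiny_bins()
  ref <- tiny_reference()
  # sample identical to reference: every usable bin sits at CN 2
  prof <- normalize_to_reference(ref, ref, bins)
  expect_true(all(abs(prof$cn[prof$usable] - 2) < 1e-12))

  # scaling chr3 counts by 1.5 yields CN ~3 there, shrunk by the extra
  # normalization mass the gained chromosome contributes (construction oracle)
  scaled <- as.numeric(ref)
  on3 <- bins$chrom == "chr3"
  scaled[on3] <- scaled[on3] * 1.5
  attr(scaled, "usable") <- attr(ref, "usable")
  prof3 <- normalize_to_reference(scaled, ref, bins)
  s <- chromosome_summary(prof3)
  mass <- 1 + 0.5 * sum(ref[on3]) / sum(ref)
  expect_equal(unname(s["chr3"]), 3 / mass, tolerance = 0.02)
  expect_equal(unname(s["chr1"]), 2 / mass, tolerance = 0.02)

  # zero reference bins are flagged unusable, not divided
  ref0 <- as.numeric(ref); ref0[5] <- 0
  prof0 <- normalize_to_reference(ref, ref0, bins)
  expect_false(prof0$usable[5])
})

test_that("profiles are invariant under count rescaling", {
  bins <- tiny_bins()
  ref <- tiny_reference()
  set.seed(11)
  sample_counts <- rpois(nrow(bins), 150)
  a <- normalize_to_reference(sample_counts, ref, bins)
  b <- normalize_to_reference(sample_counts * 7.3, ref, bins)
  expect_equal(a$cn, b$cn, tolerance = 1e-12)
})

test_that("GC correction commutes with normalization on bias-free data", {
  bins <- tiny_bins()
  ref <- tiny_reference()
  flat <- rep(120, nrow(bins))
  direct <- normalize_to_reference(flat, ref, bins)
  via_gc <- normalize_to_reference(gc_correct(flat, bins), ref, bins)
  expect_equal(direct$cn[direct$usable], via_gc$cn[via_gc$usable],
               tolerance = 1e-6)
})

test_that("chromosome summaries are medians over usable bins", {
  prof <- fake_profile(list(chr1 = c(2, 2, 2, 3, 2),
                            chr2 = c(3, 3, 3, 2, 3),
                            chr3 = c(2, 2)))
  s <- chromosome_summary(prof, min_bins = 5)
  expect_equal(unname(s["chr1"]), 2)
  expect_equal(unname(s["chr2"]), 3)
  expect_true(is.na(s["chr3"]))  # below min_bins: undefined
})

test_that("karyotype calls follow the inclusive threshold rule", {
  euploid <- fake_profile(genome_layout(sex = "XX"))
  call <- call_karyotype(euploid)
  expect_equal(call$ploidy, "euploid")
  expect_equal(call$sex, "XX")
  expect_equal(length(call$aberrations), 0L)

  tri22 <- fake_profile(genome_layout(chr22 = 3, sex = "XX"))
  call22 <- call_karyotype(tri22)
  expect_equal(unname(call22$state["chr22"]), "gain")
  expect_equal(call22$ploidy, "aneuploid")

  # threshold sweep: 2.4 is neutral at 1.5&2.5 but a gain at 1.6&2.4
  mosaic <- fake_profile(genome_layout(chr16 = 2.4, sex = "XY"))
  expect_equal(unname(call_karyotype(mosaic)$state["chr16"]), "neutral")
  expect_equal(unname(call_karyotype(mosaic,
                                     threshold_pair(1.6, 2.4))$state["chr16"]),
               "gain")
  expect_equal(call_karyotype(mosaic, threshold_pair(1.6, 2.4))$sex, "XY")

  # boundary values themselves trigger calls (detection limits)
  edge <- fake_profile(genome_layout(chr4 = 1.5, sex = "XX"))
  expect_equal(unname(call_karyotype(edge)$state["chr4"]), "loss")

  # monosomy X without Y: dosage anomaly -> undetermined sex, aneuploid
  xo <- fake_profile(genome_layout(chrX = 1, chrY = 0, sex = "XX"))
  xo_call <- call_karyotype(xo)
  expect_equal(xo_call$sex, "undetermined")
  expect_equal(xo_call$ploidy, "aneuploid")

  few <- fake_profile(list(chr1 = rep(2, 10), chr2 = rep(2, 10)))
  expect_error(call_karyotype(few), "low-quality")
  expect_error(threshold_pair(2.1, 2.5), "loss")
})

test_that("pure simulated karyotypes are recovered within tolerance", {
  # parameter recovery: autosomal summaries deviate < 0.15 at 1e6 reads
  g <- scaled_genome()
  bins <- scaled_bins()
  ref <- scaled_reference()
  k <- karyotype("-16,+18", "XY", g)
  reads <- generate_reads(builtin_signatures()$blastocyst, k, 1e6, g,
                          seed = 61)
  counts <- gc_correct(bin_counts(reads, bins), bins)
  prof <- normalize_to_reference(counts, ref, bins)
  s <- chromosome_summary(prof)
  auto <- !(names(s) %in% c("chrX", "chrY"))
  truth <- k$cn[names(s)[auto]]
  expect_lt(mean(abs(s[auto] - truth)), 0.15)
  call <- call_karyotype(prof)
  expect_equal(unname(call$state[c("chr16", "chr18")]), c("loss", "gain"))
  expect_equal(call$sex, "XY")
})

test_that("50% cumulus contamination dilutes a trisomy to the detection edge", {
  # a simulated trisomy-22 embryo mixed 1:1 with cumulus reads shows a
  # chr22 summary near 2.5
  g <- scaled_genome()
  bins <- scaled_bins()
  ref <- scaled_reference()
  emb <- generate_reads(builtin_signatures()$blastocyst,
                        karyotype("+22", "XX", g), 5e5, g, seed = 62)
  cum <- generate_reads(builtin_signatures()$cumulus,
                        karyotype(NULL, "XX", g), 5e5, g, seed = 63)
  mix <- mix_samples(emb, cum, c = 0.5, n_total = 1e6, seed = 64)
  counts <- gc_correct(bin_counts(mix, bins), bins)
  prof <- normalize_to_reference(counts, ref, bins)
  expect_equal(unname(chromosome_summary(prof)["chr22"]), 2.5,
               tolerance = 0.1 / 2.5)
})
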