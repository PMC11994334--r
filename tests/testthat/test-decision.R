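test_that("the expected-signal model reproduces the dilution arithmetic", {
  # 50% diploid contamination halves a 1&3 aneuploidy signal to 1.5&2.5
  expect_equal(expected_mixture_cn(1, 0.5), 1.5)
  expect_equal(expected_mixture_cn(3, 0.5), 2.5)
  # unmethylated-read selection (0.47 vs 0.12) lifts it back to 1.2&2.8
  expect_equal(round_half_up(expected_mixture_cn(1, 0.5, 0.47, 0.12), 1), 1.2)
  expect_equal(round_half_up(expected_mixture_cn(3, 0.5, 0.47, 0.12), 1), 2.8)
  # at 75% contamination: 1.75&2.25 raw, 1.43&2.57 after selection
  expect_equal(expected_mixture_cn(1, 0.75), 1.75)
  expect_equal(expected_mixture_cn(3, 0.75), 2.25)
  expect_equal(round_half_up(expected_mixture_cn(1, 0.75, 0.47, 0.12), 2), 1.43)
  expect_equal(round_half_up(expected_mixture_cn(3, 0.75, 0.47, 0.12), 2), 2.57)
  # no contamination: the embryonic copy number itself
  expect_equal(expected_mixture_cn(3, 0, 0.47, 0.12), 3)
})

test_that("expected mixture CN is monotone toward 2 and fixed at 2", {
  cs <- seq(0, 1, by = 0.05)
  for (cn in c(0, 1, 3, 4)) {
    v <- vapply(cs, function(c) expected_mixture_cn(cn, c, 0.47, 0.12), 0)
    d <- diff(v)
    if (cn < 2) expect_true(all(d >= -1e-12)) else expect_true(all(d <= 1e-12))
    expect_equal(v[length(v)], 2)
  }
  expect_true(all(vapply(cs, function(c)
    expected_mixture_cn(2, c, 0.9, 0.1), 0) == 2))
})

test_that("stage combination requires same-direction agreement", {
  states <- c("loss", "neutral", "gain", "undetermined")
  grid <- expand.grid(pre = states, post = states,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    pre <- stats::setNames(grid$pre[i], "chr1")
    post <- stats::setNames(grid$post[i], "chr1")
    final <- secmdecon:::combine_states(pre, post, "integrated")
    if (grid$pre[i] == grid$post[i] && grid$pre[i] %in% c("loss", "gain")) {
      expect_equal(unname(final), grid$pre[i])
    } else {
      # a direction contradiction or any non-crossing stage never yields a call
      expect_false(final %in% c("loss", "gain"))
    }
    # the AND rule can only remove calls relative to either single stage
    for (mode in c("pre_only", "decon_only")) {
      single <- secmdecon:::combine_states(pre, post, mode)
      if (final %in% c("loss", "gain")) {
        expect_equal(unname(final), unname(single))
      }
    }
  }
})

test_that("integrated calls confirm diluted aneuploidy and suppress discordance", {
  g <- tiny_genome()
  bins <- tiny_bins()
  ref <- tiny_reference()
  sig <- builtin_signatures()
  # embryo with a chr2 loss, 50% cumulus contamination
  emb <- generate_reads(sig$blastocyst, karyotype("-2", "XX", g), 2e5, g,
                        seed = 71)
  cum <- generate_reads(sig$cumulus, karyotype(NULL, "XX", g), 2e5, g,
                        seed = 72)
  mix <- mix_samples(emb, cum, c = 0.5, n_total = 2e5, seed = 73)
  res <- integrated_call(mix, bins, ref, min_autosomes = 3L)
  expect_s3_class(res, "nipgt_call")
  # raw stage shows the mosaic-level loss (~1.5), post stage the full loss (~1.2)
  expect_equal(unname(res$state["chr2"]), "loss")
  expect_equal(res$ploidy, "aneuploid")
  expect_lt(res$audit$post_cn[res$audit$chrom == "chr2"],
            res$audit$pre_cn[res$audit$chrom == "chr2"])
  expect_gt(res$retention, 0.05)

  # integrated non-neutral set is contained in each single-stage set
  for (mode in c("pre_only", "decon_only")) {
    single <- integrated_call(mix, bins, ref, min_autosomes = 3L,
                              config = decision_config(mode = mode))
    nn_int <- names(res$state)[res$state %in% c("loss", "gain")]
    nn_one <- names(single$state)[single$state %in% c("loss", "gain")]
    expect_true(all(nn_int %in% nn_one))
  }
})

test_that("euploid contaminated samples stay euploid", {
  g <- tiny_genome()
  bins <- tiny_bins()
  ref <- tiny_reference()
  sig <- builtin_signatures()
  emb <- generate_reads(sig$blastocyst, karyotype(NULL, "XX", g), 1e5, g,
                        seed = 81)
  cum <- generate_reads(sig$cumulus, karyotype(NULL, "XX", g), 1e5, g,
                        seed = 82)
  for (c_frac in c(0, 0.5, 0.9)) {
    mix <- mix_samples(emb, cum, c = c_frac, n_total = 1e5, seed = 83)
    res <- integrated_call(mix, bins, ref, min_autosomes = 3L)
    expect_equal(res$ploidy, "euploid")
  }
})

test_that("thin post-filter read sets are flagged, never silently dropped", {
  g <- tiny_genome()
  bins <- tiny_bins()
  ref <- tiny_reference()
  emb <- generate_reads(builtin_signatures()$blastocyst,
                        karyotype(NULL, "XX", g), 3e4, g, seed = 91)
  res <- integrated_call(emb, bins, ref, min_autosomes = 3L,
                         config = decision_config(min_post_reads = 1e5))
  expect_true("low_confidence_post_filter" %in% res$flags)
  expect_equal(res$ploidy, "euploid")

  # a read set emptied by the filter still returns a call object
  hyper_sig <- cell_signature("hyper", 0, 0, 1,
                              cpg_histogram = c(0, 0, 0.5, 0.5, 0))
  hyper <- generate_reads(hyper_sig, karyotype(NULL, "XX", g), 3e4, g,
                          seed = 93)
  expect_warning(
    res2 <- integrated_call(hyper, bins, ref, min_autosomes = 3L,
                            config = decision_config(min_post_reads = 10)),
    "every read")
  expect_true("empty_post_filter" %in% res2$flags)
  expect_true(all(res2$state == "undetermined"))
})

test_that("QC enforcement refuses under-sequenced samples when asked", {
  g <- tiny_genome()
  emb <- generate_reads(builtin_signatures()$blastocyst,
                        karyotype(NULL, "XX", g), 1e3, g, seed = 92)
  expect_error(integrated_call(emb, tiny_bins(), tiny_reference(),
                               min_autosomes = 3L, enforce_qc = TRUE),
               "QC")
})

test_that("decision config round-trips through YAML", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("decision:",
               "  pre_loss: 1.7", "  pre_gain: 2.3",
               "  post_loss: 1.5", "  post_gain: 2.5",
               "  min_cpg: 3", "  mode: decon_only"), path)
  cfg <- read_decision_config(path)
  expect_equal(cfg$pre_thresholds$loss, 1.7)
  expect_equal(cfg$pre_thresholds$gain, 2.3)
  expect_equal(cfg$filter_policy$min_cpg, 3L)
  expect_equal(cfg$mode, "decon_only")
  expect_equal(cfg$post_thresholds$gain, 2.5)
})
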