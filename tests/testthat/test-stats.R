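# Enrichment folds, interval shuffling, permutation Z-tests.

test_that("enrichment folds reproduce the insertion-targeting arithmetic", {
  expect_equal(round(as.numeric(enrichment_fold(0.287, 0.11)), 2), 2.61)
  expect_equal(as.numeric(enrichment_fold(0.17, 0.17)), 1)
  folds <- c(enrichment_fold(0.287, 0.11), enrichment_fold(0.511, 0.11),
             enrichment_fold(0.679, 0.17), enrichment_fold(0.305, 0.17))
  expect_equal(round(mean(as.numeric(folds)), 2), 3.26)
  expect_true(attr(enrichment_fold(0.5, 0), "undefined"))
})

test_that("shuffling preserves lengths and respects gaps, deterministically", {
  layout <- flat_layout(1e6)
  iv <- data.frame(contig = "chr1", start = c(100L, 5000L, 40000L),
                   end = c(400L, 6500L, 41000L))
  s1 <- shuffle_intervals(iv, layout, seed = 9L)
  s2 <- shuffle_intervals(iv, layout, seed = 9L)
  expect_identical(s1, s2)
  expect_equal(s1$end - s1$start, iv$end - iv$start)   # exact conservation
  expect_true(all(s1$start >= 0 & s1$end <= 1e6))

  gappy <- flat_layout(1e6, data.frame(contig = "chr1", start = 0L,
                                       end = 900000L))
  for (seed in 1:50) {
    s <- shuffle_intervals(iv[1, , drop = FALSE], gappy, seed = seed)
    expect_gte(s$start, 900000L)
    expect_lte(s$end, 1e6)
  }
  huge <- data.frame(contig = "chr1", start = 0L, end = 200000L)
  expect_error(shuffle_intervals(huge, gappy), "does not fit")
})

test_that("shuffled placements are uniform over the mappable genome", {
  layout <- flat_layout(1e6)
  iv <- data.frame(contig = "chr1", start = 0L, end = 100L)
  starts <- vapply(1:1000, function(s)
    shuffle_intervals(iv, layout, seed = s)$start, numeric(1))
  bins <- table(cut(starts, breaks = seq(0, 1e6, length.out = 11)))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("permutation Z-test finds planted enrichment and is order-invariant", {
  layout <- flat_layout(1e6)
  set.seed(3)
  # features cover ~5% of the genome
  fs <- sort(sample.int(950000L, 100L))
  features <- data.frame(contig = "chr1", start = fs, end = fs + 500L)
  # intervals planted strictly inside features
  pick <- sample(100L, 40L, replace = TRUE)
  planted <- data.frame(contig = "chr1", start = fs[pick] + 10L,
                        end = fs[pick] + 110L)
  cfg <- stats_config(n_permutations = 1000L, sidedness = "greater",
                      seed = 17L)
  res <- permutation_ztest(planted, features, layout, cfg, label = "planted")
  expect_gt(res$z, 3)
  expect_lte(res$p, 0.05)
  expect_true(res$significant)
  expect_equal(res$observed_fraction, 1)

  perm <- planted[sample(nrow(planted)), ]
  res2 <- permutation_ztest(perm, features, layout, cfg)
  expect_equal(res2$p, res$p)
  expect_equal(res2$z, res$z)
})

test_that("observed at the null mean gives z near zero; degenerate nulls flag", {
  layout <- flat_layout(1e6)
  features <- data.frame(contig = "chr1", start = 0L, end = 500000L)
  iv <- data.frame(contig = "chr1", start = (1:50) * 1000L,
                   end = (1:50) * 1000L + 100L)
  cfg <- stats_config(n_permutations = 500L, sidedness = "two_sided",
                      seed = 5L)
  res <- permutation_ztest(iv, features, layout, cfg,
                           observed_stat = NULL)
  # forcing the observed statistic onto the null mean
  res0 <- permutation_ztest(iv, features, layout, cfg,
                            observed_stat = res$expected_fraction)
  expect_lt(abs(res0$z), 0.05)
  expect_gt(res0$p, 0.9)

  empty_feats <- features[0, ]
  resd <- exon_depletion_test(iv, empty_feats, layout,
                              stats_config(n_permutations = 200L, seed = 2L))
  expect_true(resd$degenerate)
  expect_equal(resd$observed_fraction, 0)
  expect_error(permutation_ztest(iv, features, layout,
                                 stats_config(n_permutations = 100L)),
               NA)
  expect_error(stats_config(n_permutations = 50L))
})

test_that("exon depletion is detected for variants planted outside exons", {
  layout <- flat_layout(1e6)
  set.seed(8)
  es <- seq(10000L, 960000L, by = 32000L)
  exons <- data.frame(contig = "chr1", start = es, end = es + 1000L)  # ~3%
  # ~200 variants dodging exons entirely
  vs <- as.integer(outer(es, seq(2000L, 29000L, by = 4000L), "+"))
  variants <- data.frame(contig = "chr1", start = vs, end = vs + 400L)
  cfg <- stats_config(n_permutations = 1000L, seed = 23L)
  res <- exon_depletion_test(variants, exons, layout, cfg)
  expect_equal(res$observed_fraction, 0)
  expect_lte(res$p, 0.05)
  expect_equal(res$sidedness, "less")
})

test_that("exonic fraction counts any-overlap, with insertion points", {
  exons <- data.frame(contig = "chr1", start = c(100L, 1000L),
                      end = c(200L, 1200L))
  all_in <- data.frame(contig = "chr1", start = c(110L, 1050L),
                       end = c(150L, 1100L))
  expect_equal(exonic_fraction(all_in, exons), 1)
  none <- data.frame(contig = "chr1", start = c(300L, 5000L),
                     end = c(400L, 5100L))
  expect_equal(exonic_fraction(none, exons), 0)
  mix <- data.frame(contig = "chr1",
                    start = c(150L, rep(3000L, 19L)),
                    end = c(150L, rep(3100L, 19L)))  # 1 exonic point of 20
  expect_equal(exonic_fraction(mix, exons), 0.05)
})
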