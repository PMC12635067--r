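# Quality/chimera filtering rules, report accounting, substitution spectrum.

test_that("SV filter applies the type/filter/length/support/depth rules", {
  cfg <- filter_config()
  calls <- rbind(
    sv_calls(call_id = "inv", contig = "c", start = 0L, end = 100L,
             svtype = "INV", length = 100L, support = 30L, depth = 60L,
             filter = "PASS", sample_id = "s"),
    del_call("short", 0, 49),                      # 49 bp
    del_call("floor", 1000, 1050),                 # exactly 50 bp
    del_call("lowsup", 2000, 2500, support = 2L, depth = 9L),
    del_call("lowdep", 3000, 3500, support = 3L, depth = 4L),
    del_call("nopass", 4000, 4500) |> transform(filter = "LowQual"),
    del_call("good", 5000, 5500, support = 3L, depth = 5L))
  res <- filter_sv_calls(calls, cfg)
  expect_setequal(res$calls$call_id, c("floor", "good"))
  rej <- setNames(res$report$rejections$n_rejected,
                  res$report$rejections$rule)
  expect_equal(unname(rej["type"]), 1L)
  expect_equal(unname(rej["length"]), 1L)
  expect_equal(unname(rej["support"]), 1L)
  expect_equal(unname(rej["depth"]), 1L)
  expect_equal(unname(rej["filter"]), 1L)
  # conservation: input = retained + rejections
  expect_equal(res$report$n_input,
               res$report$n_retained + sum(res$report$rejections$n_rejected))
})

test_that("missing support or depth rejects under an explicit rule", {
  calls <- del_call("nosup", 0, 500)
  calls$support <- NA_integer_
  res <- filter_sv_calls(calls)
  expect_equal(nrow(res$calls), 0L)
  rej <- res$report$rejections
  expect_equal(rej$n_rejected[rej$rule == "missing_field"], 1L)
})

test_that("small-variant filter enforces depth, support, PASS and GQ tiers", {
  mk <- function(id, depth, sup, filter = "PASS", gq = 25L) {
    small_variants(variant_id = id, contig = "c", pos = 100L, ref = "C",
                   alt = "T", filter = filter, genotype = "0/1", gq = gq,
                   depth = depth, alt_support = sup, sample_id = "s")
  }
  calls <- rbind(mk("keep", 5L, 3L), mk("lowdep", 4L, 4L),
                 mk("lowsup", 9L, 2L), mk("gq19", 20L, 10L, gq = 19L))
  res <- filter_small_variants(calls, highconf = TRUE)
  expect_equal(res$calls$variant_id, "keep")
  rej <- setNames(res$report$rejections$n_rejected,
                  res$report$rejections$rule)
  expect_equal(unname(rej["depth"]), 1L)
  expect_equal(unname(rej["support"]), 1L)
  expect_equal(unname(rej["gq"]), 1L)
  # without the high-confidence tier GQ 19 survives
  res2 <- filter_small_variants(calls, highconf = FALSE)
  expect_setequal(res2$calls$variant_id, c("keep", "gq19"))
})

test_that("filtering is idempotent and monotone in its thresholds", {
  set.seed(42)
  n <- 300L
  calls <- sv_calls(
    call_id = sprintf("v%03d", 1:n), contig = "c",
    start = s <- sample.int(1e6, n), end = s,
    svtype = sample(c("DEL", "INS", "INV", "DUP"), n, replace = TRUE),
    length = sample(10:2000, n, replace = TRUE),
    support = sample(0:12, n, replace = TRUE),
    depth = sample(0:30, n, replace = TRUE),
    filter = sample(c("PASS", "LowQual"), n, replace = TRUE),
    sample_id = "s")
  calls$end <- ifelse(calls$svtype == "INS", calls$start,
                      calls$start + calls$length)
  cfg <- filter_config()
  once <- filter_sv_calls(calls, cfg)
  twice <- filter_sv_calls(once$calls, cfg)
  expect_equal(twice$calls, once$calls, ignore_attr = TRUE)
  expect_equal(twice$report$n_retained, once$report$n_retained)

  prev <- Inf
  for (minsup in 0:8) {
    r <- filter_sv_calls(calls, filter_config(min_support = minsup))
    expect_lte(r$report$n_retained, prev)
    prev <- r$report$n_retained
  }
  prev <- Inf
  for (mindep in c(0, 3, 5, 10, 20)) {
    r <- filter_sv_calls(calls, filter_config(min_locus_depth = mindep))
    expect_lte(r$report$n_retained, prev)
    prev <- r$report$n_retained
  }
})

test_that("substitution spectrum collapses purine references", {
  mk <- function(ref, alt, n = 1L) {
    small_variants(variant_id = sprintf("%s%s%d", ref, alt, seq_len(n)),
                   contig = "c", pos = seq_len(n), ref = ref, alt = alt,
                   sample_id = "s")
  }
  snvs <- rbind(mk("G", "A", 2L), mk("C", "T", 2L), mk("T", "C", 1L))
  spec <- compute_substitution_spectrum(snvs)
  expect_equal(unname(spec["C>T"]), 0.8)   # G>A counted as C>T
  expect_equal(unname(spec["T>C"]), 0.2)
  expect_equal(sum(spec), 1)

  one <- compute_substitution_spectrum(mk("A", "G"))
  expect_equal(unname(one["T>C"]), 1)

  empty <- compute_substitution_spectrum(small_variants())
  expect_true(attr(empty, "empty"))
  expect_equal(sum(empty), 0)
})

test_that("generated noise SNVs reproduce the configured C>T bias", {
  cfg <- sim_config(contig_length = 1e6, gap_fraction = 0,
                    n_germline_sv = 0L, n_mosaic_nahr = 0L,
                    n_te_insertions = 0L, n_germline_snv = 0L,
                    artifact_rate = 0, noise_snv_per_cell = 1700,
                    snv_ct_bias = 0.5, seed = 31L)
  layout <- generate_genome_layout(cfg)
  truth <- simulate_truth(layout, plant_te_annotation(layout, cfg), cfg)
  rend <- render_callsets(truth, layout, cfg)
  snvs <- do.call(rbind, lapply(rend$cells, function(x) x$snv))
  spec <- compute_substitution_spectrum(snvs)
  n <- attr(spec, "n")
  expect_gt(n, 5000L)
  sd3 <- 3 * sqrt(0.5 * 0.5 / n)
  expect_lt(abs(spec[["C>T"]] - 0.5), sd3)
})
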