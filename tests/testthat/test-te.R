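# TE content annotation, Alu subfamily grouping, full-length detection,
# NAHR classification, insertion-site targeting.

test_that("per-family coverage and dominant family follow the max rule", {
  ins <- ins_call("i1", 100, 300)
  hits <- data.frame(query = "i1", start = 0L, end = 300L, strand = "+",
                     subfamily = "AluYa5", family = "SINE/Alu",
                     divergence = 1.2)
  ann <- annotate_variant_te(ins[1, ], hits)
  expect_equal(ann$family, "SINE/Alu")
  expect_equal(ann$covered_fraction, 1)
  expect_true(ann$dominant)

  del <- del_call("d1", 0, 1000)
  hits2 <- rbind(
    data.frame(query = "d1", start = 0L, end = 250L, strand = "+",
               subfamily = "AluSx", family = "SINE/Alu", divergence = 8),
    data.frame(query = "d1", start = 400L, end = 800L, strand = "+",
               subfamily = "L1PA3", family = "LINE/L1", divergence = 5))
  ann2 <- annotate_variant_te(del[1, ], hits2)
  expect_equal(ann2$family[ann2$dominant], "LINE/L1")
  expect_equal(sort(ann2$covered_fraction), c(0.25, 0.4))

  none <- annotate_variant_te(del[1, ], hits2[0, ])
  expect_equal(nrow(none), 0L)
})

test_that("Alu subfamily group needs one element above the 80% threshold", {
  cfg <- te_config()
  mk_hit <- function(sub, frac, len = 300L) {
    data.frame(query = "i", start = 0L, end = as.integer(round(frac * len)),
               strand = "+", subfamily = sub, family = "SINE/Alu",
               divergence = 2)
  }
  v <- list(length = 300L)
  expect_equal(assign_alu_subfamily(v, mk_hit("AluSc", 0.85), cfg), "AluS")
  expect_equal(assign_alu_subfamily(v, mk_hit("AluYb8", 0.95), cfg), "AluY")
  expect_equal(assign_alu_subfamily(v, mk_hit("AluJo", 0.9), cfg), "AluJ")
  expect_equal(assign_alu_subfamily(v, mk_hit("AluY", 0.60), cfg), "none")
  expect_equal(assign_alu_subfamily(v, mk_hit("L1", 0)[0, ], cfg), "none")
  # assignment is a partition: always exactly one group
  set.seed(5)
  for (i in 1:25) {
    sub <- sample(c("AluY", "AluYa5", "AluSx", "AluSc", "AluJb"), 1)
    frac <- runif(1)
    got <- assign_alu_subfamily(v, mk_hit(sub, frac), cfg)
    expect_length(got, 1L)
    expect_true(got %in% c("AluY", "AluS", "AluJ", "none"))
  }
})

test_that("full-length detection compares masked length to consensus", {
  cfg <- te_config()
  alu295 <- data.frame(start = 0L, end = 295L, family = "SINE/Alu")
  expect_true(full_length_flag(alu295, cfg))
  l1frag <- data.frame(start = 0L, end = 1200L, family = "LINE/L1")
  expect_false(full_length_flag(l1frag, cfg))          # 1200 / 6000
  boundary <- data.frame(start = 0L, end = 270L, family = "SINE/Alu")
  expect_true(full_length_flag(boundary, cfg))         # exactly 0.9
  unk <- data.frame(start = 0L, end = 100L, family = "DNA/hAT")
  res <- full_length_flag(unk, cfg)
  expect_true(attr(res, "unknown_family"))
})

test_that("NAHR verdicts follow breakpoint same-family pairs", {
  cfg <- te_config(breakpoint_window = 50L)
  els <- rbind(
    te_row("E1", 1000, 1300, "SINE/Alu", "AluSc"),
    te_row("E2", 5000, 5300, "SINE/Alu", "AluSg"),
    te_row("E3", 9000, 15000, "LINE/L1", "L1PA2"))
  # breakpoints inside AluSc and AluSg -> NAHR-consistent
  d <- del_call("d1", 1100, 5100)
  cl <- classify_nahr(d[1, ], els, cfg)
  expect_true(cl$same_family)
  expect_equal(cl$family, "SINE/Alu")
  expect_setequal(c(cl$left_element$element_id, cl$right_element$element_id),
                  c("E1", "E2"))
  # family mismatch (Alu left, L1 right)
  d2 <- del_call("d2", 1100, 9100)
  expect_false(classify_nahr(d2[1, ], els, cfg)$same_family)
  # one element spanning the whole deletion never counts as a pair
  d3 <- del_call("d3", 9500, 14000)
  cl3 <- classify_nahr(d3[1, ], els, cfg)
  expect_false(cl3$same_family)
  expect_equal(cl3$left_element$element_id, "E3")
  expect_equal(cl3$right_element$element_id, "E3")
})

test_that("NAHR classifier agrees with brute-force pair enumeration", {
  cfg <- te_config(breakpoint_window = 50L)
  for (seed in 1:20) {
    inst <- random_nahr_instance(seed)
    got <- classify_nahr_all(inst$deletions, inst$elements, cfg)
    for (i in seq_len(nrow(inst$deletions))) {
      want <- brute_force_nahr(inst$deletions[i, ], inst$elements, 50L)
      expect_identical(got$same_family[i], want)
    }
  }
})

test_that("insertion targeting reports the containing reference family", {
  els <- rbind(
    te_row("E1", 1000, 1300, "SINE/Alu", "AluSx"),
    te_row("E2", 9000, 15000, "LINE/L1", "L1PA3"))
  ins <- data.frame(call_id = c("a", "b", "c"), contig = "chr1",
                    start = c(1100L, 500L, 9100L),
                    stringsAsFactors = FALSE)
  out <- insertion_target_class(ins, els,
                                dominant_family = c("SINE/Alu", "SINE/Alu",
                                                    "LINE/L1"))
  expect_equal(out$target_family, c("SINE/Alu", NA, "LINE/L1"))
  expect_equal(out$same_family, c(TRUE, FALSE, TRUE))
  expect_equal(out$target_element, c("E1", NA, "E2"))
})
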