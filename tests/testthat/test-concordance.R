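# sc/bulk matching, sharing classification, dropout accounting, ratios,
# population removal, VAF/occurrence bookkeeping.

test_that("match_sv applies distance, size-ratio and type rules", {
  cfg <- match_config()
  a <- del_call("a", 10000, 10500)
  b <- del_call("b", 10020, 10500)
  expect_true(match_sv(a, b, cfg))              # distance 20, ratio 0.96
  expect_true(match_sv(b, a, cfg))              # symmetric
  c2 <- del_call("c", 10000, 10200)             # ratio 0.4
  expect_false(match_sv(a, c2, cfg))
  i <- ins_call("i", 10000, 500)
  expect_false(match_sv(a, i, cfg))             # type-strict
  far <- del_call("f", 10600, 11100)
  expect_false(match_sv(a, far, cfg))           # distance 600
})

make_sharing_fixture <- function() {
  # two cells call the same DEL + INS; bulk has both plus one extra DEL
  # inside callable space and one DEL outside any cell's callable region
  cells <- list(
    cellA = rbind(del_call("A.del", 10000, 10500, sample_id = "cellA"),
                  ins_call("A.ins", 50010, 300, sample_id = "cellA")),
    cellB = rbind(del_call("B.del", 10015, 10480, sample_id = "cellB",
                           support = 14L),
                  ins_call("B.ins", 50000, 310, sample_id = "cellB")))
  bulk <- rbind(
    del_call("bulk.del", 10005, 10505, sample_id = "bulk", vaf = 0.5),
    ins_call("bulk.ins", 50005, 305, sample_id = "bulk", vaf = 0.45),
    del_call("bulk.extra", 200000, 200400, sample_id = "bulk",
             genotype = "0/1", vaf = 0.22),
    del_call("bulk.dark", 800000, 800400, sample_id = "bulk", vaf = 0.5))
  cov <- list(
    cellA = data.frame(contig = "chr1", start = c(0L, 400000L),
                       end = c(300000L, 500000L), depth = c(10L, 0L)),
    cellB = data.frame(contig = "chr1", start = 0L, end = 300000L,
                       depth = 8L),
    bulk = full_track(1e6, 50L))
  list(cells = cells, bulk = bulk, cov = cov)
}

test_that("sharing classification partitions variants by category", {
  f <- make_sharing_fixture()
  rec <- classify_sharing(f$cells, f$bulk, f$cov)
  expect_setequal(rec$category[rec$variant_id == "bulk.extra"], "bulk_only")
  # bulk.dark is outside both cells' callable regions -> excluded entirely
  expect_false("bulk.dark" %in% rec$variant_id)
  expect_equal(attr(rec, "n_bulk_excluded"), 1L)
  # merged DEL and INS both match bulk
  sc <- rec[rec$category != "bulk_only", ]
  expect_equal(nrow(sc), 2L)
  expect_setequal(sc$category, "shared")
  expect_equal(sort(unique(sc$n_cells_carrying)), 2L)
  # recall 1.0 on this noise-free fixture
  expect_equal(unname(sc_recall(rec)[c("DEL", "INS")]), c(1, 1))
  # merged representative is the highest-support member
  expect_equal(sc$support[sc$svtype == "DEL"], 14L)
})

test_that("classification is independent of input row order", {
  f <- make_sharing_fixture()
  rec1 <- classify_sharing(f$cells, f$bulk, f$cov)
  f2 <- f
  f2$cells <- rev(f2$cells)
  f2$cells$cellA <- f2$cells$cellA[rev(seq_len(nrow(f2$cells$cellA))), ]
  f2$bulk <- f2$bulk[rev(seq_len(nrow(f2$bulk))), ]
  rec2 <- classify_sharing(f2$cells, f2$bulk, f2$cov)
  expect_equal(table(rec1$category, rec1$svtype),
               table(rec2$category, rec2$svtype))
})

test_that("missing coverage for a cell is a hard, named error", {
  f <- make_sharing_fixture()
  f$cov$cellB <- NULL
  expect_error(classify_sharing(f$cells, f$bulk, f$cov), "cellB")
})

test_that("del_ins_ratio reproduces the worked bulk and sc-only ratios", {
  expect_equal(round(as.numeric(del_ins_ratio(n_del = 9331, n_ins = 12514)), 2),
               0.75)
  expect_equal(round(as.numeric(del_ins_ratio(n_del = 1433, n_ins = 525)), 2),
               2.73)
  expect_equal(as.numeric(del_ins_ratio(n_del = 10, n_ins = 10)), 1)
  und <- del_ins_ratio(n_del = 5, n_ins = 0)
  expect_true(attr(und, "undefined"))
  calls <- rbind(del_call("d", 0, 100), ins_call("i1", 500, 60),
                 ins_call("i2", 900, 60))
  expect_equal(as.numeric(del_ins_ratio(calls)), 0.5)
})

test_that("ratio_fold divides cohort ratios", {
  expect_equal(round(as.numeric(ratio_fold(2.73, 0.4765)), 2), 5.73)
  expect_equal(as.numeric(ratio_fold(1.4, 1.4)), 1)
  expect_equal(as.numeric(ratio_fold(2 * 0.8, 0.8)), 2)
  expect_true(attr(ratio_fold(1, 0), "undefined"))
})

test_that("dropout heterozygosity averages per-type het fractions", {
  mk <- function(type, n, n_het) {
    data.frame(variant_id = sprintf("%s%d", type, seq_len(n)),
               svtype = type, category = "bulk_only",
               bulk_genotype = c(rep("0/1", n_het), rep("1/1", n - n_het)),
               stringsAsFactors = FALSE)
  }
  rec <- rbind(mk("INS", 1000, 731), mk("DEL", 1000, 873))
  h <- dropout_heterozygosity(rec)
  expect_equal(unname(h$per_type["INS"]), 0.731)
  expect_equal(unname(h$per_type["DEL"]), 0.873)
  expect_equal(round(100 * h$mean, 1), 80.2)

  hom <- mk("DEL", 10, 0)
  expect_equal(dropout_heterozygosity(hom)$mean, 0)
  # a type with no bulk-only records is excluded from the mean
  mixed <- rbind(mk("DEL", 10, 10),
                 data.frame(variant_id = "i", svtype = "INS",
                            category = "shared", bulk_genotype = "0/1"))
  h2 <- dropout_heterozygosity(mixed)
  expect_true(is.na(h2$per_type["INS"]))
  expect_equal(h2$mean, 1)
})

test_that("population variants are removed by the match rule", {
  f <- make_sharing_fixture()
  rec <- classify_sharing(f$cells, f$bulk, f$cov)
  pop <- data.frame(contig = "chr1", start = 10005L, svtype = "DEL",
                    length = 500L)
  out <- remove_population_variants(rec, pop)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false(any(out$svtype == "DEL" & out$category == "shared"))
  ident <- remove_population_variants(rec, pop[0, ])
  expect_equal(nrow(ident), nrow(rec))
  expect_equal(attr(ident, "n_removed"), 0L)

  # planted n-variant removal is exact
  many <- do.call(rbind, lapply(1:10, function(i)
    del_call(sprintf("p%d", i), i * 2000, i * 2000 + 300,
             sample_id = "bulk")))
  rec2 <- classify_sharing(list(cellA = many |> transform(sample_id = "cellA")),
                           many, list(cellA = full_track(1e6, 10L)))
  out2 <- remove_population_variants(
    rec2, data.frame(contig = "chr1", start = (1:10) * 2000L,
                     svtype = "DEL", length = 300L))
  expect_equal(attr(out2, "n_removed"), 10L)
  expect_equal(nrow(out2), 0L)
})

test_that("mosaic flag uses the bulk VAF threshold", {
  expect_true(mosaic_flag(0.35)[1])
  expect_false(mosaic_flag(0.5)[1])
  z <- mosaic_flag(0)
  expect_true(z[1])
  expect_true(attr(z, "zero_evidence")[1])
  expect_true(is.na(mosaic_flag(NA_real_)[1]))
})

test_that("VAF/occurrence matrix uses callable cells as denominator", {
  rec <- data.frame(
    variant_id = c("a", "b", "c"), contig = "chr1", start = 1:3,
    end = 1:3, svtype = "INS", length = 100L,
    category = "shared", bulk_vaf = c(0.25, 0.95, 0.5),
    bulk_genotype = "0/1", cells_carrying = "x",
    n_cells_carrying = c(3L, 2L, 1L), n_cells_callable = c(6L, 2L, 0L),
    support = 5L, member_ids = "", stringsAsFactors = FALSE)
  m <- vaf_occurrence_matrix(rec, n_bins = 10L)
  expect_equal(attr(m, "n_excluded"), 1L)          # zero callable cells
  expect_equal(sum(m$count), 2L)
  # carried by 3 of 6 callable -> occurrence 0.5 (bin 6); VAF 0.25 (bin 3)
  expect_equal(m$count[m$vaf_bin == 3 & m$occ_bin == 6], 1L)
  # carried by both of 2 callable -> occurrence 1.0 (top bin)
  expect_equal(m$count[m$vaf_bin == 10 & m$occ_bin == 10], 1L)
  expect_equal(nrow(m), 100L)                      # full explicit grid
})
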