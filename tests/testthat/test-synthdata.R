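# Synthetic-data generator: layout, TE planting, truth construction,
# callset rendering, dropout asymmetry, bias recovery, io round trip.

small_cfg <- function(...) {
  sim_config(contig_length = 2e6, n_mosaic_nahr = 10L, n_te_insertions = 50L,
             n_germline_sv = 80L, n_germline_snv = 100L,
             noise_snv_per_cell = 20, seed = 7L, ...)
}

test_that("layout covers the configured gap fraction and is reproducible", {
  cfg <- sim_config(contig_length = 1e6, gap_fraction = 0.1, seed = 3L)
  layout <- generate_genome_layout(cfg)
  expect_equal(mappable_length(layout), 900000)
  cfg0 <- sim_config(contig_length = 1e6, gap_fraction = 0, seed = 3L)
  expect_equal(mappable_length(generate_genome_layout(cfg0)), 1e6)
  expect_identical(generate_genome_layout(cfg), layout)
  expect_error(sim_config(contig_length = 0), "contig")
})

test_that("TE planting reaches target densities without overlaps", {
  cfg <- sim_config(contig_length = 1e7, gap_fraction = 0, seed = 5L,
                    n_germline_snv = 0L)
  layout <- generate_genome_layout(cfg)
  te <- plant_te_annotation(layout, cfg)
  alu_bp <- sum(te$end[te$family == "SINE/Alu"] -
                  te$start[te$family == "SINE/Alu"])
  l1_bp <- sum(te$end[te$family == "LINE/L1"] -
                 te$start[te$family == "LINE/L1"])
  expect_gte(alu_bp, 1.0e6)                 # 11% of 10 Mbp, within band
  expect_lte(alu_bp, 1.2e6)
  expect_lt(abs(l1_bp / 1e7 - 0.17), 0.01)  # within one percentage point
  ord <- order(te$contig, te$start)
  expect_true(all(diff(te$start[ord]) > 0))
  expect_true(all(te$start[ord][-1] >= te$end[ord][-nrow(te)]))
  # subfamily labels come from the configured groups
  alu <- te[te$family == "SINE/Alu", ]
  expect_true(all(grepl("^Alu[YSJ]", alu$subfamily)))
  expect_true(all(te$end[te$family == "SINE/Alu"] -
                    te$start[te$family == "SINE/Alu"] <= 350))
  # determinism
  expect_identical(plant_te_annotation(layout, cfg), te)
})

test_that("zero density yields zero elements", {
  cfg <- sim_config(contig_length = 1e6,
                    te_density = c("SINE/Alu" = 0.05, "LINE/L1" = 0),
                    seed = 2L)
  layout <- generate_genome_layout(cfg)
  te <- plant_te_annotation(layout, cfg)
  expect_equal(sum(te$family == "LINE/L1"), 0L)
  expect_gt(sum(te$family == "SINE/Alu"), 0L)
})

test_that("truth construction enforces its own invariants", {
  cfg <- small_cfg()
  layout <- generate_genome_layout(cfg)
  te <- plant_te_annotation(layout, cfg)
  truth <- simulate_truth(layout, te, cfg)
  v <- truth$variants
  nahr <- v[v$mechanism == "NAHR", ]
  expect_equal(nrow(nahr), 10L)
  # both breakpoint elements exist and share the recorded family
  for (i in seq_len(nrow(nahr))) {
    le <- te[te$element_id == nahr$left_element[i], ]
    re <- te[te$element_id == nahr$right_element[i], ]
    expect_equal(le$family, re$family)
    expect_equal(le$family, nahr$family[i])
    expect_true(le$start <= nahr$start[i] && nahr$start[i] < le$end)
    expect_true(re$start <= nahr$end[i] && nahr$end[i] < re$end)
    expect_false(le$element_id == re$element_id)
  }
  # every mosaic event carries a non-empty cell set
  mosaic <- v[v$class == "mosaic", ]
  expect_true(all(nchar(mosaic$cells) > 0))
  # artifacts never carry a truth mechanism
  expect_true(all(truth$artifacts$label == "chimera"))
  # insertion sequences are >= 50 bp and match recorded length
  ins <- v[v$mechanism == "TE_insertion", ]
  expect_true(all(nchar(ins$sequence) >= 50))
  expect_equal(nchar(ins$sequence), ins$length)
})

test_that("insertion landing sites follow the configured family bias", {
  base <- list(contig_length = 2e6, n_mosaic_nahr = 0L, n_germline_sv = 0L,
               n_germline_snv = 0L, n_te_insertions = 1000L,
               te_density = c("SINE/Alu" = 0.11, "LINE/L1" = 0.17))
  mk <- function(bias, seed) {
    cfg <- do.call(sim_config, c(base, list(insertion_family_bias = bias,
                                            seed = seed)))
    layout <- generate_genome_layout(cfg)
    te <- plant_te_annotation(layout, cfg)
    simulate_truth(layout, te, cfg)$variants
  }
  # bias 1: Alu insertions land in Alu at the genomic fraction
  v1 <- mk(1, 11L)
  alu <- v1[v1$family == "SINE/Alu", ]
  n <- nrow(alu)
  hits <- sum(alu$same_family_landing)
  expect_lt(abs(hits - 0.11 * n), 3 * sqrt(n * 0.11 * 0.89))
  # bias 0: no same-family landings at all
  v0 <- mk(0, 12L)
  expect_equal(sum(v0$same_family_landing), 0L)
  # monotone recovery over bias grid
  fracs <- vapply(c(0, 1, 3, 5), function(b) {
    v <- mk(b, 13L)
    mean(v$same_family_landing)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("rendering honours dropout, artifact and VAF contracts", {
  # dropout 0, full coverage: every germline het in every cell at covered loci
  cfg <- small_cfg(dropout_prob = 0, artifact_rate = 0,
                   cell_covered_fraction = 1, cell_mean_depth = 15)
  layout <- generate_genome_layout(cfg)
  te <- plant_te_annotation(layout, cfg)
  truth <- simulate_truth(layout, te, cfg)
  rend <- render_callsets(truth, layout, cfg)
  gl <- truth$variants[truth$variants$class == "germline", ]
  depth_of <- function(track, pos) {
    k <- findInterval(pos, track$start)
    ifelse(k >= 1 & pos < track$end[pmax(k, 1)], track$depth[pmax(k, 1)], 0L)
  }
  for (cid in names(rend$cells)) {
    truth_called <- rend$call_truth$truth_id[rend$call_truth$sample_id == cid]
    covered <- depth_of(rend$coverage[[cid]], gl$start) > 0
    expect_true(all(gl$truth_id[covered] %in% truth_called))
  }
  # no INV/DUP anywhere with artifact_rate 0
  all_sv <- rbind(rend$bulk$sv, do.call(rbind, lapply(rend$cells, `[[`, "sv")))
  expect_false(any(all_sv$svtype %in% c("INV", "DUP")))
  # mosaic bulk VAF centred on carriers / (2 n_cells)
  mos <- truth$variants[truth$variants$class == "mosaic", ]
  exp_vaf <- lengths(strsplit(mos$cells, ",")) / (2 * cfg$n_cells)
  bulk_ids <- rend$call_truth[rend$call_truth$sample_id == "bulk", ]
  vaf <- rend$bulk$sv$vaf[match(bulk_ids$call_id[match(mos$truth_id,
                                                       bulk_ids$truth_id)],
                                rend$bulk$sv$call_id)]
  ok <- !is.na(vaf)
  expect_gt(sum(ok), 0.9 * nrow(mos))
  expect_lt(abs(mean(vaf[ok] - exp_vaf[ok])), 0.03)
})

test_that("heterozygous events are over-represented among cell-missing calls", {
  cfg <- small_cfg(dropout_prob = 0.4)
  layout <- generate_genome_layout(cfg)
  te <- plant_te_annotation(layout, cfg)
  truth <- simulate_truth(layout, te, cfg)
  rend <- render_callsets(truth, layout, cfg)
  gl <- truth$variants[truth$variants$class == "germline", ]
  het <- gl$genotype == "0/1"
  miss_het <- 0L; miss_hom <- 0L; keep_het <- 0L; keep_hom <- 0L
  for (cid in names(rend$cells)) {
    called <- gl$truth_id %in%
      rend$call_truth$truth_id[rend$call_truth$sample_id == cid]
    miss_het <- miss_het + sum(!called & het)
    miss_hom <- miss_hom + sum(!called & !het)
    keep_het <- keep_het + sum(called & het)
    keep_hom <- keep_hom + sum(called & !het)
  }
  frac_missing_het <- miss_het / (miss_het + miss_hom)
  frac_kept_het <- keep_het / (keep_het + keep_hom)
  expect_gt(frac_missing_het, frac_kept_het)
})

test_that("written fixtures reproduce the in-memory callsets exactly", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(cfg, dir)
  bulk <- read_sv_vcf(file.path(dir, "bulk.sv.vcf"))
  attr(bulk, "parse_report") <- NULL
  mem <- sim$rendered$bulk$sv
  bulk <- bulk[order(bulk$call_id), ]
  mem <- mem[order(mem$call_id), ]
  rownames(bulk) <- rownames(mem) <- NULL
  expect_equal(bulk, mem, ignore_attr = TRUE)
  # truth ledger and coverage round-trip
  tr <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE,
                          sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(sim$truth$variants))
  cov <- read_coverage_bed(file.path(dir, "cell01.cov.bed"))
  expect_equal(cov, sim$rendered$coverage$cell01, ignore_attr = TRUE)
  # determinism of the whole fixture
  dir2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir2)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("bulk conservation losses are counted", {
  cfg <- small_cfg()
  layout <- generate_genome_layout(cfg)
  te <- plant_te_annotation(layout, cfg)
  truth <- simulate_truth(layout, te, cfg)
  rend <- render_callsets(truth, layout, cfg)
  expect_equal(nrow(rend$bulk$sv) + rend$n_bulk_lost,
               nrow(truth$variants))
})
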