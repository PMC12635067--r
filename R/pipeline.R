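# End-to-end orchestration: simulate -> filter -> concordance ->
# TE annotation -> permutation statistics -> summary report, with a
# reproducibility manifest. All stage seeds fan out from one global seed.

#' Assemble a pipeline run configuration
#'
#' Nested configuration for every stage; unknown keys in any section are
#' rejected. The whole object serialises to/from a single YAML file with
#' [write_run_config()] / [read_run_config()].
#'
#' @param sim named list of [sim_config()] overrides.
#' @param filter named list of [filter_config()] overrides.
#' @param match named list of [match_config()] overrides.
#' @param te named list of [te_config()] overrides.
#' @param stats named list of [stats_config()] overrides
#'   (`n_permutations` defaults to 1000 here to keep full runs fast;
#'   raise it for production permutation tests).
#' @param seed global seed; stage seeds are derived at fixed offsets.
#' @param input_dir optional directory of pre-existing inputs laid out as
#'   written by [simulate_dataset()]; when `NULL` the run simulates.
#' @param min_callable_depth callable-region depth threshold.
#' @param n_vaf_bins bins per axis of the VAF/occurrence histogram.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = list(), filter = list(), match = list(),
                       te = list(), stats = list(), seed = 1L,
                       input_dir = NULL, min_callable_depth = 5L,
                       n_vaf_bins = 10L) {
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad)) stop("unknown key(s) in `", section, "`: ",
                          paste(bad, collapse = ", "))
  }
  check_keys(sim, names(formals(sim_config)), "sim")
  check_keys(filter, names(formals(filter_config)), "filter")
  check_keys(match, names(formals(match_config)), "match")
  check_keys(te, names(formals(te_config)), "te")
  check_keys(stats, setdiff(names(formals(stats_config)), "seed"), "stats")
  if (is.null(stats$n_permutations)) stats$n_permutations <- 1000L
  sim$seed <- seed
  structure(list(sim = do.call(sim_config, sim),
                 filter = do.call(filter_config, filter),
                 match = do.call(match_config, match),
                 te = do.call(te_config, te),
                 stats = do.call(stats_config, stats),
                 seed = as.integer(seed), input_dir = input_dir,
                 min_callable_depth = as.integer(min_callable_depth),
                 n_vaf_bins = as.integer(n_vaf_bins)),
            class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  raw <- list(seed = config$seed, input_dir = config$input_dir,
              min_callable_depth = config$min_callable_depth,
              n_vaf_bins = config$n_vaf_bins,
              sim = unclass(config$sim), filter = unclass(config$filter),
              match = unclass(config$match), te = unclass(config$te),
              stats = unclass(config$stats)[setdiff(names(unclass(config$stats)), "seed")])
  raw$sim$te_density <- as.list(raw$sim$te_density)
  raw$sim$alu_subfamily_weights <- as.list(raw$sim$alu_subfamily_weights)
  raw$te$consensus_length <- as.list(raw$te$consensus_length)
  raw$stats$genomic_fraction <- as.list(raw$stats$genomic_fraction)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file written by [write_run_config()] (or hand-edited);
#'   unknown keys are rejected.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top <- c("seed", "input_dir", "min_callable_depth", "n_vaf_bins",
           "sim", "filter", "match", "te", "stats")
  bad <- setdiff(names(raw), top)
  if (length(bad)) stop("unknown key(s) in run config: ",
                        paste(bad, collapse = ", "))
  for (sec in c("sim", "te", "stats")) {
    for (nm in intersect(names(raw[[sec]]),
                         c("te_density", "alu_subfamily_weights",
                           "consensus_length", "genomic_fraction"))) {
      raw[[sec]][[nm]] <- unlist(raw[[sec]][[nm]])
    }
  }
  raw$sim$seed <- NULL
  run_config(sim = raw$sim %||% list(), filter = raw$filter %||% list(),
             match = raw$match %||% list(), te = raw$te %||% list(),
             stats = raw$stats %||% list(), seed = raw$seed %||% 1L,
             input_dir = raw$input_dir,
             min_callable_depth = raw$min_callable_depth %||% 5L,
             n_vaf_bins = raw$n_vaf_bins %||% 10L)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

load_inputs <- function(dir, config) {
  need <- file.path(dir, "contigs.tsv")
  contigs <- utils::read.table(need, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  gaps <- read_bed(file.path(dir, "gaps.bed"))
  layout <- genome_layout(contigs, gaps)
  te <- te_elements_from_hits(read_repeatmasker_out(
    file.path(dir, "reference_te.out")))
  exons <- read_bed(file.path(dir, "exons.bed"))
  seq_hits <- read_repeatmasker_out(file.path(dir, "variant_sequences.out"))
  pop_path <- file.path(dir, "population_sv.tsv")
  population <- if (file.exists(pop_path) && file.size(pop_path) > 0)
    utils::read.table(pop_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
  svs <- list(); snvs <- list(); coverage <- list()
  sv_files <- sort(list.files(dir, pattern = "\\.sv\\.vcf$"))
  for (f in sv_files) {
    sid <- sub("\\.sv\\.vcf$", "", f)
    svs[[sid]] <- read_sv_vcf(file.path(dir, f),
                              cell_id = if (sid == "bulk") NA_character_ else sid)
    snv_f <- file.path(dir, paste0(sid, ".snv.vcf"))
    if (file.exists(snv_f)) snvs[[sid]] <- read_small_vcf(snv_f)
    cov_f <- file.path(dir, paste0(sid, ".cov.bed"))
    # absent tracks surface downstream, where the consumer names the sample
    if (file.exists(cov_f)) coverage[[sid]] <- read_coverage_bed(cov_f)
  }
  list(layout = layout, te = te, exons = exons, seq_hits = seq_hits,
       population = population, svs = svs, snvs = snvs, coverage = coverage)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) bulk + single-cell callsets, applies the quality
#' and chimera filters, classifies single-cell/bulk sharing inside
#' co-callable regions, annotates transposon content (insertion targeting,
#' Alu subfamilies, NAHR verdicts), runs the permutation statistics, and
#' writes every stage artifact plus a summary report and manifest under
#' `out_dir`. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created).
#' @return a `summary_report`: named list of data.frames (see
#'   [render_report()]), invisibly-attached `paths` of written artifacts.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  inputs <- run_stage("simulate", {
    if (is.null(config$input_dir)) {
      sim <- simulate_dataset(config$sim, file.path(out_dir, "sim"))
      load_inputs(file.path(out_dir, "sim"), config)
    } else {
      load_inputs(config$input_dir, config)
    }
  })

  cells <- setdiff(names(inputs$svs), "bulk")
  filt <- run_stage("filter", {
    out <- lapply(inputs$svs, filter_sv_calls, cfg = config$filter)
    snv_out <- lapply(inputs$snvs, filter_small_variants, cfg = config$filter)
    list(sv = out, snv = snv_out)
  })
  filter_table <- do.call(rbind, lapply(names(filt$sv), function(sid) {
    r <- filt$sv[[sid]]$report
    data.frame(sample_id = sid, set = "sv", n_input = r$n_input,
               n_retained = r$n_retained,
               t(stats::setNames(r$rejections$n_rejected,
                                 paste0("rej_", r$rejections$rule))),
               stringsAsFactors = FALSE)
  }))

  conc <- run_stage("concordance", {
    if (!("bulk" %in% names(filt$sv))) stop("no bulk callset found")
    cell_sets <- lapply(stats::setNames(cells, cells),
                        function(cid) filt$sv[[cid]]$calls)
    records <- classify_sharing(cell_sets, filt$sv$bulk$calls,
                                inputs$coverage, config$match,
                                config$min_callable_depth)
    recpop <- remove_population_variants(records, inputs$population,
                                         config$match)
    vafmat <- vaf_occurrence_matrix(recpop, config$n_vaf_bins)
    list(records = records, records_nopop = recpop, vafmat = vafmat)
  })

  te_ann <- run_stage("te-annotate", {
    rec <- conc$records
    ins <- rec[rec$svtype == "INS" & rec$category != "bulk_only", ,
               drop = FALSE]
    ins_tab <- annotate_insertions(ins, inputs$seq_hits, inputs$te,
                                   config$te)
    dels <- rec[rec$svtype == "DEL" & rec$category != "bulk_only", ,
                drop = FALSE]
    dels$call_id <- dels$variant_id
    nahr <- classify_nahr_all(dels, inputs$te, config$te)
    nahr$category <- dels$category[match(nahr$variant_id, dels$variant_id)]
    list(insertions = ins_tab, nahr = nahr)
  })

  stat_res <- run_stage("stats", {
    scfg <- config$stats
    scfg$seed <- config$seed + 900L
    rec <- conc$records
    sh_del <- rec[rec$svtype == "DEL" & rec$category == "shared", ,
                  drop = FALSE]
    # transposon association is a per-cell comparison: each cell's
    # filtered deletions against the family annotation
    assoc <- do.call(rbind, lapply(seq_along(cells), function(k) {
      ccfg <- scfg
      ccfg$seed <- scfg$seed + 10L * k
      cdel <- filt$sv[[cells[k]]]$calls
      cdel <- cdel[cdel$svtype == "DEL", , drop = FALSE]
      te_association_test(cdel, inputs$te, inputs$layout, ccfg,
                          label = cells[k])
    }))
    dcfg <- scfg; dcfg$seed <- config$seed + 901L
    dcfg2 <- dcfg; dcfg2$seed <- dcfg$seed + 1L
    sc_del <- rec[rec$svtype == "DEL" & rec$category != "bulk_only", ,
                  drop = FALSE]
    sc_ins <- rec[rec$svtype == "INS" & rec$category != "bulk_only", ,
                  drop = FALSE]
    depl <- rbind(
      exon_depletion_test(sc_del, inputs$exons, inputs$layout, dcfg,
                          label = "sc_deletions:exons"),
      exon_depletion_test(sc_ins, inputs$exons, inputs$layout, dcfg2,
                          label = "sc_insertions:exons"))
    folds <- insertion_enrichment_table(te_ann$insertions,
                                        scfg$genomic_fraction)
    exonic <- data.frame(
      label = c("shared_deletions", "bulk_deletions"),
      exonic_fraction = c(
        exonic_fraction(sh_del, inputs$exons),
        exonic_fraction(filt$sv$bulk$calls[
          filt$sv$bulk$calls$svtype == "DEL", , drop = FALSE],
          inputs$exons)),
      stringsAsFactors = FALSE)
    list(association = assoc, depletion = depl, folds = folds,
         exonic = exonic)
  })

  report <- run_stage("report", {
    build_report(config, inputs, filt, filter_table, conc, te_ann, stat_res)
  })
  paths <- render_report(report, out_dir)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(package_version = as.character(utils::packageVersion("mosaicSV")),
                   seed = config$seed,
                   n_permutations = config$stats$n_permutations,
                   config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(report, "paths") <- c(paths, config = file.path(out_dir, "config.yaml"),
                             manifest = file.path(out_dir, "manifest.json"))
  report
}

# Insertion-level TE annotation table for merged sc records: dominant
# family from the sequence hits of any member call, Alu subfamily group,
# full-length flag and reference-site targeting.
annotate_insertions <- function(ins_records, seq_hits, te_elements, te_cfg) {
  n <- nrow(ins_records)
  out <- data.frame(variant_id = ins_records$variant_id,
                    category = ins_records$category,
                    dominant_family = NA_character_,
                    covered_fraction = 0, subfamily_group = "none",
                    full_length = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hits <- seq_hits[seq_hits$query %in%
                       strsplit(ins_records$member_ids[i],
                                ",", fixed = TRUE)[[1L]], , drop = FALSE]
    if (nrow(hits) == 0L) next
    hits <- hits[hits$query == hits$query[1L], , drop = FALSE]
    # annotate over the member call's own sequence length when known
    len <- if ("qlen" %in% names(hits) && is.finite(hits$qlen[1L]) &&
               hits$qlen[1L] > 0L) hits$qlen[1L] else ins_records$length[i]
    v <- list(length = len, call_id = ins_records$variant_id[i])
    ann <- annotate_variant_te(v, hits)
    if (nrow(ann) == 0L) next
    dom <- ann[ann$dominant, ]
    out$dominant_family[i] <- dom$family
    out$covered_fraction[i] <- dom$covered_fraction
    out$subfamily_group[i] <- assign_alu_subfamily(v, hits, te_cfg)
    out$full_length[i] <- any(full_length_flag(hits, te_cfg))
  }
  tgt <- insertion_target_class(
    data.frame(call_id = ins_records$variant_id,
               contig = ins_records$contig, start = ins_records$start,
               stringsAsFactors = FALSE),
    te_elements, dominant_family = out$dominant_family)
  cbind(out, tgt[, c("target_element", "target_family", "same_family")])
}

insertion_enrichment_table <- function(ins_tab, genomic_fraction) {
  rows <- lapply(names(genomic_fraction), function(fam) {
    do.call(rbind, lapply(c("shared", "single_cell_only"), function(cat) {
      d <- ins_tab[!is.na(ins_tab$dominant_family) &
                     ins_tab$dominant_family == fam &
                     ins_tab$category == cat, , drop = FALSE]
      obs <- if (nrow(d)) mean(d$same_family) else NA_real_
      data.frame(family = fam, category = cat, n = nrow(d),
                 observed_fraction = obs,
                 genomic_fraction = genomic_fraction[[fam]],
                 fold = if (!is.na(obs))
                   as.numeric(enrichment_fold(obs, genomic_fraction[[fam]]))
                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$mean_fold <- mean(out$fold, na.rm = TRUE)
  out
}

build_report <- function(config, inputs, filt, filter_table, conc, te_ann,
                         stat_res) {
  rec <- conc$records
  cats <- c("shared", "single_cell_only", "bulk_only")
  types <- c("INS", "DEL")
  counts <- expand.grid(category = cats, svtype = types,
                        stringsAsFactors = FALSE)
  counts$n <- mapply(function(cat, t)
    sum(rec$category == cat & rec$svtype == t), counts$category,
    counts$svtype)
  recall <- sc_recall(rec)
  het <- dropout_heterozygosity(rec)
  ratios <- data.frame(
    set = c("bulk", "shared", "single_cell_only"),
    del_ins_ratio = c(
      as.numeric(del_ins_ratio(filt$sv$bulk$calls)),
      as.numeric(del_ins_ratio(rec[rec$category == "shared", ])),
      as.numeric(del_ins_ratio(rec[rec$category == "single_cell_only", ]))),
    stringsAsFactors = FALSE)
  sc_vs_bulk_fold <- as.numeric(ratio_fold(
    ratios$del_ins_ratio[ratios$set == "single_cell_only"],
    ratios$del_ins_ratio[ratios$set == "bulk"]))
  nahr <- te_ann$nahr
  nahr_tab <- do.call(rbind, lapply(unique(stats::na.omit(nahr$family)),
                                    function(fam) {
    data.frame(family = fam, n_nahr = sum(nahr$same_family &
                                            nahr$family == fam,
                                          na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nahr_tab)) nahr_tab <- data.frame(family = character(),
                                                n_nahr = integer())
  subfam <- te_ann$insertions
  subfam_tab <- as.data.frame(table(group = subfam$subfamily_group[
    !is.na(subfam$dominant_family) & subfam$dominant_family == "SINE/Alu"]),
    stringsAsFactors = FALSE)
  names(subfam_tab) <- c("group", "n")
  summary_tab <- data.frame(
    metric = c("n_cells", "recall_INS", "recall_DEL",
               "bulk_only_het_INS", "bulk_only_het_DEL",
               "bulk_only_het_mean", "sc_only_vs_bulk_ratio_fold",
               "n_population_removed", "n_bulk_excluded"),
    value = c(length(setdiff(names(inputs$svs), "bulk")),
              recall["INS"] %||% NA_real_, recall["DEL"] %||% NA_real_,
              het$per_type["INS"], het$per_type["DEL"], het$mean,
              sc_vs_bulk_fold,
              attr(conc$records_nopop, "n_removed"),
              attr(rec, "n_bulk_excluded")),
    stringsAsFactors = FALSE)
  structure(list(summary = summary_tab, counts = counts,
                 filter_reports = filter_table, ratios = ratios,
                 nahr = nahr, nahr_by_family = nahr_tab,
                 insertions = te_ann$insertions,
                 alu_subfamilies = subfam_tab,
                 enrichment_folds = stat_res$folds,
                 te_association = as.data.frame(stat_res$association),
                 exon_depletion = as.data.frame(stat_res$depletion),
                 exonic_fractions = stat_res$exonic,
                 sharing_records = rec,
                 vaf_occurrence = conc$vafmat),
            class = "summary_report")
}

#' Write a summary report as a TSV bundle
#'
#' One TSV per report table, written deterministically (fixed column and
#' row order); empty categories appear as explicit zero rows.
#'
#' @param report a `summary_report` from [run_pipeline()].
#' @param out_dir directory for the bundle (created).
#' @return named character vector of written paths.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "summary_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(report)) {
    tab <- report[[nm]]
    if (!is.data.frame(tab)) next
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[nm] <- path
  }
  paths
}

#' @export
print.summary_report <- function(x, ...) {
  cat("summary_report with tables:", paste(names(x), collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}

#' Heatmap of the bulk-VAF / cell-occurrence histogram
#'
#' @param vafmat result of [vaf_occurrence_matrix()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
plot_vaf_occurrence <- function(vafmat, ...) {
  m <- attr(vafmat, "matrix")
  graphics::image(x = seq(0, 1, length.out = nrow(m) + 1L),
                  y = seq(0, 1, length.out = ncol(m) + 1L),
                  z = m, xlab = "bulk VAF",
                  ylab = "single-cell occurrence fraction",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  invisible(m)
}
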