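# Synthetic single-cell + bulk callset generator with planted truth.
#
# Emulates the statistical structure the downstream analysis assumes:
# a reference transposon annotation at realistic family densities, mosaic
# NAHR deletions whose breakpoints fall on same-family repeat pairs, TE
# insertions with a configurable bias toward same-family reference
# elements, allelic dropout acting on heterozygous events, patchy
# amplification coverage, C>T-biased SNV noise and chimera-like INV/DUP /
# low-support artifact calls.

#' Simulation configuration
#'
#' Defaults describe one six-cell brain-style experiment on a 10 Mbp
#' single-contig genome: transposon densities of 11% SINE/Alu and 17%
#' LINE/L1 (the human genome-wide figures), bulk depth ~50x, patchy
#' per-cell amplification coverage averaging ~4x over covered runs, and an
#' insertion-site family bias of 3.26 (the mean fold-enrichment of TE
#' insertions into same-family reference elements reported for brain
#' single-cell data).
#'
#' @param n_cells cells per experiment (default 6).
#' @param n_contigs,contig_length genome shape (default 1 x 10 Mbp).
#' @param gap_fraction fraction of each contig that is unmappable gap.
#' @param n_gaps gap intervals per contig.
#' @param te_density named fractions of mappable genome covered per family.
#' @param alu_subfamily_weights sampling weights for AluY/AluS/AluJ groups.
#' @param n_germline_sv plain germline SVs (DEL+INS).
#' @param germline_del_ins_ratio DEL:INS composition of germline SVs
#'   (default 0.75, the bulk genome-wide ratio).
#' @param germline_het_fraction fraction of germline events that are 0/1.
#' @param n_mosaic_nahr mosaic NAHR deletions (same-family breakpoint
#'   pairs), split evenly between families.
#' @param n_te_insertions mosaic TE insertions.
#' @param insertion_family_bias fold bias of insertion landing into
#'   same-family reference elements; the same-family landing probability is
#'   `clamp(bias * te_density[family], 0, 1)`.
#' @param dropout_prob per-cell allele-dropout probability for
#'   heterozygous events.
#' @param artifact_rate expected chimera-artifact calls per cell
#'   (half INV/DUP, half low-support DEL/INS).
#' @param snv_ct_bias fraction of noise SNVs that are C>T (pyrimidine
#'   strand), default 0.498 as observed in MDA-amplified single cells.
#' @param n_germline_snv germline SNVs planted.
#' @param noise_snv_per_cell expected noise SNVs per cell.
#' @param n_population_sv germline SVs additionally flagged as known
#'   population variants (written to the population list).
#' @param bulk_depth mean bulk coverage (default 50x).
#' @param cell_mean_depth mean per-cell depth over covered runs (default 4x).
#' @param cell_covered_fraction fraction of the genome in covered runs per
#'   cell.
#' @param run_length_mean mean coverage run length in bp (geometric).
#' @param breakpoint_jitter +- bp jitter applied to single-cell call
#'   breakpoints (default 10).
#' @param exon_fraction,exon_length exon annotation shape.
#' @param sv_length_range germline/plain SV length range (log-uniform).
#' @param seed master seed; all stages derive fixed offsets from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 6L, n_contigs = 1L, contig_length = 1e7,
                       gap_fraction = 0.05, n_gaps = 10L,
                       te_density = c("SINE/Alu" = 0.11, "LINE/L1" = 0.17),
                       alu_subfamily_weights = c(AluY = 0.3, AluS = 0.5,
                                                 AluJ = 0.2),
                       n_germline_sv = 200L, germline_del_ins_ratio = 0.75,
                       germline_het_fraction = 2 / 3,
                       n_mosaic_nahr = 20L, n_te_insertions = 200L,
                       insertion_family_bias = 3.26,
                       dropout_prob = 0.2, artifact_rate = 10,
                       snv_ct_bias = 0.498, n_germline_snv = 300L,
                       noise_snv_per_cell = 100,
                       n_population_sv = 20L,
                       bulk_depth = 50, cell_mean_depth = 4,
                       cell_covered_fraction = 0.5,
                       run_length_mean = 2e4,
                       breakpoint_jitter = 10L,
                       exon_fraction = 0.03, exon_length = 1000L,
                       sv_length_range = c(50L, 2000L),
                       seed = 1L) {
  n_population_sv <- min(n_population_sv, n_germline_sv)
  stopifnot(n_cells >= 1L, n_contigs >= 1L,
            n_contigs * contig_length >= 1e4,
            gap_fraction >= 0, gap_fraction < 1,
            all(te_density >= 0), sum(te_density) < 1,
            insertion_family_bias >= 0,
            dropout_prob >= 0, dropout_prob <= 1,
            snv_ct_bias >= 0, snv_ct_bias <= 1,
            n_germline_sv >= 0L, n_mosaic_nahr >= 0L, n_te_insertions >= 0L,
            n_population_sv <= n_germline_sv,
            artifact_rate >= 0)
  if (contig_length <= 0) stop("zero-length contig in configuration")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# deterministic stage seeds fanned out from the master seed
stage_seed <- function(config, offset) (as.integer(config$seed) %% 100000L) * 17L + offset

#' Generate a genome layout from a simulation configuration
#'
#' Gaps are equal-sized, one per block of the contig, placed uniformly
#' within their block, so they are non-overlapping and cover exactly the
#' configured fraction.
#'
#' @param config a [sim_config()].
#' @return a [genome_layout()].
#' @export
generate_genome_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config, 1L), {
    contigs <- data.frame(name = sprintf("chr%d", seq_len(config$n_contigs)),
                          length = as.integer(config$contig_length),
                          stringsAsFactors = FALSE)
    gaps <- NULL
    if (config$gap_fraction > 0) {
      total_gap <- round(config$gap_fraction * config$contig_length)
      ng <- config$n_gaps
      glen <- rep(floor(total_gap / ng), ng)
      glen[1L] <- glen[1L] + (total_gap - sum(glen))
      block <- floor(config$contig_length / ng)
      gaps <- do.call(rbind, lapply(contigs$name, function(ctg) {
        start <- vapply(seq_len(ng), function(i) {
          lo <- (i - 1L) * block
          lo + floor(stats::runif(1) * (block - glen[i]))
        }, numeric(1))
        data.frame(contig = ctg, start = as.integer(start),
                   end = as.integer(start + glen), stringsAsFactors = FALSE)
      }))
    }
    if (is.null(gaps)) {
      genome_layout(contigs)
    } else {
      genome_layout(contigs, gaps)
    }
  })
}

ALU_SUBFAMILIES <- list(AluY = c("AluY", "AluYa5", "AluYb8"),
                        AluS = c("AluSx", "AluSc", "AluSg", "AluSp"),
                        AluJ = c("AluJb", "AluJo"))
L1_SUBFAMILIES <- c("L1HS", "L1PA2", "L1PA3", "L1PA4", "L1MA1")

# occupancy register over one contig: sorted non-overlapping intervals
# with O(log n) overlap queries and ordered insertion
make_register <- function() {
  env <- new.env(parent = emptyenv())
  env$starts <- list()
  env$ends <- list()
  env$overlaps <- function(contig, s, e) {
    st <- env$starts[[contig]]
    if (is.null(st) || length(st) == 0L) return(FALSE)
    en <- env$ends[[contig]]
    k <- findInterval(s, st)
    (k >= 1L && en[k] > s) || (k < length(st) && st[k + 1L] < e)
  }
  env$add <- function(contig, s, e) {
    st <- env$starts[[contig]] %||% integer(0)
    en <- env$ends[[contig]] %||% integer(0)
    k <- findInterval(s, st)
    env$starts[[contig]] <- append(st, as.integer(s), after = k)
    env$ends[[contig]] <- append(en, as.integer(e), after = k)
  }
  env
}

#' Plant a reference transposon annotation
#'
#' Places non-overlapping TE elements outside gaps until each family's
#' covered fraction of the mappable genome reaches its configured density
#' (realised fraction within one percentage point of target). Alu elements
#' are ~300 bp with subfamily labels drawn from the AluY/AluS/AluJ groups;
#' LINE/L1 elements are 500-6000 bp.
#'
#' @param layout a [genome_layout()].
#' @param config a [sim_config()].
#' @return TE element data.frame (`element_id`, `contig`, `start`, `end`,
#'   `strand`, `family`, `subfamily`, `divergence`).
#' @export
plant_te_annotation <- function(layout, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  mlen <- mappable_length(layout)
  lengths_for <- function(family, n) {
    if (family == "SINE/Alu") {
      pmin(pmax(round(stats::rnorm(n, 300, 20)), 250L), 350L)
    } else {
      as.integer(round(stats::runif(n, 500, 6000)))
    }
  }
  with_seed(stage_seed(config, 2L), {
    eng <- shuffle_engine(1L, layout)  # uniform mappable positions
    reg <- make_register()
    for (g in seq_len(nrow(layout$gaps))) {
      reg$add(layout$gaps$contig[g], layout$gaps$start[g], layout$gaps$end[g])
    }
    rows <- list()
    for (family in names(config$te_density)) {
      target <- config$te_density[[family]] * mlen
      if (target <= 0) next
      covered <- 0
      consec_fail <- 0L
      while (covered < target) {
        len <- lengths_for(family, 1L)
        p <- eng$draw()
        s <- p$start[1L]; e <- s + len; ctg <- p$contig[1L]
        clen <- layout$contigs$length[layout$contigs$name == ctg]
        if (e > clen || reg$overlaps(ctg, s, e)) {
          consec_fail <- consec_fail + 1L
          if (consec_fail > 2000L) {
            stop("requested TE density for ", family,
                 " is infeasible given gaps and existing elements")
          }
          next
        }
        consec_fail <- 0L
        reg$add(ctg, s, e)
        if (family == "SINE/Alu") {
          grp <- sample(names(config$alu_subfamily_weights), 1L,
                        prob = config$alu_subfamily_weights)
          sub <- sample(ALU_SUBFAMILIES[[grp]], 1L)
          div <- switch(grp, AluY = stats::runif(1, 0, 5),
                        AluS = stats::runif(1, 5, 15),
                        AluJ = stats::runif(1, 15, 25))
        } else {
          sub <- sample(L1_SUBFAMILIES, 1L)
          div <- stats::runif(1, 0, 20)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, start = as.integer(s), end = as.integer(e),
          strand = sample(c("+", "-"), 1L), family = family,
          subfamily = sub, divergence = round(div, 1),
          stringsAsFactors = FALSE)
        covered <- covered + len
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      return(data.frame(element_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), family = character(),
                        subfamily = character(), divergence = numeric(),
                        stringsAsFactors = FALSE))
    }
    out <- out[order(out$contig, out$start), , drop = FALSE]
    out <- cbind(element_id = sprintf("TE%06d", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate a non-overlapping exon annotation
#' @param layout a [genome_layout()].
#' @param config a [sim_config()].
#' @return data.frame `contig`, `start`, `end`.
#' @export
generate_exons <- function(layout, config) {
  n <- max(0L, round(config$exon_fraction * mappable_length(layout) /
                       config$exon_length))
  if (n == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  with_seed(stage_seed(config, 3L), {
    eng <- shuffle_engine(rep(config$exon_length, n), layout)
    reg <- make_register()
    out <- vector("list", n)
    got <- 0L
    while (got < n) {
      p <- eng$draw()
      for (i in seq_len(n - got)) {
        s <- p$start[i]; e <- s + config$exon_length; ctg <- p$contig[i]
        if (reg$overlaps(ctg, s, e)) next
        reg$add(ctg, s, e)
        got <- got + 1L
        out[[got]] <- data.frame(contig = ctg, start = as.integer(s),
                                 end = as.integer(e), stringsAsFactors = FALSE)
        if (got == n) break
      }
    }
    ex <- do.call(rbind, out)
    ex[order(ex$contig, ex$start), , drop = FALSE]
  })
}

BASES <- c("A", "C", "G", "T")

# fixed per-subfamily consensus sequence (stable across runs and seeds)
subfamily_consensus <- function(subfamily, len) {
  h <- sum(utf8ToInt(subfamily) * seq_along(utf8ToInt(subfamily)))
  with_seed(10000L + h, paste(sample(BASES, len, replace = TRUE),
                              collapse = ""))
}

mutate_sequence <- function(seq, rate = 0.02) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  paste(chars, collapse = "")
}

random_cell_subset <- function(n_cells, prob = 0.5) {
  repeat {
    m <- which(stats::runif(n_cells) < prob)
    if (length(m) > 0L) return(m)
  }
}

#' Plant the ground-truth event set
#'
#' Plants germline SVs (DEL/INS at the configured composition and
#' genotype ratio, a subset flagged as population variants), mosaic NAHR
#' deletions whose two breakpoints lie inside two distinct same-family
#' reference elements, mosaic TE insertions carrying a consensus-derived
#' sequence (2% substitution noise) that land inside a same-family
#' reference element with probability `clamp(bias * density, 0, 1)` and
#' uniformly outside same-family elements otherwise, germline SNVs, and
#' per-cell chimera artifact events.
#'
#' @param layout a [genome_layout()].
#' @param te_elements reference TE annotation from
#'   [plant_te_annotation()].
#' @param config a [sim_config()].
#' @return list of class `truth_set`: `variants` (data.frame with truth
#'   labels, mechanism, breakpoint element ids, target element, cell
#'   membership), `snvs`, `artifacts`.
#' @export
simulate_truth <- function(layout, te_elements, config) {
  stopifnot(inherits(layout, "genome_layout"), inherits(config, "sim_config"))
  with_seed(stage_seed(config, 4L), {
    reg <- make_register()  # planted DEL spans, to keep events disjoint
    rows <- list()
    add_row <- function(...) {
      rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
    }
    fams <- names(config$te_density)

    # --- mosaic NAHR deletions on same-family element pairs ---
    n_nahr <- config$n_mosaic_nahr
    if (n_nahr > 0L) {
      nahr_fams <- rep(fams, length.out = n_nahr)
      for (k in seq_len(n_nahr)) {
        fam <- nahr_fams[k]
        cand <- te_elements[te_elements$family == fam, , drop = FALSE]
        if (nrow(cand) < 2L) {
          stop("insufficient ", fam, " elements to host NAHR deletions")
        }
        placed <- FALSE
        for (try in seq_len(500L)) {
          li <- sample(nrow(cand), 1L)
          left <- cand[li, ]
          partners <- which(cand$contig == left$contig &
                              cand$start > left$end + 100L &
                              cand$start < left$start + 5e4)
          if (length(partners) == 0L) next
          right <- cand[partners[sample(length(partners), 1L)], ]
          bp_l <- left$start + sample.int(left$end - left$start, 1L) - 1L
          bp_r <- right$start + sample.int(right$end - right$start, 1L) - 1L
          if (bp_r <= bp_l + 50L) next
          if (reg$overlaps(left$contig, bp_l - 1000L, bp_r + 1000L)) next
          reg$add(left$contig, bp_l, bp_r)
          cells <- random_cell_subset(config$n_cells)
          add_row(truth_id = sprintf("NAHR%04d", k), class = "mosaic",
                  mechanism = "NAHR", contig = left$contig,
                  start = bp_l, end = bp_r, svtype = "DEL",
                  length = bp_r - bp_l, genotype = "0/1",
                  cells = paste(cells, collapse = ","),
                  left_element = left$element_id,
                  right_element = right$element_id, family = fam,
                  target_element = NA_character_,
                  same_family_landing = NA,
                  subfamily = NA_character_, sequence = NA_character_,
                  is_population = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("insufficient ", fam,
               " element pairs to host NAHR deletion ", k)
        }
      }
    }

    # --- mosaic TE insertions with family-biased landing sites ---
    if (config$n_te_insertions > 0L) {
      eng <- shuffle_engine(1L, layout)
      fam_share <- config$te_density / sum(config$te_density)
      for (k in seq_len(config$n_te_insertions)) {
        fam <- sample(fams, 1L, prob = fam_share)
        if (fam == "SINE/Alu") {
          grp <- sample(names(config$alu_subfamily_weights), 1L,
                        prob = config$alu_subfamily_weights)
          sub <- sample(ALU_SUBFAMILIES[[grp]], 1L)
          cons_len <- 300L
          frag_len <- if (stats::runif(1) < 0.8) cons_len
                      else sample(50:cons_len, 1L)
        } else {
          sub <- sample(L1_SUBFAMILIES, 1L)
          cons_len <- 6000L
          frag_len <- as.integer(round(exp(stats::runif(1, log(100),
                                                        log(6000)))))
          frag_len <- max(frag_len, 50L)
        }
        cons <- subfamily_consensus(sub, cons_len)
        frag <- substr(cons, cons_len - frag_len + 1L, cons_len)
        seq <- mutate_sequence(frag, 0.02)

        p_same <- min(max(config$insertion_family_bias *
                            config$te_density[[fam]], 0), 1)
        fam_el <- te_elements[te_elements$family == fam, , drop = FALSE]
        same <- stats::runif(1) < p_same && nrow(fam_el) > 0L
        target <- NA_character_
        repeat {
          if (same) {
            w <- fam_el$end - fam_el$start
            cumw <- cumsum(w)
            r <- floor(stats::runif(1) * cumw[length(cumw)])
            ei <- findInterval(r, cumw) + 1L
            pos <- fam_el$start[ei] + (r - c(0, cumw)[ei])
            ctg <- fam_el$contig[ei]
            target <- fam_el$element_id[ei]
          } else {
            p <- eng$draw()
            pos <- p$start[1L]; ctg <- p$contig[1L]
            if (overlaps_any(ctg, pos, pos + 1L,
                             fam_el[, c("contig", "start", "end")])) next
          }
          if (reg$overlaps(ctg, pos - 50L, pos + 50L)) next
          break
        }
        reg$add(ctg, as.integer(pos), as.integer(pos) + 1L)
        cells <- random_cell_subset(config$n_cells)
        add_row(truth_id = sprintf("TEINS%04d", k), class = "mosaic",
                mechanism = "TE_insertion", contig = ctg,
                start = as.integer(pos), end = as.integer(pos),
                svtype = "INS", length = nchar(seq), genotype = "0/1",
                cells = paste(cells, collapse = ","),
                left_element = NA_character_,
                right_element = NA_character_, family = fam,
                target_element = target, same_family_landing = same,
                subfamily = sub, sequence = seq, is_population = FALSE)
      }
    }

    # --- plain germline SVs ---
    if (config$n_germline_sv > 0L) {
      eng <- shuffle_engine(1L, layout)
      p_del <- config$germline_del_ins_ratio /
        (1 + config$germline_del_ins_ratio)
      pop_idx <- if (config$n_population_sv > 0L)
        sample(config$n_germline_sv, config$n_population_sv) else integer(0)
      for (k in seq_len(config$n_germline_sv)) {
        type <- if (stats::runif(1) < p_del) "DEL" else "INS"
        len <- as.integer(round(exp(stats::runif(1,
                                                 log(config$sv_length_range[1]),
                                                 log(config$sv_length_range[2])))))
        repeat {
          p <- eng$draw()
          pos <- p$start[1L]; ctg <- p$contig[1L]
          span <- if (type == "DEL") len else 1L
          clen <- layout$contigs$length[layout$contigs$name == ctg]
          if (pos + span > clen) next
          if (reg$overlaps(ctg, pos - 50L, pos + span + 50L)) next
          break
        }
        if (type == "DEL") reg$add(ctg, pos, pos + len)
        gt <- if (stats::runif(1) < config$germline_het_fraction) "0/1" else "1/1"
        seq <- if (type == "INS")
          paste(sample(BASES, len, replace = TRUE), collapse = "")
        else NA_character_
        add_row(truth_id = sprintf("GL%05d", k), class = "germline",
                mechanism = "plain", contig = ctg, start = as.integer(pos),
                end = as.integer(if (type == "DEL") pos + len else pos),
                svtype = type, length = len, genotype = gt,
                cells = paste(seq_len(config$n_cells), collapse = ","),
                left_element = NA_character_, right_element = NA_character_,
                family = NA_character_, target_element = NA_character_,
                same_family_landing = NA, subfamily = NA_character_,
                sequence = seq, is_population = k %in% pop_idx)
      }
    }

    variants <- do.call(rbind, rows)
    if (is.null(variants)) variants <- empty_truth_variants()

    # --- germline SNVs ---
    snvs <- NULL
    if (config$n_germline_snv > 0L) {
      eng <- shuffle_engine(1L, layout)
      p <- do.call(rbind, lapply(seq_len(config$n_germline_snv),
                                 function(i) eng$draw()))
      ref <- sample(BASES, config$n_germline_snv, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
      snvs <- data.frame(
        truth_id = sprintf("SNV%05d", seq_len(config$n_germline_snv)),
        contig = p$contig, pos = p$start + 1L, ref = ref, alt = alt,
        genotype = ifelse(stats::runif(config$n_germline_snv) <
                            config$germline_het_fraction, "0/1", "1/1"),
        stringsAsFactors = FALSE)
    } else {
      snvs <- data.frame(truth_id = character(), contig = character(),
                         pos = integer(), ref = character(),
                         alt = character(), genotype = character(),
                         stringsAsFactors = FALSE)
    }

    # --- chimera artifact events, per cell ---
    artifacts <- list()
    eng <- shuffle_engine(1L, layout)
    for (cell in seq_len(config$n_cells)) {
      n_art <- stats::rpois(1L, config$artifact_rate)
      for (k in seq_len(n_art)) {
        p <- eng$draw()
        kind <- stats::runif(1) < 0.5
        type <- if (kind) sample(c("INV", "DUP"), 1L)
                else sample(c("DEL", "INS"), 1L)
        len <- as.integer(round(exp(stats::runif(1, log(60), log(5000)))))
        artifacts[[length(artifacts) + 1L]] <- data.frame(
          truth_id = sprintf("ART.c%02d.%03d", cell, k), label = "chimera",
          cell = cell, contig = p$contig[1L], start = p$start[1L],
          end = p$start[1L] + if (type %in% c("DEL", "INV", "DUP")) len else 0L,
          svtype = type, length = len,
          low_support = !kind, stringsAsFactors = FALSE)
      }
    }
    artifacts <- if (length(artifacts)) do.call(rbind, artifacts)
    else data.frame(truth_id = character(), label = character(),
                    cell = integer(), contig = character(),
                    start = integer(), end = integer(), svtype = character(),
                    length = integer(), low_support = logical(),
                    stringsAsFactors = FALSE)
    structure(list(variants = variants, snvs = snvs, artifacts = artifacts),
              class = "truth_set")
  })
}

empty_truth_variants <- function() {
  data.frame(truth_id = character(), class = character(),
             mechanism = character(), contig = character(),
             start = integer(), end = integer(), svtype = character(),
             length = integer(), genotype = character(), cells = character(),
             left_element = character(), right_element = character(),
             family = character(), target_element = character(),
             same_family_landing = logical(), subfamily = character(),
             sequence = character(), is_population = logical(),
             stringsAsFactors = FALSE)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$variants), "variants (",
      sum(x$variants$mechanism == "NAHR"), "NAHR,",
      sum(x$variants$mechanism == "TE_insertion"), "TE insertions ),",
      nrow(x$snvs), "SNVs,", nrow(x$artifacts), "artifact events\n")
  invisible(x)
}

# piecewise-constant coverage track as alternating geometric runs
simulate_track <- function(layout, mean_depth, covered_fraction,
                           run_mean, always_covered = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(layout$contigs))) {
    ctg <- layout$contigs$name[i]
    clen <- layout$contigs$length[i]
    pos <- 0L
    while (pos < clen) {
      len <- min(stats::rgeom(1L, 1 / run_mean) + 1L, clen - pos)
      covered <- always_covered || stats::runif(1) < covered_fraction
      depth <- if (covered) stats::rnbinom(1L, size = 4, mu = mean_depth)
               else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, start = pos, end = pos + len, depth = as.integer(depth),
        stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  do.call(rbind, rows)
}

depth_at <- function(track, contig, pos) {
  out <- integer(length(pos))
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    tr <- track[track$contig == ctg, , drop = FALSE]
    k <- findInterval(pos[idx], tr$start)
    ok <- k >= 1L & pos[idx] < tr$end[pmax(k, 1L)]
    out[idx] <- ifelse(ok, tr$depth[pmax(k, 1L)], 0L)
  }
  out
}

#' Render bulk and per-cell callsets from a truth set
#'
#' Coverage tracks are drawn per sample (bulk ~`bulk_depth`x everywhere;
#' cells as patchy zero-inflated runs). Bulk support is
#' Binomial(depth, VAF) with the expected mosaic VAF equal to carrying
#' cells / (2 x n_cells); truth variants drawn to zero bulk support are
#' lost and counted. In a cell, a carried variant at a covered locus
#' always yields at least one supporting read; heterozygous events are
#' additionally lost with probability `dropout_prob` (allelic dropout).
#' Chimera artifact events are emitted as INV/DUP or low-support DEL/INS
#' call records. Single-cell breakpoints are jittered by up to
#' `breakpoint_jitter` bp.
#'
#' @param truth a [simulate_truth()] result.
#' @param layout a [genome_layout()].
#' @param config a [sim_config()].
#' @return list of class `rendered_callsets`: `bulk` (list `sv`, `snv`),
#'   `cells` (named list of the same shape), `coverage` (named list of
#'   tracks incl. `bulk`), `seq_hits` (RepeatMasker-style hits over
#'   insertion call sequences), `call_truth` (call id to truth id map),
#'   `n_bulk_lost` (truth variants with zero bulk support).
#' @export
render_callsets <- function(truth, layout, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  with_seed(stage_seed(config, 5L), {
    cells <- sprintf("cell%02d", seq_len(config$n_cells))
    coverage <- list(bulk = simulate_track(layout, config$bulk_depth, 1,
                                           config$run_length_mean,
                                           always_covered = TRUE))
    for (cid in cells) {
      coverage[[cid]] <- simulate_track(layout, config$cell_mean_depth,
                                        config$cell_covered_fraction,
                                        config$run_length_mean)
    }
    v <- truth$variants
    cell_sets <- lapply(v$cells, function(s)
      as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))

    map <- list()
    note_call <- function(call_id, sample_id, truth_id) {
      map[[length(map) + 1L]] <<- data.frame(call_id = call_id,
                                             sample_id = sample_id,
                                             truth_id = truth_id,
                                             stringsAsFactors = FALSE)
    }

    # ---- bulk SV callset ----
    n_bulk_lost <- 0L
    bulk_rows <- list()
    if (nrow(v) > 0L) {
      vaf_true <- ifelse(v$class == "germline",
                         ifelse(v$genotype == "1/1", 1, 0.5),
                         lengths(cell_sets) / (2 * config$n_cells))
      bdepth <- depth_at(coverage$bulk, v$contig, pmax(v$start, 0L))
      bdepth <- pmax(bdepth, 1L)
      support <- stats::rbinom(nrow(v), bdepth, vaf_true)
      for (i in seq_len(nrow(v))) {
        if (support[i] == 0L) { n_bulk_lost <- n_bulk_lost + 1L; next }
        id <- sprintf("bulk.%s.%05d", v$svtype[i], i)
        bulk_rows[[length(bulk_rows) + 1L]] <- sv_calls(
          call_id = id, contig = v$contig[i], start = v$start[i],
          end = v$end[i], svtype = v$svtype[i], length = v$length[i],
          sequence = v$sequence[i], support = support[i],
          depth = bdepth[i], filter = "PASS", genotype = v$genotype[i],
          gq = as.integer(30L + min(support[i], 30L)),
          vaf = round(support[i] / bdepth[i], 6), sample_id = "bulk")
        note_call(id, "bulk", v$truth_id[i])
      }
    }
    bulk_sv <- if (length(bulk_rows)) do.call(rbind, bulk_rows)
               else empty_sv_calls()

    # ---- per-cell SV callsets ----
    cell_sv <- stats::setNames(vector("list", length(cells)), cells)
    seq_hits <- list()
    for (ci in seq_along(cells)) {
      cid <- cells[ci]
      rows_c <- list()
      if (nrow(v) > 0L) {
        for (i in seq_len(nrow(v))) {
          if (!(ci %in% cell_sets[[i]])) next
          het <- v$genotype[i] == "0/1" || v$class[i] == "mosaic"
          if (het && config$dropout_prob > 0 &&
              stats::runif(1) < config$dropout_prob) next
          d <- depth_at(coverage[[cid]], v$contig[i], max(v$start[i], 0L))
          if (d == 0L) next
          vaf_cell <- if (het) 0.5 else 1
          sup <- 1L + stats::rbinom(1L, d - 1L, vaf_cell)
          jit <- if (config$breakpoint_jitter > 0)
            sample(seq(-config$breakpoint_jitter, config$breakpoint_jitter), 1L)
          else 0L
          s <- max(v$start[i] + jit, 0L)
          e <- if (v$svtype[i] == "DEL") s + v$length[i] else s
          id <- sprintf("%s.%s.%05d", cid, v$svtype[i], i)
          rows_c[[length(rows_c) + 1L]] <- sv_calls(
            call_id = id, contig = v$contig[i], start = s, end = e,
            svtype = v$svtype[i], length = v$length[i],
            sequence = v$sequence[i], support = sup, depth = d,
            filter = "PASS",
            genotype = if (het) "0/1" else "1/1",
            gq = as.integer(20L + min(sup * 5L, 40L)),
            vaf = round(sup / d, 6), sample_id = cid, cell_id = cid)
          note_call(id, cid, v$truth_id[i])
          if (v$mechanism[i] == "TE_insertion") {
            seq_hits[[length(seq_hits) + 1L]] <- data.frame(
              query = id, start = 0L, end = v$length[i], strand = "+",
              subfamily = v$subfamily[i], family = v$family[i],
              divergence = 2.0, qlen = v$length[i], stringsAsFactors = FALSE)
          }
        }
      }
      art <- truth$artifacts[truth$artifacts$cell == ci, , drop = FALSE]
      for (k in seq_len(nrow(art))) {
        d <- max(depth_at(coverage[[cid]], art$contig[k],
                          max(art$start[k], 0L)), 1L)
        sup <- if (art$low_support[k]) sample(1:2, 1L)
               else min(sample(3:8, 1L), d + 3L)
        id <- sprintf("%s.%s.a%04d", cid, art$svtype[k], k)
        rows_c[[length(rows_c) + 1L]] <- sv_calls(
          call_id = id, contig = art$contig[k], start = art$start[k],
          end = art$end[k], svtype = art$svtype[k], length = art$length[k],
          support = sup, depth = max(d, 5L), filter = "PASS",
          genotype = "0/1", gq = sample(5:25, 1L),
          vaf = round(sup / max(d, 5L), 6), sample_id = cid, cell_id = cid)
        note_call(id, cid, art$truth_id[k])
      }
      cell_sv[[cid]] <- if (length(rows_c)) do.call(rbind, rows_c)
                        else empty_sv_calls()
    }

    # ---- SNVs: bulk + per-cell (germline with dropout + C>T-biased noise) ----
    s <- truth$snvs
    bulk_snv <- small_variants()
    if (nrow(s) > 0L) {
      dep <- pmax(depth_at(coverage$bulk, s$contig, s$pos - 1L), 1L)
      vaf <- ifelse(s$genotype == "1/1", 1, 0.5)
      sup <- stats::rbinom(nrow(s), dep, vaf)
      keep <- sup > 0L
      bulk_snv <- small_variants(
        variant_id = sprintf("bulk.snv.%05d", which(keep)),
        contig = s$contig[keep], pos = s$pos[keep], ref = s$ref[keep],
        alt = s$alt[keep], filter = "PASS", genotype = s$genotype[keep],
        gq = as.integer(30L + pmin(sup[keep], 30L)), depth = dep[keep],
        alt_support = sup[keep], sample_id = "bulk")
    }
    cell_snv <- stats::setNames(vector("list", length(cells)), cells)
    pyr <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    for (ci in seq_along(cells)) {
      cid <- cells[ci]
      rows_s <- list()
      if (nrow(s) > 0L) {
        het <- s$genotype == "0/1"
        drop <- het & stats::runif(nrow(s)) < config$dropout_prob
        dep <- depth_at(coverage[[cid]], s$contig, s$pos - 1L)
        emit <- !drop & dep > 0L
        if (any(emit)) {
          sup <- 1L + stats::rbinom(sum(emit), dep[emit] - 1L,
                                    ifelse(het[emit], 0.5, 1))
          rows_s[[1L]] <- small_variants(
            variant_id = sprintf("%s.snv.%05d", cid, which(emit)),
            contig = s$contig[emit], pos = s$pos[emit], ref = s$ref[emit],
            alt = s$alt[emit], filter = "PASS", genotype = s$genotype[emit],
            gq = as.integer(20L + pmin(sup * 5L, 40L)), depth = dep[emit],
            alt_support = sup, sample_id = cid, cell_id = cid)
        }
      }
      n_noise <- stats::rpois(1L, config$noise_snv_per_cell)
      if (n_noise > 0L) {
        eng <- shuffle_engine(1L, layout)
        pts <- do.call(rbind, lapply(seq_len(n_noise), function(i) eng$draw()))
        cls <- ifelse(stats::runif(n_noise) < config$snv_ct_bias, "C>T",
                      sample(setdiff(pyr, "C>T"), n_noise, replace = TRUE))
        ra <- strsplit(cls, ">", fixed = TRUE)
        ref <- vapply(ra, `[`, "", 1L)
        alt <- vapply(ra, `[`, "", 2L)
        flip <- stats::runif(n_noise) < 0.5  # purine strand half the time
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ref[flip] <- comp[ref[flip]]
        alt[flip] <- comp[alt[flip]]
        dep <- pmax(depth_at(coverage[[cid]], pts$contig, pts$start), 1L)
        sup <- pmin(1L + stats::rpois(n_noise, 1L), dep)
        rows_s[[length(rows_s) + 1L]] <- small_variants(
          variant_id = sprintf("%s.noise.%05d", cid, seq_len(n_noise)),
          contig = pts$contig, pos = pts$start + 1L, ref = ref, alt = alt,
          filter = "PASS", genotype = "0/1",
          gq = sample(5:40, n_noise, replace = TRUE), depth = dep,
          alt_support = sup, sample_id = cid, cell_id = cid)
      }
      cell_snv[[cid]] <- if (length(rows_s)) do.call(rbind, rows_s)
                         else small_variants()
    }

    structure(list(
      bulk = list(sv = bulk_sv, snv = bulk_snv),
      cells = stats::setNames(lapply(cells, function(cid)
        list(sv = cell_sv[[cid]], snv = cell_snv[[cid]])), cells),
      coverage = coverage,
      seq_hits = if (length(seq_hits)) do.call(rbind, seq_hits)
                 else data.frame(query = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 subfamily = character(), family = character(),
                                 divergence = numeric(), qlen = integer(),
                                 stringsAsFactors = FALSE),
      call_truth = if (length(map)) do.call(rbind, map)
                   else data.frame(call_id = character(),
                                   sample_id = character(),
                                   truth_id = character(),
                                   stringsAsFactors = FALSE),
      n_bulk_lost = n_bulk_lost), class = "rendered_callsets")
  })
}

#' Simulate a complete dataset and write it to disk
#'
#' Runs layout generation, TE planting, truth simulation and callset
#' rendering, then writes every artifact in its exchange format: one SV
#' and one SNV VCF per sample, 4-column coverage BEDs, the reference TE
#' annotation as RepeatMasker `.out` and 6-column BED, exon BED,
#' insertion-sequence hits as `.out`, a population-SV list, the truth
#' ledger and the call-to-truth map as tab-separated tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisible list with the in-memory objects (`layout`,
#'   `te_elements`, `exons`, `truth`, `rendered`) and a named `paths`
#'   vector of everything written.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- generate_genome_layout(config)
  te <- plant_te_annotation(layout, config)
  exons <- generate_exons(layout, config)
  truth <- simulate_truth(layout, te, config)
  rendered <- render_callsets(truth, layout, config)
  p <- function(...) file.path(out_dir, ...)
  paths <- c(contigs = p("contigs.tsv"), gaps = p("gaps.bed"),
             te_out = p("reference_te.out"), te_bed = p("reference_te.bed"),
             exons = p("exons.bed"), seq_hits = p("variant_sequences.out"),
             truth = p("truth.tsv"), call_truth = p("call_truth.tsv"),
             population = p("population_sv.tsv"))
  utils::write.table(layout$contigs, paths[["contigs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(layout$gaps, paths[["gaps"]])
  ref_hits <- data.frame(query = te$contig, start = te$start, end = te$end,
                         strand = te$strand, subfamily = te$subfamily,
                         family = te$family, divergence = te$divergence,
                         qlen = layout$contigs$length[
                           match(te$contig, layout$contigs$name)],
                         stringsAsFactors = FALSE)
  write_repeatmasker_out(ref_hits, paths[["te_out"]])
  write_te_bed(te, paths[["te_bed"]])
  write_bed(exons, paths[["exons"]])
  write_repeatmasker_out(rendered$seq_hits, paths[["seq_hits"]])
  truth_tab <- truth$variants
  con <- file(paths[["truth"]], "w")
  writeLines(c("# truth ledger: one planted variant per row",
               "# cells: comma-separated 1-based cell indices carrying the event",
               "# same_family_landing: insertion landed inside a same-family reference element"),
             con)
  suppressWarnings(utils::write.table(truth_tab, con, sep = "\t",
                                      quote = FALSE, row.names = FALSE))
  close(con)
  utils::write.table(rendered$call_truth, paths[["call_truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pop <- truth$variants[truth$variants$is_population, , drop = FALSE]
  utils::write.table(pop[, c("contig", "start", "end", "svtype", "length")],
                     paths[["population"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  samples <- c("bulk", names(rendered$cells))
  for (sid in samples) {
    set <- if (sid == "bulk") rendered$bulk else rendered$cells[[sid]]
    sv_path <- p(paste0(sid, ".sv.vcf"))
    snv_path <- p(paste0(sid, ".snv.vcf"))
    cov_path <- p(paste0(sid, ".cov.bed"))
    write_sv_vcf(set$sv, sv_path, layout)
    write_small_vcf(set$snv, snv_path, layout)
    write_coverage_bed(rendered$coverage[[sid]], cov_path)
    paths[paste0(sid, ".sv")] <- sv_path
    paths[paste0(sid, ".snv")] <- snv_path
    paths[paste0(sid, ".cov")] <- cov_path
  }
  invisible(list(layout = layout, te_elements = te, exons = exons,
                 truth = truth, rendered = rendered, paths = paths))
}
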