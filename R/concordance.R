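# Single-cell vs bulk concordance: SV matching, cross-cell merging,
# sharing classification restricted to co-callable regions, allelic
# dropout accounting, DEL/INS ratios and the VAF/occurrence relationship.

#' SV matching configuration
#'
#' Two calls match when their types are compatible, their start breakpoints
#' lie within `max_breakpoint_distance` and their size ratio
#' (min/max length) is at least `min_size_ratio`. The default geometry
#' (500 bp, 0.7) is the conventional SV benchmarking default.
#'
#' @param max_breakpoint_distance bp (default 500).
#' @param min_size_ratio fraction in (0, 1] (default 0.7).
#' @param type_strict if `TRUE` (default) INS only matches INS, DEL only
#'   DEL, etc.
#' @return list of class `match_config`.
#' @export
match_config <- function(max_breakpoint_distance = 500L, min_size_ratio = 0.7,
                         type_strict = TRUE) {
  stopifnot(max_breakpoint_distance >= 0L,
            min_size_ratio > 0, min_size_ratio <= 1)
  structure(list(max_breakpoint_distance = as.integer(max_breakpoint_distance),
                 min_size_ratio = min_size_ratio,
                 type_strict = isTRUE(type_strict)),
            class = "match_config")
}

#' Do two SV calls match?
#'
#' Symmetric in its arguments. Calls without length (BND) match on
#' breakpoint distance alone.
#'
#' @param a,b single-row SV call data.frames (or lists) with `contig`,
#'   `start`, `svtype`, `length`.
#' @param cfg a [match_config()].
#' @return logical scalar.
#' @export
match_sv <- function(a, b, cfg = match_config()) {
  if (!identical(as.character(a$contig), as.character(b$contig))) return(FALSE)
  if (cfg$type_strict && !identical(as.character(a$svtype),
                                    as.character(b$svtype))) return(FALSE)
  if (abs(a$start - b$start) > cfg$max_breakpoint_distance) return(FALSE)
  if (!is.na(a$length) && !is.na(b$length)) {
    lo <- min(a$length, b$length); hi <- max(a$length, b$length)
    if (hi > 0 && lo / hi < cfg$min_size_ratio) return(FALSE)
  }
  TRUE
}

# Candidate matches of one query call against a call table; returns row
# indices ordered by the deterministic tie-break (smallest breakpoint
# distance, then smallest size difference, then leftmost).
match_candidates <- function(contig, start, svtype, length, table, cfg) {
  cand <- which(table$contig == contig &
                  (!cfg$type_strict | table$svtype == svtype) &
                  abs(table$start - start) <= cfg$max_breakpoint_distance)
  if (length(cand) && !is.na(length)) {
    tl <- table$length[cand]
    ratio_ok <- is.na(tl) | (pmin(tl, length) / pmax(tl, length, 1L) >=
                               cfg$min_size_ratio)
    cand <- cand[ratio_ok]
  }
  if (length(cand) > 1L) {
    d <- abs(table$start[cand] - start)
    sz <- abs(ifelse(is.na(table$length[cand]), 0L, table$length[cand]) -
                ifelse(is.na(length), 0L, length))
    cand <- cand[order(d, sz, table$start[cand])]
  }
  cand
}

#' Merge single-cell SV calls across cells
#'
#' Greedy positional clustering: calls are sorted (contig, start, end,
#' support descending) and each call joins the best-matching existing
#' cluster under the [match_config()] rule (tie-break: smallest breakpoint
#' distance, then smallest size difference, then leftmost representative),
#' or founds a new cluster. Sorting first makes the result independent of
#' input order. The cluster representative is the member with the highest
#' support (ties: leftmost, then call id).
#'
#' @param cell_callsets named list of SV call tables, one per cell; names
#'   are the cell ids (overriding any `cell_id` column).
#' @param cfg a [match_config()].
#' @return data.frame of merged variants: `merged_id`, `contig`, `start`,
#'   `end`, `svtype`, `length`, `support`, `cells` (comma-separated),
#'   `n_cells`, `member_ids` (comma-separated call ids).
#' @export
merge_cell_calls <- function(cell_callsets, cfg = match_config()) {
  stopifnot(is.list(cell_callsets), !is.null(names(cell_callsets)))
  all_calls <- do.call(rbind, lapply(names(cell_callsets), function(cid) {
    d <- cell_callsets[[cid]]
    if (nrow(d) == 0L) return(NULL)
    d$cell_id <- cid
    d
  }))
  empty <- data.frame(merged_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      svtype = character(), length = integer(),
                      support = integer(), cells = character(),
                      n_cells = integer(), member_ids = character(),
                      stringsAsFactors = FALSE)
  if (is.null(all_calls) || nrow(all_calls) == 0L) return(empty)
  ord <- order(all_calls$contig, all_calls$start, all_calls$end,
               -ifelse(is.na(all_calls$support), 0L, all_calls$support),
               all_calls$call_id)
  all_calls <- all_calls[ord, , drop = FALSE]
  n <- nrow(all_calls)
  cluster <- integer(n)
  # open-cluster representative geometry, grown as clusters are founded
  rep_contig <- character(0); rep_start <- integer(0)
  rep_type <- character(0); rep_len <- integer(0)
  for (i in seq_len(n)) {
    tab <- data.frame(contig = rep_contig, start = rep_start,
                      svtype = rep_type, length = rep_len,
                      stringsAsFactors = FALSE)
    cand <- if (nrow(tab)) match_candidates(all_calls$contig[i],
                                            all_calls$start[i],
                                            all_calls$svtype[i],
                                            all_calls$length[i], tab, cfg)
            else integer(0)
    if (length(cand)) {
      cluster[i] <- cand[1L]
    } else {
      rep_contig <- c(rep_contig, all_calls$contig[i])
      rep_start <- c(rep_start, all_calls$start[i])
      rep_type <- c(rep_type, all_calls$svtype[i])
      rep_len <- c(rep_len, all_calls$length[i])
      cluster[i] <- length(rep_start)
    }
  }
  out <- lapply(split(seq_len(n), cluster), function(idx) {
    d <- all_calls[idx, , drop = FALSE]
    sup <- ifelse(is.na(d$support), -1L, d$support)
    rep_i <- order(-sup, d$start, d$call_id)[1L]
    cells <- sort(unique(d$cell_id))
    data.frame(contig = d$contig[rep_i], start = d$start[rep_i],
               end = d$end[rep_i], svtype = d$svtype[rep_i],
               length = d$length[rep_i], support = d$support[rep_i],
               cells = paste(cells, collapse = ","),
               n_cells = length(cells),
               member_ids = paste(sort(d$call_id), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  out <- cbind(merged_id = sprintf("MRG%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

point_in_regions <- function(contig, pos, regions) {
  overlaps_any(contig, pos, pos + 1L, regions)
}

#' Classify variant sharing between single cells and bulk
#'
#' Single-cell calls are first merged across cells ([merge_cell_calls()]),
#' then each merged variant is matched one-to-one against the bulk callset
#' (greedy in position order, deterministic tie-break). Matched variants
#' are `shared`, unmatched merged variants `single_cell_only`, and bulk
#' calls unmatched by any single-cell variant but lying inside at least one
#' cell's callable region (depth >= `min_depth`) are `bulk_only`; bulk
#' calls outside every cell's callable region are excluded (counted in the
#' `n_bulk_excluded` attribute). A cell counts as callable for a variant
#' when the variant's start lies in its callable region or the cell itself
#' called the variant.
#'
#' @param cell_callsets named list of filtered SV call tables (one per
#'   cell).
#' @param bulk_callset filtered bulk SV call table.
#' @param coverage_tracks named list of coverage data.frames; must contain
#'   every cell name.
#' @param cfg a [match_config()].
#' @param min_depth callable-region depth threshold (default 5).
#' @return data.frame of sharing records: `variant_id`, `contig`, `start`,
#'   `end`, `svtype`, `length`, `category`, `bulk_vaf`, `bulk_genotype`,
#'   `cells_carrying`, `n_cells_carrying`, `n_cells_callable`, `support`;
#'   attribute `n_bulk_excluded`.
#' @export
classify_sharing <- function(cell_callsets, bulk_callset, coverage_tracks,
                             cfg = match_config(), min_depth = 5L) {
  cells <- names(cell_callsets)
  missing_cov <- setdiff(cells, names(coverage_tracks))
  if (length(missing_cov)) {
    stop("missing coverage track for sample(s): ",
         paste(missing_cov, collapse = ", "))
  }
  callable <- lapply(coverage_tracks[cells], callable_regions,
                     min_depth = min_depth)
  merged <- merge_cell_calls(cell_callsets, cfg)

  n_callable <- function(contig, pos, carrying) {
    vapply(seq_along(contig), function(i) {
      carry <- strsplit(carrying[i], ",", fixed = TRUE)[[1L]]
      cov <- vapply(cells, function(cid)
        point_in_regions(contig[i], pos[i], callable[[cid]]), logical(1))
      sum(cov | cells %in% carry)
    }, 1L)
  }

  bulk_taken <- rep(FALSE, nrow(bulk_callset))
  match_idx <- rep(NA_integer_, nrow(merged))
  if (nrow(merged) > 0L && nrow(bulk_callset) > 0L) {
    for (i in seq_len(nrow(merged))) {
      cand <- match_candidates(merged$contig[i], merged$start[i],
                               merged$svtype[i], merged$length[i],
                               bulk_callset, cfg)
      cand <- cand[!bulk_taken[cand]]
      if (length(cand)) {
        match_idx[i] <- cand[1L]
        bulk_taken[cand[1L]] <- TRUE
      }
    }
  }

  rec_merged <- NULL
  if (nrow(merged) > 0L) {
    shared <- !is.na(match_idx)
    bidx <- match_idx
    rec_merged <- data.frame(
      variant_id = merged$merged_id, contig = merged$contig,
      start = merged$start, end = merged$end, svtype = merged$svtype,
      length = merged$length,
      category = ifelse(shared, "shared", "single_cell_only"),
      bulk_vaf = ifelse(shared, bulk_callset$vaf[bidx], NA_real_),
      bulk_genotype = ifelse(shared, bulk_callset$genotype[bidx],
                             NA_character_),
      cells_carrying = merged$cells,
      n_cells_carrying = merged$n_cells,
      n_cells_callable = n_callable(merged$contig, merged$start,
                                    merged$cells),
      support = merged$support, member_ids = merged$member_ids,
      stringsAsFactors = FALSE)
  }

  rec_bulk <- NULL
  n_bulk_excluded <- 0L
  if (nrow(bulk_callset) > 0L) {
    un <- which(!bulk_taken)
    if (length(un)) {
      ncall <- n_callable(bulk_callset$contig[un], bulk_callset$start[un],
                          rep("", length(un)))
      inside <- ncall > 0L
      n_bulk_excluded <- sum(!inside)
      un <- un[inside]
      if (length(un)) {
        rec_bulk <- data.frame(
          variant_id = bulk_callset$call_id[un],
          contig = bulk_callset$contig[un], start = bulk_callset$start[un],
          end = bulk_callset$end[un], svtype = bulk_callset$svtype[un],
          length = bulk_callset$length[un], category = "bulk_only",
          bulk_vaf = bulk_callset$vaf[un],
          bulk_genotype = bulk_callset$genotype[un],
          cells_carrying = "", n_cells_carrying = 0L,
          n_cells_callable = ncall[inside],
          support = bulk_callset$support[un], member_ids = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- rbind(rec_merged, rec_bulk)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      svtype = character(), length = integer(),
                      category = character(), bulk_vaf = numeric(),
                      bulk_genotype = character(),
                      cells_carrying = character(),
                      n_cells_carrying = integer(),
                      n_cells_callable = integer(), support = integer(),
                      member_ids = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$contig, out$start, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_bulk_excluded") <- n_bulk_excluded
  out
}

#' Single-cell recall in bulk, per SV type
#' @param records sharing records from [classify_sharing()].
#' @return named numeric: shared / (shared + single_cell_only) per svtype.
#' @export
sc_recall <- function(records) {
  sc <- records[records$category %in% c("shared", "single_cell_only"), ,
                drop = FALSE]
  types <- sort(unique(sc$svtype))
  vapply(stats::setNames(types, types), function(t) {
    d <- sc[sc$svtype == t, , drop = FALSE]
    sum(d$category == "shared") / nrow(d)
  }, numeric(1))
}

#' Heterozygous fraction of bulk-only variants
#'
#' The allelic-dropout signature: among variants seen in bulk but in no
#' single cell, the fraction with a 0/1 bulk genotype, per SV type, plus
#' their unweighted mean. Types with no bulk-only records are undefined
#' and excluded from the mean.
#'
#' @param records sharing records, or any data.frame with `category`,
#'   `svtype`, `bulk_genotype`.
#' @return list with `per_type` (named numeric, NA when undefined) and
#'   `mean`.
#' @export
dropout_heterozygosity <- function(records) {
  b <- records[records$category == "bulk_only", , drop = FALSE]
  types <- sort(unique(records$svtype))
  per_type <- vapply(stats::setNames(types, types), function(t) {
    d <- b[b$svtype == t, , drop = FALSE]
    if (nrow(d) == 0L) return(NA_real_)
    mean(d$bulk_genotype == "0/1", na.rm = TRUE)
  }, numeric(1))
  list(per_type = per_type, mean = mean(per_type, na.rm = TRUE))
}

#' Deletion / insertion ratio
#'
#' @param calls optional data.frame with an `svtype` column from which DEL
#'   and INS are counted.
#' @param n_del,n_ins alternatively, explicit counts.
#' @return numeric ratio; `NA` with attribute `undefined = TRUE` when the
#'   insertion count is zero.
#' @export
del_ins_ratio <- function(calls = NULL, n_del = NULL, n_ins = NULL) {
  if (!is.null(calls)) {
    n_del <- sum(calls$svtype == "DEL")
    n_ins <- sum(calls$svtype == "INS")
  }
  if (is.null(n_del) || is.null(n_ins)) stop("give `calls` or both counts")
  if (n_ins == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  structure(n_del / n_ins, undefined = FALSE)
}

#' Fold between two DEL/INS ratios
#' @param ratio_a,ratio_b two ratios (> 0).
#' @return `ratio_a / ratio_b`; `NA` with attribute `undefined` when the
#'   denominator is zero or missing.
#' @export
ratio_fold <- function(ratio_a, ratio_b) {
  if (is.na(ratio_b) || ratio_b == 0) return(structure(NA_real_, undefined = TRUE))
  structure(as.numeric(ratio_a) / as.numeric(ratio_b), undefined = FALSE)
}

#' Remove known population variants from sharing records
#'
#' Records matching a population-SV entry under the standard match rule
#' are dropped; the removal count is attached as attribute `n_removed`.
#'
#' @param records sharing records.
#' @param population_set data.frame with `contig`, `start`, `svtype`,
#'   `length`.
#' @param cfg a [match_config()].
#' @return filtered records with attribute `n_removed`.
#' @export
remove_population_variants <- function(records, population_set,
                                       cfg = match_config()) {
  if (nrow(records) == 0L || is.null(population_set) ||
      nrow(population_set) == 0L) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  hit <- vapply(seq_len(nrow(records)), function(i) {
    length(match_candidates(records$contig[i], records$start[i],
                            records$svtype[i], records$length[i],
                            population_set, cfg)) > 0L
  }, logical(1))
  out <- records[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Flag mosaic variants by bulk allele frequency
#'
#' A variant is flagged mosaic when its bulk VAF is at or below the
#' threshold (default 0.35, low enough to separate subclonal events from
#' germline heterozygotes at VAF ~0.5 while keeping clearly confirmed
#' low-frequency events).
#'
#' @param bulk_vaf numeric vector in `[0, 1]` (NA allowed).
#' @param genotype unused placeholder for genotype-aware extensions.
#' @param threshold mosaic VAF ceiling (default 0.35, inclusive).
#' @return logical vector (NA where vaf missing) with attribute
#'   `zero_evidence` marking vaf == 0 records.
#' @export
mosaic_flag <- function(bulk_vaf, genotype = NULL, threshold = 0.35) {
  out <- bulk_vaf <= threshold
  attr(out, "zero_evidence") <- !is.na(bulk_vaf) & bulk_vaf == 0
  out
}

#' Bulk VAF vs single-cell occurrence histogram
#'
#' For shared variants, the occurrence fraction is the number of carrying
#' cells divided by the number of cells callable at the locus. Both the
#' bulk VAF and the occurrence fraction are binned on `[0, 1]`; the full
#' grid is returned (explicit zero counts) for heatmap rendering.
#'
#' @param records sharing records (population variants already removed).
#' @param n_bins bins per axis (default 10).
#' @return data.frame `vaf_bin`, `occ_bin`, `vaf_lo`, `occ_lo`, `count`
#'   over the full grid; attributes `matrix` (vaf bins x occurrence bins)
#'   and `n_excluded` (shared records with zero callable cells).
#' @export
vaf_occurrence_matrix <- function(records, n_bins = 10L) {
  sh <- records[records$category == "shared" & !is.na(records$bulk_vaf), ,
                drop = FALSE]
  excl <- sum(sh$n_cells_callable == 0L)
  sh <- sh[sh$n_cells_callable > 0L, , drop = FALSE]
  occurrence <- sh$n_cells_carrying / sh$n_cells_callable
  bin <- function(x) pmin(floor(x * n_bins), n_bins - 1L) + 1L
  m <- matrix(0L, n_bins, n_bins,
              dimnames = list(vaf = sprintf("[%.2f,%.2f)",
                                            (0:(n_bins - 1)) / n_bins,
                                            (1:n_bins) / n_bins),
                              occurrence = sprintf("[%.2f,%.2f)",
                                                   (0:(n_bins - 1)) / n_bins,
                                                   (1:n_bins) / n_bins)))
  if (nrow(sh) > 0L) {
    vb <- bin(sh$bulk_vaf); ob <- bin(occurrence)
    for (i in seq_along(vb)) m[vb[i], ob[i]] <- m[vb[i], ob[i]] + 1L
  }
  grid <- expand.grid(vaf_bin = seq_len(n_bins), occ_bin = seq_len(n_bins))
  out <- data.frame(vaf_bin = grid$vaf_bin, occ_bin = grid$occ_bin,
                    vaf_lo = (grid$vaf_bin - 1) / n_bins,
                    occ_lo = (grid$occ_bin - 1) / n_bins,
                    count = m[cbind(grid$vaf_bin, grid$occ_bin)])
  attr(out, "matrix") <- m
  attr(out, "n_excluded") <- excl
  out
}
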