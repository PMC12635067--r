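# Transposable-element classification of variants: family/subfamily
# content of variant sequences, full-length detection, NAHR deletion
# classification from same-family repeat pairs at the breakpoints, and
# insertion-site family preference.

#' TE analysis configuration
#'
#' @param dominant_fraction minimum covered fraction for a single element
#'   to define an insertion's subfamily (default 0.80, strict `>`).
#' @param breakpoint_window bp tolerance when testing whether a reference
#'   element overlaps a deletion breakpoint (default 50, absorbing caller
#'   breakpoint imprecision).
#' @param full_length_min_fraction fraction of the consensus length a
#'   masked element must reach to count as full-length (default 0.9,
#'   inclusive).
#' @param consensus_length named numeric: consensus length per family
#'   (defaults `SINE/Alu` 300 bp, `LINE/L1` 6000 bp).
#' @return list of class `te_config`.
#' @export
te_config <- function(dominant_fraction = 0.80, breakpoint_window = 50L,
                      full_length_min_fraction = 0.9,
                      consensus_length = c("SINE/Alu" = 300,
                                           "LINE/L1" = 6000)) {
  stopifnot(dominant_fraction > 0, dominant_fraction <= 1,
            breakpoint_window >= 0L,
            full_length_min_fraction > 0, full_length_min_fraction <= 1)
  structure(list(dominant_fraction = dominant_fraction,
                 breakpoint_window = as.integer(breakpoint_window),
                 full_length_min_fraction = full_length_min_fraction,
                 consensus_length = consensus_length),
            class = "te_config")
}

# Merge hit spans per grouping key and return covered bp. Spans are
# clipped to [0, len) with a warning when they exceed the variant bounds.
merged_covered_bp <- function(hits, len, by) {
  if (nrow(hits) == 0L) return(stats::setNames(integer(0), character(0)))
  s <- pmax(hits$start, 0L)
  e <- pmin(hits$end, len)
  if (any(hits$start < 0L | hits$end > len)) {
    warning("hit span(s) exceeding variant bounds were clipped")
  }
  keep <- e > s
  s <- s[keep]; e <- e[keep]; g <- hits[[by]][keep]
  if (length(s) == 0L) return(stats::setNames(integer(0), character(0)))
  vapply(split(seq_along(s), g), function(idx) {
    r <- IRanges::reduce(IRanges::IRanges(start = s[idx] + 1L, end = e[idx]))
    as.integer(sum(IRanges::width(r)))
  }, 1L)
}

#' Per-family TE content of one variant
#'
#' Merges the RepeatMasker-style hits of each family over the variant's
#' sequence (or deletion span) and reports covered fractions; a variant
#' "contains" a family when at least 1 bp is masked by it. The dominant
#' family is the one with the largest covered fraction (ties broken
#' lexicographically and flagged).
#'
#' @param variant single-row SV call (needs `length`).
#' @param hits data.frame of hits for this variant: `family`, `subfamily`,
#'   `start`, `end` (0-based half-open within the variant).
#' @return data.frame `family`, `covered_bp`, `covered_fraction`,
#'   `dominant`; attribute `tie` when the dominant family was tied.
#' @export
annotate_variant_te <- function(variant, hits) {
  len <- as.integer(variant$length)
  cov <- merged_covered_bp(hits, len, "family")
  if (length(cov) == 0L) {
    out <- data.frame(family = character(), covered_bp = integer(),
                      covered_fraction = numeric(), dominant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "tie") <- FALSE
    return(out)
  }
  fam <- sort(names(cov))  # lexicographic order fixes tie-breaking
  cov <- cov[fam]
  frac <- as.numeric(cov) / len
  dom <- which.max(frac)   # first max in lexicographic order
  out <- data.frame(family = fam, covered_bp = as.integer(cov),
                    covered_fraction = frac,
                    dominant = seq_along(fam) == dom,
                    stringsAsFactors = FALSE)
  attr(out, "tie") <- sum(frac == frac[dom]) > 1L
  out
}

#' Dominant TE family per variant, vectorised
#'
#' @param variants SV call table.
#' @param hits hit data.frame with a `query` column holding variant
#'   `call_id`s.
#' @return data.frame `call_id`, `dominant_family` (NA when no TE
#'   content), `covered_fraction`.
#' @export
dominant_te_family <- function(variants, hits) {
  out <- data.frame(call_id = variants$call_id,
                    dominant_family = NA_character_,
                    covered_fraction = 0, stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(out)
  split_hits <- split(hits, hits$query)
  for (i in seq_len(nrow(variants))) {
    h <- split_hits[[variants$call_id[i]]]
    if (is.null(h)) next
    ann <- annotate_variant_te(variants[i, ], h)
    if (nrow(ann)) {
      d <- ann[ann$dominant, ]
      out$dominant_family[i] <- d$family
      out$covered_fraction[i] <- d$covered_fraction
    }
  }
  out
}

alu_group <- function(subfamily) {
  ifelse(startsWith(subfamily, "AluY"), "AluY",
         ifelse(startsWith(subfamily, "AluS"), "AluS",
                ifelse(startsWith(subfamily, "AluJ"), "AluJ", NA_character_)))
}

#' Alu subfamily group of an insertion
#'
#' An insertion is assigned to AluY / AluS / AluJ when a single Alu element
#' covers strictly more than `dominant_fraction` (default 80%) of the
#' insertion after merging that element's hit fragments; otherwise `none`.
#' Grouping is by subfamily-name prefix (AluYb8 -> AluY, AluSc -> AluS, ...).
#'
#' @param variant single-row insertion call.
#' @param hits hits over the insertion sequence (as
#'   [annotate_variant_te()]).
#' @param cfg a [te_config()].
#' @return one of `"AluY"`, `"AluS"`, `"AluJ"`, `"none"`.
#' @export
assign_alu_subfamily <- function(variant, hits, cfg = te_config()) {
  alu <- hits[hits$family == "SINE/Alu", , drop = FALSE]
  if (nrow(alu) == 0L) return("none")
  cov <- merged_covered_bp(alu, as.integer(variant$length), "subfamily")
  frac <- as.numeric(cov) / as.integer(variant$length)
  best <- order(-frac, names(cov))[1L]
  if (frac[best] > cfg$dominant_fraction) {
    grp <- alu_group(names(cov)[best])
    if (!is.na(grp)) return(grp)
  }
  "none"
}

#' Is a masked element full-length?
#'
#' Compares the masked length of a hit against the consensus length of its
#' family; truncated LINE/L1 fragments (the norm in read-length-limited
#' data) fail this test while complete ~300 bp Alu copies pass it.
#'
#' @param hit single hit (or data.frame row set) with `start`, `end`,
#'   `family`.
#' @param cfg a [te_config()].
#' @return logical vector; unknown families fall back to the largest
#'   configured consensus and are flagged via attribute `unknown_family`.
#' @export
full_length_flag <- function(hit, cfg = te_config()) {
  masked <- hit$end - hit$start
  cons <- cfg$consensus_length[hit$family]
  unknown <- is.na(cons)
  cons[unknown] <- max(cfg$consensus_length)
  out <- masked >= cfg$full_length_min_fraction * cons
  attr(out, "unknown_family") <- unname(unknown)
  out
}

# Elements whose (window-expanded) span contains position `pos`, ordered
# by overlap with the deletion interior (desc), divergence, start.
breakpoint_candidates <- function(pos, deletion, elements, window) {
  idx <- which(elements$contig == deletion$contig &
                 elements$start - window <= pos &
                 pos < elements$end + window)
  if (length(idx) <= 1L) return(idx)
  ov <- overlap_width(elements$start[idx], elements$end[idx],
                      deletion$start, deletion$end)
  idx[order(-ov, elements$divergence[idx], elements$start[idx])]
}

#' Classify a deletion as NAHR-mediated from breakpoint repeat pairs
#'
#' A deletion is consistent with non-allelic homologous recombination when
#' its two breakpoints fall on two *distinct* reference transposon
#' elements of the same family (e.g. an AluSc at the left breakpoint and
#' an AluSg at the right). The verdict is decided over all candidate
#' element pairs at the two breakpoints; the reported representative pair
#' is chosen by largest overlap with the deletion interior, then smallest
#' divergence, then leftmost start. A single element spanning the whole
#' deletion never qualifies (distinct-element requirement). Family matching
#' is at family granularity (`SINE/Alu`, `LINE/L1`), not subfamily.
#'
#' @param deletion single-row DEL call (reference coordinates, 0-based
#'   half-open `start`/`end`).
#' @param reference_elements TE element table (see
#'   [te_elements_from_hits()]).
#' @param cfg a [te_config()]; `breakpoint_window` expands each element by
#'   the configured tolerance before the containment test.
#' @return list of class `nahr_classification`: `variant_id`,
#'   `left_element`, `right_element` (single-row data.frames or `NULL`),
#'   `same_family` (logical), `family` (when same_family).
#' @export
classify_nahr <- function(deletion, reference_elements, cfg = te_config()) {
  w <- cfg$breakpoint_window
  left <- breakpoint_candidates(deletion$start, deletion, reference_elements, w)
  right <- breakpoint_candidates(deletion$end, deletion, reference_elements, w)
  same_family <- FALSE
  family <- NA_character_
  li <- if (length(left)) left[1L] else NA_integer_
  ri <- if (length(right)) right[1L] else NA_integer_
  if (length(left) && length(right)) {
    # decide over all distinct-element pairs; report the best-ranked pair
    pairs <- expand.grid(l = left, r = right)
    pairs <- pairs[pairs$l != pairs$r, , drop = FALSE]
    fam_ok <- reference_elements$family[pairs$l] ==
      reference_elements$family[pairs$r]
    if (any(fam_ok)) {
      same_family <- TRUE
      # candidate lists are already rank-ordered; expand.grid varies `l`
      # fastest, so the first family-consistent pair is the best-ranked
      best <- which(fam_ok)[1L]
      li <- pairs$l[best]; ri <- pairs$r[best]
      family <- reference_elements$family[li]
    }
  }
  structure(list(variant_id = deletion$call_id %||% NA_character_,
                 left_element = if (!is.na(li)) reference_elements[li, , drop = FALSE] else NULL,
                 right_element = if (!is.na(ri)) reference_elements[ri, , drop = FALSE] else NULL,
                 same_family = same_family, family = family),
            class = "nahr_classification")
}

#' NAHR classification for a deletion table
#' @param deletions DEL call table.
#' @param reference_elements TE element table.
#' @param cfg a [te_config()].
#' @return data.frame `variant_id`, `left_element`, `right_element`
#'   (element ids or NA), `left_family`, `right_family`, `same_family`,
#'   `family`.
#' @export
classify_nahr_all <- function(deletions, reference_elements,
                              cfg = te_config()) {
  rows <- lapply(seq_len(nrow(deletions)), function(i) {
    cl <- classify_nahr(deletions[i, ], reference_elements, cfg)
    data.frame(
      variant_id = deletions$call_id[i],
      left_element = if (!is.null(cl$left_element)) cl$left_element$element_id else NA_character_,
      right_element = if (!is.null(cl$right_element)) cl$right_element$element_id else NA_character_,
      left_family = if (!is.null(cl$left_element)) cl$left_element$family else NA_character_,
      right_family = if (!is.null(cl$right_element)) cl$right_element$family else NA_character_,
      same_family = cl$same_family, family = cl$family,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), left_element = character(),
                      right_element = character(), left_family = character(),
                      right_family = character(), same_family = logical(),
                      family = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Reference TE family at an insertion site
#'
#' Looks up the reference element containing each insertion point (exact
#' containment, window 0 by default; if overlapping elements occur, the
#' one overlapping the point region most is taken) and compares its family
#' with the insertion's own dominant family.
#'
#' @param insertions INS call table with a `dominant_family` column (join
#'   of [dominant_te_family()]), or pass `dominant_family` separately.
#' @param reference_elements TE element table.
#' @param dominant_family optional character vector overriding the column.
#' @param window bp tolerance around the insertion point (default 0).
#' @return data.frame `call_id`, `target_element`, `target_family` (NA in
#'   unannotated sequence), `same_family`.
#' @export
insertion_target_class <- function(insertions, reference_elements,
                                   dominant_family = NULL, window = 0L) {
  if (is.null(dominant_family)) dominant_family <- insertions$dominant_family
  n <- nrow(insertions)
  target_el <- rep(NA_character_, n)
  target_fam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pos <- insertions$start[i]
    idx <- which(reference_elements$contig == insertions$contig[i] &
                   reference_elements$start - window <= pos &
                   pos < reference_elements$end + window)
    if (length(idx) == 0L) next
    if (length(idx) > 1L) {
      ov <- overlap_width(reference_elements$start[idx],
                          reference_elements$end[idx], pos, pos + 1L)
      idx <- idx[order(-ov, reference_elements$start[idx])]
    }
    target_el[i] <- reference_elements$element_id[idx[1L]]
    target_fam[i] <- reference_elements$family[idx[1L]]
  }
  data.frame(call_id = insertions$call_id, target_element = target_el,
             target_family = target_fam,
             same_family = !is.na(target_fam) & !is.na(dominant_family) &
               target_fam == dominant_family,
             stringsAsFactors = FALSE)
}
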