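# Enrichment folds and permutation statistics: interval shuffling over the
# mappable genome, normal-approximation Z-tests against the permutation
# null, TE-association and exon-depletion tests.

#' Statistics configuration
#'
#' @param genomic_fraction named numeric: fraction of the genome covered by
#'   each TE family (defaults `LINE/L1` 0.17, `SINE/Alu` 0.11, the standard
#'   human genome-wide figures).
#' @param n_permutations permutations for the null (default 10000;
#'   refused below 100).
#' @param alpha significance level (default 0.05; significance is
#'   `p <= alpha`).
#' @param sidedness `"greater"` (enrichment), `"less"` (depletion) or
#'   `"two_sided"`.
#' @param seed integer seed for the shuffling RNG (NULL = current stream).
#' @return list of class `stats_config`.
#' @export
stats_config <- function(genomic_fraction = c("LINE/L1" = 0.17,
                                              "SINE/Alu" = 0.11),
                         n_permutations = 10000L, alpha = 0.05,
                         sidedness = c("greater", "less", "two_sided"),
                         seed = NULL) {
  sidedness <- match.arg(sidedness)
  stopifnot(all(genomic_fraction > 0), all(genomic_fraction < 1),
            n_permutations >= 100L, alpha > 0, alpha < 1)
  structure(list(genomic_fraction = genomic_fraction,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, sidedness = sidedness, seed = seed),
            class = "stats_config")
}

#' Fold enrichment of an observed fraction over a genomic expectation
#' @param observed_fraction observed fraction (e.g. of insertions landing
#'   in same-family reference elements).
#' @param genomic_fraction genome-wide fraction covered by the feature.
#' @return `observed / genomic`; `NA` with attribute `undefined` when the
#'   expectation is zero.
#' @export
enrichment_fold <- function(observed_fraction, genomic_fraction) {
  if (any(genomic_fraction == 0)) return(structure(NA_real_, undefined = TRUE))
  structure(observed_fraction / genomic_fraction, undefined = FALSE)
}

# Precomputed shuffling machinery over the mappable stretches of a layout.
# For an interval of length L the valid start positions in stretch j are
# width_j - L + 1 (when positive); placement is uniform over the union.
shuffle_engine <- function(lengths, layout) {
  stretches <- mappable_regions(layout)
  widths <- stretches$end - stretches$start
  n <- length(lengths)
  ns <- nrow(stretches)
  pos <- outer(lengths, widths, function(l, w) pmax(w - l + 1, 0))
  total <- rowSums(pos)
  if (any(total <= 0)) {
    bad <- which(total <= 0)[1L]
    stop("interval of length ", lengths[bad],
         " bp does not fit in any mappable stretch")
  }
  cum <- if (ns == 1L) pos else t(apply(pos, 1L, cumsum))  # n x ns cumulative positions
  cum_before <- cbind(0, cum[, -ns, drop = FALSE])
  draw_raw <- function() {
    u <- floor(stats::runif(n) * total)      # uniform on [0, total)
    u <- pmin(u, total - 1)
    j <- rowSums(u >= cum)                   # 0-based stretch index
    offset <- u - cum_before[cbind(seq_len(n), j + 1L)]
    list(contig = stretches$contig[j + 1L],
         start = as.integer(stretches$start[j + 1L] + offset))
  }
  draw <- function() {
    p <- draw_raw()
    data.frame(contig = p$contig, start = p$start, stringsAsFactors = FALSE)
  }
  list(draw = draw, draw_raw = draw_raw, stretches = stretches)
}

#' Shuffle intervals uniformly over the mappable genome
#'
#' Interval lengths are preserved exactly; each interval is placed
#' uniformly over all start positions at which it fits entirely inside a
#' mappable (non-gap) stretch. Intra-set overlaps are permitted and
#' feature intervals are not excluded, matching the defaults of the
#' standard genome-shuffling tool.
#'
#' @param intervals data.frame `contig`, `start`, `end` (0-based
#'   half-open).
#' @param layout a [genome_layout()].
#' @param seed integer seed (NULL = current RNG stream).
#' @return data.frame `contig`, `start`, `end` with the same lengths, in
#'   input order.
#' @export
shuffle_intervals <- function(intervals, layout, seed = NULL) {
  lengths <- pmax(intervals$end - intervals$start, 1L)
  eng <- shuffle_engine(lengths, layout)
  placed <- with_seed(seed, eng$draw())
  data.frame(contig = placed$contig, start = placed$start,
             end = as.integer(placed$start + lengths),
             stringsAsFactors = FALSE)
}

# Fast overlap fraction against a reduced feature set (per contig sorted).
prepare_features <- function(features) {
  red <- reduce_intervals(features)
  split(red, red$contig)
}

overlap_fraction <- function(contig, start, end, feat_by_contig) {
  end <- pmax(end, start + 1L)
  hit <- logical(length(start))
  for (ctg in unique(contig)) {
    f <- feat_by_contig[[ctg]]
    if (is.null(f) || nrow(f) == 0L) next
    idx <- which(contig == ctg)
    k <- findInterval(start[idx], f$start)
    inside <- k >= 1L & f$end[pmax(k, 1L)] > start[idx]
    nxt <- k < nrow(f) & f$start[pmin(k + 1L, nrow(f))] < end[idx]
    hit[idx] <- inside | nxt
  }
  mean(hit)
}

#' Permutation Z-test for feature overlap
#'
#' The statistic is the fraction of intervals overlapping at least one
#' feature interval. A null distribution is built by re-placing the
#' intervals uniformly over the mappable genome `n_permutations` times
#' (lengths preserved); `z = (observed - null mean) / null SD` with a
#' normal-approximation p-value in the configured direction. The empirical
#' permutation p-value (add-one corrected) is reported alongside. A
#' degenerate null (SD = 0) yields p exactly 0 or 1 and a flag.
#'
#' @param intervals data.frame `contig`, `start`, `end` of the observed
#'   intervals (insertion points may be zero-width; they are widened to
#'   1 bp for the overlap test).
#' @param features feature intervals (TE elements, exons, ...).
#' @param layout a [genome_layout()].
#' @param cfg a [stats_config()] (sidedness, permutations, alpha, seed).
#' @param label optional label carried into the result.
#' @param observed_stat optional externally computed observed fraction;
#'   default is computed from `intervals`.
#' @return one-row data.frame of class `enrichment_result`: `label`, `n`,
#'   `observed_fraction`, `expected_fraction` (null mean), `fold`,
#'   `null_sd`, `z`, `p` (normal), `p_empirical`, `significant`,
#'   `degenerate`, `n_permutations`, `sidedness`.
#' @export
permutation_ztest <- function(intervals, features, layout,
                              cfg = stats_config(), label = NA_character_,
                              observed_stat = NULL) {
  if (cfg$n_permutations < 100L) stop("fewer than 100 permutations refused")
  if (nrow(intervals) == 0L) {
    out <- enrichment_row(label, 0L, NA_real_, NA_real_, NA_real_, NA_real_,
                          NA_real_, NA_real_, FALSE, TRUE, cfg)
    return(out)
  }
  feat <- prepare_features(features)
  obs <- observed_stat %||%
    overlap_fraction(intervals$contig, intervals$start, intervals$end, feat)
  # sorted lengths make the null independent of input row order
  lengths <- sort(pmax(intervals$end - intervals$start, 1L))
  eng <- shuffle_engine(lengths, layout)
  null <- with_seed(cfg$seed, {
    vapply(seq_len(cfg$n_permutations), function(i) {
      placed <- eng$draw_raw()
      overlap_fraction(placed$contig, placed$start, placed$start + lengths,
                       feat)
    }, numeric(1))
  })
  mu <- mean(null)
  sdv <- stats::sd(null)
  degenerate <- is.na(sdv) || sdv == 0
  if (degenerate) {
    z <- NA_real_
    p <- switch(cfg$sidedness,
                greater = as.numeric(obs <= mu),
                less = as.numeric(obs >= mu),
                two_sided = as.numeric(obs == mu))
  } else {
    z <- (obs - mu) / sdv
    p <- switch(cfg$sidedness,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z, lower.tail = TRUE),
                two_sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  }
  p_emp <- switch(cfg$sidedness,
                  greater = (1 + sum(null >= obs)) / (cfg$n_permutations + 1),
                  less = (1 + sum(null <= obs)) / (cfg$n_permutations + 1),
                  two_sided = (1 + sum(abs(null - mu) >= abs(obs - mu))) /
                    (cfg$n_permutations + 1))
  enrichment_row(label, nrow(intervals), obs, mu, sdv, z, p, p_emp,
                 p <= cfg$alpha, degenerate, cfg)
}

enrichment_row <- function(label, n, obs, mu, sdv, z, p, p_emp, sig,
                           degenerate, cfg) {
  out <- data.frame(label = label, n = n, observed_fraction = obs,
                    expected_fraction = mu,
                    fold = ifelse(!is.na(mu) && mu > 0, obs / mu, NA_real_),
                    null_sd = sdv, z = z, p = p, p_empirical = p_emp,
                    significant = isTRUE(sig), degenerate = degenerate,
                    n_permutations = cfg$n_permutations,
                    sidedness = cfg$sidedness, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Transposon association test for deletions, per family
#'
#' For each TE family the statistic is the fraction of deletions
#' overlapping at least one element of that family, tested for enrichment
#' (`greater`) against the shuffled null.
#'
#' @param deletions DEL call table or interval data.frame.
#' @param te_elements TE element table with a `family` column.
#' @param layout a [genome_layout()].
#' @param cfg a [stats_config()].
#' @param label prefix for the per-family result labels.
#' @return `enrichment_result` data.frame, one row per family; empty
#'   deletion sets yield flagged undefined rows.
#' @export
te_association_test <- function(deletions, te_elements, layout,
                                cfg = stats_config(), label = "deletions") {
  cfg$sidedness <- "greater"
  fams <- sort(unique(te_elements$family))
  rows <- lapply(seq_along(fams), function(k) {
    fam <- fams[k]
    fam_cfg <- cfg
    if (!is.null(cfg$seed)) fam_cfg$seed <- cfg$seed + k
    permutation_ztest(deletions,
                      te_elements[te_elements$family == fam, , drop = FALSE],
                      layout, fam_cfg,
                      label = paste0(label, ":", fam))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Exon depletion test
#'
#' As [permutation_ztest()] with the exon intervals as the feature set and
#' sidedness `less` (depletion).
#'
#' @param variants interval data.frame (insertions are points).
#' @param exons exon intervals.
#' @param layout a [genome_layout()].
#' @param cfg a [stats_config()].
#' @param label result label.
#' @return one-row `enrichment_result`.
#' @export
exon_depletion_test <- function(variants, exons, layout,
                                cfg = stats_config(), label = "exons") {
  cfg$sidedness <- "less"
  permutation_ztest(variants, exons, layout, cfg, label = label)
}

#' Fraction of variants overlapping exons
#' @param variants interval data.frame `contig`, `start`, `end`
#'   (insertion points widened to 1 bp).
#' @param exons exon intervals.
#' @return fraction with >= 1 bp exon overlap.
#' @export
exonic_fraction <- function(variants, exons) {
  if (nrow(variants) == 0L) return(NA_real_)
  mean(overlaps_any(variants$contig, variants$start, variants$end,
                    reduce_intervals(exons)))
}
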