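# Call-level quality and chimera filters for single-cell long-read
# callsets, with deterministic first-failing-rule reporting.

#' Filter configuration
#'
#' Thresholds follow the standard quality regime for whole-genome-amplified
#' long-read callsets: loci covered by at least 5 reads, calls supported by
#' at least 3 reads with a PASS filter flag, structural variants at least
#' 50 bp long, and exclusion of inversions/duplications (plus unresolved
#' breakends), which in MDA-amplified material are dominated by chimeric
#' amplification artifacts. The high-confidence tier additionally requires
#' genotype quality >= 20.
#'
#' @param min_locus_depth minimum reads covering the locus (default 5).
#' @param min_support minimum reads supporting the call (default 3).
#' @param require_pass require the VCF FILTER field to equal `PASS`.
#' @param min_sv_length minimum SV length in bp (default 50, inclusive;
#'   see `sv_length_inclusive`).
#' @param sv_length_inclusive if `TRUE` (default) SVs of exactly
#'   `min_sv_length` bp are kept, matching the conventional 50 bp SV floor.
#' @param min_gq_highconf genotype-quality threshold for the
#'   high-confidence tier (default 20, inclusive).
#' @param excluded_svtypes SV types dropped outright (default INV, DUP,
#'   BND — the chimera-prone classes).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_locus_depth = 5L, min_support = 3L,
                          require_pass = TRUE, min_sv_length = 50L,
                          sv_length_inclusive = TRUE,
                          min_gq_highconf = 20L,
                          excluded_svtypes = c("INV", "DUP", "BND")) {
  stopifnot(min_locus_depth >= 0L, min_support >= 0L, min_sv_length >= 0L,
            min_gq_highconf >= 0L)
  structure(list(min_locus_depth = as.integer(min_locus_depth),
                 min_support = as.integer(min_support),
                 require_pass = isTRUE(require_pass),
                 min_sv_length = as.integer(min_sv_length),
                 sv_length_inclusive = isTRUE(sv_length_inclusive),
                 min_gq_highconf = as.integer(min_gq_highconf),
                 excluded_svtypes = as.character(excluded_svtypes)),
            class = "filter_config")
}

# Shared engine: `rules` is an ordered named list of logical "reject"
# vectors (NA treated by the preceding missing-field rule). Attribution is
# first-failing-rule so reports are deterministic and conserve counts.
apply_rules <- function(calls, rules) {
  n <- nrow(calls)
  reason <- rep(NA_character_, n)
  for (nm in names(rules)) {
    rej <- rules[[nm]]
    rej[is.na(rej)] <- FALSE
    hit <- is.na(reason) & rej
    reason[hit] <- nm
  }
  retained <- calls[is.na(reason), , drop = FALSE]
  counts <- vapply(names(rules), function(nm) sum(reason == nm, na.rm = TRUE), 1L)
  report <- list(n_input = n, n_retained = nrow(retained),
                 rejections = data.frame(rule = names(rules),
                                         n_rejected = unname(counts),
                                         stringsAsFactors = FALSE))
  class(report) <- "filter_report"
  list(calls = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "in,", x$n_retained, "retained\n")
  rej <- x$rejections[x$rejections$n_rejected > 0L, , drop = FALSE]
  if (nrow(rej)) {
    for (i in seq_len(nrow(rej)))
      cat("  -", rej$rule[i], ":", rej$n_rejected[i], "\n")
  }
  invisible(x)
}

#' Filter SNV/indel calls
#'
#' Retains calls covered by at least `min_locus_depth` reads, supported by
#' at least `min_support` reads, carrying the PASS flag (when required),
#' and — in the high-confidence tier — with genotype quality at or above
#' `min_gq_highconf`. Calls with missing depth or support are rejected
#' under an explicit `missing_field` rule, never silently kept.
#'
#' @param calls small-variant table (see [small_variants()]).
#' @param cfg a [filter_config()].
#' @param highconf apply the genotype-quality rule.
#' @return list with `calls` (retained rows) and `report`
#'   (a `filter_report`: input, retained and per-rule rejection counts).
#' @export
filter_small_variants <- function(calls, cfg = filter_config(),
                                  highconf = FALSE) {
  stopifnot(inherits(cfg, "filter_config"))
  rules <- list(
    missing_field = is.na(calls$depth) | is.na(calls$alt_support) |
      (highconf & is.na(calls$gq)),
    filter = if (cfg$require_pass) calls$filter != "PASS" else rep(FALSE, nrow(calls)),
    support = calls$alt_support < cfg$min_support,
    depth = calls$depth < cfg$min_locus_depth,
    gq = if (highconf) calls$gq < cfg$min_gq_highconf else rep(FALSE, nrow(calls)))
  apply_rules(calls, rules)
}

#' Filter structural-variant calls
#'
#' Rule order is fixed (type, filter, length, support, depth) and a call is
#' attributed to the first rule it fails, so reports are deterministic and
#' `input = retained + sum(rejections)` always holds. Inversions,
#' duplications and breakends are dropped as amplification-chimera proxies;
#' BND records (which carry no length) never reach the length rule.
#'
#' @param calls SV call table (see [sv_calls()]).
#' @param cfg a [filter_config()].
#' @return list with `calls` and `report`, as [filter_small_variants()].
#' @export
filter_sv_calls <- function(calls, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  min_len <- if (cfg$sv_length_inclusive) cfg$min_sv_length else cfg$min_sv_length + 1L
  rules <- list(
    type = calls$svtype %in% cfg$excluded_svtypes,
    missing_field = is.na(calls$support) | is.na(calls$depth) |
      is.na(calls$length),
    filter = if (cfg$require_pass) calls$filter != "PASS" else rep(FALSE, nrow(calls)),
    length = calls$length < min_len,
    support = calls$support < cfg$min_support,
    depth = calls$depth < cfg$min_locus_depth)
  apply_rules(calls, rules)
}

#' Single-base substitution spectrum
#'
#' Collapses the twelve substitution types to the six pyrimidine-reference
#' classes (a G>A call is counted as C>T on the opposite strand, etc.) and
#' returns their fractions. Indels and non-ACGT alleles are ignored.
#'
#' @param snvs small-variant table; only rows with single-base ref and alt
#'   are used.
#' @return named numeric of length 6 (`C>A`, `C>G`, `C>T`, `T>A`, `T>C`,
#'   `T>G`) summing to 1 for non-empty input; attributes `n` (substitution
#'   count) and `empty` (logical).
#' @export
compute_substitution_spectrum <- function(snvs) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- !is.na(snvs$ref) & !is.na(snvs$alt) &
    nchar(snvs$ref) == 1L & nchar(snvs$alt) == 1L &
    snvs$ref %in% names(comp) & snvs$alt %in% names(comp) &
    snvs$ref != snvs$alt
  ref <- snvs$ref[ok]
  alt <- snvs$alt[ok]
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  key <- paste0(ref, ">", alt)
  counts <- vapply(classes, function(k) sum(key == k), 1L)
  n <- sum(counts)
  frac <- if (n > 0L) counts / n else stats::setNames(rep(0, 6L), classes)
  attr(frac, "n") <- n
  attr(frac, "empty") <- n == 0L
  frac
}
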