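# RepeatMasker `.out` dialect: 15 whitespace-delimited columns after two
# header lines and a blank line; query/repeat coordinates are 1-based
# inclusive. Used both for the reference transposon annotation (query =
# contig) and for per-variant sequence annotation (query = call id).

RM_HEADER <- c(
  "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)     ID",
  "")

#' Write transposon hits in the RepeatMasker `.out` dialect
#'
#' @param hits data.frame with columns `query`, `start`, `end` (0-based
#'   half-open; converted to the format's 1-based inclusive positions),
#'   `strand` (`+`/`-`; written as `+`/`C`), `subfamily`, `family`,
#'   `divergence` (percent) and optionally `score`, `qlen` (query length,
#'   used for the "(left)" column; 0 assumed when absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  stopifnot(all(c("query", "start", "end", "strand", "subfamily", "family",
                  "divergence") %in% names(hits)))
  d <- hits[order(hits$query, hits$start, hits$end), , drop = FALSE]
  score <- if ("score" %in% names(d)) d$score else rep(1000L, nrow(d))
  qlen <- if ("qlen" %in% names(d)) d$qlen else d$end
  left <- sprintf("(%d)", pmax(0L, as.integer(qlen) - d$end))
  rlen <- d$end - d$start
  rows <- sprintf("%5d %5.1f  0.0  0.0  %s %d %d %s %s  %s  %s  1  %d  (0)  %d",
                  as.integer(score), d$divergence, d$query,
                  d$start + 1L, d$end, left,
                  ifelse(d$strand == "-", "C", "+"),
                  d$subfamily, d$family, rlen, seq_len(nrow(d)))
  writeLines(c(RM_HEADER, rows), path)
  invisible(path)
}

#' Read a RepeatMasker `.out` file
#'
#' Skips the three header lines, splits rows on whitespace, and converts
#' the 1-based inclusive query positions to 0-based half-open. Rows with
#' fewer than 14 fields are skipped with a warning.
#'
#' @param path `.out` file.
#' @return data.frame `query`, `start`, `end`, `strand`, `subfamily`,
#'   `family`, `divergence`, `score`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character(0)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query = character(), start = integer(), end = integer(),
                      strand = character(), subfamily = character(),
                      family = character(), divergence = numeric(),
                      score = numeric(), qlen = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L)) {
    warning(sum(nf < 14L), " malformed row(s) with fewer than 14 fields skipped")
    fields <- fields[nf >= 14L]
  }
  if (length(fields) == 0L) return(empty)
  m <- do.call(rbind, fields)
  qleft <- suppressWarnings(as.integer(gsub("[()]", "", m[, 8L])))
  end <- as.integer(m[, 7L])
  data.frame(query = m[, 5L],
             start = as.integer(m[, 6L]) - 1L,
             end = end,
             strand = ifelse(m[, 9L] == "C", "-", "+"),
             subfamily = m[, 10L],
             family = m[, 11L],
             divergence = as.numeric(m[, 2L]),
             score = as.numeric(m[, 1L]),
             qlen = end + ifelse(is.na(qleft), 0L, qleft),
             stringsAsFactors = FALSE)
}

#' Reference TE elements from RepeatMasker-style hits
#'
#' Reinterprets hits whose query is a contig as reference transposon
#' elements and assigns stable element ids.
#'
#' @param hits data.frame as returned by [read_repeatmasker_out()].
#' @return data.frame `element_id`, `contig`, `start`, `end`, `strand`,
#'   `family`, `subfamily`, `divergence`.
#' @export
te_elements_from_hits <- function(hits) {
  d <- hits[order(hits$query, hits$start, hits$end), , drop = FALSE]
  data.frame(element_id = sprintf("TE%06d", seq_len(nrow(d))),
             contig = d$query, start = d$start, end = d$end,
             strand = d$strand, family = d$family, subfamily = d$subfamily,
             divergence = d$divergence, stringsAsFactors = FALSE)
}

#' Write reference TE elements as 6-column BED
#'
#' The BED name field packs `family;subfamily` (family strings themselves
#' contain `/`, e.g. `SINE/Alu`); score is divergence scaled by 10.
#' @param elements TE element data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(elements, path) {
  d <- elements[order(elements$contig, elements$start), , drop = FALSE]
  write_bed(data.frame(contig = d$contig, start = d$start, end = d$end,
                       name = paste(d$family, d$subfamily, sep = ";"),
                       score = as.integer(round(d$divergence * 10)),
                       strand = d$strand, stringsAsFactors = FALSE), path)
}

#' Read a 6-column TE BED written by [write_te_bed()]
#' @param path BED file.
#' @return TE element data.frame (as [te_elements_from_hits()]).
#' @export
read_te_bed <- function(path) {
  d <- read_bed(path)
  parts <- strsplit(d$name, ";", fixed = TRUE)
  data.frame(element_id = sprintf("TE%06d", seq_len(nrow(d))),
             contig = d$contig, start = d$start, end = d$end,
             strand = d$strand,
             family = vapply(parts, `[`, "", 1L),
             subfamily = vapply(parts, `[`, "", 2L),
             divergence = d$score / 10,
             stringsAsFactors = FALSE)
}
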