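# BED readers/writers (0-based half-open, the BED native convention) and
# callable-region extraction from coverage tracks.

#' Write intervals as BED3/BED6
#'
#' @param intervals data.frame with `contig`, `start`, `end` and optionally
#'   `name`, `score`, `strand` (their presence selects BED6).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  d <- intervals[order(intervals$contig, intervals$start, intervals$end), ,
                 drop = FALSE]
  if (all(c("name", "score", "strand") %in% names(intervals))) {
    lines <- paste(d$contig, d$start, d$end, d$name, d$score, d$strand,
                   sep = "\t")
  } else {
    lines <- paste(d$contig, d$start, d$end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED6 file
#' @param path BED file.
#' @return data.frame `contig`, `start`, `end` (+ `name`, `score`, `strand`
#'   when present).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  names(d)[1:3] <- c("contig", "start", "end")
  if (ncol(d) >= 6L) names(d)[4:6] <- c("name", "score", "strand")
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  d
}

#' Write a coverage track as 4-column BED
#'
#' Columns: contig, start, end, depth (0-based half-open intervals of
#' constant depth).
#' @param track data.frame `contig`, `start`, `end`, `depth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(track, path) {
  stopifnot(all(c("contig", "start", "end", "depth") %in% names(track)))
  d <- track[order(track$contig, track$start), , drop = FALSE]
  writeLines(paste(d$contig, d$start, d$end, d$depth, sep = "\t"), path)
  invisible(path)
}

#' Read a 4-column coverage BED
#' @param path file written by [write_coverage_bed()] or mosdepth-style
#'   per-window output.
#' @return data.frame `contig`, `start`, `end`, `depth`.
#' @export
read_coverage_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), depth = integer(),
                      stringsAsFactors = FALSE))
  }
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("contig", "start", "end", "depth"))
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  d$depth <- as.integer(d$depth)
  d
}

#' Callable regions of a coverage track
#'
#' Maximal merged intervals whose depth is at least `min_depth`; adjacent
#' qualifying windows are fused. Raising `min_depth` can only shrink the
#' result (bp-wise subset), which the tests assert as a property.
#'
#' @param track coverage data.frame `contig`, `start`, `end`, `depth`.
#' @param min_depth minimum depth (>= 1).
#' @return data.frame `contig`, `start`, `end`, sorted and non-overlapping.
#' @export
callable_regions <- function(track, min_depth = 5L) {
  stopifnot(min_depth >= 1L)
  keep <- track[!is.na(track$depth) & track$depth >= min_depth, , drop = FALSE]
  reduce_intervals(keep)
}
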