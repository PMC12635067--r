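#' Genome layout: contigs and unmappable gaps
#'
#' A genome layout records the contigs the analysis operates on and the
#' unmappable gap intervals that are excluded from interval shuffling and
#' from event planting in the synthetic generator. All coordinates are
#' 0-based half-open; conversions to file conventions happen only in the
#' readers and writers.
#'
#' @param contigs data.frame with columns `name` (unique character) and
#'   `length` (positive integer bp).
#' @param gaps data.frame with columns `contig`, `start`, `end` (0-based
#'   half-open). Overlapping gaps are merged; out-of-bounds gaps are an
#'   error. May be empty.
#' @return An object of class `genome_layout`: a list with elements
#'   `contigs` and `gaps` (normalised).
#' @examples
#' layout <- genome_layout(data.frame(name = "chrS", length = 1e6L))
#' mappable_length(layout)
#' @export
genome_layout <- function(contigs,
                          gaps = data.frame(contig = character(),
                                            start = integer(),
                                            end = integer())) {
  stopifnot(is.data.frame(contigs), all(c("name", "length") %in% names(contigs)))
  if (nrow(contigs) == 0L) stop("at least one contig is required")
  if (anyDuplicated(contigs$name)) stop("contig names must be unique")
  if (any(contigs$length <= 0)) stop("zero-length contig in layout")
  contigs <- data.frame(name = as.character(contigs$name),
                        length = as.integer(contigs$length),
                        stringsAsFactors = FALSE)
  gaps <- reduce_intervals(gaps)
  if (nrow(gaps) > 0L) {
    if (!all(gaps$contig %in% contigs$name)) {
      stop("gap on unknown contig: ",
           paste(setdiff(gaps$contig, contigs$name), collapse = ", "))
    }
    len <- contigs$length[match(gaps$contig, contigs$name)]
    if (any(gaps$start < 0L) || any(gaps$end > len)) {
      stop("gap interval outside its contig's bounds")
    }
  }
  structure(list(contigs = contigs, gaps = gaps), class = "genome_layout")
}

#' Mappable (non-gap) stretches of a genome layout
#'
#' @param layout a [genome_layout()].
#' @return data.frame `contig`, `start`, `end` of maximal gap-free
#'   intervals, sorted by contig order then start.
#' @export
mappable_regions <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  out <- lapply(seq_len(nrow(layout$contigs)), function(i) {
    name <- layout$contigs$name[i]
    len <- layout$contigs$length[i]
    g <- layout$gaps[layout$gaps$contig == name, , drop = FALSE]
    if (nrow(g) == 0L) {
      return(data.frame(contig = name, start = 0L, end = len,
                        stringsAsFactors = FALSE))
    }
    starts <- c(0L, g$end)
    ends <- c(g$start, len)
    keep <- ends > starts
    data.frame(contig = name, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Total mappable length of a layout, in bp
#' @param layout a [genome_layout()].
#' @return integer bp outside gaps.
#' @export
mappable_length <- function(layout) {
  m <- mappable_regions(layout)
  sum(as.numeric(m$end - m$start))
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$contigs), "contig(s),",
      fmt_count(sum(as.numeric(x$contigs$length))), "bp total,",
      fmt_count(mappable_length(x)), "bp mappable\n")
  invisible(x)
}
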