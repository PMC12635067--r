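# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation so the state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Merge possibly-overlapping 0-based half-open intervals into maximal
# disjoint ones. Accepts and returns a data.frame with contig/start/end.
reduce_intervals <- function(intervals) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(intervals, intervals$contig), function(d) {
    # IRanges is 1-based inclusive; shift on the way in and out
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(contig = d$contig[1L],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$contig, out$start), , drop = FALSE]
}

# Vectorised test: does each query interval [s, e) on `contig` overlap any
# interval of the (already reduced, sorted) feature set? Zero-width queries
# (insertion points) are widened to 1 bp so containment counts as overlap.
overlaps_any <- function(contig, start, end, features) {
  end <- pmax(end, start + 1L)
  hit <- logical(length(start))
  if (nrow(features) == 0L || length(start) == 0L) return(hit)
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    f <- features[features$contig == ctg, , drop = FALSE]
    if (nrow(f) == 0L) next
    f <- f[order(f$start), , drop = FALSE]
    k <- findInterval(start[idx], f$start)
    inside <- k >= 1L & ifelse(k >= 1L, f$end[pmax(k, 1L)] > start[idx], FALSE)
    nxt <- k < nrow(f) & f$start[pmin(k + 1L, nrow(f))] < end[idx]
    hit[idx] <- inside | nxt
  }
  hit
}

# Bases of [astart, aend) covered by [bstart, bend), vectorised.
overlap_width <- function(astart, aend, bstart, bend) {
  pmax(0L, pmin(aend, bend) - pmax(astart, bstart))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_count <- function(n) format(n, big.mark = ",", trim = TRUE)
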