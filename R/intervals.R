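# Interval arithmetic over 0-based half-open (chrom, start, end) data.frames.
# GenomicRanges does the set algebra; these helpers only translate coordinates
# (half-open 0-based <-> 1-based closed) at the boundary.

interval_frame <- function(chrom = character(), start = integer(), end = integer()) {
  data.frame(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.from_granges <- function(gr) {
  interval_frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Normalize a set of genomic intervals
#'
#' Sorts and merges overlapping or adjacent intervals. All intervals in the
#' package are 0-based half-open, so `(chr1, 10, 20)` covers positions
#' 10..19 in 0-based coordinates.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame of disjoint sorted intervals in the same convention.
#' @export
normalize_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(interval_frame())
  if (any(intervals$start >= intervals$end)) {
    stop("interval with start >= end")
  }
  .from_granges(GenomicRanges::reduce(.as_granges(intervals)))
}

#' Intersect two interval sets
#'
#' @param a,b data.frames of 0-based half-open intervals.
#' @return normalized data.frame of the intersection.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(interval_frame())
  # disjoint chromosome sets are a legal (empty) intersection, not a warning
  gr <- suppressWarnings(GenomicRanges::intersect(.as_granges(a), .as_granges(b)))
  .from_granges(gr)
}

#' Total interval length in megabases
#'
#' @param intervals data.frame of 0-based half-open intervals.
#' @return total covered length / 1e6.
#' @export
interval_mb <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  sum(intervals$end - intervals$start) / 1e6
}

# TRUE for each 1-based position lying inside the (normalized) interval set.
.pos_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L || length(pos) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pos))
  suppressWarnings(IRanges::overlapsAny(q, .as_granges(intervals)))
}
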