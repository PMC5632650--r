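# Interval helpers. All internal coordinates are 0-based half-open [start, end);
# conversion to/from 1-based inclusive happens only at I/O boundaries.

#' Merge possibly overlapping half-open intervals
#'
#' @param start,end integer vectors, 0-based half-open.
#' @return tibble with columns `start`, `end`, sorted, disjoint.
#' @keywords internal
#' @noRd
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  if (any(end <= start)) abort("intervals must satisfy start < end")
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

# total length of the union of half-open intervals
union_width <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(m$end - m$start)
}

# TRUE per interval iff it intersects any interval of the reference set
intersects_any <- function(start, end, ref_start, ref_end) {
  if (length(start) == 0L) return(logical(0))
  if (length(ref_start) == 0L) return(rep(FALSE, length(start)))
  q <- IRanges::IRanges(start = start + 1L, end = end)
  s <- IRanges::IRanges(start = ref_start + 1L, end = ref_end)
  IRanges::overlapsAny(q, s)
}

# external 1-based inclusive -> internal 0-based half-open
to_internal <- function(start1, end1) list(start = start1 - 1L, end = end1)
# and back
to_external <- function(start0, end0) list(start = start0 + 1L, end = end0)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
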