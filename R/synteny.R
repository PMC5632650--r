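# Synteny-block chaining: anchors (pairwise local alignments between genome A
# and genome B) are chained into blocks of >= min_anchors collinear anchors,
# strictly monotone on the B side (increasing = same orientation, decreasing
# = inverted), with a gap cap on both genomes; overlapping or nearby blocks
# of the same orientation are merged, and where two blocks still overlap on a
# contig only the larger one is kept.
#
# Chains are found by iterated extraction of the highest-scoring monotone
# chain (dynamic programming over anchors sorted by A-side start), so an
# isolated off-diagonal anchor inside a collinear run is skipped rather than
# splitting the run.

empty_blocks <- function() {
  tibble(block_id = integer(), contig_a = character(), contig_b = character(),
         start_a = integer(), end_a = integer(),
         start_b = integer(), end_b = integer(),
         orientation = character(), n_anchors = integer(), anchors = list())
}

validate_anchors <- function(anchors) {
  assert_cols(anchors, c("anchor_id", "contig_a", "start_a", "end_a",
                         "contig_b", "start_b", "end_b"), "anchor tibble")
  if (any(anchors$end_a <= anchors$start_a) || any(anchors$end_b <= anchors$start_b)) {
    abort("anchor intervals must satisfy start < end")
  }
  if (anyDuplicated(anchors$anchor_id)) abort("duplicate anchor ids")
  anchors
}

# longest strictly-monotone chain (direction d = +1 or -1 on B starts) with a
# gap cap on both genomes; g is sorted by (start_a, start_b); returns indices
longest_chain <- function(g, d, max_gap) {
  n <- nrow(g)
  len <- rep(1L, n)
  pred <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (d * (g$start_b[i] - g$start_b[j]) <= 0) next
      if (g$start_a[i] - g$end_a[j] > max_gap) next
      gap_b <- if (d > 0L) g$start_b[i] - g$end_b[j] else g$start_b[j] - g$end_b[i]
      if (gap_b > max_gap) next
      if (len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        pred[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  while (best != 0L) {
    chain <- c(best, chain)
    best <- pred[best]
  }
  chain
}

#' Chain anchors into synteny blocks
#'
#' Within each `(contig_a, contig_b)` pair, anchors are sorted by A-side
#' start and the highest-scoring chain whose B-side starts are strictly
#' monotone in one direction, with consecutive chain members within `max_gap`
#' on both genomes, is extracted; extraction repeats on the remaining anchors
#' until no chain reaches `min_anchors`. An isolated off-target anchor inside
#' a collinear run is therefore skipped rather than splitting the run. Block
#' orientation follows the B-side direction (increasing = `"same"`,
#' decreasing = `"inverted"`). Anchors sharing a B-side start can never occupy
#' the same block (monotonicity is strict).
#'
#' @param anchors tibble with columns `anchor_id`, `contig_a`, `start_a`,
#'   `end_a`, `contig_b`, `start_b`, `end_b` (0-based half-open).
#' @param min_anchors minimum anchors per block (default 7, the usual
#'   synteny-tool setting).
#' @param max_gap maximum gap in bp between consecutive anchors on either
#'   genome (default 100000).
#' @return tibble of class `synteny_blocks`: `block_id`, `contig_a`,
#'   `contig_b`, A- and B-side spans, `orientation` (`"same"`/`"inverted"`),
#'   `n_anchors`, `anchors` (list column of anchor ids).
#' @export
chain_anchors <- function(anchors, min_anchors = 7L, max_gap = 100000) {
  anchors <- validate_anchors(anchors)
  stopifnot(min_anchors >= 2L, max_gap >= 0)
  if (nrow(anchors) == 0L) {
    out <- empty_blocks()
    class(out) <- c("synteny_blocks", class(out))
    return(out)
  }
  groups <- split(anchors, paste(anchors$contig_a, anchors$contig_b, sep = "\r"))
  groups <- groups[order(names(groups))]
  blocks <- list()
  for (g in groups) {
    g <- arrange(g, .data$start_a, .data$start_b, .data$anchor_id)
    repeat {
      if (nrow(g) < min_anchors) break
      ch_same <- longest_chain(g, +1L, max_gap)
      ch_inv <- longest_chain(g, -1L, max_gap)
      take_same <- length(ch_same) >= length(ch_inv)   # ties favour "same"
      ch <- if (take_same) ch_same else ch_inv
      if (length(ch) < min_anchors) break
      sub <- g[ch, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- tibble(
        contig_a = sub$contig_a[1], contig_b = sub$contig_b[1],
        start_a = min(sub$start_a), end_a = max(sub$end_a),
        start_b = min(sub$start_b), end_b = max(sub$end_b),
        orientation = if (take_same) "same" else "inverted",
        n_anchors = nrow(sub),
        anchors = list(sub$anchor_id)
      )
      g <- g[-ch, , drop = FALSE]
    }
  }
  out <- if (length(blocks) > 0L) bind_rows(blocks) else empty_blocks()
  out <- arrange(out, .data$contig_a, .data$contig_b, .data$start_a)
  out$block_id <- seq_len(nrow(out))
  out <- select(out, "block_id", dplyr::everything())
  class(out) <- c("synteny_blocks", class(out))
  out
}

interval_distance <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' Merge nearby blocks and resolve residual overlaps by keeping the larger
#'
#' Two same-orientation blocks on the same contig pair are merged when both
#' their A-spans and their B-spans lie within `merge_distance` of each other
#' (anchor sets united, spans extended); merging repeats to a fixed point.
#' If two blocks still overlap on a contig afterwards, only the larger one
#' (more anchors; ties broken by longer A-span, then lower `start_a`) is
#' retained.
#'
#' @param blocks a [chain_anchors()] result.
#' @param merge_distance maximum span gap for merging, bp (default 50000).
#' @return tibble of class `synteny_blocks`.
#' @export
merge_blocks <- function(blocks, merge_distance = 50000) {
  stopifnot(inherits(blocks, "synteny_blocks"))
  b <- as_tibble(blocks)
  changed <- TRUE
  while (changed && nrow(b) > 1L) {
    changed <- FALSE
    b <- arrange(b, .data$contig_a, .data$contig_b, .data$orientation, .data$start_a)
    i <- 1L
    while (i < nrow(b)) {
      x <- b[i, ]; y <- b[i + 1L, ]
      same_pair <- x$contig_a == y$contig_a && x$contig_b == y$contig_b &&
        x$orientation == y$orientation
      if (same_pair &&
          interval_distance(x$start_a, x$end_a, y$start_a, y$end_a) <= merge_distance &&
          interval_distance(x$start_b, x$end_b, y$start_b, y$end_b) <= merge_distance) {
        b$end_a[i] <- max(x$end_a, y$end_a)
        b$start_a[i] <- min(x$start_a, y$start_a)
        b$end_b[i] <- max(x$end_b, y$end_b)
        b$start_b[i] <- min(x$start_b, y$start_b)
        b$n_anchors[i] <- x$n_anchors + y$n_anchors
        b$anchors[[i]] <- c(x$anchors[[1]], y$anchors[[1]])
        b <- b[-(i + 1L), , drop = FALSE]
        changed <- TRUE
      } else {
        i <- i + 1L
      }
    }
  }
  # keep-larger pass: blocks overlapping on either genome's contig
  b <- arrange(b, dplyr::desc(.data$n_anchors),
               dplyr::desc(.data$end_a - .data$start_a), .data$start_a)
  keep <- rep(TRUE, nrow(b))
  if (nrow(b) > 1L) {
    for (i in 2:nrow(b)) {
      for (j in seq_len(i - 1L)) {
        if (!keep[j]) next
        ov_a <- b$contig_a[i] == b$contig_a[j] &&
          interval_distance(b$start_a[i], b$end_a[i], b$start_a[j], b$end_a[j]) == 0
        ov_b <- b$contig_b[i] == b$contig_b[j] &&
          interval_distance(b$start_b[i], b$end_b[i], b$start_b[j], b$end_b[j]) == 0
        if (ov_a || ov_b) { keep[i] <- FALSE; break }
      }
    }
  }
  b <- b[keep, , drop = FALSE]
  b <- arrange(b, .data$contig_a, .data$contig_b, .data$start_a)
  b$block_id <- seq_len(nrow(b))
  class(b) <- c("synteny_blocks", class(b))
  b
}

#' Anchor-in-block fraction and block counts
#'
#' @param blocks a `synteny_blocks` tibble (typically after [merge_blocks()]).
#' @param anchors the full anchor tibble the blocks were chained from.
#' @return one-row tibble: `n_blocks`, `n_inverted`, `n_anchors_total`,
#'   `n_anchors_in_blocks`, `anchor_fraction`.
#' @export
anchor_coverage <- function(blocks, anchors) {
  anchors <- validate_anchors(anchors)
  in_blocks <- unique(unlist(blocks$anchors))
  if (!all(in_blocks %in% anchors$anchor_id)) {
    abort("blocks reference anchors absent from the anchor set")
  }
  tibble(
    n_blocks = nrow(blocks),
    n_inverted = sum(blocks$orientation == "inverted"),
    n_anchors_total = nrow(anchors),
    n_anchors_in_blocks = length(in_blocks),
    anchor_fraction = if (nrow(anchors) == 0L) 0 else
      length(in_blocks) / nrow(anchors)
  )
}
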