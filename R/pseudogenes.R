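# Pseudogene candidate calling: mask annotated genes, then interpret
# translated-homology hits landing entirely in the unmasked (intergenic)
# search space as pseudogene remnants, merging nearby hits into one call.

#' Mask annotated gene spans in a genome
#'
#' Replaces every base inside the union of the annotated gene spans with `N`,
#' the usual preparation before scanning intergenic DNA for decayed gene
#' remnants. Overlapping features are masked once.
#'
#' @param genome tibble from [read_fasta()] (`id`, `sequence`).
#' @param annotations feature tibble ([read_gff3()] layout); all features must
#'   lie within their contigs.
#' @return list of class `masked_genome` with elements `sequences` (tibble
#'   like `genome`, masked) and `ledger` (tibble `contig_id`, `start`, `end`
#'   of the disjoint masked spans, 0-based half-open).
#' @export
mask_genes <- function(genome, annotations) {
  assert_cols(genome, c("id", "sequence"), "genome tibble")
  assert_cols(annotations, c("contig_id", "start", "end"), "annotation tibble")
  unknown <- setdiff(annotations$contig_id, genome$id)
  if (length(unknown) > 0L) {
    abort(sprintf("feature(s) on unknown contig(s): %s",
                  paste(unique(unknown), collapse = ", ")))
  }
  lens <- setNames(nchar(genome$sequence), genome$id)
  if (any(annotations$end > lens[annotations$contig_id]) ||
      any(annotations$start < 0)) {
    abort("feature extends beyond its contig")
  }
  ledger <- annotations |>
    group_by(.data$contig_id) |>
    dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
    arrange(.data$contig_id, .data$start)
  seqs <- genome$sequence
  for (k in seq_len(nrow(ledger))) {
    i <- match(ledger$contig_id[k], genome$id)
    substr(seqs[i], ledger$start[k] + 1L, ledger$end[k]) <-
      strrep("N", ledger$end[k] - ledger$start[k])
  }
  out <- genome
  out$sequence <- seqs
  structure(list(sequences = out, ledger = ledger), class = "masked_genome")
}

#' @export
print.masked_genome <- function(x, ...) {
  cat(sprintf("<masked_genome> %d contig(s), %d masked span(s), %d bases masked\n",
              nrow(x$sequences), nrow(x$ledger),
              sum(x$ledger$end - x$ledger$start)))
  invisible(x)
}

#' Call candidate pseudogene intervals from translated-homology hits
#'
#' Hits at or below the e-value ceiling whose query intervals are entirely
#' disjoint from the annotated gene spans are kept (a hit partially
#' overlapping a gene span is discarded, not trimmed); kept hits on the same
#' contig whose intervals lie within `max_merge_gap` of each other are merged
#' into a single call. Calls never intersect a gene span.
#'
#' @param hits hit tibble ([read_tabular_hits()] layout) with genome contigs
#'   as queries (e.g. BLASTX of the masked genome against reference
#'   proteomes).
#' @param mask_ledger the `ledger` tibble of a [mask_genes()] result (or any
#'   tibble of gene spans: `contig_id`, `start`, `end`, 0-based half-open).
#' @param max_merge_gap merge hits separated by at most this many bp
#'   (default 100).
#' @param evalue_max e-value ceiling (default 1, the permissive cutoff
#'   appropriate for decayed sequences).
#' @return tibble with one row per call: `contig_id`, `start`, `end`
#'   (0-based half-open), `n_hits`, `best_evalue`, `subject_ids`
#'   (list column), sorted by coordinate.
#' @export
call_pseudogenes <- function(hits, mask_ledger, max_merge_gap = 100,
                             evalue_max = 1) {
  empty <- tibble(contig_id = character(), start = integer(), end = integer(),
                  n_hits = integer(), best_evalue = numeric(),
                  subject_ids = list())
  if (nrow(hits) == 0L) return(empty)
  assert_cols(mask_ledger, c("contig_id", "start", "end"), "mask ledger")
  iv <- hit_query_intervals(hits)
  iv <- iv[iv$evalue <= evalue_max, , drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  keep <- vapply(seq_len(nrow(iv)), function(i) {
    led <- mask_ledger[mask_ledger$contig_id == iv$query_id[i], , drop = FALSE]
    !any(intersects_any(iv$start[i], iv$end[i], led$start, led$end))
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  iv <- arrange(iv, .data$query_id, .data$start, .data$end)
  per_contig <- lapply(split(iv, iv$query_id), function(g) {
    gap_ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    cl <- IRanges::reduce(gap_ir, min.gapwidth = max_merge_gap + 1L,
                          with.revmap = TRUE)
    revmap <- S4Vectors::mcols(cl)$revmap
    tibble(
      contig_id = g$query_id[1],
      start = IRanges::start(cl) - 1L,
      end = IRanges::end(cl),
      n_hits = lengths(revmap),
      best_evalue = vapply(revmap, function(ix) min(g$evalue[ix]), numeric(1)),
      subject_ids = lapply(revmap, function(ix) unique(g$subject_id[ix]))
    )
  })
  arrange(bind_rows(per_contig), .data$contig_id, .data$start)
}

#' Write pseudogene calls as GFF3 and return the report tibble
#'
#' @param calls tibble from [call_pseudogenes()].
#' @param path output GFF3 path.
#' @return the report tibble (calls with external 1-based coordinates),
#'   invisibly.
#' @export
write_pseudogene_gff <- function(calls, path) {
  feats <- tibble(
    contig_id = calls$contig_id,
    start = calls$start,
    end = calls$end,
    strand = ".",
    feature_type = "pseudogene",
    id = sprintf("pseudo_%d", seq_len(nrow(calls)))
  )
  write_gff3(feats, path)
  invisible(mutate(calls, start = .data$start + 1L))
}
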