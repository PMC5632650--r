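#' Read gene annotations from a GFF3 file
#'
#' Parsing is delegated to rtracklayer; coordinates are converted from the
#' GFF3 1-based inclusive convention to the package-internal 0-based half-open
#' convention (`start = column4 - 1`, `end = column5`), and features are
#' sorted by `(contig_id, start)`. Features lacking an `ID` attribute get a
#' synthesized one (`feat_<n>`) with a warning.
#'
#' @param path path to a GFF3 file.
#' @return tibble with columns `contig_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`, `"-"` or `"."`), `feature_type`, `id`,
#'   `attributes` (list column of named character vectors).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF3 file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    return(tibble(
      contig_id = character(), start = integer(), end = integer(),
      strand = character(), feature_type = character(), id = character(),
      attributes = list()
    ))
  }
  meta <- as.data.frame(S4Vectors::mcols(gr))
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else rep(NA_character_, length(gr))
  if (anyNA(ids)) {
    warn(sprintf("%d feature(s) lack an ID attribute; IDs synthesized", sum(is.na(ids))))
    ids[is.na(ids)] <- sprintf("feat_%d", which(is.na(ids)))
  }
  attr_cols <- setdiff(names(meta), c("source", "type", "score", "phase"))
  attrs <- lapply(seq_along(gr), function(i) {
    v <- vapply(attr_cols, function(cn) {
      x <- meta[[cn]][i]
      if (is.list(x)) x <- paste(unlist(x), collapse = ",")
      as.character(x)
    }, character(1))
    v[!is.na(v)]
  })
  out <- tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(meta$type),
    id = ids,
    attributes = attrs
  )
  dplyr::arrange(out, .data$contig_id, .data$start)
}

#' Write features to GFF3
#'
#' Inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive.
#'
#' @param features tibble as returned by [read_gff3()] (the `attributes`
#'   column is optional).
#' @param path output path.
#' @param source value for GFF3 column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path, source = "endosieve") {
  assert_cols(features, c("contig_id", "start", "end", "strand", "feature_type", "id"),
              "feature tibble")
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$type <- features$feature_type
  S4Vectors::mcols(gr)$ID <- features$id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
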