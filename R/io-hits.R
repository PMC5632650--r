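#' Read a 12-column tabular homology hit file
#'
#' The standard tab-separated hit layout: query id, subject id, percent
#' identity, alignment length, mismatches, gap opens, query start, query end,
#' subject start, subject end, e-value, bit score (1-based inclusive
#' coordinates). Query coordinates are normalized so `qstart <= qend`; a hit
#' whose query coordinates arrived reversed gets `query_strand == "-"`.
#' Subject coordinates are normalized the same way into `subject_strand`.
#'
#' @param path path to the hit table (no header).
#' @param evalue_max optional e-value ceiling; rows with `evalue > evalue_max`
#'   are dropped. The number of dropped rows is recorded in the
#'   `n_filtered` attribute so no row disappears unaccounted.
#' @return tibble with columns `query_id`, `subject_id`, `pct_identity`,
#'   `aln_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `query_strand`, `subject_strand`.
#'   Coordinates remain 1-based inclusive as read; use [hit_query_intervals()]
#'   for internal coordinates.
#' @export
read_tabular_hits <- function(path, evalue_max = NULL) {
  if (!file.exists(path)) abort(sprintf("hit file not found: %s", path))
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatches", "gap_opens", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  df <- readr::read_tsv(
    path, col_names = cols,
    col_types = readr::cols(
      query_id = "c", subject_id = "c", pct_identity = "d", aln_length = "i",
      mismatches = "i", gap_opens = "i", qstart = "i", qend = "i",
      sstart = "i", send = "i", evalue = "d", bitscore = "d"
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("malformed hit table %s: line %d, column %d (%s)",
                  path, probs$row[1], probs$col[1], probs$expected[1]))
  }
  if (nrow(df) > 0L && any(df$evalue < 0)) abort("negative e-value in hit table")
  df <- as_tibble(df)
  df$query_strand <- ifelse(df$qstart <= df$qend, "+", "-")
  qs <- pmin(df$qstart, df$qend); qe <- pmax(df$qstart, df$qend)
  df$qstart <- qs; df$qend <- qe
  df$subject_strand <- ifelse(df$sstart <= df$send, "+", "-")
  ss <- pmin(df$sstart, df$send); se <- pmax(df$sstart, df$send)
  df$sstart <- ss; df$send <- se
  n_filtered <- 0L
  if (!is.null(evalue_max)) {
    keep <- df$evalue <= evalue_max
    n_filtered <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  attr(df, "n_filtered") <- n_filtered
  df
}

#' Write hits back to the 12-column tabular layout
#'
#' Inverse of [read_tabular_hits()]: strand flags are folded back into the
#' coordinate order (a `"-"` strand restores `qstart > qend`), so a
#' write/read cycle reproduces the normalized tibble exactly.
#'
#' @param hits normalized hit tibble from [read_tabular_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  assert_cols(hits, c("query_id", "subject_id", "pct_identity", "aln_length",
                      "mismatches", "gap_opens", "qstart", "qend", "sstart",
                      "send", "evalue", "bitscore"), "hit tibble")
  qstrand <- if (is.null(hits[["query_strand"]])) rep("+", nrow(hits)) else
    hits$query_strand
  sstrand <- if (is.null(hits[["subject_strand"]])) rep("+", nrow(hits)) else
    hits$subject_strand
  out <- tibble(
    query_id = hits$query_id, subject_id = hits$subject_id,
    pct_identity = hits$pct_identity, aln_length = hits$aln_length,
    mismatches = hits$mismatches, gap_opens = hits$gap_opens,
    qstart = ifelse(qstrand == "-", hits$qend, hits$qstart),
    qend = ifelse(qstrand == "-", hits$qstart, hits$qend),
    sstart = ifelse(sstrand == "-", hits$send, hits$sstart),
    send = ifelse(sstrand == "-", hits$sstart, hits$send),
    evalue = hits$evalue, bitscore = hits$bitscore
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Query-side hit intervals in internal coordinates
#'
#' Converts the 1-based inclusive query coordinates of a hit tibble to the
#' internal 0-based half-open convention.
#'
#' @param hits tibble from [read_tabular_hits()].
#' @return tibble with `query_id`, `subject_id`, `start`, `end` (0-based
#'   half-open), `evalue`.
#' @export
hit_query_intervals <- function(hits) {
  assert_cols(hits, c("query_id", "qstart", "qend"), "hit tibble")
  tibble(
    query_id = hits$query_id,
    subject_id = hits$subject_id,
    start = hits$qstart - 1L,
    end = as.integer(hits$qend),
    evalue = hits$evalue
  )
}

#' Read a counts matrix (OG-by-taxon) from TSV
#'
#' First column: row (OG) ids; header row: taxon ids; cells: non-negative
#' integer gene counts.
#'
#' @param path path to the TSV.
#' @return tibble whose first column is `og` and remaining columns are taxa.
#' @export
read_og_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  names(df)[1] <- "og"
  if (anyDuplicated(df$og)) abort("duplicate OG ids in matrix")
  counts <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(counts))) abort("duplicate taxon ids in matrix")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("matrix cells must be non-negative integers")
  }
  as_tibble(df)
}

#' Read long-format OG membership (OG id, taxon, gene id) into a counts matrix
#'
#' @param path TSV with three columns and no header: OG id, taxon, gene id.
#' @return wide counts tibble as from [read_og_matrix()].
#' @export
read_og_membership <- function(path) {
  df <- readr::read_tsv(path, col_names = c("og", "taxon", "gene"),
                        col_types = "ccc", progress = FALSE)
  if (anyDuplicated(df)) warn("duplicate (og, taxon, gene) rows collapsed")
  df |>
    distinct() |>
    dplyr::count(.data$og, .data$taxon) |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "n", values_fill = 0L) |>
    arrange(.data$og)
}
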