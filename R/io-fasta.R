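#' Read a FASTA file into a tibble
#'
#' Sequences are stored uppercase. In nucleotide mode only `A`, `C`, `G`, `T`
#' and `N` are accepted; `U` is silently meaningful RNA input and is converted
#' to `T` with a warning. In protein mode the 20 amino-acid one-letter codes,
#' `X`, `*` and the gap character `-` are accepted, so aligned FASTA reads
#' with the same function.
#'
#' @param path path to a FASTA file.
#' @param mode `"nucleotide"` (default) or `"protein"`.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `description` (remainder of the header, possibly `""`) and
#'   `sequence`.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">ctg1 symbiont", "acgtACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- stringr::str_extract(headers, "^\\S+")
  if (length(ids) > 0 && anyNA(ids)) abort("FASTA record with empty header")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+"))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    abort(sprintf("empty sequence for record '%s'", ids[nchar(seqs) == 0L][1]))
  }
  if (mode == "nucleotide" && any(stringr::str_detect(seqs, "U"))) {
    warn("'U' found in nucleotide input; converted to 'T'")
    seqs <- stringr::str_replace_all(seqs, "U", "T")
  }
  alphabet <- if (mode == "nucleotide") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX*-"
  bad <- stringr::str_locate(seqs, sprintf("[^%s]", gsub("-", "\\\\-", alphabet)))[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("illegal character '%s' in record '%s' at position %d (%s mode)",
                  substr(seqs[i], bad[i], bad[i]), ids[i], bad[i], mode))
  }
  tibble(id = unname(ids), description = unname(desc), sequence = unname(seqs))
}

#' Write a tibble of sequence records to FASTA
#'
#' Inverse of [read_fasta()]: ids, descriptions and sequences round-trip.
#'
#' @param records tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  assert_cols(records, c("id", "sequence"), "FASTA record tibble")
  desc <- if (is.null(records[["description"]])) rep("", nrow(records)) else
    records[["description"]]
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(desc == "", records$id, paste(records$id, desc))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
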