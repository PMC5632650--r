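# Phylogenomic gene filtering by average bootstrap support, and concatenation
# of the surviving per-gene alignments into a partitioned supermatrix.

#' Mean bootstrap support of a gene tree
#'
#' Arithmetic mean over all internal nodes carrying a numeric support value;
#' nodes without a value (typically the root) are excluded.
#'
#' @param tree an [ape::phylo] with supports on internal node labels (see
#'   [read_newick()]).
#' @return mean support in [0, 100]; errors when the tree carries no support.
#' @examples
#' mean_support(ape::read.tree(text = "((A,B)100,(C,D)80)30;"))
#' @export
mean_support <- function(tree) {
  s <- node_supports(tree)
  s <- s[!is.na(s)]
  if (length(s) == 0L) abort("tree carries no support values")
  mean(s)
}

#' Score gene trees and filter by mean bootstrap support
#'
#' Genes whose average bootstrap support reaches the threshold (inclusive,
#' `>=`) are selected; input order is preserved.
#'
#' @param trees named list of [ape::phylo] gene trees.
#' @param threshold minimum mean support, in [0, 100] (default 70).
#' @return tibble `gene`, `mean_support`, `selected` in input order; the
#'   selected gene ids are `gene[selected]`.
#' @export
filter_genes <- function(trees, threshold = 70) {
  stopifnot(is.list(trees), length(trees) > 0, !is.null(names(trees)),
            threshold >= 0, threshold <= 100)
  ms <- vapply(trees, mean_support, numeric(1))
  tibble(gene = names(trees), mean_support = unname(ms),
         selected = unname(ms) >= threshold)
}

#' Concatenate gene alignments into a partitioned supermatrix
#'
#' Genes are appended in input order; a taxon missing from a gene is filled
#' with gaps over that gene's columns. The partition table records each
#' gene's column range in the 1-based inclusive convention used by partition
#' files.
#'
#' @param alignments named list of alignment tibbles (columns `id` = taxon,
#'   `sequence`; all sequences within a gene equal length), e.g. from
#'   [read_fasta()] in protein mode.
#' @param taxa full taxon set; defaults to the union over genes.
#' @return object of class `supermatrix`: `alignment` (tibble `id`,
#'   `sequence`), `partitions` (tibble `gene`, `start`, `end`, 1-based
#'   inclusive), `n_characters`.
#' @export
concatenate_alignments <- function(alignments, taxa = NULL) {
  stopifnot(is.list(alignments), length(alignments) > 0,
            !is.null(names(alignments)))
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    assert_cols(aln, c("id", "sequence"), sprintf("alignment '%s'", g))
    if (anyDuplicated(aln$id)) abort(sprintf("duplicate taxon in gene '%s'", g))
    if (length(unique(nchar(aln$sequence))) != 1L) {
      abort(sprintf("unequal sequence lengths in gene '%s'", g))
    }
    if (nrow(aln) < 2L) abort(sprintf("gene '%s' has fewer than 2 taxa", g))
  }
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(alignments, function(a) a$id)))
  } else {
    extra <- setdiff(unlist(lapply(alignments, function(a) a$id)), taxa)
    if (length(extra) > 0L) {
      abort(sprintf("taxa outside the declared set: %s", paste(extra, collapse = ", ")))
    }
  }
  lens <- vapply(alignments, function(a) nchar(a$sequence[1]), numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  rows <- setNames(rep("", length(taxa)), taxa)
  for (g in names(alignments)) {
    aln <- alignments[[g]]
    block <- setNames(rep(strrep("-", nchar(aln$sequence[1])), length(taxa)), taxa)
    block[aln$id] <- aln$sequence
    rows <- paste0(rows, block)
  }
  structure(
    list(
      alignment = tibble(id = taxa, sequence = unname(rows)),
      partitions = tibble(gene = names(alignments),
                          start = as.integer(starts), end = as.integer(ends)),
      n_characters = as.integer(sum(lens))
    ),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d characters, %d partitions\n",
              nrow(x$alignment), x$n_characters, nrow(x$partitions)))
  invisible(x)
}

#' Write a supermatrix and its partition file
#'
#' @param x a [concatenate_alignments()] result.
#' @param fasta_path output FASTA path.
#' @param partition_path optional partition file path (`gene = start-end`
#'   lines).
#' @return `fasta_path`, invisibly.
#' @export
write_supermatrix <- function(x, fasta_path, partition_path = NULL) {
  stopifnot(inherits(x, "supermatrix"))
  write_fasta(x$alignment, fasta_path)
  if (!is.null(partition_path)) {
    writeLines(sprintf("%s = %d-%d", x$partitions$gene, x$partitions$start,
                       x$partitions$end), partition_path)
  }
  invisible(fasta_path)
}
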