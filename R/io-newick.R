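#' Read a rooted Newick tree with bootstrap supports on internal node labels
#'
#' Uses ape's Newick parser. Numeric internal-node labels are interpreted as
#' bootstrap support values (the common IQ-TREE/RAxML dialect) and must lie in
#' [0, 100]; non-numeric or absent labels mean "no support recorded".
#'
#' @param path path to a file containing a single Newick string.
#' @return an [ape::phylo] object. Supports, where present, are retrievable
#'   with [node_supports()].
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("Newick file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(sprintf("malformed Newick in %s: %s",
                                                     path, conditionMessage(e))))
  if (is.null(tree)) abort(sprintf("malformed Newick in %s", path))
  if (inherits(tree, "multiPhylo")) abort("expected a single Newick tree")
  if (anyDuplicated(tree$tip.label)) abort("duplicate leaf labels")
  s <- node_supports(tree)
  if (any(!is.na(s) & (s < 0 | s > 100))) {
    abort("support value outside [0, 100]")
  }
  tree
}

#' Extract numeric support values from internal node labels
#'
#' @param tree an [ape::phylo] object.
#' @return numeric vector of length `tree$Nnode`; `NA` where a node carries no
#'   numeric label.
#' @export
node_supports <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  lab <- tree$node.label
  lab[lab == ""] <- NA_character_
  suppressWarnings(as.numeric(lab))
}

#' Write a tree to a Newick file
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
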