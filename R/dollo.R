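# Dollo-parsimony gain/loss mapping of gene families (ortholog groups, OGs)
# onto a rooted species tree: each OG is gained exactly once — on the edge
# above the most recent common ancestor of the taxa possessing it — and every
# maximal subtree inside the gain clade lacking the OG is one loss event.

# children list indexed by node id
tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  kids
}

# number of present tips at or below each node (postorder accumulation)
presence_below <- function(tree, present_tips) {
  n_tip <- ape::Ntip(tree)
  npb <- integer(n_tip + tree$Nnode)
  npb[seq_len(n_tip)] <- as.integer(seq_len(n_tip) %in% present_tips)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(po))) npb[po[k, 1]] <- npb[po[k, 1]] + npb[po[k, 2]]
  npb
}

node_label <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  vapply(node, function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    lab <- tree$node.label[nd - n_tip]
    if (is.null(tree$node.label) || is.na(lab) || lab == "") {
      sprintf("node_%d", nd)
    } else {
      lab
    }
  }, character(1))
}

# single-OG Dollo reconstruction: gain node + loss edges (keyed by child node)
dollo_one <- function(tree, present_tips, kids = tree_children(tree),
                      npb = NULL) {
  present_tips <- unname(as.integer(present_tips))
  stopifnot(length(present_tips) >= 1L)
  if (is.null(npb)) npb <- presence_below(tree, present_tips)
  gain <- if (length(present_tips) == 1L) {
    present_tips
  } else {
    ape::getMRCA(tree, present_tips)
  }
  losses <- integer(0)
  stack <- kids[[gain]]
  while (length(stack) > 0L) {
    nd <- stack[1]; stack <- stack[-1]
    if (npb[nd] == 0L) {
      losses <- c(losses, nd)      # maximal absent subtree: one loss, stop here
    } else {
      stack <- c(stack, kids[[nd]])
    }
  }
  list(gain = gain, losses = sort(losses))
}

# tips present given a gain node and loss edges (children of loss edges absent)
clade_presence <- function(tree, gain, loss_children, kids = tree_children(tree)) {
  n_tip <- ape::Ntip(tree)
  present <- integer(0)
  stack <- gain
  while (length(stack) > 0L) {
    nd <- stack[1]; stack <- stack[-1]
    if (nd %in% loss_children) next
    if (nd <= n_tip) present <- c(present, nd) else stack <- c(stack, kids[[nd]])
  }
  sort(present)
}

as_presence_matrix <- function(matrix) {
  assert_cols(matrix, "og", "OG matrix")
  taxa <- setdiff(names(matrix), "og")
  counts <- as.matrix(matrix[, taxa, drop = FALSE])
  rownames(counts) <- matrix$og
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) abort("negative counts in OG matrix")
  counts
}

#' Map gene-family gains and losses on a rooted tree under Dollo parsimony
#'
#' For each OG the gain is placed on the edge above the most recent common
#' ancestor of all taxa possessing it, and one loss is charged to the root
#' edge of every maximal subtree within the gain clade containing no
#' possessing taxon. This reproduces the observed presence/absence pattern
#' exactly while minimizing losses for a single gain. Multifurcating trees
#' are handled naturally. OGs present in every taxon gain at the root node
#' and are flagged `gain_at_root` so they can be tallied either way.
#'
#' @param matrix wide counts tibble (first column `og`, remaining columns
#'   taxa; see [read_og_matrix()]). Presence is `count > 0`.
#' @param tree rooted [ape::phylo]; its tip set must equal the matrix taxa.
#' @return object of class `dollo_map` with elements
#'   `edges` (tibble `child`, `child_label`, `gains`, `losses`; one row per
#'   edge, keyed by the child node, plus a virtual root edge),
#'   `events` (tibble `og`, `gain_node`, `gain_label`, `gain_at_root`,
#'   `n_losses`, `loss_children` list column),
#'   `skipped` (OG ids with zero presences), and `tree`.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' m <- tibble::tibble(og = c("og1", "og2"),
#'                     A = c(1L, 1L), B = c(1L, 0L), C = c(0L, 1L), D = c(0L, 0L))
#' dollo_map(m, tr)
#' @export
dollo_map <- function(matrix, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) abort("species tree must be rooted")
  counts <- as_presence_matrix(matrix)
  mism <- c(setdiff(colnames(counts), tree$tip.label),
            setdiff(tree$tip.label, colnames(counts)))
  if (length(mism) > 0L) {
    abort(sprintf("matrix taxa and tree leaves differ: %s",
                  paste(mism, collapse = ", ")))
  }
  present <- counts[, tree$tip.label, drop = FALSE] > 0L
  skipped <- rownames(present)[rowSums(present) == 0L]
  use <- rownames(present)[rowSums(present) > 0L]

  kids <- tree_children(tree)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  n_nodes <- n_tip + tree$Nnode

  gains_per_node <- integer(n_nodes)
  losses_per_node <- integer(n_nodes)
  events <- vector("list", length(use))
  for (i in seq_along(use)) {
    tips <- which(present[use[i], ])
    rec <- dollo_one(tree, tips, kids = kids)
    gains_per_node[rec$gain] <- gains_per_node[rec$gain] + 1L
    losses_per_node[rec$losses] <- losses_per_node[rec$losses] + 1L
    events[[i]] <- tibble(
      og = use[i],
      gain_node = rec$gain,
      gain_label = node_label(tree, rec$gain),
      gain_at_root = rec$gain == root,
      n_losses = length(rec$losses),
      loss_children = list(rec$losses)
    )
  }
  events <- if (length(events) > 0L) bind_rows(events) else
    tibble(og = character(), gain_node = integer(), gain_label = character(),
           gain_at_root = logical(), n_losses = integer(), loss_children = list())
  edge_children <- c(tree$edge[, 2], root)   # real edges + virtual root edge
  edges <- tibble(
    child = as.integer(edge_children),
    child_label = node_label(tree, edge_children),
    is_root_edge = edge_children == root,
    gains = gains_per_node[edge_children],
    losses = losses_per_node[edge_children]
  ) |> arrange(.data$child)
  structure(list(edges = edges, events = events, skipped = skipped, tree = tree),
            class = "dollo_map")
}

#' @export
print.dollo_map <- function(x, ...) {
  cat(sprintf("<dollo_map> %d OGs mapped on %d-leaf tree (%d skipped, all-absent)\n",
              nrow(x$events), ape::Ntip(x$tree), length(x$skipped)))
  cat(sprintf("total gains: %d, total losses: %d\n",
              sum(x$edges$gains), sum(x$edges$losses)))
  invisible(x)
}

#' Leaf presence states implied by a Dollo reconstruction
#'
#' Reconstructs, for one OG event, the presence/absence state of every leaf:
#' present iff the leaf lies inside the gain clade with no loss on its path.
#'
#' @param tree rooted [ape::phylo].
#' @param gain_node gain node id.
#' @param loss_children integer vector of loss-edge child node ids.
#' @return logical vector over `tree$tip.label`.
#' @export
dollo_states <- function(tree, gain_node, loss_children = integer(0)) {
  tips <- clade_presence(tree, gain_node, loss_children)
  setNames(seq_len(ape::Ntip(tree)) %in% tips, tree$tip.label)
}

#' OGs exclusively shared between a focal taxon and a group
#'
#' Counts the OGs present in the focal taxon and in at least one group
#' member, and absent from every taxon outside the group and the focal taxon.
#'
#' @param matrix wide counts tibble (see [dollo_map()]).
#' @param focal focal taxon name.
#' @param group character vector of group taxa (must not contain `focal`).
#' @return tibble of the qualifying OG ids (`og`); the count is `nrow()`.
#' @export
exclusive_shared <- function(matrix, focal, group) {
  counts <- as_presence_matrix(matrix)
  taxa <- colnames(counts)
  stopifnot(length(group) >= 1L)
  if (focal %in% group) abort("focal taxon must not be in the group")
  unknown <- setdiff(c(focal, group), taxa)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown taxon/taxa: %s", paste(unknown, collapse = ", ")))
  }
  present <- counts > 0L
  outside <- setdiff(taxa, c(focal, group))
  keep <- present[, focal] &
    rowSums(present[, group, drop = FALSE]) > 0L &
    rowSums(present[, outside, drop = FALSE]) == 0L
  tibble(og = rownames(counts)[keep])
}

#' Paralog census: histogram of per-OG gene counts for one taxon
#'
#' @param matrix wide counts tibble (see [dollo_map()]).
#' @param taxon taxon name.
#' @return tibble `n_copies` (k >= 1), `n_ogs` (number of OGs with exactly k
#'   genes from this taxon).
#' @export
paralog_census <- function(matrix, taxon) {
  counts <- as_presence_matrix(matrix)
  if (!taxon %in% colnames(counts)) abort(sprintf("unknown taxon: %s", taxon))
  x <- counts[, taxon]
  x <- x[x > 0L]
  if (length(x) == 0L) return(tibble(n_copies = integer(), n_ogs = integer()))
  tb <- table(x)
  tibble(n_copies = as.integer(names(tb)), n_ogs = as.integer(tb))
}

#' Annotate a tree with per-edge gain:loss labels
#'
#' Writes `gains:losses` onto the internal node labels (and appends them to
#' tip labels) of the tree inside a `dollo_map`, producing the classic
#' gain/loss-annotated species tree.
#'
#' @param map a [dollo_map()] result.
#' @return an [ape::phylo] with annotated labels.
#' @export
annotate_gain_loss <- function(map) {
  stopifnot(inherits(map, "dollo_map"))
  tree <- map$tree
  n_tip <- ape::Ntip(tree)
  lab <- function(nd) {
    row <- map$edges[map$edges$child == nd, ]
    if (nrow(row) == 0L) return("")
    sprintf("+%d/-%d", row$gains, row$losses)
  }
  tree$tip.label <- sprintf("%s_%s", tree$tip.label,
                            vapply(seq_len(n_tip), lab, character(1)))
  tree$node.label <- vapply(n_tip + seq_len(tree$Nnode), lab, character(1))
  tree
}
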