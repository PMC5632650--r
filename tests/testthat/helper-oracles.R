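# Independent brute-force oracles. These deliberately avoid the package's
# internal helpers: coverage is counted per base, Dollo events are found by
# exhaustive single-gain enumeration over phangorn descendant sets.

# per-base coverage counter over 1-based inclusive query coordinates
brute_force_coverage <- function(qstart, qend, contig_length) {
  covered <- logical(contig_length)
  for (i in seq_along(qstart)) {
    lo <- min(qstart[i], qend[i])
    hi <- max(qstart[i], qend[i])
    covered[lo:hi] <- TRUE
  }
  sum(covered) / contig_length
}

# tip ids (integers) below each node, oracle-side
oracle_tipsets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, seq_len(n_tip + tree$Nnode), type = "tips")
  lapply(desc, sort)
}

# loss count for a fixed gain node: maximal subtrees under the gain whose tip
# sets contain no present tip, found by scanning all nodes
oracle_losses_for_gain <- function(tree, gain, present_tips, tipsets) {
  n_tip <- ape::Ntip(tree)
  in_clade <- vapply(seq_along(tipsets), function(nd) {
    all(tipsets[[nd]] %in% tipsets[[gain]]) && nd != gain
  }, logical(1))
  absent <- vapply(seq_along(tipsets), function(nd) {
    !any(tipsets[[nd]] %in% present_tips)
  }, logical(1))
  parent <- rep(NA_integer_, length(tipsets))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # maximal: absent, inside the clade, and parent not absent-inside-clade
  cand <- which(in_clade & absent)
  maximal <- cand[vapply(cand, function(nd) {
    p <- parent[nd]
    is.na(p) || p == gain || !(absent[p] && in_clade[p])
  }, logical(1))]
  length(maximal)
}

# exhaustive single-gain minimization: returns min loss count and the gain
# node(s) achieving it
oracle_dollo <- function(tree, present_tips) {
  tipsets <- oracle_tipsets(tree)
  feasible <- which(vapply(tipsets, function(ts) all(present_tips %in% ts),
                           logical(1)))
  losses <- vapply(feasible, function(g) {
    oracle_losses_for_gain(tree, g, present_tips, tipsets)
  }, numeric(1))
  list(min_losses = min(losses),
       best_gains = feasible[losses == min(losses)])
}

# textbook one-way ANOVA F from explicit sums of squares
oracle_anova_f <- function(groups) {
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_vals) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# hand RSCU: n_i * x_c / sum(family counts)
oracle_rscu <- function(counts_by_codon, family) {
  n_i <- length(family)
  tot <- sum(counts_by_codon[family])
  setNames(n_i * counts_by_codon[family] / tot, family)
}

random_rooted_tree <- function(n_taxa) {
  ape::rtree(n_taxa, rooted = TRUE, tip.label = sprintf("t%d", seq_len(n_taxa)))
}
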