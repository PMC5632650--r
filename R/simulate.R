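# Ground-truthed synthetic data for every pipeline stage. All generators are
# fully seeded: identical arguments + seed give identical outputs. Defaults
# emulate the study conditions of a high-GC host (~65% GC, ~25x depth) mixed
# with a low-GC endosymbiont (~44% GC, ~874x depth, a small fraction of
# contigs duplicated at ~2x depth).

local_seed <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  if (is.null(old)) {
    function() rm(".Random.seed", envir = globalenv())
  } else {
    function() assign(".Random.seed", old, envir = globalenv())
  }
}

random_dna <- function(n, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# depth with negative-binomial overdispersion around a class mean
draw_depth <- function(n, mu, dispersion) {
  pmax(1, rnbinom(n, mu = mu, size = dispersion))
}

make_hit_row <- function(query_id, subject_id, qstart, qend, evalue = 1e-30) {
  tibble(query_id = query_id, subject_id = subject_id,
         pct_identity = 90, aln_length = abs(qend - qstart) + 1L,
         mismatches = 0L, gap_opens = 0L,
         qstart = as.integer(qstart), qend = as.integer(qend),
         sstart = 1L, send = abs(qend - qstart) + 1L,
         evalue = evalue, bitscore = 200,
         query_strand = "+", subject_strand = "+")
}

# one homology hit covering roughly `coverage` of a contig, random offset
coverage_hit <- function(contig_id, subject_id, contig_len, coverage) {
  span <- max(1L, round(coverage * contig_len))
  qstart <- sample.int(contig_len - span + 1L, 1L)
  make_hit_row(contig_id, subject_id, qstart, qstart + span - 1L)
}

#' Simulate a mixed host-symbiont assembly with ground truth
#'
#' Generates contigs of both classes with class-specific GC and
#' negative-binomial depth, homology hits against a symbiont-side and a
#' host-side reference set (each contig covered on its own side, optionally
#' with cross-side noise hits), best-match hits against an aposymbiotic
#' host-only assembly (high coverage for host contigs, low for symbiont), and
#' a truth table.
#'
#' @param seed RNG seed (mandatory).
#' @param n_host,n_symbiont contig counts (defaults 150 and 50).
#' @param host_gc,symbiont_gc per-contig mean GC fractions (defaults 0.65 and
#'   0.44).
#' @param gc_sd per-contig GC jitter (SD of a truncated normal; default 0,
#'   i.e. clean class separation).
#' @param host_depth,symbiont_depth class mean depths (defaults 25 and 874).
#' @param depth_dispersion negative-binomial size parameter (default 200;
#'   the mean depth of a >= 1 kb contig averages over many positions, so its
#'   coefficient of variation around the class mean is small).
#' @param duplicate_fraction fraction of symbiont contigs planted at doubled
#'   depth (default 0.05).
#' @param length_range contig length range in bp (default 1000-5000).
#' @param coverage_range query-coverage range of same-side homology hits
#'   (default 0.6-0.95).
#' @param noise_rate probability that a contig also receives a spurious
#'   low-coverage hit on the wrong side (default 0).
#' @return list with elements `contigs` (tibble `id`, `sequence`),
#'   `truth` (`contig_id`, `class`, `duplicate`), `depth`
#'   (`contig_id`, `mean_depth`), `hits_symbiont`, `hits_host`, `hits_apo`
#'   (hit tibbles in the 12-column layout).
#' @export
simulate_mixed_assembly <- function(seed,
                                    n_host = 150L, n_symbiont = 50L,
                                    host_gc = 0.65, symbiont_gc = 0.44,
                                    gc_sd = 0,
                                    host_depth = 25, symbiont_depth = 874,
                                    depth_dispersion = 200,
                                    duplicate_fraction = 0.05,
                                    length_range = c(1000L, 5000L),
                                    coverage_range = c(0.6, 0.95),
                                    noise_rate = 0) {
  restore <- local_seed(seed); on.exit(restore())
  stopifnot(n_host >= 1, n_symbiont >= 1, noise_rate >= 0, noise_rate <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  n <- n_host + n_symbiont
  cls <- c(rep("host", n_host), rep("symbiont", n_symbiont))
  ids <- sprintf("%s_ctg_%03d", cls, c(seq_len(n_host), seq_len(n_symbiont)))
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  gc_mean <- ifelse(cls == "host", host_gc, symbiont_gc)
  gc <- pmin(0.95, pmax(0.05, gc_mean + stats::rnorm(n, 0, gc_sd)))
  seqs <- vapply(seq_len(n), function(i) random_dna(lens[i], gc[i]), character(1))

  n_dup <- round(duplicate_fraction * n_symbiont)
  dup <- rep(FALSE, n)
  if (n_dup > 0L) dup[n_host + sample.int(n_symbiont, n_dup)] <- TRUE
  depth <- numeric(n)
  depth[cls == "host"] <- draw_depth(n_host, host_depth, depth_dispersion)
  depth[cls == "symbiont" & !dup] <- draw_depth(sum(cls == "symbiont" & !dup),
                                                symbiont_depth, depth_dispersion)
  depth[dup] <- draw_depth(sum(dup), 2 * symbiont_depth, depth_dispersion)

  own_cov <- runif(n, coverage_range[1], coverage_range[2])
  hits_sym <- list(); hits_host <- list(); hits_apo <- list()
  for (i in seq_len(n)) {
    own <- coverage_hit(ids[i], sprintf("%s_ref", cls[i]), lens[i], own_cov[i])
    if (cls[i] == "symbiont") {
      hits_sym[[length(hits_sym) + 1L]] <- own
      # symbiont contigs match the aposymbiotic assembly poorly or not at all
      hits_apo[[length(hits_apo) + 1L]] <-
        coverage_hit(ids[i], "apo_ctg", lens[i], runif(1, 0.02, 0.3))
      if (runif(1) < noise_rate) {
        hits_host[[length(hits_host) + 1L]] <-
          coverage_hit(ids[i], "host_ref", lens[i], runif(1, 0.02, 0.15))
      }
    } else {
      hits_host[[length(hits_host) + 1L]] <- own
      hits_apo[[length(hits_apo) + 1L]] <-
        coverage_hit(ids[i], "apo_ctg", lens[i], runif(1, 0.8, 0.98))
      if (runif(1) < noise_rate) {
        hits_sym[[length(hits_sym) + 1L]] <-
          coverage_hit(ids[i], "symbiont_ref", lens[i], runif(1, 0.02, 0.15))
      }
    }
  }
  list(
    contigs = tibble(id = ids, description = "", sequence = seqs),
    truth = tibble(contig_id = ids, class = cls, duplicate = dup),
    depth = tibble(contig_id = ids, mean_depth = depth),
    hits_symbiont = bind_rows(hits_sym),
    hits_host = bind_rows(hits_host),
    hits_apo = bind_rows(hits_apo)
  )
}

# synonymous-codon sampling weights: one preferred codon per family carries
# weight exp(beta) (the rest weight 1), optionally tilted by codon GC content
# with exp(gc_weight * #GC). beta = gc_weight = 0 is exactly uniform usage;
# beta -> Inf collapses each family onto a single codon; gc_weight shifts
# coding GC, acting mostly at the (synonymous) third codon position.
codon_bias_weights <- function(beta, code = "11", gc_weight = 0) {
  tab <- genetic_code_table(code)
  tab |>
    filter(.data$amino_acid != "*") |>
    mutate(n_gc = stringr::str_count(.data$codon, "[GC]")) |>
    group_by(.data$amino_acid) |>
    arrange(.data$codon, .by_group = TRUE) |>
    mutate(weight = ifelse(row_number() == 1L, exp(beta), 1) *
             exp(gc_weight * .data$n_gc),
           prob = .data$weight / sum(.data$weight)) |>
    ungroup()
}

#' Simulate a coding genome with a dialled codon-usage bias
#'
#' Builds one contig of alternating intergenic spacers (i.i.d. bases at a
#' target GC) and protein-coding genes whose codons are drawn per amino-acid
#' family from biased synonymous-codon distributions. The bias level `beta`
#' maps deterministically to family distributions (see the returned `truth`):
#' `beta = 0` gives exactly uniform synonymous usage; large `beta`
#' concentrates each family on one codon.
#'
#' @param seed RNG seed (mandatory).
#' @param n_genes number of genes (default 100).
#' @param gene_codons range of gene lengths in sense codons (default 100-400).
#' @param beta codon-bias level, >= 0 (default 0).
#' @param gc_weight tilt of synonymous usage by codon GC content (default 0;
#'   positive values emulate a GC-rich host-like coding set, negative values
#'   an AT-shifted symbiont-like one, acting mostly at codon position 3).
#' @param intergenic_gc GC of intergenic spacers (default 0.5).
#' @param intergenic_length range of spacer lengths in bp (default 50-300).
#' @param code NCBI genetic code id (default `"11"`).
#' @return list with `genome` (tibble `id`, `sequence`), `annotations`
#'   (feature tibble, CDS on the + strand, stop codon included), and `truth`
#'   (per-codon sampling probabilities).
#' @export
simulate_coding_genome <- function(seed, n_genes = 100L,
                                   gene_codons = c(100L, 400L), beta = 0,
                                   gc_weight = 0,
                                   intergenic_gc = 0.5,
                                   intergenic_length = c(50L, 300L),
                                   code = "11") {
  restore <- local_seed(seed); on.exit(restore())
  stopifnot(n_genes >= 1, beta >= 0)
  w <- codon_bias_weights(beta, code, gc_weight = gc_weight)
  aas <- unique(w$amino_acid)
  fams <- split(w[, c("codon", "prob")], w$amino_acid)
  tab <- genetic_code_table(code)
  stops <- tab$codon[tab$amino_acid == "*"]
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (gi in seq_len(n_genes)) {
    spacer <- random_dna(sample(intergenic_length[1]:intergenic_length[2], 1L),
                         intergenic_gc)
    pieces <- c(pieces, spacer)
    pos <- pos + nchar(spacer)
    n_cod <- sample(gene_codons[1]:gene_codons[2], 1L)
    aa_seq <- sample(aas, n_cod, replace = TRUE)
    codons <- character(n_cod)
    for (a in unique(aa_seq)) {
      idx <- which(aa_seq == a)
      fam <- fams[[a]]
      codons[idx] <- sample(fam$codon, length(idx), replace = TRUE,
                            prob = fam$prob)
    }
    gene <- paste0(paste(codons, collapse = ""), sample(stops, 1L))
    pieces <- c(pieces, gene)
    feats[[gi]] <- tibble(contig_id = "sim_contig", start = pos,
                          end = pos + nchar(gene), strand = "+",
                          feature_type = "CDS", id = sprintf("gene_%03d", gi))
    pos <- pos + nchar(gene)
  }
  pieces <- c(pieces, random_dna(sample(intergenic_length[1]:intergenic_length[2], 1L),
                                 intergenic_gc))
  list(
    genome = tibble(id = "sim_contig", description = "",
                    sequence = paste(pieces, collapse = "")),
    annotations = bind_rows(feats),
    truth = select(w, "codon", "amino_acid", "prob")
  )
}

#' Simulate Dollo gain/loss histories on a rooted tree
#'
#' Each OG gains on a uniformly chosen node's parent edge (the root node
#' standing for the root edge); every edge strictly inside the gain clade
#' then loses the OG independently with probability `p` (a subtree under a
#' loss is gone, so nested events are not recorded). OGs whose losses erase
#' every leaf are excluded from the matrix and listed in `unobservable`.
#'
#' @param tree rooted [ape::phylo].
#' @param n_ogs number of OGs (default 1000).
#' @param p per-edge loss probability in [0, 0.5] (default 0.05).
#' @param seed RNG seed (mandatory).
#' @return list with `matrix` (wide counts tibble: `og` + one column per
#'   taxon, presences as 1), `truth` (tibble `og`, `gain_node`,
#'   `loss_children` list column, `n_losses`), and `unobservable` (og ids).
#' @export
simulate_dollo <- function(tree, n_ogs = 1000L, p = 0.05, seed) {
  restore <- local_seed(seed); on.exit(restore())
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree), p >= 0, p <= 0.5)
  kids <- tree_children(tree)
  n_tip <- ape::Ntip(tree)
  n_nodes <- n_tip + tree$Nnode
  ogs <- sprintf("og_%04d", seq_len(n_ogs))
  pres <- matrix(0L, nrow = n_ogs, ncol = n_tip,
                 dimnames = list(ogs, tree$tip.label))
  truth <- vector("list", n_ogs)
  for (i in seq_len(n_ogs)) {
    gain <- sample.int(n_nodes, 1L)
    losses <- integer(0)
    stack <- kids[[gain]]
    while (length(stack) > 0L) {
      nd <- stack[1]; stack <- stack[-1]
      if (runif(1) < p) {
        losses <- c(losses, nd)
      } else if (nd > n_tip) {
        stack <- c(stack, kids[[nd]])
      }
    }
    tips <- clade_presence(tree, gain, losses, kids = kids)
    pres[i, tips] <- 1L
    truth[[i]] <- tibble(og = ogs[i], gain_node = gain,
                         loss_children = list(sort(losses)),
                         n_losses = length(losses),
                         n_present = length(tips))
  }
  truth <- bind_rows(truth)
  observable <- truth$n_present > 0L
  mat <- as_tibble(pres[observable, , drop = FALSE], rownames = "og")
  list(matrix = mat, truth = truth[observable, ],
       unobservable = truth$og[!observable])
}

#' Simulate support-annotated gene trees with known mean supports
#'
#' Each gene gets a random rooted topology whose internal nodes carry integer
#' bootstrap supports drawn uniformly from `support_range`, so the recomputed
#' mean support equals the drawn mean exactly.
#'
#' @param seed RNG seed (mandatory).
#' @param n_genes number of gene trees (default 50).
#' @param n_taxa taxa per tree (default 8).
#' @param support_range integer range of node supports (default 30-100).
#' @return list with `trees` (named list of [ape::phylo]) and `truth`
#'   (tibble `gene`, `mean_support`).
#' @export
simulate_support_trees <- function(seed, n_genes = 50L, n_taxa = 8L,
                                   support_range = c(30L, 100L)) {
  restore <- local_seed(seed); on.exit(restore())
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  trees <- vector("list", n_genes)
  means <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    tr <- ape::rtree(n_taxa, rooted = TRUE,
                     tip.label = sprintf("t%d", seq_len(n_taxa)))
    s <- sample(support_range[1]:support_range[2], tr$Nnode, replace = TRUE)
    tr$node.label <- as.character(s)
    trees[[i]] <- tr
    means[i] <- mean(s)
  }
  names(trees) <- genes
  list(trees = trees, truth = tibble(gene = genes, mean_support = means))
}

#' Simulate a planted synteny anchor set
#'
#' Lays out `n_blocks` collinear anchor runs on one contig pair, separated by
#' more than typical chaining gap caps, with the stated fraction of blocks
#' inverted on the B side, then adds uniformly placed noise anchors.
#'
#' @param seed RNG seed (mandatory).
#' @param n_blocks planted blocks (default 10).
#' @param anchors_per_block anchors per block (default 20).
#' @param inverted_fraction fraction of blocks inverted (default 0.3).
#' @param n_noise number of uniform noise anchors (default 0).
#' @param anchor_length anchor length, bp (default 500).
#' @param intra_gap range of gaps between consecutive anchors in a block
#'   (default 500-3000 bp).
#' @param block_separation distance between consecutive blocks on both
#'   genomes (default 300000 bp, beyond the default chaining gap cap).
#' @return list with `anchors` (anchor tibble) and `truth` (tibble
#'   `block`, `orientation`, `anchor_ids` list column).
#' @export
simulate_anchors <- function(seed, n_blocks = 10L, anchors_per_block = 20L,
                             inverted_fraction = 0.3, n_noise = 0L,
                             anchor_length = 500L,
                             intra_gap = c(500L, 3000L),
                             block_separation = 300000L) {
  restore <- local_seed(seed); on.exit(restore())
  stopifnot(n_blocks >= 1, anchors_per_block >= 2,
            inverted_fraction >= 0, inverted_fraction <= 1)
  n_inv <- round(inverted_fraction * n_blocks)
  inverted <- rep(FALSE, n_blocks)
  if (n_inv > 0L) inverted[sample.int(n_blocks, n_inv)] <- TRUE
  anchors <- list(); truth <- list()
  pos_a <- 0L; pos_b <- 0L
  k <- 0L
  for (bi in seq_len(n_blocks)) {
    starts_a <- integer(anchors_per_block)
    starts_b <- integer(anchors_per_block)
    a <- pos_a; b <- pos_b
    for (j in seq_len(anchors_per_block)) {
      starts_a[j] <- a
      starts_b[j] <- b
      step <- anchor_length + sample(intra_gap[1]:intra_gap[2], 1L)
      a <- a + step
      b <- b + anchor_length + sample(intra_gap[1]:intra_gap[2], 1L)
    }
    if (inverted[bi]) starts_b <- rev(starts_b)
    ids <- sprintf("anc_%04d", k + seq_len(anchors_per_block))
    k <- k + anchors_per_block
    anchors[[bi]] <- tibble(
      anchor_id = ids, contig_a = "chrA",
      start_a = starts_a, end_a = starts_a + anchor_length,
      contig_b = "chrB",
      start_b = starts_b, end_b = starts_b + anchor_length
    )
    truth[[bi]] <- tibble(block = bi,
                          orientation = if (inverted[bi]) "inverted" else "same",
                          anchor_ids = list(ids))
    pos_a <- a + block_separation
    pos_b <- b + block_separation
  }
  anchors <- bind_rows(anchors)
  if (n_noise > 0L) {
    span_a <- max(anchors$end_a); span_b <- max(anchors$end_b)
    na <- tibble(
      anchor_id = sprintf("noise_%04d", seq_len(n_noise)),
      contig_a = "chrA",
      start_a = sample.int(span_a, n_noise),
      contig_b = "chrB",
      start_b = sample.int(span_b, n_noise)
    )
    na$end_a <- na$start_a + anchor_length
    na$end_b <- na$start_b + anchor_length
    anchors <- bind_rows(anchors, na[names(anchors)])
  }
  list(anchors = anchors, truth = bind_rows(truth))
}

#' Plant decayed gene fragments in intergenic DNA with matching hits
#'
#' Builds a small genome with annotated genes, plants `n_fragments` decayed
#' gene remnants in the intergenic spacers, and emits translated-homology
#' hits covering each remnant (plus hits over annotated genes that a
#' mask-aware caller must discard).
#'
#' @param seed RNG seed (mandatory).
#' @param n_genes annotated genes (default 20).
#' @param n_fragments planted pseudogene remnants (default 5).
#' @return list with `genome`, `annotations`, `hits`, and `truth`
#'   (tibble `fragment`, `contig_id`, `start`, `end`).
#' @export
simulate_pseudogene_scan <- function(seed, n_genes = 20L, n_fragments = 5L) {
  restore <- local_seed(seed); on.exit(restore())
  sim <- simulate_coding_genome(seed = sample.int(2^31 - 1L, 1L),
                                n_genes = n_genes,
                                gene_codons = c(50L, 150L),
                                intergenic_length = c(400L, 800L))
  ann <- sim$annotations
  # plant remnants midway inside distinct intergenic spacers
  gaps <- tibble(start = c(0L, ann$end[-nrow(ann)]), end = ann$start)
  gaps <- gaps[gaps$end - gaps$start >= 300L, ]
  pick <- gaps[sample.int(nrow(gaps), min(n_fragments, nrow(gaps))), ]
  truth <- list(); hits <- list()
  for (i in seq_len(nrow(pick))) {
    mid <- (pick$start[i] + pick$end[i]) %/% 2L
    fs <- mid - 75L; fe <- mid + 75L
    truth[[i]] <- tibble(fragment = sprintf("frag_%d", i),
                         contig_id = "sim_contig", start = fs, end = fe)
    # two abutting hits over the remnant (they must merge into one call)
    hits[[length(hits) + 1L]] <- make_hit_row("sim_contig",
                                              sprintf("ref_prot_%d", i),
                                              fs + 1L, mid)
    hits[[length(hits) + 1L]] <- make_hit_row("sim_contig",
                                              sprintf("ref_prot_%d", i),
                                              mid + 11L, fe)
  }
  # decoy hits over annotated genes
  for (j in sample(nrow(ann), min(5L, nrow(ann)))) {
    hits[[length(hits) + 1L]] <- make_hit_row("sim_contig", "decoy_prot",
                                              ann$start[j] + 10L, ann$end[j] - 10L)
  }
  list(genome = sim$genome, annotations = ann,
       hits = bind_rows(hits), truth = bind_rows(truth))
}
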