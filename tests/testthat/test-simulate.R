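test_that("generators are deterministic under a fixed seed", {
  a1 <- simulate_mixed_assembly(seed = 3, n_host = 10, n_symbiont = 5)
  a2 <- simulate_mixed_assembly(seed = 3, n_host = 10, n_symbiont = 5)
  expect_identical(a1, a2)
  a3 <- simulate_mixed_assembly(seed = 4, n_host = 10, n_symbiont = 5)
  expect_false(identical(a1$contigs$sequence, a3$contigs$sequence))

  c1 <- simulate_coding_genome(seed = 5, n_genes = 5)
  c2 <- simulate_coding_genome(seed = 5, n_genes = 5)
  expect_identical(c1, c2)

  tr <- random_rooted_tree(6)
  expect_identical(simulate_dollo(tr, 50, 0.05, seed = 6),
                   simulate_dollo(tr, 50, 0.05, seed = 6))
  expect_identical(simulate_anchors(seed = 7), simulate_anchors(seed = 7))
  expect_identical(simulate_support_trees(seed = 8, n_genes = 5),
                   simulate_support_trees(seed = 8, n_genes = 5))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(simulate_coding_genome(seed = 9, n_genes = 2))
  expect_identical(.Random.seed, before)
})

test_that("mixed-assembly GC converges to the class targets", {
  asm <- simulate_mixed_assembly(seed = 11, n_host = 100, n_symbiont = 100,
                                 length_range = c(5000L, 15000L))
  host_seq <- paste(asm$contigs$sequence[asm$truth$class == "host"], collapse = "")
  sym_seq <- paste(asm$contigs$sequence[asm$truth$class == "symbiont"], collapse = "")
  expect_gt(nchar(host_seq), 5e5)
  expect_equal(gc_fraction(host_seq), 0.65, tolerance = 0.01 / 0.65)
  expect_equal(gc_fraction(sym_seq), 0.44, tolerance = 0.01 / 0.44)
})

test_that("clean assemblies separate perfectly on the homology ratio", {
  asm <- simulate_mixed_assembly(seed = 13, n_host = 30, n_symbiont = 10,
                                 noise_rate = 0)
  feats <- contig_features(asm$contigs, asm$hits_symbiont, asm$hits_host,
                           asm$depth, hits_apo = asm$hits_apo)
  ratio <- feats$homology_ratio
  cls <- asm$truth$class
  expect_true(all(ratio[cls == "symbiont"] > 1))
  expect_true(all(ratio[cls == "host"] < 1))
})

test_that("coding-genome truth probabilities drive observed codon usage", {
  # beta = 0: uniform synonymous usage; RSCU approaches 1 everywhere
  cod <- simulate_coding_genome(seed = 15, n_genes = 60,
                                gene_codons = c(200L, 400L), beta = 0)
  expect_true(all(abs(cod$truth$prob - ave(cod$truth$prob, cod$truth$amino_acid,
                                           FUN = mean)) < 1e-12))
  cds <- extract_cds(cod$genome, cod$annotations)
  rt <- rscu(codon_counts(cds, stop_included = TRUE))
  expect_lt(rscu_sd(rt), 0.12)

  # extreme beta: one codon per family, defined RSCU values in {0, n_i}
  ext <- simulate_coding_genome(seed = 16, n_genes = 10, beta = 50)
  rt2 <- rscu(codon_counts(extract_cds(ext$genome, ext$annotations),
                           stop_included = TRUE))
  vals <- rt2[!is.na(rt2$rscu) & rt2$family_size > 1, ]
  expect_true(all(vals$rscu == 0 | vals$rscu == vals$family_size))

  # annotations consistent with the sequence: every CDS in frame, ends in stop
  lens <- nchar(cds$sequence)
  expect_true(all(lens %% 3 == 0))
  stops <- substr(cds$sequence, lens - 2, lens)
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
})

test_that("dollo simulation respects the no-loss limit and logs unobservable OGs", {
  tr <- random_rooted_tree(6)
  sim0 <- simulate_dollo(tr, n_ogs = 200, p = 0, seed = 19)
  expect_equal(length(sim0$unobservable), 0L)
  map <- dollo_map(sim0$matrix, tr)
  joined <- dplyr::left_join(map$events, sim0$truth, by = "og",
                             suffix = c("_inf", "_true"))
  expect_equal(joined$gain_node_inf, joined$gain_node_true)
  expect_true(all(joined$n_losses_inf == 0L))

  sim <- simulate_dollo(tr, n_ogs = 300, p = 0.4, seed = 20)
  expect_equal(nrow(sim$matrix) + length(sim$unobservable), 300L)
  # truth reproduces the matrix
  for (i in sample.int(nrow(sim$matrix), 10)) {
    og <- sim$matrix$og[i]
    tru <- sim$truth[sim$truth$og == og, ]
    states <- dollo_states(tr, tru$gain_node, tru$loss_children[[1]])
    expect_equal(as.integer(states[names(sim$matrix)[-1]]),
                 unname(unlist(sim$matrix[i, -1])))
  }
})

test_that("support-tree truth matches recomputed means; anchor truth matches layout", {
  st <- simulate_support_trees(seed = 21, n_genes = 20)
  recomputed <- vapply(st$trees, mean_support, numeric(1))
  expect_equal(unname(recomputed), st$truth$mean_support)

  sa <- simulate_anchors(seed = 22, n_blocks = 10, inverted_fraction = 0.3)
  expect_equal(sum(sa$truth$orientation == "inverted"), 3L)
  expect_equal(nrow(sa$anchors), 10L * 20L)
})
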