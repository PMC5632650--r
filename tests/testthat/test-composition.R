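count_of <- function(cc, codon) cc$count[cc$codon == codon]

test_that("codon_counts tallies sense and stop codons correctly", {
  cc <- codon_counts("ATGGCC")
  expect_equal(count_of(cc, "ATG"), 1L)
  expect_equal(count_of(cc, "GCC"), 1L)
  expect_equal(sum(cc$count), 2L)

  cc2 <- codon_counts("ATGTAA", stop_included = TRUE)
  expect_equal(count_of(cc2, "ATG"), 1L)
  expect_equal(count_of(cc2, "TAA"), 0L)           # terminal stop not a sense count
  expect_equal(attr(cc2, "terminal_stops"), 1L)

  cc3 <- codon_counts(character(0))
  expect_equal(sum(cc3$count), 0L)

  expect_error(codon_counts("ATGG"), "divisible by 3")
  expect_warning(codon_counts(c("ATGNNN", "ATGGCC")), "ambiguous")
})

test_that("RSCU matches its defining formula and conserves family size", {
  # Glu family {GAA:3, GAG:1} -> RSCU {1.5, 0.5}
  cc <- codon_counts("GAAGAAGAAGAG")
  rt <- rscu(cc)
  expect_equal(rt$rscu[rt$codon == "GAA"], 1.5)
  expect_equal(rt$rscu[rt$codon == "GAG"], 0.5)
  expect_equal(oracle_rscu(setNames(cc$count, cc$codon), c("GAA", "GAG")),
               c(GAA = 1.5, GAG = 0.5))

  # random counts: sum of RSCU within each defined family = family size
  set.seed(31)
  cc$count <- as.integer(rpois(nrow(cc), 5))
  rt <- rscu(cc)
  fam <- dplyr::summarise(dplyr::group_by(rt, amino_acid),
                          s = sum(rscu), n = dplyr::n(), .groups = "drop")
  defined <- !is.na(fam$s)
  expect_equal(fam$s[defined], as.numeric(fam$n[defined]), tolerance = 1e-9)

  # zero-count family undefined
  cc$count[cc$amino_acid == "C"] <- 0L
  expect_true(all(is.na(rscu(cc)$rscu[cc$amino_acid[cc$amino_acid != "*"] == "C"])))
})

test_that("rscu_sd matches hand computations and exclusion rules", {
  # uniform usage in every family -> all RSCU 1 -> SD 0
  cc <- codon_counts(character(0))
  cc$count <- ifelse(cc$is_stop, 0L, 6L)
  expect_equal(rscu_sd(rscu(cc)), 0)

  # two maximally biased 2-codon families {2,0},{2,0}: values {2,0,2,0},
  # SD = sqrt(4/3); build Lys (AAA/AAG) and Glu (GAA/GAG) only
  cc$count <- 0L
  cc$count[cc$codon %in% c("AAA", "GAA")] <- 2L
  expect_equal(rscu_sd(rscu(cc)), sqrt(4 / 3))

  # a hand-made value set {1.5, 0.5, 1.0, 1.0}: Glu {3,1}, Lys {2,2}
  cc$count <- 0L
  cc$count[cc$codon == "GAA"] <- 3L
  cc$count[cc$codon == "GAG"] <- 1L
  cc$count[cc$codon %in% c("AAA", "AAG")] <- 2L
  expect_equal(rscu_sd(rscu(cc)), sd(c(1.5, 0.5, 1, 1)))

  # Met/Trp never contribute: adding them leaves the SD unchanged
  cc2 <- cc
  cc2$count[cc2$codon %in% c("ATG", "TGG")] <- 50L
  expect_equal(rscu_sd(rscu(cc2)), rscu_sd(rscu(cc)))

  # fewer than two defined values errors
  cc$count <- 0L
  cc$count[cc$codon == "ATG"] <- 5L
  expect_error(rscu_sd(rscu(cc)), "at least 2")
})

test_that("rscu_sd is invariant under relabeling codons within families", {
  set.seed(13)
  cc <- codon_counts(character(0))
  cc$count <- as.integer(rpois(nrow(cc), 8))
  base_sd <- rscu_sd(rscu(cc))
  # swap counts of GAA and GAG (same family)
  swapped <- cc
  i <- match(c("GAA", "GAG"), cc$codon)
  swapped$count[i] <- cc$count[rev(i)]
  expect_equal(rscu_sd(rscu(swapped)), base_sd)
})

test_that("GC by codon position matches hand counts and the total-GC identity", {
  expect_equal(gc_by_codon_position("ATGGCC"),
               c(pos1 = 0.5, pos2 = 0.5, pos3 = 1.0))
  expect_equal(gc_by_codon_position("GCGGGC"), c(pos1 = 1, pos2 = 1, pos3 = 1))
  expect_equal(gc_by_codon_position("ATATTA"), c(pos1 = 0, pos2 = 0, pos3 = 0))
  expect_error(gc_by_codon_position(character(0)), "empty")

  # algebraic identity: mean of the three positional GCs = GC of the coding set
  set.seed(3)
  cds <- vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 3 * sample(30:100, 1), TRUE),
          collapse = "")
  }, character(1))
  expect_equal(mean(gc_by_codon_position(cds)),
               gc_fraction(paste(cds, collapse = "")), tolerance = 1e-12)
})

test_that("amino-acid frequencies translate correctly and sum to one", {
  af <- aa_frequencies("ATGGCC")
  expect_equal(af$frequency[af$amino_acid == "M"], 0.5)
  expect_equal(af$frequency[af$amino_acid == "A"], 0.5)
  expect_equal(sum(af$frequency), 1)

  expect_error(aa_frequencies("TAA"), "no amino-acid residues")

  cod <- simulate_coding_genome(seed = 8, n_genes = 10)
  cds <- extract_cds(cod$genome, cod$annotations)
  expect_equal(sum(aa_frequencies(cds)$frequency), 1, tolerance = 1e-9)
})

test_that("gene and intergenic lengths follow the merged-span definition", {
  ann <- tibble::tibble(contig_id = "c", start = c(9L, 49L), end = c(20L, 60L),
                        strand = "+", feature_type = "gene", id = c("a", "b"))
  lens <- gene_intergenic_lengths(ann)
  expect_equal(lens$length[lens$region == "gene"], c(11L, 11L))
  expect_equal(lens$length[lens$region == "intergenic"], 29L)

  # overlapping genes merge; no zero-length gap
  ann2 <- tibble::tibble(contig_id = "c", start = c(0L, 25L), end = c(50L, 75L),
                         strand = "+", feature_type = "gene", id = c("a", "b"))
  lens2 <- gene_intergenic_lengths(ann2)
  expect_equal(sum(lens2$region == "intergenic"), 0L)

  # single gene, linear: no intergenic region
  lens3 <- gene_intergenic_lengths(ann2[1, ])
  expect_equal(sum(lens3$region == "intergenic"), 0L)

  # circular: terminal flanks join across the origin
  lens4 <- gene_intergenic_lengths(ann[1, ], contig_lengths = c(c = 100L),
                                   circular = TRUE)
  expect_equal(lens4$length[lens4$region == "intergenic"], 89L)

  # pseudogenes excluded
  ann$feature_type[2] <- "pseudogene"
  lens5 <- gene_intergenic_lengths(ann)
  expect_equal(sum(lens5$region == "gene"), 1L)
})

test_that("group_compare agrees with textbook sums of squares and Tukey", {
  set.seed(19)
  groups <- list(a = rnorm(8, 0), b = rnorm(9, 0.5), c = rnorm(7, 2))
  df <- tibble::tibble(g = rep(names(groups), lengths(groups)),
                       y = unlist(groups))
  fit <- group_compare(df, "y", "g")
  expect_equal(fit$f_statistic, oracle_anova_f(groups), tolerance = 1e-10)
  expect_equal(nrow(fit$tukey), 3L)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$p_value, fit$p_value)

  # identical groups: F = 0, p = 1, nothing significant
  df2 <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2, 3), 2))
  fit2 <- group_compare(df2, "y", "g")
  expect_equal(fit2$f_statistic, 0)
  expect_equal(fit2$p_value, 1)
  expect_false(any(fit2$tukey$significant))

  # zero variance everywhere handled
  df3 <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(5, 6))
  fit3 <- group_compare(df3, "y", "g")
  expect_equal(fit3$f_statistic, 0)
  expect_equal(fit3$p_value, 1)
})

test_that("host-like vs symbiont-like coding sets differ most at position 3", {
  # synonymous choice is free at the third position, so GC-shifted usage
  # (GC-rich host vs AT-shifted symbiont) separates the coding sets most at
  # position 3
  host <- simulate_coding_genome(seed = 21, n_genes = 40, gc_weight = 1.5,
                                 intergenic_gc = 0.65)
  sym <- simulate_coding_genome(seed = 22, n_genes = 40, gc_weight = -0.5,
                                intergenic_gc = 0.44)
  gc_h <- gc_by_codon_position(extract_cds(host$genome, host$annotations))
  gc_s <- gc_by_codon_position(extract_cds(sym$genome, sym$annotations))
  d <- abs(gc_h - gc_s)
  expect_gt(d[["pos3"]], d[["pos2"]])
  expect_gt(d[["pos3"]], d[["pos1"]])
})
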