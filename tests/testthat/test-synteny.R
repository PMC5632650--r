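mk_anchors <- function(start_a, start_b, len = 100L, id_prefix = "a",
                       contig_a = "A1", contig_b = "B1") {
  tibble::tibble(
    anchor_id = sprintf("%s%02d", id_prefix, seq_along(start_a)),
    contig_a = contig_a, start_a = as.integer(start_a),
    end_a = as.integer(start_a + len),
    contig_b = contig_b, start_b = as.integer(start_b),
    end_b = as.integer(start_b + len)
  )
}

test_that("chain_anchors finds monotone runs with the min-anchor rule", {
  pos <- seq(0, by = 1000, length.out = 7)
  same <- chain_anchors(mk_anchors(pos, pos), min_anchors = 7)
  expect_equal(nrow(same), 1L)
  expect_equal(same$orientation, "same")
  expect_equal(same$n_anchors, 7L)

  inv <- chain_anchors(mk_anchors(pos, rev(pos)), min_anchors = 7)
  expect_equal(inv$orientation, "inverted")

  short <- chain_anchors(mk_anchors(pos[1:6], pos[1:6]), min_anchors = 7)
  expect_equal(nrow(short), 0L)

  # gap cap: a > max_gap jump splits the run
  pos2 <- c(pos, max(pos) + 300000 + seq(0, by = 1000, length.out = 7))
  two <- chain_anchors(mk_anchors(pos2, pos2), min_anchors = 7, max_gap = 100000)
  expect_equal(nrow(two), 2L)
})

test_that("chaining is order-invariant and skips isolated off-target anchors", {
  pos <- seq(0, by = 1000, length.out = 10)
  anchors <- mk_anchors(pos, pos)
  outlier <- mk_anchors(4500, 900000, id_prefix = "noise")
  all_anchors <- dplyr::bind_rows(anchors, outlier)
  set.seed(9)
  shuffled <- all_anchors[sample.int(nrow(all_anchors)), ]
  b1 <- chain_anchors(all_anchors, min_anchors = 7)
  b2 <- chain_anchors(shuffled, min_anchors = 7)
  expect_equal(b1, b2)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_anchors, 10L)   # outlier skipped, run not split
  expect_false("noise01" %in% b1$anchors[[1]])
})

test_that("blocks satisfy monotonicity and size invariants", {
  sim <- simulate_anchors(seed = 17, n_blocks = 6, anchors_per_block = 9,
                          inverted_fraction = 0.5, n_noise = 8)
  blocks <- chain_anchors(sim$anchors)
  expect_true(all(blocks$n_anchors >= 7))
  lookup <- sim$anchors
  for (i in seq_len(nrow(blocks))) {
    sub <- lookup[match(blocks$anchors[[i]], lookup$anchor_id), ]
    sub <- dplyr::arrange(sub, start_a)
    d <- diff(sub$start_b)
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("merge_blocks unifies nearby same-orientation blocks and keeps the larger on overlap", {
  pos1 <- seq(0, by = 1000, length.out = 8)
  pos2 <- seq(12000, by = 1000, length.out = 8)   # 4 kb gap: within merge range
  b <- chain_anchors(dplyr::bind_rows(
    mk_anchors(pos1, pos1, id_prefix = "p"),
    mk_anchors(pos2, pos2, id_prefix = "q")
  ), min_anchors = 7, max_gap = 2000)
  expect_equal(nrow(b), 2L)
  merged <- merge_blocks(b, merge_distance = 50000)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_anchors, 16L)
  expect_equal(merged$start_a, 0L)

  # overlapping same/inverted blocks: only the larger (9 anchors) kept;
  # the small block sits far away on B so the two cannot co-chain
  pa <- seq(0, by = 1000, length.out = 9)
  pb <- seq(200, by = 1100, length.out = 7)
  ov <- dplyr::bind_rows(
    mk_anchors(pa, pa, id_prefix = "big"),
    mk_anchors(pb, rev(pb + 20000), id_prefix = "small", contig_b = "B1")
  )
  blocks <- chain_anchors(ov, min_anchors = 7)
  expect_equal(nrow(blocks), 2L)
  kept <- merge_blocks(blocks)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$n_anchors, 9L)
  expect_equal(kept$orientation, "same")

  # disjoint distant blocks unchanged
  far <- chain_anchors(dplyr::bind_rows(
    mk_anchors(pos1, pos1, id_prefix = "x"),
    mk_anchors(pos1 + 9e6, pos1 + 9e6, id_prefix = "y")
  ), min_anchors = 7)
  expect_equal(nrow(merge_blocks(far)), 2L)
})

test_that("merge_blocks never decreases the anchors covered", {
  sim <- simulate_anchors(seed = 29, n_blocks = 8, anchors_per_block = 10,
                          n_noise = 15)
  raw <- chain_anchors(sim$anchors)
  merged <- merge_blocks(raw)
  expect_gte(length(unique(unlist(merged$anchors))),
             length(unique(unlist(raw$anchors))))
})

test_that("planted blocks are recovered exactly without noise", {
  sim <- simulate_anchors(seed = 37, n_blocks = 10, anchors_per_block = 12,
                          inverted_fraction = 0.3, n_noise = 0)
  blocks <- merge_blocks(chain_anchors(sim$anchors))
  expect_equal(nrow(blocks), 10L)
  expect_equal(sum(blocks$orientation == "inverted"), 3L)
  # exact anchor memberships
  truth_sets <- lapply(sim$truth$anchor_ids, sort)
  block_sets <- lapply(blocks$anchors, sort)
  expect_setequal(
    vapply(block_sets, paste, character(1), collapse = ","),
    vapply(truth_sets, paste, character(1), collapse = ",")
  )
  cov <- anchor_coverage(blocks, sim$anchors)
  expect_equal(cov$anchor_fraction, 1)
  expect_equal(cov$n_inverted, 3L)
})

test_that("anchor_coverage reports fractions and counts", {
  sim <- simulate_anchors(seed = 41, n_blocks = 3, anchors_per_block = 8)
  blocks <- chain_anchors(sim$anchors)
  cov <- anchor_coverage(blocks, sim$anchors)
  expect_equal(cov$n_blocks, 3L)
  expect_equal(cov$anchor_fraction, 1)
  none <- anchor_coverage(chain_anchors(sim$anchors[1:3, ]), sim$anchors)
  expect_equal(none$n_blocks, 0L)
  expect_equal(none$anchor_fraction, 0)
})
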