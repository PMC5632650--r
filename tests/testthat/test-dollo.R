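quartet <- ape::read.tree(text = "((A,B),(C,D));")

pa_matrix <- function(tree, patterns) {
  taxa <- tree$tip.label
  m <- tibble::as_tibble(as.data.frame(do.call(rbind, patterns)))
  names(m) <- taxa
  dplyr::bind_cols(tibble::tibble(og = sprintf("og_%03d", seq_along(patterns))), m)
}

test_that("dollo_map places gains at the MRCA and losses on absent subtrees", {
  m <- pa_matrix(quartet, list(
    c(1L, 1L, 0L, 0L),   # clean clade {A,B}: gain at MRCA(A,B), 0 losses
    c(1L, 0L, 1L, 0L),   # {A,C}: gain at root, losses on B and D
    c(1L, 0L, 0L, 0L)    # {A}: gain on A's terminal edge, 0 losses
  ))
  map <- dollo_map(m, quartet)
  ev <- map$events
  expect_equal(ev$n_losses, c(0L, 2L, 0L))
  expect_equal(ev$gain_label[3], "A")
  expect_true(ev$gain_at_root[2])
  expect_setequal(node_label(map$tree, ev$loss_children[[2]]) |> suppressWarnings(),
                  c("B", "D"))
  # reconstruction reproduces observed leaf states
  for (i in seq_len(nrow(ev))) {
    states <- dollo_states(quartet, ev$gain_node[i], ev$loss_children[[i]])
    expect_equal(unname(states[c("A", "B", "C", "D")] * 1L),
                 unname(unlist(m[i, c("A", "B", "C", "D")])))
  }
})

test_that("dollo_map validates tree and taxa, and reports all-absent OGs", {
  unrooted <- ape::read.tree(text = "(A,B,C,D);")
  m <- pa_matrix(quartet, list(c(1L, 1L, 0L, 0L)))
  expect_error(dollo_map(m, ape::unroot(ape::rtree(4))), "rooted")
  names(m)[2] <- "Z"
  expect_error(dollo_map(m, quartet), "differ")

  m2 <- pa_matrix(quartet, list(c(1L, 1L, 0L, 0L), c(0L, 0L, 0L, 0L)))
  map <- dollo_map(m2, quartet)
  expect_equal(map$skipped, "og_002")
  expect_equal(nrow(map$events), 1L)
})

test_that("loss minimality matches exhaustive single-gain enumeration", {
  skip_if_not_installed("phangorn")
  set.seed(53)
  for (rep in 1:10) {
    tree <- random_rooted_tree(sample(4:8, 1))
    n_tip <- ape::Ntip(tree)
    patterns <- lapply(1:20, function(i) {
      p <- rbinom(n_tip, 1L, 0.5)
      if (sum(p) == 0L) p[sample.int(n_tip, 1L)] <- 1L
      p
    })
    m <- pa_matrix(tree, patterns)
    map <- dollo_map(m, tree)
    for (i in seq_len(nrow(map$events))) {
      oracle <- oracle_dollo(tree, which(patterns[[i]] == 1L))
      expect_equal(map$events$n_losses[i], oracle$min_losses)
      expect_true(map$events$gain_node[i] %in% oracle$best_gains)
    }
  }
})

test_that("total gains equal the number of observable OGs; remapping is idempotent", {
  tree <- random_rooted_tree(6)
  sim <- simulate_dollo(tree, n_ogs = 150, p = 0.1, seed = 42)
  map <- dollo_map(sim$matrix, tree)
  expect_equal(sum(map$edges$gains), nrow(sim$matrix))
  # reconstruct leaf states from the inferred events and remap: same events
  taxa <- tree$tip.label
  states <- lapply(seq_len(nrow(map$events)), function(i) {
    as.integer(dollo_states(tree, map$events$gain_node[i],
                            map$events$loss_children[[i]]))
  })
  m2 <- pa_matrix(tree, states)
  m2$og <- map$events$og
  map2 <- dollo_map(m2, tree)
  expect_equal(map2$events$gain_node, map$events$gain_node)
  expect_equal(map2$events$loss_children, map$events$loss_children)
})

test_that("multifurcating trees are handled", {
  tri <- ape::read.tree(text = "((A,B,C),(D,E));")
  m <- pa_matrix(tri, list(c(1L, 1L, 0L, 0L, 0L)))
  map <- dollo_map(m, tri)
  # gain at the (A,B,C) node with one loss on C
  expect_equal(map$events$n_losses, 1L)
  states <- dollo_states(tri, map$events$gain_node[1], map$events$loss_children[[1]])
  expect_equal(unname(states), c(TRUE, TRUE, FALSE, FALSE, FALSE))
})

test_that("exclusive_shared counts intersections and satisfies the accounting identity", {
  m <- tibble::tibble(
    og = sprintf("og%d", 1:6),
    focal = c(1L, 1L, 1L, 0L, 1L, 1L),
    g1 = c(1L, 0L, 0L, 1L, 0L, 1L),
    g2 = c(0L, 1L, 0L, 0L, 0L, 0L),
    out = c(0L, 0L, 0L, 0L, 0L, 1L)
  )
  shared <- exclusive_shared(m, "focal", c("g1", "g2"))
  expect_setequal(shared$og, c("og1", "og2"))   # og6 leaks outside, og3 focal-only
  expect_error(exclusive_shared(m, "focal", c("focal", "g1")), "must not")
  expect_error(exclusive_shared(m, "focal", "nope"), "unknown")

  # accounting identity over a partition of the non-focal taxa
  set.seed(61)
  taxa <- c("focal", sprintf("t%d", 1:6))
  counts <- matrix(rbinom(40 * 7, 1, 0.4), ncol = 7,
                   dimnames = list(NULL, taxa))
  mm <- dplyr::bind_cols(tibble::tibble(og = sprintf("og%02d", 1:40)),
                         tibble::as_tibble(as.data.frame(counts)))
  part <- list(c("t1", "t2"), c("t3", "t4"), c("t5", "t6"))
  n_shared <- sum(vapply(part, function(g) nrow(exclusive_shared(mm, "focal", g)),
                         numeric(1)))
  present <- counts > 0
  focal_total <- sum(present[, "focal"])
  focal_unique <- sum(present[, "focal"] & rowSums(present[, -1]) == 0)
  # OGs with focal + members of >= 2 partition cells are in no exclusive set
  cell_hits <- vapply(part, function(g) rowSums(present[, g, drop = FALSE]) > 0,
                      logical(40))
  multi_cell <- sum(present[, "focal"] & rowSums(cell_hits) >= 2)
  expect_equal(n_shared + focal_unique + multi_cell, focal_total)
})

test_that("paralog_census histograms per-taxon OG sizes", {
  m <- tibble::tibble(og = sprintf("og%d", 1:5),
                      tx = c(1L, 1L, 2L, 3L, 0L), other = 1L)
  cen <- paralog_census(m, "tx")
  expect_equal(cen, tibble::tibble(n_copies = c(1L, 2L, 3L), n_ogs = c(2L, 1L, 1L)))
  expect_equal(sum(cen$n_copies * cen$n_ogs), sum(m$tx))
  expect_equal(nrow(paralog_census(dplyr::mutate(m, tx = 0L), "tx")), 0L)
})
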