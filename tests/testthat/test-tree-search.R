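test_that("three taxa have exactly one topology", {
  m <- tok_matrix(A = "01", B = "00", C = "10")
  fit <- parsimony_search(m, method = "branch-and-bound")
  expect_identical(length(fit$binary_trees), 1L)
  expect_identical(fit$best_length,
                   tree_length(fit$binary_trees[[1]], m)$total_length)
})

test_that("branch-and-bound equals exhaustive enumeration", {
  set.seed(31)
  for (rep in 1:4) {
    m <- random_matrix(6, 6, p_wild = 0.1, p_poly = 0.05)
    topo <- all_topologies(m$taxa)
    lens <- vapply(topo, function(t) tree_length(t, m)$total_length, 0L)
    fit <- parsimony_search(m, method = "branch-and-bound", collapse = FALSE)
    expect_identical(fit$best_length, min(lens))
    ref <- sort(m$taxa)
    expected <- sort(vapply(topo[lens == min(lens)], function(t)
      paste(bipartitions(t, ref), collapse = "|"), ""))
    got <- sort(vapply(fit$binary_trees, function(t)
      paste(bipartitions(t, ref), collapse = "|"), ""))
    expect_identical(got, expected)
  }
})

test_that("the exact search refuses oversized matrices", {
  m <- random_matrix(16, 2)
  expect_error(parsimony_search(m, method = "branch-and-bound"),
               "heuristic")
})

test_that("a homoplasy-free matrix yields its generating topology", {
  sim <- simulate_matrix(n_taxa = 8, n_characters = 14, p_three = 0,
                         p_origins = c(0, 1), p_missing = 0,
                         p_inapplicable = 0, p_polymorphic = 0, seed = 3)
  fit <- parsimony_search(sim$matrix, method = "branch-and-bound")
  ref <- sort(sim$tree$tip.label)
  true_key <- paste(bipartitions(sim$tree, ref), collapse = "|")
  keys <- vapply(fit$binary_trees, function(t)
    paste(bipartitions(t, ref), collapse = "|"), "")
  expect_true(true_key %in% keys)
})

test_that("heuristic search matches the exact search on random matrices", {
  set.seed(37)
  for (rep in 1:5) {
    m <- random_matrix(9, 8, p_wild = 0.1, p_poly = 0.02)
    exact <- parsimony_search(m, method = "branch-and-bound")
    heur <- suppressWarnings(
      parsimony_search(m, replicates = 20, seed = rep, max_trees = 500))
    expect_identical(heur$best_length, exact$best_length)
    expect_gte(heur$best_length, sum(min_steps(m)))
  }
})

test_that("replaying a seed reproduces the identical search result", {
  m <- stoiba_matrix()
  a <- parsimony_search(m, replicates = 10, seed = 99)
  b <- parsimony_search(m, replicates = 10, seed = 99)
  expect_identical(a$best_length, b$best_length)
  expect_identical(lapply(a$binary_trees, ape::write.tree),
                   lapply(b$binary_trees, ape::write.tree))
  expect_identical(a$log$replicate_lengths, b$log$replicate_lengths)
  c <- parsimony_search(m, replicates = 10, seed = 100)
  expect_false(identical(a$log$replicate_lengths, c$log$replicate_lengths))
})

test_that("every swap neighbourhood reaches the same optimum here", {
  m <- stoiba_matrix()
  for (sw in c("NNI", "SPR", "TBR")) {
    fit <- parsimony_search(m, replicates = 15, seed = 7, swap = sw)
    expect_identical(fit$best_length, 83L, label = sw)
  }
})

test_that("collapsing removes exactly the unforced branches", {
  # all characters invariant: nothing supports anything -> star
  m <- tok_matrix(A = "00", B = "00", C = "00", D = "00")
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  star <- collapse_unsupported(tr, m)
  expect_identical(length(bipartitions(star, sort(m$taxa))), 0L)

  # a clean split keeps its branch
  m2 <- tok_matrix(A = "0", B = "0", C = "1", D = "1")
  kept <- collapse_unsupported(tr, m2)
  expect_identical(bipartitions(kept, sort(m2$taxa)),
                   bipartitions(tr, sort(m2$taxa)))

  # contraction only ever removes bipartitions
  set.seed(41)
  for (rep in 1:6) {
    m3 <- random_matrix(7, 4, p_wild = 0.2, p_poly = 0.05)
    tr3 <- ape::rtopology(7, rooted = FALSE, tip.label = m3$taxa)
    col <- collapse_unsupported(tr3, m3)
    expect_true(all(bipartitions(col, sort(m3$taxa)) %in%
                    bipartitions(tr3, sort(m3$taxa))))
  }
})

test_that("forced-change detection matches the brute-force oracle", {
  set.seed(53)
  for (rep in 1:8) {
    n <- sample(5:6, 1)
    m <- random_matrix(n, 3, p_wild = 0.2, p_poly = 0.1)
    tr <- ape::rtopology(n, rooted = FALSE, tip.label = m$taxa)
    masks <- mpmorph:::tip_masks(tr, m)
    for (j in 1:3) {
      got <- mpmorph:::edge_forced_change(tr, masks[, j])
      want <- oracle_forced_edges(tr, m, j - 1)
      internal <- !is.na(want)
      expect_identical(got[internal], want[internal],
                       label = sprintf("rep %d char %d", rep, j - 1))
    }
  }
})

test_that("deduplication is by bipartition set", {
  a <- ape::read.tree(text = "((A,B),(C,D));")
  b <- ape::read.tree(text = "((D,C),(B,A));")   # rotation
  c <- ape::read.tree(text = "((A,C),(B,D));")   # different resolution
  expect_identical(length(dedupe_trees(c(a, b))), 1L)
  expect_identical(length(dedupe_trees(c(a, b, c))), 2L)
  expect_identical(length(dedupe_trees(c(a, a, a))), 1L)
})
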