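test_that("origin counts translate into exact lengths", {
  # zero origins everywhere: invariant characters, zero length on any tree
  sim0 <- simulate_matrix(n_taxa = 6, n_characters = 5,
                          p_origins = c(1), p_missing = 0,
                          p_inapplicable = 0, p_polymorphic = 0, seed = 1)
  expect_identical(sim0$origins, rep(0L, 5))
  any_tree <- ape::rtopology(6, rooted = FALSE,
                             tip.label = sim0$matrix$taxa)
  expect_identical(tree_length(any_tree, sim0$matrix)$total_length, 0L)

  # single origins, no ambiguity: true-tree length = number of origins
  sim1 <- simulate_matrix(n_taxa = 10, n_characters = 12,
                          p_origins = c(0, 1), p_missing = 0,
                          p_inapplicable = 0, p_polymorphic = 0, seed = 2)
  expect_identical(tree_length(sim1$tree, sim1$matrix)$total_length,
                   sum(sim1$origins))
})

test_that("true-tree length never exceeds the injected origin count", {
  for (s in 1:6) {
    sim <- simulate_matrix(n_taxa = 12, n_characters = 15,
                           p_origins = c(0.1, 0.4, 0.3, 0.2),
                           p_missing = 0, p_inapplicable = 0,
                           p_polymorphic = 0, seed = s)
    steps <- tree_length(sim$tree, sim$matrix)$steps
    expect_true(all(steps <= sim$origins))
    # with distinct derived states (3-state chars, <=2 origins), equality
    three <- sim$n_states == 3 & sim$origins <= 2
    expect_identical(unname(steps[three]), sim$origins[three])
  }
})

test_that("identical seeds reproduce identical simulations", {
  a <- simulate_matrix(seed = 77)
  b <- simulate_matrix(seed = 77)
  expect_identical(a$matrix$mask, b$matrix$mask)
  expect_identical(a$matrix$kind, b$matrix$kind)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$origins, b$origins)
  c <- simulate_matrix(seed = 78)
  expect_false(identical(a$matrix$mask, c$matrix$mask))
})

test_that("injected wildcards never raise the true-tree length", {
  for (s in 1:5) {
    clean <- simulate_matrix(n_taxa = 10, n_characters = 12,
                             p_missing = 0, p_inapplicable = 0,
                             p_polymorphic = 0, seed = s)
    tok <- matrix_tokens(clean$matrix)
    set.seed(1000 + s)
    wild <- tok
    hit <- matrix(runif(length(tok)) < 0.2, nrow(tok))
    wild[hit] <- "?"
    m2 <- char_matrix(wild)
    expect_lte(tree_length(clean$tree, m2)$total_length,
               tree_length(clean$tree, clean$matrix)$total_length)
  }
})

test_that("the rate model produces valid matrices", {
  sim <- simulate_matrix(n_taxa = 8, n_characters = 10,
                         change_model = "rate", rate = 0.4, seed = 9)
  expect_true(anyNA(sim$origins))
  expect_s3_class(sim$matrix, "char_matrix")
  expect_identical(dim(sim$matrix), c(8L, 10L))
})

test_that("homoplasy-free recovery trial recovers the truth with CI 1", {
  sim <- simulate_matrix(n_taxa = 12, n_characters = 40, p_three = 0,
                         p_origins = c(0, 1), p_missing = 0,
                         p_inapplicable = 0, p_polymorphic = 0, seed = 4)
  tr <- recovery_trial(sim, replicates = 5, seed = 4)
  expect_true(tr$true_in_mpt)
  expect_identical(tr$CI, 1)
  expect_identical(tr$best_length, tr$true_length)
})

test_that("one conflicting character pair gives two MPTs and a star", {
  m <- tok_matrix(A = "00", B = "01", C = "10", D = "11")
  # brute force over the three 4-taxon topologies
  topos <- lapply(c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));"),
                  function(s) ape::read.tree(text = s))
  lens <- vapply(topos, function(t) tree_length(t, m)$total_length, 0L)
  expect_identical(sort(lens), c(3L, 3L, 4L))
  fit <- parsimony_search(m, method = "branch-and-bound", collapse = FALSE)
  expect_identical(length(fit$binary_trees), 2L)
  cons <- strict_consensus(fit$trees)
  expect_identical(length(bipartitions(cons, sort(m$taxa))), 0L)
})

test_that("ambiguity-probability validation rejects bad configs", {
  expect_error(simulate_matrix(p_missing = 1.4), "probabilities")
  expect_error(simulate_matrix(n_taxa = 3), "4 taxa")
})
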