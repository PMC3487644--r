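test_that("textbook lengths are reproduced", {
  m <- tok_matrix(A = "0", B = "0", C = "0", D = "0")
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(character_length(tr, m, 0), 0L)  # invariant

  m2 <- tok_matrix(A = "0", B = "0", C = "1", D = "1")
  expect_identical(character_length(tr, m2, 0), 1L)  # one internal change

  m3 <- tok_matrix(A = "?", B = "?", C = "?", D = "?")
  expect_identical(character_length(tr, m3, 0), 0L)  # wildcards everywhere

  # additivity: total = sum of per-character lengths
  m4 <- tok_matrix(A = "001", B = "011", C = "101", D = "110")
  sc <- tree_length(tr, m4)
  expect_identical(sc$total_length,
                   sum(sapply(0:2, function(j) character_length(tr, m4, j))))
})

test_that("Fitch length equals the brute-force labeling oracle", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    m <- random_matrix(n, 3, p_wild = 0.2, p_poly = 0.1, max_state = 2)
    topo <- all_topologies(m$taxa)
    tr <- topo[[sample(length(topo), 1)]]
    for (j in 0:2)
      expect_identical(character_length(tr, m, j),
                       oracle_char_length(tr, m, j),
                       label = sprintf("rep %d char %d", rep, j))
  }
})

test_that("scores agree with an independent engine on the reference data", {
  m <- stoiba_matrix()
  pd <- as_phyDat(m)
  set.seed(5)
  for (rep in 1:4) {
    tr <- ape::rtopology(20, rooted = FALSE, tip.label = sample(m$taxa))
    expect_identical(tree_length(tr, m)$total_length,
                     as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("length is invariant to rooting and taxon order", {
  set.seed(11)
  m <- random_matrix(7, 5, p_wild = 0.15, p_poly = 0.05)
  tr <- ape::rtopology(7, rooted = FALSE, tip.label = m$taxa)
  base <- tree_length(tr, m)$total_length
  for (og in m$taxa[1:4])
    expect_identical(
      tree_length(ape::root(tr, og, resolve.root = TRUE), m)$total_length,
      base)
  perm <- sample(n_taxa(m))
  m2 <- m
  m2$taxa <- m$taxa[perm]
  m2$mask <- m$mask[perm, , drop = FALSE]
  m2$kind <- m$kind[perm, , drop = FALSE]
  expect_identical(tree_length(tr, m2)$total_length, base)
})

test_that("binary Fitch and the multifurcation-safe program agree", {
  set.seed(13)
  for (rep in 1:6) {
    m <- random_matrix(6, 4, p_wild = 0.2, p_poly = 0.1)
    tr <- ape::rtopology(6, rooted = FALSE, tip.label = m$taxa)
    masks <- mpmorph:::tip_masks(tr, m)
    direct <- mpmorph:::cpp_fitch_lengths(tr$edge, 6L, masks)
    dp <- vapply(1:4, function(j) mpmorph:::sankoff_steps(tr, masks[, j]), 0L)
    expect_identical(as.integer(direct), dp)
  }
})

test_that("missing leaves are reported by name", {
  m <- tok_matrix(A = "0", B = "1", C = "0", D = "1")
  tr <- ape::read.tree(text = "((A,B),(C,X));")
  expect_error(tree_length(tr, m), "X")
})

test_that("step bounds match their definitions", {
  m <- stoiba_matrix()
  expect_identical(unname(min_steps(m, 12)), 2L)  # three states in use
  s29 <- min_steps(m, 29)
  expect_identical(unname(s29), 2L)

  inv <- tok_matrix(A = "0", B = "0", C = "0", D = "0")
  expect_identical(unname(min_steps(inv, 0)), 0L)
  expect_identical(unname(max_steps(inv, 0)), 0L)

  cover <- parse_matrix("A\t0\nB\t0&1", "tsv")
  expect_identical(unname(min_steps(cover, 0)), 0L)  # state 0 covers both

  minority <- char_matrix(matrix(c(rep("1", 5), rep("0", 15)), ncol = 1,
                                 dimnames = list(paste0("t", 1:20), NULL)))
  expect_identical(unname(max_steps(minority, 0)), 5L)
})

test_that("max steps equal the star-tree length", {
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    m <- random_matrix(n, 3, p_wild = 0.2, p_poly = 0.1)
    star <- ape::read.tree(text = paste0("(", paste(m$taxa, collapse = ","), ");"))
    masks <- mpmorph:::resolved_masks(m)
    for (j in 1:3)
      expect_identical(unname(max_steps(m, j - 1)),
                       mpmorph:::sankoff_steps(star, masks[, j]))
  }
})

test_that("bounds bracket the realized steps on every tree", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    m <- random_matrix(n, 4, p_wild = 0.2, p_poly = 0.1)
    tr <- ape::rtopology(n, rooted = FALSE, tip.label = m$taxa)
    s <- tree_length(tr, m)
    expect_true(all(s$min_steps <= s$steps))
    expect_true(all(s$steps <= s$max_steps))
  }
})

test_that("turning cells into wildcards never increases s, m or g", {
  set.seed(23)
  for (rep in 1:6) {
    m <- random_matrix(6, 3, p_wild = 0, p_poly = 0.1)
    tr <- ape::rtopology(6, rooted = FALSE, tip.label = m$taxa)
    i <- sample(6, 1); j <- sample(3, 1)
    tok <- matrix_tokens(m)
    tok[i, j] <- "?"
    m2 <- char_matrix(tok)
    expect_lte(character_length(tr, m2, j - 1), character_length(tr, m, j - 1))
    expect_lte(min_steps(m2, j - 1), min_steps(m, j - 1))
    expect_lte(max_steps(m2, j - 1), max_steps(m, j - 1))
  }
})

test_that("the fixed-polymorphism variant counts the polymorphic cell", {
  m <- parse_matrix("A\t0\nB\t1\nC\t0&1\nD\t0", "tsv")
  expect_identical(unname(min_steps(m, 0, polymorphism = "free")), 1L)
  expect_identical(unname(min_steps(m, 0, polymorphism = "fixed")), 2L)
  expect_identical(unname(max_steps(m, 0, polymorphism = "free")), 1L)
  expect_identical(unname(max_steps(m, 0, polymorphism = "fixed")), 2L)
})
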