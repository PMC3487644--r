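rooted_comb <- function() ape::read.tree(text = "(A,(B,(C,D)));")

test_that("optimization requires a rooted tree and handles easy cases", {
  m <- tok_matrix(A = "00", B = "00", C = "01", D = "01")
  unrooted <- ape::read.tree(text = "((A,B),C,D);")
  expect_error(optimize_character(unrooted, m, 0), "root")

  tr <- rooted_comb()
  # invariant character: no changes in any mode
  for (mode in c("ACCTRAN", "DELTRAN", "unambiguous"))
    expect_identical(nrow(optimize_character(tr, m, 0, mode)$changes), 0L)

  # 0,0,1,1 on the comb: one unambiguous change on the (C,D) stem
  ch <- optimize_character(tr, m, 1, "unambiguous")$changes
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$from, 0L)
  expect_identical(ch$to, 1L)
  cd <- ape::getMRCA(tr, c("C", "D"))
  expect_identical(ch$node, cd)
})

test_that("both reconstructions place exactly the Fitch length in changes", {
  set.seed(61)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    m <- random_matrix(n, 4, p_wild = 0.15, p_poly = 0.05)
    tr <- ape::root(ape::rtopology(n, rooted = FALSE, tip.label = m$taxa),
                    m$taxa[1], resolve.root = TRUE)
    for (j in 0:3) {
      s <- character_length(tr, m, j)
      acc <- optimize_character(tr, m, j, "ACCTRAN")$changes
      del <- optimize_character(tr, m, j, "DELTRAN")$changes
      expect_identical(nrow(acc), s, label = sprintf("ACCTRAN rep %d", rep))
      expect_identical(nrow(del), s, label = sprintf("DELTRAN rep %d", rep))
    }
  }
})

test_that("unambiguous changes are the ACCTRAN/DELTRAN intersection", {
  set.seed(67)
  m <- random_matrix(6, 5, p_wild = 0.2, p_poly = 0.05)
  tr <- ape::root(ape::rtopology(6, rooted = FALSE, tip.label = m$taxa),
                  m$taxa[1], resolve.root = TRUE)
  syn <- synapomorphies(tr, m)
  for (j in 0:4) {
    unam <- optimize_character(tr, m, j, "unambiguous")$changes
    both <- syn[syn$character == j & syn$ambiguity == "unambiguous", ]
    expect_identical(nrow(unam), nrow(both))
  }
  expect_true(all(syn$ambiguity %in%
                  c("unambiguous", "acctran_only", "deltran_only")))
})

test_that("ACCTRAN accelerates and DELTRAN delays on the textbook case", {
  # B and the (C,D) pair derived; A keeps 0: one origin + one reversal
  # (ACCTRAN) versus two parallel origins (DELTRAN)
  m <- tok_matrix(A = "0", B = "1", C = "1", D = "0")
  tr <- rooted_comb()
  acc <- optimize_character(tr, m, 0, "ACCTRAN")$changes
  del <- optimize_character(tr, m, 0, "DELTRAN")$changes
  expect_identical(nrow(acc), 2L)
  expect_identical(nrow(del), 2L)
  # ACCTRAN gains 1 deep and reverses; DELTRAN gains twice at the tips
  expect_true(any(acc$from == 1L & acc$to == 0L))
  expect_true(all(del$from == 0L & del$to == 1L))
  expect_true(all(del$node <= length(tr$tip.label)))
})

test_that("clade support reports the stem changes with ambiguity class", {
  m <- tok_matrix(A = "001", B = "011", C = "111", D = "110")
  tr <- rooted_comb()
  cs <- clade_support(tr, m, c("C", "D"))
  expect_true(all(c("character", "from", "to", "ambiguity") %in% names(cs)))
  expect_identical(cs$character, 0L)  # only char 0 changes on the stem
  expect_identical(cs$ambiguity, "unambiguous")
  expect_error(clade_support(tr, m, c("A", "C")), "clade")
  expect_error(clade_support(tr, m, c("A", "X")), "unknown")
})

test_that("rerooting within the outgroup leaves ingroup changes alone", {
  m <- stoiba_matrix()
  fit <- parsimony_search(m, replicates = 10, seed = 3)
  tr <- fit$binary_trees[[1]]
  r1 <- root_on_outgroup(tr, "Spaethiella sp.")
  outpair <- c("Physonota alutacea", "Asteriza flavicornis")
  r2 <- tryCatch(root_on_outgroup(tr, outpair), error = function(e) NULL)
  expect_false(is.null(r2))
  # changes keyed by the clade content of their branch, restricted to
  # branches wholly inside the Elytrogona clade (far from both roots)
  ely <- grep("^Elytrogona", m$taxa, value = TRUE)
  keyed <- function(rt) {
    syn <- synapomorphies(rt, m)
    keys <- vapply(seq_len(nrow(syn)), function(i) {
      tips <- rt$tip.label[mpmorph:::tip_descendants(rt, syn$node[i])]
      paste(sort(tips), collapse = "|")
    }, "")
    inside <- vapply(strsplit(keys, "|", fixed = TRUE),
                     function(t) all(t %in% ely) && length(t) < length(ely),
                     TRUE)
    sort(paste(syn$character, syn$from, syn$to, syn$ambiguity, keys)[inside])
  }
  expect_identical(keyed(r1), keyed(r2))
})

test_that("optimization works on multifurcating consensus trees", {
  m <- stoiba_matrix()
  fit <- parsimony_search(m, replicates = 10, seed = 4)
  cons <- strict_consensus(fit$trees)
  rooted <- root_on_outgroup(cons, "Spaethiella sp.")
  syn <- synapomorphies(rooted, m)
  expect_gt(nrow(syn), 0L)
  # the brachypterous clade is recovered and its stem carries the
  # hind-wing reduction
  cl <- clade_support(rooted, m,
                      c("Stoiba angusticollis", "Stoiba bruneri",
                        "Stoiba flavicollis", "Stoiba marginata",
                        "Stoiba nigricans"))
  expect_true(29 %in% cl$character)
})
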