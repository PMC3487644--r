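# Shared fixtures and independent brute-force oracles.

# small matrix builder: rows are token strings, e.g. tok(A = "001?")
tok_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  char_matrix(m)
}

# random token matrix for round-trip / property tests
random_matrix <- function(n_taxa, n_char, p_wild = 0.1, p_poly = 0.05,
                          max_state = 2) {
  tokens <- matrix("", n_taxa, n_char)
  for (j in seq_len(n_char)) {
    k <- sample(2:(max_state + 1), 1)  # states 0..k-1
    for (i in seq_len(n_taxa)) {
      u <- runif(1)
      tokens[i, j] <- if (u < p_wild / 2) "?" else if (u < p_wild) "N"
      else if (u < p_wild + p_poly && k > 1)
        paste(sort(sample(0:(k - 1), 2)), collapse = "&")
      else as.character(sample(0:(k - 1), 1))
    }
  }
  rownames(tokens) <- paste0("t", seq_len(n_taxa))
  char_matrix(tokens)
}

# every unrooted binary topology over the given labels (n <= 7)
all_topologies <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3, n <= 7)
  trees <- list(sprintf("(%s,%s,%s);", labels[1], labels[2], labels[3]))
  grow <- function(newick_set, k) {
    if (k > n) return(newick_set)
    out <- list()
    for (s in newick_set) {
      tr <- ape::read.tree(text = s)
      for (e in seq_len(nrow(tr$edge)))
        out <- c(out, list(insert_tip_newick(tr, e, labels[k])))
    }
    grow(unique(unlist(out)), k + 1)
  }
  trees <- grow(trees, 4)
  lapply(unlist(trees), function(s) ape::read.tree(text = s))
}

# subdivide edge e of tr and attach a new tip; returns newick
insert_tip_newick <- function(tr, e, label) {
  ntip <- length(tr$tip.label)
  new_internal <- ntip + tr$Nnode + 2L
  new_tip <- ntip + 1L
  edge <- tr$edge
  edge[edge > ntip] <- edge[edge > ntip] + 1L  # shift internals for new tip
  target <- edge[e, ]
  edge[e, 2] <- new_internal
  edge <- rbind(edge, c(new_internal, target[2]), c(new_internal, new_tip))
  t2 <- list(edge = edge, tip.label = c(tr$tip.label, label),
             Nnode = tr$Nnode + 1L)
  class(t2) <- "phylo"
  t2 <- ape::read.tree(text = ape::write.tree(t2))
  ape::write.tree(t2)
}

# brute-force Fitch oracle: minimum changes over all internal-node
# labelings (states drawn from the union of observed states)
oracle_char_length <- function(tree, m, index) {
  cell_sets <- lapply(m$taxa, function(t) matrix_cell(m, t, index)$states)
  names(cell_sets) <- m$taxa
  states <- sort(unique(unlist(cell_sets)))
  if (length(states) == 0) return(0L)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(states), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_int <- grid[g, ]
    total <- 0
    ok <- TRUE
    for (r in seq_len(nrow(tr$edge))) {
      p <- tr$edge[r, 1]; v <- tr$edge[r, 2]
      ps <- assign_int[p - ntip]
      if (v <= ntip) {
        cs <- cell_sets[[tr$tip.label[v]]]
        if (!(ps %in% cs)) total <- total + 1
      } else {
        if (assign_int[v - ntip] != ps) total <- total + 1
      }
      if (total >= best) { ok <- FALSE; break }
    }
    if (ok) best <- total
  }
  as.integer(best)
}

# token matrix of a char_matrix (for rebuilding perturbed copies)
matrix_tokens <- function(m) {
  tok <- matrix("", n_taxa(m), n_characters(m), dimnames = list(m$taxa, NULL))
  for (i in seq_len(n_taxa(m))) for (j in seq_len(n_characters(m))) {
    cell <- list(states = mpmorph:::mask_states(m$mask[i, j]),
                 kind = m$kind[i, j])
    tok[i, j] <- switch(cell$kind,
                        observed = as.character(cell$states),
                        polymorphic = paste(cell$states, collapse = "&"),
                        missing = "?", inapplicable = "N")
  }
  tok
}

# brute-force forced-change oracle: for one character, is every optimal
# internal labeling forced to change across each internal edge?
oracle_forced_edges <- function(tree, m, index) {
  cell_sets <- lapply(m$taxa, function(t) matrix_cell(m, t, index)$states)
  names(cell_sets) <- m$taxa
  states <- sort(unique(unlist(cell_sets)))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  grid <- as.matrix(expand.grid(rep(list(states), tr$Nnode)))
  cost <- apply(grid, 1, function(assign_int) {
    total <- 0
    for (r in seq_len(nrow(tr$edge))) {
      p <- tr$edge[r, 1]; v <- tr$edge[r, 2]
      ps <- assign_int[p - ntip]
      if (v <= ntip) {
        if (!(ps %in% cell_sets[[tr$tip.label[v]]])) total <- total + 1
      } else if (assign_int[v - ntip] != ps) total <- total + 1
    }
    total
  })
  opt <- grid[cost == min(cost), , drop = FALSE]
  forced <- rep(NA, nrow(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; v <- tree$edge[r, 2]
    if (v <= ntip) next
    forced[r] <- !any(opt[, p - ntip] == opt[, v - ntip])
  }
  forced
}

# phangorn cross-check helpers (phangorn is an independent engine)
as_phyDat <- function(m) {
  tok <- matrix("", n_taxa(m), n_characters(m), dimnames = list(m$taxa, NULL))
  for (i in seq_len(n_taxa(m))) for (j in seq_len(n_characters(m))) {
    cell <- matrix_cell(m, m$taxa[i], j - 1)
    tok[i, j] <- switch(cell$kind,
                        observed = as.character(cell$states),
                        polymorphic = paste(cell$states, collapse = "&"),
                        missing = "?", inapplicable = "N")
  }
  states <- as.character(0:max(c(1, unlist(m$characters$observed_states))))
  polys <- unique(tok[grepl("&", tok)])
  contr <- matrix(0, nrow = length(states) + length(polys) + 2,
                  ncol = length(states),
                  dimnames = list(c(states, polys, "?", "N"), states))
  for (s in states) contr[s, s] <- 1
  for (p in polys) contr[p, strsplit(p, "&")[[1]]] <- 1
  contr["?", ] <- 1; contr["N", ] <- 1
  phangorn::phyDat(tok, type = "USER", contrast = contr)
}
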