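#' Search for all most-parsimonious trees
#'
#' Fits the maximum-parsimony estimate of topology for a character
#' matrix: finds the set of shortest trees under equal-weight unordered
#' (Fitch) parsimony, collapses branches whose minimum length over all
#' optimal reconstructions is zero, and deduplicates the resulting
#' topologies by bipartition set.
#'
#' Two engines are available.  `method = "branch-and-bound"` is exact:
#' stepwise addition in fixed taxon order with pruning on a lower bound
#' (current partial length plus the number of states required only by
#' taxa not yet added), guaranteed to return every minimal-length
#' resolved tree; it refuses matrices above `bab_ceiling` taxa.
#' `method = "heuristic"` runs `replicates` random-addition sequences,
#' each followed by branch swapping (`NNI`, `SPR` or `TBR`) that keeps
#' and swaps through *all* equal-best topologies found (up to
#' `max_trees`), pooling results over replicates.  Replaying the same
#' `seed` reproduces the identical result.
#'
#' @param x a [char_matrix].
#' @param method `"heuristic"` (default) or `"branch-and-bound"`.
#' @param replicates number of random-addition replicates.
#' @param swap branch-swapping neighbourhood: `"TBR"` (default),
#'   `"SPR"` or `"NNI"`.
#' @param seed integer seed driving the random addition orders.
#' @param max_trees cap on trees held; exceeding it flags the result
#'   as non-exhaustive (`log$overflow`).
#' @param collapse collapse unsupported branches before counting MPTs
#'   (the `"min-length-zero"` rule); the uncollapsed binary trees are
#'   kept in `binary_trees`.
#' @param bab_ceiling largest taxon count accepted by the exact search.
#' @return an object of class `parsimony_search`: list with
#'   `best_length`, `trees` (collapsed, deduplicated `multiPhylo`),
#'   `binary_trees`, `log` (settings, per-replicate lengths, swap
#'   counts), and the scored `matrix`.
#' @examples
#' m <- char_matrix(rbind(A = c("0", "0"), B = c("0", "0"),
#'                        C = c("1", "1"), D = c("1", "1"),
#'                        E = c("1", "?")))
#' fit <- parsimony_search(m, replicates = 5, seed = 1)
#' fit
#' @seealso [strict_consensus()], [ensemble_indices()], [synapomorphies()]
#' @export
parsimony_search <- function(x, method = c("heuristic", "branch-and-bound"),
                             replicates = 100, swap = c("TBR", "SPR", "NNI"),
                             seed = 42, max_trees = 10000,
                             collapse = TRUE, bab_ceiling = 14) {
  method <- match.arg(method)
  swap <- match.arg(swap)
  validate_char_matrix(x)
  n <- n_taxa(x)
  if (n < 3L || (method == "heuristic" && n < 4L))
    stop("too few taxa to search (heuristic needs 4, exact needs 3)")
  masks <- resolved_masks(x)
  if (method == "branch-and-bound") {
    if (n > bab_ceiling)
      stop(sprintf(paste0("branch-and-bound is limited to %d taxa (%d given); ",
                          "use method = \"heuristic\""), bab_ceiling, n))
    res <- cpp_branch_and_bound(masks)
    log <- list(method = method, seed = NULL)
  } else {
    if (replicates < 1L) stop("replicates must be >= 1")
    orders <- with_seed(seed, t(vapply(seq_len(replicates),
                                       function(i) sample.int(n), integer(n))))
    res <- cpp_heuristic_search(masks, orders,
                                match(swap, c("NNI", "SPR", "TBR")) - 1L,
                                as.integer(max_trees))
    log <- list(method = method, replicates = replicates, swap = swap,
                seed = seed, max_trees = max_trees,
                replicate_lengths = res$replicate_length,
                rearrangements = res$rearrangements,
                overflow = isTRUE(res$overflow))
    if (isTRUE(res$overflow))
      warning("tree buffer overflow (max_trees reached); ",
              "result may be non-exhaustive")
  }
  binary <- decode_trees(res$trees, x$taxa)
  trees <- if (collapse)
    dedupe_trees(lapply(binary, collapse_unsupported, x = x))
  else binary
  structure(list(best_length = res$best_length,
                 trees = trees,
                 binary_trees = binary,
                 log = log,
                 matrix = x,
                 call = match.call()),
            class = "parsimony_search")
}

decode_trees <- function(newicks, taxa) {
  trees <- lapply(newicks, function(s) {
    tr <- ape::read.tree(text = s)
    tr$tip.label <- taxa[as.integer(tr$tip.label)]
    tr
  })
  class(trees) <- "multiPhylo"
  trees
}

#' @export
print.parsimony_search <- function(x, ...) {
  cat("Maximum parsimony search\n")
  if (identical(x$log$method, "heuristic"))
    cat(sprintf("  heuristic: %d random-addition replicates + %s (seed %s)\n",
                x$log$replicates, x$log$swap, format(x$log$seed)))
  else
    cat("  exact branch-and-bound\n")
  cat(sprintf("  best length: %d steps\n", x$best_length))
  cat(sprintf("  MPTs: %d after collapsing/deduplication (%d binary)\n",
              length(x$trees), length(x$binary_trees)))
  invisible(x)
}

#' @export
summary.parsimony_search <- function(object, ...) {
  print(object)
  rep <- ensemble_indices(object, object$matrix)
  cat(sprintf("  ensemble indices (all characters): CI = %.2f, RI = %.2f, RC = %.2f\n",
              round_half_up(rep$CI), round_half_up(rep$RI),
              round_half_up(rep$RC)))
  invisible(object)
}

#' @export
plot.parsimony_search <- function(x, which = c("consensus", "mpts"), ...) {
  which <- match.arg(which)
  if (which == "consensus")
    ape::plot.phylo(strict_consensus(x$trees), ...)
  else {
    op <- graphics::par(mfrow = c(1, min(length(x$trees), 4L)))
    on.exit(graphics::par(op))
    for (tr in x$trees[seq_len(min(length(x$trees), 4L))])
      ape::plot.phylo(tr, ...)
  }
  invisible(x)
}

#' Collapse branches with zero minimum length
#'
#' Contracts every internal branch of a resolved tree on which no
#' character is forced to change: for each branch the minimum number of
#' changes over all optimal reconstructions is computed exactly (by an
#' inside-outside dynamic program per character), and branches whose
#' minimum is zero for every character are collapsed.  The result may
#' be multifurcating.
#'
#' The tree is treated as unrooted (a rooted input is unrooted first,
#' so that the two branches meeting at the root count as the single
#' unrooted branch they represent).  Collapsing each branch is
#' justified by some optimal reconstruction, but distinct branches may
#' need different reconstructions, so the collapsed (multifurcating)
#' tree can be longer than the input -- the rule is a statement about
#' branch support, not a length-preserving operation.
#'
#' @param tree a `phylo` tree over taxa of `x`.
#' @param x a [char_matrix].
#' @return a `phylo` tree whose bipartitions are a subset of the
#'   input's.
#' @export
collapse_unsupported <- function(tree, x) {
  if (ape::is.rooted(tree) && length(tree$tip.label) >= 3L)
    tree <- ape::unroot(tree)
  masks <- tip_masks(tree, x)
  ntip <- length(tree$tip.label)
  supported <- rep(FALSE, nrow(tree$edge))
  internal <- tree$edge[, 2L] > ntip
  for (j in seq_len(ncol(masks))) {
    if (all(supported[internal])) break
    forced <- edge_forced_change(tree, masks[, j])
    supported <- supported | forced
  }
  drop <- internal & !supported
  if (!any(drop)) return(tree)
  tr <- tree
  tr$edge.length <- ifelse(drop, 0, 1)
  tr <- ape::di2multi(tr, tol = 0.5)
  tr$edge.length <- NULL
  tr
}

# For one character, which edges carry a change in EVERY optimal
# reconstruction?  Inside-outside 0/1-cost DP; exact on any topology.
edge_forced_change <- function(tree, tipmask) {
  d <- sankoff_down(tree, tipmask)
  down <- d$down; K <- d$K; tre <- d$tree
  s_char <- min(down[d$root, ])
  nnode <- nrow(down)
  up <- matrix(0, nnode, K)  # up[v, s]: cost outside subtree(v), v = s
  edges <- tre$edge
  # preorder = reverse postorder of edges
  for (r in rev(seq_len(nrow(edges)))) {
    p <- edges[r, 1L]; v <- edges[r, 2L]
    # siblings' contribution given p = t, plus p's own outside
    sib <- down[p, ] - pmin(down[v, ], min(down[v, ]) + 1)
    tot <- up[p, ] + sib                      # cost outside v with p = t
    up[v, ] <- pmin(tot, min(tot) + 1)        # allow change on edge p-v
  }
  # zero change possible on edge (p,v) iff some state s has
  # down[v,s] + (outside v with p = s, no change on the edge) == s_char
  forced <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    p <- edges[r, 1L]; v <- edges[r, 2L]
    sib <- down[p, ] - pmin(down[v, ], min(down[v, ]) + 1)
    zero <- min(down[v, ] + up[p, ] + sib)
    forced[r] <- zero > s_char
  }
  # report in the original tree's edge order
  ord <- match(paste(tree$edge[, 1L], tree$edge[, 2L]),
               paste(edges[, 1L], edges[, 2L]))
  forced[ord]
}

#' Topology identity and deduplication
#'
#' Two unrooted trees over the same leaf set are identical when their
#' non-trivial bipartition sets are equal.  `bipartitions()` returns a
#' canonical character key per internal branch; `dedupe_trees()` keeps
#' one representative per distinct bipartition set.
#'
#' @param tree,trees `phylo` / list of `phylo` over identical leaf sets.
#' @param ref reference taxon ordering (defaults to the first tree's
#'   tip labels, sorted).
#' @return `bipartitions()`: sorted character vector of split keys.
#'   `dedupe_trees()`: a `multiPhylo` of unique topologies.
#' @export
bipartitions <- function(tree, ref = sort(tree$tip.label)) {
  ntip <- length(tree$tip.label)
  if (ntip != length(ref) || !setequal(tree$tip.label, ref))
    stop("tree leaves do not match the reference taxon set")
  tre <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- match(tre$tip.label[i], ref)
  for (r in seq_len(nrow(tre$edge))) {
    p <- tre$edge[r, 1L]; v <- tre$edge[r, 2L]
    below[[p]] <- c(below[[p]], below[[v]])
  }
  keys <- character(0)
  for (r in seq_len(nrow(tre$edge))) {
    v <- tre$edge[r, 2L]
    if (v <= ntip) next
    s <- sort(below[[v]])
    if (length(s) < 2L || length(s) > ntip - 2L) next
    if (1L %in% s) s <- setdiff(seq_len(ntip), s)
    keys <- c(keys, paste(s, collapse = "."))
  }
  sort(unique(keys))
}

#' @rdname bipartitions
#' @export
dedupe_trees <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ref <- sort(trees[[1L]]$tip.label)
  keys <- vapply(trees, function(tr)
    paste(bipartitions(tr, ref), collapse = "|"), "")
  out <- trees[!duplicated(keys)]
  class(out) <- "multiPhylo"
  out
}
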