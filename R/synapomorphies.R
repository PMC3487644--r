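#' Root a tree on an outgroup
#'
#' Convenience wrapper around [ape::root()] that roots on the branch
#' leading to the given outgroup taxon (or monophyletic outgroup set),
#' as required before mapping character-state changes.
#'
#' @param tree a `phylo`.
#' @param outgroup taxon label(s).
#' @return a rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Optimize a character on a rooted tree
#'
#' Assigns ancestral states for one unordered character on a rooted
#' tree and lists the branch-wise state changes.  The dynamic program
#' is exact on any topology (multifurcations included); `mode` selects
#' how remaining ambiguity is resolved:
#'
#' * `"ACCTRAN"` -- accelerated transformation: at each node, prefer a
#'   state *different* from the parent whenever an optimal
#'   reconstruction allows it, pulling changes toward the root.
#' * `"DELTRAN"` -- delayed transformation: prefer the parent's state
#'   whenever possible, pushing changes toward the tips.
#' * `"unambiguous"` -- only the changes shared by the ACCTRAN and
#'   DELTRAN reconstructions (same branch, same transition).
#'
#' Both full reconstructions place exactly the character's Fitch length
#' in changes.
#'
#' @param tree a *rooted* `phylo` over taxa of `x`.
#' @param x a [char_matrix].
#' @param index 0-based character index.
#' @param mode `"unambiguous"` (default), `"ACCTRAN"` or `"DELTRAN"`.
#' @return list with `changes` (data frame: `node` -- the child end of
#'   the branch, `character`, `from`, `to`, `mode`) and, for the two
#'   concrete modes, `states` (the node-state assignment).
#' @export
optimize_character <- function(tree, x, index,
                               mode = c("unambiguous", "ACCTRAN", "DELTRAN")) {
  mode <- match.arg(mode)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; use root_on_outgroup() first")
  j <- char_cols(x, index)
  masks <- tip_masks(tree, x)
  if (mode == "unambiguous") {
    acc <- reconstruct_states(tree, masks[, j], "ACCTRAN")
    del <- reconstruct_states(tree, masks[, j], "DELTRAN")
    shared <- merge(acc$changes, del$changes,
                    by = c("node", "from", "to"))[, c("node", "from", "to")]
    ch <- shared[order(shared$node), , drop = FALSE]
    changes <- data.frame(node = ch$node,
                          character = rep(index, nrow(ch)),
                          from = ch$from, to = ch$to,
                          mode = rep("unambiguous", nrow(ch)))
    return(list(changes = changes))
  }
  rec <- reconstruct_states(tree, masks[, j], mode)
  changes <- rec$changes
  changes$character <- rep(index, nrow(changes))
  changes$mode <- rep(mode, nrow(changes))
  list(changes = changes[, c("node", "character", "from", "to", "mode")],
       states = rec$states)
}

# One-character ACCTRAN/DELTRAN reconstruction on a rooted tree.
reconstruct_states <- function(tree, tipmask, mode) {
  d <- sankoff_down(tree, tipmask)
  down <- d$down; tre <- d$tree
  ntip <- length(tree$tip.label)
  nnode <- nrow(down)
  states <- integer(nnode)
  # root: lowest optimal state (deterministic for both modes)
  states[d$root] <- which.min(down[d$root, ]) - 1L
  edges <- tre$edge
  changes <- data.frame(node = integer(0), from = integer(0), to = integer(0))
  for (r in rev(seq_len(nrow(edges)))) {  # preorder
    p <- edges[r, 1L]; v <- edges[r, 2L]
    a <- states[p]
    costs <- down[v, ] + (seq_len(ncol(down)) - 1L != a)
    opt <- which(costs == min(costs)) - 1L
    states[v] <- if (mode == "ACCTRAN") {
      if (any(opt != a)) min(opt[opt != a]) else a
    } else {
      if (a %in% opt) a else min(opt)
    }
    if (states[v] != a)
      changes <- rbind(changes,
                       data.frame(node = v, from = a, to = states[v]))
  }
  list(states = states, changes = changes)
}

#' Map all character changes onto a tree
#'
#' Runs [optimize_character()] for every character and classifies each
#' branch change as `unambiguous` (present with the same transition in
#' both the ACCTRAN and DELTRAN reconstructions), `acctran_only` or
#' `deltran_only`.
#'
#' @inheritParams optimize_character
#' @return an object of class `synapomorphy_report`: data frame with
#'   columns `node` (child end of the branch), `character`, `from`,
#'   `to`, `ambiguity`.
#' @export
synapomorphies <- function(tree, x) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; use root_on_outgroup() first")
  masks <- tip_masks(tree, x)
  out <- list()
  for (j in seq_len(ncol(masks))) {
    acc <- reconstruct_states(tree, masks[, j], "ACCTRAN")$changes
    del <- reconstruct_states(tree, masks[, j], "DELTRAN")$changes
    if (nrow(acc) == 0L && nrow(del) == 0L) next
    key <- function(z) paste(z$node, z$from, z$to)
    both <- intersect(key(acc), key(del))
    cls <- function(z, only) ifelse(key(z) %in% both, "unambiguous", only)
    acc$ambiguity <- cls(acc, "acctran_only")
    del$ambiguity <- cls(del, "deltran_only")
    comb <- rbind(acc, del[!(key(del) %in% both), , drop = FALSE])
    comb <- comb[!(duplicated(key(comb))), , drop = FALSE]
    comb$character <- x$characters$index[j]
    out[[length(out) + 1L]] <- comb
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(node = integer(0), from = integer(0), to = integer(0),
               ambiguity = character(0), character = integer(0))
  res <- res[order(res$node, res$character),
             c("node", "character", "from", "to", "ambiguity")]
  rownames(res) <- NULL
  class(res) <- c("synapomorphy_report", "data.frame")
  res
}

#' @export
print.synapomorphy_report <- function(x, ...) {
  cat(sprintf("character-state changes on %d branches (%d total)\n",
              length(unique(x$node)), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Character support on a clade's stem branch
#'
#' Lists every character-state change assigned to the branch subtending
#' a clade, with its ambiguity class.  Errors if the given terminals do
#' not form a clade on the tree, reporting the smallest clade that
#' contains them.
#'
#' @inheritParams optimize_character
#' @param clade character vector of terminal labels.
#' @return data frame with columns `character`, `from`, `to`,
#'   `ambiguity` (possibly empty if no character changes on the stem).
#' @export
clade_support <- function(tree, x, clade) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted; use root_on_outgroup() first")
  idx <- match(clade, tree$tip.label)
  if (anyNA(idx)) stop("unknown terminal: ", clade[which(is.na(idx))[1L]])
  node <- if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
  desc <- tree$tip.label[tip_descendants(tree, node)]
  if (!setequal(desc, clade))
    stop("terminals do not form a clade; smallest containing clade has ",
         length(desc), " terminals: ", paste(sort(desc), collapse = ", "))
  syn <- synapomorphies(tree, x)
  res <- syn[syn$node == node, c("character", "from", "to", "ambiguity"),
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res
}

tip_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  tips <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    ch <- tree$edge[tree$edge[, 1L] == v, 2L]
    tips <- c(tips, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  sort(tips)
}
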