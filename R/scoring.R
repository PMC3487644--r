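#' Fitch parsimony length of a tree
#'
#' `tree_length()` scores a tree on a character matrix under
#' equal-weight unordered (Fitch) parsimony and returns per-character
#' realized steps together with the per-character conceivable minima
#' and maxima.  `character_length()` returns the steps of a single
#' character.
#'
#' Terminals enter the optimization as their cell's state set: a
#' polymorphic cell as the union of its states, and missing or
#' inapplicable cells as the character's full observed-state set
#' (wildcards).  Fully resolved trees are scored with the Fitch
#' downpass; multifurcating trees (e.g. consensus trees) are scored
#' with the equivalent dynamic program over explicit states, which is
#' exact for unordered characters on any topology.  The length does not
#' depend on the rooting.
#'
#' @param tree a `phylo` tree whose tip labels all occur in `x`.
#' @param x a [char_matrix].
#' @return `tree_length()`: an object of class `parsimony_score` with
#'   fields `steps` (per character), `total_length`, `min_steps`,
#'   `max_steps`.  `character_length()`: a single integer.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' tree_length(tr, m)
#' @export
tree_length <- function(tree, x) {
  masks <- tip_masks(tree, x)
  steps <- if (ape::is.binary(tree))
    cpp_fitch_lengths(tree$edge, length(tree$tip.label), masks)
  else
    vapply(seq_len(ncol(masks)), function(j)
      sankoff_steps(tree, masks[, j]), 0L)
  names(steps) <- as.character(x$characters$index)
  structure(list(steps = steps,
                 total_length = sum(steps),
                 min_steps = min_steps(x),
                 max_steps = max_steps(x)),
            class = "parsimony_score")
}

#' @rdname tree_length
#' @param index 0-based character index.
#' @export
character_length <- function(tree, x, index) {
  j <- index + 1L
  if (j < 1L || j > n_characters(x))
    stop("character index out of range: ", index)
  unname(tree_length(tree, x)$steps[j])
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("parsimony score: L = %d over %d characters\n",
              x$total_length, length(x$steps)))
  cat(sprintf("  bounds: sum(m) = %d, sum(g) = %d\n",
              sum(x$min_steps), sum(x$max_steps)))
  invisible(x)
}

# Map tree tips to resolved state-mask rows; errors name absent leaves.
tip_masks <- function(tree, x) {
  idx <- match(tree$tip.label, x$taxa)
  if (anyNA(idx))
    stop("leaf not in matrix: ", tree$tip.label[which(is.na(idx))[1L]])
  resolved_masks(x)[idx, , drop = FALSE]
}

# Exact minimum-change count for one character on an arbitrary (possibly
# multifurcating) tree: 0/1-cost dynamic program over explicit states.
sankoff_steps <- function(tree, tipmask) {
  d <- sankoff_down(tree, tipmask)
  as.integer(min(d$down[d$root, ]))
}

# Downpass cost table: down[v, s] = min changes in subtree(v) given v = s.
sankoff_down <- function(tree, tipmask) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  K <- max(c(1L, unlist(lapply(tipmask, mask_states)))) + 1L
  states <- seq_len(K) - 1L
  down <- matrix(Inf, nnode, K)
  for (i in seq_len(ntip))
    down[i, states %in% mask_states(tipmask[i])] <- 0
  tre <- ape::reorder.phylo(tree, "postorder")
  for (r in seq_len(nrow(tre$edge))) {
    p <- tre$edge[r, 1L]; v <- tre$edge[r, 2L]
    if (all(!is.finite(down[p, ])) ) down[p, ] <- 0
    child <- pmin(down[v, ], min(down[v, ]) + 1)
    down[p, ] <- down[p, ] + child
  }
  # ape roots at ntip+1
  list(down = down, root = ntip + 1L, K = K, tree = tre)
}

#' Per-character conceivable step bounds
#'
#' `min_steps()` is the smallest number of steps a character can need
#' on any tree: one less than the size of the smallest set of states
#' intersecting every cell (wildcard and polymorphic cells are covered
#' by any of their states).  `max_steps()` is the largest: the length
#' on the completely unresolved star tree, where each ambiguous cell
#' takes its best covering state.  Both are exact (exhaustive over the
#' observed-state set).
#'
#' With `polymorphism = "fixed"`, a polymorphic cell is instead treated
#' as truly carrying all its states: every state of the cell must be
#' covered (minimum) and the cell contributes a change for each state
#' the star-tree centre cannot supply (maximum).
#'
#' @param x a [char_matrix].
#' @param index 0-based character index or vector of indices; default
#'   all characters.
#' @param polymorphism `"free"` (ambiguity semantics, the default) or
#'   `"fixed"`.
#' @return integer vector of bounds, one per requested character.
#' @export
min_steps <- function(x, index = NULL, polymorphism = c("free", "fixed")) {
  polymorphism <- match.arg(polymorphism)
  vapply(char_cols(x, index), function(j) {
    cells <- column_sets(x, j)
    obs <- x$characters$observed_states[[j]]
    if (length(obs) == 0L) return(0L)
    req <- integer(0)
    if (polymorphism == "fixed") {
      poly <- x$kind[, j] == "polymorphic"
      req <- sort(unique(c(unlist(cells[poly]),
                           unlist(cells[lengths(cells) == 1L]))))
      extra <- sum(vapply(cells[poly], length, 1L) - 1L)
    } else extra <- 0L
    for (k in 0:length(obs)) {
      subs <- if (k == 0L) list(integer(0)) else
        combn(obs, k, simplify = FALSE)
      for (sub in subs) {
        if (polymorphism == "fixed" && !all(req %in% sub)) next
        if (all(vapply(cells, function(s)
          length(s) == 0L || any(s %in% sub), TRUE)))
          return(max(k - 1L, 0L) + as.integer(extra))
      }
    }
    length(obs) - 1L + as.integer(extra)
  }, 0L)
}

#' @rdname min_steps
#' @export
max_steps <- function(x, index = NULL, polymorphism = c("free", "fixed")) {
  polymorphism <- match.arg(polymorphism)
  vapply(char_cols(x, index), function(j) {
    cells <- column_sets(x, j)
    obs <- x$characters$observed_states[[j]]
    if (length(obs) == 0L) return(0L)
    scored <- x$kind[, j] %in% c("observed", "polymorphic")
    poly <- x$kind[, j] == "polymorphic"
    cost <- vapply(obs, function(c0) {
      if (polymorphism == "fixed")
        sum(vapply(cells[scored & !poly], function(s) !(c0 %in% s), TRUE)) +
          sum(vapply(cells[poly], function(s) length(setdiff(s, c0)), 1L))
      else
        sum(vapply(cells[scored], function(s) !(c0 %in% s), TRUE))
    }, 0)
    as.integer(min(cost))
  }, 0L)
}

#' Parsimony informativeness of characters
#'
#' A character is parsimony-informative when at least two of its states
#' each occur in at least two single-state (unambiguously observed)
#' cells; wildcard and polymorphic cells do not count toward any
#' state's tally.
#'
#' @inheritParams min_steps
#' @return logical vector.
#' @export
is_informative <- function(x, index = NULL) {
  vapply(char_cols(x, index), function(j) {
    obsv <- x$kind[, j] == "observed"
    if (!any(obsv)) return(FALSE)
    tab <- table(x$mask[obsv, j])
    sum(tab >= 2L) >= 2L
  }, TRUE)
}

char_cols <- function(x, index) {
  if (is.null(index)) return(seq_len(n_characters(x)))
  j <- as.integer(index) + 1L
  if (any(j < 1L | j > n_characters(x)))
    stop("character index out of range")
  j
}

column_sets <- function(x, j) {
  full <- x$characters$observed_states[[j]]
  lapply(seq_len(n_taxa(x)), function(i) {
    if (x$kind[i, j] %in% c("missing", "inapplicable")) full
    else mask_states(x$mask[i, j])
  })
}
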