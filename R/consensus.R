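#' Strict consensus of a tree set
#'
#' Returns the tree containing exactly the non-trivial bipartitions
#' shared by every input tree.  Input trees must be over identical
#' leaf sets; a single input is returned unchanged (up to branch
#' lengths).
#'
#' @param trees a `multiPhylo` (or list of `phylo`, or a single
#'   `phylo`).
#' @return a `phylo`, in general multifurcating.
#' @examples
#' ts <- c(ape::read.tree(text = "((A,B),(C,D),E);"),
#'         ape::read.tree(text = "((A,B),C,(D,E));"))
#' ape::write.tree(strict_consensus(ts))
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("need at least one tree")
  ref <- sort(trees[[1L]]$tip.label)
  for (tr in trees)
    if (!setequal(tr$tip.label, ref))
      stop("trees have mismatched leaf sets")
  if (length(trees) == 1L) {
    out <- trees[[1L]]
    out$edge.length <- NULL
    return(out)
  }
  common <- Reduce(intersect, lapply(trees, bipartitions, ref = ref))
  base <- trees[[1L]]
  keys <- edge_split_keys(base, ref)
  ntip <- length(base$tip.label)
  internal <- base$edge[, 2L] > ntip
  drop <- internal & !(keys %in% common)
  out <- base
  out$edge.length <- ifelse(drop, 0, 1)
  out <- ape::di2multi(out, tol = 0.5)
  out$edge.length <- NULL
  out
}

# Split key of each edge (non-trivial internal edges; NA otherwise),
# aligned with tree$edge rows.
edge_split_keys <- function(tree, ref) {
  ntip <- length(tree$tip.label)
  tre <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- match(tre$tip.label[i], ref)
  keys_post <- rep(NA_character_, nrow(tre$edge))
  for (r in seq_len(nrow(tre$edge))) {
    p <- tre$edge[r, 1L]; v <- tre$edge[r, 2L]
    below[[p]] <- c(below[[p]], below[[v]])
    if (v > ntip) {
      s <- sort(below[[v]])
      if (length(s) >= 2L && length(s) <= ntip - 2L) {
        if (1L %in% s) s <- setdiff(seq_len(ntip), s)
        keys_post[r] <- paste(s, collapse = ".")
      }
    }
  }
  keys_post[match(paste(tree$edge[, 1L], tree$edge[, 2L]),
                  paste(tre$edge[, 1L], tre$edge[, 2L]))]
}

#' Ensemble consistency and retention indices
#'
#' Computes the classic parsimony fit indices on a tree (or on the
#' first most-parsimonious tree of a [parsimony_search] fit, all of
#' which share the same length): the ensemble consistency index
#' `CI = sum(m) / sum(s)`, retention index
#' `RI = (sum(g) - sum(s)) / (sum(g) - sum(m))`, rescaled consistency
#' `RC = CI * RI`, and their per-character analogues
#' `ci = m/s` (undefined for invariant realized characters) and
#' `ri = (g - s)/(g - m)` (undefined when `g = m`).
#'
#' Because published ensemble values sometimes exclude
#' parsimony-uninformative characters, both conventions are always
#' computed and reported; `convention` selects which one the headline
#' values use.
#'
#' @param object a `phylo` tree or a [parsimony_search] fit.
#' @param x a [char_matrix] (taken from the fit if omitted).
#' @param convention `"all_characters"` (default) or
#'   `"informative_only"`.
#' @param polymorphism passed to [min_steps()]/[max_steps()].
#' @return an object of class `index_report`: list with `L`, `CI`,
#'   `RI`, `RC`, `convention`, `both` (a two-row data frame with the
#'   ensemble values under each convention) and `per_character`.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' ensemble_indices(tr, m)
#' @export
ensemble_indices <- function(object, x = NULL,
                             convention = c("all_characters",
                                            "informative_only"),
                             polymorphism = c("free", "fixed")) {
  convention <- match.arg(convention)
  polymorphism <- match.arg(polymorphism)
  if (inherits(object, "parsimony_search")) {
    if (is.null(x)) x <- object$matrix
    tree <- object$binary_trees[[1L]]
  } else tree <- object
  if (is.null(x)) stop("a char_matrix is required")
  s <- as.integer(tree_length(tree, x)$steps)
  m <- min_steps(x, polymorphism = polymorphism)
  g <- max_steps(x, polymorphism = polymorphism)
  inf <- is_informative(x)
  ens <- function(keep) {
    S <- sum(s[keep]); M <- sum(m[keep]); G <- sum(g[keep])
    c(L = S,
      CI = if (S > 0) M / S else NA_real_,
      RI = if (G > M) (G - S) / (G - M) else NA_real_)
  }
  both <- rbind(all_characters = ens(rep(TRUE, length(s))),
                informative_only = ens(inf))
  both <- data.frame(both)
  both$RC <- both$CI * both$RI
  head_row <- both[convention, ]
  per_char <- data.frame(index = x$characters$index,
                         informative = inf, s = s, m = m, g = g,
                         ci = ifelse(s > 0, m / s, NA_real_),
                         ri = ifelse(g > m, (g - s) / (g - m), NA_real_))
  structure(list(L = sum(s), CI = head_row$CI, RI = head_row$RI,
                 RC = head_row$RC, convention = convention,
                 polymorphism = polymorphism, both = both,
                 per_character = per_char),
            class = "index_report")
}

#' @export
print.index_report <- function(x, digits = 2, ...) {
  cat(sprintf("parsimony fit indices (%s convention, polymorphism %s)\n",
              x$convention, x$polymorphism))
  cat(sprintf("  L = %d, CI = %.*f, RI = %.*f, RC = %.*f\n", x$L,
              digits, round_half_up(x$CI, digits),
              digits, round_half_up(x$RI, digits),
              digits, round_half_up(x$RC, digits)))
  b <- x$both
  for (cv in rownames(b))
    cat(sprintf("  [%s] L = %d, CI = %.4f, RI = %.4f\n",
                cv, b[cv, "L"], b[cv, "CI"], b[cv, "RI"]))
  invisible(x)
}
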