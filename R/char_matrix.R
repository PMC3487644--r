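#' Discrete morphological character matrices
#'
#' A `char_matrix` holds a taxa-by-characters grid of state-set cells.
#' Each cell records both its *states* (a set of non-negative integers,
#' stored as a bitmask with bit *k* set for state *k*) and its *kind*:
#'
#' * `"observed"` -- a single scored state;
#' * `"polymorphic"` -- the taxon shows two or more states (Table-style
#'   `$` or `0&1` tokens);
#' * `"missing"` (`?`) and `"inapplicable"` (`N` / `-`) -- unscoreable
#'   cells.  For all optimization purposes these behave as wildcards
#'   (the character's full observed-state set); the kind flag is kept so
#'   reports can distinguish them.
#'
#' All characters are unordered (Fitch) with unit weight.  A character's
#' observed-state set is defined by the cells actually scored in the
#' matrix, not by any external state list.
#'
#' @param tokens character matrix of cell tokens with taxa as rownames
#'   (or supplied via `taxa`).  Recognised tokens: single digits,
#'   `a&b`-style multi-state tokens, `$` (shorthand for `0&1`), `?`
#'   (missing), and `N` or `-` (inapplicable).
#' @param taxa character vector of taxon labels.
#' @param descriptions optional character vector describing each
#'   character (recycled to the number of characters).
#' @return an object of class `char_matrix` with fields `taxa`,
#'   `characters` (data frame: 0-based `index`, `description`,
#'   `ordered`, `weight`, and list-column `observed_states`), `mask`
#'   (raw state bitmasks; 0 for wildcard cells) and `kind`.
#' @examples
#' m <- char_matrix(rbind(A = c("0", "0"), B = c("0", "1"),
#'                        C = c("1", "?"), D = c("1", "0&1")))
#' m
#' matrix_cell(m, "D", 1)
#' @export
char_matrix <- function(tokens, taxa = rownames(tokens), descriptions = NULL) {
  if (!is.matrix(tokens) || !is.character(tokens))
    stop("`tokens` must be a character matrix of cell tokens")
  if (nrow(tokens) == 0L || ncol(tokens) == 0L)
    stop("empty matrix: need at least one taxon and one character")
  if (is.null(taxa)) stop("taxon labels required (rownames or `taxa`)")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa))
    stop("duplicate taxon label: ", taxa[duplicated(taxa)][1L])
  n <- nrow(tokens); k <- ncol(tokens)
  mask <- matrix(0L, n, k)
  kind <- matrix("observed", n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    p <- parse_token(tokens[i, j])
    if (is.null(p))
      stop(sprintf("unrecognised token '%s' (taxon '%s', character %d)",
                   tokens[i, j], taxa[i], j - 1L))
    mask[i, j] <- p$mask
    kind[i, j] <- p$kind
  }
  if (is.null(descriptions)) descriptions <- rep("", k)
  descriptions <- rep_len(as.character(descriptions), k)
  new_char_matrix(taxa, mask, kind, descriptions)
}

# Tokens -> list(mask, kind) or NULL.
parse_token <- function(tok) {
  tok <- trimws(tok)
  if (tok == "?") return(list(mask = 0L, kind = "missing"))
  if (tok == "N" || tok == "-") return(list(mask = 0L, kind = "inapplicable"))
  if (tok == "$") return(list(mask = 3L, kind = "polymorphic"))
  if (grepl("^[0-9]$", tok))
    return(list(mask = bitwShiftL(1L, as.integer(tok)), kind = "observed"))
  if (grepl("^[0-9](&[0-9])+$", tok)) {
    s <- unique(as.integer(strsplit(tok, "&", fixed = TRUE)[[1L]]))
    if (length(s) < 2L) return(NULL)
    return(list(mask = sum(bitwShiftL(1L, s)), kind = "polymorphic"))
  }
  NULL
}

new_char_matrix <- function(taxa, mask, kind, descriptions) {
  k <- ncol(mask)
  observed <- lapply(seq_len(k), function(j)
    mask_states(Reduce(bitwOr, mask[, j], 0L)))
  characters <- data.frame(index = seq_len(k) - 1L,
                           description = descriptions,
                           ordered = FALSE, weight = 1L,
                           stringsAsFactors = FALSE)
  characters$observed_states <- observed
  rownames(mask) <- rownames(kind) <- taxa
  colnames(mask) <- colnames(kind) <- as.character(seq_len(k) - 1L)
  structure(list(taxa = taxa, characters = characters,
                 mask = mask, kind = kind),
            class = "char_matrix")
}

# Integer bitmask -> sorted vector of states.
mask_states <- function(m) {
  if (m == 0L) return(integer(0))
  which(bitwAnd(m, bitwShiftL(1L, 0:30)) > 0L) - 1L
}

states_mask <- function(s) if (length(s) == 0L) 0L else
  sum(bitwShiftL(1L, as.integer(s)))

#' @export
dim.char_matrix <- function(x) dim(x$mask)

#' Number of taxa / characters in a matrix
#' @param x a [char_matrix].
#' @return integer count.
#' @export
n_taxa <- function(x) length(x$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(x) nrow(x$characters)

#' Inspect one cell of a character matrix
#'
#' @param x a [char_matrix].
#' @param taxon taxon label.
#' @param index 0-based character index.
#' @return list with `states` (integer vector; for missing/inapplicable
#'   cells, the character's full observed-state set, i.e. the wildcard
#'   resolution) and `kind`.
#' @export
matrix_cell <- function(x, taxon, index) {
  i <- match(taxon, x$taxa)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  j <- index + 1L
  if (j < 1L || j > n_characters(x)) stop("character index out of range: ", index)
  kind <- x$kind[i, j]
  states <- if (kind %in% c("missing", "inapplicable"))
    x$characters$observed_states[[j]] else mask_states(x$mask[i, j])
  list(states = states, kind = kind)
}

# Bitmask matrix with wildcard cells resolved to the character's full
# observed-state set.  All-wildcard characters resolve to state 0 so
# they are scoreable (and invariant).
resolved_masks <- function(x) {
  m <- x$mask
  for (j in seq_len(ncol(m))) {
    full <- states_mask(x$characters$observed_states[[j]])
    if (full == 0L) full <- 1L
    wild <- m[, j] == 0L
    m[wild, j] <- full
  }
  m
}

validate_char_matrix <- function(x) {
  stopifnot(inherits(x, "char_matrix"))
  if (anyDuplicated(x$taxa)) stop("duplicate taxon labels")
  if (!identical(dim(x$mask), dim(x$kind))) stop("ragged cell grid")
  if (nrow(x$mask) != length(x$taxa)) stop("row/taxa mismatch")
  obs <- x$kind %in% c("observed", "polymorphic")
  if (any(x$mask[obs] == 0L)) stop("scored cell without states")
  if (any(x$mask[!obs] != 0L)) stop("wildcard cell with raw states")
  nstates <- matrix(vapply(x$mask, function(m) length(mask_states(m)), 1L),
                    nrow(x$mask))
  if (any(nstates[x$kind == "observed"] != 1L))
    stop("observed cell must have exactly one state")
  if (any(nstates[x$kind == "polymorphic"] < 2L))
    stop("polymorphic cell must have at least two states")
  invisible(x)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (unordered, equal weights)\n",
              n_taxa(x), n_characters(x)))
  tab <- table(factor(x$kind, levels = c("observed", "polymorphic",
                                         "missing", "inapplicable")))
  cat(sprintf("  cells: %d observed, %d polymorphic, %d missing, %d inapplicable\n",
              tab[1L], tab[2L], tab[3L], tab[4L]))
  cat("  taxa: ", paste(head(x$taxa, 4L), collapse = ", "),
      if (n_taxa(x) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
summary.char_matrix <- function(object, ...) {
  print(object)
  inf <- is_informative(object)
  cat(sprintf("  parsimony-informative characters: %d of %d\n",
              sum(inf), n_characters(object)))
  invisible(object)
}
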