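#' One-call reproduction of the reference Stoiba analysis
#'
#' Runs the full published-style analysis on the packaged *Stoiba*
#' matrix: heuristic parsimony search (random addition + branch
#' swapping), zero-minimum-length branch collapsing and topology
#' deduplication, strict consensus, ensemble fit indices under both
#' display conventions, and character support for the clades of
#' interest (the nine *Stoiba* terminals; the Cuban and Jamaican
#' subclades; the five brachypterous species) on the consensus rooted
#' on *Spaethiella* sp.
#'
#' Every number in the report is regenerable from the packaged matrix
#' and the logged seed.
#'
#' @param seed,replicates,swap,max_trees search settings (see
#'   [parsimony_search()]).
#' @param out_dir optional directory; when given, the MPTs
#'   (`mpts.nwk`), consensus (`consensus.nwk`) and the report
#'   (`report.json`) are written there.
#' @return an object of class `reproduction_report`.
#' @examples
#' \donttest{
#' rep <- reproduce_analysis(seed = 42, replicates = 20)
#' rep
#' }
#' @export
reproduce_analysis <- function(seed = 42, replicates = 100, swap = "TBR",
                               max_trees = 10000, out_dir = NULL) {
  x <- stoiba_matrix()
  fit <- parsimony_search(x, method = "heuristic", replicates = replicates,
                          swap = swap, seed = seed, max_trees = max_trees)
  cons <- strict_consensus(fit$trees)
  idx_all <- ensemble_indices(fit, x, convention = "all_characters")
  printed <- c(CI = 0.59, RI = 0.78)
  match_conv <- rownames(idx_all$both)[
    round_half_up(idx_all$both$CI) == printed["CI"] &
    round_half_up(idx_all$both$RI) == printed["RI"]]
  ci_match_conv <- rownames(idx_all$both)[
    round_half_up(idx_all$both$CI) == printed["CI"]]
  rooted <- root_on_outgroup(cons, stoiba_outgroup_root())
  clades <- stoiba_clades()
  clade_tab <- lapply(clades, function(cl) {
    present <- tryCatch({clade_support(rooted, x, cl); TRUE},
                        error = function(e) FALSE)
    list(size = length(cl), present = present,
         support = if (present) clade_support(rooted, x, cl) else NULL)
  })
  digest <- list(
    n_taxa = n_taxa(x), n_characters = n_characters(x),
    cells = as.list(table(factor(x$kind,
      levels = c("observed", "polymorphic", "missing", "inapplicable")))))
  rep <- structure(list(
    matrix_digest = digest,
    best_length = fit$best_length,
    n_mpt_collapsed = length(fit$trees),
    n_mpt_binary = length(fit$binary_trees),
    consensus = cons,
    indices = idx_all,
    matched_convention = if (length(match_conv)) match_conv else NA_character_,
    ci_matched_convention = if (length(ci_match_conv)) ci_match_conv[1L]
                            else NA_character_,
    clades = clade_tab,
    search = fit,
    log = fit$log), class = "reproduction_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

write_report <- function(rep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(rep$search$trees, file.path(out_dir, "mpts.nwk"))
  write_newick(rep$consensus, file.path(out_dir, "consensus.nwk"))
  b <- rep$indices$both
  payload <- list(
    matrix = rep$matrix_digest,
    best_length = rep$best_length,
    mpt_count = list(collapsed = rep$n_mpt_collapsed,
                     binary = rep$n_mpt_binary),
    consensus_newick = newick_string(rep$consensus),
    indices = list(
      all_characters = as.list(b["all_characters", ]),
      informative_only = as.list(b["informative_only", ]),
      matched_convention = rep$matched_convention,
      ci_matched_convention = rep$ci_matched_convention),
    clades = lapply(rep$clades, function(cl)
      list(size = cl$size, present = cl$present,
           support = if (cl$present) cl$support else NULL)),
    log = rep$log[setdiff(names(rep$log), "replicate_trees")])
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reproduction of the reference parsimony analysis\n")
  d <- x$matrix_digest
  cat(sprintf("  matrix: %d taxa x %d characters (%s)\n",
              d$n_taxa, d$n_characters,
              paste(names(d$cells), unlist(d$cells), collapse = ", ")))
  cat(sprintf("  best length: %d steps\n", x$best_length))
  cat(sprintf("  MPTs: %d collapsed / %d binary\n",
              x$n_mpt_collapsed, x$n_mpt_binary))
  b <- x$indices$both
  for (cv in rownames(b))
    cat(sprintf("  indices [%s]: CI = %.2f, RI = %.2f (L = %d)\n", cv,
                round_half_up(b[cv, "CI"]), round_half_up(b[cv, "RI"]),
                b[cv, "L"]))
  fmt <- function(v) if (all(is.na(v))) "none" else paste(v, collapse = ", ")
  cat(sprintf("  convention matching printed CI/RI pair: %s (CI alone: %s)\n",
              fmt(x$matched_convention), fmt(x$ci_matched_convention)))
  for (nm in names(x$clades)) {
    cl <- x$clades[[nm]]
    if (cl$present) {
      sup <- cl$support
      cat(sprintf("  clade %-14s (%d terminals): present; stem changes at %s\n",
                  nm, cl$size,
                  if (nrow(sup)) paste0("#", sup$character, " (", sup$from,
                                        "->", sup$to, ", ", sup$ambiguity,
                                        ")", collapse = ", ") else "none"))
    } else {
      cat(sprintf("  clade %-14s (%d terminals): NOT recovered as a clade\n",
                  nm, cl$size))
    }
  }
  invisible(x)
}

#' Read and write trees as newick
#'
#' Thin wrappers over [ape::read.tree()]/[ape::write.tree()] mapping
#' spaces in taxon labels to underscores on output and back on input.
#'
#' @param tree a `phylo` or `multiPhylo`.
#' @param file path.
#' @return `read_newick()`: a `phylo` or `multiPhylo` with underscores
#'   restored to spaces; `write_newick()`: the path, invisibly.
#' @export
write_newick <- function(tree, file) {
  writeLines(newick_string(tree), file)
  invisible(file)
}

newick_string <- function(tree) {
  fix <- function(tr) { tr$tip.label <- gsub(" ", "_", tr$tip.label); tr }
  if (inherits(tree, "multiPhylo") || (is.list(tree) && !inherits(tree, "phylo")))
    vapply(tree, function(tr) ape::write.tree(fix(tr)), "")
  else ape::write.tree(fix(tree))
}

#' @rdname write_newick
#' @export
read_newick <- function(file) {
  tr <- ape::read.tree(file)
  fix <- function(t) { t$tip.label <- gsub("_", " ", t$tip.label); t }
  if (inherits(tr, "multiPhylo")) {
    out <- lapply(tr, fix); class(out) <- "multiPhylo"; out
  } else fix(tr)
}
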