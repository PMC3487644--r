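#' The packaged Stoiba morphology matrix
#'
#' Loads the 20-taxon, 38-character adult-morphology matrix for the
#' tortoise-beetle genus *Stoiba* and its outgroups (Mesomphaliini,
#' Ischyrosonychini, Hemisphaerotini), transcribed cell-for-cell from
#' the published character table.  Characters are indexed 0-37 and are
#' unordered with equal weights.  The grid contains one polymorphic
#' cell (*Stoiba flavicollis*, hind-wing character 29, states 0 and 1),
#' four missing (`?`) and four inapplicable (`N`) cells.
#'
#' The packaged transcription is integrity-checked against a content
#' hash recorded at packaging time; a mismatch indicates a corrupted
#' installation.
#'
#' @return a validated [char_matrix] with character descriptions
#'   attached.
#' @examples
#' m <- stoiba_matrix()
#' m
#' matrix_cell(m, "Stoiba flavicollis", 29)
#' @export
stoiba_matrix <- function() {
  mat_file <- system.file("extdata", "stoiba_matrix.tsv",
                          package = "mpmorph", mustWork = TRUE)
  chr_file <- system.file("extdata", "stoiba_characters.tsv",
                          package = "mpmorph", mustWork = TRUE)
  sums <- unname(tools::md5sum(c(mat_file, chr_file)))
  expect <- c("2ffb6bddc5af9822e0bf3b34eba02971",
              "84531861da25b3b39a200b154d85d501")
  if (!identical(sums, expect))
    stop("packaged Stoiba matrix failed its integrity check; ",
         "reinstall the package")
  desc <- read.delim(chr_file, stringsAsFactors = FALSE)
  m <- parse_matrix(readLines(mat_file, warn = FALSE), "tsv",
                    descriptions = desc$description)
  stopifnot(n_taxa(m) == 20L, n_characters(m) == 38L)
  m
}

# Taxon-set shorthands for the reference analysis.
stoiba_ingroup <- function() {
  c("Stoiba angusticollis", "Stoiba bruneri", "Stoiba fascicollis",
    "Stoiba flavicollis", "Stoiba fuscicornis", "Stoiba indivisa",
    "Stoiba marginata", "Stoiba nigricans", "Stoiba swartzii")
}

stoiba_clades <- function() {
  ing <- stoiba_ingroup()
  jam <- c("Stoiba fuscicornis", "Stoiba swartzii")
  list(stoiba = ing,
       cuban = setdiff(ing, jam),
       jamaican = jam,
       brachypterous = c("Stoiba angusticollis", "Stoiba bruneri",
                         "Stoiba flavicollis", "Stoiba marginata",
                         "Stoiba nigricans"))
}

#' @rdname stoiba_matrix
#' @details `stoiba_outgroup_root()` names the taxon used to root trees
#'   for character-polarity reports: *Spaethiella* sp., the most distant
#'   outgroup sampled.
#' @export
stoiba_outgroup_root <- function() "Spaethiella sp."
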