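#' Read and write character matrices
#'
#' `parse_matrix()` reads a [char_matrix] from text in one of three
#' dialects; `write_matrix()` emits it.  The cell grid round-trips
#' exactly through every dialect (states, and the
#' missing-vs-inapplicable distinction, are preserved).
#'
#' Dialects:
#' * `"tsv"` -- one line per taxon: label, then one token per character,
#'   tab-separated, no header.  Tokens: digits, `a&b`, `$` (= `0&1`),
#'   `?`, `N` or `-`.
#' * `"nexus"` -- a `DATA`/`CHARACTERS` block with
#'   `FORMAT SYMBOLS="..." MISSING=? GAP=-;`; polymorphisms as `(01)`;
#'   the gap symbol encodes inapplicable cells.  Labels with spaces are
#'   single-quoted.
#' * `"tnt"` -- an `xread` block; polymorphisms as `[01]`; `?` missing,
#'   `-` inapplicable; spaces in labels become underscores.
#'
#' @param text character scalar (or vector of lines) to parse.
#' @param dialect one of `"tsv"`, `"nexus"`, `"tnt"`.
#' @param descriptions optional character descriptions passed to the
#'   constructed matrix.
#' @return `parse_matrix()`: a validated [char_matrix].
#'   `write_matrix()`: a character scalar of formatted text.
#' @examples
#' m <- parse_matrix("A\t0\t1\nB\t0\t$\nC\t1\t?", "tsv")
#' cat(write_matrix(m, "nexus"))
#' @export
parse_matrix <- function(text, dialect = c("tsv", "nexus", "tnt"),
                         descriptions = NULL) {
  dialect <- match.arg(tolower(dialect), c("tsv", "nexus", "tnt"))
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rows <- switch(dialect,
                 tsv = parse_tsv(lines),
                 nexus = parse_nexus(lines),
                 tnt = parse_tnt(lines))
  nch <- unique(lengths(rows$tokens))
  if (length(nch) != 1L) {
    bad <- rows$taxa[lengths(rows$tokens) != max(lengths(rows$tokens))][1L]
    stop(sprintf("ragged matrix: taxon '%s' has %d cells where %d are expected",
                 bad, length(rows$tokens[[match(bad, rows$taxa)]]), max(lengths(rows$tokens))))
  }
  if (!is.null(rows$nchar) && nch != rows$nchar)
    stop(sprintf("matrix declares %d characters but rows have %d",
                 rows$nchar, nch))
  tok <- do.call(rbind, rows$tokens)
  rownames(tok) <- rows$taxa
  m <- char_matrix(tok, descriptions = descriptions)
  validate_char_matrix(m)
}

#' Read a character matrix from a file
#' @param file path to the matrix file.
#' @inheritParams parse_matrix
#' @return a validated [char_matrix].
#' @export
read_char_matrix <- function(file, dialect = c("tsv", "nexus", "tnt")) {
  parse_matrix(readLines(file, warn = FALSE), dialect)
}

#' @rdname parse_matrix
#' @param x a [char_matrix].
#' @export
write_matrix <- function(x, dialect = c("tsv", "nexus", "tnt")) {
  dialect <- match.arg(tolower(dialect), c("tsv", "nexus", "tnt"))
  validate_char_matrix(x)
  states <- sort(unique(unlist(x$characters$observed_states)))
  if (dialect != "tsv" && any(states > 9L))
    stop("states above 9 cannot be written in the ", dialect, " alphabet")
  switch(dialect,
         tsv = write_tsv(x),
         nexus = write_nexus(x, states),
         tnt = write_tnt(x))
}

#' Write a character matrix to a file
#' @inheritParams write_matrix
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_char_matrix <- function(x, file, dialect = c("tsv", "nexus", "tnt")) {
  writeLines(write_matrix(x, dialect), file)
  invisible(file)
}

# --- tsv ------------------------------------------------------------

parse_tsv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix text")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  taxa <- vapply(parts, function(p) trimws(p[1L]), "")
  tokens <- lapply(parts, function(p) trimws(p[-1L]))
  list(taxa = taxa, tokens = tokens, nchar = NULL)
}

write_tsv <- function(x) {
  tok <- cell_tokens(x, poly = function(s) paste(s, collapse = "&"),
                     missing = "?", inapp = "N")
  paste(vapply(seq_along(x$taxa), function(i)
    paste(c(x$taxa[i], tok[i, ]), collapse = "\t"), ""), collapse = "\n")
}

# --- shared cell formatting -----------------------------------------

cell_tokens <- function(x, poly, missing, inapp) {
  out <- matrix("", n_taxa(x), n_characters(x))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    out[i, j] <- switch(x$kind[i, j],
                        observed = as.character(mask_states(x$mask[i, j])),
                        polymorphic = poly(mask_states(x$mask[i, j])),
                        missing = missing,
                        inapplicable = inapp)
  }
  out
}

# --- sequence-style tokenizer (nexus/tnt row text) ------------------

tokenize_row <- function(s, open, close, taxon) {
  s <- gsub(" ", "", s)
  toks <- character(0)
  i <- 1L
  chars <- strsplit(s, "")[[1L]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == open) {
      j <- i + 1L
      grp <- character(0)
      while (j <= length(chars) && chars[j] != close) {
        grp <- c(grp, chars[j]); j <- j + 1L
      }
      if (j > length(chars))
        stop(sprintf("unterminated polymorphism token in row for '%s'", taxon))
      toks <- c(toks, paste(grp, collapse = "&"))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

# --- nexus ----------------------------------------------------------

parse_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # bracket comments
  up <- toupper(txt)
  if (!grepl("#NEXUS", up, fixed = TRUE)) stop("not a NEXUS file")
  mstart <- regexpr("MATRIX", up)
  if (mstart < 0) stop("no MATRIX statement found")
  head_txt <- substr(up, 1L, mstart)
  nchar_decl <- NULL
  mm <- regmatches(head_txt, regexpr("NCHAR\\s*=\\s*[0-9]+", head_txt))
  if (length(mm)) nchar_decl <- as.integer(sub(".*=\\s*", "", mm))
  body <- substr(txt, mstart + attr(mstart, "match.length"), nchar(txt))
  body <- sub(";.*$", "", body)
  rows <- strsplit(body, "\n")[[1L]]
  rows <- rows[nzchar(trimws(rows))]
  taxa <- character(0); tokens <- list()
  for (r in rows) {
    r <- trimws(r)
    if (startsWith(r, "'")) {
      close <- regexpr("'", substring(r, 2L), fixed = TRUE)
      if (close < 0) stop("unterminated quoted taxon label: ", r)
      taxon <- substr(r, 2L, close)
      rest <- trimws(substring(r, close + 2L))
    } else {
      sp <- regexpr("[ \t]", r)
      if (sp < 0) stop("matrix row without states: ", r)
      taxon <- substr(r, 1L, sp - 1L)
      rest <- trimws(substring(r, sp + 1L))
    }
    taxa <- c(taxa, taxon)
    tokens <- c(tokens, list(nexus_tokens(rest, taxon)))
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon: ", taxa[duplicated(taxa)][1L])
  list(taxa = taxa, tokens = tokens, nchar = nchar_decl)
}

nexus_tokens <- function(s, taxon) {
  toks <- tokenize_row(s, "(", ")", taxon)
  vapply(toks, function(t) {
    if (t == "-") "N" else t
  }, "", USE.NAMES = FALSE)
}

write_nexus <- function(x, states) {
  sym <- paste(states, collapse = "")
  tok <- cell_tokens(x, poly = function(s) paste0("(", paste(s, collapse = ""), ")"),
                     missing = "?", inapp = "-")
  labels <- ifelse(grepl("[^A-Za-z0-9_.]", x$taxa), paste0("'", x$taxa, "'"),
                   x$taxa)
  width <- max(nchar(labels)) + 2L
  rows <- vapply(seq_along(labels), function(i)
    paste0(formatC(labels[i], width = -width), paste(tok[i, ], collapse = "")), "")
  paste(c("#NEXUS", "BEGIN DATA;",
          sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(x), n_characters(x)),
          sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=? GAP=-;", sym),
          "  MATRIX", rows, "  ;", "END;"), collapse = "\n")
}

# --- tnt ------------------------------------------------------------

parse_tnt <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  up <- toupper(txt)
  xr <- regexpr("XREAD", up)
  if (xr < 0) stop("not a TNT xread file")
  body <- substring(txt, xr + 5L)
  # optional quoted title
  body <- sub("^\\s*'[^']*'", "", body)
  m <- regexpr("^\\s*([0-9]+)\\s+([0-9]+)", body)
  if (m < 0) stop("xread without nchar/ntax declaration")
  decl <- regmatches(body, m)
  nums <- as.integer(strsplit(trimws(decl), "\\s+")[[1L]])
  nchar_decl <- nums[1L]; ntax <- nums[2L]
  body <- substring(body, m + attr(m, "match.length"))
  body <- sub(";.*$", "", body)
  rows <- strsplit(body, "\n")[[1L]]
  rows <- rows[nzchar(trimws(rows))]
  taxa <- character(0); tokens <- list()
  for (r in rows) {
    r <- trimws(r)
    sp <- regexpr("[ \t]", r)
    if (sp < 0) stop("matrix row without states: ", r)
    taxon <- substr(r, 1L, sp - 1L)
    rest <- trimws(substring(r, sp + 1L))
    taxa <- c(taxa, taxon)
    toks <- tokenize_row(rest, "[", "]", taxon)
    toks[toks == "-"] <- "N"
    tokens <- c(tokens, list(toks))
  }
  if (length(taxa) != ntax)
    stop(sprintf("xread declares %d taxa but %d rows found", ntax, length(taxa)))
  if (anyDuplicated(taxa)) stop("duplicate taxon: ", taxa[duplicated(taxa)][1L])
  list(taxa = taxa, tokens = tokens, nchar = nchar_decl)
}

write_tnt <- function(x) {
  tok <- cell_tokens(x, poly = function(s) paste0("[", paste(s, collapse = ""), "]"),
                     missing = "?", inapp = "-")
  labels <- gsub(" ", "_", x$taxa)
  width <- max(nchar(labels)) + 2L
  rows <- vapply(seq_along(labels), function(i)
    paste0(formatC(labels[i], width = -width), paste(tok[i, ], collapse = "")), "")
  paste(c(sprintf("xread 'morphological matrix' %d %d",
                  n_characters(x), n_taxa(x)),
          rows, ";"), collapse = "\n")
}
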