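## NEXUS / Newick / FASTA input-output.
##
## The morphological matrices this package targets come as NEXUS
## CHARACTERS/DATA blocks (interleaved or not, quoted labels, SYMBOLS /
## MISSING / GAP declarations, CHARSET partitions).  ape::read.nexus.data()
## covers only a subset of that dialect and silently drops the metadata we
## need (gap symbol, charsets), so matrix parsing is done here; trees go
## through ape.

read_source_text <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
}

# Remove NEXUS [comments] (possibly nested), preserving newlines.
strip_nexus_comments <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  keep <- logical(length(chars))
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    keep[i] <- depth == 0L
    if (chars[i] == "]" && depth > 0L) depth <- depth - 1L
  }
  paste(chars[keep], collapse = "")
}

# Tokenize respecting single-quoted labels.
nexus_tokens <- function(text) {
  m <- gregexpr("'[^']*'|[^ \t\r\n]+", text)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(text, list(m))[[1]]
}

#' Read a NEXUS character matrix
#'
#' Parses a CHARACTERS or DATA block (interleaved and non-interleaved
#' dialects both accepted).  The gap symbol is mapped to the missing symbol,
#' polymorphic/ambiguous cells written as `{..}` or `(..)` are read as
#' missing, and `CHARSET` definitions (in SETS or ASSUMPTIONS blocks) become
#' the partition scheme.
#'
#' @param source path to a NEXUS file, or NEXUS text.
#' @param partitions optional named list of character ranges overriding any
#'   CHARSETs in the file.
#' @return a [character_matrix()].
#' @export
read_character_matrix <- function(source, partitions = NULL) {
  text <- strip_nexus_comments(read_source_text(source))
  if (!grepl("#NEXUS", text, ignore.case = TRUE))
    stop_glasstree("not a NEXUS file (missing #NEXUS header)")
  blk <- regmatches(text, regexpr(
    "(?is)begin\\s+(characters|data)\\s*;.*?end\\s*;", text, perl = TRUE))
  if (length(blk) == 0) stop_glasstree("no CHARACTERS or DATA block found")
  blk <- blk[[1]]

  grab <- function(pat) {
    m <- regmatches(blk, regexpr(pat, blk, perl = TRUE))
    if (length(m) == 0) NA_character_ else sub(pat, "\\1", m, perl = TRUE)
  }
  ntax  <- as.integer(grab("(?is)ntax\\s*=\\s*(\\d+)"))
  nchar <- as.integer(grab("(?is)nchar\\s*=\\s*(\\d+)"))
  if (is.na(ntax) || is.na(nchar))
    stop_glasstree("DIMENSIONS with NTAX and NCHAR required")
  miss_sym <- tolower(grab("(?is)missing\\s*=\\s*(\\S)"))
  gap_sym  <- tolower(grab("(?is)gap\\s*=\\s*(\\S)"))
  symbols  <- grab("(?is)symbols\\s*=\\s*\"([^\"]*)\"")
  interleave <- grepl("(?is)interleave(\\s*=\\s*yes)?[\\s;=]", blk, perl = TRUE) &&
    !grepl("(?is)interleave\\s*=\\s*no", blk, perl = TRUE)
  if (is.na(miss_sym)) miss_sym <- "?"

  body <- regmatches(blk, regexpr("(?is)matrix\\s(.*?);", blk, perl = TRUE))
  if (length(body) == 0) stop_glasstree("no MATRIX command found")
  body <- sub("(?is)^matrix\\s", "", body, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  # collapse polymorphic / ambiguous cells to a single missing symbol
  body <- gsub("\\{[^}]*\\}|\\([^)]*\\)", miss_sym, body)

  rows <- list()
  add_chunk <- function(label, chunk) {
    label <- normalize_label(label)
    rows[[label]] <<- c(rows[[label]], strsplit(chunk, "")[[1]])
  }
  if (interleave) {
    for (line in strsplit(body, "\n")[[1]]) {
      toks <- nexus_tokens(line)
      if (length(toks) == 0) next
      add_chunk(toks[1], paste(toks[-1], collapse = ""))
    }
  } else {
    toks <- nexus_tokens(body)
    i <- 1L
    while (i <= length(toks)) {
      label <- toks[i]; i <- i + 1L
      got <- 0L
      while (got < nchar) {
        if (i > length(toks))
          stop_glasstree("ragged row: taxon '", normalize_label(label),
                         "' has ", got, " of ", nchar, " characters")
        add_chunk(label, toks[i])
        got <- got + nchar(toks[i]); i <- i + 1L
      }
    }
  }
  if (length(rows) != ntax)
    stop_glasstree("expected NTAX=", ntax, " taxa, found ", length(rows),
                   " (duplicate or missing labels?)")
  lens <- lengths(rows)
  if (any(lens != nchar))
    stop_glasstree("ragged row: taxon '", names(rows)[lens != nchar][1],
                   "' has ", lens[lens != nchar][1],
                   " characters, expected ", nchar)
  cells <- do.call(rbind, rows)
  cells <- matrix(tolower(cells), nrow = ntax,
                  dimnames = list(names(rows), NULL))
  if (!is.na(gap_sym)) cells[cells == gap_sym] <- miss_sym
  cells[cells == "-"] <- miss_sym
  if (!is.na(symbols)) {
    ok <- c(tolower(strsplit(gsub("\\s", "", symbols), "")[[1]]), miss_sym)
    bad <- !(cells %in% ok)
    if (any(bad)) {
      i <- which(bad)[1]
      stop_glasstree(sprintf(
        "undeclared symbol '%s' at taxon '%s', character %d",
        cells[i], rownames(cells)[(i - 1) %% ntax + 1],
        (i - 1) %/% ntax + 1))
    }
  }
  if (is.null(partitions)) partitions <- parse_charsets(text, nchar)
  character_matrix(cells, partitions = partitions, missing = miss_sym)
}

# CHARSET name = 1-29 31 40-45; (step modifiers like \3 not supported)
parse_charsets <- function(text, nchar_total) {
  m <- gregexpr("(?is)charset\\s+(\\S+)\\s*=\\s*([^;]*);", text, perl = TRUE)
  hits <- regmatches(text, m)[[1]]
  if (length(hits) == 0) return(NULL)
  parts <- list()
  for (h in hits) {
    name <- sub("(?is)charset\\s+(\\S+)\\s*=.*", "\\1", h, perl = TRUE)
    spec <- sub("(?is)charset\\s+\\S+\\s*=\\s*([^;]*);", "\\1", h, perl = TRUE)
    idx <- integer(0)
    for (piece in nexus_tokens(spec)) {
      if (grepl("^\\d+-\\d+$", piece)) {
        ab <- as.integer(strsplit(piece, "-")[[1]])
        idx <- c(idx, ab[1]:ab[2])
      } else if (grepl("^\\d+$", piece)) {
        idx <- c(idx, as.integer(piece))
      } else if (piece == ".") {
        idx <- c(idx, nchar_total)
      } else {
        stop_glasstree("unsupported CHARSET element '", piece, "'")
      }
    }
    parts[[name]] <- idx
  }
  # only usable as a partition scheme if disjoint and covering
  ok <- tryCatch({ validate_partitions(parts, nchar_total); TRUE },
                 error = function(e) FALSE)
  if (ok) parts else NULL
}

#' Write a character matrix as NEXUS
#'
#' @param x a [character_matrix()].
#' @param file optional path; if `NULL` the NEXUS text is returned.
#' @return invisibly, the NEXUS text.
#' @export
write_character_matrix <- function(x, file = NULL) {
  syms <- sort(unique(setdiff(as.vector(unclass(x)), missing_symbol(x))))
  labels <- sprintf("'%s'", rownames(x))
  pad <- formatC(labels, width = max(nchar(labels)) + 2, flag = "-")
  rows <- paste0("    ", pad, apply(unclass(x), 1, paste, collapse = ""))
  parts <- partitions_of(x)
  charsets <- vapply(names(parts), function(p) {
    idx <- parts[[p]]
    sprintf("  charset %s = %s;", p, format_ranges(idx))
  }, character(1))
  txt <- c("#NEXUS",
           "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x), ncol(x)),
           sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=%s GAP=-;",
                   paste(syms, collapse = ""), missing_symbol(x)),
           "  MATRIX", rows, "  ;", "END;",
           "BEGIN SETS;", charsets, "END;")
  txt <- paste(txt, collapse = "\n")
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

format_ranges <- function(idx) {
  idx <- sort(idx)
  breaks <- c(0, which(diff(idx) != 1), length(idx))
  out <- character(0)
  for (i in seq_len(length(breaks) - 1)) {
    a <- idx[breaks[i] + 1]; b <- idx[breaks[i + 1]]
    out <- c(out, if (a == b) as.character(a) else paste0(a, "-", b))
  }
  paste(out, collapse = " ")
}

#' Read a phylogenetic tree
#'
#' Accepts Newick text, a Newick file, or a NEXUS TREES block (via
#' [ape::read.nexus()]).  Exactly one tree per call.
#'
#' @param source tree text or file path.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(source) {
  text <- read_source_text(source)
  phy <- tryCatch({
    if (grepl("#NEXUS", text, ignore.case = TRUE)) {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf), add = TRUE)
      writeLines(text, tf)
      ape::read.nexus(tf)
    } else {
      ape::read.tree(text = text)
    }
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop_glasstree("tree parse error (unbalanced parentheses?)")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1) stop_glasstree("expected a single tree, found ",
                                         length(phy))
    phy <- phy[[1]]
  }
  if (is.null(phy) || is.null(phy$tip.label))
    stop_glasstree("tree parse error")
  phy$tip.label <- normalize_label(phy$tip.label)
  if (anyDuplicated(phy$tip.label))
    stop_glasstree("duplicate leaf label: ",
                   phy$tip.label[duplicated(phy$tip.label)][1])
  phy
}

#' Write a tree as Newick
#'
#' @param phy an [ape::phylo] object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @return invisibly, the Newick string.
#' @export
write_tree <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}

#' Read a FASTA alignment
#'
#' @param source path to a FASTA file, or FASTA text.
#' @param partitions optional named list of site ranges.
#' @return an [nt_alignment()].
#' @export
read_alignment <- function(source, partitions = NULL) {
  text <- read_source_text(source)
  lines <- strsplit(text, "\n")[[1]]
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop_glasstree("not FASTA: no '>' headers found")
  id <- cumsum(hdr)
  labels <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(seq_along(labels), function(i)
    paste(lines[!hdr & id == i], collapse = ""), character(1))
  names(seqs) <- labels
  nt_alignment(seqs, partitions = partitions)
}
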