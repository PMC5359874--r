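#' Discrete character matrix
#'
#' The central data container of the package: a taxa-by-characters grid of
#' single-symbol states (e.g. `"0"`/`"1"` for presence/absence morphology, or
#' `"0"`--`"3"` for parsimony-recoded nucleotides), together with a reserved
#' missing-data symbol and a named partition scheme.  Both the NEXUS missing
#' (`?`) and gap (`-`) symbols are mapped to the single internal missing
#' symbol, because downstream parsimony and likelihood computations treat
#' gaps as missing data.
#'
#' @param cells character matrix of single-symbol states; rownames are taxon
#'   labels.
#' @param partitions named list of integer vectors giving contiguous,
#'   disjoint character ranges that together cover all columns.  Default: one
#'   partition named `"all"`.
#' @param missing single reserved missing symbol (default `"?"`).
#' @param character_labels optional per-character names.
#' @return an object of class `char_matrix`.
#' @export
character_matrix <- function(cells, partitions = NULL, missing = "?",
                             character_labels = NULL) {
  if (!is.matrix(cells)) cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  cells[] <- tolower(cells)
  if (is.null(rownames(cells)))
    stop_glasstree("taxon labels (rownames) are required")
  rownames(cells) <- normalize_label(rownames(cells))
  if (anyDuplicated(rownames(cells)))
    stop_glasstree("duplicate taxon label: ",
                   rownames(cells)[duplicated(rownames(cells))][1])
  if (nchar(missing) != 1L) stop_glasstree("missing symbol must be one character")
  if (is.null(partitions)) {
    partitions <- list(all = seq_len(ncol(cells)))
  }
  partitions <- lapply(partitions, as.integer)
  validate_partitions(partitions, ncol(cells))
  if (!is.null(character_labels)) {
    stopifnot(length(character_labels) == ncol(cells))
    colnames(cells) <- character_labels
  }
  structure(cells,
            missing = missing,
            partitions = partitions,
            class = c("char_matrix", "matrix", "array"))
}

validate_partitions <- function(partitions, nchar_total) {
  if (is.null(names(partitions)) || any(names(partitions) == ""))
    stop_glasstree("partitions must be named")
  idx <- unlist(partitions, use.names = FALSE)
  if (anyDuplicated(idx))
    stop_glasstree("partition ranges overlap")
  if (!setequal(idx, seq_len(nchar_total)))
    stop_glasstree("partition ranges must cover all characters")
  invisible(TRUE)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("<char_matrix> %d taxa x %d characters; missing='%s'\n",
              nrow(x), ncol(x), missing_symbol(x)))
  cat("partitions:",
      paste(sprintf("%s(%d)", names(partitions_of(x)),
                    lengths(partitions_of(x))), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname character_matrix
#' @param x a `char_matrix`.
#' @export
missing_symbol <- function(x) attr(x, "missing")

#' @rdname character_matrix
#' @export
partitions_of <- function(x) attr(x, "partitions")

#' Per-character state alphabets
#'
#' Ordered observed (non-missing) symbols of each character.
#'
#' @param x a `char_matrix`.
#' @return list of character vectors, one per column.
#' @export
state_alphabet <- function(x) {
  miss <- missing_symbol(x)
  lapply(seq_len(ncol(x)), function(j) {
    s <- sort(unique(x[, j]))
    s[s != miss]
  })
}

#' Summarize a character matrix
#'
#' Reports dimensions, the number of distinct alignment patterns (unique
#' full-height columns, compared after case-folding, counted within each
#' partition and summed), and the missing-data fraction.  Ambiguity codes in
#' raw molecular data count as their own symbols for pattern identity.
#' Because published missing-data percentages do not always state whether
#' ambiguity codes were counted as missing, the fraction is reported under
#' both conventions.
#'
#' @param x a `char_matrix` or `nt_alignment`.
#' @return a `matrix_summary` list: `n_taxa`, `n_characters`,
#'   `distinct_patterns` (named per-partition vector), `distinct_patterns_total`,
#'   `missing_fraction`, and `missing_fraction_with_ambiguities` (identical to
#'   `missing_fraction` for non-nucleotide data).
#' @export
summarize_matrix <- function(x) {
  miss <- missing_symbol(x) %||% "?"
  parts <- partitions_of(x) %||% list(all = seq_len(ncol(x)))
  m <- unclass(x)
  m[] <- tolower(m)
  per_part <- vapply(parts, function(idx) {
    cols <- apply(m[, idx, drop = FALSE], 2, paste, collapse = "\r")
    length(unique(cols))
  }, integer(1))
  is_missing <- m == miss | m == "-"
  ambig <- m %in% c("r", "y", "s", "w", "k", "m", "b", "d", "h", "v", "n", "x")
  out <- list(
    n_taxa = nrow(m),
    n_characters = ncol(m),
    distinct_patterns = per_part,
    distinct_patterns_total = sum(per_part),
    missing_fraction = mean(is_missing),
    missing_fraction_with_ambiguities = mean(is_missing | ambig)
  )
  class(out) <- "matrix_summary"
  out
}

#' @export
print.matrix_summary <- function(x, ...) {
  cat(sprintf("%d taxa, %d characters, %d distinct patterns, %.1f%% missing\n",
              x$n_taxa, x$n_characters, x$distinct_patterns_total,
              100 * x$missing_fraction))
  invisible(x)
}

#' Concatenate character matrices
#'
#' Joins blocks column-wise into a supermatrix.  Partitions are named per
#' source block.  Under the `"union"` policy, taxa absent from a block are
#' filled with the missing symbol for that block's characters; under
#' `"intersection"` only shared taxa are kept.
#'
#' @param blocks list of `char_matrix` objects (names become partition
#'   prefixes; unnamed blocks are called `block1`, `block2`, ...).
#' @param policy `"union"` (fill missing) or `"intersection"`.
#' @return a `char_matrix`.
#' @export
concatenate_matrices <- function(blocks, policy = c("union", "intersection")) {
  policy <- match.arg(policy)
  stopifnot(length(blocks) >= 1)
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    names(blocks) <- paste0("block", seq_along(blocks))
  taxa_sets <- lapply(blocks, rownames)
  taxa <- if (policy == "union") Reduce(union, taxa_sets)
          else Reduce(intersect, taxa_sets)
  if (length(taxa) == 0) stop_glasstree("no taxa shared between blocks")
  miss <- missing_symbol(blocks[[1]])
  widths <- vapply(blocks, ncol, integer(1))
  out <- matrix(miss, length(taxa), sum(widths), dimnames = list(taxa, NULL))
  parts <- list()
  at <- 0L
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    cols <- at + seq_len(ncol(blk))
    shared <- intersect(taxa, rownames(blk))
    sub <- unclass(blk)[shared, , drop = FALSE]
    sub[sub == missing_symbol(blk)] <- miss # normalize missing symbols
    out[shared, cols] <- sub
    sub_parts <- partitions_of(blk)
    if (length(sub_parts) == 1L) {
      parts[[names(blocks)[b]]] <- cols
    } else {
      for (p in names(sub_parts))
        parts[[paste(names(blocks)[b], p, sep = ".")]] <- at + sub_parts[[p]]
    }
    at <- at + ncol(blk)
  }
  labels <- unlist(lapply(blocks, function(b) colnames(b) %||% rep(NA, ncol(b))),
                   use.names = FALSE)
  if (all(is.na(labels))) labels <- NULL
  character_matrix(out, partitions = parts, missing = miss,
                   character_labels = labels)
}

#' Nucleotide alignment
#'
#' A light container for an aligned set of equal-length nucleotide
#' sequences over the IUPAC alphabet plus gap.
#'
#' @param sequences named character vector of equal-length strings, or a
#'   taxa-by-sites character matrix of single symbols.
#' @param partitions optional named list of site ranges.
#' @return an object of class `nt_alignment` (a character matrix).
#' @export
nt_alignment <- function(sequences, partitions = NULL) {
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences))) stop_glasstree("sequences must be named")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1)
      stop_glasstree("sequences have unequal lengths")
    m <- if (lens[1] == 0) {
      matrix(character(0), length(sequences), 0)
    } else {
      do.call(rbind, strsplit(tolower(sequences), ""))
    }
    rownames(m) <- names(sequences)
  }
  storage.mode(m) <- "character"
  m[] <- tolower(m)
  rownames(m) <- normalize_label(rownames(m))
  if (anyDuplicated(rownames(m)))
    stop_glasstree("duplicate taxon label: ",
                   rownames(m)[duplicated(rownames(m))][1])
  if (is.null(partitions)) partitions <- list(all = seq_len(ncol(m)))
  partitions <- lapply(partitions, as.integer)
  if (ncol(m) > 0) validate_partitions(partitions, ncol(m))
  structure(m, partitions = partitions, missing = "?",
            class = c("nt_alignment", "matrix", "array"))
}

#' @export
print.nt_alignment <- function(x, ...) {
  cat(sprintf("<nt_alignment> %d taxa x %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

IUPAC_AMBIGUITY <- c("r", "y", "s", "w", "k", "m", "b", "d", "h", "v", "n", "x")

#' Recode a nucleotide alignment for parsimony
#'
#' Recodes sequence data so mixed-type parsimony programs can analyze it
#' alongside morphology: A is replaced with 0, C with 1, G with 2 and T
#' (or U) with 3; every IUPAC ambiguity code (N, R, Y, ...) and all gaps are
#' recoded as missing, since gaps are treated as missing data in the
#' parsimony analyses.
#'
#' @param alignment an `nt_alignment` (or character matrix of nucleotide
#'   symbols).
#' @return a `char_matrix` over the alphabet `0123`, preserving partitions.
#' @export
recode_nucleotides <- function(alignment) {
  m <- tolower(unclass(alignment))
  if (ncol(m) == 0) {
    out <- matrix(character(0), nrow(m), 0, dimnames = dimnames(m))
    return(structure(out, missing = "?", partitions = list(),
                     class = c("char_matrix", "matrix", "array")))
  }
  map <- c(a = "0", c = "1", g = "2", t = "3", u = "3",
           "-" = "?", "?" = "?", "." = "?",
           setNames(rep("?", length(IUPAC_AMBIGUITY)), IUPAC_AMBIGUITY))
  bad <- !(m %in% names(map))
  if (any(bad)) {
    i <- which(bad)[1]
    stop_glasstree(sprintf(
      "non-IUPAC symbol '%s' at taxon '%s', site %d",
      m[i], rownames(m)[(i - 1) %% nrow(m) + 1], (i - 1) %/% nrow(m) + 1))
  }
  out <- matrix(map[m], nrow(m), ncol(m), dimnames = dimnames(m))
  character_matrix(out, partitions = partitions_of(alignment), missing = "?")
}
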