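## Morphology-based phylogenetic placement ("binning"): attach taxa that
## lack sequence data onto a molecular reference tree, scoring every
## candidate edge by weighted parsimony.  Characters are weighted by how
## well they fit the reference tree (their retention index), which
## down-weights characters incongruent with the molecular backbone.

#' Calibrate per-character placement weights
#'
#' The weight of character c is its retention index on the reference tree,
#' computed over the taxa shared between tree and matrix: RI = (g - s) /
#' (g - m).  Characters with no room for homoplasy on the reference
#' (g = m, e.g. constant or singleton characters) cannot be incongruent
#' with it and keep full weight 1 -- this is what makes clean-data
#' leave-one-out placement exact, since a query's cherry-defining
#' characters are singletons on the pruned reference.  Characters entirely
#' missing on the reference get weight 0.
#'
#' @param reference_tree phylo whose leaves are a subset of the matrix taxa.
#' @param morphology a [character_matrix()].
#' @return numeric vector of weights in `[0, 1]`, one per character.
#' @export
calibrate_weights <- function(reference_tree, morphology) {
  shared <- intersect(reference_tree$tip.label, rownames(morphology))
  if (length(shared) == 0)
    stop_glasstree("no taxa shared between reference tree and matrix")
  res <- fitch_length(reference_tree, morphology)
  per <- res$per_character
  w <- numeric(nrow(per))
  ok <- per$max_steps > per$min_steps
  w[ok] <- (per$max_steps[ok] - per$steps[ok]) /
    (per$max_steps[ok] - per$min_steps[ok])
  # no room for homoplasy => perfectly congruent (unless entirely missing)
  miss <- missing_symbol(morphology)
  scored <- colSums(unclass(morphology)[shared, , drop = FALSE] != miss) > 0
  w[!ok & scored] <- 1
  if (all(w == 0))
    warning("all placement weights are zero")
  pmax(w, 0)
}

#' Place one query taxon on a reference tree
#'
#' The query is attached in turn to every edge of the reference tree and
#' each attachment is scored by the weighted parsimony length
#' sum_c w_c * s_c.  Edges are ranked ascending; ties are broken by edge
#' index (ape edge-matrix order) and flagged.  On a rooted binary
#' reference the second root-child edge duplicates the first as an
#' unrooted attachment point and is excluded from the ranking.
#'
#' @param reference_tree phylo.
#' @param weights per-character weights (see [calibrate_weights()]).
#' @param morphology a [character_matrix()] scoring reference taxa and the
#'   query.
#' @param query_taxon taxon label present in `morphology` but not in the
#'   tree.
#' @return a `placement_result`: `query`, `ranking` (data.frame edge,
#'   score), `best_edge`, `tie`.
#' @export
place_query <- function(reference_tree, weights, morphology, query_taxon) {
  query_taxon <- normalize_label(query_taxon)
  if (!query_taxon %in% rownames(morphology))
    stop_glasstree("query '", query_taxon, "' absent from matrix")
  if (query_taxon %in% reference_tree$tip.label)
    stop_glasstree("query '", query_taxon, "' already in the reference tree")
  miss <- missing_symbol(morphology)
  scored <- sum(morphology[query_taxon, ] != miss & weights > 0)
  if (all(morphology[query_taxon, ] == miss))
    stop_glasstree("query '", query_taxon, "' has no scored characters")
  if (scored == 0)
    warning("query '", query_taxon,
            "' has no scored character with positive weight")
  keep <- c(reference_tree$tip.label, query_taxon)
  sub <- character_matrix(unclass(morphology)[keep, , drop = FALSE],
                          missing = miss)
  enc <- encode_parsimony(sub)
  w_pat <- vapply(seq_len(enc$n_patterns), function(k)
    sum(weights[enc$pattern_of == k]), numeric(1))
  n_edge <- nrow(reference_tree$edge)
  rows <- match(reference_tree$tip.label, colnames(enc$masks))
  scores <- as.numeric(.fitch_addition_scores_cpp(
    reference_tree$edge, length(reference_tree$tip.label), enc$masks, rows,
    match(query_taxon, colnames(enc$masks)), w_pat, enc$n_states))
  # on a rooted binary reference the two root-child edges describe the
  # same unrooted attachment; the second is redundant and excluded
  root <- length(reference_tree$tip.label) + 1L
  root_edges <- which(reference_tree$edge[, 1] == root)
  candidates <- seq_len(n_edge)
  if (length(root_edges) == 2) candidates <- candidates[-root_edges[2]]
  ord <- candidates[order(scores[candidates], candidates)]
  best <- ord[1]
  tie <- sum(scores[candidates] <= scores[best] + 1e-9) > 1
  res <- list(query = query_taxon,
              ranking = data.frame(edge = ord, score = scores[ord],
                                   row.names = NULL),
              best_edge = best, tie = tie)
  class(res) <- "placement_result"
  res
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("placement of '%s': best edge %d (score %.4g)%s\n",
              x$query, x$best_edge, x$ranking$score[1],
              if (x$tie) " [tie]" else ""))
  invisible(x)
}

#' Place several queries and build a composite tree
#'
#' Queries are placed independently, each against the original reference
#' tree (so results do not depend on placement order); the composite tree
#' then grafts every query at its best edge, inserting a degree-3 node
#' with a unit-length pendant edge.
#'
#' @inheritParams place_query
#' @param queries character vector of query labels (disjoint from the
#'   reference leaves).
#' @return list with `placements` (list of `placement_result`) and
#'   `composite_tree` (phylo).
#' @export
place_all <- function(reference_tree, weights, morphology, queries) {
  queries <- normalize_label(queries)
  if (any(queries %in% reference_tree$tip.label))
    stop_glasstree("queries must be disjoint from reference leaves")
  placements <- lapply(queries, function(q)
    place_query(reference_tree, weights, morphology, q))
  names(placements) <- queries
  composite <- reference_tree
  # grafting changes edge indices, so insert in decreasing edge order of a
  # stable mapping: re-place each query's chosen split onto the growing tree
  for (q in queries) {
    # identify the original edge by the leaf set below it
    e <- placements[[q]]$best_edge
    child <- reference_tree$edge[e, 2]
    below <- if (child <= length(reference_tree$tip.label))
      reference_tree$tip.label[child]
    else ape::extract.clade(reference_tree, child)$tip.label
    node2 <- locate_clade(composite, below)
    # use the edge above the MRCA of the original leaf set
    e2 <- which(composite$edge[, 2] == node2)
    if (length(e2) == 0) { # split no longer present (query inside); root
      composite <- join_trees(composite, q)
    } else {
      composite <- attach_clade_keep_lengths(composite, e2, q)
    }
  }
  list(placements = placements, composite_tree = composite)
}
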