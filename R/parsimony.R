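## Parsimony scoring: Fitch/Hartigan step counts, per-character bounds,
## ensemble homoplasy indices, implied weighting, and MP character tracing.

# Internal: encode a char_matrix for bitmask parsimony.
# Returns list(masks = taxa x pattern integer matrix, weights, pattern_of
# = char -> pattern index, states = global symbol vector).
encode_parsimony <- function(matrix) {
  m <- unclass(matrix)
  miss <- missing_symbol(matrix)
  states <- sort(setdiff(unique(as.vector(m)), miss))
  if (length(states) > 30)
    stop_glasstree("more than 30 distinct states not supported")
  code <- setNames(bitwShiftL(1L, seq_along(states) - 1L), states)
  pat_key <- apply(m, 2, paste, collapse = "\r")
  upat <- unique(pat_key)
  pattern_of <- match(pat_key, upat)
  first_col <- match(upat, pat_key)
  # pattern-major layout (patterns x taxa): per-taxon pattern vectors are
  # contiguous, which the C++ kernel relies on for cache locality
  masks <- matrix(0L, length(upat), nrow(m),
                  dimnames = list(NULL, rownames(m)))
  for (k in seq_along(upat)) {
    col <- m[, first_col[k]]
    obs <- col != miss
    # missing behaves as the union of the character's observed states
    full <- if (any(obs)) sum(code[unique(col[obs])]) else sum(code)
    v <- integer(nrow(m))
    v[obs] <- code[col[obs]]
    v[!obs] <- as.integer(full)
    masks[k, ] <- v
  }
  list(masks = masks, pattern_of = pattern_of, states = states,
       n_states = length(states), n_patterns = length(upat))
}

# Internal: per-pattern Fitch steps of `phy` given an encoding (rows of
# enc$masks are matched to tip labels).
fitch_steps <- function(phy, enc) {
  idx <- match(phy$tip.label, colnames(enc$masks))
  if (anyNA(idx))
    stop_glasstree("leaf '", phy$tip.label[is.na(idx)][1],
                   "' absent from matrix")
  .fitch_steps_cpp(phy$edge, length(phy$tip.label), enc$masks, idx,
                   enc$n_states)
}

#' Minimum and maximum steps of a character
#'
#' For an unordered character, the minimum conceivable number of steps on
#' any tree is (number of distinct observed states) - 1, and the maximum
#' (attained on the star tree) is (number of scored taxa) - (count of the
#' most frequent observed state).  Missing cells are excluded.
#'
#' @param matrix a [character_matrix()].
#' @param character_index column index (vectorized).
#' @return a data.frame with columns `min_steps` (m) and `max_steps` (g).
#' @export
character_step_bounds <- function(matrix,
                                  character_index = seq_len(ncol(matrix))) {
  miss <- missing_symbol(matrix)
  out <- t(vapply(character_index, function(j) {
    col <- matrix[, j]
    col <- col[col != miss]
    if (length(col) == 0)
      stop_glasstree("character ", j, " is entirely missing; bounds undefined")
    tab <- table(col)
    c(min_steps = length(tab) - 1L,
      max_steps = length(col) - max(tab))
  }, c(min_steps = 0, max_steps = 0)))
  data.frame(character = character_index,
             min_steps = as.integer(out[, 1]),
             max_steps = as.integer(out[, 2]))
}

#' Parsimony score of a tree against a matrix
#'
#' Computes per-character observed steps by the Fitch down-pass (with the
#' state-vote generalization at polytomies), with missing cells acting as
#' the universal state set.  Characters entirely missing on the tree's leaf
#' set contribute zero steps.  Step bounds are computed on the induced leaf
#' set, and the ensemble consistency (CI), retention (RI) and rescaled
#' consistency (RC) indices are attached.
#'
#' @param tree an [ape::phylo] tree whose leaves are a subset of the
#'   matrix taxa.
#' @param matrix a [character_matrix()].
#' @return a `parsimony_result`: data.frame `per_character` (steps, bounds,
#'   homoplasy), `tree_length`, and indices `CI`, `RI`, `RC`.
#' @export
fitch_length <- function(tree, matrix) {
  if (!all(tree$tip.label %in% rownames(matrix))) {
    bad <- setdiff(tree$tip.label, rownames(matrix))
    stop_glasstree("leaf '", bad[1], "' absent from matrix")
  }
  sub <- character_matrix(unclass(matrix)[tree$tip.label, , drop = FALSE],
                          partitions = partitions_of(matrix),
                          missing = missing_symbol(matrix))
  enc <- encode_parsimony(sub)
  steps_pat <- fitch_steps(tree, enc)
  s <- as.integer(steps_pat[enc$pattern_of])
  miss <- missing_symbol(sub)
  all_missing <- colSums(unclass(sub) != miss) == 0
  bounds <- matrix(0L, ncol(sub), 2)
  if (any(!all_missing)) {
    b <- character_step_bounds(sub, which(!all_missing))
    bounds[!all_missing, ] <- cbind(b$min_steps, b$max_steps)
  }
  per <- data.frame(character = seq_len(ncol(sub)),
                    steps = s,
                    min_steps = bounds[, 1],
                    max_steps = bounds[, 2],
                    homoplasy = s - bounds[, 1])
  res <- list(per_character = per, tree_length = sum(s))
  class(res) <- "parsimony_result"
  idx <- ensemble_indices(res)
  res[names(idx)] <- idx
  res
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat(sprintf("TL = %d, CI = %.2f, RI = %.2f, RC = %.2f (%d characters)\n",
              x$tree_length, x$CI, x$RI, x$RC, nrow(x$per_character)))
  invisible(x)
}

#' Ensemble homoplasy indices
#'
#' CI = sum(m_i)/sum(s_i); RI = (sum(g_i) - sum(s_i)) / (sum(g_i) - sum(m_i));
#' RC = CI * RI.  Characters with g_i = m_i (no room for homoplasy) are
#' excluded from the RI sums.  Values are reported unrounded; use
#' `round_half_up(x, 2)` semantics when comparing against printed statistics.
#'
#' @param result a `parsimony_result` from [fitch_length()].
#' @return list with elements `CI`, `RI`, `RC`.
#' @export
ensemble_indices <- function(result) {
  per <- result$per_character
  if (sum(per$steps) == 0)
    stop_glasstree("total length is 0; CI undefined")
  CI <- sum(per$min_steps) / sum(per$steps)
  keep <- per$max_steps > per$min_steps
  RI <- if (any(keep)) {
    (sum(per$max_steps[keep]) - sum(per$steps[keep])) /
      (sum(per$max_steps[keep]) - sum(per$min_steps[keep]))
  } else NA_real_
  list(CI = CI, RI = RI, RC = CI * RI)
}

#' Implied-weights score
#'
#' Goloboff's fit function: each character contributes h/(h + K) where h is
#' its homoplasy (observed minus minimum steps) and K the concavity
#' constant.  Smaller is better; the score is what implied-weights searches
#' minimize, down-weighting overly homoplastic characters.
#'
#' @param result a `parsimony_result`, or an integer vector of per-character
#'   homoplasies.
#' @param K concavity constant (> 0), default 3.
#' @return the fitted score (numeric scalar).
#' @export
implied_weight_score <- function(result, K = 3) {
  stopifnot(K > 0)
  h <- if (inherits(result, "parsimony_result"))
    result$per_character$homoplasy else result
  sum(h / (h + K))
}

## ---- MP character tracing (Sankoff marginal dynamic programming) --------

# Internal unit-cost Sankoff down-pass / up-pass over one character.
# Returns list(down, up): (n_nodes) x k cost matrices, and tree info.
sankoff_costs <- function(tree, states_obs, k) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  INF <- 1e9
  down <- matrix(0, n_all, k)
  for (i in seq_len(n_tip)) {
    if (is.na(states_obs[i])) next # missing: all-zero costs
    down[i, ] <- INF
    down[i, states_obs[i]] <- 0
  }
  post <- rev(node_preorder(tree))
  for (v in post) {
    if (v <= n_tip) next
    for (ch in kids[[as.character(v)]]) {
      # min_t( [s != t] + down[ch, t] )
      best <- min(down[ch, ])
      down[v, ] <- down[v, ] + pmin(down[ch, ] , best + 1)
    }
  }
  up <- matrix(0, n_all, k)
  pre <- node_preorder(tree)
  parent_of <- integer(n_all)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  for (v in pre) {
    if (v == root) next
    p <- parent_of[v]
    sibs <- setdiff(kids[[as.character(p)]], v)
    ctx <- up[p, ]
    for (sb in sibs) {
      best <- min(down[sb, ])
      ctx <- ctx + pmin(down[sb, ], best + 1)
    }
    # up[v, t] = min_s( ctx[s] + [s != t] )
    best <- min(ctx)
    up[v, ] <- pmin(ctx, best + 1)
  }
  list(down = down, up = up, root = root, n_tip = n_tip,
       parent_of = parent_of, kids = kids)
}

# preorder sequence of node ids (root first)
node_preorder <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- n_tip + 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(stack, ch)
  }
  out
}

#' Most-parsimonious ancestral state sets (MP character tracing)
#'
#' Computes, for every node, the set of states that appear in at least one
#' most-parsimonious reconstruction (MPR set), via unit-cost dynamic
#' programming (exact on trees with polytomies).  Also reports state
#' changes along one deterministic resolution: the root takes the smallest
#' optimal state, each child the smallest state optimal given its parent.
#'
#' @param tree an [ape::phylo] tree.
#' @param matrix a [character_matrix()].
#' @param character_index single column index.
#' @return list with `mpr_sets` (list over nodes, in ape node order),
#'   `states` (symbols), `min_steps`, `resolution` (state per node), and
#'   `changes` (data.frame of edge, from, to).
#' @export
mp_trace <- function(tree, matrix, character_index) {
  miss <- missing_symbol(matrix)
  col <- unclass(matrix)[, character_index]
  col <- col[tree$tip.label]
  if (anyNA(col))
    stop_glasstree("leaf absent from matrix")
  states <- sort(unique(col[col != miss]))
  if (length(states) == 0)
    stop_glasstree("character ", character_index, " is entirely missing")
  k <- length(states)
  obs <- match(col, states) # NA for missing
  sc <- sankoff_costs(tree, obs, k)
  total <- sc$down + sc$up
  minlen <- min(total[sc$root, ])
  n_all <- nrow(total)
  mpr <- lapply(seq_len(n_all), function(v)
    states[which(abs(total[v, ] - min(total[v, ])) < 0.5)])
  # deterministic resolution: smallest-state tie-break, preorder
  resolution <- integer(n_all)
  pre <- node_preorder(tree)
  for (v in pre) {
    if (v == sc$root) {
      resolution[v] <- which.min(sc$down[v, ])
    } else {
      p <- resolution[sc$parent_of[v]]
      cand <- sc$down[v, ] + as.numeric(seq_len(k) != p)
      resolution[v] <- which.min(cand)
    }
  }
  ed <- tree$edge
  from <- states[resolution[ed[, 1]]]
  to <- states[resolution[ed[, 2]]]
  chg <- data.frame(edge = seq_len(nrow(ed)),
                    parent = ed[, 1], child = ed[, 2],
                    from = from, to = to)[from != to, , drop = FALSE]
  list(mpr_sets = mpr, states = states, min_steps = minlen,
       resolution = states[resolution], changes = chg)
}
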