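#' Search configuration for maximum parsimony
#'
#' @param K concavity constant of the implied-weights fit function
#'   (default 3.0, the conventional default).
#' @param n_random_additions number of random-addition-sequence starts.
#' @param swap_strategy branch-swapping neighbourhood: `"NNI"`, `"SPR"` or
#'   `"TBR"` (SPR with re-rooting of the pruned subtree).
#' @param seed RNG seed; searches are deterministic given the seed.
#' @param objective `"equal_weights"` (minimize tree length) or
#'   `"implied_weights"` (minimize Goloboff fit, see
#'   [implied_weight_score()]).
#' @param keep_max maximum number of co-optimal trees to collect.
#' @return a `search_config` list.
#' @export
search_config <- function(K = 3, n_random_additions = 10,
                          swap_strategy = c("TBR", "SPR", "NNI"),
                          seed = 1L,
                          objective = c("equal_weights", "implied_weights"),
                          keep_max = 64L) {
  stopifnot(K > 0, n_random_additions >= 1)
  list(K = K, n_random_additions = as.integer(n_random_additions),
       swap_strategy = match.arg(swap_strategy), seed = as.integer(seed),
       objective = match.arg(objective), keep_max = as.integer(keep_max))
}

# Internal: scoring closure for a matrix under a config.
make_scorer <- function(matrix, config) {
  enc <- encode_parsimony(matrix)
  w <- tabulate(enc$pattern_of, nbins = enc$n_patterns) # chars per pattern
  miss <- missing_symbol(matrix)
  m_pat <- vapply(seq_len(enc$n_patterns), function(k) {
    j <- which(enc$pattern_of == k)[1]
    col <- matrix[, j]
    n_obs <- sum(col != miss)
    if (n_obs == 0) 0L else length(unique(col[col != miss])) - 1L
  }, integer(1))
  implied <- config$objective == "implied_weights"
  K <- config$K
  score <- function(phy) {
    steps <- fitch_steps(phy, enc)
    if (implied) {
      h <- steps - m_pat
      sum(w * h / (h + K))
    } else {
      sum(w * steps)
    }
  }
  attr(score, "enc") <- enc
  attr(score, "w") <- w
  score
}

# Internal: one steepest-descent swap pass; returns improved tree or NULL.
best_neighbour <- function(phy, score_fn, strategy, current) {
  best <- NULL
  best_score <- current
  consider <- function(t2) {
    s <- score_fn(t2)
    if (s < best_score - 1e-9) {
      best <<- t2
      best_score <<- s
    }
  }
  if (strategy == "NNI") {
    for (t2 in nni_neighbours(phy)) consider(t2)
  } else {
    for (v in spr_candidates(phy)) {
      parts <- tryCatch(detach_clade(phy, v), error = function(e) NULL)
      if (is.null(parts)) next
      subs <- if (strategy == "TBR") subtree_rerootings(parts$sub)
              else list(parts$sub)
      for (sub in subs) {
        for (e in seq_len(nrow(parts$pruned$edge))) {
          consider(attach_clade(parts$pruned, e, sub))
        }
      }
    }
  }
  if (is.null(best)) NULL else list(tree = best, score = best_score)
}

# Internal: collect co-optimal trees reachable through equal-score moves.
collect_ties <- function(phy, score_fn, strategy, best_score, keep_max) {
  found <- list(phy)
  names(found) <- tree_signature(phy)
  queue <- list(phy)
  while (length(queue) > 0 && length(found) < keep_max) {
    cur <- queue[[1]]; queue <- queue[-1]
    neigh <- if (strategy == "NNI") nni_neighbours(cur) else {
      out <- list()
      for (v in spr_candidates(cur)) {
        parts <- tryCatch(detach_clade(cur, v), error = function(e) NULL)
        if (is.null(parts)) next
        subs <- if (strategy == "TBR") subtree_rerootings(parts$sub)
                else list(parts$sub)
        for (sub in subs)
          for (e in seq_len(nrow(parts$pruned$edge)))
            out[[length(out) + 1L]] <- attach_clade(parts$pruned, e, sub)
      }
      out
    }
    for (t2 in neigh) {
      if (score_fn(t2) > best_score + 1e-9) next
      key <- tree_signature(t2)
      if (!is.null(found[[key]])) next
      found[[key]] <- t2
      queue[[length(queue) + 1L]] <- t2
      if (length(found) >= keep_max) break
    }
  }
  found
}

#' Heuristic maximum-parsimony tree search
#'
#' Seeded random-addition-sequence starts followed by steepest-descent
#' branch swapping (NNI, SPR or TBR) under equal or implied weights.
#' Returns every distinct unrooted topology found attaining the best score
#' (up to `config$keep_max`), ordered by canonical Newick string.
#'
#' @param matrix a [character_matrix()] with at least 4 taxa.
#' @param config a [search_config()].
#' @return list with `trees` (list of phylo), `score` (best objective
#'   value), and `tree_length` (raw, unweighted length of the first best
#'   tree -- the statistic conventionally printed even for implied-weights
#'   searches).
#' @export
mp_search <- function(matrix, config = search_config()) {
  taxa <- rownames(matrix)
  if (length(taxa) < 4) stop_glasstree("need at least 4 taxa to search")
  score_fn <- make_scorer(matrix, config)
  equal_cfg <- config; equal_cfg$objective <- "equal_weights"
  length_fn <- make_scorer(matrix, equal_cfg)

  best_score <- Inf
  best_set <- list()
  with_seed(config$seed, {
    for (rep in seq_len(config$n_random_additions)) {
      ord <- sample(taxa)
      phy <- ape::read.tree(text = sprintf("((%s,%s),%s);",
                                           ord[1], ord[2], ord[3]))
      # addition placements scored by (equal-weights) length in C++;
      # the configured objective drives the branch swapping that follows
      enc <- attr(length_fn, "enc")
      w <- attr(length_fn, "w")
      for (tx in ord[-(1:3)]) {
        rows <- match(phy$tip.label, colnames(enc$masks))
        cand_scores <- .fitch_addition_scores_cpp(
          phy$edge, length(phy$tip.label), enc$masks, rows,
          match(tx, colnames(enc$masks)), w, enc$n_states)
        phy <- attach_tip(phy, which.min(cand_scores), tx)
      }
      sc <- score_fn(phy)
      repeat {
        impr <- best_neighbour(phy, score_fn, config$swap_strategy, sc)
        if (is.null(impr)) break
        phy <- impr$tree; sc <- impr$score
      }
      if (sc < best_score - 1e-9) {
        best_score <- sc
        best_set <- collect_ties(phy, score_fn, config$swap_strategy,
                                 sc, config$keep_max)
      } else if (sc < best_score + 1e-9) {
        more <- collect_ties(phy, score_fn, config$swap_strategy,
                             sc, config$keep_max)
        for (key in names(more))
          if (is.null(best_set[[key]]) && length(best_set) < config$keep_max)
            best_set[[key]] <- more[[key]]
      }
    }
  })
  ord <- order(vapply(best_set, canonical_newick, character(1)))
  trees <- unname(best_set[ord])
  list(trees = trees, score = best_score,
       tree_length = as.integer(length_fn(trees[[1]])))
}

#' Consensus tree
#'
#' Strict consensus keeps the splits present in every input tree; majority
#' consensus keeps splits whose frequency strictly exceeds `threshold`.
#'
#' @param trees list of phylo objects on identical leaf sets.
#' @param mode `"strict"` or `"majority"`.
#' @param threshold majority threshold (default 0.5).
#' @return a phylo object (possibly with polytomies).
#' @export
consensus_tree <- function(trees, mode = c("strict", "majority"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(length(trees) >= 1)
  labels <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, labels))
      stop_glasstree("trees have mismatched leaf sets")
  split_lists <- lapply(trees, tree_splits)
  freq <- table(unlist(split_lists))
  keep <- if (mode == "strict") names(freq)[freq == length(trees)]
          else names(freq)[freq / length(trees) > threshold]
  clades <- strsplit(keep, "|", fixed = TRUE)
  tree_from_clades(clades, labels)
}

#' Character bootstrap support
#'
#' Resamples characters with replacement, repeats a (reduced-effort)
#' parsimony search per pseudoreplicate, and reports for every internal
#' split of the reference tree the percentage of replicates whose best tree
#' contains it.
#'
#' @param matrix a [character_matrix()].
#' @param config a [search_config()]; each replicate uses a single
#'   random-addition start with this config's swap strategy and objective.
#' @param replicates number of pseudoreplicates (>= 1).
#' @param seed RNG seed for the resampling (independent of `config$seed`).
#' @param reference_tree tree whose splits are annotated; defaults to the
#'   first tree of a full `mp_search` under `config`.
#' @return list with `tree` (reference phylo with bootstrap percentages as
#'   `node.label`) and `support` (named vector, split key -> BS).
#' @export
bootstrap_support <- function(matrix, config = search_config(),
                              replicates = 100, seed = config$seed,
                              reference_tree = NULL) {
  stopifnot(replicates >= 1)
  if (is.null(reference_tree))
    reference_tree <- mp_search(matrix, config)$trees[[1]]
  ref_splits <- tree_splits(reference_tree)
  counts <- setNames(numeric(length(ref_splits)), ref_splits)
  rep_cfg <- config
  rep_cfg$n_random_additions <- 1L
  rep_cfg$keep_max <- 1L
  for (r in seq_len(replicates)) {
    rep_cfg$seed <- derive_seed(seed, r)
    cols <- with_seed(derive_seed(seed, 2L * r + 1L),
                      sample.int(ncol(matrix), replace = TRUE))
    bm <- character_matrix(unclass(matrix)[, cols, drop = FALSE],
                           missing = missing_symbol(matrix))
    res <- mp_search(bm, rep_cfg)
    got <- tree_splits(res$trees[[1]])
    hit <- ref_splits %in% got
    counts[hit] <- counts[hit] + 1
  }
  bs <- 100 * counts / replicates
  out <- reference_tree
  out$node.label <- bs_node_labels(reference_tree, bs)
  list(tree = out, support = bs)
}

# Map split-keyed BS values onto internal node labels of `phy`.
bs_node_labels <- function(phy, bs) {
  ntip <- length(phy$tip.label)
  ref <- sort(phy$tip.label)[1]
  labs <- character(phy$Nnode)
  for (v in seq_len(phy$Nnode) + ntip) {
    tips <- ape::extract.clade(phy, v)$tip.label
    side <- if (ref %in% tips) setdiff(phy$tip.label, tips) else tips
    key <- paste(sort(side), collapse = "|")
    labs[v - ntip] <- if (key %in% names(bs))
      format(round_half_up(bs[[key]], 0)) else ""
  }
  labs
}
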