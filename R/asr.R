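## Maximum-likelihood marginal ancestral-state reconstruction under Mk
## variants, clade lookup, and the regrafting used for topology-sensitivity
## analyses.

#' Marginal ancestral-state reconstruction
#'
#' For one character, computes at every node the proportional likelihood
#' (pl) of each state: the normalized marginal likelihood obtained by
#' combining the tipward (pruning) partials with the rootward flow, with
#' the root prior taken from the model (equilibrium frequencies by
#' default -- the conventional default for the asymmetric model).
#' Polytomies are treated as hard.  Trees without branch lengths use unit
#' lengths, the convention for parsimony trees.
#'
#' An artificial all-zero outgroup, if present, should be kept in the tree
#' (it roots the reconstruction) but simply not queried: it is a coding
#' device, not a taxon.
#'
#' @param tree rooted phylo.
#' @param matrix a [character_matrix()].
#' @param character column index or name.
#' @param model a fitted `mk_model` (see [optimize_model()]), or one with
#'   rates supplied.
#' @param decision_threshold pl below which the node is flagged ambiguous
#'   (presentational only; default 0.95).
#' @return an `asr_result`: `pl` (nodes x states matrix, ape node order),
#'   `states`, `model`, `loglik`, `ambiguous` (logical per node).
#' @export
marginal_asr <- function(tree, matrix, character, model,
                         decision_threshold = 0.95) {
  j <- if (is.character(character)) match(character, colnames(matrix))
       else character
  if (is.na(j) || j < 1 || j > ncol(matrix))
    stop_glasstree("unknown character: ", character)
  si <- state_indices(matrix[, j, drop = FALSE], model)
  if (!all(tree$tip.label %in% rownames(si$idx)))
    stop_glasstree("leaf '",
                   setdiff(tree$tip.label, rownames(si$idx))[1],
                   "' absent from matrix")
  obs <- si$idx[tree$tip.label, 1]
  if (all(is.na(obs)))
    stop_glasstree("character ", character, " is entirely missing on the tree")
  k <- model$k
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  lens <- tree_branch_lengths(tree)
  rates <- gamma_category_rates(model$gamma_shape, model$n_categories)
  prior <- root_prior_vector(model)
  pl <- matrix(0, n_all, k)
  total_lik <- 0
  kids_e <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  pre <- node_preorder(tree)
  post <- rev(pre)
  parent_edge <- integer(n_all)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  for (r in rates) {
    P <- edge_pmats(model, lens, r)
    down <- matrix(1, n_all, k)
    for (i in seq_len(n_tip)) {
      if (!is.na(obs[i])) {
        down[i, ] <- 0
        down[i, obs[i]] <- 1
      }
    }
    contrib <- matrix(1, n_all, k) # per child node: P %*% down, on parent states
    for (v in post) {
      if (v <= n_tip) {
        ch_nodes <- integer(0)
      } else {
        for (e in kids_e[[as.character(v)]]) {
          ch <- tree$edge[e, 2]
          contrib[ch, ] <- as.vector(P[[e]] %*% down[ch, ])
          down[v, ] <- down[v, ] * contrib[ch, ]
        }
      }
    }
    up <- matrix(1, n_all, k)
    up[n_tip + 1L, ] <- prior
    for (v in pre) {
      if (v == n_tip + 1L) next
      p <- tree$edge[parent_edge[v], 1]
      flow_p <- up[p, ] * down[p, ] / pmax(contrib[v, ], 1e-300)
      up[v, ] <- as.vector(flow_p %*% P[[parent_edge[v]]])
    }
    pl <- pl + (1 / length(rates)) * (up * down)
    total_lik <- total_lik + (1 / length(rates)) *
      sum(prior * down[n_tip + 1L, ])
  }
  pl <- pl / pmax(rowSums(pl), 1e-300)
  colnames(pl) <- si$symbols
  res <- list(character = character, states = si$symbols, model = model,
              pl = pl, loglik = log(total_lik),
              ambiguous = apply(pl, 1, max) < decision_threshold)
  class(res) <- "asr_result"
  res
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("ASR of character %s: %d nodes, states {%s}\n",
              as.character(x$character), nrow(x$pl),
              paste(x$states, collapse = ",")))
  invisible(x)
}

#' Locate a clade by its leaves
#'
#' Returns the most recent common ancestor (node id) of a set of leaf
#' labels; a single leaf returns that tip's id.
#'
#' @param tree phylo.
#' @param leaves character vector of leaf labels.
#' @return integer node id (ape numbering).
#' @export
locate_clade <- function(tree, leaves) {
  leaves <- normalize_label(leaves)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing) > 0)
    stop_glasstree("leaf '", missing[1], "' not in tree")
  if (length(leaves) == 0) stop_glasstree("empty clade query")
  if (length(leaves) == 1) return(match(leaves, tree$tip.label))
  if (setequal(leaves, tree$tip.label))
    return(length(tree$tip.label) + 1L)
  ape::getMRCA(tree, leaves)
}

#' Prune and regraft a clade
#'
#' Removes the clade identified by `clade` (MRCA of the given leaves) and
#' reattaches it as sister to the attachment point (the MRCA of
#' `attachment` leaves, or a tip).  New edges receive unit length when the
#' tree carries branch lengths.  Used for topology-sensitivity analyses of
#' ancestral-state reconstructions.
#'
#' @param tree rooted phylo.
#' @param clade character vector of leaf labels (the moving clade).
#' @param attachment character vector of leaf labels (the new sister
#'   group); must be disjoint from `clade`.
#' @return a phylo.
#' @export
regraft <- function(tree, clade, attachment) {
  clade <- normalize_label(clade)
  attachment <- normalize_label(attachment)
  if (length(intersect(clade, attachment)) > 0)
    stop_glasstree("clade and attachment overlap")
  node <- locate_clade(tree, clade)
  clade_tips <- if (node <= length(tree$tip.label)) tree$tip.label[node]
                else ape::extract.clade(tree, node)$tip.label
  if (!setequal(clade_tips, clade))
    stop_glasstree("clade query is not monophyletic in the tree (MRCA spans ",
                   length(clade_tips), " leaves)")
  parts <- detach_clade(tree, node)
  target <- locate_clade(parts$pruned, attachment)
  if (target == length(parts$pruned$tip.label) + 1L) {
    # attach at the root: new root above everything
    return(join_trees(parts$pruned, as_subtree(parts$sub)))
  }
  e <- which(parts$pruned$edge[, 2] == target)
  attach_clade_keep_lengths(parts$pruned, e, parts$sub)
}

as_subtree <- function(sub) {
  if (is.character(sub)) {
    new_phylo(matrix(c(2L, 1L), 1, 2), sub, 1L)
  } else sub
}

# attach_clade preserving lengths when present (new edges get length 1)
attach_clade_keep_lengths <- function(phy, edge_index, sub) {
  has_len <- !is.null(phy$edge.length)
  out <- attach_clade(phy, edge_index, sub)
  if (has_len) out$edge.length <- rep(1, nrow(out$edge))
  out
}

# New root joining two rooted trees (or tip labels) as its two children.
join_trees <- function(a, b) {
  a <- as_subtree(a); b <- as_subtree(b)
  na <- length(a$tip.label); nb <- length(b$tip.label)
  ma <- a$Nnode; mb <- b$Nnode
  Ea <- a$edge; Eb <- b$edge
  Ea[a$edge > na] <- a$edge[a$edge > na] + nb + 1L
  Eb[b$edge <= nb] <- b$edge[b$edge <= nb] + na
  Eb[b$edge > nb] <- b$edge[b$edge > nb] + na + ma + 1L
  root <- na + nb + 1L
  a_root <- na + nb + 2L
  b_root <- na + nb + ma + 2L
  E <- rbind(c(root, a_root), c(root, b_root), Ea, Eb)
  # single-tip subtrees: their "root" is the tip itself
  if (ma == 0 || na == 1) { } # handled by as_subtree always giving Nnode>=1
  new_phylo(E, c(a$tip.label, b$tip.label), ma + mb + 1L)
}

#' Tabulated ancestral-state report
#'
#' Fits each requested model to each character (rates estimated by ML
#' unless supplied), runs [marginal_asr()], and reports the proportional
#' likelihoods at the queried clades, rounded half-up to two decimals --
#' the conventional "Mk1/aMk2 = x/y" reporting style.
#'
#' @param tree rooted phylo.
#' @param matrix a [character_matrix()].
#' @param characters vector of column indices or names.
#' @param clade_queries named list of leaf-label vectors.
#' @param models character vector from `c("Mk1", "aMk2")`, or a named list
#'   of `mk_model` templates.
#' @param root_prior root prior for the templates (default equilibrium).
#' @param seed seed for the fitting multi-starts.
#' @param ascertainment passed to the fit (default `"none"`).
#' @return data.frame with one row per (character, clade, model): fitted
#'   rates, log-likelihood, and one `pl_<state>` column per state.
#' @export
asr_report <- function(tree, matrix, characters, clade_queries,
                       models = c("Mk1", "aMk2"),
                       root_prior = "equilibrium", seed = 1L,
                       ascertainment = "none") {
  if (is.character(models)) {
    templates <- lapply(models, function(m) {
      switch(m,
             Mk1 = mk_model(k = 2, mode = "symmetric",
                            root_prior = root_prior),
             aMk2 = mk_model(k = 2, mode = "asymmetric",
                             root_prior = root_prior),
             stop_glasstree("unknown model name: ", m))
    })
    names(templates) <- models
  } else templates <- models
  if (is.null(names(clade_queries)))
    stop_glasstree("clade_queries must be a named list")
  rows <- list()
  chars <- sort(characters)
  for (ch in chars) {
    for (mn in sort(names(templates))) {
      fit <- optimize_model(tree, matrix[, ch, drop = FALSE],
                            templates[[mn]],
                            ascertainment = ascertainment, seed = seed)
      asr <- marginal_asr(tree, matrix, ch, fit$model)
      for (cl in sort(names(clade_queries))) {
        node <- locate_clade(tree, clade_queries[[cl]])
        pls <- round_half_up(asr$pl[node, ], 2)
        row <- data.frame(character = as.character(ch), clade = cl,
                          model = mn,
                          rate_q = if (fit$model$mode == "symmetric")
                            fit$model$q else NA_real_,
                          rate_q01 = fit$model$q01 %||% NA_real_,
                          rate_q10 = fit$model$q10 %||% NA_real_,
                          loglik = fit$loglik)
        for (s in seq_along(asr$states))
          row[[paste0("pl_", asr$states[s])]] <- pls[s]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$character, out$clade, out$model), , drop = FALSE]
}
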