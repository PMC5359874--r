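# Independent oracles and fixture builders used across the suite.  These
# deliberately avoid the package's own algorithms: parsimony lengths come
# from exhaustive enumeration of ancestral assignments, likelihoods from
# summation over all internal-state configurations, topologies from
# explicit edge-insertion enumeration.

# All unrooted topologies on a label set (as rooted-at-trifurcation phylo).
all_topologies <- function(labels) {
  stopifnot(length(labels) >= 3)
  trees <- list(ape::read.tree(text = sprintf("(%s,%s,%s);",
                                              labels[1], labels[2],
                                              labels[3])))
  for (tx in labels[-(1:3)]) {
    acc <- list()
    for (tr in trees)
      for (e in seq_len(nrow(tr$edge)))
        acc[[length(acc) + 1L]] <- glasstree:::attach_tip(tr, e, tx)
    trees <- acc
  }
  trees
}

# Exhaustive unit-cost parsimony length of one character: minimize the
# number of state-changing edges over all internal-node assignments.
# obs: integer state per tip (NA = missing), k states.
oracle_steps <- function(tree, obs, k) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(obs, grid[g, ])
    cost <- 0
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      p <- assign_all[tree$edge[e, 1]]
      c_ <- assign_all[tree$edge[e, 2]]
      if (is.na(c_)) next # missing tip: free choice, costs nothing extra
      if (!is.na(p) && p != c_) cost <- cost + 1
      if (!ok) break
    }
    # missing tips: assign them to their parent's state (cost 0), so skip
    best <- min(best, cost)
  }
  best
}

# Unit-cost Sankoff dynamic programming (independent R implementation).
oracle_sankoff <- function(tree, obs, k) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  INF <- 1e9
  cost <- matrix(0, n_all, k)
  for (i in seq_len(n_tip)) {
    if (is.na(obs[i])) next
    cost[i, ] <- INF
    cost[i, obs[i]] <- 0
  }
  rec <- function(v) {
    ch <- kids[[as.character(v)]]
    if (is.null(ch)) return(invisible(NULL))
    for (c_ in ch) {
      rec(c_)
      add <- vapply(seq_len(k), function(s)
        min(cost[c_, ] + (seq_len(k) != s)), numeric(1))
      cost[v, ] <<- cost[v, ] + add
    }
  }
  rec(n_tip + 1L)
  min(cost[n_tip + 1L, ])
}

# Likelihood of one character by explicit summation over internal states.
oracle_loglik <- function(tree, obs, model) {
  k <- model$k
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  lens <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge))
          else tree$edge.length
  rates <- glasstree::gamma_category_rates(model$gamma_shape,
                                           model$n_categories)
  prior <- glasstree:::root_prior_vector(model)
  total <- 0
  miss_tips <- which(is.na(obs))
  tip_grid <- if (length(miss_tips) > 0)
    as.matrix(expand.grid(rep(list(seq_len(k)), length(miss_tips))))
  else matrix(0, 1, 0)
  int_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  for (r in rates) {
    P <- lapply(lens, function(t)
      glasstree::transition_probabilities(model, t, r))
    lik_r <- 0
    for (tg in seq_len(nrow(tip_grid))) {
      obs2 <- obs
      if (length(miss_tips) > 0) obs2[miss_tips] <- tip_grid[tg, ]
      for (ig in seq_len(nrow(int_grid))) {
        assign_all <- c(obs2, int_grid[ig, ])
        p <- prior[assign_all[n_tip + 1L]]
        for (e in seq_len(nrow(tree$edge)))
          p <- p * P[[e]][assign_all[tree$edge[e, 1]],
                          assign_all[tree$edge[e, 2]]]
        lik_r <- lik_r + p
      }
    }
    total <- total + lik_r / length(rates)
  }
  log(total)
}

# Marginal ancestral probabilities by joint enumeration.
oracle_marginals <- function(tree, obs, model) {
  k <- model$k
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  lens <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge))
          else tree$edge.length
  prior <- glasstree:::root_prior_vector(model)
  P <- lapply(lens, function(t)
    glasstree::transition_probabilities(model, t))
  int_grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n_int)))
  marg <- matrix(0, n_int, k)
  for (ig in seq_len(nrow(int_grid))) {
    assign_all <- c(obs, int_grid[ig, ])
    p <- prior[assign_all[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      c_ <- assign_all[tree$edge[e, 2]]
      if (is.na(c_)) next
      p <- p * P[[e]][assign_all[tree$edge[e, 1]], c_]
    }
    for (v in seq_len(n_int))
      marg[v, int_grid[ig, v]] <- marg[v, int_grid[ig, v]] + p
  }
  marg / rowSums(marg)
}

# Homoplasy-free binary matrix: one character per non-root internal edge
# of the (rooted) tree, replicated.
clean_split_matrix <- function(tr, reps = 2) {
  nt <- length(tr$tip.label)
  cols <- list()
  for (v in (nt + 2):(nt + tr$Nnode)) {
    tips <- ape::extract.clade(tr, v)$tip.label
    col <- ifelse(tr$tip.label %in% tips, "1", "0")
    for (r in seq_len(reps)) cols[[length(cols) + 1L]] <- col
  }
  m <- do.call(cbind, cols)
  rownames(m) <- tr$tip.label
  character_matrix(m)
}

# Random small character matrix (possibly with missing cells).
random_matrix <- function(n_taxa, n_char, k = 2, miss_prob = 0.1) {
  syms <- as.character(seq_len(k) - 1L)
  m <- matrix(sample(syms, n_taxa * n_char, replace = TRUE), n_taxa, n_char)
  m[matrix(runif(length(m)) < miss_prob, n_taxa, n_char)] <- "?"
  # ensure no all-missing characters
  for (j in seq_len(n_char))
    if (all(m[, j] == "?")) m[1, j] <- sample(syms, 1)
  rownames(m) <- paste0("t", seq_len(n_taxa))
  character_matrix(m)
}

random_binary_tree <- function(labels) {
  tr <- ape::rtree(length(labels), tip.label = sample(labels))
  tr$edge.length <- NULL
  tr
}

expect_same_topology <- function(a, b) {
  expect_true(setequal(a$tip.label, b$tip.label))
  expect_identical(glasstree:::tree_signature(a),
                   glasstree:::tree_signature(b))
}

# Edges of `ref` lying within (or on the stem of) the clade spanned by
# `tips_set`; used to judge phylogenetic placements.
edges_within_clade <- function(ref, tips_set) {
  sn <- locate_clade(ref, tips_set)
  al <- which(ref$edge[, 2] == sn)
  if (sn > length(ref$tip.label)) {
    cl_tips <- ape::extract.clade(ref, sn)$tip.label
    al <- c(al, which(vapply(seq_len(nrow(ref$edge)), function(e) {
      ch <- ref$edge[e, 2]
      tips <- if (ch <= length(ref$tip.label)) ref$tip.label[ch]
              else ape::extract.clade(ref, ch)$tip.label
      all(tips %in% cl_tips)
    }, logical(1))))
  }
  unique(al)
}

# Smallest true clade properly containing the query's attachment edge
# (the clade of the query's grandparent), minus the query itself.
true_parent_clade_tips <- function(true_tree, query) {
  qi <- match(query, true_tree$tip.label)
  p <- true_tree$edge[true_tree$edge[, 2] == qi, 1]
  ge <- which(true_tree$edge[, 2] == p)
  if (length(ge) == 0) return(setdiff(true_tree$tip.label, query))
  gp <- true_tree$edge[ge, 1]
  setdiff(ape::extract.clade(true_tree, gp)$tip.label, query)
}
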