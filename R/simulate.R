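## Seeded generators for trees, discrete characters, nucleotide alignments
## and structured missingness.  These emulate the statistical shape of the
## study data (two subclasses, small binary morphology matrices filtered to
## parsimony-informative characters, a 4-partition molecular supermatrix
## with block missingness) so that every downstream stage is testable with
## known truth.

#' Simulate a random tree
#'
#' Yule or birth-death trees via [ape::rphylo()] (conditioned on the number
#' of tips; ultrametric), or an unconstrained simulation for a fixed time
#' span via [ape::rlineage()] with extinct lineages pruned.
#'
#' @param n_taxa number of tips (conditioned mode).
#' @param model `"yule"` or `"birth-death"`.
#' @param birth,death per-lineage rates (death forced to 0 under Yule).
#' @param time if non-`NULL`, run an unconstrained simulation for this time
#'   span instead of conditioning on `n_taxa` (the tree may be `NULL` if
#'   the process dies out or only one lineage survives).  The process
#'   starts at the root split, i.e. from two lineages, so the expected
#'   extant tip count of a pure-birth run is `2 * exp(birth * time)`.
#' @param seed RNG seed.
#' @return a phylo (tips labelled `t1`, `t2`, ...), or `NULL` in
#'   unconstrained mode if fewer than 2 lineages survive.
#' @export
simulate_tree <- function(n_taxa = NULL, model = c("yule", "birth-death"),
                          birth = 1, death = 0, time = NULL, seed = 1L) {
  model <- match.arg(model)
  if (model == "yule") death <- 0
  stopifnot(birth > 0, death >= 0)
  with_seed(seed, {
    if (!is.null(time)) {
      phy <- ape::rlineage(birth, death, Tmax = time)
      if (death > 0) phy <- tryCatch(ape::drop.fossil(phy),
                                     error = function(e) NULL)
      if (is.null(phy) || length(phy$tip.label) < 2) return(NULL)
      phy$tip.label <- paste0("t", seq_along(phy$tip.label))
      return(phy)
    }
    stopifnot(n_taxa >= 2)
    if (n_taxa == 2) {
      phy <- ape::read.tree(text = "(t1:1,t2:1);")
      return(phy)
    }
    phy <- ape::rphylo(n_taxa, birth, death)
    phy$tip.label <- paste0("t", seq_len(n_taxa))
    phy
  })
}

# evolve states down the tree; returns n_all x n integer state matrix
evolve_states <- function(tree, model, n, rates_per_char) {
  k <- model$k
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  lens <- tree_branch_lengths(tree)
  prior <- root_prior_vector(model)
  states <- matrix(0L, n_all, n)
  states[n_tip + 1L, ] <- sample.int(k, n, replace = TRUE, prob = prior)
  pre <- node_preorder(tree)
  parent_edge <- integer(n_all)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  cats <- unique(rates_per_char)
  for (v in pre) {
    if (v == n_tip + 1L) next
    e <- parent_edge[v]
    ps <- states[tree$edge[e, 1], ]
    for (r in cats) {
      sel <- which(rates_per_char == r)
      P <- transition_probabilities(model, lens[e], r)
      for (s in seq_len(k)) {
        hit <- sel[ps[sel] == s]
        if (length(hit) > 0)
          states[v, hit] <- sample.int(k, length(hit), replace = TRUE,
                                       prob = P[s, ])
      }
    }
  }
  states
}

is_parsimony_informative <- function(col_states, k) {
  tab <- tabulate(col_states, nbins = k)
  sum(tab >= 2) >= 2
}

#' Simulate discrete characters on a tree
#'
#' Root states are drawn from the model's root prior; states evolve
#' edge-wise via the model's transition probabilities (optionally with
#' discrete-gamma rate variation across characters).  With
#' `informative_only = TRUE`, characters are rejection-sampled until `n`
#' parsimony-informative ones are obtained, mirroring matrices that only
#' include parsimony-informative characters (the ascertainment the
#' likelihood correction conditions on).
#'
#' @param tree phylo with branch lengths.
#' @param model an `mk_model`.
#' @param n number of characters to return.
#' @param informative_only filter to parsimony-informative characters.
#' @param seed RNG seed.
#' @param max_tries rejection cap (error if infeasible).
#' @return list with `matrix` (a [character_matrix()] with symbols
#'   `"0"..`), `truth` (list: `node_states` matrix over all nodes,
#'   `rates_per_char`, `model`, `n_rejected`).
#' @export
simulate_discrete_characters <- function(tree, model, n,
                                         informative_only = FALSE,
                                         seed = 1L, max_tries = 200) {
  if (informative_only && length(tree$tip.label) < 4)
    stop_glasstree("informative-only filtering needs >= 4 taxa")
  n_tip <- length(tree$tip.label)
  k <- model$k
  with_seed(seed, {
    kept_states <- NULL
    kept_rates <- numeric(0)
    n_rejected <- 0L
    tries <- 0L
    while (is.null(kept_states) || ncol(kept_states) < n) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop_glasstree("informative-only filtering infeasible: ",
                       n_rejected, " characters rejected; ",
                       "is the rate high enough?")
      batch <- max(n - if (is.null(kept_states)) 0 else ncol(kept_states),
                   16L)
      cat_rates <- gamma_category_rates(model$gamma_shape,
                                        model$n_categories)
      rates <- sample(cat_rates, batch, replace = TRUE)
      st <- evolve_states(tree, model, batch, rates)
      if (informative_only) {
        ok <- vapply(seq_len(batch), function(j)
          is_parsimony_informative(st[seq_len(n_tip), j], k), logical(1))
        n_rejected <- n_rejected + sum(!ok)
      } else ok <- rep(TRUE, batch)
      kept_states <- cbind(kept_states, st[, ok, drop = FALSE])
      kept_rates <- c(kept_rates, rates[ok])
    }
    kept_states <- kept_states[, seq_len(n), drop = FALSE]
    kept_rates <- kept_rates[seq_len(n)]
    cells <- matrix(as.character(kept_states[seq_len(n_tip), ] - 1L),
                    n_tip, n, dimnames = list(tree$tip.label, NULL))
    list(matrix = character_matrix(cells),
         truth = list(node_states = kept_states - 1L,
                      rates_per_char = kept_rates, model = model,
                      n_rejected = n_rejected))
  })
}

#' Simulate a nucleotide alignment
#'
#' Site-i.i.d. simulation under a GTR model with (continuous) gamma rate
#' multipliers across sites when `gamma_shape` is set.
#'
#' @param tree phylo with branch lengths.
#' @param model a [gtr_model()].
#' @param length number of sites.
#' @param seed RNG seed.
#' @return an [nt_alignment()].
#' @export
simulate_alignment <- function(tree, model = gtr_model(), length, seed = 1L) {
  n_tip <- base::length(tree$tip.label)
  if (length == 0) {
    seqs <- setNames(rep("", n_tip), tree$tip.label)
    return(nt_alignment(seqs))
  }
  with_seed(seed, {
    rates <- if (is.null(model$gamma_shape)) rep(1, length)
             else rgamma(length, shape = model$gamma_shape,
                         rate = model$gamma_shape)
    # bin continuous rates to limit distinct transition matrices
    rates <- signif(rates, 2)
    st <- evolve_states(tree, model, length, rates)
    syms <- c("a", "c", "g", "t")
    cells <- matrix(syms[st[seq_len(n_tip), ]], n_tip, length,
                    dimnames = list(tree$tip.label, NULL))
    nt_alignment(cells)
  })
}

#' Mask cells as missing
#'
#' `"uniform"` masks cells i.i.d.; `"taxon-block"` masks whole partitions
#' for randomly chosen taxa (mimicking unsequenced taxa / missing markers)
#' until the requested overall fraction is approximately reached;
#' `"partition-block"` does the same sampling per partition.
#'
#' @param matrix a [character_matrix()] or [nt_alignment()].
#' @param fraction target overall missing fraction in `[0, 1)`.
#' @param pattern `"uniform"`, `"taxon-block"` or `"partition-block"`.
#' @param seed RNG seed.
#' @return the masked matrix, with attribute `achieved_fraction`.
#' @export
apply_missingness <- function(matrix, fraction,
                              pattern = c("uniform", "taxon-block",
                                          "partition-block"),
                              seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(fraction >= 0, fraction < 1)
  miss <- missing_symbol(matrix) %||% "?"
  if (fraction == 0) {
    attr(matrix, "achieved_fraction") <- mean(unclass(matrix) == miss)
    return(matrix)
  }
  m <- unclass(matrix)
  parts <- partitions_of(matrix) %||% list(all = seq_len(ncol(m)))
  with_seed(seed, {
    if (pattern == "uniform") {
      mask <- matrix(runif(base::length(m)) < fraction, nrow(m), ncol(m))
      m[mask] <- miss
    } else {
      blocks <- expand.grid(taxon = seq_len(nrow(m)),
                            part = seq_along(parts))
      ord <- if (pattern == "taxon-block") sample(nrow(blocks))
             else unlist(lapply(sample(seq_along(parts)), function(p)
               sample(which(blocks$part == p))))
      total <- base::length(m)
      need <- fraction * total - sum(m == miss)
      for (b in ord) {
        if (need <= 0) break
        idx <- parts[[blocks$part[b]]]
        row <- blocks$taxon[b]
        fresh <- sum(m[row, idx] != miss)
        if (fresh == 0) next
        m[row, idx] <- miss
        need <- need - fresh
      }
    }
  })
  out <- if (inherits(matrix, "nt_alignment")) {
    nt_alignment(m, partitions = parts)
  } else {
    character_matrix(m, partitions = parts, missing = miss,
                     character_labels = colnames(matrix))
  }
  attr(out, "achieved_fraction") <- mean(m == miss)
  out
}

#' Study-like synthetic dataset
#'
#' Generates a complete synthetic analogue of the study data: one true
#' tree containing two "subclasses" (a small and a large clade),
#' parsimony-informative binary morphology for every genus (a separate
#' matrix per subclass), and a 4-partition molecular alignment in which
#' only a configurable fraction of genera (default ~45%, the study's
#' sequence coverage) have data, with additional per-marker dropout among
#' the sequenced genera (default 30%, the supermatrix missingness level).
#' Truth records (true trees, ancestral states, generating parameters) are
#' kept for downstream accuracy checks.
#'
#' @param n_small,n_large genus counts of the two subclasses (defaults 13
#'   and 113: 126 genera in total).
#' @param morph_chars characters per subclass morphology matrix (defaults
#'   29 and 108).
#' @param mol_sites sites per molecular partition (defaults sum to 4806).
#' @param sequenced_fraction fraction of genera with molecular data.
#' @param marker_dropout within-sequenced-taxa missing fraction of the
#'   molecular matrix.
#' @param morph_rate total leaving rate of the binary morphology model.
#' @param gamma_shape gamma shape for the molecular model.
#' @param seed RNG seed; every internal stage derives its own stream.
#' @return a `study_set` list: `tree`, `tree_small`, `tree_large`,
#'   `morphology` (list small/large), `molecular` (masked
#'   [nt_alignment()]), `sequenced_taxa`, `truth`.
#' @export
make_study_like_dataset <- function(n_small = 13, n_large = 113,
                                    morph_chars = c(29, 108),
                                    mol_sites = c(r18s = 1500, r28s = 2100,
                                                  r16s = 600, coi = 606),
                                    sequenced_fraction = 0.45,
                                    marker_dropout = 0.30,
                                    morph_rate = 0.6,
                                    gamma_shape = 0.5,
                                    seed = 1L) {
  t_small <- simulate_tree(n_small, "yule", seed = derive_seed(seed, 1))
  t_large <- simulate_tree(n_large, "yule", seed = derive_seed(seed, 2))
  t_small$tip.label <- sprintf("A_genus%02d", seq_len(n_small))
  t_large$tip.label <- sprintf("H_genus%03d", seq_len(n_large))
  # equalize depths, then join under a root with unit stem edges
  t_small$edge.length <- t_small$edge.length /
    max(ape::node.depth.edgelength(t_small))
  t_large$edge.length <- t_large$edge.length /
    max(ape::node.depth.edgelength(t_large))
  tree <- join_trees(t_small, t_large)
  tree$edge.length <- c(0.3, 0.3, t_small$edge.length, t_large$edge.length)

  mk <- mk_model(k = 2, q = morph_rate)
  morph_small <- simulate_discrete_characters(
    t_small, mk, morph_chars[1], informative_only = TRUE,
    seed = derive_seed(seed, 3))
  morph_large <- simulate_discrete_characters(
    t_large, mk, morph_chars[2], informative_only = TRUE,
    seed = derive_seed(seed, 4))

  gtr <- gtr_model(exchangeabilities = c(1, 4, 1, 1, 4, 1),
                   base_freqs = c(0.26, 0.22, 0.27, 0.25),
                   gamma_shape = gamma_shape)
  aln <- NULL
  at <- 0L
  parts <- list()
  for (p in seq_along(mol_sites)) {
    blk <- simulate_alignment(tree, gtr, mol_sites[p],
                              seed = derive_seed(seed, 10 + p))
    aln <- if (is.null(aln)) unclass(blk) else cbind(aln, unclass(blk))
    parts[[names(mol_sites)[p] %||% paste0("part", p)]] <-
      at + seq_len(mol_sites[p])
    at <- at + mol_sites[p]
  }
  aln <- nt_alignment(aln, partitions = parts)

  all_taxa <- tree$tip.label
  n_seq <- max(4L, round(sequenced_fraction * base::length(all_taxa)))
  sequenced <- with_seed(derive_seed(seed, 20),
                         sort(sample(all_taxa, n_seq)))
  m <- unclass(aln)
  m[setdiff(all_taxa, sequenced), ] <- "?"
  aln_masked <- nt_alignment(m, partitions = parts)
  aln_masked <- apply_missingness(
    aln_masked,
    fraction = min(0.98, (1 - sequenced_fraction) +
                     sequenced_fraction * marker_dropout),
    pattern = "taxon-block", seed = derive_seed(seed, 21))

  structure(list(
    tree = tree, tree_small = t_small, tree_large = t_large,
    morphology = list(small = morph_small$matrix,
                      large = morph_large$matrix),
    molecular = aln_masked,
    sequenced_taxa = sequenced,
    truth = list(morph_small = morph_small$truth,
                 morph_large = morph_large$truth,
                 gtr = gtr, seed = seed)),
    class = "study_set")
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf(
    "<study_set> %d + %d genera; morphology %d + %d chars; %d molecular sites\n",
    length(x$tree_small$tip.label), length(x$tree_large$tip.label),
    ncol(x$morphology$small), ncol(x$morphology$large), ncol(x$molecular)))
  invisible(x)
}
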