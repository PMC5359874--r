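test_that("per-character step bounds match their definitions", {
  m <- character_matrix(rbind(t1 = "0", t2 = "0", t3 = "1", t4 = "1"))
  b <- character_step_bounds(m)
  expect_equal(b$min_steps, 1L)
  expect_equal(b$max_steps, 2L)

  const <- character_matrix(rbind(t1 = "0", t2 = "0", t3 = "0"))
  bc <- character_step_bounds(const)
  expect_equal(c(bc$min_steps, bc$max_steps), c(0L, 0L))

  # three states, one each: min = max = 2 on any tree (star included)
  tri <- character_matrix(rbind(t1 = "0", t2 = "1", t3 = "2"))
  bt <- character_step_bounds(tri)
  expect_equal(c(bt$min_steps, bt$max_steps), c(2L, 2L))

  allmiss <- character_matrix(rbind(t1 = "?", t2 = "?"))
  expect_error(character_step_bounds(allmiss), "missing")
})

test_that("Fitch lengths agree with enumeration and Sankoff on random instances", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(4:6, 1)
    k <- sample(2:3, 1)
    tr <- random_binary_tree(paste0("t", 1:n))
    cm <- random_matrix(n, 5, k = k, miss_prob = 0.15)
    res <- fitch_length(tr, cm)
    for (j in 1:5) {
      col <- unclass(cm)[tr$tip.label, j]
      syms <- sort(unique(col[col != "?"]))
      obs <- match(col, syms)
      expect_equal(res$per_character$steps[j],
                   oracle_steps(tr, obs, length(syms)),
                   info = sprintf("rep %d char %d (enumeration)", rep, j))
      expect_equal(res$per_character$steps[j],
                   oracle_sankoff(tr, obs, length(syms)),
                   info = sprintf("rep %d char %d (sankoff)", rep, j))
    }
  }
})

test_that("tree length is invariant under re-rooting", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- random_binary_tree(paste0("t", 1:7))
    cm <- random_matrix(7, 8, k = 2)
    tl <- fitch_length(tr, cm)$tree_length
    for (og in sample(tr$tip.label, 3)) {
      tr2 <- ape::root(tr, outgroup = og, resolve.root = TRUE)
      expect_equal(fitch_length(tr2, cm)$tree_length, tl)
    }
  }
})

test_that("Fitch handles polytomies exactly (vote generalization)", {
  set.seed(13)
  star <- ape::read.tree(text = "(t1,t2,t3,t4,t5);")
  for (rep in 1:10) {
    cm <- random_matrix(5, 4, k = 3, miss_prob = 0.2)
    res <- fitch_length(star, cm)
    for (j in 1:4) {
      col <- unclass(cm)[star$tip.label, j]
      syms <- sort(unique(col[col != "?"]))
      obs <- match(col, syms)
      expect_equal(res$per_character$steps[j],
                   oracle_steps(star, obs, length(syms)))
    }
  }
})

test_that("ensemble indices follow their formulas and edge cases", {
  tr <- read_tree("((A,B),(C,D));")
  clean <- character_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  res <- fitch_length(tr, clean)
  expect_equal(res$CI, 1)
  expect_equal(res$RI, 1)

  # maximally homoplastic: s = g so its RI contribution is 0
  hom <- character_matrix(rbind(A = "0", B = "1", C = "0", D = "1"))
  res2 <- fitch_length(tr, hom)
  expect_equal(res2$RI, 0)
  expect_equal(res2$per_character$steps, 2L)

  allconst <- character_matrix(rbind(A = "0", B = "0", C = "0", D = "0"))
  expect_error(ensemble_indices(fitch_length(tr, allconst)), "undefined")

  # index invariance under character reordering
  set.seed(5)
  cm <- random_matrix(4, 10, k = 2)
  rownames(cm) <- c("A", "B", "C", "D")
  cm <- character_matrix(unclass(cm))
  perm <- sample(10)
  cm2 <- character_matrix(unclass(cm)[, perm, drop = FALSE])
  r1 <- fitch_length(tr, cm)
  r2 <- fitch_length(tr, cm2)
  expect_equal(r1$CI, r2$CI)
  expect_equal(r1$RI, r2$RI)
})

test_that("implied-weights scores match the fit function and an exhaustive oracle", {
  expect_equal(implied_weight_score(0L, K = 3), 0)
  expect_equal(implied_weight_score(3L, K = 3), 0.5)

  # exhaustive check on all 105 6-taxon topologies
  set.seed(21)
  cm <- random_matrix(6, 6, k = 2, miss_prob = 0)
  topos <- all_topologies(rownames(cm))
  expect_length(topos, 105)
  K <- 3
  for (tr in topos[sample(length(topos), 12)]) {
    res <- fitch_length(tr, cm)
    manual <- 0
    for (j in 1:6) {
      col <- unclass(cm)[tr$tip.label, j]
      syms <- sort(unique(col))
      h <- oracle_steps(tr, match(col, syms), length(syms)) -
        (length(syms) - 1)
      manual <- manual + h / (h + K)
    }
    expect_equal(implied_weight_score(res, K), manual, tolerance = 1e-12)
  }

  # K -> infinity ranks topologies like equal-weights length (ties in
  # length are ties in score, so check monotone consistency pairwise)
  scores_iw <- vapply(topos, function(tr)
    implied_weight_score(fitch_length(tr, cm), K = 1e7), numeric(1))
  lengths <- vapply(topos, function(tr)
    fitch_length(tr, cm)$tree_length, numeric(1))
  o <- order(lengths)
  expect_true(all(diff(scores_iw[o]) > -1e-12))
  expect_true(all(abs(diff(scores_iw[o])[diff(lengths[o]) == 0]) < 1e-9))
})

test_that("MP tracing reproduces exhaustive MPR sets and a sensible resolution", {
  tr <- read_tree("((A,B),(C,D));")
  const <- character_matrix(rbind(A = "1", B = "1", C = "1", D = "1"))
  tt <- mp_trace(tr, const, 1)
  expect_true(all(vapply(tt$mpr_sets, identical, TRUE, "1")))
  expect_equal(nrow(tt$changes), 0L)

  set.seed(31)
  for (rep in 1:15) {
    tr5 <- random_binary_tree(paste0("t", 1:5))
    cm <- random_matrix(5, 1, k = sample(2:3, 1), miss_prob = 0.1)
    col <- unclass(cm)[tr5$tip.label, 1]
    if (all(col == "?")) next
    syms <- sort(unique(col[col != "?"]))
    k <- length(syms)
    obs <- match(col, syms)
    tt <- mp_trace(tr5, cm, 1)
    # brute force: states of each internal node over all optimal assignments
    n_tip <- 5
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), tr5$Nnode)))
    tipgrid <- which(is.na(obs))
    costs <- apply(grid, 1, function(g) {
      assign_all <- c(obs, g)
      cost <- 0
      for (e in seq_len(nrow(tr5$edge))) {
        c_ <- assign_all[tr5$edge[e, 2]]
        if (is.na(c_)) next
        if (assign_all[tr5$edge[e, 1]] != c_) cost <- cost + 1
      }
      cost
    })
    best <- min(costs)
    expect_equal(tt$min_steps, best)
    for (v in seq_len(tr5$Nnode)) {
      states_v <- sort(unique(syms[grid[costs == best, v]]))
      expect_equal(sort(tt$mpr_sets[[n_tip + v]]), states_v,
                   info = sprintf("rep %d node %d", rep, v))
    }
    # the deterministic resolution attains the minimum
    expect_equal(sum(tt$resolution[tr5$edge[, 1]] !=
                       tt$resolution[tr5$edge[, 2]]), best)
  }
})

test_that("parsimony lengths agree with an independent library implementation", {
  skip_if_not_installed("phangorn")
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    tr <- random_binary_tree(paste0("t", 1:n))
    cm <- random_matrix(n, 12, k = 2, miss_prob = 0.1)
    pd <- phangorn::phyDat(unclass(cm), type = "USER",
                           levels = c("0", "1"), ambiguity = "?")
    expect_equal(fitch_length(tr, cm)$tree_length,
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})
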