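test_that("transition probabilities have the right limits and match expm", {
  for (mod in list(mk_model(k = 2, q = 0.7),
                   mk_model(k = 4, q = 1.3),
                   mk_model(mode = "asymmetric", q01 = 0.5, q10 = 2))) {
    expect_equal(transition_probabilities(mod, 0), diag(mod$k))
    Pinf <- transition_probabilities(mod, 500)
    pi <- stationary_frequencies(mod)
    for (i in seq_len(mod$k))
      expect_equal(unname(Pinf[i, ]), pi, tolerance = 1e-8)
    expect_equal(rowSums(transition_probabilities(mod, 0.37)),
                 rep(1, mod$k), tolerance = 1e-12)
    expect_error(transition_probabilities(mod, -1), ">= 0")
  }

  # closed form vs generic matrix exponential (eigen oracle), k = 2
  mod <- mk_model(k = 2, q = 0.9)
  Q <- matrix(c(-0.9, 0.9, 0.9, -0.9), 2, 2, byrow = TRUE)
  for (t in c(0.1, 0.5, 2)) {
    eg <- eigen(Q)
    expm <- eg$vectors %*% diag(exp(eg$values * t)) %*% solve(eg$vectors)
    expect_equal(transition_probabilities(mod, t), expm, tolerance = 1e-10)
  }
  # asymmetric closed form vs expm
  mod2 <- mk_model(mode = "asymmetric", q01 = 0.4, q10 = 1.7)
  Q2 <- matrix(c(-0.4, 0.4, 1.7, -1.7), 2, 2, byrow = TRUE)
  eg <- eigen(Q2)
  expm2 <- eg$vectors %*% diag(exp(eg$values * 0.8)) %*% solve(eg$vectors)
  expect_equal(transition_probabilities(mod2, 0.8), expm2,
               tolerance = 1e-10)

  # GTR rows are stochastic and converge to the base frequencies
  g <- gtr_model(exchangeabilities = c(1, 3, 1, 1, 3, 1),
                 base_freqs = c(0.3, 0.2, 0.2, 0.3))
  expect_equal(rowSums(transition_probabilities(g, 0.5)), rep(1, 4),
               tolerance = 1e-10)
  expect_equal(unname(transition_probabilities(g, 400)[2, ]),
               g$base_freqs, tolerance = 1e-8)
})

test_that("pruning log-likelihood equals state enumeration on random trees", {
  # single leaf, equal prior: log(1/2)
  one <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "A",
                        Nnode = 1L, edge.length = 1), class = "phylo")
  cm1 <- character_matrix(matrix("0", 1, 1, dimnames = list("A", NULL)))
  mod <- mk_model(k = 2, q = 1, root_prior = "equal")
  expect_equal(pruning_loglik(one, cm1, mod)$loglik, log(0.5) +
                 log(transition_probabilities(mod, 1)[1, 1] /
                       transition_probabilities(mod, 1)[1, 1]),
               tolerance = 1e-9)

  set.seed(9)
  for (rep in 1:15) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    models <- list(mk_model(k = 2, q = runif(1, 0.2, 2)),
                   mk_model(mode = "asymmetric", q01 = runif(1, 0.2, 2),
                            q10 = runif(1, 0.2, 2)),
                   mk_model(k = 2, q = 0.8, gamma_shape = 0.7))
    mod <- models[[sample(3, 1)]]
    cm <- random_matrix(n, 3, k = 2, miss_prob = 0.2)
    rownames(cm) <- tr$tip.label
    cm <- character_matrix(unclass(cm))
    got <- pruning_loglik(tr, cm, mod)
    for (j in 1:3) {
      col <- unclass(cm)[tr$tip.label, j]
      obs <- ifelse(col == "?", NA, match(col, c("0", "1")))
      expect_equal(got$per_character[j], oracle_loglik(tr, obs, mod),
                   tolerance = 1e-8,
                   info = sprintf("rep %d char %d", rep, j))
    }
  }
})

test_that("likelihood is invariant to root placement under symmetric Mk", {
  set.seed(19)
  tr <- ape::rtree(6)
  cm <- random_matrix(6, 5, k = 2)
  rownames(cm) <- tr$tip.label
  cm <- character_matrix(unclass(cm))
  mod <- mk_model(k = 2, q = 0.6)
  base <- pruning_loglik(tr, cm, mod)$loglik
  for (og in tr$tip.label[1:3]) {
    tr2 <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(pruning_loglik(tr2, cm, mod)$loglik, base,
                 tolerance = 1e-8)
  }
})

test_that("excluded-pattern probabilities behave at the limits and sum correctly", {
  tiny <- ape::read.tree(text = "((A:1e-8,B:1e-8):1e-8,(C:1e-8,D:1e-8):1e-8);")
  mod <- mk_model(k = 2, q = 1)
  expect_equal(excluded_pattern_probability(tiny, mod, "variable"), 1,
               tolerance = 1e-5)

  long <- ape::read.tree(text = "((A:60,B:60):60,(C:60,D:60):60);")
  expect_equal(excluded_pattern_probability(long, mod, "variable"),
               2 / 16, tolerance = 1e-6)
  expect_equal(excluded_pattern_probability(long, mod, "informative"),
               10 / 16, tolerance = 1e-6)

  # correction increases every variable pattern's log-likelihood
  set.seed(3)
  tr <- ape::rtree(5)
  cm <- random_matrix(5, 4, k = 2, miss_prob = 0)
  rownames(cm) <- tr$tip.label
  cm <- character_matrix(unclass(cm))
  raw <- pruning_loglik(tr, cm, mod, "none")$per_character
  cor <- pruning_loglik(tr, cm, mod, "variable")$per_character
  expect_true(all(cor > raw))

  # conditioned probabilities over retained (informative) patterns sum to 1
  tr4 <- ape::read.tree(text = "((A:0.6,B:0.4):0.5,(C:0.3,D:0.7):0.2);")
  pats <- as.matrix(expand.grid(rep(list(c("0", "1")), 4)))
  keep <- apply(pats, 1, function(p) min(table(p)) >= 2 &&
                  length(unique(p)) == 2)
  total <- 0
  P_exc <- excluded_pattern_probability(tr4, mod, "informative")
  for (i in which(keep)) {
    m <- matrix(pats[i, ], 4, 1, dimnames = list(c("A", "B", "C", "D"),
                                                 NULL))
    ll <- pruning_loglik(tr4, character_matrix(m), mod,
                         "informative")$loglik
    total <- total + exp(ll)
  }
  expect_equal(total, 1, tolerance = 1e-8)
  expect_true(P_exc > 0 && P_exc < 1)
})

test_that("discrete gamma has mean one and recovers homogeneity as alpha grows", {
  for (a in c(0.3, 1, 5)) {
    r <- gamma_category_rates(a, 4)
    expect_length(r, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  set.seed(8)
  tr <- ape::rtree(5)
  cm <- random_matrix(5, 6, k = 2)
  rownames(cm) <- tr$tip.label
  cm <- character_matrix(unclass(cm))
  hom <- pruning_loglik(tr, cm, mk_model(k = 2, q = 0.8))$loglik
  gam <- pruning_loglik(tr, cm, mk_model(k = 2, q = 0.8,
                                         gamma_shape = 5000))$loglik
  expect_equal(gam, hom, tolerance = 1e-4)
})

test_that("ML fitting recovers rates and flags the boundary for constant data", {
  tree <- simulate_tree(32, "yule", seed = 11)
  sim <- simulate_discrete_characters(tree, mk_model(q = 0.5), 300,
                                      seed = 12)
  fit <- optimize_model(tree, sim$matrix, mk_model(q = 1), seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$q - 0.5) / 0.5, 0.25)

  # deterministic given seed
  fit2 <- optimize_model(tree, sim$matrix, mk_model(q = 1), seed = 2)
  expect_identical(fit$model$q, fit2$model$q)

  # constant character drives the rate to the lower bound
  const <- character_matrix(matrix("0", length(tree$tip.label), 1,
    dimnames = list(tree$tip.label, NULL)))
  fit3 <- optimize_model(tree, const, mk_model(q = 1), seed = 2)
  expect_lt(fit3$model$q, 1e-4)
})

test_that("nucleotide likelihoods agree with an independent library implementation", {
  skip_if_not_installed("phangorn")
  tr <- simulate_tree(8, "yule", seed = 3)
  g <- gtr_model() # Jukes-Cantor corner of GTR
  al <- simulate_alignment(tr, g, 120, seed = 4)
  mine <- pruning_loglik(tr, al, g)$loglik
  pd <- phangorn::phyDat(unclass(al), type = "DNA")
  ref <- phangorn::pml(tr, pd, model = "JC")
  expect_equal(mine, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})
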