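test_that("tree simulation is seeded, sized, and matches birth theory", {
  t2 <- simulate_tree(2, "yule", seed = 1)
  expect_equal(length(t2$tip.label), 2L)

  a <- simulate_tree(10, "yule", seed = 3)
  b <- simulate_tree(10, "yule", seed = 3)
  expect_identical(write_tree(a), write_tree(b))
  expect_true(ape::is.ultrametric(a, tol = 1e-6))

  # unconstrained pure birth from the root split (two starting
  # lineages): E[N(t)] = 2 exp(b t)
  nb <- vapply(1:300, function(i) {
    tr <- simulate_tree(model = "yule", birth = 1, time = 1.2,
                        seed = 1000 + i)
    if (is.null(tr)) 1 else length(tr$tip.label)
  }, numeric(1))
  expect_equal(mean(nb), 2 * exp(1.2), tolerance = 0.12)
})

test_that("character simulation respects the model and the informative filter", {
  tr <- simulate_tree(40, "yule", seed = 9)
  # near-zero rate: everything constant, informative-only then errors
  sim0 <- simulate_discrete_characters(tr, mk_model(q = 1e-7), 20,
                                       seed = 5)
  expect_true(all(apply(unclass(sim0$matrix), 2,
                        function(x) length(unique(x))) == 1))
  expect_error(simulate_discrete_characters(tr, mk_model(q = 1e-7), 20,
                                            informative_only = TRUE,
                                            seed = 5, max_tries = 3),
               "infeasible")
  expect_error(simulate_discrete_characters(simulate_tree(2, seed = 1),
                                            mk_model(), 5,
                                            informative_only = TRUE),
               "4 taxa")

  # informative-only output really is parsimony-informative
  simI <- simulate_discrete_characters(tr, mk_model(q = 0.5), 50,
                                       informative_only = TRUE, seed = 6)
  counts <- apply(unclass(simI$matrix), 2, function(x) min(table(x)))
  expect_true(all(counts >= 2))
  expect_gte(simI$truth$n_rejected, 0)

  # high rate: leaf frequencies approach equilibrium
  simE <- simulate_discrete_characters(tr, mk_model(q = 30), 400, seed = 7)
  expect_equal(mean(unclass(simE$matrix) == "1"), 0.5, tolerance = 0.05)

  # asymmetric stationary frequency pi0 = q10 / (q01 + q10)
  simA <- simulate_discrete_characters(
    tr, mk_model(mode = "asymmetric", q01 = 0.3, q10 = 2.7), 400,
    seed = 8)
  expect_equal(mean(unclass(simA$matrix) == "0"), 0.9, tolerance = 0.05)

  # truth records match the emitted tips
  expect_equal(unname(unclass(simI$matrix)),
               matrix(as.character(
                 simI$truth$node_states[seq_len(40), ]), 40),
               ignore_attr = TRUE)
})

test_that("alignment simulation hits stationary composition and reproduces", {
  tr <- simulate_tree(12, "yule", seed = 13)
  g <- gtr_model(base_freqs = c(0.4, 0.1, 0.1, 0.4))
  al <- simulate_alignment(tr, g, 2000, seed = 2)
  freq_a <- mean(unclass(al) == "a")
  expect_equal(freq_a, 0.4, tolerance = 0.05)
  expect_identical(unclass(simulate_alignment(tr, g, 50, seed = 4)),
                   unclass(simulate_alignment(tr, g, 50, seed = 4)))
  empty <- simulate_alignment(tr, g, 0, seed = 1)
  expect_equal(ncol(empty), 0L)
})

test_that("missingness masking reaches its target with the right structure", {
  set.seed(2)
  cm <- random_matrix(20, 40, k = 2, miss_prob = 0)
  attr(cm, "partitions") <- list(p1 = 1:20, p2 = 21:40)

  same <- apply_missingness(cm, 0, seed = 1)
  expect_identical(unclass(same)[, ], unclass(cm)[, ])

  u <- apply_missingness(cm, 0.3, "uniform", seed = 3)
  expect_equal(attr(u, "achieved_fraction"), 0.3, tolerance = 0.06)

  tb <- apply_missingness(cm, 0.5, "taxon-block", seed = 4)
  expect_equal(attr(tb, "achieved_fraction"), 0.5, tolerance = 0.05)
  # masked cells come as whole taxon x partition blocks
  mm <- unclass(tb) == "?"
  for (p in partitions_of(tb)) {
    per_taxon <- rowSums(mm[, p, drop = FALSE])
    expect_true(all(per_taxon %in% c(0L, length(p))))
  }

  # achieved fraction concentrates on the target across seeds
  fr <- vapply(1:25, function(s)
    attr(apply_missingness(cm, 0.35, "uniform", seed = s),
         "achieved_fraction"), numeric(1))
  expect_equal(mean(fr), 0.35, tolerance = 0.02)
})

test_that("the study-like generator matches the study's shape and reproduces", {
  ds <- make_study_like_dataset(n_small = 6, n_large = 14,
                                morph_chars = c(8, 20),
                                mol_sites = c(p1 = 120, p2 = 80),
                                seed = 5)
  expect_equal(length(ds$tree$tip.label), 20L)
  expect_equal(ncol(ds$morphology$small), 8L)
  expect_equal(ncol(ds$morphology$large), 20L)
  expect_equal(ncol(ds$molecular), 200L)
  expect_true(all(ds$sequenced_taxa %in% ds$tree$tip.label))

  morph_all <- concatenate_matrices(list(small = ds$morphology$small,
                                         large = ds$morphology$large))
  te <- build_total_evidence(ds$molecular, morph_all)
  frac <- summarize_matrix(te)$missing_fraction
  expect_gte(frac, 0.4)
  expect_lte(frac, 0.8)

  ds2 <- make_study_like_dataset(n_small = 6, n_large = 14,
                                 morph_chars = c(8, 20),
                                 mol_sites = c(p1 = 120, p2 = 80),
                                 seed = 5)
  expect_identical(unclass(ds$molecular)[, ], unclass(ds2$molecular)[, ])
  expect_identical(write_tree(ds$tree), write_tree(ds2$tree))

  # a noise-free analogue is solvable end to end
  tr <- simulate_tree(8, "yule", seed = 77)
  cm <- clean_split_matrix(tr, reps = 3)
  found <- mp_search(cm, search_config(n_random_additions = 2,
                                       swap_strategy = "SPR", seed = 1))
  expect_same_topology(ape::unroot(found$trees[[1]]), ape::unroot(tr))
})
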