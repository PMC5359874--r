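#' Mk model for discrete characters
#'
#' Continuous-time Markov model with k states.  In `"symmetric"` mode all
#' changes share one rate: `q` is the total leaving rate, i.e. branch
#' lengths are in expected substitutions when `q = 1`.  In
#' `"asymmetric"` mode (k = 2 only) gains (0 to 1, rate `q01`) and losses
#' (1 to 0, rate `q10`) differ; this is the asymmetrical 2-parameter model
#' (aMk2), whose stationary frequency of state 0 is `q10/(q01+q10)`.
#'
#' @param k number of states (default 2).
#' @param mode `"symmetric"` (Mk1-style) or `"asymmetric"` (aMk2, k = 2).
#' @param q total leaving rate (symmetric mode).
#' @param q01,q10 gain and loss rates (asymmetric mode).
#' @param gamma_shape optional shape of a discrete-gamma rate distribution
#'   across characters (`NULL` = rate-homogeneous).
#' @param n_categories number of discrete gamma categories (default 4).
#' @param root_prior `"equilibrium"` (default), `"equal"`, or a numeric
#'   probability vector of length k.
#' @return an object of class `mk_model`.
#' @export
mk_model <- function(k = 2, mode = c("symmetric", "asymmetric"),
                     q = 1, q01 = NULL, q10 = NULL,
                     gamma_shape = NULL, n_categories = 4,
                     root_prior = "equilibrium") {
  mode <- match.arg(mode)
  if (mode == "asymmetric") {
    if (k != 2) stop_glasstree("asymmetric mode requires k = 2")
    q01 <- q01 %||% 1; q10 <- q10 %||% 1
    stopifnot(q01 > 0, q10 > 0)
  } else {
    stopifnot(q > 0)
  }
  if (!is.null(gamma_shape)) stopifnot(gamma_shape > 0)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k,
              abs(sum(root_prior) - 1) < 1e-8)
  } else {
    root_prior <- match.arg(root_prior, c("equilibrium", "equal"))
  }
  structure(list(k = as.integer(k), mode = mode, q = q, q01 = q01, q10 = q10,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 root_prior = root_prior),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  if (x$mode == "symmetric")
    cat(sprintf("Mk model: k=%d, symmetric, q=%.4g", x$k, x$q))
  else
    cat(sprintf("Mk model: k=2, asymmetric, q01=%.4g, q10=%.4g", x$q01, x$q10))
  if (!is.null(x$gamma_shape))
    cat(sprintf(", gamma(alpha=%.3g, %d cat.)", x$gamma_shape,
                x$n_categories))
  cat("\n")
  invisible(x)
}

#' GTR model for nucleotides
#'
#' General-time-reversible substitution model, normalized to one expected
#' substitution per unit branch length, optionally with discrete-gamma
#' rate variation across sites.
#'
#' @param exchangeabilities six positive rates in the order AC, AG, AT, CG,
#'   CT, GT.
#' @param base_freqs stationary frequencies of A, C, G, T (sum to 1).
#' @param gamma_shape,n_categories as in [mk_model()].
#' @return an object of class `gtr_model` (also inherits `mk_model`
#'   behavior where generic).
#' @export
gtr_model <- function(exchangeabilities = rep(1, 6),
                      base_freqs = rep(0.25, 4),
                      gamma_shape = NULL, n_categories = 4) {
  stopifnot(length(exchangeabilities) == 6, all(exchangeabilities > 0),
            length(base_freqs) == 4, abs(sum(base_freqs) - 1) < 1e-8)
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- exchangeabilities[c(1, 2, 4, 3, 5, 6)]
  Q <- Q + t(Q)
  Q <- Q * rep(base_freqs, each = 4)   # Q[i,j] = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freqs * diag(Q))
  Q <- Q / mu
  structure(list(k = 4L, Q = Q, base_freqs = base_freqs,
                 exchangeabilities = exchangeabilities,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 root_prior = "equilibrium"),
            class = c("gtr_model", "mk_model"))
}

#' Stationary distribution of a model
#' @param model an `mk_model` or `gtr_model`.
#' @return numeric vector of state frequencies.
#' @export
stationary_frequencies <- function(model) {
  if (inherits(model, "gtr_model")) return(model$base_freqs)
  if (model$mode == "symmetric") return(rep(1 / model$k, model$k))
  tot <- model$q01 + model$q10
  c(model$q10 / tot, model$q01 / tot)
}

root_prior_vector <- function(model) {
  if (is.numeric(model$root_prior)) return(model$root_prior)
  if (model$root_prior == "equal") return(rep(1 / model$k, model$k))
  stationary_frequencies(model)
}

#' Transition probability matrix
#'
#' Closed forms for the symmetric k-state and asymmetric 2-state models;
#' eigendecomposition of the rate matrix for GTR.
#'
#' @param model an `mk_model` or `gtr_model`.
#' @param t branch length (>= 0).
#' @param rate optional rate multiplier (gamma category rate).
#' @return a k x k row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (t < 0) stop_glasstree("branch length must be >= 0")
  t <- t * rate
  if (inherits(model, "gtr_model")) {
    eg <- eigen_gtr(model)
    P <- eg$U %*% diag(exp(eg$values * t), 4) %*% eg$Uinv
    P[P < 0] <- 0
    return(P / rowSums(P))
  }
  k <- model$k
  if (model$mode == "symmetric") {
    mu <- model$q / (k - 1)               # per-pair rate
    stay <- 1 / k + (k - 1) / k * exp(-k * mu * t)
    move <- (1 - stay) / (k - 1)
    P <- matrix(move, k, k)
    diag(P) <- stay
    P
  } else {
    tot <- model$q01 + model$q10
    pi0 <- model$q10 / tot
    pi1 <- model$q01 / tot
    e <- exp(-tot * t)
    matrix(c(pi0 + pi1 * e, pi0 - pi0 * e,
             pi1 - pi1 * e, pi1 + pi0 * e), 2, 2)
  }
}

eigen_gtr <- function(model) {
  if (!is.null(model$.eigen)) return(model$.eigen)
  # symmetrize: B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric
  sp <- sqrt(model$base_freqs)
  B <- diag(sp) %*% model$Q %*% diag(1 / sp)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / sp) %*% eg$vectors
  Uinv <- t(eg$vectors) %*% diag(sp)
  list(values = eg$values, U = U, Uinv = Uinv)
}

#' Discrete gamma category rates
#'
#' Equal-probability categories, each represented by its within-category
#' mean (the standard discretization); mean rate is 1.
#'
#' @param alpha gamma shape.
#' @param n number of categories.
#' @return numeric vector of n rates.
#' @export
gamma_category_rates <- function(alpha, n = 4) {
  if (is.null(alpha)) return(1)
  # X ~ Gamma(alpha, alpha); E[X | bin] scales as
  # n * (F_{alpha+1}(b_{i+1}) - F_{alpha+1}(b_i)) with the same rate
  b <- qgamma(seq(0, 1, length.out = n + 1), shape = alpha, rate = alpha)
  n * diff(pgamma(b, shape = alpha + 1, rate = alpha))
}

## ---- pruning likelihood -------------------------------------------------

# Map matrix cells to 1-based state indices (NA = missing), plus symbols.
state_indices <- function(matrix, model) {
  m <- tolower(unclass(matrix))
  if (inherits(model, "gtr_model") || inherits(matrix, "nt_alignment")) {
    symbols <- c("a", "c", "g", "t")
    m[m == "u"] <- "t"
    m[m %in% c(IUPAC_AMBIGUITY, "-", "?", ".")] <- NA
  } else {
    miss <- missing_symbol(matrix) %||% "?"
    m[m == miss | m == "-"] <- NA
    symbols <- sort(unique(as.vector(m[!is.na(m)])))
    if (length(symbols) > model$k)
      stop_glasstree("matrix has ", length(symbols),
                     " observed states but model has k = ", model$k)
    digits <- as.character(seq_len(model$k) - 1L)
    if (all(symbols %in% digits)) {
      # canonical digit coding: "0" is always state 0, "1" state 1, ...
      # even when a character happens not to observe every symbol
      symbols <- digits
    } else if (length(symbols) < model$k) {
      symbols <- c(symbols, paste0(".pad", seq_len(model$k - length(symbols))))
    }
  }
  idx <- matrix(match(m, symbols), nrow(m), ncol(m),
                dimnames = dimnames(m))
  list(idx = idx, symbols = symbols)
}

# Edge-wise transition matrices for a rate multiplier.
edge_pmats <- function(model, lengths, rate) {
  lapply(lengths, function(t) transition_probabilities(model, t, rate))
}

tree_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    structure(rep(1, nrow(tree$edge)), unit_lengths = TRUE)
  } else {
    if (any(tree$edge.length < 0))
      stop_glasstree("negative branch lengths")
    tree$edge.length
  }
}

# Core pruning over patterns for one rate category.
# tip_idx: n_tip x n_pat matrix of state indices (NA = missing).
# Returns list(partials_root = n_pat x k, logscale = n_pat, down = list of
# per-node partial matrices if keep_partials).
prune_category <- function(tree, tip_idx, k, P, keep_partials = FALSE) {
  n_tip <- nrow(tip_idx)
  n_pat <- ncol(tip_idx)
  n_all <- n_tip + tree$Nnode
  kids_e <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  down <- vector("list", n_all)
  logscale <- numeric(n_pat)
  for (i in seq_len(n_tip)) {
    L <- matrix(0, n_pat, k)
    ok <- !is.na(tip_idx[i, ])
    L[cbind(which(ok), tip_idx[i, ok])] <- 1
    L[!ok, ] <- 1
    down[[i]] <- L
  }
  post <- rev(node_preorder(tree))
  for (v in post) {
    if (v <= n_tip) next
    L <- matrix(1, n_pat, k)
    for (e in kids_e[[as.character(v)]]) {
      ch <- tree$edge[e, 2]
      L <- L * (down[[ch]] %*% t(P[[e]]))
    }
    mx <- pmax(apply(L, 1, max), 1e-300)
    L <- L / mx
    logscale <- logscale + log(mx)
    down[[v]] <- L
  }
  list(root = down[[n_tip + 1L]], logscale = logscale,
       down = if (keep_partials) down else NULL)
}

# Per-pattern log-likelihoods, gamma-averaged.  tip_idx rows must be in
# tree tip order.
pattern_logliks <- function(tree, tip_idx, model) {
  lens <- tree_branch_lengths(tree)
  rates <- gamma_category_rates(model$gamma_shape, model$n_categories)
  prior <- root_prior_vector(model)
  k <- model$k
  percat <- vapply(rates, function(r) {
    P <- edge_pmats(model, lens, r)
    pr <- prune_category(tree, tip_idx, k, P)
    log(pmax(as.vector(pr$root %*% prior), 1e-300)) + pr$logscale
  }, numeric(ncol(tip_idx)))
  percat <- matrix(percat, ncol = length(rates))
  # average likelihood over equally weighted categories (log-sum-exp)
  mx <- apply(percat, 1, max)
  mx + log(rowMeans(exp(percat - mx)))
}

#' Probability of excluded patterns (ascertainment correction)
#'
#' When matrices contain only variable (or only parsimony-informative)
#' characters, the likelihood must condition on that ascertainment.  This
#' computes the probability that a character is constant
#' (`"variable"` mode) or constant-or-singleton (`"informative"` mode,
#' where a singleton has exactly one leaf differing from the rest), by
#' pruning over the corresponding complete leaf patterns.
#'
#' @param tree phylo with branch lengths (unit lengths assumed otherwise).
#' @param model an `mk_model`.
#' @param mode `"variable"` or `"informative"`.
#' @return probability in (0, 1).
#' @export
excluded_pattern_probability <- function(tree, model,
                                         mode = c("variable", "informative")) {
  mode <- match.arg(mode)
  k <- model$k
  n_tip <- length(tree$tip.label)
  pats <- matrix(rep(seq_len(k), each = n_tip), n_tip, k) # constant patterns
  if (mode == "informative" && n_tip >= 2) {
    for (i in seq_len(n_tip)) {
      for (bg in seq_len(k)) for (alt in seq_len(k)) {
        if (alt == bg) next
        col <- rep(bg, n_tip); col[i] <- alt
        pats <- cbind(pats, col)
      }
    }
  }
  ll <- pattern_logliks(tree, pats, model)
  p <- sum(exp(ll))
  min(max(p, 0), 1 - 1e-12)
}

#' Log-likelihood of a character matrix under an Mk/GTR model
#'
#' Felsenstein pruning over unique patterns, with per-node scaling,
#' equal-weight discrete-gamma rate categories, and optional
#' ascertainment-bias correction: with correction, each character's
#' log-likelihood is reduced by `log(1 - P_excluded)`.
#'
#' Trees without branch lengths are scored with all lengths set to 1
#' (the convention for parsimony trees); this is flagged in the result.
#'
#' @param tree phylo; leaves must be scored (or missing) in `matrix`.
#' @param matrix a [character_matrix()] or [nt_alignment()].
#' @param model an `mk_model` or `gtr_model`.
#' @param ascertainment `"none"`, `"variable"` or `"informative"`.
#' @return list with `loglik`, `per_character`, `P_excluded`,
#'   `unit_branch_lengths`.
#' @export
pruning_loglik <- function(tree, matrix, model,
                           ascertainment = c("none", "variable",
                                             "informative")) {
  ascertainment <- match.arg(ascertainment)
  si <- state_indices(matrix, model)
  missing_tips <- setdiff(tree$tip.label, rownames(si$idx))
  if (length(missing_tips) > 0)
    stop_glasstree("leaf '", missing_tips[1], "' absent from matrix")
  idx <- si$idx[tree$tip.label, , drop = FALSE]
  key <- apply(idx, 2, paste, collapse = "\r")
  upat <- unique(key)
  map <- match(key, upat)
  tip_idx <- idx[, match(upat, key), drop = FALSE]
  ll_pat <- pattern_logliks(tree, tip_idx, model)
  per <- ll_pat[map]
  P_exc <- 0
  if (ascertainment != "none") {
    P_exc <- excluded_pattern_probability(tree, model, ascertainment)
    per <- per - log(1 - P_exc)
  }
  list(loglik = sum(per), per_character = per, P_excluded = P_exc,
       unit_branch_lengths = is.null(tree$edge.length))
}

## ---- maximum-likelihood fitting ----------------------------------------

#' Fit model parameters by maximum likelihood
#'
#' Bounded quasi-Newton optimization on the log scale with seeded
#' multi-start (the default 3 starts: the template's values plus random
#' log-uniform draws).  Free parameters may be any of `"q"`, `"q01"`,
#' `"q10"`, `"gamma_shape"` for Mk models.
#'
#' @param tree phylo.
#' @param matrix a [character_matrix()].
#' @param model template `mk_model` providing fixed values and mode.
#' @param free_parameters character vector of parameter names to estimate.
#' @param ascertainment passed to [pruning_loglik()].
#' @param n_starts number of optimization starts (>= 1).
#' @param seed RNG seed for the extra starts.
#' @param lower,upper rate bounds (default 1e-6 and 100).
#' @return list with `model` (fitted), `loglik`, `converged`, `starts`
#'   (per-start diagnostics).
#' @export
optimize_model <- function(tree, matrix, model,
                           free_parameters = if (model$mode == "symmetric")
                             "q" else c("q01", "q10"),
                           ascertainment = "none",
                           n_starts = 3, seed = 1L,
                           lower = 1e-6, upper = 100) {
  stopifnot(length(free_parameters) >= 1)
  obj <- function(logpar) {
    m2 <- model
    m2[free_parameters] <- as.list(exp(logpar))
    res <- tryCatch(pruning_loglik(tree, matrix, m2, ascertainment)$loglik,
                    error = function(e) -Inf)
    if (!is.finite(res)) 1e10 else -res
  }
  p0 <- log(pmin(pmax(unlist(model[free_parameters]), lower), upper))
  starts <- list(p0)
  if (n_starts > 1) {
    extra <- with_seed(seed, replicate(n_starts - 1, {
      runif(length(free_parameters), log(0.01), log(10))
    }, simplify = FALSE))
    starts <- c(starts, extra)
  }
  fits <- lapply(starts, function(s) {
    nlminb(s, obj, lower = log(lower), upper = log(upper),
           control = list(abs.tol = 1e-8, rel.tol = 1e-10, eval.max = 500,
                          iter.max = 300))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  fitted <- model
  fitted[free_parameters] <- as.list(exp(best$par))
  list(model = fitted, loglik = -best$objective,
       converged = best$convergence == 0 ||
         grepl("converg", best$message, ignore.case = TRUE),
       starts = data.frame(
         objective = vapply(fits, `[[`, numeric(1), "objective"),
         convergence = vapply(fits, `[[`, numeric(1), "convergence")))
}

#' Optimize branch lengths under a likelihood model
#'
#' Coordinate-wise Brent optimization of each branch, repeated for a few
#' sweeps.  Intended for polishing lengths on a fixed topology (full ML
#' tree search is out of scope).
#'
#' @param tree phylo (unit lengths assumed if absent).
#' @param matrix data matrix or alignment.
#' @param model an `mk_model` or `gtr_model`.
#' @param sweeps number of passes over all edges.
#' @param max_length upper bound per branch.
#' @return list with `tree` (lengths updated) and `loglik`.
#' @export
optimize_branch_lengths <- function(tree, matrix, model, sweeps = 2,
                                    max_length = 20) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  for (s in seq_len(sweeps)) {
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        t2 <- tree
        t2$edge.length[e] <- x
        -pruning_loglik(t2, matrix, model)$loglik
      }
      opt <- stats::optimize(f, c(1e-8, max_length), tol = 1e-6)
      tree$edge.length[e] <- opt$minimum
    }
  }
  list(tree = tree, loglik = pruning_loglik(tree, matrix, model)$loglik)
}
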