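# Posterior sampling: configuration, initialization, the full samplers, and
# R-level access to the individual full-conditional updates (exposed mainly
# for diagnostics and distributional testing).

#' MCMC configuration
#'
#' Settings for [fitGroM()].  Defaults follow the package's standard
#' estimation schedule: 15000 iterations, 10000 burn-in, thinning 5,
#' Metropolis-Hastings-within-Gibbs with lognormal proposal scale
#' `sigmaAlpha = 0.02` and Gamma(2, 1) hyperprior on the total concentration
#' `alpha_0` (with a uniform prior on `alpha / alpha_0` over the simplex).
#' The fully Gibbs sampler instead places independent Gamma(`a0`, `b0`)
#' priors on each `alpha_k` and updates them through Beta/CRT augmentation.
#'
#' @param iterations total MCMC iterations.
#' @param burnin discarded initial iterations (`< iterations`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param sampler `"mh"` (Metropolis-Hastings-within-Gibbs) or `"gibbs"`
#'   (fully Gibbs with Beta/CRT augmentation).
#' @param sigmaAlpha lognormal proposal scale for the MH alpha update.
#' @param aAlpha,bAlpha Gamma(shape, rate) hyperprior on `alpha_0` (MH path).
#' @param a0,b0 Gamma(shape, rate) prior on each `alpha_k` (Gibbs path).
#' @param seed RNG seed used by [fitGroM()]; `NULL` continues the current
#'   stream.
#' @param init `"prior_random"` (draw every unknown from its prior) or
#'   `"provided"` (pass a state to [fitGroM()]).
#' @param collapseEvery every `collapseEvery`-th iteration the grouping is
#'   updated by the partially collapsed move (each `s_j` drawn with the
#'   latent assignments integrated out, then `z` redrawn); other iterations
#'   use the plain conditional-on-`z` grouping update.  `0` disables the
#'   collapsed move.  See the vignette: the conditional-on-`z` update alone
#'   cannot cross the likelihood barriers between grouping configurations,
#'   so chains started from random initial values freeze in merged
#'   groupings without this move.
#' @param anneal length of the annealed burn-in ramp: during the first
#'   `anneal` iterations the data term of the collapsed grouping move is
#'   scaled by `it/anneal`, letting items sort across groups before the
#'   grouping likelihood barriers lock in; the concentration vector is kept
#'   away from zero during the ramp so no profile dies while the grouping is
#'   still sorting.  Must not exceed `burnin` (the retained draws always
#'   come from the exact kernel).  Default `min(burnin, 2400)`; `0` disables
#'   annealing.
#' @return a validated list of class `mcmcControl`.
#' @export
mcmcControl <- function(iterations = 15000L, burnin = 10000L, thin = 5L,
                        sampler = c("mh", "gibbs"), sigmaAlpha = 0.02,
                        aAlpha = 2, bAlpha = 1, a0 = 1, b0 = 1,
                        seed = NULL, init = c("prior_random", "provided"),
                        collapseEvery = 25L, anneal = NULL) {
  sampler <- match.arg(sampler)
  init <- match.arg(init)
  iterations <- as.integer(iterations)
  burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (burnin < 0L || thin < 1L) stop("need burnin >= 0 and thin >= 1")
  if (sigmaAlpha <= 0) stop("sigmaAlpha must be positive")
  if (any(c(aAlpha, bAlpha, a0, b0) <= 0))
    stop("hyperparameters must be positive")
  collapseEvery <- as.integer(collapseEvery)
  if (collapseEvery < 0L) stop("collapseEvery must be >= 0")
  if (is.null(anneal)) anneal <- min(burnin, 2400L)
  anneal <- as.integer(anneal)
  if (anneal > burnin)
    stop("anneal must not exceed burnin (retained draws must come from the",
         " exact kernel)")
  structure(list(iterations = iterations, burnin = burnin, thin = thin,
                 sampler = sampler, sigmaAlpha = sigmaAlpha,
                 aAlpha = aAlpha, bAlpha = bAlpha, a0 = a0, b0 = b0,
                 seed = seed, init = init, collapseEvery = collapseEvery,
                 anneal = anneal),
            class = "mcmcControl")
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), n, byrow = TRUE)
  bad <- rowSums(x) <= 0
  if (any(bad)) x[bad, which.max(alpha)] <- 1
  x / rowSums(x)
}

# Draw a full chain state from the priors.
.priorState <- function(n, p, d, G, K, control) {
  xi <- as.vector(.rdirichlet(1L, rep(1, G)))
  s <- sample.int(G, p, replace = TRUE, prob = xi)
  lambda <- lapply(seq_len(p), function(j)
    t(.rdirichlet(K, rep(1, d[j]))))
  alpha <- if (control$sampler == "mh") {
    a0tot <- rgamma(1L, shape = control$aAlpha, rate = control$bAlpha)
    as.vector(a0tot * .rdirichlet(1L, rep(1, K)))
  } else {
    rgamma(K, shape = control$a0, rate = control$b0)
  }
  alpha <- pmax(alpha, 1e-8)
  Pi <- .rdirichlet(n, alpha)
  Z <- matrix(0L, n, G)
  for (g in seq_len(G))
    Z[, g] <- max.col(log(Pi) + matrix(-log(-log(runif(n * K))), n), "first")
  list(s = s, lambda = lambda, Pi = Pi, Z = Z, xi = xi, alpha = alpha)
}

# Validate/coerce a response matrix; d taken from the "categories" attribute
# when present, otherwise from the observed maxima.
.checkResponses <- function(y, d = NULL) {
  y <- as.matrix(y)
  if (anyNA(y)) {
    idx <- which(is.na(y), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing response at row %d, column %d", idx[1], idx[2]))
  }
  if (any(y != round(y))) stop("responses must be integer category codes")
  storage.mode(y) <- "integer"
  if (is.null(d)) d <- attr(y, "categories")
  if (is.null(d)) d <- apply(y, 2L, max)
  d <- as.integer(d)
  if (length(d) != ncol(y)) stop("categories must name every item")
  for (j in seq_len(ncol(y))) {
    if (any(y[, j] < 1L))
      stop(sprintf("item %d has codes below 1 (1-based coding required)", j))
    if (any(y[, j] > d[j]))
      stop(sprintf("item %d has codes above its category count %d", j, d[j]))
    if (d[j] < 2L) stop(sprintf("item %d must have at least 2 categories", j))
  }
  attr(y, "categories") <- d
  y
}

#' Fit a dimension-grouped mixed membership model by MCMC
#'
#' Cycles the full-conditional updates in the order: table columns, then
#' membership scores, then per-group assignments, then the item grouping and
#' its weights, then the Dirichlet concentrations (Metropolis-Hastings with
#' lognormal proposals, or the Beta/CRT augmented Gibbs step, per
#' `control$sampler`).  Per-draw pointwise log-likelihood values are stored
#' at thinning time so [waic()] is exact with respect to the retained draws.
#'
#' @param y `n x p` integer response matrix (or [GroMSim-class]), 1-based
#'   category codes; per-item category counts are taken from a `categories`
#'   attribute when present, else from the observed maxima.
#' @param G,K numbers of variable groups and extreme profiles.
#' @param control an [mcmcControl()] list.
#' @param init list with elements `s`, `lambda`, `Pi`, `Z`, `xi`, `alpha`
#'   when `control$init == "provided"`.
#' @return a [GroMFit-class].
#' @examples
#' sim <- simulateResponses(benchmarkScenario(2, 30, 6), n = 60, seed = 1)
#' fit <- fitGroM(responses(sim), G = 6, K = 2,
#'                control = mcmcControl(iterations = 200, burnin = 100,
#'                                      thin = 2, seed = 1))
#' fit
#' @export
fitGroM <- function(y, G, K, control = mcmcControl(), init = NULL) {
  if (is(y, "GroMSim")) y <- responses(y)
  if (!inherits(control, "mcmcControl"))
    stop("control must come from mcmcControl()")
  y <- .checkResponses(y)
  d <- attr(y, "categories")
  n <- nrow(y); p <- ncol(y)
  G <- as.integer(G); K <- as.integer(K)
  if (G < 1L || K < 1L) stop("G and K must be >= 1")
  if (!is.null(control$seed)) set.seed(control$seed)
  state <- if (control$init == "provided") {
    if (is.null(init)) stop("init state required when init = 'provided'")
    init
  } else {
    .priorState(n, p, d, G, K, control)
  }
  lamCube <- if (is.list(state$lambda))
    .tablesToCube(state$lambda, d, K) else state$lambda
  res <- cpp_run_chain(
    y - 1L, d, G, K,
    control$iterations, control$burnin, control$thin,
    control$sampler == "gibbs",
    control$sigmaAlpha, control$aAlpha, control$bAlpha,
    control$a0, control$b0, control$collapseEvery, control$anneal,
    as.integer(state$s) - 1L, lamCube, state$Pi,
    state$Z - 1L, state$xi, state$alpha)
  sDraws <- res$s + 1L
  storage.mode(sDraws) <- "integer"
  new("GroMFit",
      draws = list(s = sDraws, alpha = res$alpha, xi = res$xi,
                   lambda = res$lambda),
      logLik = res$logLik,
      acceptance = as.numeric(res$accept),
      control = unclass(control),
      d = d,
      itemNames = colnames(y) %||% sprintf("item%d", seq_len(p)),
      n = as.integer(n), G = G, K = K,
      finalState = res$finalState)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ------------------------------------------------------------------------
# Single full-conditional updates.  `state` is a plain list with elements
# s (1-based groups), lambda (list of tables), Pi, Z (1-based), xi, alpha;
# `y` uses 1-based categories.  Each function redraws one block.

.stateCube <- function(state, d, K)
  .tablesToCube(state$lambda, d, K)

#' Single full-conditional updates
#'
#' Low-level access to the sampler's individual blocks, operating on a plain
#' state list (`s`, `lambda`, `Pi`, `Z`, `xi`, `alpha`; 1-based codes).
#' Intended for distributional diagnostics; [fitGroM()] runs the same
#' compiled updates internally.
#'
#' * `updateItemTables`: table columns from Dirichlet(1 + category counts).
#' * `updateMembership`: membership rows from
#'   Dirichlet(`alpha` + assignment counts).
#' * `updateAssignments`: per-group profile assignments from their
#'   categorical full conditional (log space).
#' * `updateGrouping`: item grouping from its categorical full conditional,
#'   then the group weights `xi` from Dirichlet(1 + group counts).
#' * `updateAlphaMH`: lognormal-proposal Metropolis-Hastings step for
#'   `alpha`; attaches the acceptance indicator as attribute `accepted`.
#' * `updateAlphaGibbs`: Beta/CRT augmented Gibbs step for `alpha`.
#'
#' @param state chain state list.
#' @param y 1-based integer response matrix.
#' @param d per-item category counts.
#' @param control an [mcmcControl()] list (hyperparameters).
#' @return the state list with the block redrawn.
#' @name updates
NULL

#' @rdname updates
#' @export
updateItemTables <- function(state, y, d = apply(y, 2L, max)) {
  K <- length(state$alpha)
  cube <- cpp_update_lambda(y - 1L, as.integer(d), state$s - 1L,
                            state$Z - 1L, K, max(d))
  state$lambda <- .cubeToTables(cube, d)
  state
}

#' @rdname updates
#' @export
updateMembership <- function(state, y) {
  out <- cpp_update_pi(state$Z - 1L, state$alpha)
  state$Pi <- out$Pi
  state$logPi <- out$logPi
  state$Slog <- as.numeric(out$Slog)
  state
}

#' @rdname updates
#' @export
updateAssignments <- function(state, y, d = apply(y, 2L, max)) {
  K <- length(state$alpha)
  Z <- cpp_update_z(y - 1L, state$s - 1L, .stateCube(state, d, K),
                    state$Pi, length(state$xi))
  state$Z <- Z + 1L
  state
}

#' @rdname updates
#' @export
updateGrouping <- function(state, y, d = apply(y, 2L, max)) {
  K <- length(state$alpha)
  out <- cpp_update_s(y - 1L, .stateCube(state, d, K), state$Z - 1L,
                      state$xi, length(state$xi))
  state$s <- as.integer(out$s) + 1L
  state$xi <- as.numeric(out$xi)
  state
}

#' @rdname updates
#' @export
updateGroupingCollapsed <- function(state, y, d = apply(y, 2L, max)) {
  K <- length(state$alpha)
  out <- cpp_update_s_collapsed(y - 1L, .stateCube(state, d, K), state$Pi,
                                state$s - 1L, state$xi, length(state$xi))
  state$s <- as.integer(out$s) + 1L
  state$xi <- as.numeric(out$xi)
  state
}

#' @rdname updates
#' @export
updateAlphaMH <- function(state, y, control = mcmcControl()) {
  Slog <- state$Slog %||% colSums(log(state$Pi))
  out <- cpp_update_alpha_mh(state$alpha, Slog, nrow(state$Pi),
                             control$sigmaAlpha, control$aAlpha,
                             control$bAlpha)
  state$alpha <- as.numeric(out$alpha)
  attr(state, "accepted") <- out$accepted
  attr(state, "logRatio") <- out$logRatio
  state
}

#' @rdname updates
#' @export
updateAlphaGibbs <- function(state, y, control = mcmcControl()) {
  state$alpha <- as.numeric(
    cpp_update_alpha_gibbs(state$alpha, state$Z - 1L, control$a0,
                           control$b0))
  state
}

#' Chinese Restaurant Table draw
#'
#' Number of occupied tables after `m` sequential arrivals at concentration
#' `r`: a sum over `l = 1, ..., m` of independent Bernoulli draws with
#' success probability r/(r+l-1).  Gives 0 for `m = 0` and is always at
#' least 1 for `m >= 1`.
#'
#' @param m nonnegative integer count.
#' @param r positive concentration.
#' @return an integer table count in `[min(1, m), m]`.
#' @export
sampleCRT <- function(m, r) {
  if (m < 0 || m != round(m)) stop("m must be a nonnegative integer")
  if (r <= 0) stop("r must be positive")
  cpp_rcrt(as.integer(m), r)
}

#' Pointwise log-likelihood under a given state
#'
#' `log p(y_i | theta)` for every subject, with the membership scores held
#' at their current values (the quantity accumulated for WAIC).
#'
#' @inheritParams updates
#' @return numeric vector of length `n`.
#' @export
pointwiseLogLik <- function(state, y, d = apply(y, 2L, max)) {
  K <- length(state$alpha)
  as.numeric(cpp_pointwise_loglik(y - 1L, state$s - 1L,
                                  .stateCube(state, d, K), state$Pi,
                                  length(state$xi)))
}
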