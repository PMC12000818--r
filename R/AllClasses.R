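#' Parameter set of a dimension-grouped mixed membership model
#'
#' A `GroMModel` bundles the three population parameter blocks of the model:
#' the item grouping (a partition of the `p` items into `G` groups, stored as
#' a label vector `groups`), the per-item conditional probability tables
#' (`tables`, one `d_j x K` matrix per item whose column `k` is the response
#' distribution of item `j` under extreme latent profile `k`), and the
#' Dirichlet concentration vector `alpha` of the membership scores.
#'
#' Column sums of every table must equal one.  The constructor renormalizes
#' columns whose sums deviate from one by less than `1e-6` and rejects larger
#' deviations; the stored object satisfies the column-sum invariant to
#' `1e-10`.
#'
#' @slot groups integer vector of length `p`, group label of each item in
#'   `1..nGroups`.
#' @slot nGroups number of groups `G` (some may be empty).
#' @slot tables list of `p` numeric matrices, item `j`'s of size `d_j x K`.
#' @slot alpha positive numeric vector of length `K`.
#' @slot label free-form tag (e.g. the benchmark scenario name).
#'
#' @seealso [GroMModel()], [benchmarkScenario()], [simulateResponses()]
#' @export
setClass("GroMModel",
  representation(groups = "integer", nGroups = "integer",
                 tables = "list", alpha = "numeric", label = "character"))

setValidity("GroMModel", function(object) {
  p <- length(object@groups)
  G <- object@nGroups
  if (length(G) != 1L || G < 1L) return("nGroups must be a single integer >= 1")
  if (any(object@groups < 1L) || any(object@groups > G))
    return("item group labels must lie in 1..nGroups")
  if (length(object@tables) != p)
    return("need one probability table per item")
  K <- length(object@alpha)
  if (K < 1L || any(!is.finite(object@alpha)) || any(object@alpha <= 0))
    return("alpha must be positive and finite")
  for (j in seq_len(p)) {
    tab <- object@tables[[j]]
    if (!is.matrix(tab) || !is.numeric(tab))
      return(sprintf("table %d is not a numeric matrix", j))
    if (nrow(tab) < 2L)
      return(sprintf("item %d must have at least 2 categories", j))
    if (ncol(tab) != K)
      return(sprintf("table %d must have K = %d columns", j, K))
    if (any(tab < 0) || any(tab > 1))
      return(sprintf("table %d has entries outside [0, 1]", j))
    if (any(abs(colSums(tab) - 1) > 1e-10))
      return(sprintf("columns of table %d do not sum to 1 (tol 1e-10)", j))
  }
  TRUE
})

#' Construct a GroMModel
#'
#' @param groups integer vector of item group labels in `1..nGroups`.
#' @param tables list of `d_j x K` probability tables, one per item; each
#'   column must sum to one (deviations below `1e-6` are renormalized).
#' @param alpha positive Dirichlet concentration vector of length `K`.
#' @param nGroups number of groups; defaults to `max(groups)`.
#' @param label optional free-form tag.
#' @return A [GroMModel-class] object.
#' @examples
#' m <- GroMModel(groups = c(1, 1, 2, 2),
#'                tables = rep(list(matrix(c(.8, .2, .3, .7), 2)), 4),
#'                alpha = c(0.4, 0.5))
#' nItems(m)
#' @export
GroMModel <- function(groups, tables, alpha, nGroups = max(groups),
                      label = "") {
  groups <- as.integer(groups)
  tables <- lapply(seq_along(tables), function(j) {
    tab <- as.matrix(tables[[j]])
    storage.mode(tab) <- "double"
    cs <- colSums(tab)
    if (any(abs(cs - 1) >= 1e-6))
      stop(sprintf("columns of table %d deviate from sum 1 by >= 1e-6", j))
    sweep(tab, 2L, cs, "/")
  })
  new("GroMModel", groups = groups, nGroups = as.integer(nGroups),
      tables = tables, alpha = as.numeric(alpha),
      label = as.character(label))
}

#' Dataset simulated from a dimension-grouped mixed membership model
#'
#' Holds the `n x p` categorical response matrix together with the latent
#' quantities that generated it (membership scores and per-group profile
#' assignments), the generating [GroMModel-class] and the seed used.
#'
#' @slot responses integer `n x p` matrix with entries in `1..d_j`.
#' @slot membership numeric `n x K` matrix of Dirichlet membership scores.
#' @slot assignments integer `n x G` matrix of profile realizations.
#' @slot model the generating [GroMModel-class].
#' @slot seed the RNG seed.
#' @export
setClass("GroMSim",
  representation(responses = "matrix", membership = "matrix",
                 assignments = "matrix", model = "GroMModel",
                 seed = "numeric"))

setValidity("GroMSim", function(object) {
  n <- nrow(object@responses)
  if (nrow(object@membership) != n || nrow(object@assignments) != n)
    return("latent matrices must have one row per subject")
  if (ncol(object@responses) != nItems(object@model))
    return("response columns must match the model's item count")
  d <- itemCategories(object@model)
  for (j in seq_len(ncol(object@responses))) {
    yj <- object@responses[, j]
    if (anyNA(yj) || any(yj < 1L) || any(yj > d[j]))
      return(sprintf("responses of item %d outside 1..%d", j, d[j]))
  }
  TRUE
})

#' Posterior samples from the MCMC samplers
#'
#' Thinned draws of the grouping vector, the Dirichlet concentrations, the
#' group weights and the stacked conditional probability tables, together
#' with per-draw pointwise log-likelihood values (used by [waic()]) and
#' Metropolis-Hastings acceptance indicators.
#'
#' The stacked table format places item `j`'s `d_j` rows at offset
#' `sum(d[seq_len(j - 1)])`, matching the layout used for profile alignment.
#'
#' @slot draws list with elements `s` (`T x p`), `alpha` (`T x K`),
#'   `xi` (`T x G`) and `lambda` (`sum(d) x K x T` array).
#' @slot logLik `T x n` matrix, entry `(t, i)` is `log p(y_i | theta_t)`.
#' @slot acceptance per-iteration MH acceptance indicators (all `NA` for the
#'   augmented Gibbs sampler).
#' @slot control the [mcmcControl()] list used.
#' @slot d per-item category counts.
#' @slot itemNames item names carried over from the data.
#' @slot n,G,K problem dimensions.
#' @slot finalState list with the last raw state of the chain.
#' @export
setClass("GroMFit",
  representation(draws = "list", logLik = "matrix", acceptance = "numeric",
                 control = "list", d = "integer", itemNames = "character",
                 n = "integer", G = "integer", K = "integer",
                 finalState = "list"))

setValidity("GroMFit", function(object) {
  T <- nrow(object@draws$s)
  if (nrow(object@draws$alpha) != T || nrow(object@logLik) != T ||
      dim(object@draws$lambda)[3] != T)
    return("draw blocks disagree on the number of retained draws")
  TRUE
})

#' Posterior summary of a fitted model
#'
#' Produced by [summarizeFit()]: the posterior-mode grouping, posterior-mean
#' parameters, WAIC, and — when a reference model is supplied — the profile
#' permutation aligning the estimate to the reference plus ARI and RMSE
#' recovery measures.
#'
#' @slot grouping posterior-mode item grouping.
#' @slot nGroups number of groups of the fit.
#' @slot lambdaMean posterior mean of the stacked tables (`sum(d) x K`),
#'   columns in the sampler's own label order.
#' @slot alphaMean posterior mean of the Dirichlet concentrations.
#' @slot permutation profile permutation aligning estimate to reference
#'   (`NA` when no reference was given).
#' @slot rmseLambda,rmseAlpha root mean squared errors after alignment.
#' @slot ari adjusted Rand index of the grouping against the reference.
#' @slot waic,lppd,pWAIC2 model fit criteria.
#' @slot emptyGroups `TRUE` if the posterior-mode grouping leaves at least
#'   one group without items.
#' @slot d per-item category counts.
#' @export
setClass("GroMSummary",
  representation(grouping = "integer", nGroups = "integer",
                 lambdaMean = "matrix", alphaMean = "numeric",
                 permutation = "integer", rmseLambda = "numeric",
                 rmseAlpha = "numeric", ari = "numeric", waic = "numeric",
                 lppd = "numeric", pWAIC2 = "numeric",
                 emptyGroups = "logical", d = "integer"))

#' Report of an identifiability check
#'
#' Returned by [checkStrict()], [checkKRP()] and [checkGeneric()].  `passed`
#' is the conjunction of all sub-conditions of the check; `details` carries
#' per-condition diagnostics (group sizes, numerical ranks, category-count
#' products, offending items or groups, and the partition used).
#'
#' @slot passed overall flag.
#' @slot type which check produced the report (`"strict"`, `"krp"` or
#'   `"generic"`).
#' @slot details named list of diagnostics.
#' @export
setClass("GroMCheck",
  representation(passed = "logical", type = "character", details = "list"))
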