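# Probability structure of the dimension-grouped mixed membership model:
# Khatri-Rao products, Dirichlet product moments, the core tensor, and the
# conditional / marginal probability mass functions.

#' Khatri-Rao (column-wise Kronecker) product
#'
#' Column `k` of the result is the Kronecker product of column `k` of `A`
#' with column `k` of `B`.  Chaining the product over the items of a
#' partition part yields the stacked table whose column rank drives the
#' identifiability conditions.
#'
#' @param A,B numeric matrices with the same number of columns.
#' @return a `(nrow(A) * nrow(B)) x ncol(A)` matrix.
#' @examples
#' khatriRao(diag(2), diag(2))
#' @export
khatriRao <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("khatriRao: column counts differ (", ncol(A), " vs ", ncol(B), ")")
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (k in seq_len(ncol(A))) out[, k] <- kronecker(A[, k], B[, k])
  out
}

#' Dirichlet product moment
#'
#' Computes `E[prod_k pi_k^{m_k}]` for `pi ~ Dirichlet(alpha)` via the
#' rising-factorial closed form
#' `prod_k prod_{i=0}^{m_k - 1} (alpha_k + i) / prod_{i=0}^{M - 1}
#' (alpha_0 + i)` with `M = sum(m)`, evaluated through `lgamma` for
#' stability.
#'
#' @param alpha positive Dirichlet concentration vector.
#' @param m nonnegative integer multiplicity vector of the same length.
#' @return a probability in `[0, 1]`.
#' @examples
#' dirichletMoment(c(1, 1), c(2, 0))  # E[pi_1^2] = 1/3
#' @export
dirichletMoment <- function(alpha, m) {
  if (length(m) != length(alpha))
    stop("m must have the same length as alpha")
  if (any(m < 0) || any(m != round(m)))
    stop("multiplicities must be nonnegative integers")
  a0 <- sum(alpha)
  exp(sum(lgamma(alpha + m) - lgamma(alpha)) -
        (lgamma(a0 + sum(m)) - lgamma(a0)))
}

#' Core tensor of the hybrid decomposition
#'
#' The `G`-mode tensor with entries
#' `phi[k_1, ..., k_G] = E[pi_{k_1} ... pi_{k_G}]` under
#' `pi ~ Dirichlet(alpha)`.  Entries are nonnegative and sum to one, and the
#' tensor is invariant under simultaneous index permutation when `alpha` is
#' exchangeable.
#'
#' @param alpha positive Dirichlet concentration vector of length `K`.
#' @param G number of modes (variable groups), `G >= 1`.
#' @param cap refuse to materialize more than this many entries.
#' @return a numeric array of dimension `rep(K, G)` (a vector when `G = 1`).
#' @export
coreTensor <- function(alpha, G, cap = 1e7) {
  K <- length(alpha)
  if (G < 1) stop("G must be >= 1")
  if (K^G > cap)
    stop("core tensor would have ", K, "^", G, " entries (> cap); ",
         "use the per-subject latent-variable likelihood instead")
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), G)))
  a0 <- sum(alpha)
  logden <- lgamma(a0 + G) - lgamma(a0)
  lognum <- rep(0, nrow(grid))
  for (k in seq_len(K)) {
    mk <- rowSums(grid == k)
    lognum <- lognum + lgamma(alpha[k] + mk) - lgamma(alpha[k])
  }
  phi <- exp(lognum - logden)
  if (G == 1L) phi else array(phi, dim = rep(K, G))
}

# Stack per-item tables into the (sum d_j) x K matrix form.
.stackTables <- function(tables) do.call(rbind, tables)

# Per-group log-likelihood matrix: entry (g, k) is
# sum_{j in group g} log lambda_j[y_j, k].
.groupLogLik <- function(y, groups, tables, G, K) {
  A <- matrix(0, G, K)
  for (j in seq_along(y)) {
    lj <- tables[[j]][y[j], ]
    A[groups[j], ] <- A[groups[j], ] + ifelse(lj > 0, log(lj), -Inf)
  }
  A
}

.logSumExp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Probability of a response vector given the membership scores
#'
#' Evaluates `prod_g sum_k pi_k prod_{j: s_j = g} lambda_{j, y_j, k}`, the
#' conditional pmf of one subject's responses given its membership vector.
#' Accumulation is in log space with a log-sum-exp per group; a category
#' with zero probability under every profile in some group yields 0 (or
#' `-Inf` on the log scale), not an error.
#'
#' @param y integer response vector of length `p` (1-based categories).
#' @param model a [GroMModel-class]; only its grouping and tables are used
#'   here (the mixing distribution enters through `pi`).
#' @param pi membership vector on the `K`-simplex.
#' @param log return the log probability?
#' @return a probability (or its log).
#' @export
pmfGivenMembership <- function(y, model, pi, log = FALSE) {
  stopifnot(is(model, "GroMModel"))
  K <- nProfiles(model)
  A <- .groupLogLik(y, itemGroups(model), itemTables(model),
                    model@nGroups, K)
  lpi <- ifelse(pi > 0, base::log(pi), -Inf)
  ll <- sum(apply(A, 1L, function(row) .logSumExp(lpi + row)))
  if (log) ll else exp(ll)
}

#' Marginal probability of a response vector
#'
#' Integrates the membership scores out:
#' `sum_{k_1..k_G} prod_g prod_{j: s_j = g} lambda_{j, y_j, k_g} *
#' phi[k_1, ..., k_G]` with the Dirichlet product-moment core tensor.  The
#' `K^G`-term enumeration is refused (rather than silently approximated)
#' beyond `cap` entries.
#'
#' @inheritParams pmfGivenMembership
#' @param cap maximum number of core-tensor entries to enumerate.
#' @return a probability (or its log).
#' @export
marginalPmf <- function(y, model, log = FALSE, cap = 1e7) {
  stopifnot(is(model, "GroMModel"))
  K <- nProfiles(model)
  G <- model@nGroups
  if (K^G > cap)
    stop("marginal pmf needs ", K, "^", G, " core entries (> cap); ",
         "use the per-subject latent-variable likelihood instead")
  alpha <- dirichletAlpha(model)
  A <- .groupLogLik(y, itemGroups(model), itemTables(model), G, K)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), G)))
  a0 <- sum(alpha)
  logphi <- -(lgamma(a0 + G) - lgamma(a0))
  for (k in seq_len(K)) {
    mk <- rowSums(grid == k)
    logphi <- logphi + lgamma(alpha[k] + mk) - lgamma(alpha[k])
  }
  terms <- logphi
  for (g in seq_len(G)) terms <- terms + A[g, grid[, g]]
  ll <- .logSumExp(terms)
  if (log) ll else exp(ll)
}

#' Model-implied joint distribution of two items
#'
#' The `d_j x d_j2` probability table of a pair of items under the model.
#' For items in the same group the single shared profile draw gives
#' `P(c, c') = sum_k (alpha_k / alpha_0) lambda_j[c, k] lambda_j2[c', k]`;
#' for items in different groups the profile draws are coupled only through
#' the membership scores, so the mixture weights are the second-order
#' Dirichlet moments `E[pi_k pi_k']`.
#'
#' @param model a [GroMModel-class].
#' @param j,j2 distinct item indices.
#' @return a probability matrix whose margins equal the items' univariate
#'   marginals.
#' @export
pairwiseMarginal <- function(model, j, j2) {
  stopifnot(is(model, "GroMModel"))
  if (j == j2) stop("j and j2 must be distinct items")
  alpha <- dirichletAlpha(model)
  a0 <- sum(alpha)
  L1 <- itemTables(model)[[j]]
  L2 <- itemTables(model)[[j2]]
  g <- itemGroups(model)
  if (g[j] == g[j2]) {
    W <- diag(alpha / a0, nrow = length(alpha))
  } else {
    W <- outer(alpha, alpha) / (a0 * (a0 + 1))
    diag(W) <- alpha * (alpha + 1) / (a0 * (a0 + 1))
  }
  L1 %*% W %*% t(L2)
}
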