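# Seeded forward simulation and the built-in benchmark truth scenarios.

# The six 3 x 4 conditional probability tables used by the benchmark
# simulation scenarios (three categories per item, four extreme profiles);
# every column sums to one, so retaining the leading K columns for K < 4
# again yields valid tables.
.benchmarkTables <- function() {
  list(
    matrix(c(0.1, 0.8, 0.1,  0.7, 0.2, 0.1,  0.3, 0.4, 0.3,
             0.1, 0.1, 0.8), 3),
    matrix(c(0.1, 0.2, 0.7,  0.8, 0.1, 0.1,  0.1, 0.6, 0.3,
             0.2, 0.5, 0.3), 3),
    matrix(c(0.1, 0.2, 0.7,  0.8, 0.1, 0.1,  0.2, 0.5, 0.3,
             0.9, 0.05, 0.05), 3),
    matrix(c(0.1, 0.8, 0.1,  0.1, 0.2, 0.7,  0.8, 0.1, 0.1,
             0.3, 0.6, 0.1), 3),
    matrix(c(0.2, 0.6, 0.2,  0.7, 0.2, 0.1,  0.3, 0.4, 0.3,
             0.1, 0.1, 0.8), 3),
    matrix(c(0.1, 0.2, 0.7,  0.8, 0.1, 0.1,  0.1, 0.1, 0.8,
             0.2, 0.6, 0.2), 3))
}

#' Benchmark simulation truth
#'
#' Constructs the ground-truth parameter sets used by the package's
#' simulation studies.  Items have three categories each; item `j`'s table
#' is the `((j - 1) mod 6) + 1`-th of six fixed 3 x 4 tables, truncated to
#' its leading `K` columns (and renormalized per column, a no-op here since
#' every column already sums to one); the Dirichlet truth is `(0.4, 0.5)`,
#' `(0.4, 0.5, 0.6)` or `(0.4, 0.5, 0.6, 0.7)` for `K = 2, 3, 4`.  The
#' grouping matrix stacks `p/G` copies of the identity up to a row
#' permutation; the permutation is chosen so that groups are consecutive
#' item blocks (`items 1..p/G` form group 1, and so on), which makes every
#' group hold a diverse set of tables rather than `p/G` copies of the same
#' one.
#'
#' @param K number of extreme profiles, 2, 3 or 4.
#' @param p,G items and groups; one of (30, 6), (60, 12), (90, 15).
#' @return a [GroMModel-class] tagged `K<K>_p<p>_G<G>`.
#' @examples
#' benchmarkScenario(3, 30, 6)
#' @export
benchmarkScenario <- function(K, p = 30, G = 6) {
  if (!K %in% 2:4) stop("K must be 2, 3 or 4")
  if (!(p == 30 && G == 6) && !(p == 60 && G == 12) && !(p == 90 && G == 15))
    stop("(p, G) must be one of (30, 6), (60, 12), (90, 15)")
  base <- .benchmarkTables()
  tables <- lapply(seq_len(p), function(j) {
    tab <- base[[((j - 1L) %% 6L) + 1L]][, seq_len(K), drop = FALSE]
    sweep(tab, 2L, colSums(tab), "/")
  })
  alpha <- c(0.4, 0.5, 0.6, 0.7)[seq_len(K)]
  groups <- rep(seq_len(G), each = p / G)
  GroMModel(groups, tables, alpha, nGroups = G,
            label = sprintf("K%d_p%d_G%d", K, p, G))
}

#' Simulate responses from the generative process
#'
#' Draws `pi_i ~ Dirichlet(alpha)`, `z_{i,g} | pi_i ~ Categorical(pi_i)`
#' and `y_{i,j} | z_{i,s_j} = k ~ Categorical(lambda_j[, k])`.  Subjects are
#' generated one at a time, so under a fixed seed enlarging `n` extends the
#' dataset rather than reshuffling it; identical `(model, n, seed)` give
#' bit-identical output.
#'
#' @param model a [GroMModel-class].
#' @param n number of subjects.
#' @param seed RNG seed (set via [set.seed()]); use `NULL` to continue the
#'   current RNG stream.
#' @return a [GroMSim-class] with 1-based response codes.
#' @export
simulateResponses <- function(model, n, seed = NULL) {
  stopifnot(is(model, "GroMModel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- itemCategories(model)
  lam <- .tablesToCube(itemTables(model), d, nProfiles(model))
  out <- cpp_simulate(d, itemGroups(model) - 1L, lam,
                      dirichletAlpha(model), as.integer(n), model@nGroups)
  y <- out$y + 1L
  storage.mode(y) <- "integer"
  colnames(y) <- sprintf("item%d", seq_len(ncol(y)))
  Z <- out$Z + 1L
  storage.mode(Z) <- "integer"
  new("GroMSim", responses = y, membership = out$Pi, assignments = Z,
      model = model, seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

# list of d_j x K tables -> dmax x K x p cube (zero-padded rows).
.tablesToCube <- function(tables, d, K) {
  p <- length(tables)
  cube <- array(0, c(max(d), K, p))
  for (j in seq_len(p)) cube[seq_len(d[j]), , j] <- tables[[j]]
  cube
}

# dmax x K x p cube -> list of d_j x K tables.
.cubeToTables <- function(cube, d) {
  lapply(seq_along(d), function(j) cube[seq_len(d[j]), , j, drop = FALSE][, , 1])
}
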