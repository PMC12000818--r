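# Shared fixtures and independent oracles, all built in code.

# Random valid probability tables (columns on the simplex).
randomTables <- function(p, d, K) {
  lapply(seq_len(p), function(j) {
    x <- matrix(rgamma(d[j] * K, 1), d[j], K)
    sweep(x, 2L, colSums(x), "/")
  })
}

randomModel <- function(p = 4, G = 2, K = 2, d = rep(2L, p),
                        alpha = seq(0.4, by = 0.1, length.out = K),
                        seed = 1) {
  set.seed(seed)
  GroMModel(groups = rep_len(seq_len(G), p), tables = randomTables(p, d, K),
            alpha = alpha, nGroups = G)
}

# Independent brute-force oracle for the marginal pmf: enumerate every
# assignment tuple (k_1, ..., k_G), weight by the Dirichlet product moment
# computed directly from its multiplicities, and accumulate plain products.
bruteMarginal <- function(y, model) {
  G <- nGroups(model)
  K <- nProfiles(model)
  groups <- itemGroups(model)
  tables <- itemTables(model)
  alpha <- dirichletAlpha(model)
  tuples <- as.matrix(expand.grid(rep(list(seq_len(K)), G)))
  total <- 0
  for (r in seq_len(nrow(tuples))) {
    k <- tuples[r, ]
    w <- dirichletMoment(alpha, tabulate(k, K))
    lik <- 1
    for (j in seq_along(y)) lik <- lik * tables[[j]][y[j], k[groups[j]]]
    total <- total + w * lik
  }
  total
}

# Monte-Carlo oracle for the marginal pmf: average the membership-conditional
# pmf over Dirichlet draws, vectorized independently of the package's
# log-space implementation.
mcMarginal <- function(y, model, draws = 1e5) {
  G <- nGroups(model)
  K <- nProfiles(model)
  groups <- itemGroups(model)
  tables <- itemTables(model)
  Pi <- matrix(rgamma(draws * K, rep(dirichletAlpha(model), each = draws)),
               draws)
  Pi <- Pi / rowSums(Pi)
  val <- rep(1, draws)
  for (g in seq_len(G)) {
    lg <- rep(1, K)
    for (j in which(groups == g)) lg <- lg * tables[[j]][y[j], ]
    val <- val * as.vector(Pi %*% lg)
  }
  c(mean = mean(val), se = stats::sd(val) / sqrt(draws))
}

# A chain state consistent with a model, for exercising single updates.
stateFromModel <- function(model, sim) {
  list(s = itemGroups(model), lambda = itemTables(model),
       Pi = membership(sim), Z = assignments(sim),
       xi = rep(1 / nGroups(model), nGroups(model)),
       alpha = dirichletAlpha(model))
}

# Partition plan used by the binary-item Khatri-Rao example configuration
# (G = 3, p = 18, d = 2, K = 3; consecutive item pairs cycle through the
# groups, and each group is split into its three pairs).
krpExamplePlan <- function() {
  list(list(c(1L, 2L), c(7L, 8L), c(13L, 14L)),
       list(c(3L, 4L), c(9L, 10L), c(15L, 16L)),
       list(c(5L, 6L), c(11L, 12L), c(17L, 18L)))
}

krpExampleGroups <- function() rep_len(rep(1:3, each = 2), 18)
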