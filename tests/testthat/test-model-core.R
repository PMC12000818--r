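# Probability structure: Khatri-Rao products, Dirichlet moments, the core
# tensor and the conditional/marginal pmfs.

test_that("khatriRao is the column-wise Kronecker product", {
  expect_equal(khatriRao(diag(2), diag(2)),
               matrix(c(1, 0, 0, 0, 0, 0, 0, 1), 4))
  a <- c(0.1, 0.5, 0.9); b <- c(0.2, 0.4, 0.8)
  A <- rbind(a, 1 - a); B <- rbind(b, 1 - b)
  K <- khatriRao(A, B)
  expect_equal(dim(K), c(4L, 3L))
  # row structure (a b, a(1-b), (1-a) b, (1-a)(1-b)) per column
  expect_equal(K[, 1], c(0.02, 0.08, 0.18, 0.72))
  expect_equal(K[2, ], a * (1 - b))
  expect_equal(qr(K)$rank, 3L)
  expect_error(khatriRao(diag(2), diag(3)), "column counts")
})

test_that("khatriRao chains associatively over an item set", {
  set.seed(5)
  tabs <- randomTables(3, c(2, 3, 2), 4)
  chained <- Reduce(khatriRao, tabs)
  direct <- khatriRao(khatriRao(tabs[[1]], tabs[[2]]), tabs[[3]])
  expect_equal(chained, direct)
  expect_equal(dim(chained), c(12L, 4L))
})

test_that("dirichletMoment matches the rising-factorial closed form", {
  a <- c(0.4, 0.5, 0.6)
  expect_equal(dirichletMoment(a, c(1, 0, 0)), 0.4 / 1.5)  # Dirichlet mean
  expect_equal(dirichletMoment(a, c(0, 0, 0)), 1)          # empty product
  expect_equal(dirichletMoment(c(1, 1), c(2, 0)), 1 / 3)   # E[pi_1^2], unif
  # direct rising-factorial ratio for a mixed multiplicity
  expect_equal(dirichletMoment(a, c(2, 1, 0)),
               (0.4 * 1.4 * 0.5) / (1.5 * 2.5 * 3.5))
  expect_error(dirichletMoment(a, c(-1, 1, 0)), "nonnegative")
  expect_error(dirichletMoment(a, c(1, 1)), "length")
})

test_that("coreTensor holds Dirichlet product moments and normalizes", {
  expect_equal(coreTensor(c(0.4, 0.5, 0.6), 1), c(0.4, 0.5, 0.6) / 1.5)
  phi <- coreTensor(c(1, 1), 2)
  expect_equal(phi, matrix(c(1/3, 1/6, 1/6, 1/3), 2), tolerance = 1e-12)
  expect_equal(sum(coreTensor(c(0.4, 0.5, 0.6), 3)), 1, tolerance = 1e-8)
  set.seed(2)
  for (r in 1:100) {
    alpha <- rgamma(sample(2:4, 1), shape = 1) + 0.05
    expect_equal(sum(coreTensor(alpha, sample(1:3, 1))), 1,
                 tolerance = 1e-8)
  }
  # exchangeable alpha: invariant under simultaneous mode permutation
  phi3 <- coreTensor(c(0.7, 0.7, 0.7), 3)
  expect_equal(phi3, aperm(phi3, c(2, 3, 1)))
  expect_error(coreTensor(rep(1, 10), 9, cap = 1e6), "cap")
})

test_that("pmfGivenMembership evaluates the per-group mixture product", {
  # degenerate K = 1: plain product of probabilities
  m1 <- randomModel(p = 3, G = 2, K = 1, d = rep(3L, 3), alpha = 1)
  y <- c(2L, 1L, 3L)
  expect_equal(pmfGivenMembership(y, m1, pi = 1),
               prod(vapply(1:3, function(j) itemTables(m1)[[j]][y[j], 1], 0)))
  # vertex of the simplex picks one profile
  m <- randomModel(p = 4, G = 2, K = 3, d = rep(2L, 4),
                   alpha = c(0.4, 0.5, 0.6))
  y <- c(1L, 2L, 2L, 1L)
  expect_equal(pmfGivenMembership(y, m, pi = c(0, 1, 0)),
               prod(vapply(1:4, function(j) itemTables(m)[[j]][y[j], 2], 0)))
  # hand-built case with per-group inner sums 0.3 and 0.6
  m2 <- GroMModel(groups = c(1, 2),
                  tables = list(matrix(c(0.2, 0.8, 0.4, 0.6), 2),
                                matrix(c(0.4, 0.6, 0.8, 0.2), 2)),
                  alpha = c(1, 1))
  expect_equal(pmfGivenMembership(c(1L, 1L), m2, pi = c(0.5, 0.5)), 0.18)
  # zero-probability category yields 0 / -Inf, not an error
  m0 <- GroMModel(groups = 1L,
                  tables = list(matrix(c(0, 1, 0, 1), 2)), alpha = c(1, 1))
  expect_identical(pmfGivenMembership(1L, m0, pi = c(0.5, 0.5)), 0)
  expect_identical(pmfGivenMembership(1L, m0, pi = c(0.5, 0.5), log = TRUE),
                   -Inf)
})

test_that("pmf is invariant to a simultaneous profile-label permutation", {
  set.seed(9)
  m <- randomModel(p = 4, G = 2, K = 3, d = rep(3L, 4),
                   alpha = c(0.4, 0.5, 0.6))
  y <- c(1L, 3L, 2L, 2L)
  pi <- c(0.2, 0.5, 0.3)
  for (r in 1:5) {
    perm <- sample(3)
    mp <- GroMModel(itemGroups(m),
                    lapply(itemTables(m), function(tab) tab[, perm]),
                    dirichletAlpha(m)[perm], nGroups = 2)
    expect_equal(pmfGivenMembership(y, mp, pi[perm]),
                 pmfGivenMembership(y, m, pi))
    expect_equal(marginalPmf(y, mp), marginalPmf(y, m))
  }
})

test_that("marginalPmf equals brute-force generative enumeration", {
  set.seed(11)
  cases <- list(c(p = 3, G = 2, K = 2), c(p = 4, G = 2, K = 3),
                c(p = 2, G = 1, K = 3), c(p = 4, G = 1, K = 2))
  for (cs in cases) {
    m <- randomModel(p = cs["p"], G = cs["G"], K = cs["K"],
                     d = rep(2L, cs["p"]),
                     alpha = 0.3 + 0.2 * seq_len(cs["K"]))
    patterns <- as.matrix(expand.grid(rep(list(1:2), cs["p"])))
    tot <- 0
    for (r in seq_len(nrow(patterns))) {
      y <- as.integer(patterns[r, ])
      v <- marginalPmf(y, m)
      expect_equal(v, bruteMarginal(y, m), tolerance = 1e-10)
      tot <- tot + v
    }
    expect_equal(tot, 1, tolerance = 1e-10)  # total probability
  }
})

test_that("marginalPmf reduces to the latent class model when G = 1", {
  set.seed(12)
  m <- randomModel(p = 4, G = 1, K = 3, d = rep(3L, 4),
                   alpha = c(0.4, 0.5, 0.6))
  nu <- dirichletAlpha(m) / sum(dirichletAlpha(m))
  y <- c(2L, 1L, 3L, 2L)
  lcm <- sum(vapply(1:3, function(k)
    nu[k] * prod(vapply(1:4, function(j) itemTables(m)[[j]][y[j], k], 0)),
    0))
  expect_equal(marginalPmf(y, m), lcm, tolerance = 1e-12)
})

test_that("marginalPmf with one group per item is the full Tucker form", {
  set.seed(13)
  p <- 3
  m <- randomModel(p = p, G = p, K = 2, d = rep(2L, p), alpha = c(0.4, 0.5))
  m@groups <- seq_len(p)  # s_j = j
  y <- c(1L, 2L, 1L)
  phi <- coreTensor(dirichletAlpha(m), p)
  tucker <- 0
  for (k1 in 1:2) for (k2 in 1:2) for (k3 in 1:2)
    tucker <- tucker + phi[k1, k2, k3] *
      itemTables(m)[[1]][y[1], k1] * itemTables(m)[[2]][y[2], k2] *
      itemTables(m)[[3]][y[3], k3]
  expect_equal(marginalPmf(y, m), tucker, tolerance = 1e-12)
})

test_that("marginalPmf agrees with its Monte-Carlo average", {
  set.seed(21)
  m <- randomModel(p = 4, G = 2, K = 3, d = rep(3L, 4),
                   alpha = c(0.4, 0.5, 0.6))
  y <- c(1L, 3L, 2L, 1L)
  mc <- mcMarginal(y, m, draws = 1e5)
  expect_lt(abs(marginalPmf(y, m) - mc["mean"]), 3 * mc["se"])
})

test_that("marginalPmf refuses oversized core enumerations", {
  m <- randomModel(p = 6, G = 6, K = 4, d = rep(2L, 6),
                   alpha = rep(0.5, 4))
  m@groups <- 1:6
  expect_error(marginalPmf(rep(1L, 6), m, cap = 1000), "cap")
})

test_that("pairwiseMarginal matches structure and simulation", {
  set.seed(31)
  m <- randomModel(p = 4, G = 2, K = 3, d = rep(3L, 4),
                   alpha = c(0.4, 0.5, 0.6))
  # normalization and margins, same-group and cross-group pairs
  for (pair in list(c(1, 3), c(1, 2))) {
    P <- pairwiseMarginal(m, pair[1], pair[2])
    expect_equal(sum(P), 1, tolerance = 1e-12)
    margin <- as.vector(itemTables(m)[[pair[1]]] %*%
                          (dirichletAlpha(m) / sum(dirichletAlpha(m))))
    expect_equal(rowSums(P), margin, tolerance = 1e-12)
  }
  expect_error(pairwiseMarginal(m, 2, 2), "distinct")
  # an item whose columns are identical is independent of every partner
  tabs <- itemTables(m)
  tabs[[2]] <- matrix(rep(c(0.5, 0.3, 0.2), 3), 3)
  mi <- GroMModel(itemGroups(m), tabs, dirichletAlpha(m), nGroups = 2)
  P <- pairwiseMarginal(mi, 2, 4)
  expect_equal(P, outer(rowSums(P), colSums(P)), tolerance = 1e-12)
  # empirical joint frequencies on a large simulation
  sim <- simulateResponses(m, 1e5, seed = 99)
  y <- responses(sim)
  P13 <- pairwiseMarginal(m, 1, 3)
  emp <- table(factor(y[, 1], levels = 1:3), factor(y[, 3], levels = 1:3))
  emp <- emp / sum(emp)
  se <- sqrt(P13 * (1 - P13) / 1e5)
  expect_true(all(abs(emp - P13) < 3 * se + 1e-12))
})
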