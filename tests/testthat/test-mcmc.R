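# Individual full-conditional updates against hand-computed distributions,
# plus chain bookkeeping.  The joint-distribution (Geweke) validation of the
# full sweep lives in the acceptance suite.

test_that("mcmcControl validates its inputs", {
  expect_error(mcmcControl(iterations = 100, burnin = 100), "burnin")
  expect_error(mcmcControl(thin = 0), "thin")
  expect_error(mcmcControl(sigmaAlpha = 0), "sigmaAlpha")
  expect_error(mcmcControl(aAlpha = -1), "positive")
  expect_error(mcmcControl(anneal = 600, burnin = 500,
                           iterations = 1000), "anneal")
  expect_s3_class(mcmcControl(), "mcmcControl")
})

test_that("table update draws from Dirichlet(1 + category counts)", {
  # 4 subjects, counts (3, 1, 0) for profile 1 -> Dirichlet(4, 2, 1)
  y <- matrix(c(1L, 1L, 1L, 2L), 4, 1)
  state <- list(s = 1L, lambda = list(matrix(1 / 3, 3, 2)),
                Pi = matrix(0.5, 4, 2), Z = matrix(1L, 4, 1),
                xi = 1, alpha = c(1, 1))
  set.seed(51)
  R <- 4000
  draws <- replicate(R, updateItemTables(state, y, d = 3)$lambda[[1]])
  expect_true(all(abs(colSums(draws[, 1, ]) - 1) < 1e-12))  # simplex
  mean1 <- rowMeans(draws[, 1, ])
  target <- c(4, 2, 1) / 7
  se <- sqrt(target * (1 - target) / (7 + 1) / R) * 3  # conservative
  expect_true(all(abs(mean1 - target) < 5 * se))
  # profile 2 unused: prior Dirichlet(1, 1, 1), mean 1/3
  mean2 <- rowMeans(draws[, 2, ])
  expect_true(all(abs(mean2 - 1 / 3) < 0.03))
})

test_that("membership update draws from Dirichlet(alpha + counts)", {
  # G = 2, z_i = (1, 1), alpha = (0.4, 0.5) -> Dirichlet(2.4, 0.5)
  y <- matrix(1L, 1, 2)
  state <- list(s = c(1L, 2L), lambda = rep(list(matrix(0.5, 2, 2)), 2),
                Pi = matrix(0.5, 1, 2), Z = matrix(1L, 1, 2),
                xi = c(0.5, 0.5), alpha = c(0.4, 0.5))
  set.seed(52)
  R <- 6000
  draws <- replicate(R, updateMembership(state, y)$Pi[1, ])
  expect_true(all(abs(rowMeans(draws) - c(2.4, 0.5) / 2.9) < 0.01))
  expect_true(all(abs(draws[1, ] + draws[2, ] - 1) < 1e-12))
})

test_that("assignment update matches its categorical full conditional", {
  # pi = (0.3, 0.7), one binary item, lambda(1, .) = (0.9, 0.2):
  # P(z = 1) = 27/41
  y <- matrix(1L, 1, 1)
  state <- list(s = 1L, lambda = list(matrix(c(0.9, 0.1, 0.2, 0.8), 2)),
                Pi = matrix(c(0.3, 0.7), 1), Z = matrix(1L, 1, 1),
                xi = 1, alpha = c(1, 1))
  set.seed(53)
  R <- 20000
  draws <- replicate(R, updateAssignments(state, y, d = 2)$Z[1, 1])
  phat <- mean(draws == 1)
  p <- 27 / 41
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / R))
  # equal tables across profiles: posterior equals pi
  state$lambda <- list(matrix(c(0.6, 0.4, 0.6, 0.4), 2))
  draws2 <- replicate(R, updateAssignments(state, y, d = 2)$Z[1, 1])
  expect_lt(abs(mean(draws2 == 1) - 0.3), 3 * sqrt(0.3 * 0.7 / R))
})

test_that("grouping update matches its categorical full conditional", {
  # n = 2 toy case: g = 1 score .9 * .1, g = 2 score .2 * .8 -> P(s=1) = .36
  y <- matrix(c(1L, 2L), 2, 1)
  state <- list(s = 1L, lambda = list(matrix(c(0.9, 0.1, 0.2, 0.8), 2)),
                Pi = matrix(0.5, 2, 2),
                Z = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                xi = c(0.5, 0.5), alpha = c(1, 1))
  set.seed(54)
  R <- 20000
  draws <- replicate(R, updateGrouping(state, y, d = 2)$s)
  expect_lt(abs(mean(draws == 1) - 0.36), 3 * sqrt(0.36 * 0.64 / R))
  # identical assignments across groups: posterior proportional to xi
  state$Z <- matrix(1L, 2, 2)
  state$xi <- c(0.8, 0.2)
  draws2 <- replicate(R, updateGrouping(state, y, d = 2)$s)
  expect_lt(abs(mean(draws2 == 1) - 0.8), 3 * sqrt(0.8 * 0.2 / R))
})

test_that("collapsed grouping update agrees with enumeration on a toy case", {
  # single item, z marginalized: P(s_j = g) propto xi_g prod_i m_i({j})
  # with m_i independent of g when all other groups are empty, so the
  # posterior must reduce to xi
  y <- matrix(c(1L, 2L), 2, 1)
  state <- list(s = 1L, lambda = list(matrix(c(0.9, 0.1, 0.2, 0.8), 2)),
                Pi = matrix(c(0.3, 0.7, 0.3, 0.7), 2),
                Z = matrix(1L, 2, 2), xi = c(0.7, 0.3), alpha = c(1, 1))
  set.seed(55)
  R <- 20000
  draws <- replicate(R, updateGroupingCollapsed(state, y, d = 2)$s)
  expect_lt(abs(mean(draws == 1) - 0.7), 3 * sqrt(0.7 * 0.3 / R))
  # two items: iterating the scan is a Gibbs sampler on (s_1, s_2) whose
  # stationary law is the z-marginalized grouping posterior; compare its
  # empirical cell frequencies with direct enumeration
  y2 <- cbind(c(1L, 2L), c(2L, 1L))
  lam <- list(matrix(c(0.9, 0.1, 0.2, 0.8), 2),
              matrix(c(0.3, 0.7, 0.6, 0.4), 2))
  Pi <- matrix(c(0.3, 0.6, 0.7, 0.4), 2)
  xi <- c(0.6, 0.4)
  m_block <- function(items, i) {
    if (!length(items)) return(1)
    sum(Pi[i, ] * apply(vapply(items, function(j) lam[[j]][y2[i, j], ],
                               numeric(2)), 1, prod))
  }
  w <- matrix(0, 2, 2)
  for (s1 in 1:2) for (s2 in 1:2)
    w[s1, s2] <- xi[s1] * xi[s2] *
      prod(sapply(1:2, function(i)
        m_block(which(c(s1, s2) == 1), i) *
          m_block(which(c(s1, s2) == 2), i)))
  w <- w / sum(w)
  state2 <- list(s = c(1L, 2L), lambda = lam, Pi = Pi,
                 Z = matrix(1L, 2, 2), xi = xi, alpha = c(1, 1))
  set.seed(56)
  counts <- matrix(0, 2, 2)
  M <- 20000
  for (r in seq_len(M)) {
    state2 <- updateGroupingCollapsed(state2, y2, d = c(2L, 2L))
    state2$xi <- xi  # hold the weights fixed; the scan redraws them
    counts[state2$s[1], state2$s[2]] <- counts[state2$s[1], state2$s[2]] + 1
  }
  expect_true(all(abs(counts / M - w) < 3 * sqrt(w * (1 - w) / M) + 0.01))
})

test_that("CRT draws have the right support and mean", {
  expect_identical(sampleCRT(0, 0.5), 0L)
  set.seed(57)
  expect_true(all(replicate(50, sampleCRT(1, 2)) == 1L))
  expect_error(sampleCRT(3, 0), "positive")
  expect_error(sampleCRT(-1, 1), "nonnegative")
  R <- 20000
  draws <- replicate(R, sampleCRT(10, 0.5))
  mu <- sum(0.5 / (0.5 + 0:9))
  v <- sum((0.5 / (0.5 + 0:9)) * (1 - 0.5 / (0.5 + 0:9)))
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(v / R))
  expect_true(all(draws >= 1 & draws <= 10))
})

test_that("MH alpha step records acceptance and proposes positive values", {
  set.seed(58)
  state <- list(s = 1L, lambda = list(matrix(0.5, 2, 2)),
                Pi = matrix(c(0.3, 0.7), 1), Z = matrix(1L, 1, 1),
                xi = 1, alpha = c(0.4, 0.5),
                Slog = log(c(0.3, 0.7)))
  for (r in 1:50) {
    out <- updateAlphaMH(state, NULL, mcmcControl(sigmaAlpha = 0.5))
    expect_true(all(out$alpha > 0))
    expect_type(attr(out, "accepted"), "logical")
  }
})

test_that("augmented Gibbs alpha step keeps alpha positive", {
  set.seed(59)
  state <- list(alpha = c(0.4, 0.5),
                Z = matrix(sample(1:2, 40, TRUE), 20, 2))
  for (r in 1:20) {
    state <- updateAlphaGibbs(state, NULL, mcmcControl())
    expect_true(all(is.finite(state$alpha) & state$alpha > 0))
  }
})

test_that("run_chain bookkeeping and determinism hold", {
  sim <- simulateResponses(benchmarkScenario(2, 30, 6), 60, seed = 1)
  ctl <- mcmcControl(iterations = 240, burnin = 120, thin = 4, seed = 9)
  fit <- fitGroM(sim, 6, 2, control = ctl)
  expect_equal(nDraws(fit), 30L)
  expect_equal(dim(logLikDraws(fit)), c(30L, 60L))
  expect_equal(dim(lambdaDraws(fit)), c(90L, 2L, 30L))
  fit2 <- fitGroM(sim, 6, 2, control = ctl)
  expect_identical(groupDraws(fit), groupDraws(fit2))
  expect_identical(alphaDraws(fit), alphaDraws(fit2))
  expect_identical(logLikDraws(fit), logLikDraws(fit2))
  # gibbs path runs and has no MH acceptance trace
  fitG <- fitGroM(sim, 6, 2,
                  control = mcmcControl(iterations = 240, burnin = 120,
                                        thin = 4, seed = 9,
                                        sampler = "gibbs"))
  expect_true(is.na(acceptanceRate(fitG)))
  expect_false(is.na(acceptanceRate(fit)))
  expect_error(fitGroM(sim, 6, 2, control = list(iterations = 10)),
               "mcmcControl")
})
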