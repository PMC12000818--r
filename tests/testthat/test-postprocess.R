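# Posterior summaries: grouping mode, profile alignment, recovery metrics,
# WAIC, dimension selection, Cramér's V.

test_that("groupingMode takes per-item majorities with smallest-index ties", {
  draws <- rbind(c(1L, 1L, 2L), c(1L, 1L, 2L), c(1L, 2L, 2L))
  expect_equal(groupingMode(draws, nGroups = 3), c(1L, 1L, 2L))
  expect_equal(groupingMode(rbind(c(1L, 2L)), nGroups = 2), c(1L, 2L))
  # exact tie goes to the smaller group index
  expect_equal(groupingMode(rbind(1L, 2L), nGroups = 2), 1L)
  expect_error(groupingMode(matrix(integer(0), 0, 2), nGroups = 2),
               "no grouping draws")
})

test_that("alignProfiles recovers permutations and repairs collisions", {
  set.seed(61)
  tabs <- randomTables(5, rep(3L, 5), 3)
  ref <- do.call(rbind, tabs)
  expect_equal(alignProfiles(ref, ref), 1:3)
  expect_equal(alignProfiles(ref[, c(2, 1, 3)], ref), c(2L, 1L, 3L))
  # small perturbations never disturb the alignment
  for (r in 1:100) {
    noisy <- ref + matrix(runif(length(ref), -0.01, 0.01), nrow(ref))
    expect_equal(alignProfiles(noisy, ref), 1:3)
  }
  # collision: two reference rows argmax to the same column; repaired
  est <- ref[, c(1, 1, 2)] + 1e-6
  perm <- alignProfiles(est, ref)
  expect_setequal(perm, 1:3)
  expect_error(alignProfiles(ref[1:5, ], ref), "dimensions")
})

test_that("parameterRMSE pools table entries and aligns alpha", {
  set.seed(62)
  tabs <- randomTables(4, rep(3L, 4), 2)
  alpha <- c(0.4, 0.5)
  expect_equal(parameterRMSE(tabs, tabs, alpha, alpha, 1:2),
               c(lambda = 0, alpha = 0))
  expect_equal(parameterRMSE(tabs, tabs, c(0.5, 0.4), c(0.4, 0.5),
                             1:2)[["alpha"]], 0.1)
  # invariance under identical permutation of both sides
  est <- lapply(tabs, function(tab) tab + 0.01 * matrix(rnorm(6), 3))
  r1 <- parameterRMSE(est, tabs, c(0.45, 0.52), alpha, 1:2)
  perm <- c(2L, 1L)
  estP <- lapply(est, function(tab) tab[, perm])
  tabsP <- lapply(tabs, function(tab) tab[, perm])
  r2 <- parameterRMSE(estP, tabsP, c(0.45, 0.52)[perm], alpha[perm], 1:2)
  expect_equal(r1, r2)
  expect_error(parameterRMSE(tabs, tabs, alpha, alpha, c(1, 1)),
               "bijection")
})

test_that("adjustedRandIndex matches the contingency formula", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
  set.seed(63)
  for (r in 1:20) {
    s1 <- sample(1:4, 30, TRUE)
    s2 <- sample(1:3, 30, TRUE)
    expect_equal(adjustedRandIndex(s1, s2),
                 unname(mclust::adjustedRandIndex(s1, s2)))
    # invariance under relabeling
    relab <- sample(4)[s1]
    expect_equal(adjustedRandIndex(relab, s2),
                 adjustedRandIndex(s1, s2))
  }
})

test_that("waic matches its closed form on small cases", {
  # identical draws: zero complexity penalty
  ll <- rbind(log(c(0.5, 0.2)), log(c(0.5, 0.2)))
  w <- waic(ll)
  expect_equal(w[["pWAIC2"]], 0)
  expect_equal(w[["waic"]], -2 * (log(0.5) + log(0.2)))
  # n = 1, T = 2 with p = 0.5 and 0.25
  ll2 <- matrix(log(c(0.5, 0.25)), 2, 1)
  w2 <- waic(ll2)
  expect_equal(w2[["lppd"]], log(0.375))
  expect_equal(w2[["pWAIC2"]], log(2)^2 / 2)
  expect_equal(w2[["waic"]], -2 * (log(0.375) - log(2)^2 / 2))
  expect_error(waic(matrix(0, 1, 3)), "at least 2")
})

test_that("summarizeFit aligns to a reference and flags empty groups", {
  m <- benchmarkScenario(2, 30, 6)
  sim <- simulateResponses(m, 150, seed = 3)
  fit <- fitGroM(sim, 6, 2,
                 control = mcmcControl(iterations = 900, burnin = 300,
                                       thin = 3, seed = 4))
  s <- summarizeFit(fit, reference = m)
  expect_s4_class(s, "GroMSummary")
  expect_setequal(s@permutation, 1:2)
  expect_true(is.finite(s@waic))
  expect_equal(s@waic, unname(waic(fit)["waic"]))
  expect_equal(s@emptyGroups,
               any(tabulate(groupingMode(fit), 6) == 0L))
  # fitting with far more groups than the data occupy flags empties
  fitBig <- fitGroM(sim, 15, 2,
                    control = mcmcControl(iterations = 400, burnin = 200,
                                          thin = 2, seed = 5))
  sBig <- summarizeFit(fitBig)
  expect_true(is.na(sBig@rmseLambda))
})

test_that("selectDimensions excludes empty-group fits and minimizes WAIC", {
  m <- benchmarkScenario(2, 30, 6)
  sim <- simulateResponses(m, 200, seed = 6)
  ctl <- mcmcControl(iterations = 600, burnin = 300, thin = 3, seed = 7)
  sel <- selectDimensions(sim, Gvalues = 6, Kvalues = 2, control = ctl)
  expect_equal(nrow(sel$table), 1L)
  if (!sel$table$emptyGroups) {
    expect_equal(sel$G, 6)
    expect_equal(sel$K, 2)
  } else {
    expect_true(is.na(sel$G))
  }
})

test_that("sample Cramér's V matches its chi-square definition", {
  # counts [[20, 10], [10, 20]] -> V = 1/3
  y <- cbind(rep(c(1L, 1L, 2L, 2L), c(20, 10, 10, 20)),
             rep(c(1L, 2L, 1L, 2L), c(20, 10, 10, 20)))
  V <- cramersVSample(y)
  expect_equal(V[1, 2], 1 / 3, tolerance = 1e-12)
  expect_equal(diag(V), c(1, 1))
  # identical items associate perfectly
  y2 <- cbind(y[, 1], y[, 1])
  expect_equal(cramersVSample(y2)[1, 2], 1)
  # independent uniform items: V near 0
  set.seed(64)
  y3 <- matrix(sample(1:3, 2e5, TRUE), ncol = 2)
  expect_lt(cramersVSample(y3)[1, 2], 0.02)
  # degenerate item handled with a warning
  y4 <- cbind(rep(1L, 30), rep(1:3, 10))
  expect_warning(V4 <- cramersVSample(y4, d = c(2L, 3L)), "single")
  expect_equal(V4[1, 2], 0)
})

test_that("model-based Cramér's V is the population analogue", {
  set.seed(65)
  m <- randomModel(p = 4, G = 2, K = 2, d = rep(3L, 4),
                   alpha = c(0.4, 0.5))
  V <- cramersVModel(m)
  expect_equal(V, t(V))
  expect_equal(diag(V), rep(1, 4))
  # identical table columns carry no association
  tabs <- itemTables(m)
  tabs[[3]] <- matrix(rep(c(0.2, 0.3, 0.5), 2), 3)
  mi <- GroMModel(itemGroups(m), tabs, dirichletAlpha(m), nGroups = 2)
  expect_equal(unname(cramersVModel(mi)[3, -3]), rep(0, 3),
               tolerance = 1e-8)
  # agrees with the sample version on a large simulation
  sim <- simulateResponses(m, 1e5, seed = 66)
  Vs <- cramersVSample(responses(sim))
  expect_lt(max(abs(V - Vs)), 0.02)
})
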