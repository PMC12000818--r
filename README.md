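# gromm — dimension-grouped mixed membership models for categorical data

`gromm` fits **dimension-grouped mixed membership models** to multivariate
unordered categorical data such as survey, questionnaire or disability
items.  Mixed membership models give every subject a simplex weight vector
π<sub>i</sub> over K *extreme latent profiles* instead of a single cluster
label.  The dimension-grouped variant adds one discrete structural
parameter: a partition of the p items into G groups.  A subject realizes
**one** profile draw z<sub>i,g</sub> ~ Categorical(π<sub>i</sub>) per
group, shared by all items in that group:

    y_ij | z_{i,s_j} = k  ~  Categorical(Λ_j[, k]),      j = 1..p
    z_{i,1..G} | π_i      ~  iid Categorical(π_i)
    π_i                   ~  Dirichlet(α)

With G = 1 this is the latent class model (CP decomposition of the cell
probability tensor); with G = p it is the grade-of-membership model (Tucker
decomposition); intermediate G gives a hybrid decomposition whose core
tensor holds the Dirichlet product moments E[π<sub>k1</sub>…π<sub>kG</sub>].
The grouping improves parsimony and is itself identifiable from data under
checkable Khatri-Rao rank conditions, which the package exposes as
executable diagnostics.

The package provides:

* seeded simulation from the generative process and built-in benchmark
  truth scenarios (`simulateResponses()`, `benchmarkScenario()`);
* two MCMC samplers with closed-form full conditionals — Metropolis-
  Hastings-within-Gibbs (lognormal proposals for α) and a fully Gibbs
  sampler using Beta/Chinese-Restaurant-Table augmentation — plus a
  partially collapsed grouping move and an annealed burn-in that make the
  grouping actually mix (`fitGroM()`, `mcmcControl()`);
* identifiability checkers (`checkStrict()`, `checkKRP()`,
  `checkGeneric()`);
* posterior summaries: posterior-mode grouping, permutation-aligned
  estimates, adjusted Rand index, RMSE, WAIC and WAIC-based selection of
  (G, K) with the empty-group exclusion rule, and sample/model-based
  Cramér's V association matrices (`summarizeFit()`, `waic()`,
  `selectDimensions()`, `cramersVSample()`, `cramersVModel()`);
* plain-text file formats (response CSV, model and posterior archives) and
  a `gromm` command-line script (`inst/scripts/gromm`) with
  `simulate` / `fit` / `summarize` / `select` / `check` subcommands.

## Worked example

Simulate 1000 subjects from the benchmark truth with p = 30 items in G = 6
groups and K = 3 profiles, fit the model from a random prior
initialization, and compare the posterior summaries with the truth:

```r
library(gromm)

truth <- benchmarkScenario(K = 3, p = 30, G = 6)
sim   <- simulateResponses(truth, n = 1000, seed = 1)
fit   <- fitGroM(sim, G = 6, K = 3, control = mcmcControl(seed = 2))
summ  <- summarizeFit(fit, reference = truth)
summ
```

```
GroMSummary
  posterior-mode grouping: 5 5 5 5 5 4 4 4 4 4 1 1 1 1 1 6 6 6 6 6 2 2 2 2 2 3 3 3 3 3 
  WAIC: 54599.57 (lppd -26370.05, pWAIC2 929.74)
  vs reference: ARI 1.000, RMSE(Lambda) 0.0272, RMSE(alpha) 0.0279
```

The grouping is recovered exactly (ARI 1: group labels are arbitrary, the
partition is what matters — items 1–5 form one group, 6–10 another, …).
The stacked conditional probability tables deviate from the truth by 0.027
RMSE per entry and the Dirichlet concentrations (truth 0.4, 0.5, 0.6) by
0.028 after profile alignment.  `acceptanceRate(fit)` reports the
Metropolis-Hastings acceptance rate of the α step (≈ 0.62 here), and
`waic(fit)` the information criterion used by `selectDimensions()` to pick
G and K on real data.

Before interpreting a fitted grouping, `checkGeneric(itemCategories(truth),
itemGroups(truth), K = 3, nGroups = 6)` verifies that the configuration
satisfies the generic identifiability dimension bounds.

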