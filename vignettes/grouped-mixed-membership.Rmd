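---
title: "Dimension-grouped mixed membership models: model, samplers, and design notes"
author: "gromm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimension-grouped mixed membership models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gromm)
```

## The model

`gromm` fits dimension-grouped mixed membership models to an $n \times p$
matrix of unordered categorical responses, $y_{ij} \in \{1, \dots, d_j\}$.
There are $K$ *extreme latent profiles*; item $j$ carries a $d_j \times K$
conditional probability table $\Lambda_j$ whose column $k$ is the response
distribution of item $j$ for a subject wholly of profile $k$.  Each subject
$i$ has a membership vector $\pi_i$ on the $K$-simplex,
$\pi_i \sim \mathrm{Dirichlet}(\alpha)$.

The distinguishing structure is a partition of the $p$ items into $G$
groups, encoded by labels $s_j \in \{1,\dots,G\}$ (equivalently a binary
$p \times G$ matrix $L$ with one 1 per row).  A subject draws **one**
profile realization per group,
$z_{i,g} \mid \pi_i \sim \mathrm{Categorical}(\pi_i)$, shared by all items
of that group:
$$
y_{ij} \mid z_{i,s_j} = k \;\sim\; \mathrm{Categorical}(\Lambda_j[, k]).
$$
With $G = 1$ the model is the classical latent class model (each subject
effectively in one class per record, CP tensor structure); with $G = p$ it
is the grade-of-membership model (one draw per item, Tucker structure).
Intermediate $G$ interpolates: the marginal cell probabilities form the
hybrid decomposition
$$
P(y_i = c) \;=\; \sum_{k_1 \cdots k_G}
  \prod_{g} \prod_{j : s_j = g} \lambda_{j, c_j, k_g}
  \; \phi_{k_1 \cdots k_G},
\qquad
\phi_{k_1 \cdots k_G} = E\!\left[\pi_{k_1} \cdots \pi_{k_G}\right],
$$
where the core tensor $\Phi$ collects Dirichlet product moments, available
in closed form as rising-factorial ratios (`dirichletMoment()`,
`coreTensor()`).  `marginalPmf()` evaluates the sum directly and refuses
(rather than approximates) when $K^G$ exceeds a cap, since the per-subject
latent-variable likelihood is then the right tool.

Category codes are 1-based at every user-facing boundary (files, matrices,
accessors) and 0-based inside the compiled code; the mapping round-trips
exactly.  All likelihood accumulation is in log space with a log-sum-exp
per group.

## Identifiability diagnostics

Three executable checkers mirror the model's identifiability theory:

* `checkStrict()`: every group must hold at least three items whose table
  has full numerical column rank $K$ (this identifies $\Lambda$ and
  $\Phi$); additionally every item needs at least two distinct table
  columns for the grouping itself to be identifiable.  Both flags are
  reported separately.
* `checkKRP()`: the rank requirement is moved to chained Khatri-Rao
  (column-wise Kronecker) products over a 3-way partition of each group —
  strictly weaker, and the relevant regime when $d_j < K$ (e.g. binary
  items with $K = 3$).
* `checkGeneric()`: replaces ranks by the dimension counts
  $\prod_{j \in \text{part}} d_j \ge K$, sufficient for full rank at
  generic (almost all) parameter values.  When no partition is supplied,
  one is searched — exhaustively for groups of up to 12 items, greedily
  (largest $d_j$ onto the lightest part) for larger groups; the theory only
  requires that *some* valid partition exists, so any found partition
  suffices.

Numerical rank uses singular values with a relative tolerance
(`rankTol * largest singular value`, default `1e-8`), the practical reading
of exact-rank conditions in floating point.

Note one subtlety of the built-in benchmark truths: with three-category
items and five-item groups (the $(p,G) = (30,6)$ and $(60,12)$ layouts), a
3-way partition necessarily contains a single-item part with product
$3 < K$ when $K = 4$, so the generic checker genuinely fails there; six-item
groups ($(90,15)$) support $K = 4$.  The checker reports what the dimension
bound supports rather than smoothing this over.

## Priors and the two samplers

The Bayesian specification is: uniform Dirichlet priors on each table
column and on the group weights $\xi$ ($s_j \sim \mathrm{Categorical}(\xi)$);
for the Metropolis-Hastings-within-Gibbs path, $\alpha_0 = \sum_k \alpha_k
\sim \mathrm{Gamma}(a_\alpha, b_\alpha)$ with $\alpha/\alpha_0$ uniform on
the simplex; for the fully Gibbs path, independent
$\alpha_k \sim \mathrm{Gamma}(a_0, b_0)$.

A sweep updates, in order: table columns (conjugate Dirichlet with 1 +
category counts), membership rows (Dirichlet with $\alpha$ + assignment
counts), assignments $z_{i,g}$ (categorical, log space), the grouping
$(s, \xi)$, and finally $\alpha$ — either by a lognormal-proposal MH step
or by the Beta/CRT augmented Gibbs step, in which
$q_i \sim \mathrm{Beta}(G, \alpha_0)$,
$t_{ik} \sim \mathrm{CRT}(Z^{\mathrm{mult}}_{ik}, \alpha_k)$ and
$\alpha_k \sim \mathrm{Gamma}(a_0 + \sum_i t_{ik},\,
b_0 - \sum_i \log(1 - q_i))$ with shape–**rate** parameterization (the rate
update $b_0 - \sum_i \log(1-q_i)$ only makes sense as a rate).

Two derivations worth recording:

* **MH acceptance ratio.**  The prior is placed on $(\alpha_0, \eta)$ with
  $\eta = \alpha/\alpha_0$ uniform; as a density in $\alpha$ this carries
  the change-of-variables Jacobian $\alpha_0^{-(K-1)}$.  The acceptance
  ratio therefore uses the prior factor
  $(\alpha_0^\star/\alpha_0)^{a_\alpha - K}$ together with the
  $\Gamma$-function ratio to the $n$-th power, the
  $\prod_k (\prod_i \pi_{ik})^{\alpha^\star_k - \alpha_k}$ data term and
  the lognormal proposal Jacobian $\prod_k \alpha^\star_k / \alpha_k$.
  Dropping the change-of-variables term biases $\alpha$ upward; the
  package's Geweke joint-distribution test (see below) pins this down
  empirically.
* **Log-space membership draws.**  $\sum_i \log \pi_{ik}$ is the
  sufficient statistic of both $\alpha$ updates.  For small $\alpha_k$,
  Dirichlet draws underflow to exact 0/1 on the probability scale and the
  statistic degenerates to $\pm\infty$, which turns the MH step into a
  one-way ratchet.  Membership rows are therefore drawn in log space via
  $\mathrm{Gamma}(a) \stackrel{d}{=} \mathrm{Gamma}(a+1)\,U^{1/a}$, keeping
  the statistic finite for concentrations far below the underflow
  threshold (real survey fits can have $\hat\alpha_k \sim 10^{-4}$).

## Mixing: the collapsed grouping move and the annealed burn-in

The plain grouping conditional
$P(s_j = g \mid -) \propto \xi_g \prod_i \lambda_{j, y_{ij}, z_{i,g}}$
scores each candidate group with that group's *current* assignment column.
Around any locally adapted configuration these scores differ by hundreds of
log units (they grow linearly in $n$), so single-site moves essentially
never fire: chains started from random draws freeze within a handful of
sweeps in merged groupings, even though every conditional is exactly right.
Two measures address this, both on by default and both configurable in
`mcmcControl()`:

* **Partially collapsed grouping move** (`collapseEvery`): $s_j$ is drawn
  from its full conditional with $z$ *integrated out*,
  $P(s_j = g \mid s_{-j}, \Lambda, \Pi, \xi, y) \propto
  \xi_g \prod_i m_i(B_g \cup \{j\}) / m_i(B_g)$, where
  $m_i(S) = \sum_k \pi_{ik} \prod_{j' \in S} \lambda_{j', y_{ij'}, k}$ is
  the group-block mixture likelihood and $B_g$ is group $g$'s item set
  without $j$.  Immediately afterwards $z$ is redrawn from its conditional,
  before anything else conditions on it — the standard partially collapsed
  Gibbs construction, so the kernel is exact.  Mixture scores are graded
  where hard-assignment scores are winner-take-all, which is what lets
  items migrate.
* **Annealed burn-in** (`anneal`): the first `anneal` iterations run the
  collapsed move with its data term scaled by a temperature that ramps from
  0 to 1 — quadratically, since grouping merges lock in at temperatures of
  order $1/n$ and the schedule should spend most of its time there.  The
  ramp is repeated in three cycles; each end-of-cycle state is scored by
  its total $z$-marginalized data log-likelihood, and the best-scoring
  state is restored when annealing ends, making the mode search robust to
  a single ramp freezing a wrong merge.  $\alpha$ is floored at 0.05 during
  the ramp so that no profile dies (a concentration component collapsing
  toward zero while the grouping is still sorting is absorbing — its
  profile is never used again).  The ramp must end inside the burn-in, so
  every retained draw comes from the exact, untempered kernel.

With defaults (`collapseEvery = 25`, `anneal = min(burnin, 2400)`), chains
from random prior initializations recover the generating grouping with
ARI 1 and parameter RMSEs at the magnitudes shown below; with both disabled
(`collapseEvery = 0, anneal = 0` — the plain printed sweep) the same chains
freeze at ARI 0.1–0.5.  Sweep-level correctness is established by a Geweke
"getting it right" test in the test suite: on a tiny model
($n = 3, p = 4, G = 2, K = 2$), moments of parameters and data under
marginal-conditional simulation (prior then data) match those under
successive-conditional simulation (sweep then data redraw) at the 1% level
over $10^4$ sweeps.

No ordering constraint is imposed during sampling; profile labels are
aligned post hoc (below), matching standard mixed-membership practice.
Empty groups are allowed during sampling and flagged afterwards.

## Benchmark truths and what the simulations do (and do not) show

`benchmarkScenario(K, p, G)` builds the package's ground-truth parameter
sets: three categories per item; six fixed $3 \times 4$ tables cycled over
items, truncated to their leading $K$ columns (each printed column already
sums to one, so truncation needs no renormalization — the constructor
would renormalize deviations below $10^{-6}$ anyway); Dirichlet truths
$(0.4, 0.5)$, $(0.4, 0.5, 0.6)$, $(0.4, 0.5, 0.6, 0.7)$ for $K = 2, 3, 4$;
and a grouping matrix of $p/G$ stacked identity blocks.  The identity
stacking is only defined up to a row permutation; the package uses
consecutive blocks (items $1..p/G$ form group 1, and so on) so that each
group holds a *diverse* set of tables.  The cyclic alternative makes every
group $p/G$ copies of a single table, and two of the six tables differ in
just one column, leaving two groups nearly indistinguishable — an artifact
of the permutation choice, not of the model.

`simulateResponses()` draws subjects strictly one at a time
($\pi_i$, then $z_i$, then $y_i$), so a fixed seed and a larger $n$ extend
a dataset instead of reshuffling it.  The generator emulates exactly the
model's assumptions — independent subjects, exact Dirichlet memberships,
no missing data, correctly specified $K$ and $G$.  Passing recovery tests
on these data shows the estimation machinery is sound under the model; it
does not certify behavior under misspecification, missingness, or
real-data deviations.

Typical recovery at the package's standard schedule (15000 iterations,
10000 burn-in, thinning 5, $(a_\alpha, b_\alpha) = (2, 1)$,
$\sigma_\alpha = 0.02$, random prior initialization) on data simulated from
the benchmark truths, medians over 10 replicates as recomputed by
`scripts/acceptance.R` and the acceptance test suite:

* $(n, p, G, K) = (1000, 30, 6, 3)$: ARI of the posterior-mode grouping 1.00,
  RMSE($\Lambda$) $\approx 0.027$, RMSE($\alpha$) $\approx 0.03$–$0.04$.
* $(500, 90, 15, 2)$: ARI 1.00, RMSE($\Lambda$) $\approx 0.024$.
* $(1500, 30, 6, 4)$: ARI 1.00 in most replicates,
  RMSE($\Lambda$) $\approx 0.026$.
* $(250, 30, 6, 2)$: ARI 1.00 — at this small $n$ the posterior still
  concentrates on the generating grouping, and the annealed collapsed
  sampler finds it; samplers relying on single-site conditional moves
  report partial recovery (ARI $\sim 0.74$) in this regime, which is a
  mode-finding artifact rather than a property of the posterior.

The Metropolis-Hastings acceptance rate of the $\alpha$ step at
$\sigma_\alpha = 0.02$ is $\approx 0.86$ at $n = 250$ and decreases with
sample size ($\approx 0.62$ at $n = 1000$, $K = 3$; $\approx 0.46$ at
$n = 1500$, $K = 4$): the posterior standard deviation of $\log \alpha_k$
shrinks as $n^{-1/2}$ while the proposal scale stays fixed, so
$E[\min(1, r)] \approx 2\Phi(-\sigma_\alpha \sqrt{I(\alpha)}/2)$ falls —
the familiar fixed-scale random-walk behavior.  Reports of uniformly
high acceptance across sample sizes at this proposal scale are not
reproducible under the acceptance ratio derived above.

## Summaries, alignment, WAIC and selection

* `groupingMode()` takes the per-item majority across retained draws (ties
  to the smallest group index).
* `alignProfiles()` stacks tables into $(\sum_j d_j) \times K$ form and
  matches columns by the row-argmax of the reference–estimate inner-product
  matrix; argmax collisions (possible in finite samples) are repaired
  greedily in decreasing inner-product order so the result is always a
  bijection.  Posterior means are computed from raw retained draws and
  aligned once, post hoc (per-draw alignment is available via
  `alignDraws = TRUE`).
* `parameterRMSE()` pools squared errors over all table entries
  $(j, c, k)$ and, separately, over the $K$ aligned concentrations.
* `waic()` uses $-2(\mathrm{lppd} - p_{\mathrm{WAIC2}})$ with the
  $(T-1)$-denominator variance of the pointwise log-likelihoods; those are
  stored per retained draw at thinning time, so WAIC is exact with respect
  to the retained sample.
* `selectDimensions()` fits a $(G, K)$ grid and picks the smallest WAIC
  among fits whose posterior-mode grouping leaves no group empty — a fit
  whose $\bar L$ has an all-zero column is excluded even if its WAIC is
  smallest, because unoccupied groups cannot be interpreted.
* `cramersVSample()` / `cramersVModel()` give the classical and the
  model-implied (population-level, $n$-free) Cramér's V between all item
  pairs; the model version plugs the analytic pairwise marginals into the
  mean-square contingency rather than simulating, since it depicts what the
  fitted model implies.

## Numerical choices and scales used by the test suite

Tolerances: table columns must sum to 1 within $10^{-10}$ after
construction (inputs deviating by less than $10^{-6}$ are renormalized,
larger deviations rejected); numerical rank tolerance $10^{-8}$ relative;
core tensor cap $10^7$ entries; collapsed-scan products are accumulated in
chunks renormalized at $10^{\pm 280}$.

The simulation studies in the tests and in `scripts/acceptance.R` use 10
replicates per setting, and the WAIC selection study uses 10 datasets at
$(n, p, G, K) = (1000, 30, 6, 3)$ with shortened chains (2600 iterations,
1700 burn-in) for the grid fits — selection needs WAIC differences, not
publication-grade posterior means.  The Geweke validation runs $10^4$
sweeps on the tiny model.  These sizes are the package's choices for a
routine check; scaling any of them up is a matter of changing one constant.

## Known limitations

* The WAIC here is *conditional*: the pointwise likelihood holds each
  subject's membership vector at its sampled value, as in the definition
  the selection procedure is built on.  Conditional-level criteria of this
  kind are known to be generous to extra latent dimensions — an additional
  profile can absorb blended subjects through their individual membership
  vectors — and on data simulated from a $K = 3$ truth the $K = 4$
  candidate often attains a comparable or lower WAIC, while the number of
  groups $G$ is selected reliably and $K$ is never underselected.  Treat
  the $K$ chosen by `selectDimensions()` as an upper bound worth probing
  with the identifiability checkers and with fits at $K - 1$.

* Point estimation of individual memberships $\pi_i$ is not covered by the
  identifiability theory implemented here; the checkers address population
  parameters $(L, \Lambda, \Phi, \alpha)$ only.
* Missing responses are rejected, not modeled (complete-case analysis).
* The WAIC grid search refits every candidate from scratch; there is no
  warm-starting across the grid.
* The samplers assume $G$ and $K$ are fixed within one fit; no
  nonparametric or trans-dimensional moves are provided.
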