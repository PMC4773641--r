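---
title: "Cross-level isomorphism and homology in Bayesian multilevel SEM: models, design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-level isomorphism and homology in Bayesian multilevel SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Multilevel research routinely measures constructs at the individual level and
relates their cluster aggregates at the group level. Two distinct forms of
cross-level equivalence are in play: *isomorphism* (the measurement model —
pattern and magnitude of loadings — is the same at the within-cluster and
between-cluster levels) and *homology* (the structural regressions between
constructs are the same across levels). `msemiso` implements a Monte Carlo
pipeline for studying how violations of loading isomorphism, when ignored by
imposing cross-level equality constraints, bias conclusions about homology in
two-level structural equation models with binary indicators.

## The generating model

Two constructs are each measured by six binary items (items 1–6 exogenous,
7–12 endogenous; items 1 and 7 are referents with loadings fixed at 1 at both
levels). For cluster $c$ and individual $p$, the latent response of item $i$
(construct $g(i)$) is

$$y^*_{pi} = \nu_{ci} + \lambda^w_i\, \eta^w_{g(i),p} + \varepsilon_{pi},
  \qquad \varepsilon_{pi} \sim N(0, 1),$$
$$\nu_{ci} = \lambda^b_i\, \eta^b_{g(i),c} + \delta_{ci},
  \qquad \delta_{ci} \sim N(0, \theta^b_i),$$

with $y_{pi} = 1$ iff $y^*_{pi} > \tau_i$ and all thresholds $\tau_i = 0$ in
the population. The within residual variance is 1 (probit). Structurally,

$$\eta^w_{endo} = \beta_w\, \eta^w_{exo} + \zeta^w, \qquad
  \eta^b_{endo} = \beta_b\, \eta^b_{exo} + \zeta^b,$$

with $\phi^w_{exo} = \operatorname{Var}(\zeta^w) = 1$. Homologous cells use
$(\beta_w, \beta_b) = (0.44, 0.44)$; non-homologous cells use $(0.31, 0.44)$,
values taken from published leader–member exchange/empowerment estimates at
the individual and team level.

**Non-isomorphism.** Zero to three non-referent items of one construct (the
highest-numbered ones) receive an inflated *between* loading
$\lambda^b_i = 1 + \Delta$ while $\lambda^w_i = 1$, reflecting the
empirical regularity that between-level loadings tend to be larger. The
default $\Delta = 0.5$ (between loading 1.5 at `make_population_model()`)
sits in the 1.3–2$\times$ between/within ratio range reported in applied
multilevel CFA and represents the minor-to-moderate violation regime this
design probes; it is configurable because the appropriate magnitude is a
substantive choice, and all directional conclusions below hold across
$\Delta \in [0.5, 1.5]$ in our pilots.

## ICC calibration

The indicator intraclass correlation is controlled by the between-level
variances. For a unit-loading exogenous indicator the within total
latent-response variance is $\phi^w_{exo} + 1 = 2$, so the total between
variance $t$ solves $t/(t + 2) = \mathrm{ICC}$ exactly. $t$ is split between
factor and indicator-residual variance with a constant factor share of
$0.5133$, anchored so that $\phi^b_{exo} = 0.44$ at ICC $0.30$ (the one
between-variance value the study design pins down). Endogenous indicators
have within total variance $2 + \beta_w^2$; their between variances solve the
same identity, and the endogenous between residual variance is obtained in
closed form as

$$\zeta^b_{endo} = 0.5133\, t_{endo} - \beta_b^2\, \phi^b_{exo},
  \qquad t_{endo} = (2 + \beta_w^2)\,\frac{\mathrm{ICC}}{1-\mathrm{ICC}},$$

so indicators of both constructs hit the target ICC exactly. The calibration
applies to isomorphic indicators; items with inflated between loadings have
correspondingly higher ICCs, which is part of the manipulated violation.
`empirical_indicator_icc()` verifies the calibration on retained latent
responses (debug mode of `simulate_dataset()`).

## Estimation

`fit_msem()` is a Gibbs sampler with truncated-normal augmentation of the
latent responses. All full conditionals are conjugate; one cycle updates (a)
$y^*$, (b) within factor scores (bivariate normal per person), (c) cluster
random intercepts, (d) between factor scores, (e) item intercepts
($\tau_i = -\mu_i$; the threshold is fixed at 0 and the intercept free, an
equivalent parameterization that mixes better than direct threshold moves),
(f) loadings, (g) between residual variances, (h) factor/residual variances,
(i) structural paths. Under the *constrained* approach the within and
between loadings of designated items are a single parameter drawn from the
product of both levels' conditionals — an exact equality constraint. The
core loop is compiled (Rcpp); typical fits at $j = 30$, $n = 20$ run in a
few seconds.

**Priors** (uninformative, matching the study design): loadings
$N(1, 0.1)$ — variance, not SD; variances flat on $(0, \infty)$ (the
limiting inverse gamma, drawn as $\mathrm{IG}(n/2 - 1, S/2)$); thresholds
flat; structural paths $N(\text{generating value}, 0.1)$, supplied per cell
by `priors_for_model()` so the prior mass sits in the region of the
generating value.

**Convergence** is monitored by the proportional scale reduction
$\mathrm{PSR} = \sqrt{(W + B/n)/W}$ over every free parameter, computed on
the second half of the chain split in two (or across chains when
`n_chains >= 2`), checked every `check_interval` iterations with early
stopping at `psr_threshold` (default 1.05) and a hard cap
`max_iterations`. Constant chains are assigned PSR 1 by convention. With the
all-parameter criterion, these models typically need 3,000–9,000 iterations;
fits that hit the cap are returned flagged `converged = FALSE` and are
excluded from bias aggregates (but counted in rates). Burn-in discards the
first half; equal-tailed 2.5/97.5% quantiles form the credible intervals.
Multi-chain agreement can additionally be checked with per-parameter
two-sample Kolmogorov–Smirnov tests (`ks_between_chains()`, thinned to every
10th draw to mitigate autocorrelation).

**Point estimates.** Per-replication point estimates fed into the bias
aggregates are posterior *medians* (the convention of the commercial SEM
software this design mirrors). With flat variance priors and 30 clusters the
between-variance posteriors are strongly right-skewed, so posterior means
run tens of percent above the median; `summarize_cell(point_estimate =
"mean")` switches conventions if desired.

**Posterior predictive checking.** `compute_ppp()` uses a likelihood-ratio
discrepancy comparing observed against model-implied frequencies of the 12
item margins and all 66 same-person pairwise 2×2 tables (orthant
probabilities of the implied bivariate normal latent responses). The exact
discrepancy used by commercial SEM software is not public; this one is
documented, swappable, and calibrated (PPP ≈ 0.5 for correctly specified
fits, ≈ 0 under gross misfit in our tests).

## Performance metrics

`relative_bias()` is $100(\hat\theta - \theta)/\theta$; bands follow the
usual reporting convention — under 10% acceptable, 10–20% substantial
(boundaries inclusive, a choice the band definition leaves open), above 20%
unacceptable. `sum_loading_bias()` sums signed loading errors over the free
(non-referent) loadings of a construct at one level.
`coverage_rate()` is the share of 95% equal-tailed credible intervals
containing the generating value (the interval type is our choice; highest-
density intervals are not materially different for these unimodal
posteriors). `summarize_cell()` aggregates replications, excluding
non-converged or inadmissible fits from bias/coverage aggregates while
reporting their rates; per-replication point estimates are retained so Monte
Carlo standard errors can be computed for any cell mean.

## The experiment runner

`build_condition_grid()` enumerates the full 2 (approach) × 2 (structural
form) × 2 (position) × 3 ($j \in \{30, 50, 100\}$) × 4 (ICC $\in \{0.05,
0.10, 0.20, 0.30\}$) × 4 (0–3 non-isomorphic items) = 384-cell design in a
fixed lexicographic order, so cell indices are stable. Seeding is
hierarchical and schedule-independent: cell seeds are
`global_seed + cell_index`, replication $r$ uses `base_seed + r`, and every
dataset/fit is bit-reproducible from its seed. `run_experiment()` sweeps any
grid subset (YAML-configurable), writes per-cell summaries incrementally,
skips cached cells on re-run, and logs failures without aborting the sweep.
Cells and replications are embarrassingly parallel by construction;
aggregation is order-insensitive. `render_tables()` reproduces the study's
table layouts (measurement and structural variants), rounding percent biases
to integers and coverages/loading sums to two decimals, and by default drops
ICC 0.05 cells from misspecification comparisons because structural
parameters are poorly estimated there even under correct specification.

## Scaled-down study sizes

The full design is 384 cells × 1000 replications of MCMC — far beyond a
single desk run. Package defaults and shipped checks use: 100 replications
per cell in `run_experiment()` (configurable to 1000), 50 replications for
the headline reproduction cells in `scripts/acceptance.R`, 30 for secondary
cells in the test suite, and chains capped at 10,000 iterations with PSR
early stopping. At these sizes, Monte Carlo standard errors on cell-mean
relative biases of structural paths are roughly 3–5 percentage points, which
is the resolution at which reproduction checks are asserted.

## What the generator does and does not emulate

The synthetic data reproduce the study conditions exactly as specified:
balanced clusters, binary items, zero thresholds, probit within residuals,
and the ICC calibration above. They do not emulate features of real rating
data — unbalanced clusters, missing responses, ordinal scales with more than
two categories, cross-loadings, or within-level residual correlations — so
passing reproduction checks demonstrates correctness of the pipeline under
the stated model, not robustness of the substantive conclusions to these
realities (all are listed out of scope by the design).

## Known limitations and open reconstruction choices

Two quantities of the design cannot be pinned down from first principles and
are documented as explicit design choices here:

* **Non-isomorphic loading magnitudes.** The generating values are carried
  by a figure not available in machine-readable form; $\Delta$ is therefore
  a parameter (default 0.5, above). Directional results — over-estimation of
  the within path and under-estimation of the between path when
  exogenous-side non-isomorphism is ignored, and the reverse for
  endogenous-side — are insensitive to this choice; the magnitudes of
  individual cells are not.
* **Between-level loading-sum signs.** Under a hard cross-level equality
  constraint the between-loading estimate of a constrained item equals its
  within-loading estimate, so the between-level loading-sum bias must fall
  below the within-level one by exactly $k\Delta$ for $k$ constrained items.
  Constrained fits therefore necessarily produce *negative* between-level
  loading sums when the generating between loadings are the higher ones — a
  purely arithmetic consequence of the constraint worth keeping in mind when
  comparing against reports of positive between-level loading bias.
* **Small-sample behaviour of between variances.** With flat variance
  priors, 30 clusters and low ICC, the posterior for the between factor
  variance is diffuse and right-skewed; even correctly specified cells show
  median-based upward bias of tens of percent at ICC 0.10. Estimates
  stabilize with higher ICC and more clusters, matching the general finding
  that low ICC plus few clusters rules out accurate between-level inference
  without stronger priors or larger samples.
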