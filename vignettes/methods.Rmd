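---
title: "Models and methods for testing mosaic brain evolution on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for testing mosaic brain evolution on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Mammalian brains are networks of components whose sizes scale tightly with
one another. Whether that scaling reflects hard developmental coupling
("concerted" evolution) or can be broken by selection on individual
components ("mosaic" evolution) is tested by three kinds of signal on a
phylogeny:

1. **Grade shifts** — a clade sitting above or below the allometric line
   that links a component (cerebrum CX, cerebellum CB) to the rest of the
   brain (RoB), indicating clade-wide selective expansion of that component
   independent of overall brain size.
2. **Component co-evolution** — residual association between CX and CB after
   removing their shared dependence on RoB, at the species level and at the
   individual level.
3. **Rate heterogeneity** — branches or clades where a component's Brownian
   rate of change departs from the background, indicating episodes of
   independent evolution even between components that generally co-vary.

This package implements the full inferential stack for those tests:
maximum-likelihood phylogenetic generalized least squares (PGLS) with
Pagel's lambda, phylogenetic t-tests, a Gaussian phylogenetic mixed model
over individual records, and a reversible-jump variable-rates model
compared to the single-rate null by stepping-stone marginal likelihoods.
Aquatic clades such as whales and dolphins are the motivating case — their
data require splicing a well-resolved clade timetree into a broader
mammalian backbone, constructing RoB from component measurements, and
excluding species whose component sums exhaust the whole brain.

## Data model and dataset assembly

All masses are analysed as log10 species means; means are taken on the raw
scale and logged afterwards, and mass and volume are treated as
equivalent. RoB is brain − CX − CB, with olfactory bulbs subtracted where
measured, because lineages with reduced olfaction would otherwise show
deflated RoB and a spurious component grade shift. A species is excluded
when (brain − CX − CB)/brain falls at or below a relative tolerance
(default `1e-3`): component measurements that exhaust the brain must
include other structures. The tolerance guards rounded published values;
exclusion is monotone in it, and every exclusion is logged with its reason.

Tree splicing (`splice_clade`) replaces a backbone clade with a donor
subtree after multiplying every donor branch by the ratio of the clade's
crown age in the backbone to its crown age in the donor, so node ages stay
continuous across the junction. Where the two ages disagree after
rescaling, the branch above the spliced clade absorbs the difference; the
adjustment is reported in the result's `splice` attribute rather than
applied silently, since the choice of where to absorb dating conflict is a
curation decision, not an algorithmic one.

## PGLS with Pagel's lambda

The regression model is `y = X beta + e`, `e ~ N(0, sigma2 * V_lambda)`,
where `V` holds shared root-to-ancestor path lengths (the Brownian
expectation) and lambda multiplies its off-diagonals. Conventions:

* `beta` is the GLS solution; `sigma2` is estimated by maximum likelihood
  (divisor `n`) so that likelihoods, likelihood-ratio tests and AIC
  (`2k − 2 logLik`, counting `beta`, `sigma2`, and lambda when free) are
  mutually consistent.
* Standard errors carry the `n/(n − k)` correction and t-statistics are
  referred to `n − k` degrees of freedom, with `k` the number of regression
  coefficients only — lambda and `sigma2` are not charged to the t-test
  df. This matches the df conventions of the field's ML implementations
  and reconciles ML model comparison with classical GLS t-tests.
* Lambda is restricted to `[0, 1]`. Values above 1 can leave the
  covariance non-positive-definite off ultrametric trees, and the
  scientific contrast of interest is "full Brownian signal vs attenuated
  signal". When free, lambda is maximized on the profile likelihood by a
  coarse grid (step 0.1) followed by golden-section refinement, with the
  boundary values re-checked; the profile is smooth but can be maximized
  at either boundary, which a pure interior search would miss. The
  convergence tolerance is `1e-8` on the profile log-likelihood —
  iteration-count settings of other tools are not portable, a tolerance
  is.
* The "phylogenetic t-test" for a grade shift is the t-statistic of a
  binary clade indicator added to the design; its coefficient is the
  shift in log10 units.

`pmc_power` implements the parametric-bootstrap (phylogenetic Monte Carlo)
check on lambda model comparisons: simulate under both fitted models, refit
both to every simulated dataset, and report the probability that data from
the free-lambda fit exceed the null distribution's 95th percentile. Small
clades have little power to pin lambda down, which is why fixed-lambda
models are reported as the primary analysis and free-lambda fits as
sensitivity checks.

## The phylogenetic mixed model

Individual measurements are modelled as
`y_ij = x_ij' b + u_j + e_ij`, with species effects
`u ~ N(0, sigma2_phylo * A)` and `A` the tree's Brownian covariance scaled
to unit root-to-tip height (so `sigma2_phylo` is a between-species variance
on the trait scale). Sampling is blocked Gibbs: `(b, u)` jointly
multivariate normal given the variances; the G-side variance uses a
parameter-expanded prior (working variance scaled inverse-chi-squared with
`V = 1, nu = 1`, times a normal expansion multiplier with mean 0 and
variance 1000), which mixes far better than a plain inverse-gamma when the
variance is small; the residual variance uses `V = 1, nu = 0.002`; fixed
effects get a diffuse normal prior (variance `1e8`). Reported summaries are
the posterior mean, 0.025–0.975 quantile interval, and pMCMC
(`2 * min(P(draws ≤ 0), P(draws ≥ 0))`, floored at one over the number of
draws). Default chain settings (50 000 iterations, 10 000 burn-in, thin
20) are desk-scale; an effective-sample-size warning fires below 200.

## The variable-rates model

Rate heterogeneity is modelled by multiplicative scalars attached to single
branches or whole clades (a clade scalar covers the stem branch and all its
descendants; overlapping scalars compound multiplicatively). Given the
scalars, each branch length is multiplied by its effective scalar and the
regression likelihood is the usual Gaussian one on the rescaled tree.

Because a global scalar is indistinguishable from rescaling `sigma2`, the
background rate is a free parameter and scalars are interpreted against
it; reporting always uses effective per-branch multipliers, so any
redundant global component cancels out of per-branch comparisons.

The sampler is reversible-jump MCMC: birth of a scalar on a uniformly
chosen free (branch-or-clade, edge) slot with its value drawn from the
prior, death of a uniformly chosen scalar, and lognormal random-walk
resizing, interleaved with conjugate Gibbs updates of `beta` and `sigma2`.
Proposing births from the prior makes the acceptance ratio collapse to the
likelihood ratio times the count-prior ratio, which keeps the sampler
correct with minimal bookkeeping. Several structural attempts are made per
iteration (default 3) — each costs one O(n) pruning pass, so this buys
mixing almost for free.

Priors (all exposed in `vr_prior`, because marginal likelihoods are
prior-sensitive): scalar count truncated Poisson(1) — rate shifts should
be rare a priori; scalar values lognormal(0, 1.5) — median 1, with
order-of-magnitude shifts (×0.1, ×10) within about 1.6 prior sd, the
magnitude of shift the model is built to detect; `beta ~ N(0, 10^2)` and
`sigma2 ~ inverse-gamma(0.5, 0.5)`, both weakly informative on log-mass
scales. Proper priors on every parameter are required for the marginal
likelihood to exist.

Likelihood evaluations use a pruning (three-point) pass implemented in
C++: one postorder sweep returns `[X y]' V^-1 [X y]` and `log|V|` in
O(n) per evaluation, with polytomies merged sequentially. A dense
Cholesky route exists in R and the two are held to `1e-10` agreement in
the tests, so the fast path is always cross-checked against the readable
one.

**Stepping-stone marginal likelihoods** bridge prior and posterior through
power posteriors at Beta(0.4, 1) quantile powers (concentrating stones near
the prior, where the integrand changes fastest), K = 32 by default, each
stone's expectation estimated from the chain at the lower power and
warm-started from the previous stone. Support is summarized as
`BF = 2 (log MLh_VR − log MLh_null)`, with 5–10 labelled strong and > 10
very strong. Post-processing multiplies branch lengths by posterior mean
or median scalars (medians are the conservative summary), ranks branches
by scaled/raw ratio with rootward-first tie-breaking, and flags branches
whose multiplier departs from 1 in one direction in more than 95% of
samples — the flagging rule is stated explicitly because "deviant branch"
has no canonical definition.

## The synthetic-data generator

Everything above is validated against data generated under the model the
analysis assumes: RoB evolves by Brownian motion on the tree; CX and CB
follow `a + b·RoB + delta·clade + error` with tree-structured errors that
may be correlated between components (rho) and may carry branch-rate
scalars; individuals are species means plus independent log-scale noise.
The default mammal-scale scenario uses 141 species with a 17-tip focal
clade carrying a grade shift of 0.5 log10 units in both components and a
component-error correlation of 0.6 — sizes and effects chosen to mirror a
mammal-wide brain dataset with a strongly shifted marine clade. The
variable-rates scenario uses 64 tips with a tenfold rate shift on a clade
of about a quarter of the tips; that clade fraction makes the
marginal-likelihood gain of the true model comparable to strong empirical
rate shifts (Bayes factors in the tens), so detection is expected but not
trivial.

What the generator does *not* emulate: measurement error correlated across
components, unequal individual counts, non-Brownian processes
(Ornstein–Uhlenbeck, early-burst), fossil tips, and topology error.
Passing tests therefore demonstrate correctness of the inference under its
own assumptions — parameter recovery, calibration, estimator consistency —
not robustness to real-data pathologies.

## Validation suite and problem sizes

The test suite ties every estimator to an independent oracle: PGLS to
explicit Cholesky-whitening GLS (and to `nlme::gls` with a Pagel
correlation), the pruning likelihood to dense matrix algebra, the
stepping-stone estimator to an adaptive-quadrature marginal likelihood of
the conjugate single-rate model, and pMCMC to normal tail probabilities.
Calibration runs use: 500 replicates for the type-I error of the
phylogenetic t-test on 100-tip trees (binomial acceptance band around
0.05); 200 replicates for recovery of a 0.3 grade shift (tolerance ±0.05
on the mean); 100 replicates per lambda in {0, 0.5, 1} on 200-tip trees
(tolerance ±0.1); 50 replicates for animal-model interval coverage
(≥ 90% at nominal 95%); and ten seeds per condition for the
variable-rates Bayes-factor separation (BF > 10 with the planted tenfold
shift in at least 8 of 10, BF < 5 under homogeneous Brownian motion in at
least 8 of 10). Stepping-stone runs in these checks use 16 stones with
1500 iterations each — about a quarter of the default production
settings — which the consistency checks show is already within the
estimator's Monte-Carlo error for problems of this size.

## Known limitations

* Lambda above 1 and other branch-length transforms (kappa, delta) are out
  of scope.
* The variable-rates sampler explores scalar *location* by uniform birth
  proposals; on trees with many hundreds of branches, discovery of a
  single shifted branch needs proportionally longer chains.
* Stepping-stone standard errors ignore within-stone autocorrelation and
  should be read as lower bounds; the tests rely on replicate seeds, not
  on the reported SE.
* The mixed model is Gaussian-only and puts the random effect at species
  level; within-species structure (sex, age, source collection) is not
  modelled.
* Bayes factors depend on the scalar priors; conclusions should be checked
  under perturbed `vr_prior` settings, which is why every constant is an
  argument rather than a buried default.
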