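---
title: "Models and methods behind milkphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind milkphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkphylo)
```

## The problem

Mammalian milks are routinely summarized by the concentrations of fat,
protein and sugar (g/100 g). Across species these concentrations span two
orders of magnitude, covary strongly with one another (high-fat seal milks
have almost no sugar; dilute primate and equid milks are low in fat and
protein and high in sugar), and are strongly clustered by clade. That mix of
features frustrates ordinary comparative regression: ecological predictors
such as aquatic lifestyle are themselves conservative and clade-specific, so
"controlling for phylogeny" removes most of the signal one hopes to detect.

milkphylo implements three complementary ways of describing such data on a
phylogeny, plus the plumbing around them:

1. a **trivariate phylogenetic mixed model** that estimates ecological fixed
   effects together with the phylogenetic and residual covariance of the
   three concentrations;
2. **Kolmogorov–Smirnov Importance (KSI)** tests that rank clades by how
   distinctive their trait distributions are, in one, two or three trait
   dimensions (the multivariate case uses the exact Peacock statistic);
3. a **scalar Ornstein–Uhlenbeck (OU) shift model** that places jumps in
   selective optima on tree edges, selects how many regimes the data support,
   and imputes missing trait values from the fitted model.

A synthetic-data module generates trees, covariates and traits with exactly
the statistical structure these methods assume, so every stage is testable
end to end without any external data.

## Scales and transforms

Concentrations are proportions of the whole secretion, so all modeling is on
the logit scale: `logit(p) = log(p / (1 - p))` maps (0, 1) onto the real
line and respects both boundaries, which log or identity scales do not once
values range from under 1% (sugar in some seals) to 60% (fat in the same
seals). Raw g/100 g values are divided by 100 before the transform. Values of
exactly zero usually mean "below detection", not zero; the loader maps them
to missing with a warning rather than clamping, because a clamped
pseudo-value would act as an extreme outlier on the logit scale.

Continuous life-history predictors (female mass, reproductive output,
relative lactation length) are log10-transformed to reduce skew and
mean-centered so the intercept refers to an average mammal. Aquatic
adaptation is an ordinal 0–3 code (terrestrial, partly, mostly, completely
aquatic); diet is categorical with herbivore as the reference level.

Compiled milk data are error-prone, so a quality screen regresses dry matter
on the sum of the macronutrients; species with |studentized residual| above a
threshold (default 3; the criterion is a config knob because inspection of
such outliers is ultimately manual) are flagged. The report is advisory —
curation decisions belong to the analyst, not the code.

Trees are rescaled to unit height by default. Nothing in the likelihoods
requires this, but it makes the phylogenetic covariance per unit tree depth,
the selection strength `alpha` and its half-life `ln 2 / alpha` dimensionless
multiples of the tree height, and heritabilities scale-free, so results are
comparable across trees.

## The phylogenetic mixed model

With `n` species, trait matrix `Y` (n × 3, logit scale) and design `X`
(n × 9: intercept, arid, aquatic, two diet dummies, mass, output, lactation,
precociality), the model is

```
vec(Y) ~ Normal( vec(X B),  Sigma_P ⊗ A + Sigma_R ⊗ I )
```

where `A` is the Brownian-motion relatedness matrix (shared branch length
from the root), `Sigma_P` the 3 × 3 phylogenetic covariance and `Sigma_R`
the residual covariance. Derived quantities are the phylogenetic
heritabilities `h2_i = Sigma_P[i,i] / (Sigma_P[i,i] + Sigma_R[i,i])` (1 =
pure Brownian motion) and the phylogenetic and residual correlations.
Missing trait cells are handled by marginalization — row selection of the
stacked Gaussian — which is the exact likelihood under ignorable
missingness; no imputation enters the fit.

Two backends share one contract. The default is maximum likelihood: both
covariance matrices are parameterized by their Cholesky factors with
log-diagonals (so every parameter vector is a valid PD pair), the fixed
effects are profiled out by GLS at each step, and a quasi-Newton search runs
over the remaining 12 parameters. The optimizer tolerance (relative 1e-8) was
chosen by checking that tightening it by two orders of magnitude changes
heritabilities by less than 1e-3 on preset-scale data. Coefficient intervals
and p-values on this path are Wald (Gaussian GLS conditional on the
estimated covariances); a parametric bootstrap (`nboot > 0`) supplies
percentile intervals and tail-fraction p-values for every quantity including
heritabilities and correlations. The bootstrap is not the default because it
multiplies the fit cost by the replicate count while the Wald and bootstrap
answers agree closely for the coefficient block at the study scale.

The second backend is Bayesian: the coefficient matrix has an exact Gaussian
conditional and is Gibbs-sampled; the covariance parameters move by adaptive
random-walk Metropolis under weakly informative Normal(0, 2²) priors on the
log-Cholesky scale. Intervals are posterior quantiles; p-values are the
two-sided posterior tail fraction `2 min(Pr(b > 0), Pr(b < 0))`, the usual
convention for MCMC mixed models. Because heritabilities and correlations
are computed per draw, their intervals respect the [0, 1] and [−1, 1]
ranges by construction.

Numerical care: factorizations first try a clean Cholesky and only fall back
to a relative ridge of 1e-8 × mean diagonal when the matrix is numerically
indefinite, so small-instance likelihoods agree with textbook densities to
1e-8 while degenerate inputs (e.g. `Sigma_R = 0`) remain usable.

## KSI: clade distinctiveness

For a clade C among the currently retained species, the statistic is the
two-sample Kolmogorov–Smirnov distance between trait values inside and
outside C, scaled by `sqrt(n1 n2 / (n1 + n2))` so clades of different sizes
are comparable (this is the factor that makes the unscaled KS distance
asymptotically pivotal). Empirical CDFs are evaluated at all pooled data
points, so ties are exact. For two or three traits the distance is the exact
Peacock statistic: the maximum over all `2^d` axis orientations and all grid
points formed by pooled per-axis coordinates of the ECDF discrepancy. The
implementation counts by d-dimensional prefix sums over that grid (C++),
which is algebraically identical to full enumeration — the test suite checks
equality against a brute-force oracle — at `O(2^d prod(m_k))` rather than
`O(2^d n prod(m_k))` cost. Exactness is the point at comparative-data scale
(about 124 species); a guard refuses trivariate inputs beyond 400 pooled
points, where the grid no longer fits comfortably in memory.

The search is iterative: score every internal node whose clade keeps at
least `min_clade` species (default 4) on each side, report the best node,
remove its species, repeat. This produces a series of clades of declining
distinctiveness; the statistic of each winner is also reported relative to
the first winner (KSI/max). Two conventions needed fixing where the
procedure is underdetermined:

- **Ties.** The two children of the root define the same inside/outside
  split, so their statistics are identical. Ties resolve to the smaller
  clade — the interpretable side of the split (one reports "pinnipeds", not
  "everything except pinnipeds").
- **Nodesets.** Neighbouring nodes along the winner's ancestor/descendant
  chain whose statistic is at least `nodeset_frac` (default 0.95) of the
  winner's are reported as near-equivalent, making ambiguity about the exact
  most recent common ancestor visible instead of hiding it.

Two structural properties temper interpretation. First, the scaled statistic
of a clade with `n1` of `n` species is capped at `sqrt(n1 (n - n1) / n)` even
under complete separation, so small clades can never outscore the
distinctiveness attainable by clades near half the tree: rankings compare
evidence, not effect size. Second, under phylogenetically correlated
evolution (Brownian motion and relatives) deep clades are *genuinely*
coherently displaced, so high KSI scores across many clades are the expected
signature of the null evolutionary process, not false positives; the
package's power tests therefore plant signal on an exchangeable background,
where the planted clade is the only real structure. On real comparative data
KSI is a descriptive ranking of where in the tree the trait distributions
are most unusual.

Species missing a trait are dropped listwise within each trait set, so sets
avoiding the patchily measured trait retain more species. Univariate KSI is
invariant to monotone transforms; the multivariate grid statistic is
invariant to per-coordinate monotone transforms applied to both samples
jointly (also property-tested), so running on the logit scale is a
convention, not a substantive choice. No analytic p-values are attached:
the procedure is used as a ranking, and a permutation null is available by
shuffling tip values.

## Scalar-OU shift regimes

All three traits follow an OU process with a common selection strength
`alpha` and a rate matrix `R`; "shifts" are jumps of the optimum vector
placed at the start of tree edges, so each tip inherits the regime of the
most recent shift on its root path. Tip covariance has the closed form
`R ⊗ C_alpha` with
`C_alpha[i,j] = exp(-alpha(d_i + d_j - 2 t_ij)) (1 - exp(-2 alpha t_ij)) / (2 alpha)`,
which is the Brownian matrix at `alpha = 0`. On an ultrametric tree the mean
effect of a shift on its descendant tips is a clade indicator times
`1 - exp(-alpha tau)` (`tau` = time from the shift to the tips), so for fixed
`alpha` the model is a multivariate GLS in which choosing shift locations is
a column-selection problem. The fitter exploits this:

- candidate edges are ranked by a group lasso (common support across the
  three traits) of whitened trait values on whitened edge indicators, with a
  forward step seeded by the best smaller model and hill-climbing swaps, all
  scored by the exact profile likelihood;
- `alpha` is profiled over a grid: the Brownian limit 0 plus log-spaced
  values in [1e-3, 50] per unit tree height (half-life from ~700 down to
  ~0.014 tree heights). Ties prefer the smallest `alpha`;
- missing cells are filled by imputation-EM: conditional means given the
  current parameters, alternating with re-selection and re-fitting. The
  observed-data likelihood — not the completed-data one — is what is profiled
  and penalized;
- shifts sit on internal edges only, and every regime (including the root's)
  must keep at least one tip, which removes trivially unidentifiable
  allocations.

The number of shifts K is selected by minimizing a penalized likelihood over
K = 0..K_max. The default penalty is BIC-like with a selection correction,
`-2 logL + p(K) log N + 2 log C(E, K)` (`p(K)` free parameters, `N` observed
cells, `E` internal edges): picking the best of E edges inflates the maximal
likelihood gain by roughly `log E` per shift, and without the correction the
null (pure Brownian) case selects spurious shifts. A plain BIC is available;
the criterion is pluggable. The full criterion curve is always stored so
near-ties between neighbouring K are visible rather than silently resolved.

**Reported regime values.** Regime rows of `Theta` are expected tip-level
trait values: the root level plus cumulative fitted mean changes. In the
strong-pull (equilibrium) limit these equal the OU optima; under weak pull
the raw optimum (mean change divided by `1 - exp(-alpha tau)`) is barely
identifiable and diverges as `alpha → 0`, while the mean level is what the
data constrain and what regime tables in this literature effectively report.
Back-transformed g/100 g values accompany the logit values.

**Equivalence classes.** On an ultrametric tree, every allocation of K
shifts that colours the tips into the same regimes spans the same space of
tip means and therefore attains the identical maximized likelihood.
`equivalent_solutions()` enumerates these allocations (exhaustively when
`choose(E, K)` is small, otherwise by single-edge substitution search), and
the lexicographically smallest edge set is the canonical report.

## The synthetic-data generator

The generator is first-class, tested code, because every statistical claim
in the test suite is a claim about recovery from data whose truth is known.
Defaults are fixed at the study conditions: 124 species on a unit-height
pure-birth tree; phylogenetic heritabilities (0.976, 0.997, 0.872) and
phylogenetic correlations (0.675, −0.750, −0.473) for (fat, protein, sugar),
residual correlations (0.156, 0.380, 0.251) — published comparative
estimates for mammalian milk — assembled into `Sigma_P` and `Sigma_R` with
total logit-scale variances (1.5, 1.0, 2.0), values chosen once as a
realistic logit-scale spread for traits ranging two orders of magnitude in
percent terms (the sources report heritabilities and correlations, not
absolute variances). Fixed effects are the published coefficient table, the
root state the published intercepts, and 15 of 124 sugar values are masked
completely at random. Ecological covariates get phylogenetic signal by
thresholding Brownian liabilities (20% arid; 85/5/5/5% aquatic levels;
50/30/20% diet; precociality by quartiles), because the clade-confounding of
predictors is precisely the difficulty the methods must survive.

A six-regime scenario (`milk_shift_scenario()`) plants the published
selection regimes — four disjoint clades plus two nested inside the
pinniped-like one — with mean changes equal to the logit differences between
the published regime optima and root composition. Because the published pull
is very weak (half-life several times the tree height), tip data are
generated in the Brownian limit with step-change means; OU simulation with
`alpha > 0` uses the exact Gaussian transition and is tested against its
stationary law separately.

What the generator does **not** emulate: intraspecific variation and assay
heterogeneity (which act as measurement error and would shrink both
heritabilities and coefficients), non-random missingness (real sugar gaps
concentrate in species whose sugars fall below detection), taxonomic
imbalance of real mammal trees, and correlation between covariates beyond
what shared liabilities induce. Passing recovery tests therefore show the
estimators work under the model's own assumptions at the study scale — not
that any particular empirical dataset satisfies those assumptions.

## Test and problem sizes

The recovery tests run at the scale the methods target: 124 species, 20
replicate seeds for mixed-model recovery (median heritability error under
0.1, correlation signs), 20 seeds each for KSI power (+10 sd planted clade
ranked first) and shift selection (two planted shifts of 8 stationary sd
recovered with K = 2; pure Brownian data selecting K = 0), with at least 18
of 20 required where single-replicate noise is expected. Oracle tests use
brute-force enumeration (KS/Peacock), textbook Gaussian densities
(likelihoods), and closed-form GLS (ancestral states, profiled effects).

## Known limitations

- The exact trivariate Peacock statistic is memory-bound around a few
  hundred pooled points; an approximate large-n variant is not implemented.
- The shift model assumes a common `alpha` across traits and an ultrametric
  tree for its linear-model search path; per-trait selection strengths are
  out of scope.
- K-selection constants are a pragmatic approximation to penalized-selection
  theory, not a clone of any published criterion; near-ties in the stored
  criterion curve should be inspected rather than trusting the argmin.
- ML variance components carry the usual small-sample downward bias; at
  124 species with 9 fixed effects this is visible in the third decimal of
  heritabilities, well inside the recovery tolerances used here.
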