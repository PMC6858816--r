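# milkphylo

Multivariate phylogenetic analysis of mammalian milk macronutrient
composition: who this is for — comparative biologists asking why milk fat,
protein and sugar concentrations differ so much across mammals, how strongly
they coevolve along the phylogeny, and which clades (pinnipeds, primates,
perissodactyls, marsupials, ...) have genuinely distinctive milks rather than
ordinary Brownian scatter.

Concentrations are proportions, so everything is modeled on the logit scale.
The package implements three complementary analyses behind one data model,
plus quality control, figures, a synthetic-data generator, and a pipeline
orchestrator:

1. **Trivariate phylogenetic mixed model.** With trait matrix *Y* (n × 3,
   logit scale), design *X* (n × 9 ecological/life-history predictors) and
   Brownian relatedness matrix *A*,

   vec(*Y*) ~ N( vec(*X B*), Σ_P ⊗ *A* + Σ_R ⊗ *I* ),

   estimated by maximum likelihood (log-Cholesky quasi-Newton, GLS-profiled
   fixed effects; Wald or parametric-bootstrap inference) or by MCMC
   (Gibbs for *B*, adaptive Metropolis for the covariances). Reported:
   coefficient table, phylogenetic heritabilities
   h² = Σ_P[ii]/(Σ_P[ii]+Σ_R[ii]), and phylogenetic/residual correlations.
   Missing trait cells are marginalized exactly.

2. **KSI (Kolmogorov–Smirnov Importance) clade tests.** For each clade, the
   sample-size-scaled KS distance √(n₁n₂/(n₁+n₂)) · sup|F̂_in − F̂_out|
   between trait distributions inside and outside the clade; for trait pairs
   and triples the exact multidimensional Peacock statistic (all 2^d axis
   orientations × the pooled coordinate grid, computed by prefix sums in
   C++). An iterative search reports ranked clades, KSI/max ratios, and
   nodesets of near-equivalent neighbouring nodes.

3. **Scalar-OU shift regimes.** All traits share one selection strength α;
   shifts are jumps of the optimum vector on internal edges. For fixed α the
   ultrametric-tree model is a multivariate GLS with an edge-selection
   problem (group-lasso ranking + forward step + swaps), profiled over an α
   grid including the Brownian limit. K is selected by a penalized
   likelihood with a selection-correction term; missing values are imputed
   as conditional means (imputation-EM); equivalent shift allocations
   (identical tip colourings) are enumerated. Phylogenetic half-life:
   ln 2 / α tree heights.

See `vignettes/milkphylo-methods.Rmd` for the models, conventions and
numerical choices in detail.

## Worked example

```r
library(milkphylo)

# a 124-species synthetic dataset generated at published mammalian-milk
# parameter values (heritabilities, correlations, effects; 15 missing sugar)
sim <- simulate_milk_dataset("paper124", seed = 1)
fit <- fit_pmm(sim$data, seed = 1)
fit
#> Phylogenetic mixed model fit (ml), 124 species, logLik = -273.77
#>   h2: fat 0.984, protein 0.996, sugar 0.895
#>   phylogenetic correlations (fp, fs, ps): 0.68, -0.797, -0.33
```

The heritability estimates (0.984, 0.996, 0.895) recover the generating
values (0.976, 0.997, 0.872): almost all variance in milk composition is
phylogenetic. The correlation signs — fat–protein positive, fat–sugar and
protein–sugar negative — recover the generating coevolution pattern
(0.675, −0.750, −0.473): fatty milks carry protein with them and exclude
sugar.

```r
# plant the published six-regime scenario and ask the data how many regimes
# they support
sc <- milk_shift_scenario(seed = 5)
fit2 <- select_K(sc$traits, sc$tree, K_max = 8)
fit2
#> Scalar-OU shift fit: K = 4 shifts, alpha = 0 (half-life Inf tree heights), logLik = -58.98
#>   shift edges: 72, 185, 202, 207
round(fit2$Theta_pct[, "fat"], 1)
#> [1] 10.6  1.0 57.8 35.8 34.0
```

Four of the six planted regimes are strong enough to be detected at this
noise level (the two two-species nested subclades are not); the regime
covering the pinniped-like clade has a fitted fat level of 57.8 g/100 g
against a planted 59.8 (the gap is one realization of clade-level Brownian
noise). The 15 missing sugar values are imputed from the fitted model
(`fit2$imputed`).

```r
# which clades have distinctive milks, using all three traits jointly?
k3 <- ksi_search(sc$tree, sc$traits, c("fat", "protein", "sugar"), n_ranks = 3)
k3[, c("rank", "label", "statistic", "ratio", "n_in")]
#>   rank label statistic     ratio n_in
#> 1    1 nd156  3.746784 1.0000000   17
#> 2    2 nd127  3.216423 0.8584490   34
#> 3    3 nd137  2.637048 0.7038164   10
```

The rank-1 clade (KSI/max = 1 by definition) is exactly the planted
primate-like regime, rank 3 is exactly the marsupial-like regime, and rank 2
is an ancestor of the pinniped-like clade — the iterative search reports
distinctive clades in statistic order, with ambiguity between a clade and
its neighbours captured in the `nodeset` column.

A full run — QC, transforms, mixed model, KSI over all seven trait sets,
shift detection, figures, manifest — is one call (or the bundled CLI):

```r
paths <- make_demo_dataset("tiny", seed = 1, dir = "demo")
run_pipeline(paths$config)
```

```sh
inst/cli/milkphylo demo --preset paper124 --seed 1 --out demo
inst/cli/milkphylo run --config demo/config.yaml
```

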