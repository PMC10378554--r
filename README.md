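# copulamodules

Low-dimensional modules of count dependence via vine copulas and weighted
NMF.

## What this solves

Populations of simultaneously recorded neurons (and count data generally)
interact in ways that pairwise linear correlations miss: spike counts are
discrete and skewed, and their co-variation concentrates in the tails —
cells that emit large counts together, or fall silent together.
`copulamodules` characterizes this dependence non-parametrically and then
compresses it into a handful of interpretable patterns:

1. **Counts → copulas.** Each variable is mapped to the unit interval with
   the *distributional transform*
   `G(x, V) = F⁻(x) + V·(F(x) − F⁻(x))`, which places every discrete
   observation uniformly inside its CDF jump, giving a well-defined
   empirical copula for discrete data.
2. **C-vine factorization.** The joint copula of *d* variables is
   decomposed into `d(d−1)/2` bivariate conditional copulas
   (`fit_cvine()`), ordered by Kendall-tau sums, with conditional inputs
   produced by h-functions `h(x|y) = ∂C(x,y)/∂y` under the simplifying
   assumption. Every pair is screened by a two-sample two-dimensional
   Kolmogorov–Smirnov test (permutation p-values); independent pairs — the
   majority, in practice — are pruned. Densities are estimated either with
   a rational-quadratic spline normalizing-flow (uniform base, maximum
   likelihood, random hyperparameter search with a 10% holdout) or a fast
   smoothed-histogram fallback.
3. **Copula modules.** The retained densities, vectorized into a matrix
   `X` (pairs × G²), are factorized as `X ≈ WH` with non-negative `W`
   (pair coefficients) and `H` (shared "copula modules") by multiplicative
   updates — optionally *weighted* (`wnmf()`) by per-pair matrices `V`
   built from the margins' quantile gap `g(u) = |F⁻¹(u) − u|`,
   rotation-summed and smoothed so reconstruction errors in all four tail
   corners are penalized most. The rank is selected by speckled (scattered
   held-out entries) 5-fold cross-validation.

Benchmark generators (`make_benchmark()`, `generate_population()`) rebuild
the validation study — Clayton (θ=5) and Frank (θ=6) copulas and their
rotations coupled to Poisson margins — so every stage is testable without
external data.

## Worked example

A 20-variable synthetic population with two hubs: variable 1 couples to
variables 2–9 through lower-tail (Clayton θ=5) dependence, variable 10 to
variables 11–17 through upper-tail (Clayton rotated 180°) dependence,
everything else independent:

```r
library(copulamodules)

cl <- parametric_copula("clayton", 5)
cl180 <- parametric_copula("clayton", 5, rotation = 180)
spec <- synthetic_population_spec(20, 2000, edges = c(
  lapply(2:9, function(j) list(1, j, cl)),
  lapply(11:17, function(j) list(10, j, cl180))))
counts <- generate_population(spec, seed = 1)

res <- run_pipeline(run_config(seed = 1, ranks = 1:4, grid_size = 50),
                    counts = counts)
#> pipeline: 2000 observations x 20 variables
#> vine: 190 pair copulas, 172 independent (pruned), 18 retained
#> speckled CV: selected rank 4
print(res$cv)
#> Speckled 5-fold CV (WNMF, holdout 10%): ranks 1-4
#> selected rank: 4 (plateau onset: 4; alpha1 = 0, alpha2 = 0)
#> mean validation MSE by rank:
#>      1      2      3      4 
#> 0.3372 0.1744 0.1969 0.1578
head(round(coef(res$fit)[res$row_order, ], 2), 3)
#>               [,1] [,2] [,3] [,4]
#> v10,v15|v1,v8 0.08 2.96 0.00 0.55
#> v10,v12|v1,v8 0.59 2.77 0.04 0.24
#> v10,v14|v1,v8 0.68 2.69 0.02 0.28
```

The 18 retained pair copulas are the 15 planted hub edges plus 3
false-positive conditional pairs (consistent with the 5% test level over
190 edges). The sorted coefficients recover the planted block structure:
every hub-10 pair loads on module 2 (upper-tail dependence) and every
hub-1 pair on module 4 (lower-tail dependence, shown by
`plot(res$fit, G = 50)`), while the two remaining modules absorb a
false-positive pair and residual estimation structure — which is why the
cross-validation, scoring pure reconstruction, settles on rank 4 rather
than 2. `report_by_tree(res)` tabulates module usage by vine tree. With
`run_config(output = "results/")` all stage artifacts (vine JSON, density
archive, coefficient tables, CV report) are written to disk; the same
pipeline is scriptable via `inst/cli/copulamodules`.

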