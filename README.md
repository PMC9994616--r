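# zetaform

Forms of multisite similarity (zeta diversity) decline in ecological
communities.

## The problem

The number of species shared by two or more sites is a fundamental measure
of spatial variation in species composition. Zeta diversity of order *i*,
written ζ<sub>i</sub>, is the average number of species shared by *i* sites;
as more sites are combined, ζ<sub>i</sub> declines, at a rate increasingly
controlled by the most widespread species. Across empirical site-by-species
matrices this decline overwhelmingly follows one of two parametric forms:

- **exponential** — ζ<sub>i</sub> = a · exp(−b · i), classically read as
  stochastic (species-level) community assembly;
- **power law** — ζ<sub>i</sub> = c · i<sup>−d</sup>, classically read as
  niche-based sorting.

`zetaform` computes exact zeta declines from incidence matrices, classifies
communities between the two forms by Akaike weights on the linearized fits,
and implements the simulation machinery that explains *when* each form
arises:

- a spatially implicit **finite negative binomial (FNB)** sampling null
  model: the probability that a species with N<sub>i</sub> individuals and
  clumping k<sub>i</sub> appears in a sample covering a fraction α of the
  extent, giving the analytic decline
  ζ<sub>m</sub> = Σ<sub>i</sub> p<sub>i</sub><sup>m</sup>; used to sweep
  sampling grain, relative-abundance evenness (log series, lognormal,
  broken stick) and conspecific aggregation (k<sub>i</sub> = k·N<sub>i</sub>·α);
- **matrix-structure simulations** (nested, evenly spaced gradients,
  compartmented, continuous, ecotone, random) with a fill-preserving
  perturbation algorithm that randomizes interspecific association while
  tracking the checkerboard C-score and the classified form;
- the **community biodiversity property battery** — probability of
  interspecific encounter (PIE), Morisita aggregation, C-score, mean
  pairwise Spearman association, singleton proportion, matrix fill — with
  standardized effect sizes (SES) against three null models (fixed-margin
  tables, quantitative shuffle, curveball);
- a **synthetic community generator** with known ground truth and an
  end-to-end pipeline (`run_dataset()`, `compare_forms()`) contrasting
  properties between the two forms with a mixed logistic model.

## Worked example

```r
library(zetaform)
coll <- generate_study_collection(n_datasets = 4, seed = 1)
m <- coll[[3]]$matrix                  # a 30 x 40 abundance matrix
fit <- fit_decline(m)                  # first-10-order zeta decline fit
fit
#> Multisite similarity (zeta) decline fit
#>   orders used: 1-10 (10 orders)
#>   winner: power
#>   wAIC: exponential = 0.02275, power = 0.9773
#>   exponential: a = 13.35, b = 0.2693  (AIC -4.157)
#>   power:       c = 16.54, d = 1.123  (AIC -11.68)
```

The decline over the first 10 orders is best described by a power law
(Akaike weight 0.98): about 16.5 species are shared per site on average,
falling as i^−1.12 — the signature of a community whose most widespread
species remain shared across many sites. `coef(fit)`, `predict(fit)`,
`residuals(fit)` and `plot(fit)` behave as for any fitted model.

The property battery for the same matrix:

```r
rec <- run_dataset(m, dataset_id = "ds003", n_null = 199, seed = 9)
rec$properties
#> Community biodiversity properties (focal: sp1, sp2, sp3, sp4 )
#>   PIE pooled / sample mean: 0.905 / 0.866
#>   Morisita mean: 1.37  (SES 12)
#>   Spearman mean: -0.113  (SES -1.48)
#>   C-score: 10.2  (SES -0.631)
#>   singletons: 0   fill: 0.355
```

The four most abundant species are mildly aggregated within sites
(Morisita 1.37, far above its fixed-margins null, SES 12) and essentially
unassociated with one another (mean Spearman ρ = −0.11). Batch analyses use
`run_pipeline()` on a collection and `compare_forms()` to test whether a
property differs between exponential and power-law communities.

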