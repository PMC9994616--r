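---
title: "Two forms of multisite similarity decline: models, simulations and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two forms of multisite similarity decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zetaform)
```

## Zeta diversity and the two competing models

For a binary site-by-species matrix with $n$ sites, zeta diversity of order
$i$ is the expected number of species shared by $i$ sites. A species
occupying $o$ sites is present in $\binom{o}{i}$ of the $\binom{n}{i}$
site combinations, so the exact expectation is

$$\zeta_i \;=\; \sum_s \binom{o_s}{i} \Big/ \binom{n}{i},$$

which `zeta_exact()` evaluates through log-binomial coefficients without
enumeration. $\zeta_1$ is mean site richness, $\zeta_i$ is non-increasing,
and only the most widespread species contribute at high orders. A
Monte-Carlo estimator (`zeta_sample()`) exists purely as a validation
counterpart.

Two parametric forms are fitted to the decline:
exponential $\zeta_i = a\,e^{-b i}$ and power law $\zeta_i = c\,i^{-d}$.
`fit_decline()` fits both by ordinary least squares on the linearized
(log) scale over the same orders, and expresses relative support as Akaike
weights, $w \propto e^{-\Delta\mathrm{AIC}/2}$. A weight of 1 means no
support for the alternative; 0.5 means equal support. The winner is the
form with the larger weight; fits within 2 AIC units are additionally
flagged `ambiguous`.

### Numerical and convention choices

* **AIC convention.** Both models are Gaussian OLS fits to the same
  log-scale response, so AIC is computed from the Gaussian log-likelihood
  of the log residuals with $k = 3$ parameters (intercept, slope, residual
  variance). Any additive constant cancels in $\Delta$AIC, which is all
  the weights use; a test cross-checks $\Delta$AIC against `lm()` +
  `AIC()`.
* **Zero zeta values.** Orders with $\zeta_i = 0$ have no defined
  logarithm and are dropped with a warning; at least three positive orders
  are required.
* **Degenerate declines.** If the log-zeta sequence is constant (e.g.
  every species saturated), the two forms are indistinguishable; the fit
  is flagged `degenerate` and experiments report `NA` weights for such
  cells rather than an arbitrary winner.
* **Number of orders.** Communities are classified from the first 10
  orders, the convention that balances discrimination between the forms
  against the site counts available in typical datasets. When a matrix has
  10 or fewer sites, `select_max_order()` supplies the fallback: the
  occupancy count of the most widespread species or
  $\ln 0.05 / \ln p_1$ sites, whichever is smaller, never fewer than 5
  orders ($p_1$ = occupancy fraction of the most widespread species; if
  $p_1 = 1$ all sites are usable).

## The abundance-based (FNB) null model

The spatially implicit null model asks which declines can arise when
species are placed *independently* of one another. If the individuals of a
species follow a finite negative binomial within the extent, the
probability that a sample covering fraction $\alpha = a/A$ of the extent
contains the species is

$$p_i \;=\; 1 - \frac{\Gamma(N_i + k_i/\alpha - k_i)\,\Gamma(k_i/\alpha)}
{\Gamma(N_i + k_i/\alpha)\,\Gamma(k_i/\alpha - k_i)},$$

and the expected decline over $m$ independent samples is
$\zeta_m = \sum_i p_i^m$ (`zeta_fnb()`). The clumping parameter follows
density-dependent scaling $k_i = k\,N_i\,\alpha$ with a single
community-level factor $k$; $k = 0.94$ is the published calibration of a
50-ha stem-mapped forest census at a 400 m² grain, and the default extent
and abundance pool (500,000 m², 300 species, 211,000 individuals) match
that census. Evaluation is in log space; for moderate abundances
($N_i \le 10^4$) an exact product-sum of log ratios is used instead of
log-gamma differences, which keeps the large-$k$ (random placement,
binomial) limit accurate to well below $10^{-6}$ relative error.

Relative abundance enters through deterministic *expected* rank abundance
vectors (`generate_rad()`): log series (Fisher's $\alpha$ solved from
$S = \alpha\ln(1 + N/\alpha)$, ranks by inverting the species-count tail),
lognormal (equally spaced quantiles; $\sigma_{\log}$ defaults to 1, which
places its evenness between the other two), and broken stick
($N_i = (N/S)\sum_{j\ge i} 1/j$), rounded by largest remainder so totals
are conserved. Using expected vectors rather than random draws makes the
scenario sweeps fully deterministic, matching the analytic character of
the model; evenness ordering (log series < lognormal < broken stick by
PIE) is asserted by test.

`grain_experiment()` sweeps sampling grain over
$\{25, \dots, 10000\}$ m² (the exact published ladder is not printed; a
doubling ladder spanning the published range is used) and
`aggregation_experiment()` sweeps $k$ from 0.1 (strong aggregation) to 10
(near-random placement) at a 100 m² grain. Three regularities emerge, each
asserted by the acceptance tests: exponential support vanishes for grains
above 400 m²; at fine grain, support increases with RAD evenness; and
support increases with aggregation strength but falls away again as
placement approaches random. Expected matrix fill (mean alpha over gamma
diversity) uses $\mathbb{E}[\gamma] = \sum_i (1 - (1-p_i)^{n})$ with $n$
the number of non-overlapping samples in the extent, capped at 100 (the
sample count behind the published fill panel is not stated; the cap only
affects very fine grains).

## Matrix structures and the perturbation experiment

Interspecific association is studied on 20 × 20 incidence matrices at fill
≈ 0.5, so that fill itself cannot drive the form. The idealized kinds are
deterministic: *nested* (most widespread species saturated, occupancies
declining linearly to 1, left-aligned; the published occupancy sequence is
not printed), *gradient_even* (equal-width contiguous ranges, evenly
spaced starts), *turnover_compartmented* (two site blocks with exactly two
shared species, each occupying half of each block so fill stays at 0.5)
and *clementsian_strict* (no shared species). The individual-based kinds
draw Poisson(50) site totals allocated multinomially: *continuous* uses
one lognormal species-probability vector for all sites; *ecotone* uses
opposed lognormal gradients for the two species guilds plus two
Bernoulli(0.9) generalists. *random* is iid Bernoulli(fill).

`perturb_step()` implements the fill-preserving randomization: choose a
site at random, turn one presence (of a species occupying ≥ 2 sites, so no
species is lost) into an absence and one absence into a presence. Row
sums, fill and species count are conserved at every iteration — asserted
per step in the tests — while column sums drift, erasing interspecific
structure. `perturbation_experiment()` tracks the C-score (mean
checkerboard units per species pair, computed over **all** species;
restricting to focal species is an empirical-battery convention only) and
the exponential Akaike weight per iteration, averaged over replicates.

Two design notes deserve emphasis:

* Under all-combinations zeta, the evenly spaced gradient declines
  *hypergeometrically* — $\zeta_i = S\binom{w}{i}/\binom{n}{i}$ for range
  width $w$ — which is faster than any exponential, so `gradient_even`
  classifies exponential with weight ≈ 1. Nested and continuous
  structures, whose most widespread species are (near-)saturated, classify
  power law; random, strictly Clementsian and two-compartment structures
  classify exponential. Perturbing a power-law start raises the C-score
  and the exponential weight together, approximately linearly, toward the
  random-matrix level; random starts stay at weight ≈ 1 throughout.
* A single saturated species contributes exactly 1 to every order of
  zeta, which is enough to flip a random (exponential) matrix to power
  law (`add_saturated_species()`); `occupancy_threshold_experiment()`
  quantifies this by forcing the most widespread species of random-fill
  matrices to an occupancy fraction $p_1$ and locating the smallest $p_1$
  at which power law becomes the majority classification over 200
  replicates per level. At the dense fill (0.5) of the matrix experiments
  this switch sits near $p_1 = 0.9$ — the same threshold emerges from
  classifying the expected curve
  $\zeta_i = (S-1)\,0.5^i + \binom{m}{i}/\binom{n}{i}$ — and it moves
  toward lower occupancy for the sparser matrices typical of field data;
  the `fill` argument exposes this sensitivity.

## Community biodiversity properties and null models

For abundance matrices the battery in `community_properties()` quantifies
the three property families that define compositional structure:

* **Evenness** — Hurlbert's PIE,
  $\frac{N}{N-1}\bigl(1 - \sum (n_i/N)^2\bigr)$, pooled across sites and
  averaged per site.
* **Conspecific aggregation** — the Morisita index
  $I = Q \sum_j n_j(n_j - 1) / (N(N-1))$ per species (1 = random, $Q$ =
  maximal aggregation), averaged over the focal species. Species with
  fewer than 2 individuals have no defined index and are excluded with a
  warning.
* **Interspecific association** — mean pairwise Spearman correlation of
  untransformed abundances over focal pairs (zero-variance vectors are
  skipped with a warning), and the incidence-based C-score
  $(r_i - S_{ij})(r_j - S_{ij})$ averaged over focal pairs.

Focal species default to the four most abundant (ties broken by occupancy,
then column order), with `top_quartile` and `above_median` variants.
Standardized effect sizes use 999 null matrices by default,
$\mathrm{SES} = (\mathrm{obs} - \overline{\mathrm{null}})/\mathrm{sd}(\mathrm{null})$
with the sample standard deviation; a constant null ensemble yields an
undefined flag rather than an infinite score. The null models match each
statistic's invariances: `stats::r2dtable` fixed-margin tables for
Morisita, vegan's individual-based quantitative shuffle (`c0_both`,
preserving each species' total and occupancy count) for Spearman, and
vegan's curveball (preserving all margins; 5 × species trades of burn-in
per draw, a conservative default for matrices of this size) for the
C-score, computed on the focal submatrix (a full-matrix variant is
available). Conservation of every stated margin on every draw, the
hypergeometric law of the 2 × 2 fixed-margins case, the two-state orbit of
the 2 × 2 checkerboard under curveball, and near-zero SES under the
self-null are all asserted by tests.

## Synthetic study collections and the empirical pipeline

`generate_community()` builds CESTES-like abundance matrices whose knobs
map one-to-one onto the property families: RAD shape and $\sigma_{\log}$
(evenness), negative-binomial dispersion `k_agg` via gamma-multiplier
mixing of the multinomial allocation (aggregation; small $k$ = clumped),
association mode (`random`, `gradient`, `compartment` — the latter
alternates abundance ranks between blocks so the focal species are
segregated), and a forced occupancy fraction `p1_target` for the most
widespread species (implemented post hoc by thinning/augmenting presences,
which slightly perturbs column totals — no standard generative family
fixes $p_1$ exactly). Defaults (30 × 40, Poisson site totals of mean 40,
$\sigma_{\log} = 1.5$) give matrix fill near 0.3, the sparseness typical
of empirical community matrices; denser defaults would push the
$p_1$ threshold upward and blur the two generated classes. The generator
emulates count matrices with controlled structure; it does not emulate
spatial autocorrelation within sites, detection error, or the trait and
environment tables of real databases — passing tests therefore validate
the machinery, not any claim about particular field systems.

`generate_study_collection()` mixes exponential-inducing specs
(compartmented, $p_1 = 0.5$, strong aggregation) with power-inducing ones
(random association, $p_1 = 0.95$, weak aggregation), with consecutive
datasets sharing a study id. `run_dataset()` classifies (binarized,
first 10 orders, order-selection fallback below 11 sites) and computes the
battery; `compare_forms()` regresses form (exponential = 1) on one
property with a random intercept per study (`lme4::glmer`), falling back
to a plain logistic model when studies are singletons or the mixed fit
fails, and to a Firth bias-reduced logistic — flagged — under complete
separation, which strong built-in effects readily produce.
`compare_context()` handles continuous covariates by the same logistic
route and categorical ones by chi-square. Batch determinism comes from
per-dataset seeds derived by stable hashing of dataset ids.

## Problem sizes and limitations

The simulation experiments in the tests use trimmed problem sizes chosen
to exercise every property at comfortable statistical resolution:
enumeration oracles up to 6 × 8 matrices, 30–50 replicates for majority
classifications, 8–10 replicates × 40–50 iterations for perturbation
trajectories, 19–199 null matrices inside pipeline checks (999 remains
the analysis default), and 200 replicates per occupancy level in the
threshold experiment. Known limitations: the three-parameter
power–exponential decline model is deliberately out of scope; the reader
accepts integer counts only (`round = TRUE` for near-integer data);
mixed-logistic estimates are validated by parameter recovery on synthetic
collections rather than against any particular solver; and the $p_1$
forcing perturbs column totals slightly.
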