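---
title: "Assessing small plant populations: importance values, niche metrics, demography, red-list rules, and soil-trait ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing small plant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichepop)
```

`nichepop` implements the quantitative core of a conservation assessment
for a narrowly distributed plant: the kind of analysis done for cliff
herbs such as *Salvia daiguii* (Zhangjiajie, Hunan), whose entire known
range is a handful of sites and whose communities are surveyed with a
few fixed-area quadrats. This vignette explains the models and
conventions behind each stage, the choices that were genuinely open,
and what the simulation-based tests do and do not demonstrate.

## Importance values

Within a quadrat, a species' importance value averages three relative
components, each a percent of the plot total:

$$\mathrm{IV} = \frac{\mathrm{RA} + \mathrm{RH} + \mathrm{RC}}{3},$$

where RA is relative abundance (individual counts), RH relative height,
and RC relative cover. Because each component sums to 100 within a
plot, so do the IVs; `importance_values()` enforces this to $10^{-9}$
and completes the species-by-plot grid with zeros for absentees.

Two conventions needed a decision:

* **RH uses the per-species mean height**, not count-weighted summed
  heights. Field protocols record one mean height per species per
  quadrat; both options are arithmetically sensible, but the mean is
  what the recorded variable supports. The choice is fixed in code
  rather than configurable because the input schema only carries the
  mean.
* **Cross-plot summaries (`iv_summary()`) default to the
  population-SD standard error**, $\sqrt{\sum(x-\bar x)^2/n}/\sqrt n$.
  Published importance tables in this literature are commonly computed
  in spreadsheets whose default SD is the population form; only this
  convention reproduces the bundled reference column (for example the
  row with plot IVs 16.66, 1.67, 29.51, 25.07 gives SE 5.31; the
  sample-SD convention would give 6.13). `se = "sample"` switches to
  the $n-1$ form.
* Display filtering of minor species (e.g. "IV > 1%") is a reporting
  option in the pipeline only; niche metrics are always computed on the
  full table.

## Niche breadth and overlap

With quadrats as resource states and a species' per-plot IVs as its
resource-use vector $\mathbf{v}$:

* **Levins breadth** $B = 1/\sum_k p_k^2$ with
  $p_k = v_k / \sum_j v_j$, ranging from 1 (single-plot specialist) to
  the number of plots (uniform use). A brute-force grid search over the
  3-plot simplex in the tests confirms the uniform vector is the
  maximiser.
* **Shannon breadth** $B_s = -\sum_k p_k \ln p_k$ with
  $0 \ln 0 := 0$. Here the convention genuinely matters. Under the
  `"iv-fraction"` convention $p_k = v_k/100$: the percent IVs are read
  directly as fractions of the plot community, *without* renormalising
  within the species. Under `"normalized"`, $p_k = v_k/\sum v$.
  Recomputing the bundled reference table shows its Levins column is
  the normalised form while its Shannon column is the IV-fraction form
  — a mixed convention that `niche_breadth(convention = "classic")`
  reproduces; `"normalized"` applies the same normalisation to both.
* **Pianka overlap**
  $O_{ij} = \sum_k p_{ik}p_{jk} \big/ \sqrt{\sum_k p_{ik}^2 \sum_k p_{jk}^2}$
  is scale-invariant in each species (the normalisations cancel), so
  raw IVs are used directly. It is 1 exactly for proportional vectors
  and 0 exactly for disjoint plot supports; property tests fuzz the
  scale invariance and check both boundary characterisations.

`overlap_census()` counts pairs at or above a threshold **inclusively**
(default 0.50): on the bundled published matrix the count at 0.50 is 43
of 78 pairs, which includes the single printed 0.50 cell — a strict
inequality would give 42. Zeros on recomputed matrices are detected at
$|o| < 10^{-12}$, never by rounding.

A caveat the tests surface deliberately: a published 2-decimal IV table
does not always recompute its own derived columns exactly, because the
original calculations used unrounded working values. On the bundled
tables, three Levins cells and five overlap cells (including one
printed 0.00 between two species that in fact share a quadrat) differ
from recomputation by more than 0.005, and one mean by 0.01. The
package reports what the printed inputs imply; the bundled published
overlap matrix is kept as its own fixture (`salvia_overlap()`) so the
published census counts (78/43/13) remain reproducible as printed.

## Demography

`census_totals()` and `stage_percentages()` aggregate stage-structured
censuses (adult / juvenile / seedling, summing exactly to totals) with
percentages rounded half-up to 2 decimals. `decline_flags()` compares
each site's two most recent surveys. Historical cells that only bound a
count ("<200") are treated as censored: the default `"pessimistic"`
policy uses the bound as the earlier total (so a fall from "under 200"
to a handful of plants is a decline), while `"optimistic"` refuses to
flag any comparison against a censored value, since the true earlier
count could have been arbitrarily small. The overall flag compares
aggregate totals over sites present in both of the two most recent
years; a site first surveyed in the latest year carries no trend
information and is excluded.

## Red-list rules

`assess_criterion_c()` encodes IUCN v3.1 criterion C: fewer than
250 / 2,500 / 10,000 mature individuals for CR / EN / VU, with
subcriterion C2 requiring an observed continuing decline plus at least
one qualifying condition — a(i), no subpopulation above 50 / 250 /
1,000 mature individuals, or b, extreme fluctuation. Extreme
fluctuation is an asserted input: the order-of-magnitude test behind it
needs census time series the demography module does not attempt to
judge. `assess_criterion_d()` encodes the very-small-population
criterion (CR < 50, EN < 250, VU D1 < 1,000). Criteria A, B and E need
range geometries, quantified trend rates, or extinction-probability
models outside the package's inputs, and are deliberately not encoded.
The PSESP screen's cutoffs (mature < 5,000; populations ≤ 5) are
explicit configuration, since that designation's criteria are
descriptive policy rather than numeric standard.

Boundary tests pin the thresholds exactly (249 is CR, 250 is EN, and so
on), and a monotonicity property checks that fewer mature individuals
never yields a less-threatened category.

## Redundancy analysis

`rda_fit()` implements constrained ordination from first principles:
both matrices are column-standardised (z-scores by default — traits mix
centimetres and counts, soil variables mix pH with mg/kg; `"center"` is
available when units are homogeneous), the responses are regressed on
the explanatory matrix by QR least squares, and the constrained axes
are the eigenvectors of the fitted-value covariance. Eigenvalues
partition the fitted variance, and axis percentages are reported
against the total response variance, so constrained plus residual
variance equals the total to $10^{-9}$.

The fit requires strictly more samples than explanatory variables
(rather than the stricter `n > p + 1`): this admits the exact
full-rank case in which the constraints span the whole centred sample
space and the analysis must reduce to PCA of the responses — the
equivalence is tested against a direct spectral decomposition on 5 × 4
matrices to $10^{-9}$, and a second oracle cross-checks eigenvalues
against an independent constrained-ordination implementation.
`forward_select()`, which computes pseudo-F statistics, does require
residual degrees of freedom (`n > k + 1`).

Forward selection is greedy on added fitted variance, with ties broken
lexicographically. For the variable selected at each step:

* **pseudo-F** $= \dfrac{\Delta V / 1}{(V_{tot} - V_{model}) / (n - k - 1)}$,
  with $k$ the model size including the new variable;
* **contribution** is $\Delta V$ as a percent of the all-variable
  constrained variance, so a full selection's contributions sum to 100;
* **p-values** come from permuting reduced-model residuals: responses
  are reconstructed as reduced-model fit plus row-permuted residuals,
  and $p = (1 + \#\{F^\ast \ge F\})/(n_{perm}+1)$, with 999
  permutations by default (floor $1/1000$) under one seeded stream per
  call.

One statistical caution: when many candidates compete, the first
*selected* variable's naive p-value is anti-conservative, because the
maximum-F variable was chosen before testing (the familiar selection
bias of stepwise constrained ordination). The type-I-error simulation
therefore evaluates the permutation machinery on a single null
candidate, where the p-value must be uniform; with 200 replicates the
rejection rate at $\alpha = 0.05$ is required to sit within three
binomial standard errors of 0.05. Users ranking many soil variables
should read early-step p-values as descriptive, or apply a correction
such as Blanchet-style double stopping.

## Synthetic data: what it emulates, and what it does not

The generators draw with one private, seeded RNG stream per call (the
caller's `.Random.seed` is untouched), and every generated table passes
the same validation as read data.

* `sim_community()` emulates a 62-species, 4-quadrat herb survey:
  Bernoulli occupancy (default 0.4, conditioned on each species
  occurring somewhere) yields site-restricted species; counts are
  rounded lognormal (meanlog 1.5, sdlog 1) because observed IVs span
  two orders of magnitude — heavier-tailed than Poisson; heights are
  truncated normal around 25 cm; covers are Beta(1, 8) fractions
  scaled to percent.
* `sim_census()` uses binomial thinning (default 15% loss per
  interval) with multinomial stages on the simplex (0.23, 0.72, 0.05) —
  the juvenile-dominated, seedling-poor structure of a
  recruitment-limited relict population. Thinning is verified against
  its expectation by Monte-Carlo (600 replicates, within three standard
  errors).
* `sim_soil_traits()` spans organic matter uniformly over 44–118 g/kg
  (the observed contrast between cliff soils and enriched garden
  substrate), keeps pH in a narrow slightly alkaline band (7.9 ± 0.15),
  and builds each trait from a shared standardised signal
  `om_effect · z(OM) + ph_effect · z(pH)` (defaults 1 and −0.5), small
  random nuisance loadings (SD 0.1) on the other eleven soil variables,
  and Gaussian noise (SD 0.5). Parameter-recovery tests require OM to
  be selected first — and pH before any nuisance variable — in at
  least 95 of 100 seeded simulations at n = 60.

None of the generators model spatial structure, temporal
autocorrelation, observation error in cover estimation, or
between-site heterogeneity in stage structure. Passing recovery tests
therefore shows the estimators work when their assumptions hold, not
that field data satisfy those assumptions.

## Numerical conventions and problem sizes

* Published-table comparisons use ±0.005 on recomputed, unrounded
  values against 2-decimal cells (±0.01 for census percentages);
  rendering uses round-half-up, matching printed tables, via
  `round_half_up()`.
* `write_table()` output is byte-stable for identical input — fixed
  decimal rendering, `\n` endings, no locale dependence — so pipeline
  bundles diff cleanly across runs.
* Degenerate inputs fail loudly with typed errors: all-zero plots,
  all-zero IV rows, constant columns under z-scoring, rank-deficient
  constraint matrices (naming the collinear columns), censuses whose
  stages contradict their totals.
* The simulation studies in the test suite use 200 null replicates for
  the type-I check, 100 seeds for selection recovery at n = 60 with 99
  permutations per test, and 600 Monte-Carlo replicates for the
  thinning check — sizes chosen so the full suite runs comfortably on a
  laptop while keeping binomial error bands narrow enough to be
  meaningful.

## Known limitations

* The overlap census of the *published* matrix and of a recomputed one
  can legitimately differ by one pair at the 0.50 boundary and one
  zero (see the rounding caveat above); both views are exposed.
* Criterion C's condition a(ii) (fraction of mature individuals in one
  subpopulation) is not implemented; a(i) activates only when the
  largest-subpopulation count is supplied.
* The RDA assumes linear trait–soil responses; unimodal responses
  (CCA) are out of scope.
* Forward selection has no built-in stopping rule: it ranks all
  variables (use `steps` to truncate), leaving model-size decisions to
  the analyst.
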