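---
title: "Modelling land-use and land-cover change scenarios with lulcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling land-use and land-cover change scenarios with lulcsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lulcsim)
```

## The modelling problem

`lulcsim` implements the standard hybrid pipeline for projecting land-use and
land-cover (LULC) change on a regular categorical grid, of the kind widely
applied to tropical deforestation frontiers such as the Colombian Amazon:

1. **Historical change analysis.** Two co-registered categorical maps at
   dates $t_0$ and $t_1$ are cross-tabulated; minor transitions are filtered
   out (the packaged seven-class analysis ignores transitions under
   5,000 ha) and the survivors are grouped into *submodels* — degradation
   (intact forest to fragmented/shrub covers), substitution (vegetation to
   pastures and crops) and regeneration (recovery toward forest).
2. **Driver screening.** Candidate explanatory rasters (distances to cover
   classes, patch sizes, accessibility, climate, ...) are screened by
   Cramér's V against the cover map; drivers with $V \ge 0.15$ enter the
   model. Continuous drivers are discretised into 256 equal-width bins
   before the $\chi^2$ computation, mirroring the convention of the
   established land-change modelling software this pipeline re-implements.
3. **Transition potentials.** A one-hidden-layer perceptron per submodel is
   trained on balanced samples of changed and persistent cells
   ($y = f(\sum_i w_i x_i)$ with sigmoid $f$), yielding a per-cell,
   per-transition potential in $[0,1]$, plus an *accuracy rate* (AR, percent
   of held-out samples classified correctly) and a *skill measure*
   $S = (A - E)/(1 - E)$, $E = 1/\text{(number of outcome classes)}$.
4. **Demand.** A first-order Markov chain estimated from the same map pair
   projects class areas to the horizon. The matrix can be annualized (matrix
   root), powered, overridden by scenario-specific external matrices, or
   calibrated to an annual forest-loss trajectory.
5. **Allocation.** Demanded change is placed on the highest-potential cells,
   under scenario constraints (masks that zero a transition's potential,
   e.g. protected areas) and incentives (masks that multiply it, e.g.
   mining titles or conservation agreements).
6. **Validation.** A simulated map is compared with an observed one through
   the confusion matrix, overall Cohen's kappa and the per-class kappa index
   of agreement (KIA).

Because the real basin-scale rasters behind such studies are not publicly
archived, the package is built to be *verifiable without them*: a synthetic
landscape generator plants a known transition matrix and known driver
responses, and every stage of the pipeline is tested by recovering what was
planted.

## Scenario parameterisation

Three scenario archetypes are built in (`build_scenario()`):

* **Trend (business as usual).** The historical Markov matrix as-is;
  optionally a conservation-agreement incentive on the
  pastures-to-fragmented recovery transition.
* **Extractivist.** An external matrix with intensified forest loss; a
  mining-titles incentive on forest-loss transitions; an annual-loss
  trajectory ramping linearly from the 2008–2016 mean loss to **+40%** of it
  at the 2040 horizon. The "+40%" narrative is read as a year-to-year ramp
  reaching +40% at the horizon; a constant +40% jump is available via
  `extractivist_mode = "jump"` in `loss_trajectory()`.
* **Sustainable development.** An external matrix favouring persistence and
  regeneration; total constraints on forest loss inside protected areas,
  indigenous reservations and on slopes steeper than 100%; a loss
  trajectory applying a multiplier that ramps linearly from **0.20** (an
  immediate 80% cut of the 2002–2016 mean) to **0.01** (a 99% cut) at the
  horizon. The linear interpolation between the two printed anchors is the
  package's reading of a "gradual year-by-year reduction"; no functional
  form is prescribed by the narrative.

Scenario external matrices are printed to two decimals in the source tables
and their rows sum to 0.98–1.00; `load_scenario_matrix()` renormalizes each
row and records the factors. The packaged extractivist table is incomplete
as printed (one row missing, one row with run-together digits); the affected
rows carry a `suspect` flag rather than a silent repair, and the missing row
is filled from the trend matrix the external models were derived from.
Scenario matrices are applied as one-shot horizon matrices (as printed);
annual stepping is available through `annualize()`.

Incentive magnitudes are never quantified in the source narratives; the
default multiplier is 1.5, configurable per mask. Constraints zero the
potential rather than removing demand, so demand unmet under constraints is
reported in the allocation ledger — this matches the qualitative account of
recovery compensating blocked deforestation.

## Numerical choices

* **Annualization** uses the eigendecomposition matrix root. Roots of
  empirical LULC matrices generically carry small negative entries; these
  are clipped to zero and rows renormalized, with the pre-repair
  reconstruction error checked against `1e-6` and the repair magnitude
  stored as an attribute. Matrices with non-positive or strongly complex
  eigenvalues are rejected with a pointer toward interval subdivision.
  Matrices that *are* exact powers of a non-negative annual matrix
  round-trip to floating-point accuracy.
* **Demand integerisation** uses largest-remainder (Hamilton) apportionment
  per source class, so per-class outflows track the real-valued recursion
  within one cell per step.
* **Allocation** is greedy ranked allocation: per transition, eligible
  cells are taken in descending potential until demand is met; a cell
  eligible for several transitions goes to the one where it holds its
  highest potential, with seeded uniform tie-breaking; a second pass lets
  transitions with remaining demand take unclaimed eligible cells so that
  feasible demand is not left unmet by the conflict rule. This is a
  declared approximation to the undocumented multi-objective allocator of
  the commercial tool; its correctness surface is the end-to-end closure
  test below. Unmet demand is carried into the next step (disable with
  `carry_unmet = FALSE`).
* **MLP training** is full-batch backpropagation with momentum on
  cross-entropy loss, sigmoid hidden and output units, one output node per
  transition-or-persistence class, min–max feature standardization frozen
  into the model, and early stopping when held-out accuracy has not
  improved for `patience` epochs. Function defaults (learning rate 0.01,
  momentum 0.5, 10,000-epoch cap, patience 100) are deliberately
  conservative; the pipeline configuration uses a stronger setting
  (8 hidden units, learning rate 0.5, momentum 0.9, 5,000 epochs, patience
  1,000) that converges quickly on the balanced, standardized samples the
  sampler produces. All of these are exposed; none is prescribed by the
  source analysis, which reports no hyperparameters.
* **KIA** is the conditional (user's) kappa
  $\kappa_i = (p_{ii} - p_{i\cdot}p_{\cdot i}) / (p_{i\cdot} -
  p_{i\cdot}p_{\cdot i})$. Published agreement tables print two KIA columns
  without defining them; `validation_report()` therefore emits both
  conditionings (observed-side and simulated-side), with rows = observed
  fixed in all outputs.
* **Degenerate inputs**: both-maps-constant-and-equal yields kappa 1 by
  stated convention; a constant driver yields $V = 0$ with a warning; a
  class absent at $t_0$ yields an identity matrix row with a warning; a
  class absent from a map yields an all-infinite distance layer with a
  warning.

## The synthetic landscape

`synthetic_config()` defines a fully self-contained study system. The
defaults are fixed once and used by the whole verification suite:

* 128 × 128 cells of 60 m (the analysis resolution; 256 × 256 for the
  large-sample recovery checks), four classes — forest, fragmented
  vegetation, pastures and crops, water — with priors 0.55/0.20/0.20/0.05,
  roughly the forest-dominated composition of an Amazonian frontier
  landscape.
* A 14-year true matrix (matching a 2002→2016-style interval) with forest
  persistence 0.90, degradation forest→fragmented 0.08, substitution
  fragmented→pasture 0.10, mild regeneration pasture→fragmented 0.05, and
  inert water.
* Three drivers: distance to pastures (planted effect −2.5 — change
  concentrates near existing pastures), an accessibility gradient (planted
  effect +1.5, which also biases where pastures sit in the *initial* map,
  as real accessibility does), and a smooth random field with zero planted
  effect, the negative control for driver screening.
* The planted potential is $\sigma(\sum_k w_k (z_k - 1/2))$ over min–max
  standardized drivers. Which cells change is decided by ranked allocation
  on this potential plus Gaussian jitter (`noise_sd = 0.02`); destinations
  follow smooth per-destination preference surfaces. The jitter is kept
  small relative to the ~0.8 potential spread because the generator's
  self-consistency contract — simulating with the true matrix and true
  potentials must reproduce the planted future with overall kappa ≥ 0.9 —
  bounds how much unexplained selection noise the system may contain.
  Per-class counts use largest-remainder apportionment of the true matrix
  rows, so Markov estimation stays unbiased by construction.
* The initial map is the argmax of per-class Gaussian random fields
  (smoothed white noise, `patchiness` = blur radius in cells) with offsets
  iteratively calibrated to the priors. This is a neutral-landscape
  construction rather than literal region growth; it satisfies the same
  contract (spatial autocorrelation, all classes present, determinism under
  seed, frequencies near priors). Because priors are always honoured, the
  degenerate single-class limit at extreme patchiness is excluded by
  design.

What the synthetic system deliberately does **not** emulate: real Amazonian
patch geometry and road networks, spatially heterogeneous transition
regimes, class-dependent driver responses, temporal driver dynamics, and
map-production error. Passing the recovery suite therefore demonstrates
that the machinery is correct and unbiased under the model's own
assumptions — not that the model is adequate for any particular real
landscape.

## Verification strategy and problem sizes

The test suite verifies, at sizes chosen to keep a full run around ten
seconds:

* hand-arithmetic oracles for Cramér's V, kappa, KIA and the skill measure
  (exact);
* brute-force equality of the distance transform on 24 × 24 grids;
* recovery of the planted transition matrix within 3 binomial standard
  errors per entry, and planted-vs-noise driver separation at $V = 0.15$,
  at 256 × 256 (the noise field's $V$ sits near 0.12–0.15 at this size —
  spatial autocorrelation inflates finite-sample association, which is
  exactly why the screening threshold exists);
* trained-potential discrimination (AUC ≥ 0.85 pooled over the two dominant
  transitions) at 256 × 256;
* the closure test: one-interval simulation with true matrix and true
  potentials reproduces the planted future with kappa ≥ 0.9, full demand
  satisfaction, and exact `achieved + unmet = demanded` accounting at
  128 × 128;
* constraint dominance: an all-true protection mask on forest-loss
  transitions yields zero forest-loss allocations under arbitrarily
  inflated demand;
* arithmetic on the packaged printed tables (14 major transitions;
  substitution total 1,847,399 ha; degradation total 730,765 ha; the
  2040 scenario areas and their percentage changes).

One transcription tension in the packaged tables is preserved rather than
resolved: the narrative figure of ~0.66 Mha for forests degrading to
fragmented cover matches the Amazon-forests row alone (664,181 ha), while
the two contributing table rows sum to 712,921 ha. Both rows ship verbatim.

## Known limitations

* The allocator is a greedy approximation; pixel-exact agreement with the
  commercial tool's allocation is out of scope, and published full-scale
  validation statistics (overall kappa 0.91 on the 2018 hold-out) require
  the original rasters, which have no public accession.
* Annualization is undefined for matrices with non-positive eigenvalues
  (strong oscillatory regimes); such regimes do not occur in
  diagonally-dominant LULC matrices but the error path is explicit.
* Only an overall Cramér's V per driver is computed, not per-class
  variants.
* Grid I/O is plain-text ESRI ASCII grid plus CSV legends; there is no
  reprojection — inputs must share one grid.
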