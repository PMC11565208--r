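---
title: "Models and methods: C4 gas exchange, stomatal limitation, and whole-plant water use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: C4 gas exchange, stomatal limitation, and whole-plant water use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4wue)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generator does and does not emulate, and the numerical choices that were
genuinely open.

## The C4 A/ci model

The demand side of leaf gas exchange is modelled with the reduced
enzyme-limited C4 form

$$A(c_i) = \min\!\left(\frac{V_{pmax}\, c_i}{c_i + K_p},\; V_{max}\right) - R_d ,$$

with $c_i$ the intercellular CO2 mole fraction (µmol mol⁻¹), $V_{pmax}$
the apparent maximum PEPC carboxylation rate and $V_{max}$ the
CO2-saturated asymptote (both µmol m⁻² s⁻¹), $K_p$ the Michaelis constant
of PEPC for CO2 (µmol mol⁻¹) and $R_d$ day respiration (µmol m⁻² s⁻¹).
Assumptions worth stating explicitly:

- **Mesophyll CO2 equals $c_i$.** There is no mesophyll-conductance term;
  the two quantities the model is used to estimate — the initial slope
  (governed by $V_{pmax}/K_p$) and the asymptote ($V_{max}$) — are
  *apparent* capacities on the $c_i$ basis.
- **Hard minimum.** $V_{max}$ is defined as the asymptote of the curve, so
  the saturated branch is exactly flat and the two branches meet at a sharp
  inflection $c_i^* = V_{max} K_p / (V_{pmax} - V_{max})$, finite only when
  $V_{pmax} > V_{max}$. No empirical curvature parameter smooths the kink.
- **No bundle-sheath leakiness, light-limited branch, or temperature
  response.** Curves are measured at one saturating light level and one
  temperature; the model describes that operating regime only.
- µmol mol⁻¹ and µbar are treated as interchangeable at ambient pressure.

Defaults $K_p = 80$ µmol mol⁻¹ and $R_d = 2$ µmol m⁻² s⁻¹ are typical C4
literature values, declared (not estimated) and overridable everywhere a
`c4_params` or `fit_config` is accepted.

## Operating point, stomatal limitation, iWUE

Supply of CO2 through stomata is $A = g_{s,\mathrm{CO2}}\,(c_a - c_i)$ with
$g_{s,\mathrm{CO2}} = g_{s,\mathrm{H2O}}/1.6$ (the diffusivity ratio of the
two gases; instruments report the water-vapour conductance).
`solve_operating_point()` intersects supply with demand; because demand is
non-decreasing and supply strictly decreasing in $c_i$, the crossing is
unique. On the saturated branch the solution is closed-form
($c_i = c_a - (V_{max}-R_d)/g_{s,\mathrm{CO2}}$); otherwise the root is
bracketed and bisected to a residual below $10^{-10}$.

Stomatal limitation compares the operating point with a hypothetical leaf
whose $c_i$ equals the atmospheric $c_a$ (no diffusive resistance):

$$\mathrm{SL} = \frac{A(c_a) - A(c_{i,\mathrm{op}})}{A(c_a)} .$$

Both terms are evaluated on the *fitted* curve, not on raw observations, a
deliberate convention: measurement noise then cannot produce negative SL.
The only geometric route to SL < 0 is $c_{i,\mathrm{op}} > c_a$, which is
clipped to 0 with a warning. SL is undefined at or below the compensation
point ($A(c_a) \le 0$), which is an error rather than a silent NA. While
the operating point stays on the saturated branch, SL is exactly 0 — the
quantitative core of the claim that a C4 leaf can trade conductance for
water savings at no assimilation cost. `sl_scenario()` packages this:
starting above the inflection (e.g. $c_{i,\mathrm{op}}/c_a = 0.4$), a 20%
conductance reduction leaves SL unchanged at 0; pushing the operating point
below $c_i^*$ makes SL grow steeply.

Intrinsic water-use efficiency is $A_N / g_{s,\mathrm{H2O}}$
(µmol CO2 per mol H2O), reported on the water-vapour basis.

## Curve fitting

`fit_aci()` minimises $\sum_i (a_{n,i} - A(c_{i,i}))^2$ with $K_p$ fixed
and $\{V_{pmax}, V_{max}, R_d\}$ free by default (bounds (0, 500], (0, 200]
and [0, 10] respectively). The piecewise model is linear in all three
parameters *conditional on* assigning each point to a branch, so the core
of the optimiser alternates branch assignment with exact linear least
squares — on noiseless data this terminates at the exact solution, which is
how the machine-level recovery tests are possible. Because the assignment
iteration is only locally convergent, it is run from a deterministic grid
of multistart scale factors around `initial_guess()` (max observed $a_n$
plus $R_d$ for $V_{max,0}$; the low-$c_i$ slope inverted through the
hyperbola for $V_{pmax,0}$), and the best candidate is polished with
Nelder–Mead on the raw objective. The perturbation grid is fixed rather
than randomly drawn: fits are then bit-reproducible and independent of the
global RNG state, and point order is made irrelevant by sorting internally.

Identifiability deserves care with this protocol. The stepped-CO2 sequence
(400, 200, 50, 150, 300, 400, 500, 600, 700, 800, 1200 µmol mol⁻¹) is
retained verbatim — including both 400 steps, which the protocol repeats
deliberately and which `validate_protocol()` uses as a drift check. At a
typical conductance, only the lowest two or three steps produce operating
$c_i$ below the inflection. Two consequences:

- With $R_d$ free and a *single* sub-inflection point, the noiseless
  problem has a one-dimensional family of exact fits (the saturated level
  pins $V_{max}-R_d$ and the lone low point one combination of $V_{pmax}$
  and $R_d$). The estimates are then reported but should not be
  over-interpreted; fixing $R_d$ restores identifiability.
- `identifiable_vmax` is `FALSE` unless at least two points lie on the
  saturated branch of the *fitted* curve. One nominally saturated point is
  often an artefact of where the optimiser placed the kink in noisy data,
  so a single point is not treated as evidence for the asymptote. Flagged
  fits are excluded from $V_{max}$ group summaries by
  `analyze_experiment()`; their $V_{max}$ value (max $a_n$ + $R_d$) is a
  lower bound kept so prediction still works.

Convergence is declared at a relative RSS change of $10^{-10}$; freeing a
parameter never increases RSS (a nested-model property asserted in tests).

## Water budget

Relative soil water content references three per-pot masses: the
tare-plus-dry-soil mass, a constant plant-mass estimate from a destructive
harvest at the start of withholding (no growth interpolation over the short
window), and the saturated mass:
$\mathrm{rSWC} = 100\,(m - m_{dry})/(m_{sat} - m_{dry})$ with
$m_{dry}$ the tare + dry soil + plant total. The denominator is the
available water between saturation and the dry-basis reference, because
pots are soaked to approximately 100% rSWC at the start; values outside
[0, 100] are clamped with a warning rather than erroring, since small
weighing errors at the boundaries are routine. Daily water use is the
day-to-day mass decrement, clamped at 0 (watering events are not
modelled), and soil evaporation is not separated from transpiration — no
bare-pot controls exist in this design, so the decrement is attributed to
the plant. When no clamp fires, the decrements sum *exactly* to initial
minus final mass; that conservation identity is asserted in the tests.
Whole-plant leaf area is the sum over leaves of width × length with no
shape-correction factor.

## Statistics

The statistical layer mirrors standard greenhouse practice. Technical
subsamples (e.g. four fields of view per leaf) are averaged to one value
per replicate plant before any test. One-way ANOVA is the classical
decomposition via `lm()`. Two-way factorial ANOVA uses sum-to-zero coding
and partial (Type-III) sums of squares, computed by column-dropping the
model matrix — on balanced designs this coincides with the sequential
decomposition term by term (asserted in tests), so the choice only matters
if a design loses a replicate. Repeated-measures ANOVA is the univariate
split-plot-in-time: the between factor is tested against the
subject-within-group mean square, time and the interaction against the
residual; no sphericity correction is applied, and an incomplete
subject × time grid is an error rather than silently unbalanced. Tukey HSD
uses $q = |\bar y_i - \bar y_j| / \sqrt{(MS_W/2)(1/n_i + 1/n_j)}$ with
p-values from the studentized-range distribution (`ptukey`, itself a
numerical integration of that CDF); the two-group identity
$q = \sqrt{2}\,|t|$ is verified to $10^{-6}$ against the pooled t-test.
Letter displays are built greedily over the pairwise significance matrix.
Least-squares means come from sum-coded linear models (via `emmeans`): on
unbalanced data a marginal lsmean is the unweighted average of cell means,
not the raw marginal mean. For dry-down time courses, per-day one-way
ANOVA + Tukey flags the days and pairs that separate; days are treated as
independent families with no across-day multiplicity correction, matching
how such figures are annotated.

## The synthetic generator

`simulate_experiment()` generates every input table the analysis reads,
from one seed, so the full pipeline is testable without measured data. Its
defaults define the study conditions and are configuration, not estimates:

- **Gas exchange.** Ten plants per genotype. Each plant draws one
  multiplicative conductance deviate (CV 5%) around
  $g_{s,\mathrm{base}} \times$ the genotype's `gs_scale`
  ($g_{s,\mathrm{base}} = 0.30$ mol m⁻² s⁻¹, placing the wild-type
  operating $c_i/c_a$ near 0.4, above the inflection); $g_s$ is held
  constant across CO2 steps within a curve (the fit uses only the
  $(A, c_i)$ pairs, so a $g_s$–$c_a$ feedback would add realism the
  estimators never see). Each step's $(c_i, A)$ is the solved operating
  point, and recorded $A$ gets multiplicative Gaussian noise (CV 2%).
  With noise at zero every recorded point satisfies supply = demand
  exactly — the property the tests lean on.
- **Genotype effects** mirror a wild type plus a strong and a moderate
  engineered low-density line: $g_s$ scales 1.0 / 0.68 / 0.82, $V_{pmax}$
  scales 1.0 / 0.68 / 0.79, $V_{max}$ scales 1.0 / 0.80 / 1.0, and
  abaxial/adaxial densities of 120/75 stomata mm⁻² scaled down 43–61% and
  30–36%, with the abaxial surface always denser.
- **Dry-down.** A bucket model: 3000 g of plant-available water, potential
  use 500 g day⁻¹ at unit $g_s$ and leaf-area scaling (so the wild type
  exhausts its bucket in about six days of a nine-day withholding), with
  relative transpiration equal to 1 above a fraction-of-transpirable-soil-
  water threshold of 0.4 and declining linearly to 0 below it, lognormal
  multiplicative noise (CV 5%) on daily decrements, and masses
  reconstructed from decrements so conservation holds exactly.
- **Stomata.** Field counts are Poisson with mean density × 0.64 mm²
  (800 × 800 µm fields, four per transect, leaves four to six, both
  surfaces); complex widths/lengths are zero-truncated Gaussians, six per
  plant.

What the generator does *not* emulate — and hence what passing tests do
not show about measured data: instrument drift and match-valve artefacts
in gas-exchange logs, $g_s$ responses to the changing cuvette CO2,
within-leaf spatial gradients in stomatal density, separate soil
evaporation, day-to-day environmental variation during the dry-down, and
any correlation between a plant's conductance and its leaf area beyond the
genotype means. Within-plant and between-plant variance components are
both exposed as parameters precisely because measured values for them are
not available.

## Problem sizes and numerical choices

The test suite runs the oracle comparisons at deliberately modest sizes —
the operating-point solver against a 0.001-µmol mol⁻¹ grid search on 100
random parameter draws, recovery at 10 replicate curves, permutation nulls
at 20,000 draws — chosen so the whole suite completes in well under a
minute while keeping Monte-Carlo error far below the asserted tolerances.
Ties at the kink are resolved by assigning a point whose PEPC branch value
equals $V_{max}$ to the saturated branch. Degenerate inputs are errors
with named causes (empty curves, missing day-0 weighings, non-monotone
day sequences, empty design cells, incomplete repeated-measures grids)
rather than NA propagation.

## Known limitations

The model's $V_{pmax}$ and $V_{max}$ are apparent, $c_i$-basis quantities;
no mesophyll conductance, leakiness, or temperature correction is applied.
SL is defined on the fitted curve, so a badly fitting curve biases SL.
The statistical layer covers fixed-effects ANOVA only — no REML mixed
models, and no sphericity corrections for repeated measures. The bucket
dry-down is a one-pool model with a single threshold; it reproduces the
qualitative contrast between fast- and slow-transpiring genotypes, not
soil-physics detail.
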