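---
title: "Models and conventions behind cuprackit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind cuprackit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuprackit)
```

`cuprackit` implements the quantitative workup of a microplate CUPRAC
antioxidant assay: choosing the solvent blend for the Trolox reference,
validating the calibration, quantifying Trolox-equivalent antioxidant
capacity (TEAC), and comparing samples. This vignette records the models,
their assumptions, and every numerical convention the package had to fix
where standard assay protocols leave a choice open.

## The mixture model

Solvent blends live on the ternary simplex: methanol (z₁), ethanol (z₂)
and water (z₃) volume fractions with z₁ + z₂ + z₃ = 1. The response
surface is the canonical quadratic Scheffé polynomial with no intercept —
on the simplex an intercept is confounded with the linear terms, so the
six free parameters are the three vertex responses k₁, k₂, k₃ and three
blending (interaction) coefficients k₁₂, k₁₃, k₂₃. Fitting needs a design
of rank 6: at minimum the three vertices and the three binary blends.
`fit_scheffe()` refuses rank-deficient designs and names the unsupported
terms.

The response actually modeled is not the raw absorbance ψ but the scaled
signal Φ = ψ·σ<sub>average</sub>, where σ<sub>average</sub> is the mean
replicate standard deviation of the observation's composition *class*
(pure solvent, binary blend, or ternary blend). This class-wise scaling
folds the very different measurement scatter of the three classes into
the modeled response. Its inverse, ψ = Φ/σ<sub>average</sub>, makes the
predicted absorbance **discontinuous across class boundaries**: an edge
composition (binary, σ = 0.046 AU for the reference screen) and a nearby
interior composition (ternary, σ = 0.060 AU) divide the same Φ by
different constants. This is intentional and matters for optimization —
on the reference screen the interior holds a slightly higher Φ, but after
division by the larger ternary σ the best *absorbance* sits on the
methanol–water edge.

Conventions adopted:

* Compositions whose printed fractions sum to within 0.02 of 1 (e.g. the
  0.33/0.33/0.33 centroid) are renormalized to sum exactly 1; larger
  deviations are rejected as data errors.
* A fraction counts as "present" above `zero_tol = 1e-6`; printed designs
  use exact zeros, so this only guards floating-point noise.
* Least squares runs on all replicate observations rather than replicate
  means; with balanced replication the two coincide.
* Class σ averages are the unweighted mean over blends of the per-blend
  sample SD (n − 1). The bundled reference screen carries the σ map it
  was published with (0.039/0.046/0.060 AU at 3 decimals) as part of the
  dataset; re-estimating from the replicates reproduces those values up
  to the quoted rounding, and either map can be supplied explicitly.
* Coefficients are displayed at 3 decimals; JSON reports keep full
  precision.

## Optimization over the simplex

`optimize_composition()` maximizes the back-transformed ψ by exhaustive
evaluation over a simplex lattice (default pitch 0.005, which must divide
1 evenly), augmented with the closed-form stationary point of Φ on each
edge, t = (kᵢ − kⱼ + kᵢⱼ)/(2kᵢⱼ), and the interior stationary point from
the Lagrangian linear system. Because the class discontinuity could hide
a maximum from a pure lattice search, edges and interior are always
examined separately; the lattice itself contains every vertex and edge
point of its pitch. Ties within 10⁻¹² AU are broken toward larger
methanol fraction, then larger water fraction — a deterministic,
documented preference rather than an arbitrary index order. A dedicated
test asserts the returned optimum dominates every lattice point at pitch
0.01 and every stationary candidate.

On the bundled screen the fitted k₁₃ (0.111) is within one unit in the
third decimal of the value published with the data (0.112): the published
coefficients were computed from unrounded instrument signals, while the
shipped table — like any printed table — carries 3-decimal absorbances.
The same rounding shifts the predicted maximum (1.322 vs 1.332 AU, 0.8%).
The optimum composition itself is insensitive: 0.64:0.36 methanol/water
to two decimals either way.

## Calibration validation

The line y = φx + β is fitted by ordinary least squares. Linearity is a
*joint* decision: Pearson r > 0.990 (r itself, not r²) **and**
lack-of-fit F below its α = 0.05 critical value. The lack-of-fit ANOVA
splits the residual sum of squares about the line into pure error
(replicate scatter about level means, df = n − L) and lack of fit (level
means about the line, df = L − 2); the F ratio always carries the
lack-of-fit mean square in the numerator (one-sided test). The suite
cross-checks this decomposition against R's nested-model `anova()` on
`lm` fits, an independent route to the same quantities.

Open conventions fixed here:

* **σ_blank.** The LOD/LOQ formulas (3.3σ/φ, 10σ/φ) need a blank SD.
  Default: sample SD of the blank-level endpoint absorbances. A
  configurable alternative uses the residual SD of the regression. Both
  are legitimate ICH readings; reports record which was used. On the
  bundled calibration the replicate estimator gives LOD 0.82 µM / LOQ
  2.47 µM; their ratio is 10/3.3 by construction, always.
* **Accuracy at the blank.** Percent deviation from a nominal of zero is
  undefined, so the 0 µM level reports the absolute back-calculated
  deviation in µM instead; all non-blank levels report
  100·(x̂ − x)/x against a ±15% acceptance bound.
* **Endpoint rule.** A kinetic series contributes its final reading by
  default; averaging the last N readings is available where the end of
  the monitored window is noisy.
* **Precision.** CVs pool every replicate × timepoint reading within a
  concentration level, so they reflect both replicate scatter and drift
  over the monitored window.
* **Molar absorptivity.** ε = φ·10⁶/h converts an AU/µM slope at path
  h (default 0.50 cm, the solution height of a 250 µL fill) to
  L mol⁻¹ cm⁻¹; the slope's standard error propagates linearly.

## TEAC quantification

TEAC = ΔA·V_f·V_i/(ε·V_s·W_s·h) is evaluated exactly in mol/g, the
formula's natural unit; display defaults to mmol/g. Geometry defaults
(V_f = 0.25 mL, V_i = 10 mL, V_s = 0.10 mL, W_s = 0.080 g, h = 0.50 cm)
describe the standard setup; extraction details are carried as provenance
metadata only. Negative ΔA is allowed (a sample can absorb less than the
reagent blank) but warned about, and when a calibration stage precedes
quantification the pipeline warns whenever an observed ΔA exceeds the
absorbance span of the validated range — a guard against silently
extrapolating the calibration. Well-to-sample assignment is always an
explicit user-supplied layout table; plate layouts are never inferred.

## Group comparison

The comparison sequence mirrors routine assay statistics: Cochran's C
(largest variance over the variance total, with critical value
1/(1 + (k−1)/F(1 − α/k; n−1, (k−1)(n−1)))) screens variance homogeneity —
it is only defined for a common replicate count and is skipped otherwise;
one-way ANOVA is computed from per-group n/mean/SD, which makes raw and
summary inputs exactly equivalent; and the "multiple-range test" is
implemented as Fisher's LSD with the pooled within-group mean square,
with Tukey's HSD as a more conservative option — LSD matches the default
behavior of the desktop statistics packages such comparisons are usually
run in. Homogeneous subsets are the connected components of the
non-significant-pair graph (transitive merging), reported in mean order.
Summary input without a stated n assumes triplicates — the near-universal
practice in this assay — and the assumption is flagged in the report.
Displayed p-values are floored at 10⁻¹²; stored values are exact.

## What the synthetic data emulate

The generators draw Gaussian, homoscedastic noise within a composition
class or concentration level — the simplest model consistent with
replicate scatter in this kind of data, and deliberately no more:

* `gen_mixture_table()`: the 7-point simplex screen (vertices, edge
  midpoints, centroid), mean ψ = Φ(z)/σ_class, noise SD = σ_class (times
  an optional `noise_scale`; 0 gives exact data).
* `gen_calibration()`: triplicates on y = 0.013x + 0.039 with σ = 0.004
  AU by default — chosen to reproduce residuals of the scale seen in the
  bundled calibration.
* `gen_kinetic()`: base + drift·t + noise, one reading per minute.
* `gen_samples()`: inverts the TEAC formula to place sample wells at a
  target capacity; blanks sit at the calibration intercept.

Everything is deterministic given the seed, and generators emit the same
CSV dialects the readers parse. Real plates additionally show edge
effects, evaporation drift, heteroscedastic and correlated noise; none of
that is modeled, so passing simulation tests demonstrates correctness of
the *computations*, not robustness to instrument artifacts.

Simulation sizes used by the test suite are package choices balancing
statistical resolution against a fast default run: 200 seeds for
coefficient-recovery coverage (≥95% of runs within 3 estimated SEs of
truth), 2,000 null datasets for the ANOVA type-I calibration (expected
rejection rate 0.05 ± 0.015 at that resolution), and 200 seeds for the
subset-pattern simulation.

## Known limitations

* The class-σ transform is taken as the published procedure defines it;
  the package does not attempt to justify it as a variance-stabilizing
  device, and alternative weightings (e.g. WLS on ψ) are out of scope.
* LOD/LOQ depend on an estimator choice for σ_blank that published
  protocols often leave unstated; reproducing a particular published
  limit may require trying both estimators.
* With triplicate groups, the multiple-range test has limited power: the
  subset-pattern simulation in the acceptance suite computes a recurrence
  rate near 0.5 for a mean pattern whose adjacent gaps differ only
  two-fold relative to the replicate SD, and a noncentral-t power
  calculation shows no noise scale or replicate count pushes that
  particular pattern's rate near 0.9. Pattern-level conclusions from
  n = 3 experiments should be treated as observations about one dataset,
  not reproducible properties of the underlying means.
* Cochran's C requires balanced groups; no unbalanced generalization is
  provided.
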