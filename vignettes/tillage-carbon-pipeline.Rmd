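---
title: "Equivalent-soil-mass carbon stocks, soil quality and multifunctionality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-soil-mass carbon stocks, soil quality and multifunctionality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrisoc)
```

# The problem this package addresses

Long-term tillage trials in wheat–maize double-cropping systems ask
whether loosening practices (deep tillage in the wheat season,
subsoiling in the maize season) move organic carbon and biological
activity into deeper soil layers. Answering that question from
plot-level profile measurements requires a chain of derived quantities —
mass-corrected carbon stocks, composite quality indices, a
multifunctionality index — plus the split-plot trial statistics that sit
around them. `agrisoc` implements that chain as one tested pipeline and
pairs it with a synthetic-trial generator, so every stage can be
exercised and calibrated without access to any particular field
campaign's raw data.

The trial structure assumed throughout is a split-plot design: a
wheat-season main-plot factor with levels rotary tillage (`RT`) and
deep tillage (`DT`), crossed with a maize-season sub-plot factor with
levels no-tillage (`NT`), subsoiling between rows (`SBR`) and subsoiling
within rows (`SIR`); six treatments, three replicate blocks (18 plots),
sampled in five 10 cm layers from 0 to 50 cm, in one or more years.

# Equivalent-soil-mass carbon storage

A fixed-depth stock `sum_i bd_i * T_i * C_i * 10` (Mg ha^-1, with `bd`
in g cm^-3, thickness `T` in m and `C` in g kg^-1) compares different
amounts of soil whenever treatments change bulk density — precisely the
situation a tillage trial creates. The equivalent-soil-mass (ESM)
correction fixes the comparison mass instead. For cumulative level
`j`, the reference mass `M_j` is the maximum cumulative soil mass over
all profiles in the comparison scope, and

```
storage_j = [ sum_{i<=j} M_soil,i * C_i  +  (M_j - sum_{i<=j} M_soil,i) * C_extra ] * 0.001
```

with `M_soil,i = bd_i * T_i * 10000` in Mg ha^-1 and concentrations in
kg Mg^-1 (numerically equal to g kg^-1). Because `M_j` is a maximum
over the scope, the deficit term is non-negative by construction; a
stack heavier than its reference is treated as a scope mismatch and
raises an error rather than being truncated.

Design choices that the formula itself leaves open:

* **`C_extra` policy.** The top-up concentration is only defined as
  "the carbon content of the additional soil". The default
  (`"next-layer"`) uses the concentration of the layer immediately below
  the cumulative level — the soil that would physically be included to
  reach `M_j` — falling back to the deepest layer's own concentration at
  the profile bottom. `"same-layer"` is available; the policy used is
  recorded in the output.
* **Reference scope.** Defaults to within-year (bulk density drifts
  between years), across all treatments. `scope = "pooled"` computes one
  set of reference masses overall. The scope is an explicit argument,
  never implicit.
* **Aggregation.** The default `"per-replicate"` builds one stack per
  plot (reference masses are maxima over plots in scope), preserving
  replicate spread so storage can feed the ANOVA and LSD letters.
  `"replicate-mean-first"` averages bulk density and SOC per treatment
  before stacking; reference masses are then maxima over treatment
  means. On noise-free data the two agree exactly (storage is linear in
  concentrations at fixed masses), which is asserted in the tests.
* **Depth.** The cumulative computation stops at 0–40 cm by default
  (four levels) even when a fifth layer is sampled; `max_depth_cm = 50`
  extends it.

A numerical property worth stating: holding reference masses fixed,
`d storage_j / d M_soil,i = (C_i - C_extra_j) * 0.001` for `i <= j`, so
inflating a layer's mass raises or lowers storage depending on whether
that layer is richer or poorer than the top-up soil. The test suite
verifies this slope numerically. Monotonicity of storage in `j` holds
whenever deficits are small relative to layer masses (the realistic
regime — bulk density differences between treatments are a few
percent); it is asserted on generated datasets, not on adversarial
stacks, because a large deficit combined with a steep concentration
drop can in principle break it.

# Soil quality index

Each indicator is scored linearly to [0, 1] within a normalization
scope: `x / x_max` for more-is-better indicators and `x_min / x` for
less-is-better ones (the decreasing form is implemented as the standard
bounded ratio; an unbounded `x / x_min` reading would contradict the
0–1 scale the scoring is defined to produce). The composite is the
radar-area form

```
SQI = 0.5 * sum_i s_i^2 * sin(2*pi/n)
```

implemented exactly as printed in the field's literature: a sum over
per-indicator squared scores with no cross terms. Note this is *not*
the literal area of the radar polygon — that would be the cyclic
adjacent-product form `0.5 * sin(2*pi/n) * sum_i s_i * s_{i+1}`, which
depends on indicator ordering. The printed form is order-invariant
(asserted in the tests); the polygon form is available via
`sqi_method = "polygon"` but is off by default.

Defaults that are genuine decisions rather than given facts:

* **Indicator roster** (n = 9): SOC, LOC, NLOC, DOC, MBC, invertase,
  urease, neutral phosphatase (more-is-better) and bulk density
  (less-is-better). With n = 9 the attainable maximum is
  `4.5 * sin(2*pi/9) ≈ 2.89`, comfortably above the SQI values such
  trials report (up to ~2.8), which a smaller roster would not allow.
* **Normalization scope**: per year, pooled across treatments,
  replicates and depths. Pooling across depths is essential: if min–max
  bounds were taken per layer, the depth gradient would be scored away
  and SQI could not decline with depth as observed.
* A degenerate indicator (constant within scope) scores 1 with a
  warning rather than failing the run.

# Ecosystem multifunctionality

The three enzyme activities (invertase, urease, neutral phosphatase)
proxy soil functions. Each is z-scored — `(x - mean) / SD` — over the
standardization scope (per year by default, pooled across all samples),
and EMF is the mean of a sample's three z-scores. Pooling across
depths makes surface samples positive and deep samples negative, which
is the printed behaviour of such indices. Sample SD (n−1) is the
default convention; population SD is available. EMF is invariant to
positive affine rescaling of any single enzyme (units cancel), asserted
to 1e-12 in the tests.

# Trial statistics

* **Factorial ANOVA**: fixed-effects year × depth × tillage with all
  interactions (two-way year × tillage for yield), on balanced complete
  layouts only, with the *pooled residual* as the single error stratum —
  mirroring how such trials print a single error mean square. A true
  split-plot stratification (whole-plot vs sub-plot errors) would test
  the wheat-season factor against plot-to-plot variance; with the pooled
  error, whole-plot tests are anti-conservative when plot effects are
  present. The generator's calibration studies therefore switch plot
  effects off (see below). Depth is categorical throughout.
* **LSD letters**: Fisher's least significant difference with the
  pooled within-group mean square, unprotected (letters are produced
  whether or not the omnibus F is significant, matching figure-level
  usage), summarized by an insert-and-absorb compact letter display.
  The letter-sharing relation is *exactly* the pairwise
  non-significance relation — verified against brute-force all-pairs
  t-tests on randomized instances. With zero pooled MSE, groups with
  unequal means are distinct and equal means share a letter.
* **Correlations**: Pearson r with raw two-sided p per depth layer and
  year, treatments and replicates pooled; no multiplicity adjustment
  (the customary raw-p heatmap convention). Constant variables yield
  `NA` with an explanatory note.
* **Random-forest importance**: regression forests (500 trees by
  default), importance as the unscaled mean increase in out-of-bag MSE
  when a predictor is permuted. Significance follows the
  response-permutation scheme of `rfPermute`-style analyses: the forest
  is refit `n_permutations` times (default 100) with the response
  shuffled, and `p = (1 + #(null >= observed)) / (n_permutations + 1)`.
  Bit-for-bit reproducible under a fixed seed.
* **EMF ~ SQI**: ordinary least squares with slope test and R².

# The synthetic generator

The generator emulates the *statistical structure* of the trial, not
its soil physics. The value of variable `v` for plot `p`, layer `i` is

```
surface_mean_v * depth_decay_v^(i-1) * multiplier_v(treatment, band) *
  year_factor_v * exp(plot_effect_p) * (1 + eps)
```

with `eps ~ N(0, residual_cv)` per observation and
`plot_effect_p ~ N(0, plot_sd)` drawn once per plot and shared across
layers and years — the split-plot correlation. Noise is multiplicative
(lognormal-style) so strictly positive variables stay positive and CVs
are depth-stable. Treatment effects enter as multipliers on the depth
bands 0–20, 20–40 and 40–50 cm, matching how contrasts in such trials
are reported. LOC is generated as a fraction of SOC clamped to
(0.01, 0.35], so `loc <= soc` holds by construction (labile fractions
above ~35% of SOC are outside the reported range). Each variable draws
from its own substream (seed derived by hashing the variable name), so
adding a variable never shifts the others' draws; the exponent
convention is `depth_decay^(i-1)`, i.e. the surface layer equals
`surface_mean` exactly, which the noise-free-limit test pins down.

Default levels are chosen to land in the ranges comparable fluvo-aquic
trials print: bulk density 1.45–1.70 g cm^-3 (increasing with depth,
decay 1.04 per layer), SOC 7–16 g kg^-1 (decay 0.82), DOC 30–61
mg kg^-1, MBC 50–190 mg kg^-1, enzymes from ~0.7 to ~30 mg g^-1 24h^-1,
yield around 6000 kg ha^-1. Default *noise* levels are anchored to the
error mean squares such trials print: an SOC error mean square of
0.05 (g kg^-1)^2 at a grand mean near 11 g kg^-1 corresponds to a
residual CV of about 2%, so residual CVs default to 2–5% with a smaller
(1–3%) plot-level component. Under these defaults a +10% planted SOC
effect in the 20–40 cm band of two treatments is detected by the
tillage F-test in ≥90% of simulated trials — the power a real trial of
this design demonstrably achieved, given the F statistics it reports.

`null_design_spec()` removes *all* structure (flat depth profiles, unit
multipliers, no plot effects): every observation is iid noise around a
constant, every ANOVA term is null, and the 5% level of each term can
be checked by simulation. `demo_design_spec()` plants qualitative
subsoiling effects (lower BD; carbon pools and enzymes up near the
surface under RT + subsoiling and in the 20–40 cm band under DT +
subsoiling; higher yield under subsoiling), which makes the demo
pipeline reproduce the qualitative pattern of interest: a strong
positive EMF–SQI association, carbon pools ranked as the main EMF
drivers, and deep-layer gains under `DT-SBR`/`DT-SIR`.

What the generator deliberately does **not** model: mechanistic carbon
dynamics (no RothC/Century), spatial autocorrelation between plots,
weather, measurement-method error structure, or year × treatment
interactions unless configured. Passing tests on synthetic data
therefore demonstrate that the *computational chain* is correct and
well-calibrated under the design's statistical structure — not that any
particular field result is reproduced.

# Numerical choices and degenerate inputs

* Generated values must be strictly positive; a non-positive draw is
  redrawn (fresh residual only) up to 100 times, then errors. At the
  default CVs a redraw is a ~25-sigma event, so the truncation bias is
  nil in practice.
* Validation rejects rows (never repairs them): non-positive
  measurements, bulk density outside (0.5, 2.2) g cm^-3, `loc > soc`,
  malformed layer intervals, unknown treatment codes, non-numeric
  fields at read time. Missing design cells are reported, not imputed.
* `esm_storage` tolerates a relative deficit of −1e-9 (floating point)
  and errors beyond that. Stacks must tile 0..max_depth contiguously.
* Letters: ties at the LSD boundary are measure-zero; the comparison is
  strict (`|diff| > LSD`).
* CSV round-trips use full-precision shortest-representation numeric
  formatting, so write → read is value-identical and repeated writes
  are byte-identical (the basis of the manifest determinism check).

# Problem sizes used by the test suite

The suite runs the calibration studies at sizes chosen to give tight
Monte-Carlo error while keeping a laptop run comfortable: 1000 null
trials for the ANOVA level check (binomial SE ≈ 0.007 at the 5% level),
200 trials for power and contrast direction, 1000 random stacks for the
ESM oracle, 10 000 random score vectors for the SQI bound, 200 random
instances for the letter-display oracle, and 50 seeds (one-year trials,
300 trees, 60 permutations) for the planted-driver recovery. The
pipeline determinism check runs the full chain twice with a reduced
forest (100 trees, 10 permutations) — determinism does not depend on
forest size.

# Known limitations

* The ANOVA offers only the pooled-error model; REML/mixed-model
  estimation of the split-plot strata is out of scope.
* The ESM monotonicity-in-depth property is guaranteed only in the
  small-deficit regime (see above).
* The SQI indicator roster and both scoping rules are decisions;
  composite indices are not uniquely defined by their formulas, and all
  of these are exposed as configuration rather than claimed as the only
  valid reading.
* No plotting: every output is a tidy table, intended to feed the
  user's own figure code.
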