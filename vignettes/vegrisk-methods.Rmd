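---
title: "vegrisk: methods, calibration choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vegrisk: methods, calibration choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegrisk)
```

# The exposure model

`vegrisk` implements the USEPA ingestion-pathway chain for toxic elements
(Pb, Cd, Zn, Ni) and nitrate in vegetables. The chronic daily intake for a
demographic group is

$$Intake = \frac{ED \cdot C \cdot EF \cdot IR}{BW \cdot AT}$$

with $C$ the concentration (mg·kg⁻¹ dry weight), $IR$ the intake rate
(kg·day⁻¹), $EF$ the exposure frequency (day·yr⁻¹), $ED$ the exposure
duration (yr), $BW$ the body weight (kg) and $AT$ the averaging time
(days). Hazard quotients divide intake by the oral reference dose
($HQ = Intake/RfD$), hazard indices sum them ($HI = \sum HQ$), carcinogenic
risk multiplies intake by the oral slope factor
($CR = Intake \cdot S_F \cdot 10^{-3}$) and total carcinogenic risk sums the
carcinogens. The model is ingestion-only: dermal and inhalation routes,
bioaccessibility corrections and nitrosamine chemistry are out of scope.

The bundled constants are the IRIS reference doses (Pb 0.00357, Cd 0.001,
Zn 0.3, Ni 0.02, NO3 1.6 mg·kg⁻¹·day⁻¹), the oral slope factors (Cd 0.38,
Pb 0.0085, Ni 1.7 (mg·kg⁻¹·day⁻¹)⁻¹) and three exposure profiles
(children: IR 0.13, ED 6, BW 18.6; adult males: IR 0.26, ED 30, BW 66.2;
adult females: IR 0.26, ED 30, BW 57.3; all at EF 365, carcinogenic AT
25,550 days). Everything is overridable through `analyte()`,
`exposure_profile()` and the YAML config.

## The averaging-time convention

The tabulated exposure parameters list a single non-carcinogenic AT of
10,950 days for all groups. Under that convention the children-to-adult HQ
ratio would be $(IR_a ED_a/BW_a)/(IR_c ED_c/BW_c) \approx 2.8$ — adults
above children — which contradicts the published per-group HQ tables the
package is calibrated against. Those tables are reproduced exactly by the
standard USEPA non-carcinogenic convention $AT = ED \times 365$ per group,
under which the ratio collapses to $(IR_a/BW_a)/(IR_c/BW_c)$: 0.5619 for
adult males and 0.6492 for adult females, independent of analyte and
concentration. `at_convention = "ed_years"` is therefore the default;
`"table"` applies the tabulated value verbatim for users who want the
literal parameterisation. (Only the Cd and Pb rows of the source tables are
consistent with *any* single convention; the Zn/Ni/nitrate adult rows imply
a ratio near 0.11 that no AT choice reproduces, so the package reproduces
the Cd/Pb-consistent convention and leaves the discrepancy documented
here.)

## The 10⁻³ factor in the carcinogenic-risk equation

The published risk equation carries an explicit $10^{-3}$ scaling whose
provenance is not explained (it may be a g→kg unit correction). It is
required to land the nickel CR values in the printed 10⁻⁶ range from
plausible concentrations, so `compute_cr()` retains it verbatim as the
`unit_factor = 1e-3` default; passing `unit_factor = 1` disables it.

## Risk bands

HQ/HI bands: below 0.1 insignificant, 0.1–1 low, 1–4 moderate, ≥ 4 very
high. CR bands: below 10⁻⁶ not significant, then decade bands up to
"relatively high" above 10⁻³. The sources are silent on boundary
membership; intervals here are closed on the left (an HQ of exactly 1 is
"moderate"), which keeps classification monotone and unambiguous.

# Monte Carlo uncertainty propagation

Concentrations are modelled lognormal — the conventional choice for
positive, right-skewed environmental measurements — parameterised by
*moment matching* from the arithmetic mean and SD that concentration
surveys report: $\sigma^2 = \ln(1 + (sd/mean)^2)$,
$\mu = \ln(mean) - \sigma^2/2$. By default only the concentration is
random, because the calibration sources give distributions for nothing
else; `ir_spec`/`bw_spec` extend the simulation to a random intake rate and
body weight. The default iteration count is 50,000; a seed is mandatory.
Summaries are the sample mean and the empirical 95th percentile with linear
interpolation between order statistics (`quantile()` type 7) — percentile
conventions differ between implementations, so the choice is pinned and
tested against the closed form $\exp(\mu + 1.6449\sigma)$.

Because HQ and CR are linear in $C$, the simulation mean must match the
deterministic value at the mean concentration up to Monte Carlo error; the
test suite checks this within four standard errors at 50,000 iterations,
and the 95th percentile against the lognormal closed form within 2%.

# Sobol sensitivity analysis

Variance-based first-, second- and total-order indices are estimated from a
Saltelli cross-sampling design: two base matrices $A$, $B$ of `n_base` rows
and the column-swap matrices $AB_i$ (plus $BA_i$ when second-order indices
are requested), costing $n(p+2)$ or $n(2p+2)$ model evaluations. The
estimators are the standard low-variance choices: Saltelli (2010) for
$S_i$, Jansen for $S_{T_i}$, and the Saltelli (2002) identity for
$S_{ij}$. Small-sample estimates can be slightly negative; they are
reported as-is (useful as a convergence diagnostic) while
`classify_sensitivity()` clips at zero before applying the published label
cut-points (insensitive < 0.01 ≤ sensitive ≤ 0.1 < highly sensitive).

Sampling is plain pseudo-random Monte Carlo by default, matching the
"Monte Carlo technique" framing of the source analysis. For validation at
fixed `n_base` the package also provides `sampling = "halton"`, a
2p-dimensional Halton sequence randomised by a seed-dependent
Cranley–Patterson rotation: at `n_base = 4096` it recovers the analytic
Ishigami indices within 0.02 absolute for any seed, a precision plain
pseudo-random sampling only reaches near n ≈ 10⁵. A Latin-hypercube option
(`"lhs"`) exists but stratifies only the marginals and does not materially
reduce the cross-term estimator noise.

`risk_model_adapter()` binds the risk equations as the model $f$: factor
columns named `IR`, `BW`, `EF`, `ED` override exposure factors, analyte
names override concentrations, and anything absent is held at its baseline.
The default factor space (`risk_factor_space()`) draws concentrations
lognormal at their survey CVs and IR/BW lognormal with CV 0.2 — a typical
dietary-survey spread, stated as an assumption, since the source analysis
does not disclose its input distributions. A consequence worth knowing:
with the survey concentration CVs (0.33–0.9) the concentration factors, not
the intake rate, dominate the carcinogenic-risk variance. The published
IR-first ranking (first-order index 0.591, total 0.913) is only obtainable
with much narrower concentration uncertainty than the survey itself
reports, so the package makes no attempt to reproduce those index values
and the tests assert structural properties instead (null factors inert,
$S_{T_i} \ge S_i$, dominance where the model puts the variance, agreement
with a brute-force double-loop estimator within 0.05).

# Spatial interpolation

`idw_interpolate()` is global-neighbourhood inverse distance weighting,
$\hat v(q) = \sum_i w_i v_i / \sum_i w_i$ with $w_i = d_i^{-power}$ and
Euclidean $d_i$: the simplest faithful reading of "neighbouring sites'
values weighted by inverse distance". The power defaults to 2 (the common
GIS default; the source does not state one). Zero distance short-circuits
to the site value, making the interpolator exact; weights normalise to one
(checked to 10⁻¹²), so the surface is bounded by the data range and cannot
overshoot. Coordinates are treated as planar; longitude/latitude input is
accepted via `project_lonlat()`, an equirectangular local projection that
warns about its approximation (fine at city scale, inappropriate for
continental extents). Grids are cell-centre sampled, row-major from the
top-left, and exported as standard ESRI ASCII rasters plus long-format CSV.

# The synthetic generator and its calibration

No site-level measurements are published, so `generate_sites()` emulates
the survey the analysis assumes: 21 sites across 11 districts (district
membership is cosmetic metadata), two vegetables, five analytes,
right-skewed concentrations. Calibration (`calibrate_targets()`) inverts
the risk equations against the published children's tables — the children's
rows are the ones internally consistent with the adults under the
`ed_years` convention:

* Cd, Pb, Zn, NO3: mean concentration from the children's HQ,
  $C = HQ \cdot RfD \cdot BW / IR$;
* Ni: from the children's CR instead (7.93×10⁻⁶ → 7.786 mg/kg), because its
  HQ-implied mean (13.5 mg/kg) exceeds the published spatial maximum
  (8.092 mg/kg);
* NO3's HQ-implied mean (1293 mg/kg) is capped at the published range
  maximum (859.275 mg/kg);
* any mean still outside its admissible range is clamped to the range
  midpoint with a warning — this fires for Zn (implied 44.6 mg/kg against a
  range of 2.333–18.275) and for Pb in carrot (6.96 vs max 6.794).

CVs come from the published HQ mean ± SD (HQ is linear in concentration, so
the CVs transfer). Each concentration is drawn from the moment-matched
lognormal *truncated by resampling* to the published spatial range —
resampling rather than clipping preserves the in-range lognormal shape.
The published ranges pool radish and carrot (the source wording is
ambiguous; pooled is assumed).

## What the synthetic data can and cannot reproduce

Truncation pulls realised means below their targets whenever a target sits
near a range edge: ~3% for Cd, ~40% for nitrate and Ni (whose targets sit
at or near the range maximum). Large-sample tests therefore validate the
generator against the *analytic truncated-lognormal mean* — the law the
generator actually draws from — rather than the untruncated target.

A structural consequence: the published children-radish HI of 23.77 cannot
be recovered from data confined to the published concentration ranges.
At the range-maximum concentrations the per-analyte HQ ceilings are Zn
0.43, Ni 2.83, NO3 3.75 (children, `ed_years`), so even a generator pinned
to the maxima tops out at HI ≈ 19.4, and the calibrated generator realises
≈ 16 after truncation. This is an internal inconsistency of the source
summary statistics (HQ tables vs printed concentration ranges), not a
sampling artefact; the end-to-end recovery test in the acceptance suite
documents it by failing the published value at its stated 15% band while
the component-wise calibration tests all pass. Users fitting the package to
*real* site data are unaffected — the limitation is specific to
back-deriving synthetic data from the published aggregates.

The generator also does not emulate analytical chemistry error: no LOD/LOQ
censoring, no measurement noise, no inter-vegetable correlation at a site.
Passing tests therefore demonstrate the correctness of the risk arithmetic
and the distributional plumbing, not robustness to censored or correlated
field data.

# Numerical choices and degenerate inputs

* HI/TCR over an empty analyte set is an error, not zero — missing
  toxicity data stays loud; likewise `compute_cr()` refuses analytes
  without a slope factor (Zn, NO3) rather than returning 0.
* `fit_lognormal()` requires strictly positive mean and SD; the sd→0 limit
  degenerates cleanly to a point mass (σ→0, μ→ln mean).
* Truncated resampling aborts after 1000 rounds if the window captures too
  little mass, rather than looping forever.
* Zero total variance in `estimate_indices()` (a constant model) is an
  explicit error.
* Report display rounds HQ/HI to 2 decimals (3 significant figures below
  1) and CR/TCR to 3 significant figures; all computation is full
  precision.

# Problem sizes used by the test suite

The suite runs in seconds by choosing the smallest sizes at which each
statistical check is sharp: Monte Carlo moment checks at 20,000–50,000
iterations; Saltelli designs of 1024–8192 base samples (Halton-sampled
where a fixed-n accuracy bound is asserted); the brute-force double-loop
oracle at 4096 × 64 evaluations per factor with the classical
inner-variance bias correction; synthetic validation at 2000 sites; the
pipeline smoke tests at 10 sites, 300 iterations and 64 base samples. All
stochastic tests fix their seeds.
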