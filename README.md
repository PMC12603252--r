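# vegrisk

Dietary health-risk assessment for potentially toxic elements (Pb, Cd, Zn,
Ni) and nitrate in vegetables, written for exposure scientists and
environmental epidemiologists who need the full USEPA ingestion-pathway
chain — deterministic point estimates, probabilistic uncertainty, global
sensitivity analysis and spatial interpolation — as reproducible, tested R
code rather than spreadsheet or point-and-click workflows.

## The model

For a demographic group with intake rate *IR* (kg·day⁻¹), exposure frequency
*EF* (day·yr⁻¹), exposure duration *ED* (yr), body weight *BW* (kg) and
averaging time *AT* (days), the chronic daily intake of an analyte at
concentration *C* (mg·kg⁻¹ dry weight) is

    Intake = (ED × C × EF × IR) / (BW × AT)

from which the package computes

* **HQ = Intake / RfD** — hazard quotient against the oral reference dose,
  and **HI = Σ HQ** across co-occurring analytes;
* **CR = Intake × S_F × 10⁻³** — incremental lifetime cancer risk from the
  oral slope factor (over the carcinogenic averaging time), and
  **TCR = Σ CR** across carcinogens;
* risk-band labels at the conventional HQ cut-points (0.1, 1, 4) and CR
  cut-points (10⁻⁶ … 10⁻³).

Around that deterministic core sit four more components:

* **Monte Carlo uncertainty** — lognormal concentration distributions
  (moment-matched from arithmetic mean ± SD) propagated through the risk
  equations, 50,000 iterations by default, with mean and 95th-percentile
  summaries;
* **Sobol sensitivity analysis** — Saltelli cross-sampled first-, second-
  and total-order variance shares of the risk output over concentration and
  exposure-factor distributions (Saltelli-2010/Jansen/Saltelli-2002
  estimators; plain Monte Carlo, shifted-Halton or Latin-hypercube
  sampling);
* **IDW spatial interpolation** — exact, range-bounded inverse-distance
  weighting of site-level concentrations onto regular grids, exported as
  ESRI ASCII rasters;
* **a calibrated synthetic generator** — 21 sites × 2 vegetables (radish,
  carrot) × 5 analytes with right-skewed concentrations whose means are
  back-derived from published hazard-quotient and cancer-risk tables, so
  every stage is testable without field data.

## Worked example

```r
library(vegrisk)

# children's hazard quotient for 1.3465 mg/kg cadmium in radish
compute_hq(1.3465, "children", "Cd")
#> [1] 9.411022

# hazard index over the five analytes (children, radish)
compute_hi(c(9.411, 2.95, 1.04, 4.72, 5.65))
#> [1] 23.771

# children's cancer risk for 7.786 mg/kg nickel
compute_cr(7.786, "children", "Ni")
#> [1] 7.929521e-06

# calibrated synthetic survey -> deterministic report
fx  <- pipeline_fixture(seed = 1)
rep <- risk_report(fx$concentrations)
rep
#> <risk_report> 3 group(s) x 2 vegetable(s), 5 analyte(s)
#>         group vegetable    hi      tcr   hi_band tcr_band
#>  adult_female    carrot 15.07 1.77e-05 very high   medium
#>  adult_female    radish 10.30 1.81e-05 very high   medium
#>    adult_male    carrot 13.04 1.53e-05 very high   medium
#>    adult_male    radish  8.91 1.56e-05 very high   medium
#>      children    carrot 23.21 5.45e-06 very high      low
#>      children    radish 15.86 5.56e-06 very high      low

# lognormal Monte Carlo around the cadmium mean (mean HQ ~ deterministic HQ)
sim <- simulate_hq(fit_lognormal(1.3465, 0.831), "children", "Cd",
                   n_iter = 50000, seed = 1)
summarize_simulation(sim)
#>      mean       p95
#>  9.415271 20.496154

# inverse-distance weighting, three sites at distances 1, 2, 4
s <- site_set(1:3, x = c(1, 0, -4), y = c(0, 2, 0), value = c(1, 2, 3))
idw_interpolate(s, 0, 0)
#> [1] 1.285714
```

The report says: at the calibrated concentrations every group × vegetable
HI exceeds 4 ("very high" non-carcinogenic band), children's TCR sits in
the low band (10⁻⁶–10⁻⁵), and adult TCRs reach the medium band because their
thirty-year exposure duration dominates the lifetime averaging.

A single-command pipeline (synthetic data → risk → Monte Carlo → Sobol →
IDW, with a JSON run manifest) is available both as `run_pipeline()` and as
a thin CLI:

```sh
Rscript inst/cli/vegrisk.R all --seed 7 --out-dir out/
```

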