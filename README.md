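# lurevp

Volatility and attractiveness analysis for raspberry-ketone fruit-fly
lures.

Male lures for raspberry-ketone-responding *Bactrocera* fruit flies —
cuelure (CL), melolure (ML), raspberry ketone (RK) and ester/ether
analogs — differ in volatility and in how strongly male flies respond to
them. This package implements the complete analysis chain linking the
two, for chemical ecologists and insect-pest researchers:

* **Antoine thermodynamics** — evaluate, invert and fit the vapour-pressure
  law `log10(P/kPa) = A − B/(T + C)` from isothermal boiling data, derive
  the enthalpy of vaporisation via Clausius–Clapeyron,
  `ΔHvap = ln(10)·B·R·T²/(T+C)²`, and propagate the ±1 K boiling-onset
  uncertainty into a vapour-pressure uncertainty.
* **DSC onset extraction** — boiling-onset temperatures from heat-flow
  traces by baseline/tangent intersection.
* **Fly counting** — threshold segmentation of cage-bioassay frames with
  per-fly-area calibration and Spearman rank-concordance validation.
* **Response kinetics** — the constrained exponential approach
  `p(t) = p_max − (p_max − 0.5)·exp(−t/k)`, forced through the random
  baseline `p(0) = 0.5` by construction.
* **Structure–activity ANCOVA** — sequential (type I) analysis of
  covariance of `p_max` on structural cluster and vapour pressure.
* **Synthetic data generators** — seeded, ground-truthed simulators for
  every pipeline input (boiling series, endotherms, cage frames, count
  series), plus the published Antoine parameter sets for all nine lure
  compounds as fixtures.

## Worked example

```r
library(lurevp)

# cuelure's fitted Antoine law, extrapolated to room temperature
cl <- lure_antoine_params("CL")
vapour_pressure(cl, 298.15, warn_extrapolation = FALSE)
#> [1] 7.542483e-06
enthalpy_of_vaporisation(cl, 298.15, warn_extrapolation = FALSE)
#> [1] 82.72072
```

Cuelure's vapour pressure at 298.15 K is 7.54 × 10⁻⁶ kPa with an
enthalpy of vaporisation of 82.7 kJ mol⁻¹ — the law is fitted on boiling
data between 498 and 587 K, so the room-temperature value is an
extrapolation (hence the suppressed warning).

```r
# simulate a 5-replicate cage bioassay (30 flies visible per frame,
# frames every 5 s over 0-170 s) and refit the kinetics
s <- simulate_response_series(true_pmax = 0.91, true_k = 15,
                              n_flies = 30, seed = 1)
fit_response_series(s)
#> response fit (n = 35): p_max = 0.911 +/- 0.011, A = 0.411, k = 16.87 +/- 2.69 s, r2 = 0.935
```

The mean-then-fit estimate recovers the generating maximum response
(0.91) within its confidence interval; the curve passes through
(0 s, 0.5) exactly because the constraint is structural.

```r
# golden consistency of the shipped summary tables
reproduce_tables()
#> table reproduction: 26/26 cells pass
```

This recomputes all 18 room-temperature vapour-pressure and enthalpy
values from the shipped Antoine coefficients (agreement within one unit
in the third significant figure) and the 8 pre-exponential identities
`A = p_max − 0.5` (within 0.01).

`run_pipeline(out_dir, seed)` chains the whole synthetic analysis —
endotherm simulation, onset extraction, Antoine refitting,
room-temperature prediction, kinetics refitting and the
structure-clustered ANCOVA — writing every intermediate CSV with a
provenance header.

See the methods vignette (`vignettes/lure-volatility.Rmd`) for the
models, numerical choices and limitations.

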