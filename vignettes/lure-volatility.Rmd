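---
title: "Methods: lure volatility, response kinetics and structure-activity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lure volatility, response kinetics and structure-activity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurevp)
```

# The scientific problem

Male lures for raspberry-ketone-responding fruit flies — cuelure, melolure,
raspberry ketone itself and a series of ester and ether analogs — differ
both in how volatile they are and in how strongly flies respond to them.
`lurevp` implements the full chain of analysis that connects the two: from
boiling observations made by differential scanning calorimetry (DSC) to a
fitted vapour-pressure law per compound, and from cage-bioassay images to a
fitted response-kinetics curve per compound, joined at the end by an
analysis of covariance asking whether volatility or molecular structure
drives attractiveness.

The raw laboratory measurements behind the published parameter tables are
not deposited anywhere, so the package pairs every analysis step with a
synthetic-data generator that emulates the corresponding measurement with
known ground truth. The shipped fixtures are the published *summary*
tables (Antoine coefficients, room-temperature vapour pressures, kinetics
fits); everything upstream of them is simulated.

# Vapour pressure: the Antoine law

Each compound's saturation vapour pressure is described by the Antoine
equation

$$\log_{10}(P/\mathrm{kPa}) = A - \frac{B}{T/\mathrm{K} + C},$$

fitted to isothermal boiling points $(T_i, P_i)$ by minimising
$\sum_i (\log_{10} P_i - \log_{10} \hat P_i)^2$. Temperatures are always
kelvin internally (CSV readers accept Celsius and convert on ingest);
pressures are always kPa.

**Fitting strategy.** The Antoine parameters are strongly correlated: for
any fixed $C$ the model is *linear* in $A$ and $B$. `fit_antoine()`
therefore profiles the objective over $C$ — an exact linear solve inside a
one-dimensional search — rather than running a three-parameter nonlinear
optimiser. The search is seeded at the Clausius–Clapeyron line ($C = 0$),
bracketed on a coarse grid (half-width 500 K, 201 points) and refined by
`optimize()`. This is both more robust than a free three-parameter descent
(no divergence for poor starts) and exactly self-consistent: refitting
noise-free points regenerates the curve to below $10^{-6}$ in
$\log_{10} P$. The constraint $\min(T) + C > 1$ K keeps the denominator
away from zero during the search. The fitted validity range is the data
range; evaluation outside it is permitted — the room-temperature table
*requires* extrapolating roughly 200 K below the boiling data — but raises
a `lurevp_extrapolation` warning.

**Enthalpy of vaporisation.** Combining the Clausius–Clapeyron relation
$d\ln P/dT = \Delta H_{vap}/(R T^2)$ with the derivative of the Antoine
law gives the closed form

$$\Delta H_{vap} = \ln(10)\, B R \,\frac{T^2}{(T+C)^2},$$

with $R = 8.314462$ J mol$^{-1}$ K$^{-1}$. The test suite checks this
against a finite-difference $R T^2\, d\ln P/dT$ for every fixture.

**Uncertainty from onset reading.** The dominant experimental uncertainty
is the $\pm 1$ K reading of the boiling onset. The published uncertainty
band does not state whether the 1 K perturbation was applied upward,
downward or symmetrically; `vp_sensitivity()` adopts the symmetric central
difference $100\,(P(T{+}1) - P(T{-}1))/(2 P(T))$ as canonical — it is the
even-handed choice and lies between the two one-sided variants, which
remain available via `direction = "up"/"down"`.

# DSC onset extraction

One DSC scan at a controlled pressure yields one boiling point: the
*onset* of the boiling endotherm. The published analysis delegates the
onset construction to instrument software following standard
thermal-analysis guidelines, so the algorithm here is the package's own
deterministic implementation of that practice:

1. fit a straight baseline to the leading fraction of the scan (default
   0.4, configurable);
2. smooth the signal with a centred moving average (default width 5,
   odd only);
3. locate the endotherm's steepest descent at the *half-depth* sample of
   the baseline-corrected signal;
4. fit the tangent by regression over the mid-flank of the descent (the
   samples between 25 % and 75 % of its depth);
5. report the intersection of tangent and baseline.

Two numerical choices deserve comment. Taking a naive `argmin` of the
pointwise derivative selects whichever sample the noise made look
steepest; that systematically overestimates the tangent slope and biases
the onset late. The half-depth sample is a noise-robust proxy for the
inflection that coincides with it exactly on a linear descent. Similarly,
a tangent fitted to a handful of near-coincident samples inherits their
noise almost undamped; regressing over the mid-flank stretch averages it
down while remaining exactly the tangent line for a linear flank. With
these choices the onset of a simulated endotherm with noise at 1 % of the
endotherm depth is recovered within 0.2 K, comfortably inside the
$\pm 1$ K experimental reading error the uncertainty analysis assumes.
Baseline noise is estimated by the median absolute deviation of the
baseline residuals (Gaussian-consistent scaling); a trace where nothing
drops 5 noise-SDs below the baseline is rejected as having no endotherm.

# Counting flies in bioassay frames

Frames are 8-bit grayscale images of the ceiling areas under the treated
and untreated odour sources. Counting follows the threshold-and-divide
approach: binarise the region of interest (dark flies on a light mesh by
default; polarity is configurable since it is a property of the rig),
take the total foreground area, and divide by the area representing one
fly. Per-fly area is calibrated as the *median* over calibration frames
of foreground area divided by the known count. Fractional counts round to
the nearest integer with ties to even, which is unbiased over many
frames. The automatic threshold maximises inter-class variance on the ROI
histogram (Otsu's criterion, via `EBImage::otsu()`); a manual per-run
threshold is first-class because the original workflow set thresholds by
hand per experimental run.

Counting validation uses Spearman rank concordance (`concordance()`),
reporting both $\rho$ (mid-ranks, so ties are handled) and
$S = \sum d_i^2$; for untied ranks $\rho = 1 - 6S/(n(n^2-1))$.

# Response kinetics

The response probability at time $t$ is the fraction of observed flies in
the treated area, $p = n_T/(n_T + n_U)$; frames with no flies in either
view are missing values, not zeros. The kinetics of attraction follow an
exponential approach to an asymptote, constrained to the random baseline
$p(0) = 0.5$:

$$p(t) = p_{max} - (p_{max} - 0.5)\,e^{-t/k}.$$

The constraint is imposed by substitution — the model has exactly two free
parameters $(p_{max}, k)$ — so every fitted curve passes through
$(0, 0.5)$ to machine precision and the pre-exponential magnitude is
identically $A = p_{max} - 0.5$. (A growth form with a *positive*
exponent would diverge; the decaying-approach form is the only reading
consistent with positive published $A$ values and the $p(0)=0.5$
constraint.) Fitting is Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with relative tolerance $10^{-9}$ on the residual
sum of squares — equivalently on the reduced $\chi^2$ — starting from
$p_{max} = \max(p)$ and $k = 15$ s, both configurable. The fit window is
0–170 s by default. 95 % intervals come from the single-fit parameter
covariance with $t_{n-2}$ quantiles; note that intervals derived from
replicate scatter would be a different (and not necessarily matching)
quantity. The reported $r^2$ is the ordinary coefficient of
determination; an adjusted variant is available by option. Data flat at
$p = 0.5$ are consistent with the constraint for *any* $k$; the fit
returns $p_{max}=0.5$ with $k$ flagged unidentifiable rather than
erroring. Pairwise comparison of fitted maxima (`compare_pmax()`) uses
disjointness of 95 % intervals — an explicit surrogate, since the exact
multiple-comparison procedure behind the published letter groupings is
not specified.

Replicates are averaged before fitting by default (mean-then-fit), which
matches the published workflow; per-replicate fitting is available.

# Structure-activity ANCOVA

Compounds split into two structural clusters: cluster 1 retains both the
phenolic ester group and the intact 2-butanone side chain; cluster 2 has
either functionality modified. `ancova_pmax_vp()` fits the compound-level
linear model

$$p_{max} \sim \mathrm{cluster} + f(VP) + \mathrm{cluster}{:}f(VP)$$

and reports *sequential* (type I) sums of squares in that order, giving
the residual 4 degrees of freedom on the eight bioassayed compounds that
the published F statistics imply. The covariate scale is a genuinely open
choice — the published analysis does not state it — and with the lure
series spanning three decades of vapour pressure, $\log_{10}$ is the
default; the linear scale is selectable, and the qualitative conclusion
(structure significant, volatility not) holds under both. For the same
reason the published cluster F value itself is treated as qualitative
rather than as a reproduction target. Replicate-level input is rejected
with a message instead of being silently aggregated, because the degrees
of freedom would silently change meaning.

# Synthetic data: what it emulates and what it does not

* `simulate_boiling_series()` — boiling temperatures at controlled
  pressures with Gaussian onset noise (default SD 1 K, the experimental
  reading uncertainty).
* `simulate_dsc_trace()` — idealised endotherm: straight (optionally
  sloped) baseline, linear descent starting exactly at the onset, linear
  recovery, additive Gaussian noise proportional to depth. Real
  endotherms are curved near the onset and broadened by pinhole-size
  effects; none of that physics is modelled, so onset-recovery results
  here bound only the *algorithmic* error, not instrument effects.
* `render_cage_frames()` — dark elliptical blobs of nominal area 25 px
  with jittered aspect and orientation on a light background (200 × 200
  px frames, intensities 40 on 220, pixel noise SD 6); overlap is
  permitted above 40 flies to mimic crowding under the lure. Square
  blobs of exact area support exact-bookkeeping checks. Real frames have
  uneven illumination, wing shadows and flies touching the window edge;
  counting accuracy measured here is an idealised upper bound.
* `simulate_response_series()` — per-frame counts
  $n_T \sim \mathrm{Binomial}(n, p(t))$ under the constrained
  exponential mean, with frames every 5 s over 0–170 s and five
  replicates by default (30 flies visible per frame). Frames are
  independent, whereas real flies persist between 5-s frames
  (autocorrelation); the simplification preserves the mean model but
  understates the serial dependence of real residuals, so
  confidence-interval coverage on real data may differ from the
  simulated coverage.

All generators are pure functions of their arguments and seed; a fixed
seed gives byte-identical output, and no generator touches global RNG
state.

# Workflow and problem sizes

`reproduce_tables()` recomputes the room-temperature vapour pressures and
enthalpies from the shipped Antoine coefficients and checks them against
the published table within one unit in the third significant figure (one
compound's printed pressure sits exactly on a rounding boundary of the
recomputed value, so "agrees after rounding to 3 significant figures"
would be too strict by half an ulp), plus the $A = p_{max} - 0.5$
identity within 0.01. `run_pipeline()` chains the full synthetic
analysis — simulate endotherms at 8 pressures per compound, extract
onsets, refit the Antoine laws, predict vapour pressure at 298.15 K,
simulate and refit the response kinetics of the eight bioassayed
compounds, and run the ANCOVA — writing every intermediate CSV with a
provenance header (package version, seed, configuration hash).

The test suite exercises parameter recovery at deliberately modest sizes:
200 seeds for the kinetics-recovery study, 200 rendered frames for the
counting error study, 40 seeds for the extrapolation calibration, 25
seeds for onset recovery. These sizes give Monte-Carlo error comfortably
smaller than the margins being tested while keeping the default test run
fast.

```{r example}
cl <- lure_antoine_params("CL")
vapour_pressure(cl, 298.15, warn_extrapolation = FALSE)
enthalpy_of_vaporisation(cl, 298.15, warn_extrapolation = FALSE)

s <- simulate_response_series(0.91, 15, n_flies = 30, seed = 1)
fit_response_series(s)
```

# Known limitations

* The Antoine extrapolation from boiling temperatures (460–600 K) down to
  298.15 K spans ~200 K; small coefficient perturbations produce large
  relative changes in the extrapolated pressure (the Monte-Carlo
  calibration in the test suite quantifies this leverage). The published
  table values are reproduced exactly because the fixtures carry the
  published coefficients.
* The published relative-volatility column is internally inconsistent
  with its own pressure column (ratios recomputed from the printed
  pressures differ from the printed ratios, e.g. ~554 vs 589 for the
  most volatile ester); `relative_vp()` therefore always computes ratios
  from evaluated laws, and the printed ratio column is shipped for
  reference only.
* No fly-level tracking, shape classification or behavioural agent
  model; the image module counts area, nothing more.
* The exact statistical procedure behind the published pairwise letter
  groupings is unstated; interval disjointness is an explicit,
  documented surrogate.
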