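---
title: "The four-population phytoplankton absorption model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The four-population phytoplankton absorption model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(fourpop)
library(dplyr)
```

## The model

Spectral phytoplankton absorption $a_{ph}(\lambda)$ is treated as the sum of
contributions from four phytoplankton groups — picophytoplankton (cells
smaller than 2 µm), nanophytoplankton (2–20 µm), dinoflagellates and diatoms
(both larger than 20 µm):

$$a_{ph}(\lambda) = \sum_{i=1}^{4} a_i^*(\lambda)\, C_i,$$

where $a_i^*(\lambda)$ is the chlorophyll-specific absorption coefficient of
group $i$ (m² per mg chlorophyll-a) and $C_i$ its chlorophyll-a
concentration (mg m⁻³). The novelty over classical two- and
three-population formulations is that the $C_i$ respond to sea-surface
temperature (SST), so community structure — and through it both the
magnitude and the spectral shape of absorption — shifts with the thermal
environment.

The partition works through two exponential saturation functions. Combined
pico+nano chlorophyll ($C_{1,2}$, cells < 20 µm) and picophytoplankton
chlorophyll ($C_1$) saturate with total chlorophyll $C$:

$$C_{1,2} = C_{1,2}^m\left[1 - \exp\left(-\frac{D_{1,2}}{C_{1,2}^m}
C\right)\right], \qquad
C_1 = C_1^m\left[1 - \exp\left(-\frac{D_1}{C_1^m} C\right)\right].$$

$D_{1,2}$ and $D_1$ are the fractions held by each size class as $C \to 0$;
$C_{1,2}^m$ and $C_1^m$ are asymptotic maxima. All four are logistic
functions of SST (the asymptotes through $1 - \mathrm{logistic}$, with a
negative slope coefficient for $C_{1,2}^m$, so small-cell chlorophyll
saturates lower in warm water while its low-chlorophyll *fraction* rises).
Nanophytoplankton take the difference $C_2 = C_{1,2} - C_1$ and
microphytoplankton the remainder $C_{3,4} = C - C_{1,2}$, which is split
between dinoflagellates and diatoms by a further rising logistic of SST with
slope $\alpha = 0.10$ °C⁻¹ and midpoint $\beta = 32.5$ °C. In the North
Atlantic range (roughly 0–31 °C) the dinoflagellate share therefore stays
below one half, growing toward warm water.

`community_params()` packages the published sixteen logistic coefficients
plus $(\alpha, \beta)$; `astar_table()` packages the calibrated
$a_i^*(\lambda)$ with robust standard deviations at the twelve model
wavebands (412–682 nm). Both are overridable everywhere, and both ship as
plain config files under `inst/extdata/`.

```{r}
group_chlorophyll(chl = c(0.05, 1, 5), sst = 18)
```

### Numerical choices and degenerate inputs

With the packaged parameters the partition is well behaved analytically
($0 < D_1 \le D_{1,2} < 1$ over any realistic SST). User-supplied
parameters need not be, so the implementation clamps
$C_{1,2} \le C$ and $C_1 \le C_{1,2}$ before differencing, and computes the
diatom share as $C_{3,4} - C_3$ rather than $(1-q)\,C_{3,4}$; chlorophyll
conservation $\sum_i C_i = C$ then holds to rounding error for *any*
parameter set, and all concentrations are non-negative. Zero chlorophyll
yields an all-zero partition; the total specific absorption
$a^*(\lambda) = a_{ph}/C$ is reported at $C = 0$ as its analytic
low-chlorophyll limit (continuity, rather than `NaN`). SST outside the
0–30.8 °C calibration range warns but computes, because extrapolation to
fixed SST levels is a deliberate use of the model. `NA` inputs propagate
`NA`; spectral interpolation between bands is piecewise linear and refuses
to extrapolate beyond 412–682 nm.

## Calibration

`fit_band()` retrieves the four coefficients at one waveband from
observations of $(C, \mathrm{SST}, a_{ph})$ by least squares in linear
absorption space, with the community parameters held fixed: the group
chlorophylls are then known regressors and the model is linear in the
$a_i^*$. The fit is a bounded Levenberg–Marquardt minimisation
(`minpack.lm`) with a lower bound of zero on every coefficient, since
negative absorption is unphysical; because the problem is linear the
minimiser coincides with the non-negative least-squares solution, which the
test suite verifies against an independent NNLS routine to 10⁻⁸. Projected
LM alone loses several digits in the free coefficients when a bound is
active, so the solver polishes the solution by refitting the interior
coefficients and checking the gradient of clamped ones (an active-set
polish); a coefficient held at zero is flagged (`at_bound`), not silently
clipped. A rank-deficient design — for instance identical $(C,
\mathrm{SST})$ replicated — raises a singular-fit error naming the
degenerate columns.

`bootstrap_fit()` resamples whole observation records with replacement
(default 1000 resamples), refits each, and summarises every coefficient by
the bootstrap median and a robust standard deviation, defined here as the
median absolute deviation scaled by 1.4826 (the estimator is not specified
further in the source literature; this convention is documented rather than
inferred). Resamples that fail to converge are excluded and counted, with a
warning above 10 % failures. All resampling flows through one seeded
generator, so results are bit-reproducible for a fixed seed, and when
several bands are fitted together (`fit_astar()`) every band sees the same
record resamples.

```{r}
obs <- observation_grid(n_chl = 20, sst_values = c(5, 15, 25),
                        bands = c(443, 550))
fit_band(obs, 443)
```

Noise-free closed-loop data recover the generating table essentially
exactly — the model is linear in its parameters and identifiable on any
well-conditioned design.

## Uncertainty propagation

Group absorption is a product $a_i^*\, C_i$, so to first order its relative
uncertainty is the root-sum-square
$f_{a,i} = \sqrt{f_{a^*,i}^2 + f_{C,i}^2}$ (no covariance term, matching
the first-order expansion). $f_{a^*,i}$ comes from the packaged table
(sd/value); $f_{C,i}$ typically arrives as a log₁₀-space error on a
chlorophyll product. The log/linear bridge treats the linear variable as
lognormal: with $s = \sigma_{\log}\ln 10$, the bias-corrected linear mean
is $e^{m + s^2/2}$ and the relative standard deviation
$\sqrt{e^{s^2}-1}$, independent of the mean. These closed forms are an
implementation convention (the antecedent appendix is not reproduced here)
and are validated against large Monte-Carlo lognormal samples in the tests.

`map_uncertainty()` applies the scalar chain pixel-wise over gridded
chlorophyll and SST, with per-group log uncertainties supplied either as
constants or per pixel; `owt_uncertainty()` builds the per-pixel form from
a user-supplied optical-water-type class map and per-class table, because
the published per-class statistics are not reproduced in the available
source. Masked pixels propagate their mask. Rasters are long tibbles, with
CSV and CF-style netCDF writers.

## The forward ocean-colour model

To illustrate how temperature-driven community shifts move the blue-to-green
ratio of remote-sensing reflectance, the absorption model is embedded in a
deliberately simple case-1 closure:

$$R_{rs}(\lambda) \propto \frac{b_b(\lambda)}{a(\lambda) + b_b(\lambda)},$$

with $a = a_w + a_{ph} + a_{CDOM}$ and $b_b = b_{bw} + b_{bp}$. Defaults:
pure-seawater absorption per band following standard laboratory
determinations; pure-seawater backscattering
$0.00144\,(\lambda/500)^{-4.32}$ m⁻¹; CDOM tied to phytoplankton as
$0.2\,a_{ph}(443)\,e^{-0.014(\lambda-443)}$; particulate backscattering
$0.0012\,C^{0.62}(\lambda/555)^{-1}$ m⁻¹; proportionality factor
0.089 sr⁻¹. Every constant is a config entry (`reflectance_config()`,
YAML-serialisable) because the original appendix formulation is not
available in the source text — this component reproduces qualitative
structure, not published curves, and the tests assert exactly that: the
maximum band ratio $\max(R_{rs}(443),R_{rs}(490),R_{rs}(510))/R_{rs}(555)$
falls monotonically with chlorophyll, and below 1 mg m⁻³ cool water shows
the higher ratio, because the community shifts from picophytoplankton
(strong blue absorbers per unit chlorophyll) toward nanophytoplankton as
SST falls. Under these defaults the SST separation of the curves is
concentrated in the oligotrophic range, peaking near 0.05 mg m⁻³.

```{r}
ratio_surface(chl = c(0.03, 0.3, 3), sst = c(10, 24)) |>
  tidyr::pivot_wider(names_from = sst, values_from = ratio)
```

## Evaluation statistics

Model skill is summarised in log₁₀ space, where absorption and chlorophyll
are approximately normal: `rmse_log10()` ($\Psi$; a constant decade offset
gives exactly 1), `pearson_log10()`, `compare_rmse_ci()` (t-based intervals
on $\Psi$ from the standard error of the mean squared log error — with
centred normal residuals the squared errors have variance $2\Psi^4$, giving
$\mathrm{se} = \Psi^2\sqrt{2/n}$; the exact estimator is under-specified in
the source, so this delta-method convention is documented here) and
`compare_correlations()` (standard Fisher r-to-z two-sample comparison).

## Synthetic data

`simulate_observations()` draws chlorophyll log-uniformly over
0.01–30 mg m⁻³ and SST uniformly over 0–30.8 °C — the span of the
calibration data the model was built from — evaluates the forward model
noise-free, and applies independent multiplicative lognormal noise per band
(no spectral covariance; a documented simplification, since real
measurement error correlates across neighbouring bands).
`simulate_raster()` builds small scenes with a log-chlorophyll gradient
along longitude, an SST gradient along latitude and a shared random mask.
Generated data carry their generating parameters, so every calibration and
propagation stage is testable closed-loop.

What passing closed-loop tests show is that the implementation inverts its
own forward model under the stated noise; they cannot show that the model
describes any particular ocean, which requires the in-situ match-up data
the original calibration used.

## Problem sizes and defaults used in the checks

The closed-loop calibration checks use a 40-point log-spaced chlorophyll
grid crossed with 20 (tests) or 6 (reported targets) SST levels; the
stochastic recovery check uses 500 records (50 × 10 grid), 20 % relative
noise, 200 bootstrap resamples and 20 seeds, accepting coefficients within
two robust standard deviations. Balanced crossed designs are used for these
checks because unbalanced random sampling occasionally drives the (small,
weakly constrained) nanophytoplankton coefficient to its zero bound, which
degenerates the bootstrap spread. Monte-Carlo validation of the lognormal
transform uses 10⁶ draws at 1 %.

## Known limitations

* The community partition and coefficient table are a North Atlantic
  calibration; applying them elsewhere extrapolates both.
* The forward reflectance model is a one-term closure without
  bidirectional effects, Raman scattering or an independent CDOM pool; only
  signs and monotonic structure should be interpreted.
* The first-order uncertainty propagation omits any covariance between
  $a_i^*$ and $C_i$ and between groups.
* Comparison models (power-law, three-population, polynomial band-ratio
  algorithm) take their published coefficients as inputs; none are bundled.
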