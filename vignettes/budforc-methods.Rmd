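---
title: "Modelling spring phenology with temperature- and photoperiod-triggered bud growth"
author: "budforc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spring phenology with temperature- and photoperiod-triggered bud growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budforc)
```

## The model

Winter-deciduous trees pass through successive dormancy stages before
spring: endodormancy, broken by chilling exposure, and ecodormancy,
released by accumulated warmth ("forcing"). One-phase process models
skip the chilling stage and track only the forcing phase, but they
must decide *when* forcing accumulation begins. budforc's central
model family treats that decision — the bud growth initiation trigger —
as a fitted mechanism with two alternative environmental cues.

From the trigger date $D_{start}$ onward, the daily bud growth rate is
a sigmoid function of daily mean air temperature $T_t$:

$$R_f(T_t) = \frac{1}{1 + e^{f_a (T_t - f_b)}}, \qquad f_a < 0,\ f_b > 0,$$

so the rate rises from 0 toward 1 as days warm, passing 0.5 at the
midpoint $f_b$. The bud growth state is the running sum
$S_f = \sum_{t = D_{start}}^{D_s} R_f(T_t)$, and the phenological event
(first leaf unfolding or first flowering) is predicted on the first
day $D_s$ on which $S_f$ reaches the forcing requirement $F^*$. The
start day itself contributes to the sum.

The two sub-models differ only in the trigger:

* **temperature trigger** — $D_{start}$ is the first day with
  $T_t > T_{start}$ after the climatological coldest date of the
  winter, pinned at January 20th of the event year (the search starts
  January 21st);
* **photoperiod trigger** — $D_{start}$ is the first day with
  daylength $P_t > P_{start}$ after the shortest-daylength date,
  pinned at day-of-year 355 of the previous calendar year.

Both sub-models have four fitted parameters
($T_{start}$ or $P_{start}$, $f_a$, $f_b$, $F^*$). Both
threshold comparisons are strict, and "after" means strictly after:
the search begins the following day. Pinning the solstice to DOY 355
makes it fall on December 20th in leap years; the one-day astronomic
drift is far below the model's sensitivity.

Three classical one-phase comparison models accumulate from a fixed
January 1st anchor instead of a fitted trigger: a plain sigmoid
forcing model (3 parameters), a photothermal variant whose daily rate
is weighted by the daylength fraction of the day ($P_t/24$,
3 parameters), and a growing-degree model whose rate is
$(P_t/10)\max(T_t - T_{base}, 0)$ (2 parameters). Their published
formulations vary in detail; the canonical literature forms are
implemented here, with the fixed January 1st start for all three. The
parameter counts (4, 3, 3, 2) feed the AICc penalty.

Daylength is computed from latitude and day of year with the Forsythe
revised-Schoolfield formulation: solar declination from the day-angle
approximation, then the hour-angle arccosine with a daylength
coefficient $p$ (degrees of solar elevation defining day's edge). The
default $p = 0.8333^\circ$ — the top of the refracted solar disc
touching the horizon — reproduces the 11.0 h to 13.2 h annual
daylength span at the study gradient's southern edge (18.2°N):

```{r daylength}
round(daylength(18.2, c(355, 172)), 1)
```

The arccosine argument is clamped to $[-1, 1]$, so polar day and night
degrade gracefully to 24 h and 0 h.

## Non-occurrence

A parameter vector may never fire its trigger, or never accumulate
$F^*$ by December 31st. Non-occurrence is a first-class value (`NA`
in predictions), not an error. During calibration each non-occurring
year contributes a fixed 100-day penalty residual, which keeps the
objective finite and strongly disfavours such parameter regions
without a discontinuity the annealer would have to jump.

## Calibration

Each site–species–phenophase series is fitted independently by
minimising the RMSE between observed and predicted dates with a
Metropolis simulated annealer: uniform random start in the bounds,
Gaussian proposals reflected at the bounds, acceptance probability
$e^{-\Delta/\tau}$ for uphill moves, geometric cooling
($\tau \leftarrow 0.9\,\tau$ per stage), and the best-ever solution
across independent restarts returned. Defaults: initial temperature
10 d, 60 stages of 200 iterations, 5 restarts, proposal SD 0.1 of
each bound width. Default search bounds are
$T_{start} \in [-5, 25]\,°C$, $P_{start} \in [6, 20]$ h,
$f_a \in [-2, -0.01]$, $f_b \in [0.1, 30]\,°C$,
$F^* \in [1, 200]$, $T_{base} \in [-5, 15]\,°C$.

One refinement proved necessary: because observed and predicted dates
are whole days, the RMSE surface is piecewise constant with unit-step
plateaus, and fixed-width proposals (10% of the bound width) stall
about half a day from the optimum. The proposal SD is therefore
annealed along with the temperature — scaled by
$\sqrt{\tau/\tau_0}$, floored at 2% of its initial value — so early
stages still traverse the whole box while late stages resolve
individual plateaus. With this schedule, noise-free synthetic series
are recovered to mean RMSE ≈ 0.3 d (individual seeds occasionally
settle on a one-day plateau).

The better of the temperature- and photoperiod-triggered fits (lower
RMSE) is the *selected optimum* for a series; an exact tie goes to
the photoperiod variant, an arbitrary but fixed and documented rule —
and not a purely cosmetic one, since at warm stations the two
sub-models can attain exactly equal RMSE (see Limitations).

Fits are scored by RMSE, Nash–Sutcliffe efficiency (1 = perfect, 0 =
no better than predicting the mean date, negative = worse), the
small-sample corrected AICc
$n\ln(\mathrm{SSE}/n) + 2n(k+1)/(n-k-2)$ (undefined and an error for
$n \le k+2$), and Pearson correlation with its two-sided p-value
(significance threshold 0.05). A zero-variance observed series makes
NSE's denominator zero; the sentinel $-\infty$ is returned rather
than an error. Leave-one-out cross-validation refits the model $n$
times, each fold excluding one year and predicting it with parameters
calibrated on the rest; fold $f$ uses annealer seed
$\texttt{rng\_seed} + f$, so folds are reproducible but follow
independent search trajectories (the full-series fit is *not* reused
as fold initialisation, which would leak information across folds).

## Data cleaning

Observed series are screened in a single pass: observations farther
than two sample standard deviations (n−1 denominator) from the series
mean are removed, with the statistics computed once on the full input
series — re-applying the rule with the original statistics is a
no-op, while recomputation could cascade and is deliberately not
done. Series shorter than 10 years after screening are rejected.
Screening precedes the length filter. Temperature series must be
contiguous; gaps of at most 3 days can be filled by linear
interpolation (logged), larger gaps are an error.

## The synthetic generator

The real observation network behind models of this kind is not
redistributable, so the package generates data with the statistical
structure the models assume. Daily mean temperature is a seasonal
sinusoid plus stationary AR(1) noise:

$$T(d) = \mu - A\cos\!\left(\frac{2\pi (d - d_{peak} + 182.5)}{365.25}\right) + e(d),$$

with $e(d) = \rho\, e(d-1) + \varepsilon_d$ and the innovation SD set
so that the marginal SD equals the configured `noise_sd`. Defaults
($\rho = 0.7$, marginal SD 3 °C) give day-to-day persistence typical
of mid-latitude weather. Phenology observations are generated by
running a known ("truth") forward model and adding rounded Gaussian
observation noise (default SD 1 d); an every-other-day observation
grid that snaps dates to odd days of year is available, emulating
networks whose observers visit on alternate days. Years in which the
truth model predicts no event are dropped with a warning, as a field
observer records a date only when the event is seen.

`make_network()` scales this to a latitude gradient emulating an
East Asian monsoon transect (18.2–53.6°N): the annual mean falls by
0.7 °C per degree latitude from 22 °C at the southern end, while the
seasonal amplitude grows northward (8 °C + 0.35 °C per degree),
reflecting the stronger continentality of the northern monsoon
region. Stations are assigned climate zones by latitude bands and a
generating trigger by a latitude rule — photoperiod south of 33°N,
temperature north — creating a testable north–south gradient in
trigger frequencies. The default record is 34 years.

The default truth parameters deserve a note. The temperature-trigger
truth uses $T_{start} = 10\,°C$ *above* the sigmoid midpoint
$f_b = 8\,°C$, so the threshold truncates days whose forcing rates
are substantial: the trigger is mechanistically operative in the
generated data. A threshold well below the midpoint would cut only
near-zero-rate days, producing data that are "temperature-triggered"
in name only and that the photoperiod sub-model fits equally well.
The photoperiod truth uses $P_{start} = 12$ h, crossed near the
spring equinox at every study latitude and comfortably inside each
station's annual daylength range.

What the generator does **not** emulate: precipitation, humidity and
frost; spatial correlation of weather between stations; trends
(warming) within the record; observation gaps; and chilling dynamics
— the truths are one-phase models, so tests show that the machinery
recovers one-phase structure, not that one-phase structure is true of
real forests.

## Derived climate metrics

Three station-level metrics summarise the winter–spring environment
relative to a series' mean event date: winter temperature (mean over
December–February, all winter days weighted equally), winter duration
(mean count of days below 5 °C from November 1st to the mean event
date), and spring temperature variation — the mean across years of
the standard deviation of linearly detrended temperature in the
60-day window ending the day before the mean event date. Detrending
is within each year's window; detrending across years per calendar
day would be a defensible alternative but is not implemented.
Trigger-frequency summaries can be binned by these metrics (10-day
winter-duration bins, 0.1 °C variation bins), with bins under 5 sites
excluded as unreliable.

## Numerical choices

* Sigmoid exponents are clamped at ±700 before `exp`, saturating the
  rate at 0 or 1 instead of overflowing.
* Predictions are reported as day-of-year of the phenology year;
  under the photoperiod trigger a prediction can fall in the previous
  December, giving values ≤ 0 rather than wrapping.
* A perfect fit makes AICc's $\ln(\mathrm{SSE}/n)$ singular; SSE is
  floored at the smallest positive double, yielding a very negative
  but finite score.
* The annealer restores the caller's RNG state, so calibration is
  reproducible without perturbing the session.
* Problem sizes in the test suite were chosen to exercise realistic
  conditions at desk scale: 30–34-year series for recovery checks,
  12-year series for structural cross-validation checks, 20 stations
  for the network scenario, and a reduced annealer budget
  (2 restarts, 40 stages of 120 iterations) wherever fit *quality* is
  not itself the property under test; noise-free cross-validation
  folds use the full default budget because under-converged fold fits
  inflate the held-out error.

## Limitations

* **Trigger identifiability degrades at warm stations.** Where spring
  temperatures sit far above $f_b$, forcing rates saturate and a
  temperature trigger with a low threshold mimics a fixed start date;
  the two sub-models can then attain equal — or, by overfitting
  observation noise, even lower-than-truth — RMSE, and minimum-RMSE
  selection between them becomes unstable. On the default synthetic
  gradient this leaves roughly one station in twenty (always among
  the warmest) with an effectively arbitrary trigger label, so strict
  monotonicity of zone-level percentages across small southern zones
  (n = 2–3) fails in a substantial fraction of realisations even
  though 19–20 of 20 triggers are recovered. Zone cells this small
  are flagged (`small`) in summaries for exactly this reason.
* The RMSE surface's integer-day plateaus mean reported parameter
  values are representatives of a plateau, not unique optima;
  $f_a$, $f_b$ and $F^*$ trade off along a ridge. Assessments should
  rest on predicted dates, not raw parameter values.
* Comparison-model formulations follow canonical literature forms;
  published variants differ (e.g. fitted rather than fixed start
  anchors) and would shift AICc comparisons.
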