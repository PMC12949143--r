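---
title: "Lung volume from two-breath CO2 rebreathing: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung volume from two-breath CO2 rebreathing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rebreathe)
```

## The measurement model

The method treats the lung as a single CO2-equilibrating compartment of
volume ELV — the gas volume at end-expiration (FRC) plus the lung tissue
and pulmonary capillary blood in which CO2 dissolves. Breathing through an
external dead space of known volume DV returns, on every inspiration, the
CO2 that the previous expiration parked there. The first expiration fills
the dead space with gas at partial pressure avPet; re-inspiring that CO2
volume (avPet·DV) into ELV raises the end-tidal value by

$$\Delta P_{et} = \frac{avP_{et} \cdot DV}{ELV}.$$

As rebreathing continues, recirculation and metabolic CO2 production bend
the rise onto a saturating exponential with rate constant $k \approx 0.06$
s$^{-1}$; the plateau is reached in roughly $\ln(10)/0.06 \approx 38$ s.
Only the first two breaths are used. With the cumulative rises
$\Delta P_{et,1} = P_{et}(1) - P_{et}(0)$ and
$\Delta P_{et,2} = P_{et}(2) - P_{et}(0)$,

$$\Delta P_{et} = \tfrac12\,(\Delta P_{et,1} + w\,\Delta P_{et,2}), \qquad
ELV = \frac{2\,avP_{et}\,DV}{\Delta P_{et,1} + w\,\Delta P_{et,2}}, \qquad
FRC = K \cdot ELV.$$

The *cumulative* convention for $\Delta P_{et,2}$ is essential: it is the
only reading under which the weighted-mean expression and the ELV formula
with its leading factor 2 are the same equation, and in the linear
(slow-kinetics) limit it reduces gracefully to the single-breath formula.

### The second-breath weight

Under single-exponential kinetics with per-breath decay
$\rho = e^{-kT}$ (T the breath period), the cumulative rises satisfy
$\Delta P_{et,2} = \Delta P_{et,1}(1 + \rho)$. The weight

$$w = \frac{1}{1 + e^{-kT}}$$

therefore makes $\tfrac12(\Delta P_{et,1} + w\,\Delta P_{et,2}) =
\Delta P_{et,1}$ identically — the estimator is exact whatever $k$, which
is the package's primary test oracle. At typical kinetics ($k = 0.06$
s$^{-1}$, $T = 5$ s) the formula gives
`r round(second_breath_weight(0.06, 5), 3)`, the origin of the fixed
default 0.57. The weight formula itself is a reconstruction from the
stated kinetics; the shipped default remains the fixed constant, and
`weight = "auto"` is the opt-in refinement.

With the fixed weight the zero-noise error is bounded and sign-predictable
across the clinically observed breathing-rate range (4.6–16.8 breaths/min).
The ideal weight $1/(1+\rho)$ grows as breaths lengthen, so at slow rates
0.57 is too small, the weighted rise is underestimated and ELV
overestimated (about +9% at 4.6/min); the error crosses zero near 12.7/min
(where the ideal weight equals 0.57) and reaches about −1.5% at 16.8/min.
The test suite tabulates this bias curve.

When `weight = "auto"` is requested, $\rho$ is fitted in breath-index space
($P_{et}(n) = p_0 + \Delta p_\infty(1 - \rho^n)$ by Levenberg–Marquardt
least squares over all detected breaths) and $w = 1/(1+\rho)$. Fitting
against the breath index rather than the detected breath *times* is
deliberate: threshold-crossing times are quantised to the sample grid,
which would inject ~$10^{-3}$ relative error into a time-domain rate
estimate; timing irregularity is the QC's job, not the weight's. The
separate `fit_rebreathing_kinetics()` provides the time-domain fit
($k$, plateau, baseline) for records long enough to support it.

## Capnogram segmentation

Breath detection uses an adaptive mid-range threshold with hysteresis.
Design choices that matter:

* **Quantile envelope.** The threshold is the mean of the running 20th and
  80th percentiles over a sliding window of `window_breaths` (default 2)
  nominal breath periods, with hysteresis of 10% of the running range. An
  adaptive threshold is mandatory during rebreathing — the inspiratory
  trough rises breath by breath, so any fixed threshold fails after a few
  breaths. Quantiles rather than the absolute min/max make the envelope
  robust to the brief near-zero room-air samples at the start of the
  record, which would otherwise drag the threshold below the first
  inspiratory troughs and merge breaths 0 and 1.
* **Baseline trim.** A flat pre-measurement baseline longer than 1 s is
  trimmed (everything within 1 s of the first rise above baseline + 25% of
  range is kept) so that a long idle recording cannot dominate the
  envelope or the nominal-period estimate.
* **Nominal period.** Estimated from threshold crossings of a 0.5 s
  moving-average of the signal; raw-signal crossings chatter under
  analyzer noise. Intervals under 0.5 s are discarded as chatter.
* **Phase hygiene.** Phases shorter than `min_phase_s` (default 0.25 s)
  are merged into their neighbour. Detected expiratory phases containing
  an interior valley deeper than 0.4 kPa — twice the no-respiratory-signal
  floor, evaluated on a `min_phase_s` moving average so noise cannot fake
  a valley — are recursively split: such valleys are inspirations that the
  running envelope bridged, which happens under very uneven breathing. The
  criterion is absolute rather than range-relative because breath
  amplitudes can differ enough that a genuine inspiration is small
  compared with the phase's overall range.
* **End-tidal extraction.** Pet is the maximum of the median-of-3 smoothed
  signal over the final 25% of the expiratory phase; the median filter
  suppresses single-sample spikes and the window targets the
  alveolar-plateau end value. Ties take the later sample (closer to true
  end-expiration). Both the window fraction and the hysteresis are
  configurable.
* **Units.** Internal unit is kPa; mmHg input is converted (×0.133322).
  ELV itself is a pressure *ratio* and therefore unit-invariant; only I/O
  and noise-magnitude defaults care.
* A breath already in progress at the first sample is dropped: its onset
  was not observed and its end-tidal value is unreliable. Breath index 0
  is the first *complete* expiration — the one that fills the dead space —
  and all rises are referenced to it.

## The simulator

The simulator exists so that every stage can be tested against known
ground truth, since no subject-level clinical data are published. It
emulates a sidestream-sampled rebreathing capnogram:

* **Kinetics.** Breath-wise $P_{et}(n) = p_0 + \Delta p_\infty(1-\rho^n)$
  with $\rho = e^{-kT}$ and $\Delta p_\infty = p_0\,DV/(ELV\,(1-\rho))$.
  This parameterisation makes the first-breath rise *exactly* the ideal
  increment $p_0\,DV/ELV$, so zero-noise parameter recovery is an exact
  oracle by construction. Metabolic CO2 production and recirculation are
  not modelled mechanistically; their net effect is absorbed into the
  single exponential, which is exactly how the method itself summarises
  the kinetics.
* **Waveform.** Each breath renders as a sigmoid expiratory upstroke
  (0.4 s), an alveolar plateau with positive slope terminating at that
  breath's Pet (held flat over the last ~0.08 s so the plateau end lies on
  the sample grid — without this, grid misalignment alone would add
  ~3·10⁻³ kPa of error and no exactness oracle would exist), and a sigmoid
  inspiratory downstroke to the trough. During rebreathing the trough is
  the dead-space gas level — the previous end-tidal decayed by 20% through
  fresh-gas-free mixing — not the near-zero of open-air breathing.
* **Analyzer.** First-order lag (default τ = 0.15 s), transport delay
  (default 0.5 s) and additive Gaussian noise (default SD 0.05 kPa) —
  typical sidestream figures, all configurable. One seeded RNG stream per
  call; the caller's RNG state is untouched.
* **Defaults as study conditions.** Tidal volume 1.1 L and respiratory
  rate 11/min are the study-population means; DV = 0.148 L throughout;
  baseline Pet 5 kPa is a typical adult end-tidal value; default true ELV
  3.7 L corresponds to FRC ≈ 3 L at K = 0.82.
* **Artifacts.** The two clinically reported failure modes:
  `irregular_breathing` jitters each cycle's duration and amplitude by
  independent multiplicative log-normal factors (log-SD = severity) with
  cycle-wise time-warping and resampling; `leak` scales all pressures from
  the start of breath 1 onward by (1 − severity), emulating dead-space CO2
  escaping at the mouthpiece. A leak large enough to matter (severity
  above the ~5% relative first-breath rise) makes the Pet sequence
  non-rising — exactly the pattern the leak QC flag looks for — while a
  small leak yields a computable but high-biased ELV (the apparent rise
  shrinks, inflating the volume).

What the simulator does *not* emulate: ventilation/perfusion
heterogeneity, CO2 dissociation-curve chemistry, cardiogenic oscillations,
and drift or curvature of real alveolar plateaus. Passing tests therefore
demonstrate correctness of the estimator and robustness to noise, lag,
delay, baseline and the two artifact modes — not performance on real
patients.

## Quality control

QC never throws; it flags:

* `dv_tv_low` / `dv_tv_high` — DV/TV outside 0.10–0.25 (only when a tidal
  volume is supplied). Below the envelope the per-breath rise is
  comparable to measurement noise; above it breathing is disturbed.
* `irregular` — coefficient of variation of the breath periods around the
  three breaths that enter the formula exceeds 0.25. Irregular breathing
  is the main clinical source of variability.
* `leak_suspected` — $\Delta P_{et,1} \le 0$ or $P_{et}(2) < P_{et}(1)$:
  the accumulation pattern is broken.
* `insufficient_breaths` — fewer than three usable breaths (this includes
  records where segmentation itself fails).

At the simulator's artifact severity of 0.5 the leak flag fires
deterministically and clean fixtures are essentially never flagged. For
irregular breathing the detection rate is about 95% (90–98% across seed
streams): part of the injected records are drawn with period CVs that
genuinely fall below the 0.25 limit (no regularity check can flag those),
and the most extreme amplitude excursions can place an entire breath cycle
below its neighbours' troughs, where no threshold detector can see it.

## Agreement statistics

Bland–Altman from first principles: bias = mean(method − reference),
limits of agreement = bias ± 1.96·SD of differences (n − 1 denominator;
1.96, not 2.0). Percentage error PE = 1.96·SD / mean(reference), with
PE < 0.30 as the exchangeability criterion. The PE denominator is the
*reference* mean by default (configurable to the pooled mean — conventions
differ between authors and the choice matters when methods are biased).
Repeated observations are treated as independent in the primary analysis;
the replicate-averaged pathway (`average_replicates()`) is the separate,
explicitly chosen alternative. For independent errors, averaging two
replicates divides PE by √2 — the clinically observed improvement is
nearer a factor of 2, which the √2 prediction does not contradict since
within-subject variability is not purely independent noise. The paired and
unpaired t-tests wrap the standard implementations, adding the degenerate
zero-variance conventions (identical samples: t = 0, p = 1; zero variance
with nonzero mean difference: p = 0); the unpaired test defaults to the
Welch form since equal variances cannot be assumed.

## Alveolar geometry

The proportionality FRC = K·ELV has a geometric sanity check: spreading a
typical adult's lung tissue (500–700 mL) plus capillary blood (100 mL)
over the alveolar surface (90 m²) gives a layer $h = (V_t+V_b)/A$ of
6.7–8.9 µm (the unit happy-coincidence 1 mL/m² = 1 µm is asserted in a
test, not assumed silently). Representing FRC as a single average alveolus
(sphere, r = 125 µm) and ELV as the same sphere plus the layer, the volume
ratio $r^3/(r+h)^3$ evaluates to 0.86–0.81 — bracketing K = 0.82. The
package reports this direct computation; slightly different published
renderings of the same check exist, and no test asserts anything but the
direct arithmetic.

## Numerical choices and problem sizes

* Exactness tolerances: the zero-noise pipeline oracle is asserted at
  1e-6 relative ELV error (measured ~1e-15) over the grid ELV ∈ {2,3,4,5} L
  × RR ∈ {5,8,11,17}/min.
* The kinetics fit starts from the closed-form increment ratio
  $\rho_0 = \Delta_2/\Delta_1$, clamped to (0.005, 0.995), so on exact
  data the optimiser starts at the optimum; non-convergence falls back to
  the fixed weight.
* Statistical calibration uses 5000 null replicates for each t-test
  (type-I error asserted within 0.05 ± 0.01) and 200 simulated cohorts of
  10 subjects for the Bland–Altman and averaging properties; artifact
  detection uses 100 seeded runs per condition. These sizes give
  Monte-Carlo standard errors several times smaller than the asserted
  tolerances while keeping the default suite fast.
* Degenerate inputs are contracts, not crashes: flat traces report "no
  respiratory signal" (running range < 0.2 kPa), short records
  "insufficient breaths", non-rising Pet "non-rising Pet"; QC functions
  never throw.

## Known limitations

* The method presumes the mid-dead-space sample represents the dead-space
  average (linear-gradient argument); any systematic offset between that
  value and the airway-opening end-tidal value is not modelled — the two
  are treated as equal.
* K = 0.82 is a healthy-adult constant; disease shifts it (≈0.88 non-ARDS,
  ≈0.77 severe ARDS in mechanically ventilated patients). It is exposed as
  a parameter, not estimated.
* Tidal volume is user-supplied for the DV/TV check; the package does not
  estimate TV from the capnogram.
* The clinical headline agreement numbers (bias ≈ 0.04 L, PE 0.54 single /
  0.23 averaged against a methane-dilution reference) derive from
  unpublished subject-level data and are therefore documented, not
  reproduced; the statistics machinery is validated on simulated cohorts
  with known truth instead.
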