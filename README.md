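# rebreathe

Bedside lung-volume estimation from two-breath CO₂ rebreathing, for
respiratory physiologists and biomedical engineers working with sidestream
capnometry.

## The method

Functional residual capacity (FRC) is normally measured with body
plethysmography or gas-dilution equipment. A much simpler alternative needs
only an external dead space of precisely known volume (DV, here 0.148 L)
and an end-tidal CO₂ monitor. The subject breathes in and out of the dead
space, starting with an expiration. That first expiration fills the dead
space with gas whose CO₂ partial pressure is `avPet` (sampled at the
mid-dead-space port, which represents the average over the whole dead space
because the axial gradient is close to linear when DV/TV < 0.25). On the
next inspiration that CO₂ volume, `avPet·DV`, is returned into the
CO₂-equilibrating volume of the lung — the *effective lung volume* ELV
(gas plus lung tissue plus capillary blood) — raising the end-tidal value
by

```
ΔPet = avPet · DV / ELV        ⇒        ELV = avPet · DV / ΔPet
```

Rebreathing drives Pet upward along a saturating exponential (rate constant
k ≈ 0.06 s⁻¹, plateau in 30–40 s). Only the first two breaths — the nearly
linear part — are used, with the second breath's cumulative rise
down-weighted because it already bends off the linear trend:

```
ΔPet = 0.5 · (ΔPet1 + w · ΔPet2)
ELV  = 2.0 · avPet · DV / (ΔPet1 + w · ΔPet2)
FRC  = K · ELV,   K = 0.82 in health
```

where `ΔPet1 = Pet(1) − Pet(0)`, `ΔPet2 = Pet(2) − Pet(0)` and the weight
`w = 1/(1 + e^(−kT))` evaluates to 0.57 at typical kinetics (k = 0.06 s⁻¹,
breath period T = 5 s); 0.57 is the shipped default and `weight = "auto"`
re-estimates it per record from the fitted wash-in.

The package implements the whole chain: breath segmentation and end-tidal
extraction from raw capnograms, the estimator with quality-control gating
(DV/TV envelope, breathing regularity, leak detection), a ground-truth
rebreathing simulator for validation, Bland–Altman agreement statistics
with the percentage-error exchangeability criterion, and an
alveolar-geometry consistency check of the constant K.

## Worked example

```r
library(rebreathe)

params <- simulator_params(elv_true = 3.4, rr = 12, tv = 1.1, seed = 42)
trace  <- simulate_capnogram(params, n_breaths = 6)
est    <- estimate_rebreathing(trace, dead_space = 0.148,
                               weight = "auto", tv = 1.1)
est
#> <rebreathing_estimate>
#>   avPet   5.043 kPa   dPet1 0.190   dPet2 0.367   w 0.566
#>   ELV     3.751 L     FRC 3.076 L (K = 0.82)
#>   QC      clean
```

The simulated subject has a true ELV of 3.4 L; with realistic analyzer
noise (SD 0.05 kPa), lag and transport delay the single-shot estimate comes
out at 3.75 L — a ~10% error, typical for one measurement, which is why
repeated measurements are averaged in practice. `avPet` is the end-tidal
value of breath 0 (the dead-space-filling expiration), `dPet1`/`dPet2` the
cumulative rises of breaths 1 and 2 over it, `w` the second-breath weight
refitted from this record's kinetics, and `QC clean` states that no flag
(dead-space/tidal-volume ratio, irregular breathing, suspected leak,
insufficient breaths) was raised.

Method comparison against a reference technique:

```r
pairs <- measurement_pairs(c("a","b","c","d"),
                           method_value    = c(3.1, 2.6, 3.3, 2.4),
                           reference_value = c(3.0, 2.8, 3.2, 2.6))
bland_altman(pairs)
#> <agreement_stats> n = 4
#>   bias -0.050 L, SD 0.173 L, LoA [-0.389, 0.289] L
#>   percentage error 0.117 -> exchangeable (PE < 0.30)
```

Geometric consistency of K = 0.82 (tissue + blood spread as a layer over
the alveolar surface, sphere-in-sphere volume ratio):

```r
alveolar_consistency()
#>   tissue_volume_ml     h_um frc_elv_ratio
#> 1              500 6.666667     0.8556625
#> 2              700 8.888889     0.8137602
```

## Command line

A thin wrapper (installed under `inst/cli/rebreathe.R`) exposes the
pipeline as subcommands:

```sh
Rscript inst/cli/rebreathe.R simulate --elv 3.0 --rr 12 --seed 1 --out trace.csv
Rscript inst/cli/rebreathe.R estimate trace.csv --dead-space 0.148 --weight auto
Rscript inst/cli/rebreathe.R agree pairs.csv --average
Rscript inst/cli/rebreathe.R geometry --tissue 600
```

Traces are two-column CSV (`time_s,pco2_kpa`, or `pco2_mmhg` with automatic
conversion); structured results are schema-tagged JSON.

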