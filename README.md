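# insolegait

Data-processing and gait-analysis pipeline for a 64-cell optoelectronic
pressure-sensitive foot insole, plus a synthetic gait simulator so that every
stage can be developed and validated without the hardware.

The package targets researchers and engineers working with instrumented
insoles for wearable gait analysis: it turns raw per-cell voltage streams
into vertical ground reaction force (νGRF), centre-of-pressure (CoP)
trajectories, gait-phase labels and temporal gait parameters, and provides
the comparison statistics used to validate an insole against a force
platform.

## The model

Each of the 64 silicone cells is an optoelectronic force-to-voltage
transducer with working range 0–500 kPa over 1 cm² (50 N full scale). Its
de-offset output voltage *v* (≤ 0 under load) maps to a compressive force by
a sum of two exponentials with a noise threshold:

    F(v) = 0                                   if v > v0   (v0 = −0.02 V)
    F(v) = A1·exp(c1·v) + A2·exp(c2·v)         if v ≤ v0

with the aggregate (firmware) coefficients A1 = 21.386 N, c1 = 4.834 V⁻¹,
A2 = −22.30 N, c2 = −0.401 V⁻¹. Per-cell models are fitted by constrained
nonlinear least squares (`fit_calibration()`); the aggregate model pools all
cells' samples (`aggregate_calibration()`).

From the per-cell forces Fᵢ and cell coordinates (xᵢ, yᵢ):

    νGRF  = Σ Fᵢ
    CoPx  = Σ Fᵢ·xᵢ / νGRF ,  CoPy = Σ Fᵢ·yᵢ / νGRF

with νGRF set to 0 and the CoP undefined (NaN) whenever νGRF > −20 N. The
y axis runs from 0 mm (toe) to 250 mm (heel). Each 100 Hz sample is then
classified into one of three gait phases:

    CoP undefined                →  SW   (swing)
    νGRF ≤ −20 N, CoPy > 125 mm  →  ST1  (initial contact + mid-stance)
    νGRF ≤ −20 N, CoPy ≤ 125 mm  →  ST2  (terminal stance + pre-swing)

Heel strikes (SW→stance) and toe offs (stance→SW) delimit steps; the first
and last two steps of a trial are trimmed, and stance/swing/double-support
durations, their % of stride, and cadence = 1/(Δt_ST + Δt_SW) are reported
per foot. Step νGRF profiles are resampled to 100 points over stance and
compared by NRMSE = RMSE/(max−min of the insole profile), Pearson
correlation, and the MAE of paired stance durations.

The signal path mirrors the on-board firmware: per-channel de-offset,
causal 2nd-order Butterworth low-pass at 40 Hz, decimation from 1200 Hz to
100 Hz.

## Worked example

Simulate nine steps of steady walking (stance 0.80 s, swing 0.45 s,
double-peak νGRF of a 75 kg subject), run the full pipeline, and summarize:

```r
library(insolegait)

scenario <- gait_scenario(n_steps = 9, seed = 42)
trial    <- generate_trial(scenario)          # raw 1200 Hz voltage streams
left     <- process_stream(trial$left,  "left")
right    <- process_stream(trial$right, "right")
ds       <- double_support(left$phases, right$phases)
trial_summary(left$steps, right$steps, ds)
```

```
    side   parameter   mean       sd n
1   left dt_stance_s  0.770 4.44e-16 5
2   left  dt_swing_s  0.480 4.87e-16 5
3   left  stance_pct 61.600 3.69e-14 5
4   left   swing_pct 38.400 3.69e-14 5
5   left  cadence_hz  0.800 1.11e-16 5
6   left     dt_ds_s  0.149 3.33e-03 5
7   left      ds_pct 11.911 2.67e-01 5
8  right dt_stance_s  0.780 4.00e-16 5
...
```

Nine simulated steps minus two trimmed at each end leave five analyzed steps
per foot. The true stance is 0.80 s: the −20 N stance threshold detects
contact a few samples late and lift-off a few samples early, so the
recovered stance (0.77–0.78 s) is some 20–30 ms short — the pipeline's
intrinsic detection delay — while cadence is exact (0.800 Hz) because both
step boundaries shift equally. Double support recovers 0.149–0.151 s against
a true 0.175 s for the same reason.

The per-cell worst-case error of the −0.02 V noise threshold:

```r
round(abs(force_from_voltage(-0.02, default_calibration())), 2)
#> 3.06
```

A command-line wrapper with `simulate`, `calibrate`, `process` and `compare`
subcommands is installed at `inst/cli/insolegait.R`.

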