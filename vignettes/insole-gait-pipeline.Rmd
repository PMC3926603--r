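---
title: "From raw insole voltages to gait parameters: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw insole voltages to gait parameters: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolegait)
```

This vignette explains the science implemented by `insolegait`: the
transduction model of the 64-cell optoelectronic insole, the signal path,
the biomechanical quantities, the threshold-based gait segmentation, the
simulator that stands in for the hardware, and the design choices taken
where the problem left them open.

## The transduction model

Each silicone cell is a force-to-voltage transducer: load deforms the cell,
a curtain occludes the light path between an LED and a photodiode, and the
de-offset output voltage *v* falls below zero. The calibration curve is a
sum of two exponentials,

$$F(v) = A_1 e^{c_1 v} + A_2 e^{c_2 v}, \qquad v \le v_0 = -0.02\ \mathrm{V},$$

with $F(v) \equiv 0$ above the noise threshold $v_0$. The sign pattern
$A_1 > 0$, $c_1 > 0$, $A_2 < 0$, $c_2 < 0$ is enforced structurally
(`calibration_model()`); it guarantees $dF/dv > 0$ everywhere on the branch,
so the curve is strictly increasing and numerically invertible. Forces are
negative under compression throughout the computational layer; report layers
may display magnitudes.

The threshold creates a jump of $|F(v_0)| \approx 3.06$ N at $v_0$ for the
aggregate coefficients: any cell loaded below that force reads exactly zero.
This is the per-cell worst case of the thresholding error; across 64 cells
it accumulates to $64 \times 3.06 \approx 195.8$ N, and the single shared
calibration curve leaves a residual of roughly 5% of the 50 N per-cell full
scale, i.e. up to $64 \times 2.5 = 160$ N when every cell is fully loaded.
These closed-form figures are asserted in the test suite.

**Fitting.** `fit_calibration()` uses a deterministic multi-start: a coarse
grid over $(c_1, c_2)$ with linear least squares for $(A_1, A_2)$ at each
node, the best starts refined by Levenberg–Marquardt (`minpack.lm::nlsLM`)
under box constraints that pin the sign pattern. The constraints remove the
label-swap degeneracy of two-exponential fits ($A_1 \leftrightarrow A_2$).
No randomness is involved, so fits are reproducible by construction. On
noise-free forward-model data the coefficients are recovered to better than
$10^{-4}$ relative with $R^2 = 1$.

**Aggregate model.** "One curve for all cells" is implemented as a fit to
the *pooled* samples of all 64 cells, not as the average of per-cell
coefficients: pooled fitting is what produces an aggregate curve whose
coefficients differ from the coefficient means, and its residual is
necessarily at least the per-cell average — the pattern a shared firmware
curve shows against per-cell characterization. Coefficient averaging was
rejected because the mean of exponential-family coefficients does not give
the mean curve.

**Inversion.** `voltage_from_force()` (needed by the simulator) uses a
monotone lookup grid plus vectorized Newton polishing; residuals are below
$10^{-9}$ N. Forces in the dead band $(F(v_0), 0)$ have no pre-image and
raise a domain error.

## Signal path

The on-board chain is mirrored exactly: per-channel de-offset against an
operator-chosen unloaded window (default: the first 0.5 s), low-pass
filtering at 40 Hz, decimation from 1200 Hz to 100 Hz keeping every 12th
sample.

The filter family and order are not dictated by the hardware description,
only the cut-off. We use a causal 2nd-order Butterworth by default: a
real-time microcontroller runs a causal IIR section, and the low order keeps
the group delay (≈ 6 ms at low frequency) consistent with the observed
event-detection latency of a few tens of milliseconds. Order and zero-phase
(forward–backward) filtering are configurable for offline work. A
2nd-order design attenuates a 55 Hz component to ≈ 0.47 of passband — enough
for anti-aliasing at the 50 Hz output Nyquist given the 40 Hz cut-off, but
not a brick wall; users needing stronger stopband rejection should raise
`order`. The unit tests check the measured attenuation against the filter's
analytic frequency response rather than a fixed figure, so the property
tested is "the implementation realizes its own design" plus a coarse
attenuation bound.

## νGRF, CoP and the −20 N rule

`compute_vgrf_cop()` computes the force sum and the force-weighted centroid
per frame. The centroid is computed from the raw sums *first*; the −20 N
rule is applied afterwards: frames with $\nu GRF > -20$ N report zero force
and an undefined CoP (a typed NaN, serialized as `"NaN"`, never a silent 0).
The ordering matters only for frames that the rule zeroes — computing the
centroid before zeroing reproduces the defined/undefined dichotomy exactly,
with no frame ever carrying a CoP without a force. Equality at exactly
−20 N counts as loaded, matching the `≤` in the segmentation rule.

Pressure maps (`pressure_map()`) connect the lattice cells into squares and
interpolate bilinearly; deliberately **no** smoothing and no outlier
removal, so the map shows the data the sensors produced. Nodal pressure is
$|F_i|$/area (50 N over 1 cm² = 500 kPa, the full scale).

## Gait segmentation and temporal parameters

Classification is a total, causal, per-sample rule: swing when the CoP is
undefined; ST1 (initial contact + mid-stance) while the CoP is in the rear
half ($CoP_y > 125$ mm); ST2 (terminal stance + pre-swing) otherwise. Heel
strike is any SW→stance transition, toe off any stance→SW transition, both
timed at the first sample of the new phase — a quantization of at most one
sample (10 ms) consistent with a real-time design. Direct SW→ST2 contacts
(forefoot-first) still count as contact onset but are flagged atypical,
since the rule set permits them and dropping them would silently lose
steps. No debouncing is applied by default — the −20 N threshold is the
noise gate — but a minimum-phase-duration filter (30 ms when enabled) is
available for pathological inputs.

Steps are heel-strike-to-heel-strike intervals per foot; the first and last
two steps of a trial are trimmed so that only steady-state gait is
analyzed. Double support DS_L is the overlap of left-ST1 with right-ST2
(the interval preceding a left single support), DS_R the mirror image; each
run of overlapping samples becomes one record. Cadence is
$1/(\Delta t_{ST} + \Delta t_{SW})$. All standard deviations use the
sample ($n-1$) denominator.

Step νGRF profiles are resampled to 100 points over the *stance* phase
(not the full stride), because stance is the portion a force platform can
confirm; the resampling span is configurable. NRMSE is implemented exactly
as RMSE divided by the insole profile's range — a dimensionless quantity of
order 1 for similar profiles.

## The simulator

`generate_trial()` emulates what the hardware would produce during steady
walking, with known ground truth:

1. **νGRF template** — a piecewise raised-cosine curve through
   $(0,0) \to (p_1, \mathrm{peak}_1) \to (m, \mathrm{valley}) \to
   (p_2, \mathrm{peak}_2) \to (1,0)$ over stance. Raised-cosine segments
   are C¹, have zero slope at every control point, and therefore produce
   *exactly* two local maxima, analytically placed: $p_1 = 0.20$ (inside
   the physiological 15–25% weight-acceptance window) and $p_2 = 0.75$
   (inside the 70–80% push-off window). Defaults scale to subject weight:
   peaks 1.15/1.10 × BW, valley 0.75 × BW for a 75 kg subject.
2. **CoP trajectory** — $CoP_y$ descends monotonically 240 → 20 mm along a
   half-cosine (heel strike in the rear half, a single crossing of the
   125 mm boundary at ≈ 51% of stance), while $CoP_x$ follows the foot
   centreline (heel ≈ 40, arch ≈ 50, toe ≈ 40 mm) so the CoP always stays
   inside the sensed hull.
3. **Load distribution** — `distribute_pressure()` spreads the total force
   over cells within a 30 mm Gaussian footprint of the CoP (5–20 cells)
   and shifts the Gaussian centre by 2-D Newton iterations until the
   force-weighted centroid matches the requested CoP to $10^{-6}$ mm, with
   the force sum exact by construction.
4. **Transduction inverse** — forces beyond the threshold force invert
   through the calibration curve; dead-band forces map to $v_0$; unloaded
   cells to 0 V. Per-channel static offsets (≈ 1.3 V, the photodiode
   resting level) and Gaussian noise (0.005 V) are added. The noise level
   keeps unloaded cells 4σ away from the −0.02 V threshold, so spurious
   contacts are vanishingly rare — the same logic by which the device's
   thresholds suppress false positives.

Timing: with the right foot offset $\Delta t_{ST} - ds$ after each left
heel strike, periodic gait pins the double supports at $DS_R = ds$ and
$DS_L = \Delta t_{ST} - \Delta t_{SW} - ds$; the symmetric default
$ds = (\Delta t_{ST} - \Delta t_{SW})/2$ (0.175 s for the default
0.80/0.45 s stance/swing) makes both equal, and infeasible combinations are
rejected at scenario construction. Defaults (stance 0.80 s, swing 0.45 s,
cadence 0.80 Hz, DS ≈ 0.17 s) correspond to slow, steady adult walking.

**What the simulator does not emulate:** step-to-step variability (every
stance reuses one template), shear loads, soft-tissue dynamics, ADC
quantization, transmission loss, inter-subject foot-shape differences, and
the drift-free-but-imperfect realities of physical sensors. Passing the
recovery tests therefore demonstrates that the *pipeline* is correct and
self-consistent under the stated transduction law — not that the physical
device achieves these accuracies on human data.

## Numerical choices and degenerate inputs

* Threshold comparisons are literal and signed: stance iff
  $\nu GRF \le -20$ N; `>` above threshold means zeroed.
* The stance template with equal peaks and valley degenerates to a smooth
  plateau — valid, not an error.
* `extract_steps()` on fewer than $2\,\mathrm{trim} + 1$ steps returns an
  empty result with a warning rather than partial statistics.
* A stream that starts mid-stance yields a toe off first; the leading
  partial stance never forms a step.
* Constant-voltage (never loaded) input flows through the whole pipeline to
  an empty summary and a clean exit.
* CSV dialect is fixed (comma, `.` decimal, `NaN` sentinel) and all
  readers/writers are mutually inverse on it, so re-runs are reproducible
  file-for-file.

## Problem sizes used in the checks

The end-to-end recovery checks simulate 24 steps per foot (≈ 31 s of gait,
1200 Hz × 64 channels) and require stance, swing and double-support
durations within ±40 ms of ground truth (4 samples at 100 Hz, consistent
with the threshold crossing delay plus filter group delay) and cadence
within ±0.02 Hz; unit tests use 3–9 steps. The detection delay is visible
and systematic: stance is recovered ≈ 25–30 ms short because contact is
detected after the force crosses 20 N and lift-off before it; cadence is
exact because consecutive heel strikes shift equally.

## Known limitations

* The shared aggregate curve is the shipped default, as in the device
  firmware; per-cell models are supported (`frame_forces()` accepts a list
  of 64) but per-cell calibration data must be supplied.
* Event timing is quantized to the 100 Hz grid; sub-sample interpolation of
  the threshold crossing would reduce the systematic stance bias but would
  no longer mirror the real-time implementation.
* NRMSE normalizes by the insole profile's range; comparisons against
  references on a different scale are meaningful only through the Pearson
  coefficient.
* The pressure-map mesh requires cells on a common 10 mm lattice (true of
  the default layout); arbitrary layouts fall back to isolated nodal
  values where no complete lattice square exists.
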