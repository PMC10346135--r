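---
title: "Validating IMU-based ROM against motion capture: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating IMU-based ROM against motion capture: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinagree)
```

## 1. What the package models

A single thigh- or trunk-worn inertial measurement unit (IMU) reports its
orientation as unit quaternions at 30 Hz; an optoelectronic motion-capture
system tracks the same body segment at 100 Hz. Seven guided motor tasks
(semi-squat, hip abduction/flexion/extension, knee extension, anterior trunk
flexion, trunk bending) are each performed as 10 repetitions of a
rest–ramp–hold–return cycle. The validation question is whether the
working-phase range of motion (ROM) measured by the IMU agrees with the
reference system, and how sensitive it is to the sensor being worn slightly
rotated around the limb.

Because raw paired recordings of this kind are not freely distributable, the
package's first-class citizen is a synthetic session generator with known
ground truth. Every downstream stage — synchronization, segmentation, the
agreement suite, the misplacement analysis — is exercised and tested against
that generator.

## 2. The synthetic stated world

`make_template(task)` builds the task profile; `sim_config()` +
`generate_session()` render one paired session. Defaults are the validation
study's stated conditions wherever those are published, and declared
realistic choices elsewhere:

| parameter | default | why |
|---|---|---|
| IMU rate | 30 Hz | device export rate |
| reference rate | 100 Hz | camera system rate |
| repetitions | 10 per side | protocol |
| target ROM per task | published reference-system mean (`published_rom_summary()`) | stated world |
| cohort size | 21 | study cohort |
| IMU / reference angle noise SD | 1.0° / 0.5° | the device datasheet gives only a <5 % bound; these are declared values |
| per-repetition amplitude SD | 1.0° | real subjects vary repetition-to-repetition; both systems see the same true motion, so this variability is shared |
| inter-system offset | 2° | arbitrary nonzero constant, removed by the pipeline |
| stream lag | 0.5 s (15 samples) | an unknown constant delay the sync stage must recover |
| stomp artifact | 3 half-sine spikes over ~0.2 s at t = 0.5 s, 20 m/s² on the IMU x-acceleration and 30 mm on the marker channel | the protocol describes "a few spikes visible from both systems"; count/amplitude are declared |
| cycle timing | 2 s rest, 0.5 s smoothstep ramps, 6 s hold, 3 s lead-in | see §4: chosen once so the ROM statistic recovers a noise-free plateau to 0.1° |
| misplacement angle θ | 11.46° | a circumferential shift of 10 % of the thigh diameter equals arc/radius = 2 × 0.1 rad |

Movement is generated single-axis (the tasks are predominantly uniplanar):
the true angle α(t) becomes the quaternion for a rotation about the sensor
z axis; misplacement pre-multiplies every sample by a fixed rotation about
the longitudinal x axis. An optional `coupling_deg` adds a secondary y-axis
rotation proportional to α(t); see §7.

Cohort simulation (`run_task_validation()`) draws each participant's true
reference ROM from the published mean/SD and an inter-system difference from
the published mean difference with SD √(RMSE² − diff²), correlated with the
target so the per-system SDs both match the published table. Draws are
**moment-matched** by default: the sample mean/SD (and the target–difference
correlation) are forced to the nominal values exactly. This is a standard
variance-reduction device; it makes a single simulated cohort reproduce its
nominal summary instead of a random perturbation of it, which is what a
validation-against-published-summary workflow needs. Set
`moment_match = FALSE` for free sampling.

Deterministic seeding: `generate_session()` uses a local RNG seeded from
`rng_seed` and restores the caller's RNG state; cohort drivers derive
per-participant child seeds with one `sample.int()` call from the master
seed, so any participant/arm can be regenerated independently.

## 3. Synchronization

The reference marker channel is down-sampled 100 → 30 Hz with a zero-phase
Blackman-windowed-sinc FIR low-pass (default cutoff 12 Hz = 0.8 × the new
Nyquist, 301 taps) followed by linear interpolation onto the 30 Hz grid;
DC is preserved exactly and content above the new Nyquist is suppressed
below 5 %.

Both artifact channels — the IMU x-acceleration and the down-sampled marker
trajectory — are then filtered with the *same* causal 3rd-order 5 Hz
Butterworth filter (bilinear design, exact −3 dB point at the cutoff).
Filtering both sides is a deliberate deviation from filtering the IMU side
only: a causal filter delays the spikes by its group delay, and applying it
to one channel only would bias the lag estimate by several samples, while
applying it to both cancels the delay exactly. Channels are median-centred
before filtering (the marker channel has a ~1 m DC level whose start-up
transient would otherwise swamp the spikes) and z-normalized before
correlation, since their physical units differ.

The lag is the integer shift maximizing the normalized cross-correlation of
the isolated artifact windows, ties broken toward zero; no sub-sample
refinement is attempted (alignment is at the 30 Hz IMU rate, ≈33 ms
resolution). The inter-system offset is the difference of the rest-phase
means over the first second of the aligned pair — the lead-in rest — and is
subtracted from the IMU trace. On noise-free sessions the injected integer
lag and the offset are recovered exactly; the test suite also verifies ≥95 %
exact recovery at SNR 10 over 100 seeds.

## 4. Segmentation and the working-phase ROM

Repetition boundaries are the local minima between excursion peaks whose
topographic prominence is at least 25 % of the trace's global excursion.
Two numerical guards matter in practice:

* the trace is smoothed with a zero-phase 4 Hz FIR before detection —
  well above the movement band, low enough that white sensor noise cannot
  fake a prominent peak on small-ROM tasks;
* peaks not separated by a valley at least one prominence deep are merged —
  noise-free plateaus are exactly flat and would otherwise register several
  tied peaks per hold.

Each cycle is resampled to 101 points (the gait-cycle convention; the value
is a free parameter). The cycle is amplitude-normalized to [0, 1] and the
**working phase** is the longest run above τ = 0.9 — the plateau on which
the subject holds the near-maximal excursion. The ROM statistic is

> ROM = mean(raw angle over the working phase) − rest baseline,

i.e. how well the excursion is *maintained*, not the peak excursion;
max − min is exposed only as a `mode = "max_min"` diagnostic, and a
`"final_position"` mode (last working-phase sample minus baseline) is
provided for comparison. The rest baseline is the mean of the pre-task rest
window, shared with the offset-estimation stage. Traces whose dominant
excursion is negative relative to the starting rest level (bending to the
opposite side) are negated before segmentation so ROM is always positive.

Because the working phase includes the ramp samples that exceed 0.9 of the
plateau, the statistic has a small negative bias relative to the plateau:
about 3.5 % of the normalized amplitude over the ~20 % of each ramp that
lies in the band. The default timing (0.5 s ramps, 6 s hold) keeps that bias
below 0.1° even for the largest task ROM (~71°); this is why the generator's
timing defaults are what they are, fixed once and not tuned afterwards.

Bilateral tasks are pooled to 20 repetitions per participant after a paired
t-test on the per-repetition ROMs of the two sides (the protocol pools after
finding "no significant difference" but names no test; the paired t-test is
our declared choice). A significant pre-test produces a warning, never a
silent drop — with matched sides this fires at roughly the nominal 5 % rate.

## 5. The agreement suite

All statistics operate on per-participant mean ROMs (one pair per
participant), not on individual repetitions:

* **Accuracy** = (1 − |ROM_IMU − ROM_ref| / ROM_ref) × 100. The formula is
  scale-invariant and can go negative when the difference exceeds the
  reference ROM.
* **RMSE** = √(Σ(ŷᵢ − yᵢ)² / n), population (1/n) form.
* **Pearson r** with the two-sided t-transform p-value (`stats::cor.test`).
* **Lin's CCC** = 2s_xy / (s_x² + s_y² + (x̄ − ȳ)²) with biased (1/n)
  moments — the original estimator's convention, stated because cohort n is
  small. |CCC| ≤ |PCC| holds identically (CCC = r·C_b, C_b ∈ (0, 1]).
* **Bland–Altman**: bias = mean difference, limits of agreement =
  bias ± 1.96 SD(differences); the report carries the (pair-mean,
  difference) scatter payload.
* **SEM / MCID**: SEM = SD·√(1 − R) with MCID = 1 SEM. Two conventions had
  to be fixed because the published formula leaves them open: the SD is the
  pooled between-participant SD √((SD²_IMU + SD²_ref)/2), and the
  reliability R — nominally the variance ratio of the two systems — is
  clamped to min(ratio, 1/ratio) so that √(1 − R) stays real regardless of
  which system is more variable. Note the shipped published summary's MCID
  column is *not* derivable from its own SD columns under this (or any
  simple) reading of the formula, so the clamped pooled rule is a documented
  package convention, not a reproduction.
* **Anderson–Darling** composite-normality test with Stephens'
  small-sample correction and the standard piecewise p-value approximation;
  the test suite verifies its empirical size (3–7 % at α = 0.05, n = 200)
  and power against uniform data.

No multiple-testing correction is applied across tasks, matching the
original analysis.

## 6. Misplacement sensitivity

`run_misplacement_arm()` runs matched sessions (same seed, same noise
realization) with the sensor frame rotated by −θ (medial), 0, or +θ
(lateral) and compares displaced against correct per-participant ROMs:
RMSE and mean shift per arm. Under the pure axial-rotation model the
extracted in-plane ROM is atan2(cos θ · sin A, cos A) ≈ A·cos θ: even in
±θ and non-increasing in |θ| on [0°, 60°] — both property-tested.

The published sensitivity table, measured on real subjects, is *asymmetric*
(medial displacement raised hip-extension ROM). A pure axial rotation
cannot produce that; plausibly it reflects out-of-plane compensatory motion
leaking into the measured plane. The generator therefore offers an opt-in
`coupling_deg` term — secondary rotation about the frontal axis
proportional to the main excursion — which breaks the medial/lateral
symmetry; the symmetric model remains the default because the physical
mechanism is not identifiable from summary data.

## 7. What a green test does and does not establish

The generator emulates: two rates and clocks, Euler-convention differences,
constant offset, integer lag, per-system noise, shared repetition
variability, stomp artifacts, axial misplacement, cohort heterogeneity
matched to the published second moments. It does **not** emulate soft-tissue
artifact, marker occlusion/relabeling, sensor-fusion drift, non-stationary
lag, fatigue trends across repetitions, or pathological movement patterns.
Green pipeline tests therefore establish internal correctness of the
algorithms and faithful recovery of the stated world — not clinical
validity on new human data. The cohort-level correlation structure is
matched only to second moments; printed PCC/CCC values from the real cohort
are not mutually consistent with its printed means/SDs/RMSEs under any
bivariate-normal model, so they are reproduced only approximately by
construction.

## 8. Degenerate inputs and numerical edges

* Quaternions are validated to unit norm (1e−6 working tolerance, 1e−3 on
  CSV re-import); q and −q are equivalent everywhere.
* Gimbal lock (|middle Euler angle| > 89.99°) is flagged; trace extraction
  carries the last well-defined angle forward. The in-scope tasks stay far
  from ±90° in the middle angle.
* Constant traces: segmentation, working-phase isolation, cross-correlation
  and the normality test all reject degenerate (zero-excursion/variance)
  inputs with explicit errors rather than returning artifacts.
* The lag search is bounded (±2 s default) and requires ≥3 overlapping
  samples; correlation ties resolve toward zero lag.
* CSV import reports the offending data row for non-finite values,
  non-monotone time stamps, and non-unit quaternions.
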