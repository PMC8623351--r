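---
title: "Automated tSCS calibration: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated tSCS calibration: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscscalib)
```

## The calibration problem

Transcutaneous spinal cord stimulation (tSCS) delivers current through
paraspinal surface electrodes to recruit afferent fibers in the lumbosacral
posterior roots. Its therapeutic use — notably sub-threshold stimulation for
spasticity control — depends on two per-patient settings: *which* of several
rostrocaudally arranged electrode positions overlies the target roots, and
*at what amplitude* posterior root-muscle (PRM) reflexes first appear there.
Experts settle both by inspecting evoked EMG from lower-limb muscles while
stepping through electrode sites and amplitudes. `tscscalib` automates that
procedure: it consumes the raw multi-muscle EMG sweeps recorded during a
paired-pulse, multi-electrode, amplitude-ramp protocol and returns a rated
response matrix plus a therapy recommendation.

The discriminating physiology is post-activation depression: a PRM reflex
evoked 50 ms after an identical first stimulus is strongly attenuated,
whereas a direct motor response (M-wave, from efferent-axon stimulation)
is not. Each double stimulus therefore probes both response presence and
response identity.

## Protocol model

A calibration session steps through electrode positions $n$ (caudal to
rostral, default 1–4) and stimulation amplitudes $I = 5, 10, \dots, 75$ mA,
delivering three double stimuli (inter-pulse interval 50 ms) per
combination. EMG is sampled at 1 kHz from left/right quadriceps (LQ, RQ)
and triceps surae (LTS, RTS); each limb's two channels share one wireless
sensor, hence one clock. Each sweep holds roughly 600 samples beginning
shortly before the first stimulus. All protocol and analysis parameters
live in one configuration object:

```{r}
cfg <- tscs_protocol()
cfg
```

## Pipeline stages

### Synchronization

Wireless sensors provide no hardware trigger, so the first stimulation
artifact must be located in the EMG itself. The sweep is double
differentiated with a scaled discrete Laplacian, $4(x_{k-1} - 2x_k +
x_{k+1})$, which amplifies the near-discontinuous artifact against smooth
EMG. A sample is an artifact candidate when four conditions hold: the
absolute double-differentiated signal exceeds three standard deviations of
its own stimulus-free tail (samples 300–600) both there (C1) and exactly one
inter-pulse interval later (C2, the second pulse's artifact), does **not**
exceed it two intervals later (C3, rejecting periodic false hits), and the
median-free raw signal changes sign at the sample (C4, the zero crossing of
a charge-balanced biphasic pulse). The earliest candidate within samples
10–200 becomes $t = 0$, and the sweep is cropped to $-30$ to $300$ ms (331
samples at 1 kHz). Detection runs on the quadriceps channels only, where
artifacts are largest; if both channels fire, the earlier onset wins, with
ties to LQ — the tie rule is a package choice, as is using the sample
(denominator $n-1$) standard deviation.

Sweeps in which C1 never holds are *baseline* (no detectable stimulus,
typical below ~20 mA and at the most rostral electrode); their first 331
samples are kept for noise profiling. Sweeps with super-threshold
deflections but no full candidate are discarded, as are sweeps whose onset
sits too close to a recording edge for the full crop window — padding is
deliberately not attempted, because every downstream measurement window up
to 300 ms must contain real data.

Indexing note: the package uses R's native 1-based sample indexing
throughout, which coincides with the protocol's sample numbering
$\tilde t = 1..600$; all windows are specified in milliseconds and
converted via the sampling rate.

### Pre-filtering

Each retained sweep channel is median-centered, blanked to zero on the
closed intervals $[-2, 2]$ and $[48, 52]$ ms around the two artifacts,
band-stop filtered (second-order Butterworth, 43–47 Hz) against powerline
interference, and low-pass filtered (first-order Butterworth, 300 Hz). Both
filters are applied forward and backward, so the cascade has zero net
phase: response latencies in the 10–45 ms windows are not shifted (the
effective magnitude response is squared). The forward–backward pass uses
odd-reflection edge padding of three filter orders so startup transients
decay outside the sweep. After filtering, the blanked intervals are forced
back to zero so artifact ringing cannot leak into measurement windows. The
43–47 Hz band edges are kept as specified by the source procedure even
though European mains is 50 Hz; both edges are configurable
(`bandstop_hz`).

A narrow 4 Hz-wide notch settles over roughly 250 ms, a substantial part of
a 331 ms sweep; complete suppression of a pure in-band tone is therefore
only observed on longer windows, and the test suite checks the 20-fold
(< 0.05) attenuation contract on a 1 s window.

### Noise profile, similarity gate, averaging

The muscle-specific base noise level $\bar{\mathrm{emg}}_i$ is the standard
deviation of all filtered samples with $100 \le t \le 300$ ms pooled over
every aligned and baseline sweep of the session. Baseline sweeps have no
$t = 0$; the same positional window (samples 131–331 of the extract) is
used, which is a package decision. Discarded sweeps are excluded.
Movement-corrupted but alignable sweeps *do* enter the pool — an inherent
property of the procedure, mitigated by pooling across the whole session.

Repetitions of one (muscle, $n$, $I$) must replicate before they are
trusted: the RMSE between each pair over 5–45 ms plus 55–95 ms (excluding
both blanks) must stay below 16 times the muscle's base noise level, an
empirically chosen factor exposed as `similarity_factor`. The largest
mutually similar subset is averaged if it has at least two members,
otherwise the cell is *invalid*. With three repetitions at most four
subsets exist; equal-size ties resolve to the lowest repetition indices for
determinism. Kept repetitions are cropped to $-1$ to 200 ms (202 samples)
and averaged pointwise. A cell whose repetitions are all baseline is rated
"no response" rather than invalid — *invalid* is reserved for failed
similarity, so that low-amplitude baseline cells do not inflate the
session's invalid-cell ratio.

### Rating

From each averaged response, peak-to-peak amplitudes are measured 10–45 ms
after each stimulus ($\mathrm{amp}_1$; $\mathrm{amp}_2$ in 60–95 ms), and
the suppression ratio is

$$\mathrm{sup} = \mathrm{clip}\!\left(1 -
  \frac{\mathrm{amp}_2}{\mathrm{amp}_1},\ 0,\ 1\right),$$

1 meaning complete post-activation depression (reflex-like), 0 equal-sized
responses (M-wave-like). With $\mathrm{amp}_1 = 0$ no suppression is
assessable and the ratio is defined as 0. Each cell is then labeled:

| label | color | condition |
|---|---|---|
| no response | gray | $\mathrm{amp}_1 \le 6\,\bar{\mathrm{emg}}_i$ **or** $\mathrm{amp}_1 \le 50\ \mu V$ |
| reflex | green | both gates exceeded **and** $\mathrm{sup} > 0.60$ |
| presumed M-wave | yellow | both gates exceeded **and** $\mathrm{sup} \le 0.60$ |
| invalid | red | no similar repetitions |

All inequalities are strict exactly as written; the rules partition the
feature space. The two amplitude gates, the factor 6, and the 60%
suppression threshold are configurable (`min_amp_uV`, `noise_sd_factor`,
`suppression_threshold`). Configuration validation refuses measurement
windows that overlap the blanked intervals, which would otherwise silently
measure forced zeros.

### Recommendation

Two independent methods derive therapy settings from the rating matrix.
The *ranking approach* keeps (electrode, amplitude) pairs with reflexes in
at least two muscles and sorts lexicographically: more green labels first,
then smaller $I - I'(n)$ (with $I'(n)$ the electrode's amplitude threshold,
the lowest amplitude with any green at $n$), then lower $I$; residual ties
go to the more caudal electrode (a determinism choice). The *cost function
approach* scores every pair with

$$J(n, I) = \frac{1}{4}\sum_{i}
  \frac{\mathrm{amp}_{1,i}(n, I)}{\overline{\mathrm{amp}}_{1,i}}\,
  \mathrm{sup}_i(n, I),$$

normalizing each muscle by its maximal first-response amplitude anywhere in
the session; invalid cells contribute zero. The cost method selects the
electrode of the globally maximal $J$. Both methods set the therapy
amplitude to 90% of the selected electrode's threshold, floored to the
amplitude grid (so $0.9 \times 40 = 36 \to 35$ mA on a 5 mA grid), which
also guarantees sub-threshold stimulation; flooring can be disabled
(`rounding = "none"`). $I'$ is defined per electrode (first green in any
muscle), and when no pair meets the minimal requirement the recommendation
is explicitly absent with a reason — both choices where the procedure's
description leaves room. When the two methods disagree (observed rarely in
practice), both results are reported side by side and an agreement flag is
set; the package does not arbitrate.

## The simulator

`tscs_simulate_session()` generates raw sessions with known ground truth so
the whole pipeline can be validated end to end. Per (muscle, electrode) it
draws a sigmoid recruitment curve (midpoint = recruitment threshold, slope
1.5 mA, saturation 400 µV), a response type (reflex: suppression 0.85;
M-wave: 0.05; none), and a physiological latency (12 ms quadriceps, 20 ms
triceps surae). Sweeps are Gaussian noise (SD 4 µV) plus a small 45 Hz
component (3 µV, exercising the notch), two 2-sample biphasic artifact
spikes (±1500 µV) at an onset jittered uniformly over samples 31–81, and
the two responses, the second scaled by $1 - \mathrm{sup}$. The spike pair
genuinely exercises C1–C4 including the sign-change test; because the
Laplacian spreads the spike over adjacent samples, the detector may fire
one sample early depending on the local noise sign — a property of the
method, harmless downstream, and visible in the tests as a ±1 sample
tolerance on simulated onsets.

Defaults constitute a high signal-to-noise regime (artifact ≫ 20× noise
SD, response saturation 8× the 50 µV gate) in which label recovery is
expected to be near-perfect; the test suite requires ≥ 95% cell-label
accuracy, exact recovery of every electrode threshold, and the correct best
electrode across 20 seeds, on the full 4-position × 15-amplitude grid. The
default truth recruits all four muscles at electrode 2 (thresholds 40 mA
triceps surae, 45 mA quadriceps), triceps surae only at electrode 1,
quadriceps reflexes plus triceps surae M-waves at electrode 3, and nothing
at electrode 4 — a typical caudal-to-rostral pattern with electrode 2
overlying the target roots.

Optional features exercise the failure branches: per-electrode artifact
scaling near zero produces baseline/discarded sweeps, and
`corrupt_rate > 0` injects stimulus-locked low-frequency movement bursts
confined to the first 90 ms after the stimulus. The confinement mirrors
stimulus-evoked movement and keeps the 100–300 ms noise window clean; a
whole-sweep disturbance would instead inflate the pooled noise level and
(correctly, per the method's definition) loosen the similarity gate.

What the simulator does **not** model: volume conduction and electrode
geometry, motoneuron-pool statistics, amplitude-dependent artifact shape,
non-Gaussian or non-stationary background EMG (e.g. dyskinesia), and
latency jitter between repetitions. Passing its recovery tests therefore
demonstrates the correctness of the signal-processing and decision logic
under the stated assumptions, not clinical performance on real recordings.

## Numerical choices and degenerate inputs

* Millisecond windows are converted to sample indices by rounding the
  boundaries to the nearest sample; all intervals are closed.
* The Laplacian is undefined at the first and last sample; both are set to
  zero. Candidates are restricted to samples 10–200, so the edges never
  matter.
* C2/C3 offsets are the inter-pulse interval (and twice it) in samples;
  at sampling rates other than 1 kHz they scale with the rate.
* A zero sample counts as a sign change against any nonzero neighbor in
  C4; exact zero ties are vanishingly rare in µV data.
* Sweeps shorter than the dispersion tail window raise an error rather
  than silently estimating from too few samples.
* `sup` with $\mathrm{amp}_1 = 0$ is 0 (no assessable suppression), so
  such cells can never be rated reflex.
* Therapy flooring below the lowest grid value yields `NA` with the raw
  value retained — it cannot occur on the default grid, where thresholds
  are at least 5 mA.

## Problem sizes used in validation

The test suite runs the full default grid (4 positions × 15 amplitudes × 3
repetitions × 4 muscles, 600-sample sweeps) for the 20-seed end-to-end
recovery study, and smaller 2-position grids for I/O, report, and
corruption tests; these sizes were chosen to exercise every branch at
desk scale. `scripts/acceptance.R` reruns the complete pipeline on one
full-grid session per invocation.
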