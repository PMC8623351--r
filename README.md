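# tscscalib

Automated calibration of transcutaneous spinal cord stimulation (tSCS)
from evoked EMG responses.

## The problem

Therapeutic tSCS — e.g. sub-threshold stimulation for spasticity control —
requires choosing, per patient, the paraspinal electrode position that
overlies the lumbosacral posterior roots and a stimulation amplitude just
below the reflex threshold there. Clinically this is settled by an expert
who inspects electromyographic (EMG) responses of lower-limb muscles while
stepping through electrode sites and amplitudes. `tscscalib` automates
that analysis for a paired-pulse, multi-electrode, amplitude-ramp
calibration protocol: four electrode positions (caudal→rostral), double
stimuli (50 ms inter-pulse interval) repeated three times per amplitude on
a 5–75 mA grid, EMG at 1 kHz from bilateral quadriceps (LQ, RQ) and
triceps surae (LTS, RTS).

The discriminating physiology is **post-activation depression**: a
posterior root-muscle (PRM) reflex evoked 50 ms after an identical first
stimulus is strongly suppressed, while a direct motor response (M-wave) is
not. With peak-to-peak amplitudes `amp1`, `amp2` measured 10–45 ms after
each stimulus, the suppression ratio

    sup = clip(1 − amp2/amp1, 0, 1)

separates reflexes (`sup > 0.60`) from presumed M-waves. Each (muscle,
electrode `n`, amplitude `I`) cell is rated **gray** (no response: `amp1 ≤
6·noise` or `≤ 50 µV`), **green** (reflex), **yellow** (M-wave), or
**red** (invalid: repetitions did not replicate). Two independent methods
then recommend therapy settings:

* **ranking approach** — lexicographic sort of pairs with ≥ 2 green
  muscles: more greens, then smaller `I − I′(n)` (distance to the
  electrode's first-green threshold `I′`), then lower `I`;
* **cost function approach** — `J(n,I) = mean_i( amp1_i/max_amp1_i ·
  sup_i )`, electrode of the globally maximal `J`.

Both set the therapy amplitude to 90 % of the selected electrode's `I′`,
floored to the amplitude grid (40 mA → 35 mA).

The pipeline stages in between — stimulation-artifact detection by double
differentiation (a scaled discrete Laplacian with four acceptance
conditions), re-timing to `t = 0`, artifact blanking, zero-phase
Butterworth band-stop (43–47 Hz) and low-pass (300 Hz) filtering,
muscle-specific noise profiling, and an RMSE similarity gate over
repetitions — are described in
`vignettes/tscs-calibration-methods.Rmd`.

## Worked example

Sessions are tibbles (one row per sweep channel, samples nested); a seeded
simulator with known ground truth stands in for a recording:

```r
library(tscscalib)

cfg  <- tscs_protocol()                                 # default protocol
sess <- tscs_simulate_session(tscs_sim_truth(cfg), cfg, seed = 42)
cal  <- tscs_calibrate(sess, cfg)
cal
#> <tscs_calibration>
#>   240 rated cells (4 muscles x 60 electrode/amplitude pairs)
#>   labels: m_wave=12, no_response=176, reflex=52
#>   invalid cell ratio: 0.0%
#> <tscs_recommendation>
#>   ranking approach: electrode 2, threshold 40 mA, therapy 35 mA
#>   cost approach:    electrode 2, threshold 40 mA, therapy 35 mA (J = 0.846)
#>   methods agree on electrode: TRUE
```

240 cells = 4 muscles × 4 electrodes × 15 amplitudes. The simulated truth
recruits all four muscles at electrode 2 with the first reflex at 40 mA;
the pipeline recovers that electrode, the 40 mA threshold, and recommends
90 % of it floored to the grid: 35 mA. Results are ordinary tibbles:

```r
tidy(cal$recommendation)
#> # A tibble: 2 × 5
#>   method  electrode_position threshold_mA therapy_mA      J
#>   <chr>                <int>        <dbl>      <dbl>  <dbl>
#> 1 ranking                  2           40         35 NA
#> 2 cost                     2           40         35  0.846

head(cal$recommendation$rank_table, 5)
#> # A tibble: 5 × 5
#>    rank electrode_position amplitude_mA green_count delta_threshold_mA
#>   <int>              <int>        <dbl>       <int>              <dbl>
#> 1     1                  2           45           4                  5
#> 2     2                  2           50           4                 10
#> 3     3                  2           55           4                 15
#> 4     4                  2           60           4                 20
#> 5     5                  2           65           4                 25
```

`autoplot(cal$rating)` draws the color-coded rating matrix;
`plot_responses(cal$responses, 2, cfg)` overlays the averaged evoked
responses at electrode 2. `write_tscs_calibration(cal, "report/")` emits a
schema-validated JSON report plus a CSV rating table, and
`tscs_report_text("report/report.json")` renders them as text tables.
Recorded sessions are read from long-format CSV with
`read_tscs_session("session.csv", cfg)`; thin command-line wrappers live
in `inst/cli/` (`calibrate.R`, `simulate.R`, `report.R`).

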