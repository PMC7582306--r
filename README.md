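# mwlfusion

Multi-measure mental-workload (MWL) analysis for one-to-many UAV
supervision sessions.

## The problem

A single operator supervising a growing fleet of unmanned aircraft
experiences rising mental workload. Questionnaires can only sample workload
between mission phases; continuous estimation needs physiological proxies,
cross-validated against an objective task-performance measure and — because
every physiological sensor has its own failure modes — fused across
sensors. `mwlfusion` implements that measurement chain end to end for
sessions with the canonical timeline *5 min rest / three 10-min mission
phases of increasing difficulty / 5 min rest*, together with a
deterministic synthetic-session generator so the whole pipeline is testable
without recorded data. It is aimed at human-factors / neuroergonomics
researchers prototyping workload instrumentation.

## The measures

* **EEG workload index** (per 5-s window, after a zero-phase 0.5–30 Hz
  bandpass, linear detrending, Welch PSD and band integration):

  index = mean(θ_F4, θ_C4) / mean(α_O1, α_O2),

  with θ the 4–7 Hz and α the 8–12 Hz band power — frontal/central theta
  rises and occipital alpha falls with workload. Values beyond 3 SD from
  the mean are replaced by the non-outlier mean, then a 60-s moving
  average exposes the trends.
* **Visual entropy**: gaze samples (binocular averaging with monocular
  fallback) are assigned to screen regions of interest, collapsed into
  dwell-to-dwell transitions, and the conditional entropy
  H = −Σᵢ p(Xᵢ) Σⱼ p(Yᵢⱼ|Xᵢ) log₂ p(Yᵢⱼ|Xᵢ) (bits) is computed in sliding
  60-s windows. Disordered scanning (high H) accompanies high workload.
* **Secondary-task index**: a weighted count of pending vehicle-maintenance
  tasks scored from flight logs (navigation accuracy, comm strength, fuel
  margin, autopilot hold, team assignment, sensors), up to 6 points per
  vehicle, summed over the fleet with last-observation-carried-forward.
* **Controller inputs**: click counts in 2-min bins.
* **Fusion + statistics**: min-max-normalized measures fused as convex
  weighted sums (50/50, 70/30, 30/70), phase-level one-way ANOVA with
  Tukey HSD, and cross-participant Pearson correlation summaries of all
  six features.

## Worked example

```r
library(mwlfusion)

cfg <- session_config(seed = 42, levels = c(0.05, 0.2, 0.55, 0.9, 0.1))
bundle <- simulate_session(cfg)
a <- analyze_session(bundle)

subset(a$phase_summary, measure == "eeg_index")
#>   participant   measure    phase      mean          z
#> 1          P1 eeg_index  PreRest 0.2562336 -0.5888590
#> 2          P1 eeg_index   Phase1 0.2284807 -0.8205103
#> 3          P1 eeg_index   Phase2 0.3873825  0.5058294
#> 4          P1 eeg_index   Phase3 0.5098269  1.5278630
#> 5          P1 eeg_index PostRest 0.2519849 -0.6243230

head(a$correlations$by_participant, 3)
#>                       pair participant        cc
#> 1 eeg_index~visual_entropy          P1 0.5914148
#> 2     eeg_index~task_index          P1 0.4949070
#> 3  eeg_index~control_input          P1 0.7125359
```

The per-phase mean EEG index climbs across the three mission phases
(0.23 → 0.39 → 0.51) and relaxes after the mission — the latent workload
profile (`levels`) recovered from the synthetic EEG alone. The correlation table lists every pair of the
six features; in multi-participant studies (`run_study()`) the fused
physiological measure typically correlates with the task index at least as
strongly as either physiological measure alone.

The same pipeline runs over CSV files:

```r
run_simulate(cfg, out_dir = "session01")   # eeg.csv, gaze.csv, uav_logs.csv, ...
run_analyze("session01")                   # eeg_index.csv, anova.csv, ...
run_report("session01")                    # report.txt
```

or from a shell via `Rscript inst/cli/mwl.R {simulate|analyze|report} ...`.

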