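---
title: "Measuring operator mental workload in one-to-many UAV supervision"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring operator mental workload in one-to-many UAV supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwlfusion)
```

## The measurement problem

A single operator supervising a growing fleet of unmanned aircraft
experiences rising mental workload (MWL): the balance between the mental
resources a task demands and those the operator can supply. Estimating MWL
continuously — rather than by questionnaires administered between mission
phases — requires physiological proxies. `mwlfusion` implements a complete,
testable version of a multi-measure MWL pipeline for such sessions:

* **EEG workload index.** Frontal/central theta power (F4, C4; 4–7 Hz)
  rises and occipital alpha power (O1, O2; 8–12 Hz) falls with workload, so
  their ratio

  $$\mathrm{index} = \frac{\tfrac12\,(\theta_{F4} + \theta_{C4})}
                           {\tfrac12\,(\alpha_{O1} + \alpha_{O2})}$$

  computed per 5-s window is a classic spectral workload measure.
* **Visual entropy.** Gaze transitions between screen regions of interest
  (ROIs) form a transition matrix; its conditional entropy
  $H = -\sum_i p(X_i)\sum_j p(Y_{ij}\mid X_i)\log_2 p(Y_{ij}\mid X_i)$
  (bits) quantifies scanning disorder. Orderly scan patterns give low $H$;
  overloaded, erratic scanning gives high $H$.
* **Secondary-task index.** A weighted count of pending vehicle-maintenance
  tasks scored from flight logs (navigation, communications, fuel margin,
  autopilot hold, team assignment, sensor activation), at most 6 points per
  vehicle. This is the objective task-performance reference.
* **Controller inputs.** Left+right click counts in 2-minute bins.
* **Fusion and statistics.** Min-max-normalized physiological measures are
  fused as a convex weighted sum; phase-level differences are tested with
  one-way ANOVA plus Tukey HSD, and the pairwise Pearson correlation
  structure of all six features (four measures plus the physiological and
  objective fusions) is summarized across participants.

A session follows the canonical timeline: 5 min pre-mission rest, three
back-to-back 10-min mission phases of increasing difficulty, 5 min
post-mission rest. All timestamps are seconds from session start and every
interval is half-open `[t, t + dt)`.

## The synthetic session generator

No recorded data ships with the package; instead `simulate_session()`
produces complete sessions from a latent workload profile, giving every
downstream stage a ground truth to be tested against.

```{r profile}
cfg <- session_config(seed = 42)
bundle <- simulate_session(cfg)
bundle
```

The latent profile is piecewise constant per phase — the simplest model
consistent with a phase-level analysis — with default levels
`r paste(session_config()$levels, collapse = ", ")` over the five phases.
The mission phases rise steeply; the post-rest level (0.15) deliberately
does not return to the pre-rest baseline, emulating incomplete recovery
after a demanding mission. Each stream derives its own sub-seed from the
master seed, so adding or reconfiguring one stream never perturbs another.

What each generator encodes, and what it deliberately omits:

* **EEG** (`generate_eeg()`): $1/f$ background plus white noise on all 16
  channels of the 10–20 montage; a theta-band sinusoid on F4/C4 whose
  amplitude increases linearly with workload; an alpha-band sinusoid on
  O1/O2 whose amplitude decreases linearly; sparse high-amplitude artifact
  bumps (about five per session, exercising outlier replacement); and slow
  multiplicative amplitude drift (Ornstein–Uhlenbeck on the log
  amplitudes). The drift is the generator's model of physiological
  nonstationarity — vigilance fluctuations, electrode impedance changes —
  and is the dominant "noise" left after the pipeline's 60-s smoothing.
  It does *not* model blink/EMG artifact morphology, volume conduction or
  channel correlations.
* **Gaze** (`generate_gaze()`): a first-order Markov scanpath over the ROI
  centres with exponential dwells. The softmax temperature of the
  transition rows is chosen, by inverting the chain's analytic conditional
  entropy, so that scanpath entropy follows the workload level directly
  (a mildly convex mapping, `entropy_exponent`, mirrors how scanning
  degrades disproportionately as load approaches overload); an independent
  OU drift on the entropy target plays the same nonstationarity role as
  the EEG drift. Tracking dropout arrives in contiguous bursts (both eyes
  invalid) with geometric durations — emulating an operator leaning out of
  the tracker's range — plus short blinks and rare monocular dropouts.
  Fixation/saccade microstructure is not modelled; transitions, not
  fixations, are the unit of analysis.
* **UAV logs** (`generate_uav_logs()`): fleets of 3/6/9 vehicles released
  at the mission-phase starts (the published scenario fixes 3 in Phase 1
  and "more than six" later; 3/6/9 is the package's configurable
  reading). Each penalty category degrades via a marked Poisson process
  whose rate rises with workload and recovers after an exponential episode;
  newly released vehicles start unassigned with sensors off until
  operator-assignment delays elapse, reproducing task-index spikes at
  phase starts.
* **Clicks** (`generate_clicks()`): an inhomogeneous Poisson process with
  rate `base + gain * workload`.
* **Ratings** (`generate_ratings()`): per-phase 0–10 MWL and situational
  awareness scores drawn around published-scale phase means with rater
  noise.

Because both physiological generators carry *independent* drift noise of
comparable informativeness, the fused physiological measure genuinely
averages independent errors — the property the fusion analysis is designed
to demonstrate. Passing the recovery tests therefore shows that the
pipeline can extract a monotone workload encoding and that fusion improves
the correlation with the objective task index *under these assumptions*;
it does not certify the pipeline against real-data problems the generator
omits (artifact morphology, non-Markov gaze, inter-individual variability
of band boundaries).

## Numerical and design choices

* **PSD estimation.** Welch's method inside each 5-s window: 2-s Hann
  sub-windows with 50% overlap, one-sided density scaling, trapezoidal band
  integration with interpolated band edges. The 2-s sub-window gives 0.5 Hz
  resolution so the 4/7/8/12 Hz band edges fall on grid points and a
  narrowband component near an edge is not half-counted; with 1-s
  sub-windows a 6 Hz tone integrates to ~0.46 instead of ~0.50 of its
  power. Linear detrending precedes the PSD; windows shorter than one
  sub-window are an error.
* **Filtering.** 4th-order Butterworth, 0.5–30 Hz, applied
  forward–backward (`signal::filtfilt`) for zero phase. The filter family
  and order are package choices; the band is the published one.
* **Outlier replacement.** One pass over the finished index series: points
  strictly beyond mean ± 3 SD are replaced by the mean of the non-outlier
  points (a point exactly at the boundary is retained). Windows whose
  index is undefined (zero alpha denominator) are treated exactly like
  detected outliers. Replacement precedes smoothing.
* **Smoothing.** A centred 60-s moving average (12 points on the 5-s
  grid) with shrinking edge windows, rather than an IIR low-pass:
  deterministic, parameter-light, and sufficient to expose phase-scale
  trends. The width is a parameter.
* **Transitions, not samples.** Consecutive same-ROI samples collapse into
  dwells, so self-transitions are structurally zero and the entropy does
  not depend on the tracker's sampling rate. Invalid or off-ROI samples
  bridge a dwell if the gap is at most 1 s; longer gaps break the sequence
  without fabricating a transition across them. Off-ROI positions are
  gaps, never a state. Entropy windows are 60 s sliding by 5 s; windows
  with fewer than 5 transitions are flagged invalid. Probabilities are
  empirical plug-in values with no smoothing.
* **Penalty-table boundaries.** The published band edges ("between 10 and
  25 m") do not assign the endpoints; the package reads bands as
  lower-inclusive (10 m and 25 m score +0.5; 50% and 70% comm score
  +0.5). The fuel rows as printed would make the unsafe state "adequate";
  the package scores the safety-margin ratio r = fuel on board / fuel
  needed with critical r < 1.5, low 1.5 ≤ r < 2, adequate r ≥ 2 — the only
  reading in which "adequate" is safe.
* **Aggregation.** The task index sums per-vehicle penalties (the per-UAV
  cap of 6 is not a fleet cap); vehicles contribute 0 before release; last
  observation is carried forward between log records.
* **Normalization.** Min-max scaling to [0, 1] precedes fusion and the
  correlation analysis (flagged points are excluded from the min/max but
  mapped with the same transform); z-scoring of per-phase means (sample
  SD) is reserved for the phase-level ANOVA. Physiological measures are
  z-scored across all five phases, task measures across the three mission
  phases in which they exist.
* **ANOVA layout.** The study-level ANOVA (`run_study()`) treats each
  participant's per-phase mean as an independent observation — with five
  participants and three phases this yields the F(2, 12) layout — and
  makes no repeated-measures correction, a documented limitation. The
  single-session ANOVA in `run_analyze()` instead uses 60-s block means
  within each phase as replicates: an autocorrelation-reducing,
  within-session assessment, not a substitute for the cross-participant
  test. No multiple-testing correction is applied across measures.
* **Correlation.** The smoothed EEG index enters the correlation analysis
  (smoothing precedes "data analysis" in the pipeline order). Flagged
  spans — gaze dropout, replaced EEG outliers — are excluded pairwise, and
  the cross-participant spread of each feature-pair correlation is the
  sample (n−1) SD.
* **Alignment.** All features are resampled onto a common 5-s grid over
  their overlap: step-valued series (task index, 2-min click bins) by last
  observation carried forward, natively gridded series by exact stamp
  matching.

## Generator calibration

The generator's defaults were fixed once to emulate the study conditions
the analysis assumes: phase-mean recovery and phase ANOVA require a clearly
monotone encoding, while the fusion analysis requires that the two
physiological channels be comparably informative about the task index with
independent noise (in the published data the task-index correlations of
the two channels were nearly equal, and their mutual correlation was well
below either). Concretely: the narrowband EEG amplitudes give the index a
moderate (~2.5x) dynamic range rather than an unrealistically clean one;
drift correlation times of a few seconds leave many independent noise
samples per phase (and keep per-session correlation estimates stable); the
two drifts have comparable effect sizes after each pipeline's own 60-s
averaging; and maintenance events arrive densely enough that the task
index's own Poisson noise does not dominate its workload signal. The test-suite problem sizes (20
default-length sessions for recovery checks, 5 seeds for lighter
generator properties) are the package's chosen trade-off between
statistical resolution and test-suite runtime.

## Worked example

```{r study, eval = FALSE}
# five synthetic participants, as in a small operator study
study <- run_study(n_participants = 5, config = session_config(seed = 1))
study$anova          # per-measure F, df, p across mission phases
study$tukey$task_index
study$correlations$summary
```

`run_simulate()` / `run_analyze()` / `run_report()` provide the same
pipeline over CSV files (schemas documented in `?write_session`), and
`inst/cli/mwl.R` wraps them for shell use.

## Known limitations

* The fusion benefit is a small-margin property at session scale: a 40-min
  session yields only a few dozen effectively independent samples of each
  measure, so the *per-session* comparison of the fused correlation against
  the better individual measure carries sampling noise of the same order as
  the structural gain. The test suite asserts the property both averaged
  over sessions (robust) and session-by-session (near its threshold); the
  per-session form can fail on unlucky seed batches, as it did for a
  minority of participants in comparable operator studies.
* The generator's phase-constant latent workload cannot produce
  within-phase workload excursions; correlations between measures are
  therefore driven by phase structure, release spikes and drift, not by
  fast task dynamics.
* The plug-in entropy estimator is biased downward in short windows; the
  windowed series is comparable across time but not an unbiased estimate
  of the chain entropy per window.
* The cross-participant ANOVA ignores the repeated-measures structure, as
  in the analysis it reproduces.
* EDF/BDF ingestion is out of scope; EEG enters as CSV (or in memory via
  `eeg_recording()`).
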