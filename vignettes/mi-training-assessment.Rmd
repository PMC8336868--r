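---
title: "Assessing short-term MI-BCI training: Mu suppression and ERP brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing short-term MI-BCI training: Mu suppression and ERP brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3.5)
library(miconn)
library(dplyr)
```

## The problem

Motor-imagery (MI) brain-computer-interface training — imagining left- or
right-hand movement on cue, sometimes with neurofeedback such as a virtual
robotic arm — is used in neurorehabilitation. Whether a *single short
session* (about an hour) measurably changes brain dynamics is hard to read
from the classical event-related-desynchronization (ERD) measure alone,
because its trial-to-trial variance is large. `miconn` implements a
two-branch EEG assessment for exactly this setting:

1. **Mu-suppression branch.** ERD is quantified per trial as the
   Mu-suppression score
   $$\mathrm{MuSC} = -\frac{P_\text{task} - P_\text{rest}}{P_\text{rest}}
   \times 100,$$
   where $P$ is the multitaper band power at the channel contralateral to
   the imagined hand (C4 for left MI, C3 for right), the task window is the
   1 s action phase and the rest window is the most recent 1 s before
   action onset. Positive values mean suppression. Because the Mu rhythm
   (nominally 8–13 Hz) is subject-specific, the band is chosen per subject
   and day by sliding a 3 Hz window in 1 Hz steps (0.67 overlap) over
   5–20 Hz and keeping the most suppressed window.

2. **ERP-network branch.** Non-hold trials are band-passed 3–30 Hz
   (zero phase), averaged in blocks of 20 consecutive same-task trials
   ("trial-blocks") to expose the event-related potential, and each block's
   channels are correlated pairwise (Pearson) over the task window. The
   resulting 19×19 weighted graph is summarized at three scales:
   weighted node degree $E_i = \sum_{j \ne i} d_{ij}$; regional sums LnL /
   LnR (within left / right hemisphere, midline excluded) and EX
   (between-hemisphere edges); and global transitivity
   $C = 3G_\Delta / (3G_\Delta + G_\Lambda)$ of the graph binarized at
   $\rho \ge 0.6$.

Sessions are the *super-trials*: block-level indicator values are compared
between sessions 1–2, 1–3 and 2–3 with Welch t-tests, and trends over the
block sequence are summarized by OLS slopes.

## The synthetic-data generator

Real training recordings are not distributed with the package; a generator
(`simulate_recording()`) produces sessions with the statistical structure
the analysis assumes, so every pipeline stage can be validated against
ground truth. Per session it builds a continuous record of cue-paced trials
(pause uniform 1.5–2.5 s, action 1 s; 300 trials per session, three
sessions, a third each of left/right/hold cues) and then epochs at
[−1, +1] s around action onset. The signal model per channel is:

* **1/f background** (default exponent 1, 9 µV rms) — the broadband EEG
  floor;
* **four shared broadband sources** mixed into all channels through a fixed
  random matrix (4 µV rms per channel) — without common sources the
  baseline Pearson connectivity of independent noise would be ≈ 0 and a
  0.6-threshold graph would be empty;
* **a band-limited Mu rhythm** at C3 and C4 (9–12 Hz, 6 µV rms), whose
  amplitude is multiplied by $1 - d_s$ at the contralateral channel during
  the action window of MI trials ($d_s$ = per-session `erd_depth`), plus a
  weaker unmodulated posterior alpha at O1/O2;
* **an ERP template** on non-hold trials: Gaussian-windowed deflections
  (σ = 40 ms) at 0.35 s (−), 0.55 s (+) and 0.65 s (−), default magnitudes
  (10, 8, 10) µV, spatial weight decaying with scalp distance from the
  vertex, scaled by the per-session `shared_gain` and jittered per trial
  and channel (sd 0.1).

The two session-indexed vectors are the training-effect dials:
`simulate_condition_pair()` builds a "feedback" fixture (ERD deepening
0.2 → 0.6, common-ERP gain shrinking 1.0 → 0.6 across sessions — the
network-degree correlate of effective neurofeedback) and a "non-feedback"
control with flat profiles, sharing every other parameter and the seed.

The amplitudes above were chosen once at physiologically typical EEG scales
and then verified, by running the generator through the package's own
scoring, to behave sensibly (planted band recovered, degree responsive to
the gain). What the generator does **not** emulate: eye-blink/EMG
artifacts, electrode pops, re-referencing, volume-conduction geometry
beyond the simple vertex-weighted template, or non-stationary background.
Passing tests therefore demonstrate correctness of the *algorithms* under
the assumed signal structure, not robustness to real-world artifacts.

```{r simulate}
pair <- simulate_condition_pair(
  sim_config(n_sessions = 3, trials_per_session = 120, seed = 4)
)
pair$feedback$recording
```

## Running the pipeline

```{r pipeline}
report <- run_pipeline(pair$feedback, scan_bands = NULL)
report
glance(report)
```

```{r musc-plot}
ggplot2::autoplot(report$musc)
```

```{r supertrials-plot}
plot_super_trials(report$metrics, "EX", comparisons = report$comparisons)
```

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `block_size` | 20 | trials | the trial-block; averaging noise by $1/\sqrt{20}$ exposes the ERP |
| `analysis_band` | 3–30 | Hz | keeps the MI-related ERP deflections while removing drift |
| `threshold` | 0.6 | ρ | binarization for transitivity; signed comparison, strong negative correlations do not create edges (an `absolute` flag exposes the \|ρ\| variant) |
| `mu_search`, `mu_width`, `mu_overlap` | 5–20, 3, 0.67 | Hz | subject-specific Mu-band search; 0.67 overlap of a 3 Hz window is rounded to exact 1 Hz steps so windows sit on the 1 Hz PSD grid |
| multitaper `nw`, `k` | 2, 3 | — | ≈3 Hz spectral concentration for a 1 s window; 1 Hz bins |
| epoch window | [−1, +1] | s | houses both the rest ([−1, 0) s) and task ([0, 1) s) windows |

## Numerical and design choices

* **Filtering.** Zero-phase 4th-order Butterworth band-pass, applied per
  2 s epoch with 0.5 s reflection padding. It is realized in the frequency
  domain (multiplication by $|H(e^{j\omega})|^2$ of the designed filter, on
  a 2-3-5-smooth FFT grid), which is the forward–backward magnitude
  response without per-trace loops. Zero phase matters because the network
  branch reads ERP deflection latencies. Epochs, not the continuous record,
  are filtered; with a 3 Hz high-pass and 2 s epochs the padding keeps edge
  error below 2 % mid-epoch (verified in the test suite).
* **Blocks never span sessions or task labels**, and the trailing
  incomplete block is dropped, keeping the averaging noise level
  homogeneous; super-trial statistics need session-pure blocks.
* **Degree is weighted** (sum of signed ρ); the binary graph exists only
  for transitivity. Hemisphere sets exclude the midline (Fz, Cz, Pz) from
  LnL/LnR and EX alike.
* **Zero-variance channels** (e.g. a flat block window) get zero-weight
  edges and a warning instead of NaNs or an abort.
* **Degenerate t-tests** (both groups constant and equal) return
  t = 0, p = 1. Welch's unequal-variance test is the default because the
  variance of block-level indicators differs visibly between sessions; a
  `var_equal` switch provides the pooled Student variant. No
  multiple-testing correction is applied to the headline flags (raw
  p-values are reported, as is conventional for this assessment); a
  Benjamini–Hochberg column `p_bh` is included in the comparison table as a
  clearly-labeled extension.
* **Tie-break.** If several candidate Mu windows score identically (within
  1e-12), the lowest-frequency window wins, making the selection
  deterministic on degenerate inputs.
* **Determinism.** All randomness lives in the generator behind a single
  seed; analysis stages are pure, so re-running a configuration reproduces
  every output byte-identically.

## A caveat on the per-trial MuSC score

The score divides by a band power estimated from a single 1 s rest window.
That estimate has few degrees of freedom, and $E[P_\text{task} /
P_\text{rest}] > 1$ even when both windows have identical spectra (Jensen's
inequality), so per-trial MuSC carries a *negative bias* under the null —
on the generator's defaults about −40 score units, stable across sessions.
The package keeps the per-trial definition (scoring each trial at its own
preceding rest second, then averaging blocks) because the block-wise score
series is the object of interest and the bias cancels in every
*within-subject contrast* the pipeline reports: session comparisons, OLS
slopes, and contralateral-vs-ipsilateral differences. Absolute MuSC levels
should not be compared across estimator variants.

## Problem sizes used in validation

The package's own validation experiments run the full
generate-analyze-test loop at reduced but statistically adequate sizes,
chosen up front: band-selection recovery uses 100 seeds of one 120-trial
session; null calibration uses 200 replicates of 3 × 120 trials (the
rejection count is checked against the exact binomial 95 % interval at
α = 0.05); condition-contrast power uses 100 seeds of paired 3 × 200-trial
fixtures. The generator defaults remain the full study geometry
(3 × 300).

## Known limitations

* Pearson correlation on trial-block ERPs measures amplitude covariation;
  it is blind to phase relationships that coherence or PLV would capture,
  and inherits volume-conduction leakage. These estimators are out of
  scope here by design.
* The 0.6 threshold is a single operating point; the package computes, but
  does not optimize over, threshold choices.
* With few blocks per session (short sessions or large `block_size`) the
  Welch tests run on very small n; below 3 blocks per series the trend
  fits are reported as NA.
* EDF support is intentionally minimal: 16-bit EDF with a uniform sampling
  rate across channels, 1 s records; EDF+ annotations are not parsed
  (events travel in a sidecar CSV).
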