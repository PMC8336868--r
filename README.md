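# miconn

Assessment of **short-term motor-imagery BCI training** from 19-channel
10-20 EEG: Mu-suppression (ERD) scoring with subject-specific band
selection, and ERP-trial-block functional-connectivity brain networks
evaluated at node, hemisphere and whole-brain scale, with super-trial trend
statistics. A ground-truth-known synthetic MI-EEG generator makes every
stage testable end to end.

Who it is for: researchers evaluating whether a single (~1 h,
3-session) MI training run — with or without neurofeedback — changed a
subject's EEG dynamics, and anyone needing a reproducible reference
implementation of these indicators.

## The methods in brief

**Mu-suppression score (per trial, contralateral channel):**

```
MuSC = -((P_task - P_rest) / P_rest) * 100
```

`P` is the multitaper band power (DPSS, NW = 2, 3 tapers) in the
subject-specific Mu band; the task window is the 1 s action phase, the rest
window the preceding 1 s. The band is selected per subject/day by sliding a
3 Hz window in 1 Hz steps over 5–20 Hz and keeping the most suppressed
window. Scores are averaged in 20-trial blocks and trended with an OLS
fitting line.

**ERP brain network (per 20-trial block):** non-hold trials are band-passed
3–30 Hz (zero-phase Butterworth), averaged per block into an ERP, and
channels are correlated pairwise (Pearson) over the task window. The
weighted graph gives

* node degree `E_i = sum_{j != i} d_ij`,
* regional degrees LnL / LnR (within-hemisphere edge sums, midline
  excluded) and EX (between-hemisphere sum),
* global/hemispheric transitivity `3*G_triangle / (3*G_triangle + G_open)`
  on the graph binarized at `rho >= 0.6`.

Sessions are *super-trials* (1–3); block-level indicators are compared
pairwise with Welch t-tests (`*` p < 0.05, `**` p < 0.01).

## Worked example

```r
library(miconn)

# matched pair of simulated conditions: "feedback" plants a training effect
# (ERD deepening, common-ERP gain shrinking across sessions), the control
# holds both profiles flat
pair <- simulate_condition_pair(
  sim_config(n_sessions = 3, trials_per_session = 120, seed = 4)
)

report <- run_pipeline(pair$feedback, scan_bands = NULL)
report
#> <mi_report>
#>   Mu band (per day): [9, 12] Hz
#>   MuSC slope: 5.22 (p = 0.00643 )
#>   task-window regional super-trial 1 vs 3 comparisons:
#>     EX   t =  13.97  p = 0.000219 **
#>     LnL  t =   7.87  p = 0.000234 **
#>     LnR  t =   4.02  p = 0.00812 **

glance(report)
#> # A tibble: 1 x 6
#>   musc_slope musc_slope_p mu_lo mu_hi min_degree_p_1_vs_last n_blocks
#>        <dbl>        <dbl> <dbl> <dbl>                  <dbl>    <int>
#> 1       5.22      0.00643     9    12              0.0000753       12
```

Reading the output: band selection recovered the planted 9–12 Hz Mu band;
the Mu-suppression series *rises* over the blocks (slope 5.22 per block,
the feedback signature), while every regional network degree drops
significantly from super-trial 1 to 3 (`**`) — the planted
training effect, detected by the network branch. Running the same pipeline
on `pair$nonfeedback` yields non-significant comparisons.

Useful pieces on their own:

```r
sel    <- select_mu_band(rec)                    # sliding-window band choice
series <- musc_series(rec, sel)                  # block MuSC tibble
blocks <- make_trial_blocks(bandpass(rec, 3, 30))
conn   <- pearson_connectivity(blocks[1, ], "task")
node_degree(conn, c("C3", "C4"))
transitivity_coef(binarize(conn, 0.6))
ggplot2::autoplot(series)                        # MuSC scatter + red OLS line
plot_super_trials(report$metrics, "EX", comparisons = report$comparisons)
```

I/O: `write_epochs_table()` / `read_epochs_table()` (lossless plain-text
CSV with a `#` metadata header: `sampling_rate`, `onset_index`, `channels`,
per-trial labels; body columns `trial, channel, sample_index, value`),
`write_edf()` / `read_edf()` (minimal 16-bit EDF, 1 s records) with an
events sidecar CSV (`trial_index, session, day, task_label, onset_sample`).
A shell wrapper lives at `inst/scripts/run_pipeline.R`.

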