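# nwreflex

Analysis of laser-evoked nociceptive withdrawal reflexes in spinal cord
injury (SCI) versus non-disabled control (NDC) cohorts, from surface EMG to
clinical statistics.

## The problem

Brief radiant-heat (laser) pulses applied to the leg excite thinly
myelinated A-delta nociceptors (~5–30 m/s) and unmyelinated C-fibers
(~0.5–2 m/s). In a hyperexcitable spinal cord — the situation after SCI —
these afferents trigger withdrawal reflexes recordable as EMG bursts over
the tibialis anterior (TA) and soleus (SO). Because the two fiber classes
conduct at very different speeds, their reflex components separate into an
early time window (TW1, 90–600 ms) and a late one (TW2, 1000–3000 ms). The
package implements the full analysis for stimulus-locked epochs
(two channels, 1000 Hz, −500…+3000 ms around the pulse):

* **Preprocessing** — zero-phase Butterworth band-pass 1–450 Hz,
  segmentation, full-wave rectification.
* **Detection** — a reflex event is polyphasic activity exceeding
  `mu_bg + 2 sigma_bg` of the rectified pre-stimulus background, with a
  10 ms persistence criterion, dip-bridging/merging rules, a ≥ 3-phase
  criterion on the unrectified trace, and artifact guards. Each event
  carries onset latency, peak, AUC (area under the background-corrected
  rectified curve, µV·s) and its time-window label.
* **Aggregation** — per-participant response rates and responder flags per
  site and window, latency/AUC summaries, TA/SO co-activation, analgesia
  flags, and conduction velocity `CV = distance / Δlatency` from the
  latency shift between a distal (sole of foot, FS) and proximal (fibula
  head, FH) stimulation site, using per-site median latencies.
* **Clinical statistics** — Wilcoxon rank-sum with effect size
  `r = |Z|/√N` (exact enumeration for combined n ≤ 12), Fisher's exact 2×2
  with φ, Kendall τ-b with tie corrections, and the η coefficient
  `√(SS_between/SS_total)`, wired into the cohort's analysis battery with a
  one-/two-tailed policy and pairwise-complete missing-data handling.
* **Synthetic cohorts** — a seeded generator producing epochs, trial
  manifests and clinical tables with the cohort-level structure the
  analysis assumes (response rates, latency/CV distributions, magnitude
  contrast, co-activation patterns, an inverse pain–spasticity
  association), so the whole pipeline is testable without any recordings.

## Worked example

```r
library(nwreflex)

cfg <- run_config(seed = 3, n_trials = 60,
                  clinical = clinical_sim_params(n_sci = 15, n_ndc = 12))
res <- run_pipeline(cfg)          # simulate -> filter -> detect -> summarize
print(res)
#> <nwr_analysis>
#>   27 participants, 4860 trials (4860 valid), 1051 reflex events
#>   events by window: intermediate=2, none=1, TW1=285, TW2=763
#>   conduction velocity (TW2, FS-FH): 5 defined, median 1.66 m/s
#>   battery: 30 tests
```

The counts show the group contrast the pipeline is built to expose —
early-window (A-delta) events occur only in the SCI group, late-window
(C-fiber) events dominate, and the defined conduction-velocity estimates
fall in the C-fiber range. `res$battery` holds the statistical battery; on
the packaged 15-participant SCI reference table alone,

```r
bat <- run_battery(NULL, reference_cohort())
subset(bat$results, analysis == "fisher_CPG_vs_spasticity")
#>                   analysis       method statistic  p_value tails effect_size
#> 3 fisher_CPG_vs_spasticity fisher_exact         2 0.040559   two    0.607143
```

i.e. clinically relevant spasticity is inversely associated with central
neuropathic pain (p = 0.04, φ = 0.61), and `eta_CPG_vs_SCAT` yields
η = 0.69 for the association of neuropathic-pain grading with spasticity
severity.

See `vignettes/nwreflex-methods.Rmd` for the model, the generator's
assumptions, parameter defaults with units, and known limitations.

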