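# e4tools

Signal analysis for Empatica E4 wearable recordings: an R toolkit for
clinicians and researchers who study physiological reactivity —
electrodermal activity (EDA), heart rate and heart-rate variability (HRV),
skin temperature, and movement — in daily life rather than in the lab.

The E4 exports one zip archive per recording, each CSV carrying the Unix
start time (row 1) and sampling frequency (row 2): EDA at 4 Hz, blood
volume pulse at 64 Hz, heart rate at 1 Hz, temperature and acceleration,
plus a two-column inter-beat-interval (IBI) file and optional button-press
tags. e4tools reads and writes that dialect and implements the analysis
stack around it:

- **EDA** — upsampling to 8 Hz, zero-phase FIR low-pass filtering,
  artifact screening of 5-s epochs (pluggable classifier with a documented
  rule-based default), validity masking (0.01–100 µS), and detection of
  skin-conductance responses (SCRs) with the standard feature set:
  amplitude (≥ 0.005 µS), rise time, maximum derivative, decay time,
  width, area under the curve, and peaks per analyzable minute.
- **HRV** — physiological plausibility filtering of the IBI series
  (resting HR bounded to 40–180 bpm → max RR 1.5 s, windowed max/min RR
  ratio ≤ 1.1 per 10 s; a single-missed-beat allowance doubles both to
  3 s and 2.2), time-domain measures (mean HR, SDNN, RMSSD, pNN50) and
  Welch band powers (VLF/LF/HF) on the interpolated tachogram.
- **Movement & temperature** — acceleration magnitude
  `sqrt(x² + y² + z²)/64` in g, high-movement flagging above 1.07 g, and
  mean/min/max/median summaries.
- **Calendar & tags** — day-month-year annotation tables synchronized and
  clipped to session time in an explicit display timezone.
- **Cutting & batch** — fixed-width bins written back as E4-dialect
  archives (30 min in 5-min bins → 6 archives), and folder-level batch
  processing into traceable result containers with a run manifest.
- **Reporting** — deterministic, self-contained HTML reports with plots,
  calendar shading, tag lines, and the summary table.
- **Synthetic sessions** — a seeded generator producing full archives
  with ground truth (SCR times/amplitudes, RR anomalies, artifact epochs,
  movement bursts), so every detector is testable without any recording.

## Worked example

```r
library(e4tools)

spec <- synth_spec(duration = 600, seed = 42,
  scr_events = data.frame(time = c(60, 180, 420),
                          amplitude = c(0.4, 0.25, 0.6), rise = 2, decay = 4),
  movement_bursts = data.frame(start = 300, end = 330, g = 1.2))
synth_session_zip(spec, "session.zip")      # archive + .truth.json sidecar

session <- read_session("session.zip")
session
#> <e4_session> session.zip
#>   EDA     2400 samples @     4 Hz
#>   BVP    38400 samples @    64 Hz
#>   HR       600 samples @     1 Hz
#>   TEMP   19200 samples @    32 Hz
#>   ACC    19200 samples @    32 Hz
#>   IBI      699 beats

row <- summarize_interval(session, 0, 600)
```

which prints, formatted:

```
mean EDA        2.010 uS        # tonic level ~2 uS baseline
SCR rate        0.30 peaks/min  # the 3 injected SCRs over 10 min
mean HR         70.0 bpm        # generator's resting rate
RMSSD           27.7 ms         # from the 20 ms beat jitter
mean temp       33.00 degC
mean movement   1.010 g         # 1 g at rest + one 30-s burst
EDA artifacts   0%              # clean signal: no epochs flagged
beats accepted  100%            # all intervals physiologically plausible
movement flag   TRUE            # the burst overlaps the interval:
                                # interpret HRV with caution
```

The three injected responses are recovered exactly (0.30/min × 10 min =
3 peaks), every beat of the clean RR series passes the plausibility
filter, and the movement burst trips the high-movement warning that
guards HRV interpretation. `render_report(session, row, path =
"report.html")` wraps the same numbers in a self-contained HTML report.

See `vignette("e4-signal-analysis")` for the methods: filter design,
artifact rules, peak geometry, RR filtering order, spectral estimation,
and what the synthetic generator does and does not emulate.

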