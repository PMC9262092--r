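---
title: "Methods: wearable signal analysis with e4tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable signal analysis with e4tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e4tools)
```

## Scope

e4tools analyzes physiological recordings from the Empatica E4 wristband:
electrodermal activity (EDA, in microSiemens), blood volume pulse (BVP),
the device's derived heart rate and inter-beat intervals (IBI), skin
temperature, and tri-axial acceleration. The device exports one zip per
recording, each CSV carrying the Unix start time in row 1 and the sampling
frequency in row 2 (IBI instead lists `(seconds since start, interval)`
pairs). The package reads and writes that dialect, preprocesses and
artifact-screens the signals, extracts features, synchronizes user-written
calendar annotations, cuts sessions into analysis bins, batch-processes
folders of recordings, and renders HTML summary reports.

Out of scope by design: beat detection from the raw BVP waveform (the
vendor's algorithm is undisclosed, so the IBI file is taken as given),
beat correction or imputation, non-linear HRV measures, and
deconvolution-based tonic/phasic EDA decomposition (tonic level is
reported as the interval mean).

## The session container

A `signal_stream` is a uniformly sampled matrix anchored at a Unix start
time; sample *i* (0-based) occurs at `start + i/fs`. When several same-day
recordings are merged (a wearer turning the device off produces multiple
files per day), the time between recordings is kept as a *recorded gap* on
the stream rather than NaN padding: no samples are fabricated, timestamps
after a gap shift by its duration, and downstream epoching simply drops
windows that straddle a gap. Gapped streams cannot be written back to the
single-block E4 dialect; cutting into contiguous pieces first is required.
Merging refuses overlapping recordings and recordings from different
calendar days (in the session's display timezone).

Timestamps are displayed using an explicit `tz_offset` in minutes rather
than the host timezone, so the same archive renders identically on any
machine; calendar events are interpreted in that same display zone, which
matches how wearers write down local clock times.

## EDA preprocessing

The native 4 Hz EDA signal is upsampled to 8 Hz by linear interpolation —
monotone, so interpolation can never fabricate a peak — and low-pass
filtered with a 33-tap linear-phase FIR (Hamming design, 1 Hz cutoff,
unit-normalized DC gain). SCR energy sits below ~1 Hz, so the cutoff
removes sensor noise while leaving response morphology intact.

Zero phase matters here: any phase lag would bias rise- and decay-time
estimates. A symmetric (linear-phase) FIR applied once, centered, is
exactly zero-phase; we pad the segment ends by replicating the boundary
samples so the filter does not ring against an implicit zero baseline.
(Running a forward-backward pass would square the magnitude response
without changing the phase argument; the centered single pass keeps the
designed response and better-behaved edges.) Streams shorter than about
three filter lengths are upsampled but left unfiltered. One consequence
worth knowing: the filter rounds the onset and apex corners of an SCR, so
measured trough-to-apex amplitudes sit ~2% below the generating kernel's
amplitude and rise times read slightly long. Tests account for exactly
this discretization/smoothing error and nothing else.

Validity rules: samples below 0.01 uS (electrode lift-off, "approaching
zero") or above 100 uS (device range) are masked out of peak detection
and summaries. Both bounds are configurable (`eda_config()`).

## Artifact screening

The signal is screened in 5-s epochs. The original screening algorithm is
a support vector machine trained on expert-labeled data; its weights were
never published, so the classifier here is *pluggable*: any linear
decision function over the epoch feature vector can be supplied as a
model file, and a documented rule set ships as the default. Features per
epoch: mean, max, min, max absolute first and second difference, and Haar
wavelet detail statistics at the one-second and half-second scales (the
canonical discontinuity detectors at the two stated time scales).

Default rules: an epoch is an artifact when its maximum per-sample jump
exceeds 10 uS/s, or when its range exceeds **both** 20% of the
whole-signal range **and** 1 uS. The absolute floor matters: a relative
rule alone would always flag the epoch containing the largest genuine SCR
(amplitudes rarely exceed ~1 uS in 5 s, while electrode artifacts
routinely jump several uS). Ternary mode adds an "unclear" band at half
of either threshold. These rules are deliberately simple, documented, and
reproducible; they are not a re-implementation of the unpublished SVM,
and labels from any stronger classifier can be plugged in unchanged.

## SCR peak detection and features

On the preprocessed signal, a peak starts at the last local minimum
before a rising limb and peaks at the following local maximum. Amplitude
is apex minus start value; only rises of at least 0.005 uS count as
responses (threshold on *amplitude*, the standard reading). Peaks whose
rise overlaps an artifact epoch or an invalid sample are discarded.
Recovery features are computed when the signal falls to half the
amplitude before the next response begins: `decay_time` (half-recovery
minus apex), `width` (between the half-amplitude crossings of the rising
and falling limbs, crossings linearly interpolated between samples), and
`auc` (trapezoidal integral of the signal above the start level, start to
half-recovery). Otherwise those fields are `NA` — a truncated recovery is
not extrapolated. The SCR rate ("peaks per minute") divides the count by
*analyzable* minutes: valid, artifact-free time only.

## RR filtering and HRV

Wrist PPG beat series carry artifacts, so intervals pass physiological
plausibility rules before any HRV statistic: resting heart rate is taken
to stay within 40–180 bpm, so an interval is rejected outright below
`60/180 ≈ 0.33` s or above the single-missed-beat allowance of
`2 × 60/40 = 3` s. Within any 10-s window the max/min ratio of accepted
intervals may not exceed `2 × 1.1 = 2.2`; when a window violates it, the
later beat of the offending pair is rejected first and the window
re-evaluated — a deterministic tie-break that makes the filter idempotent.
Finally, an interval longer than 1.5 s whose windowed ratio also exceeds
1.1 is rejected (a long beat out of keeping with its neighbours, no
missed-beat excuse). Rule order — hard bounds, then windowed ratio, then
the single-interval rule — is a documented choice where several orderings
would be defensible. Setting `missed_beat_factor = 1` disables the
allowance entirely. The result reports accepted versus original beat
counts; no beats are corrected or re-inserted.

Time-domain measures use the standard minimal set over accepted beats:
mean HR (`60/mean(RR)`), SDNN, RMSSD, and pNN50. For spectral analysis
the instantaneous rate (60/interval at each accepted beat) is linearly
interpolated onto a uniform 4 Hz grid, converted to an RR tachogram in
ms, mean-removed, and fed to a Welch estimator (Hann window, 120-s
segments, 50% overlap, scaled so integrated power equals variance). Band
powers integrate the PSD over VLF 0.003–0.04, LF 0.04–0.15 and HF
0.15–0.4 Hz; at least 120 s of data are required. HRV should only be
interpreted at rest, so interval summaries carry a `movement_present`
flag whenever high movement overlaps the interval — a warning, not a
block.

## Movement and temperature

Acceleration magnitude is `sqrt(x² + y² + z²)/64` in gravity units (the
E4 reports signed counts spanning ±2 g at 64 counts/g). High-movement
periods are maximal intervals where a 1-s centered rolling mean exceeds
1.07 g — about 7% above rest; the paper-style default threshold applies
to the windowed mean rather than instantaneous samples, since a window is
needed for "mean acceleration" to be defined at all. Temperature and all
other channels share one summary contract: mean, min, max, median over
valid samples.

## Cutting, batching, reporting

The cutter divides a timeframe into half-open `[t, t + width)` bins —
floor((end−start)/width) of them, the partial trailing bin dropped with a
log line — each bin a complete session rebased to its own start, writable
as an E4-dialect archive (the canonical example: 30 minutes in 5-minute
bins gives 6 archives). Batch processing maps a folder of archives
through the full pipeline, one result container per input named after its
stem (JSON metadata plus CSV tables in a zip — a language-neutral
replacement for an R-native serialization), failures logged per archive
and never fatal, with a run manifest.

Reports are single-file HTML with deterministic, package-built SVG line
plots (no plotting device involved, so output is byte-stable; the report
timestamp is injectable for testing). Sessions at or under 2 h plot raw;
longer sessions use 1-min means. Preset display ranges: EDA 0–20 uS, HR
40–160 bpm, temperature 24–38 °C, movement 0.98–1.25 g. Calendar events
shade the plots, tags draw red verticals, and optional reference lines
mark the mean or a custom value. Every number in the summary table is
copied from the computed summary; the template recomputes nothing.

## The synthetic-session generator

All tests run on generated sessions with ground truth; no recordings are
shipped. The EDA model is baseline + SCR kernels + Gaussian noise, where
a kernel rises linearly to its amplitude over `rise` seconds and decays
exponentially with constant `decay` — a closed form matching standard SCR
geometry closely enough to test every feature exactly. Defaults describe
a quiet resting recording: 2 uS tonic level; noise at the device
quantization floor (0.9 nS resolution, so step/sqrt(12) ≈ 0.00026 uS);
70 bpm with 20 ms beat jitter (a typical resting RMSSD scale); 33 °C
wrist skin; a device at rest (1 g) outside requested movement bursts.
Injectable ground-truth defects: artifact epochs (5 uS step, dropout to
zero, 8 uS spike), RR anomalies (missed beat = two intervals merged;
ectopic-short = one interval halved), and movement bursts. The BVP
channel is a placeholder harmonic series at the beat rate, present only
to exercise the archive dialect — no beat detection runs on it.

Generation is fully deterministic given the spec's seed (each stream
derives its own substream seed, so adding one stream never perturbs
another). What the generator does *not* emulate: real electrode drift,
skin-potential artifacts correlated across channels, heat transients, or
realistic PPG morphology — so green tests demonstrate algorithmic
correctness on the stated signal model, not clinical validity on real
wrist data.

## Numerical and testing choices

- Archive round trips are exact at the on-disk precision: floats print
  with 6 decimals, integers unpadded; archives are written with a fixed
  timestamp so identical content is byte-identical.
- Half-amplitude crossing times are linearly interpolated between
  samples; trapezoidal integration uses the interpolated endpoint.
- Welch total power is checked against tachogram variance (Parseval);
  with ~15 min of jittered beats the estimator sits within 5% of the
  variance, which is the tolerance the property tests use.
- Test problem sizes: property loops use 15–30 s sessions (100 round
  trips), 5–35 min signals for HRV spectra, and a 30-min session for the
  cutter example — small enough for a routine test run, long enough that
  every window/segment length is exercised at its default.
- Degenerate inputs are contracts, not crashes: empty payloads parse to
  zero-sample streams, empty intervals raise "no analyzable data",
  sub-epoch streams yield zero epochs, and fewer than two accepted beats
  refuse HRV.

## Known limitations

The default artifact rules are intentionally conservative substitutes for
a trained classifier and will miss subtle artifacts an expert would flag;
the plug-in model interface exists precisely so a trained linear decision
function can replace them. Amplitudes of closely spaced SCRs are measured
against a locally decaying baseline, so trains closer than roughly
`rise + 3·decay` seconds bias amplitudes low (the generator refuses to
build them). HRV spectra from wrist PPG are only meaningful at rest, and
the package flags rather than forbids movement overlap.
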