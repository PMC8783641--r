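---
title: "Methods: laminar LFP analysis with lfpkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: laminar LFP analysis with lfpkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpkit)
```

# Scope

lfpkit analyzes multi-channel laminar local field potential (LFP)
recordings from the hippocampus: it detects sharp-wave ripples (SWRs),
fast ripples and interictal epileptiform discharges (IEDs) during
immobility; decomposes signals with Morlet wavelets into relative power
spectra and laminar theta power/phase profiles; extracts theta cycles with
linear phase interpolation and quantifies gamma amplitude as a function of
theta phase on LFP and current-source-density (CSD) signals; and computes
the theta-gamma modulation index (MI). A seeded synthetic laminar-LFP
generator with a ground-truth event manifest makes every stage verifiable
without access to recordings.

# Preprocessing

Recordings acquired at high rates are low-pass filtered and downsampled to
the analysis rate (default 1034 Hz). The anti-alias cutoff is 40% of the
*output* rate — 413.6 Hz when targeting 1034 Hz — so the retained band is
comfortably inside the new Nyquist limit. The filter is a cascade of two
zero-phase (forward-backward) order-4 Butterworth passes. Two design
points deserve a note:

* A single order-8 design would be sharper on paper, but at the very small
  normalized cutoffs implied by a 32 kHz input it is numerically unstable
  in transfer-function form. The cascade of two order-4 zero-phase passes
  is stable everywhere we need it and attenuates a 500 Hz component to
  about 3% when targeting 1034 Hz.
* Resampling after filtering is done by cubic-spline interpolation onto
  the target time grid. This handles non-integer rate ratios (e.g.
  32000/1034) without the impractically long polyphase FIR filters an
  exact rational design would require; after anti-alias filtering the
  signal is smooth at the input rate, so spline interpolation is accurate
  to well below the noise floor (theta-band power is preserved within 1%).

All band-pass filters in the package are zero-phase Butterworth filters,
order 4 per direction by default — phase fidelity matters because several
analyses read instantaneous phase. Very narrow low-frequency bands (the
1-4 Hz delta band at 1034 Hz) are numerically unstable at order 4 in
transfer-function form; `bandpass()` verifies stability on an impulse and
halves the order until the response decays, so delta-band filtering runs
at order 2. This is an implementation constraint, not a tunable.

# Event detection

All detectors share one primitive, `envelope_sd()`: band-pass filter,
magnitude of the analytic signal (computed by the standard FFT
construction), Gaussian smoothing, and standardization by baseline
statistics computed over the immobility periods. Two details:

* **Smoothing width.** The ripple-band envelope is smoothed with a
  Gaussian of sigma = 8 ms (about 1.5 ripple cycles). Narrower kernels
  (4 ms) leave beat dips — interference between an event and band-limited
  background — that split a supra-threshold run just under the 15 ms
  minimum and cost recall on clearly supra-threshold events. Slow bands
  (sharp waves, IEDs, the raw envelope) use sigma = 10 ms. Both are
  configurable in `detection_params()`.
* **Iterative baseline.** Baseline mean and SD are computed over all
  immobility samples, then refined once after excluding samples more than
  3 provisional SD above baseline. Without the refinement the events to be
  detected inflate their own detection units (about 20% SD inflation at
  0.4 events/s), deflating every z value; on an event-free signal the
  refinement changes almost nothing, so the standardization identity
  (baseline mean 0 SD, SD 1) still holds.

The detection rules themselves are threshold rules on this envelope:
ripples are 150-250 Hz excursions above 3 SD for at least 15 ms, with
boundaries extended to the surrounding 1 SD crossings and events closer
than 40 ms combined; sharp waves are 4-50 Hz excursions above 2.5 SD whose
supra-threshold span lasts 20-400 ms; an SWR is a ripple overlapping a
sharp wave (ties resolved to maximal overlap); bursts chain SWRs whose
consecutive peaks fall within 200 ms (chains of 1/2/3/>3 are
singlets/doublets/triplets/higher). Fast ripples (250-600 Hz, truncated at
95% of Nyquist when the rate cannot represent 600 Hz) must show at least
six filtered oscillation peaks each above 5 SD of the band-passed baseline
and pass a spectral-dominance check (peak power above 200 Hz must exceed
peak power at 75-125 Hz). IEDs must exceed 5 SD in both the 60-80 Hz
envelope and the raw envelope. Immobility periods themselves are maximal
stretches with speed below 1.5 cm/s and a low theta/delta power ratio
lasting over 20 s; criterion blips shorter than 2 s are bridged, since the
segmentation targets sustained behavioural states, and the ratio is
smoothed over 10 s for this purpose (the original workflow's manual
adjustment step has no automatic equivalent; gap-bridging is our
replacement for it).

Per-event ripple features: the peak frequency is the argmax of Morlet
power (a 51-centre bank spanning 150-250 Hz, i.e. 2 Hz steps) at the event
peak, and the cycle count is the number of positive band-passed peaks
above 25% of the event maximum. Peak-frequency estimates of brief
transients carry a small upward bias (about 1% here) inherent to the
time-frequency trade-off: shorter wavelets at higher centre frequencies
match a 50 ms burst slightly better than longer ones below it. The 2 Hz
bank step absorbs this bias; it does not affect group contrasts, which
compare like with like.

# Spectral analysis

`wavelet_transform()` convolves a signal with complex Morlet wavelets
(default 6 cycles) normalized so that a unit-amplitude tone at the centre
frequency yields unit response amplitude — power is therefore in signal
units squared. A consequence worth knowing: the equivalent noise bandwidth
of an amplitude-normalized Morlet grows linearly with centre frequency, so
the wavelet spectrum of white noise rises linearly with frequency rather
than being flat. The tests assert exactly this analytic expectation.
Relative power expresses each frequency's time-averaged power within theta
epochs as a percentage of the total (summing to 100 by construction), with
100 linearly spaced centres over 2-100 Hz by default.

Theta epochs are stretches where the theta (6-10 Hz) to delta (1-4 Hz)
power ratio exceeds 2 while the animal moves faster than 2 cm/s, at least
1 s long; the ratio is band-passed RMS power in sliding 1 s windows. The
thresholds are heuristics exposed in the API — the original workflow
adjusted epochs manually, which cannot be reproduced automatically.

The laminar profile reports per-channel theta power and the circular mean
phase difference against a reference channel (conventionally str.
pyramidale), reproducing the progressive phase shift and power maximum
toward str. lacunosum-moleculare on laminar probes.

# Theta cycles, CSD and coupling

`extract_theta_cycles()` implements cycle-by-cycle phase: the signal is
filtered broadly (1-40 Hz) and in the theta band (6-10 Hz); theta zero
crossings define alternating search windows in which the broad-band
extrema localize each peak and trough; phase is interpolated linearly from
0 at a peak through 180 at the trough to 360 at the next peak. Cycles
never span epoch boundaries (cycles overlapping a boundary are dropped,
not truncated), and epochs shorter than one theta period are skipped with
a message. On a pure sinusoid this assigns exactly 180 degrees at every
trough.

CSD is the unsmoothed second spatial difference along each shank's
contiguous depth runs, `(LFP[n-1] - 2 LFP[n] + LFP[n+1]) / d^2`, with
microvolt samples converted to millivolts so the output is mV/mm^2; the
first and last contact of each run are excluded, and runs need at least
three contiguous depths. Linear depth gradients map to exactly zero, which
is the point: volume-conducted components are removed.

The 16-bin gamma-by-phase profile applies 65 Morlet wavelets (20-150 Hz)
and z-scores each frequency's amplitude across all in-cycle samples of the
session before averaging per phase bin; z-scoring across samples (rather
than across cycle means) was chosen because it weights every sample
equally and makes the occupancy-weighted profile mean exactly zero, which
is a convenient invariant to test. Gamma sub-bands average bank centres
within slow (25-55 Hz), mid (65-90 Hz) and fast (100 Hz up to the bank
maximum) ranges.

The modulation index uses 18 phase bins (the convention of the entropy
based MI), separate from the 16-bin profile. Phase comes from the 6-12 Hz
band via the analytic signal; amplitude per 5 Hz window (20-200 Hz) is the
Morlet amplitude at the window centre. The wavelet choice is deliberate: a
zero-phase Butterworth of 5 Hz bandwidth at 1034 Hz has an impulse
response longer than a theta cycle and cannot resolve theta-rate amplitude
modulation at all (its sidebands fall outside the window), whereas the
Morlet's bandwidth scales with frequency and passes them. Only theta
epochs longer than 1.5 s enter the calculation. MI is the normalized
entropy deficit `(log N - H) / log N` of the amplitude-by-phase
distribution: 0 for phase-independent amplitude, 1 for amplitude
concentrated in a single bin. MI is invariant to amplitude scaling and
bounded in [0, 1] for any input.

# The synthetic generator

`generate_session()` builds sessions whose statistical structure matches
what the analyses assume: laminar theta (default 8 Hz) with per-layer
amplitudes rising toward str. LM and a progressive phase shift reaching
180 degrees there; gamma sub-bands whose envelopes follow
`1 + depth * cos(phase - preferred)` against the reference theta phase
(slow gamma near the trough in str. radiatum, mid gamma at the peak in
str. LM, fast gamma near the trough in str. pyramidale); 1/f-shaped plus
white Gaussian noise; an alternating immobility/locomotion speed trace at
50 frames/s (default 60 s/30 s bouts, 10 cm/s locomotion); and
Poisson-placed SWRs during immobility (default 0.4 events/s, ripple
180 Hz/60 ms at 6 SD, sharp wave 80 ms at 4 SD — the 4 SD default mirrors
the ~3.8 SD median sharp-wave amplitude reported for such recordings),
with optional fast ripples, IEDs, and explicitly requested doublet/triplet
bursts with fixed intra-burst gaps. Identical configuration and seed give
bit-identical output.

Choices that matter for interpreting test results:

* **Gamma carrier.** Coupled gamma rides on band-limited Gaussian noise
  spanning the coupling band, not a pure tone. A tone is pathological for
  sub-band amplitude analysis — all its modulation sidebands fall outside
  any window narrower than twice the theta frequency — while real gamma is
  broadband. A `carrier = "tone"` option remains for analytically exact
  construction tests.
* **Amplitude calibration.** Injected amplitudes are stated in
  baseline-SD units *as seen by the detectors*: each waveform is scaled
  through the same band-pass + smoothed-envelope chain the detector
  applies (a sharp-wave bump loses most of its energy below the 4 Hz band
  edge, so naive scaling would inject far weaker events than nominal).
  Fast ripples are calibrated in SD units of the band-passed trace itself,
  matching their per-peak criterion, and use a flat-topped (Tukey)
  envelope so that at least six cycles carry full amplitude.
* **Immobility is low-theta.** Theta (and coupled gamma) amplitude is
  multiplied by 0.1 during immobility bouts. The immobility criterion in
  the analysis selects low-theta stillness; a synthetic immobility state
  with substantial residual theta would sit on the segmentation threshold
  and contaminate the sharp-wave band baseline.
* **Event placement.** Events are placed uniformly within immobility
  bouts, at least 250 ms apart and 300 ms from bout edges, so that
  singlet/doublet labels are unambiguous unless bursts are explicitly
  requested. Event counts are Poisson draws with mean rate x eligible
  time.

What the generator does **not** emulate: spike trains and their ripple
phase locking, biophysical (compartmental) current sources, non-stationary
theta frequency drift, behavioural structure beyond alternating bouts, and
electrode artifacts. Passing tests therefore certify the signal-processing
chain — thresholds, phase conventions, spectral estimators, ground-truth
recovery — not robustness to every pathology of in vivo data.

# Statistics and reporting

Session summaries aggregate incidence (events per second of immobility),
ripple peak power, median wavelet peak frequency, mean cycles and
duration, burst-type percentages (which partition 100%), and the Pearson
correlation between sharp-wave amplitude and ripple power across events.
Group comparisons are thin wrappers over standard tests: a two-sided
Mann-Whitney U test for scalar fields, and per-bin Welch t tests with
Holm-Sidak step-down correction for phase-bin curves (the step-down
adjustment is implemented in-package because `p.adjust` offers Holm but
not the Sidak variant; tests verify it against a brute-force
recomputation). The behavioural discrimination index is
`(Tmo - Tuo) / (Tmo + Tuo)`.

# Problem sizes used in the test-suite

The packaged tests run synthetic sessions of 150-600 s at 1034 Hz — large
enough for stable envelope baselines (hundreds of events at the default
incidence) and for MI estimation over tens of theta epochs, while a full
run of the suite stays in the minutes range on a single core. The
group-direction check uses two cohorts of 8 sessions per group in each of
two independently seeded replicates, mirroring session-level group
comparisons at reduced scale.

# Known limitations

* The "manual adjustment" step of theta-epoch selection in the original
  workflow has no automatic equivalent; thresholds are exposed instead.
* At the 1034 Hz analysis rate the nominal 250-600 Hz fast-ripple band
  exceeds Nyquist and is truncated to 250-491 Hz (with a warning); run
  fast-ripple detection on higher-rate data when available.
* Ripple peak power defaults to the envelope maximum; wavelet peak power
  is available via `ripple_features()`. Which the original used is not
  determinable.
* Peak-frequency estimates of brief transients carry the small upward
  bias described above.
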