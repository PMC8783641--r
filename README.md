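# lfpkit

Analysis of multi-channel laminar local field potential (LFP) recordings
from the hippocampus, for electrophysiologists who record along the
CA1–dentate axis with silicon probes and need the standard battery of
state- and layer-resolved analyses:

* **Sharp-wave ripple (SWR) detection** during immobility: ripples are
  150–250 Hz envelope excursions above 3 SD of baseline for ≥ 15 ms in
  str. pyramidale (boundaries at the 1 SD crossings, events closer than
  40 ms combined), sharp waves are 2.5 SD excursions of the 4–50 Hz
  envelope lasting 20–400 ms in str. radiatum, and an SWR is their
  temporal conjunction. Bursts chain SWRs whose peaks fall within 200 ms
  (singlets/doublets/triplets). Fast ripples (250–600 Hz, ≥ 6
  supra-threshold cycles, with a spectral-dominance artifact check) and
  interictal discharges (60–80 Hz and raw envelopes both > 5 SD) cover the
  pathological side.
* **Morlet spectral analysis**: banks of complex Morlet wavelets (100
  centres over 2–100 Hz by default) give instantaneous power and phase,
  relative power spectra (per-frequency percentage of the total), and
  laminar theta power/phase profiles against a reference channel.
* **Theta cycle-by-cycle coupling**: theta cycles are extracted by linear
  phase interpolation between peaks and troughs anchored at theta-band
  zero crossings (0° at peaks, 180° at troughs); gamma amplitude (65
  wavelets, 20–150 Hz) is z-scored and binned into 16 theta-phase bins,
  on LFP or on current source density (CSD), the second spatial
  derivative `CSD(n,t) = (LFP(n−1,t) − 2·LFP(n,t) + LFP(n+1,t)) / d²`.
* **Modulation index**: the entropy-based MI,
  `MI = (log N − H) / log N`, where `H` is the Shannon entropy of the
  gamma-amplitude distribution over `N = 18` theta-phase bins —
  0 when amplitude ignores phase, 1 when it concentrates in one bin.
* **A synthetic laminar-LFP generator** (`generate_session()`) producing
  seeded sessions with laminar theta, phase-locked gamma, 1/f + white
  noise, a speed trace, Poisson SWR trains and a ground-truth manifest, so
  the whole pipeline is verifiable end-to-end with no external data.

## Worked example

Simulate a 5-minute session, detect SWRs, and measure theta–gamma
coupling on the CSD of the str. LM channel:

```r
library(lfpkit)

cfg <- synth_config(duration_s = 300, swr_rate_hz = 0.4, seed = 42)
ses <- generate_session(cfg)
ses$recording
#> <lfp_recording> 8 channels x 310200 samples @ 1034 Hz (300.0 s from t=0 s)

params <- detection_params()
ratio  <- theta_delta_ratio(get_channel(ses$recording, "s1d2"), 1034,
                            at_times_s = ses$speed$times_s, window_s = 10)
imm     <- find_immobility_periods(ses$speed, ratio, params)
ripples <- detect_ripples(get_channel(ses$recording, "s1d2"), 1034, imm, params)
ripples <- ripple_features(ripples, get_channel(ses$recording, "s1d2"), 1034, params)
spws    <- detect_spws(get_channel(ses$recording, "s1d3"), 1034, imm, params)
swrs    <- pair_swr(ripples, spws, params)
s <- summarize_session(swrs, classify_bursts(swrs, params), imm, "demo")
#> SWRs: 57   incidence: 0.296 events/s
#> median peak frequency: 184.0 Hz   mean cycles: 9.1   mean duration: 54.1 ms
#> burst mix: 100% singlets, 0% doublets, 0% triplets

epochs <- detect_theta_epochs(get_channel(ses$recording, "s1d2"), 1034, ses$speed)
csd <- compute_csd(ses$recording, ses$map)
mi  <- modulation_index(get_csd_channel(csd, "s1d5"),
                        get_csd_channel(csd, "s1d5"), 1034, epochs)
band_mi(mi, c(65, 90))
#> [1] 0.0069   # LM-CSD mid-gamma MI, preferred phase ~10 deg (theta peak)
```

Reading the numbers: the detected incidence (0.296 events/s) sits below
the injected rate (0.4/s) because the default sharp-wave amplitude
(4 SD, matching the ~3.8 SD median amplitude typical of such recordings)
is close to its own 2.5 SD detection threshold — detection-conditioned
incidence always underestimates the generative rate. With clearly
supra-threshold events (≥ 6 SD) recall and precision both exceed 0.9 (see
`tests/testthat/test-acceptance.R`). The per-event features (median
frequency near the injected 180 Hz, ~9 cycles, ~54 ms) and the mid-gamma
MI locked at the theta peak on the LM CSD reproduce the injected session
structure.

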