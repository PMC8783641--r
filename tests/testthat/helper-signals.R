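# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# Hann-windowed oscillatory burst (amplitude in the same units as the host
# signal).
hann_burst <- function(rate_hz, freq_hz, dur_ms, amp) {
  n <- max(3L, round(dur_ms / 1000 * rate_hz))
  t <- (seq_len(n) - 1L) / rate_hz
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  amp * w * sin(2 * pi * freq_hz * t)
}

# Rectangular-envelope burst: crisp supra-threshold edges for testing the
# boundary/merge rules without smoothing blur.
rect_burst <- function(rate_hz, freq_hz, dur_ms, amp) {
  n <- max(3L, round(dur_ms / 1000 * rate_hz))
  t <- (seq_len(n) - 1L) / rate_hz
  amp * sin(2 * pi * freq_hz * t)
}

# add a waveform centred at `center_s`
add_at <- function(x, w, center_s, rate_hz) {
  n <- length(w)
  i0 <- round(center_s * rate_hz) + 1L - n %/% 2L
  x[i0:(i0 + n - 1L)] <- x[i0:(i0 + n - 1L)] + w
  x
}

# detection-chain gain of a waveform shape: peak of its smoothed band
# envelope per unit amplitude (test bursts are scaled by this so their
# nominal SD value is what the detector sees)
wave_gain <- function(wave, band, rate_hz, sigma_s) {
  pad <- numeric(round(0.5 * rate_hz))
  w <- c(pad, wave, pad)
  flt <- if (is.null(band)) w else bandpass(w, band, rate_hz)
  max(smooth_gaussian(Mod(analytic_signal(flt)), sigma_s, rate_hz)) /
    max(abs(wave))
}

# baseline mean/SD of the smoothed band envelope (for SD-unit calibration
# of test bursts); mirrors the detector's refined baseline
band_env_stats <- function(x, band, rate_hz, sigma_s) {
  flt <- if (is.null(band)) x else bandpass(x, band, rate_hz)
  env <- smooth_gaussian(Mod(analytic_signal(flt)), sigma_s, rate_hz)
  m <- mean(env); s <- sd(env)
  keep <- (env - m) / s <= 3
  list(m = mean(env[keep]), s = sd(env[keep]))
}

# full detection chain on a generated session (shank-1 default channels)
detect_session_swrs <- function(ses, params = detection_params()) {
  rate <- ses$recording$rate_hz
  x_pyr <- get_channel(ses$recording, "s1d2")
  x_rad <- get_channel(ses$recording, "s1d3")
  ratio <- theta_delta_ratio(x_pyr, rate, at_times_s = ses$speed$times_s,
                             window_s = params$immobility_ratio_window_s)
  imm <- find_immobility_periods(ses$speed, ratio, params)
  rip <- detect_ripples(x_pyr, rate, imm, params)
  spw <- detect_spws(x_rad, rate, imm, params)
  swr <- pair_swr(rip, spw, params)
  list(immobility = imm, ripples = rip, spws = spw, swrs = swr)
}

# recall/precision of detected peaks against ground-truth peaks
match_events <- function(det_peaks, gt_peaks, tol_s = 0.05) {
  recall <- if (length(gt_peaks)) {
    mean(vapply(gt_peaks, function(p) any(abs(det_peaks - p) <= tol_s), logical(1)))
  } else NA_real_
  precision <- if (length(det_peaks)) {
    mean(vapply(det_peaks, function(p) any(abs(gt_peaks - p) <= tol_s), logical(1)))
  } else NA_real_
  list(recall = recall, precision = precision)
}
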