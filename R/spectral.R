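# Morlet wavelet time-frequency analysis, theta-epoch detection, relative
# power spectra and laminar theta power/phase profiles.

#' Morlet wavelet bank
#'
#' Linearly spaced complex Morlet wavelets (endpoints inclusive), e.g. 100
#' wavelets from 2 to 100 Hz for broadband spectra or 65 from 20 to 150 Hz
#' for the cycle-by-cycle gamma analysis.
#'
#' @param fmin,fmax frequency range, Hz; must lie inside (0, rate/2).
#' @param n number of centres (>= 2).
#' @param n_cycles wavelet width in cycles (>= 3; default 6).
#' @param rate_hz sampling rate, Hz.
#' @return a `wavelet_bank` object.
#' @export
make_bank <- function(fmin, fmax, n, n_cycles = 6, rate_hz) {
  if (fmin <= 0 || fmax <= fmin)
    stop("need 0 < fmin < fmax", call. = FALSE)
  if (fmax >= nyquist(rate_hz))
    stop(sprintf("fmax %g Hz is at or above the Nyquist frequency %g Hz",
                 fmax, nyquist(rate_hz)), call. = FALSE)
  if (n < 2) stop("need at least 2 wavelet centres", call. = FALSE)
  if (n_cycles < 3) stop("n_cycles must be >= 3", call. = FALSE)
  structure(list(center_freqs_hz = seq(fmin, fmax, length.out = n),
                 n_cycles = n_cycles, rate_hz = rate_hz),
            class = "wavelet_bank")
}

# complex Morlet wavelet, normalized so that a unit-amplitude tone at the
# centre frequency yields a response of magnitude ~1 (amplitude units).
morlet_wavelet <- function(freq_hz, n_cycles, rate_hz) {
  sigma_t <- n_cycles / (2 * pi * freq_hz)
  half <- ceiling(4 * sigma_t * rate_hz)
  t <- (-half:half) / rate_hz
  g <- exp(-t ^ 2 / (2 * sigma_t ^ 2))
  w <- g * exp(1i * 2 * pi * freq_hz * t)
  w * (2 / sum(g))
}

#' Morlet wavelet transform
#'
#' Convolves a single-channel signal with every wavelet of the bank to give
#' instantaneous power (amplitude squared, microvolts squared for microvolt
#' input) and phase. Samples within half a wavelet support of either edge
#' are flagged in `edge`.
#'
#' @param x numeric vector.
#' @param bank a [make_bank()] result.
#' @return a `tf_map`: `power` and `phase` (freq x time matrices), `freqs_hz`,
#'   `rate_hz`, `edge` (logical freq x time matrix of edge-contaminated
#'   samples).
#' @export
wavelet_transform <- function(x, bank) {
  n <- length(x)
  freqs <- bank$center_freqs_hz
  max_half <- ceiling(4 * bank$n_cycles / (2 * pi * min(freqs)) * bank$rate_hz)
  if (n <= 2L * max_half + 1L)
    stop(sprintf("signal too short (%d samples) for the longest wavelet support (%d samples)",
                 n, 2L * max_half + 1L), call. = FALSE)
  nfft <- stats::nextn(n + 2L * max_half + 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  power <- matrix(0, nrow = length(freqs), ncol = n)
  phase <- matrix(0, nrow = length(freqs), ncol = n)
  edge <- matrix(FALSE, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[k], bank$n_cycles, bank$rate_hz)
    half <- (length(w) - 1L) %/% 2L
    W <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::fft(X * W, inverse = TRUE) / nfft
    resp <- conv[(half + 1L):(half + n)]        # centre-aligned
    power[k, ] <- Mod(resp) ^ 2
    phase[k, ] <- Arg(resp)
    if (half > 0L) {
      edge[k, seq_len(min(half, n))] <- TRUE
      edge[k, seq.int(max(1L, n - half + 1L), n)] <- TRUE
    }
  }
  structure(list(power = power, phase = phase, freqs_hz = freqs,
                 rate_hz = bank$rate_hz, edge = edge),
            class = "tf_map")
}

#' Detect theta epochs
#'
#' Maximal intervals in which the theta/delta power ratio exceeds the
#' threshold while the animal is walking or running (speed above the
#' locomotion threshold), each at least `min_epoch_s` long. Fully
#' automatic — no manual adjustment step.
#'
#' @param x single-channel LFP (reference theta channel), microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param speed a [speed_trace()], or `NULL` to skip the locomotion gate.
#' @param ratio_threshold theta/delta power ratio cutoff (default 2).
#' @param speed_threshold_cm_s locomotion speed cutoff (default 2 cm/s).
#' @param min_epoch_s minimum epoch duration, seconds (default 1).
#' @param window_s ratio smoothing window, seconds.
#' @param t_start_s time of the first sample.
#' @return data frame: `start_s`, `end_s`, `mean_ratio`.
#' @export
detect_theta_epochs <- function(x, rate_hz, speed = NULL, ratio_threshold = 2,
                                speed_threshold_cm_s = 2, min_epoch_s = 1,
                                window_s = 1, t_start_s = 0) {
  ratio <- theta_delta_ratio(x, rate_hz, window_s = window_s,
                             t_start_s = t_start_s)
  mask <- ratio > ratio_threshold
  if (!is.null(speed)) {
    tt <- t_start_s + (seq_along(x) - 1L) / rate_hz
    spd <- stats::approx(speed$times_s, speed$speed_cm_s, xout = tt,
                         rule = 2)$y
    mask <- mask & (spd > speed_threshold_cm_s)
  }
  runs <- runs_from_mask(mask)
  rows <- list()
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, "start"]; b <- runs[k, "end"]
    dur <- (b - a + 1L) / rate_hz
    if (dur < min_epoch_s) next
    rows[[length(rows) + 1L]] <- data.frame(
      start_s = t_start_s + (a - 1L) / rate_hz,
      end_s = t_start_s + b / rate_hz,
      mean_ratio = mean(ratio[a:b]))
  }
  if (!length(rows))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      mean_ratio = numeric(0)))
  do.call(rbind, rows)
}

#' Relative power spectrum over epochs
#'
#' Time-averages wavelet power over the epoch samples and expresses each
#' frequency as a percentage of the total spectrum (sums to 100).
#'
#' @param tf a [wavelet_transform()] result.
#' @param epochs data frame (`start_s`, `end_s`) inside the map span.
#' @param t_start_s time of the first map sample.
#' @return a `relative_power_spectrum` data frame: `freqs_hz`,
#'   `relative_power_percent`.
#' @export
relative_power <- function(tf, epochs, t_start_s = 0) {
  if (nrow(epochs) == 0L) stop("epochs must be non-empty", call. = FALSE)
  mask <- periods_to_mask(epochs, ncol(tf$power), tf$rate_hz, t_start_s)
  if (!any(mask)) stop("epochs cover no samples of the map", call. = FALSE)
  avg <- rowMeans(tf$power[, mask, drop = FALSE])
  out <- data.frame(freqs_hz = tf$freqs_hz,
                    relative_power_percent = 100 * avg / sum(avg))
  class(out) <- c("relative_power_spectrum", "data.frame")
  out
}

#' Relative power within a frequency band
#'
#' @param spectrum a [relative_power()] result.
#' @param band pair (low, high) in Hz; must intersect the spectrum's range.
#' @return summed relative power (percent) over bins with centres in the
#'   band.
#' @export
band_relative_power <- function(spectrum, band) {
  if (band[2] < min(spectrum$freqs_hz) || band[1] > max(spectrum$freqs_hz))
    stop(sprintf("band %g-%g Hz lies outside the spectrum range %g-%g Hz",
                 band[1], band[2], min(spectrum$freqs_hz),
                 max(spectrum$freqs_hz)), call. = FALSE)
  sel <- spectrum$freqs_hz >= band[1] & spectrum$freqs_hz <= band[2]
  sum(spectrum$relative_power_percent[sel])
}

#' Laminar theta power and phase profile
#'
#' For every channel: theta-band (6-10 Hz) power over the epochs and the
#' circular mean phase difference versus a reference channel, in degrees in
#' (-180, 180]. Reproduces the progressive theta phase shift and the power
#' peak toward str. LM on laminar probes.
#'
#' @param rec an `lfp_recording`.
#' @param map matching `channel_map` (layer labels are carried through).
#' @param epochs theta epochs (`start_s`, `end_s`).
#' @param reference_channel channel id used as the phase reference
#'   (conventionally the str. pyramidale site).
#' @param theta_band band, Hz.
#' @return data frame: `channel_id`, `layer`, `theta_power_uv2`,
#'   `phase_shift_deg`.
#' @export
laminar_theta_profile <- function(rec, map, epochs, reference_channel,
                                  theta_band = c(6, 10)) {
  if (!(as.character(reference_channel) %in% rec$channel_ids))
    stop(sprintf("unknown reference channel '%s'", reference_channel),
         call. = FALSE)
  if (nrow(rec$samples) < 2L)
    stop("need at least 2 channels for a laminar profile", call. = FALSE)
  mask <- periods_to_mask(epochs, n_samples(rec), rec$rate_hz, rec$t_start_s)
  if (!any(mask)) stop("epochs cover no samples", call. = FALSE)
  ref <- analytic_signal(bandpass(get_channel(rec, reference_channel),
                                  theta_band, rec$rate_hz))
  out <- data.frame(channel_id = rec$channel_ids,
                    layer = map$layer[match(rec$channel_ids, map$channel_id)],
                    theta_power_uv2 = NA_real_, phase_shift_deg = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rec$samples))) {
    flt <- bandpass(rec$samples[i, ], theta_band, rec$rate_hz)
    an <- analytic_signal(flt)
    out$theta_power_uv2[i] <- mean(flt[mask] ^ 2)
    dphi <- Arg(an[mask] * Conj(ref[mask]))
    out$phase_shift_deg[i] <- wrap_deg(atan2(mean(sin(dphi)), mean(cos(dphi))) *
                                         180 / pi)
  }
  out
}
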