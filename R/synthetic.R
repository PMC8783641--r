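# Seeded synthetic laminar-LFP sessions with a ground-truth manifest.
#
# The generator emulates the statistical structure the analysis stages
# assume: layer-dependent theta with a progressive phase shift and a power
# peak in str. LM, gamma sub-bands amplitude-locked to specific theta
# phases, Poisson sharp-wave-ripple trains during immobility (ripple in
# str. pyramidale co-occurring with a sharp wave in str. radiatum),
# optional fast ripples and interictal discharges, 1/f + white background
# noise, and an alternating immobility/locomotion speed trace.

#' Default laminar profile for one shank
#'
#' Eight sites spanning the CA1-dentate axis: theta amplitude grows toward
#' str. LM (where theta power peaks) and the theta phase shifts
#' progressively, reaching ~180 degrees in str. LM relative to the
#' pyramidal layer.
#'
#' @param sites_per_shank number of sites (profiles are recycled/truncated
#'   to this count).
#' @return data frame with `layer`, `theta_amp_uv`, `theta_phase_deg`.
#' @export
default_layer_profiles <- function(sites_per_shank = 8) {
  base <- data.frame(
    layer = c("str_oriens", "str_pyramidale", "str_radiatum", "str_radiatum",
              "str_LM", "dg_moleculare", "dg_granule", "hilus"),
    theta_amp_uv = c(40, 50, 80, 120, 200, 150, 100, 80),
    theta_phase_deg = c(0, 0, 45, 90, 180, 200, 210, 220),
    stringsAsFactors = FALSE)
  base[rep_len(seq_len(nrow(base)), sites_per_shank), , drop = FALSE]
}

#' Default theta-gamma coupling specification
#'
#' Slow gamma in str. radiatum locked near the theta trough, mid gamma in
#' str. LM locked at the theta peak, fast gamma in str. pyramidale near the
#' trough — the laminar coupling motif the coupling analyses look for.
#'
#' @return list of coupling specs (band, preferred phase, depth, amplitude,
#'   layer).
#' @export
default_coupling_specs <- function() {
  list(
    list(band = c(25, 55),  pref_phase_deg = 180, depth = 0.4, amp_uv = 15,
         layer = "str_radiatum"),
    list(band = c(65, 90),  pref_phase_deg = 0,   depth = 0.6, amp_uv = 12,
         layer = "str_LM"),
    list(band = c(100, 150), pref_phase_deg = 180, depth = 0.4, amp_uv = 10,
         layer = "str_pyramidale"))
}

#' Synthetic session configuration
#'
#' @param duration_s session length, seconds.
#' @param rate_hz sampling rate, Hz (default 1034, the analysis rate).
#' @param n_shanks,sites_per_shank probe geometry (default 4 x 8).
#' @param site_spacing_mm vertical site spacing, mm (default 0.2).
#' @param theta_freq_hz theta frequency, Hz.
#' @param layer_profiles per-site data frame (`layer`, `theta_amp_uv`,
#'   `theta_phase_deg`), recycled across shanks; default
#'   [default_layer_profiles()].
#' @param coupling_specs list of coupling specs as in
#'   [default_coupling_specs()]; depths must lie in \[0, 1\].
#' @param swr_rate_hz sharp-wave-ripple rate during immobility, events/s.
#' @param swr_params list: `freq_hz` ripple frequency, `amp_sd` ripple
#'   amplitude in baseline envelope SD units, `duration_ms`, `spw_amp_sd`,
#'   `spw_duration_ms`.
#' @param ied_rate_hz,fast_ripple_rate_hz pathological event rates during
#'   immobility, events/s.
#' @param ied_params,fast_ripple_params amplitude/duration/frequency of the
#'   injected pathological waveforms (SD units as for SWRs).
#' @param noise list: `pink_exponent` (1/f^a slope), `pink_sd_uv`,
#'   `white_sd_uv`.
#' @param speed_profile list: `immobility_s`, `locomotion_s` (alternating
#'   bout durations; `locomotion_s = 0` gives an all-immobility session),
#'   `speed_cm_s` locomotion speed, `frame_rate_hz` (default 50).
#' @param theta_immobility_factor theta/gamma amplitude multiplier during
#'   immobility (theta is low while the animal is still).
#' @param bursts list: `doublets`, `triplets`, `gap_ms` — explicitly
#'   injected SWR burst groups with fixed intra-burst peak gaps.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   sessions.
#' @return a validated `synth_config` object.
#' @export
synth_config <- function(duration_s = 180, rate_hz = 1034,
                         n_shanks = 1, sites_per_shank = 8,
                         site_spacing_mm = 0.2, theta_freq_hz = 8,
                         layer_profiles = NULL, coupling_specs = NULL,
                         swr_rate_hz = 0.4,
                         swr_params = list(freq_hz = 180, amp_sd = 6,
                                           duration_ms = 60, spw_amp_sd = 4,
                                           spw_duration_ms = 80),
                         ied_rate_hz = 0,
                         ied_params = list(freq_hz = 70, amp_sd = 8,
                                           duration_ms = 40),
                         fast_ripple_rate_hz = 0,
                         fast_ripple_params = list(freq_hz = 300, amp_sd = 8,
                                                   duration_ms = 40),
                         noise = list(pink_exponent = 1, pink_sd_uv = 30,
                                      white_sd_uv = 10),
                         speed_profile = list(immobility_s = 60,
                                              locomotion_s = 30,
                                              speed_cm_s = 10,
                                              frame_rate_hz = 50),
                         theta_immobility_factor = 0.1,
                         bursts = list(doublets = 0, triplets = 0,
                                       gap_ms = 120),
                         seed = 1) {
  if (is.null(layer_profiles)) layer_profiles <- default_layer_profiles(sites_per_shank)
  if (is.null(coupling_specs)) coupling_specs <- default_coupling_specs()
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  fail <- function(field, msg)
    stop(sprintf("invalid synth_config field '%s': %s", field, msg),
         call. = FALSE)
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    fail("duration_s", "must be > 0")
  if (cfg$rate_hz <= 0) fail("rate_hz", "must be > 0")
  top <- max(c(cfg$theta_freq_hz,
               unlist(lapply(cfg$coupling_specs, `[[`, "band")),
               if (cfg$swr_rate_hz > 0) cfg$swr_params$freq_hz,
               if (cfg$ied_rate_hz > 0) cfg$ied_params$freq_hz,
               if (cfg$fast_ripple_rate_hz > 0) cfg$fast_ripple_params$freq_hz))
  if (cfg$rate_hz <= 2 * top)
    fail("rate_hz", sprintf("must exceed twice the highest synthesized frequency (%g Hz)", top))
  for (sp in cfg$coupling_specs) {
    if (sp$depth < 0 || sp$depth > 1)
      fail("coupling_specs", sprintf("modulation depth %g outside [0, 1]", sp$depth))
    if (sp$band[1] <= 0 || sp$band[2] <= sp$band[1])
      fail("coupling_specs", "band must satisfy 0 < low < high")
  }
  for (f in c("swr_rate_hz", "ied_rate_hz", "fast_ripple_rate_hz"))
    if (cfg[[f]] < 0) fail(f, "rates must be >= 0")
  if (nrow(cfg$layer_profiles) != cfg$sites_per_shank)
    fail("layer_profiles", sprintf("need %d per-site rows, got %d",
                                   cfg$sites_per_shank, nrow(cfg$layer_profiles)))
  if (cfg$site_spacing_mm <= 0) fail("site_spacing_mm", "must be > 0")
  if (cfg$speed_profile$immobility_s < 0 || cfg$speed_profile$locomotion_s < 0)
    fail("speed_profile", "bout durations must be >= 0")
  if (cfg$speed_profile$immobility_s + cfg$speed_profile$locomotion_s <= 0)
    fail("speed_profile", "at least one bout duration must be > 0")
  if (cfg$theta_immobility_factor < 0 || cfg$theta_immobility_factor > 1)
    fail("theta_immobility_factor", "must lie in [0, 1]")
  invisible(cfg)
}

# Alternating bout schedule: data frame (start_s, end_s, state); the session
# starts with an immobility bout.
bout_schedule <- function(cfg) {
  sp <- cfg$speed_profile
  durs <- c(sp$immobility_s, sp$locomotion_s)
  states <- c("immobility", "locomotion")
  out <- list(); t0 <- 0; k <- 1L
  while (t0 < cfg$duration_s) {
    d <- durs[(k - 1L) %% 2L + 1L]
    if (d > 0) {
      out[[length(out) + 1L]] <- data.frame(
        start_s = t0, end_s = min(t0 + d, cfg$duration_s),
        state = states[(k - 1L) %% 2L + 1L], stringsAsFactors = FALSE)
      t0 <- t0 + d
    }
    k <- k + 1L
  }
  do.call(rbind, out)
}

# 1 during locomotion, theta_immobility_factor during immobility, per sample.
state_factor <- function(cfg, times_s) {
  sched <- bout_schedule(cfg)
  f <- rep(cfg$theta_immobility_factor, length(times_s))
  for (i in which(sched$state == "locomotion")) {
    sel <- times_s >= sched$start_s[i] & times_s < sched$end_s[i]
    f[sel] <- 1
  }
  f
}

#' 1/f-shaped Gaussian noise
#'
#' Spectrum-shaped white noise: amplitude scaled by f^(-exponent/2), then
#' standardized to the requested SD.
#'
#' @param n number of samples.
#' @param exponent power-spectrum exponent a in 1/f^a.
#' @param sd_target output standard deviation.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, sd_target = 1) {
  if (n < 2L) return(rep(0, n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  # frequency index per FFT bin (two-sided)
  k <- c(seq_len(ceiling(n / 2)), seq.int(floor(n / 2), 1L))[seq_len(n)]
  fidx <- c(0, k[-1])
  scale <- c(0, fidx[-1] ^ (-exponent / 2))
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s * sd_target
  x
}

#' Laminar theta components for a session
#'
#' Channel-by-time matrix of theta oscillations with the per-layer amplitude
#' and phase offsets of `config$layer_profiles`, attenuated during
#' immobility bouts. The reference theta phase (offset 0, degrees, 0 = peak)
#' is attached as attribute `phase_deg`.
#'
#' @param config a `synth_config`.
#' @return channels x time numeric matrix (microvolts) with attributes
#'   `phase_deg`, `times_s` and `channel_ids`.
#' @export
generate_laminar_theta <- function(config) {
  profiles <- config$layer_profiles
  if (is.null(profiles) || !all(c("layer", "theta_amp_uv", "theta_phase_deg")
                                %in% names(profiles)))
    stop("invalid synth_config field 'layer_profiles': missing per-channel profile columns",
         call. = FALSE)
  n <- round(config$duration_s * config$rate_hz)
  times <- (seq_len(n) - 1L) / config$rate_hz
  phase <- 2 * pi * config$theta_freq_hz * times
  fac <- state_factor(config, times)
  n_ch <- config$n_shanks * config$sites_per_shank
  out <- matrix(0, nrow = n_ch, ncol = n)
  for (s in seq_len(config$n_shanks)) {
    for (d in seq_len(config$sites_per_shank)) {
      i <- (s - 1L) * config$sites_per_shank + d
      out[i, ] <- profiles$theta_amp_uv[d] * fac *
        cos(phase + profiles$theta_phase_deg[d] * pi / 180)
    }
  }
  attr(out, "phase_deg") <- (phase * 180 / pi) %% 360
  attr(out, "times_s") <- times
  attr(out, "channel_ids") <- session_channel_ids(config)
  out
}

session_channel_ids <- function(cfg) {
  unlist(lapply(seq_len(cfg$n_shanks), function(s)
    sprintf("s%dd%d", s, seq_len(cfg$sites_per_shank))))
}

session_channel_map <- function(cfg) {
  channel_map(
    channel_id = session_channel_ids(cfg),
    shank = rep(seq_len(cfg$n_shanks), each = cfg$sites_per_shank),
    depth = rep(seq_len(cfg$sites_per_shank), cfg$n_shanks),
    spacing_mm = cfg$site_spacing_mm,
    layer = rep(cfg$layer_profiles$layer, cfg$n_shanks))
}

#' Single-channel theta signal with phase-coupled gamma
#'
#' Test fixture for the coupling analyses: theta at `theta_freq` plus a
#' gamma carrier at the centre of `amp_band` whose envelope is
#' `gamma_amp * (1 + depth * cos(theta_phase - pref_phase))`.
#'
#' @param theta_freq theta frequency, Hz.
#' @param amp_band gamma band (pair, Hz); the carrier sits at its centre.
#' @param pref_phase_deg preferred theta phase of the gamma envelope
#'   (degrees, 0 = theta peak).
#' @param depth modulation depth in \[0, 1\].
#' @param duration_s signal length, seconds.
#' @param rate_hz sampling rate, Hz.
#' @param seed optional seed for the carrier/noise components.
#' @param theta_amp,gamma_amp component amplitudes.
#' @param noise_sd white-noise SD added to the sum (0 = noise-free).
#' @param carrier `"noise"` (default): band-limited Gaussian noise spanning
#'   `amp_band`, realistic broadband gamma whose amplitude survives narrow
#'   analysis windows; `"tone"`: a pure sinusoid at the band centre
#'   (analytically convenient, but a pure tone carries no amplitude
#'   fluctuation inside a sub-band narrower than twice the theta
#'   frequency).
#' @return list: `signal`, `theta`, `gamma`, `envelope` (the imposed
#'   modulation envelope), `theta_phase_deg`, `times_s`, `rate_hz`.
#' @export
synthesize_coupled_oscillation <- function(theta_freq, amp_band, pref_phase_deg,
                                           depth, duration_s, rate_hz,
                                           seed = NULL, theta_amp = 1,
                                           gamma_amp = 0.5, noise_sd = 0,
                                           carrier = c("noise", "tone")) {
  if (depth < 0 || depth > 1)
    stop("modulation depth must lie in [0, 1]", call. = FALSE)
  check_band(amp_band, rate_hz, "amp_band")
  carrier <- match.arg(carrier)
  n <- round(duration_s * rate_hz)
  times <- (seq_len(n) - 1L) / rate_hz
  phase <- 2 * pi * theta_freq * times
  theta <- theta_amp * cos(phase)
  body <- function() {
    car <- if (carrier == "tone") {
      cos(2 * pi * mean(amp_band) * times)
    } else {
      gamma_carrier(n, amp_band, rate_hz)
    }
    env <- gamma_amp * (1 + depth * cos(phase - pref_phase_deg * pi / 180))
    gamma <- env * car
    noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    list(signal = theta + gamma + noise, theta = theta, gamma = gamma,
         envelope = env, theta_phase_deg = (phase * 180 / pi) %% 360,
         times_s = times, rate_hz = rate_hz)
  }
  if (!is.null(seed)) with_seed(seed, body()) else body()
}

# band-limited unit-mean-envelope Gaussian carrier
gamma_carrier <- function(n, band, rate_hz) {
  x <- bandpass(stats::rnorm(n), band, rate_hz)
  x / mean(Mod(analytic_signal(x)))
}

# Hann-windowed event waveforms ---------------------------------------------

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}

# Tukey (tapered-cosine) window: flat top with cosine flanks of total
# fraction `alpha`; fast-ripple bursts need sustained per-cycle amplitude.
tukey_window <- function(n, alpha = 0.4) {
  if (n == 1L) return(1)
  x <- (seq_len(n) - 1L) / (n - 1L)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

fast_ripple_waveform <- function(rate_hz, freq_hz, duration_ms, amp_uv) {
  n <- max(3L, round(duration_ms / 1000 * rate_hz))
  t <- (seq_len(n) - 1L) / rate_hz
  amp_uv * tukey_window(n) * sin(2 * pi * freq_hz * t)
}

ripple_waveform <- function(rate_hz, freq_hz, duration_ms, amp_uv) {
  n <- max(3L, round(duration_ms / 1000 * rate_hz))
  t <- (seq_len(n) - 1L) / rate_hz
  amp_uv * hann_window(n) * sin(2 * pi * freq_hz * t)
}

spw_waveform <- function(rate_hz, duration_ms, amp_uv) {
  n <- max(3L, round(duration_ms / 1000 * rate_hz))
  -amp_uv * hann_window(n)
}

# Add `wave` centred at `center_s` into `x`; errors if outside extent.
add_waveform <- function(x, wave, center_s, rate_hz, t_start_s = 0) {
  n <- length(wave)
  c_idx <- round((center_s - t_start_s) * rate_hz) + 1L
  i0 <- c_idx - n %/% 2L
  i1 <- i0 + n - 1L
  if (i0 < 1L || i1 > length(x))
    stop(sprintf("event at %g s extends outside the signal extent", center_s),
         call. = FALSE)
  x[i0:i1] <- x[i0:i1] + wave
  x
}

#' Inject one sharp-wave-ripple into a channel pair
#'
#' Adds a Hann-windowed ripple-frequency burst to the pyramidale channel and
#' a concurrent inverted-Hann slow deflection to the radiatum channel, both
#' centred at `time_s`. All other samples are untouched.
#'
#' @param signal_pyr,signal_rad numeric vectors (str. pyramidale / str.
#'   radiatum channels), microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param time_s event centre (peak) time, seconds.
#' @param params list: `freq_hz`, `amp_uv`, `duration_ms`, `spw_amp_uv`,
#'   `spw_duration_ms` (amplitudes in microvolts).
#' @param t_start_s time of the first sample.
#' @return list: modified `pyr` and `rad` vectors.
#' @export
inject_swr <- function(signal_pyr, signal_rad, rate_hz, time_s, params,
                       t_start_s = 0) {
  rip <- ripple_waveform(rate_hz, params$freq_hz, params$duration_ms,
                         params$amp_uv)
  spw <- spw_waveform(rate_hz, params$spw_duration_ms, params$spw_amp_uv)
  list(pyr = add_waveform(signal_pyr, rip, time_s, rate_hz, t_start_s),
       rad = add_waveform(signal_rad, spw, time_s, rate_hz, t_start_s))
}

# Uniform placement of event centre times within immobility bouts, keeping
# `margin_s` clear of bout edges and `min_sep_s` between any two centres
# (already-placed times included). Returns as many as can be placed.
place_event_times <- function(n, bouts, margin_s, min_sep_s, occupied = numeric(0)) {
  eff <- pmax(0, (bouts$end_s - bouts$start_s) - 2 * margin_s)
  if (n <= 0 || sum(eff) <= 0) return(numeric(0))
  placed <- numeric(0)
  tries <- 0L
  while (length(placed) < n && tries < 400L * n) {
    tries <- tries + 1L
    u <- stats::runif(1, 0, sum(eff))
    b <- findInterval(u, cumsum(c(0, eff)), rightmost.closed = TRUE)
    b <- min(b, nrow(bouts))
    t0 <- bouts$start_s[b] + margin_s + (u - cumsum(c(0, eff))[b])
    if (all(abs(c(placed, occupied) - t0) >= min_sep_s) ||
        (length(placed) == 0L && length(occupied) == 0L))
      placed <- c(placed, t0)
  }
  sort(placed)
}

# Baseline mean/SD of the smoothed band-limited envelope over immobility
# samples; converts SD-unit amplitudes to microvolts.
baseline_env_stats <- function(x, band, rate_hz, imm_mask, sigma_s) {
  flt <- if (is.null(band)) x else bandpass(x, band, rate_hz)
  env <- smooth_gaussian(Mod(analytic_signal(flt)), sigma_s, rate_hz)
  m <- mean(env[imm_mask]); s <- stats::sd(env[imm_mask])
  # same refined (supra-3SD-excluded) baseline the detectors use
  keep <- imm_mask & (env - m) / s <= 3
  if (sum(keep) >= 2L) {
    m2 <- mean(env[keep]); s2 <- stats::sd(env[keep])
    if (is.finite(s2) && s2 > 0) { m <- m2; s <- s2 }
  }
  list(mean = m, sd = s)
}

# Peak of the smoothed band-limited envelope of a unit-amplitude waveform:
# the gain of the detection chain for this waveform shape. Injected
# amplitudes are divided by this so that "amplitude_sd" refers to the
# envelope the detector actually sees (a sharp-wave bump, for instance,
# has most of its energy below the 4 Hz band edge and would otherwise be
# injected far weaker than its nominal SD value).
waveform_env_gain <- function(wave, band, rate_hz, sigma_s) {
  pad <- numeric(round(0.5 * rate_hz))
  w <- c(pad, wave, pad)
  flt <- if (is.null(band)) w else bandpass(w, band, rate_hz)
  max(smooth_gaussian(Mod(analytic_signal(flt)), sigma_s, rate_hz)) /
    max(abs(wave))
}

#' Generate a synthetic laminar LFP session with ground truth
#'
#' Assembles laminar theta, phase-coupled gamma, 1/f + white noise, and
#' Poisson-placed sharp-wave ripples (plus optional fast ripples, interictal
#' discharges and explicitly requested SWR bursts) during immobility bouts.
#' Event amplitudes are calibrated in baseline-SD units against the
#' pre-injection background so detection thresholds are meaningful.
#'
#' @param config a `synth_config`.
#' @return list: `recording` (`lfp_recording`), `map` (`channel_map`),
#'   `speed` (`speed_trace`), `ground_truth` (event manifest data frame with
#'   a `coupling` attribute), `config`.
#' @export
generate_session <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, {
    rate <- config$rate_hz
    n <- round(config$duration_s * rate)
    times <- (seq_len(n) - 1L) / rate
    sched <- bout_schedule(config)
    imm_bouts <- sched[sched$state == "immobility", , drop = FALSE]
    imm_mask <- rep(FALSE, n)
    for (i in seq_len(nrow(imm_bouts)))
      imm_mask[times >= imm_bouts$start_s[i] & times < imm_bouts$end_s[i]] <- TRUE

    # -- speed trace (50 frames/s by default) --
    sp <- config$speed_profile
    ft <- seq(0, config$duration_s - 1 / sp$frame_rate_hz, by = 1 / sp$frame_rate_hz)
    spd <- numeric(length(ft))
    for (i in seq_len(nrow(sched))) {
      sel <- ft >= sched$start_s[i] & ft < sched$end_s[i]
      if (sched$state[i] == "immobility") {
        spd[sel] <- pmin(1.2, pmax(0, 0.4 + stats::rnorm(sum(sel), 0, 0.15)))
      } else {
        spd[sel] <- pmax(2.5, sp$speed_cm_s + stats::rnorm(sum(sel), 0, 0.5))
      }
    }
    speed <- speed_trace(ft, spd, sp$frame_rate_hz)

    # -- background: theta + coupled gamma + noise --
    theta_mat <- generate_laminar_theta(config)
    phase_rad <- attr(theta_mat, "phase_deg") * pi / 180
    fac <- state_factor(config, times)
    n_ch <- nrow(theta_mat)
    samples <- theta_mat
    layers <- rep(config$layer_profiles$layer, config$n_shanks)
    for (spc in config$coupling_specs) {
      env <- spc$amp_uv * fac *
        (1 + spc$depth * cos(phase_rad - spc$pref_phase_deg * pi / 180))
      g <- env * gamma_carrier(n, spc$band, rate)
      for (i in which(layers == spc$layer)) samples[i, ] <- samples[i, ] + g
    }
    for (i in seq_len(n_ch)) {
      samples[i, ] <- samples[i, ] +
        pink_noise(n, config$noise$pink_exponent, config$noise$pink_sd_uv) +
        stats::rnorm(n, 0, config$noise$white_sd_uv)
    }

    # -- event placement --
    channel_ids <- session_channel_ids(config)
    pyr_idx <- which(layers == "str_pyramidale")
    rad_idx <- which(layers == "str_radiatum")
    per_shank_first <- function(idx) {
      shank_of <- (idx - 1L) %/% config$sites_per_shank + 1L
      idx[!duplicated(shank_of)]
    }
    pyr_ch <- per_shank_first(pyr_idx)
    rad_ch <- per_shank_first(rad_idx)
    t_imm <- sum(imm_bouts$end_s - imm_bouts$start_s)
    want_events <- config$swr_rate_hz > 0 || config$ied_rate_hz > 0 ||
      config$fast_ripple_rate_hz > 0 ||
      config$bursts$doublets > 0 || config$bursts$triplets > 0
    if (want_events && (length(pyr_ch) == 0L))
      stop("invalid synth_config field 'layer_profiles': no str_pyramidale site to host events",
           call. = FALSE)
    if ((config$swr_rate_hz > 0 || config$bursts$doublets > 0 ||
         config$bursts$triplets > 0) && length(rad_ch) == 0L)
      stop("invalid synth_config field 'layer_profiles': no str_radiatum site to host sharp waves",
           call. = FALSE)

    min_sep <- 0.25
    margin <- 0.3
    occupied <- numeric(0)
    gt <- list()

    # amplitude calibration against the pre-injection background (shank 1)
    if (want_events && t_imm > 0) {
      x_pyr <- samples[pyr_ch[1L], ]
      swrp <- config$swr_params
      rip_stats <- baseline_env_stats(x_pyr, c(150, 250), rate, imm_mask, 0.008)
      rip_gain <- waveform_env_gain(
        ripple_waveform(rate, swrp$freq_hz, swrp$duration_ms, 1),
        c(150, 250), rate, 0.008)
      rip_amp_uv <- (rip_stats$mean + swrp$amp_sd * rip_stats$sd) / rip_gain
      spw_amp_uv <- NA_real_
      if (length(rad_ch)) {
        x_rad <- samples[rad_ch[1L], ]
        spw_stats <- baseline_env_stats(x_rad, c(4, 50), rate, imm_mask, 0.010)
        spw_gain <- waveform_env_gain(
          spw_waveform(rate, swrp$spw_duration_ms, 1), c(4, 50), rate, 0.010)
        spw_amp_uv <- (spw_stats$mean + swrp$spw_amp_sd * spw_stats$sd) / spw_gain
      }

      inject_swr_all <- function(t0) {
        prm <- list(freq_hz = swrp$freq_hz, amp_uv = rip_amp_uv,
                    duration_ms = swrp$duration_ms, spw_amp_uv = spw_amp_uv,
                    spw_duration_ms = swrp$spw_duration_ms)
        for (k in seq_along(pyr_ch)) {
          res <- inject_swr(samples[pyr_ch[k], ],
                            samples[rad_ch[min(k, length(rad_ch))], ],
                            rate, t0, prm)
          samples[pyr_ch[k], ] <<- res$pyr
          samples[rad_ch[min(k, length(rad_ch))], ] <<- res$rad
        }
        half <- swrp$duration_ms / 2000
        data.frame(type = "swr", start_s = t0 - half, end_s = t0 + half,
                   peak_s = t0, channel = channel_ids[pyr_ch[1L]],
                   amplitude_sd = swrp$amp_sd, freq_hz = swrp$freq_hz,
                   stringsAsFactors = FALSE)
      }

      # Poisson SWR train
      n_swr <- stats::rpois(1, config$swr_rate_hz * t_imm)
      swr_times <- place_event_times(n_swr, imm_bouts, margin, min_sep, occupied)
      occupied <- c(occupied, swr_times)
      for (t0 in swr_times) gt[[length(gt) + 1L]] <- inject_swr_all(t0)

      # explicit burst groups (doublets/triplets with fixed gaps)
      gap_s <- config$bursts$gap_ms / 1000
      n_groups <- config$bursts$doublets + config$bursts$triplets
      if (n_groups > 0) {
        sizes <- c(rep(2L, config$bursts$doublets), rep(3L, config$bursts$triplets))
        anchors <- place_event_times(n_groups, imm_bouts, margin + 3 * gap_s,
                                     min_sep + 3 * gap_s, occupied)
        for (gidx in seq_along(anchors)) {
          if (gidx > length(sizes)) break
          for (m in seq_len(sizes[gidx])) {
            t0 <- anchors[gidx] + (m - 1L) * gap_s
            occupied <- c(occupied, t0)
            row <- inject_swr_all(t0)
            row$type <- "swr"
            gt[[length(gt) + 1L]] <- row
          }
        }
      }

      # fast ripples
      if (config$fast_ripple_rate_hz > 0) {
        frp <- config$fast_ripple_params
        fr_band <- c(250, min(600, 0.95 * nyquist(rate)))
        # fast-ripple amplitude is calibrated in SD units of the band-passed
        # signal itself (the per-peak criterion's units), not envelope units
        sigma_f <- stats::sd(bandpass(x_pyr, fr_band, rate)[imm_mask])
        fr_amp_uv <- frp$amp_sd * sigma_f
        n_fr <- stats::rpois(1, config$fast_ripple_rate_hz * t_imm)
        fr_times <- place_event_times(n_fr, imm_bouts, margin, min_sep, occupied)
        occupied <- c(occupied, fr_times)
        for (t0 in fr_times) {
          wv <- fast_ripple_waveform(rate, frp$freq_hz, frp$duration_ms, fr_amp_uv)
          for (k in pyr_ch)
            samples[k, ] <- add_waveform(samples[k, ], wv, t0, rate)
          half <- frp$duration_ms / 2000
          gt[[length(gt) + 1L]] <- data.frame(
            type = "fast_ripple", start_s = t0 - half, end_s = t0 + half,
            peak_s = t0, channel = channel_ids[pyr_ch[1L]],
            amplitude_sd = frp$amp_sd, freq_hz = frp$freq_hz,
            stringsAsFactors = FALSE)
        }
      }

      # interictal discharges
      if (config$ied_rate_hz > 0) {
        iep <- config$ied_params
        raw_stats <- baseline_env_stats(x_pyr, NULL, rate, imm_mask, 0.010)
        filt_stats <- baseline_env_stats(x_pyr, c(60, 80), rate, imm_mask, 0.010)
        ied_wave <- ripple_waveform(rate, iep$freq_hz, iep$duration_ms, 1)
        ied_gain_raw <- waveform_env_gain(ied_wave, NULL, rate, 0.010)
        ied_gain_filt <- waveform_env_gain(ied_wave, c(60, 80), rate, 0.010)
        # satisfy both the raw- and filtered-envelope criteria at amp_sd
        ied_amp_uv <- max(
          (raw_stats$mean + iep$amp_sd * raw_stats$sd) / ied_gain_raw,
          (filt_stats$mean + iep$amp_sd * filt_stats$sd) / ied_gain_filt)
        n_ied <- stats::rpois(1, config$ied_rate_hz * t_imm)
        ied_times <- place_event_times(n_ied, imm_bouts, margin, min_sep, occupied)
        occupied <- c(occupied, ied_times)
        for (t0 in ied_times) {
          wv <- ripple_waveform(rate, iep$freq_hz, iep$duration_ms, ied_amp_uv)
          for (k in pyr_ch)
            samples[k, ] <- add_waveform(samples[k, ], wv, t0, rate)
          half <- iep$duration_ms / 2000
          gt[[length(gt) + 1L]] <- data.frame(
            type = "ied", start_s = t0 - half, end_s = t0 + half,
            peak_s = t0, channel = channel_ids[pyr_ch[1L]],
            amplitude_sd = iep$amp_sd, freq_hz = iep$freq_hz,
            stringsAsFactors = FALSE)
        }
      }
    }

    ground_truth <- if (length(gt)) {
      g <- do.call(rbind, gt)
      g <- g[order(g$peak_s), , drop = FALSE]
      rownames(g) <- NULL
      g
    } else {
      data.frame(type = character(0), start_s = numeric(0), end_s = numeric(0),
                 peak_s = numeric(0), channel = character(0),
                 amplitude_sd = numeric(0), freq_hz = numeric(0),
                 stringsAsFactors = FALSE)
    }
    attr(ground_truth, "coupling") <- do.call(rbind, lapply(
      config$coupling_specs, function(spc) data.frame(
        band_low_hz = spc$band[1], band_high_hz = spc$band[2],
        pref_phase_deg = spc$pref_phase_deg, depth = spc$depth,
        layer = spc$layer, stringsAsFactors = FALSE)))
    attr(ground_truth, "immobility") <- imm_bouts[, c("start_s", "end_s")]

    rec <- lfp_recording(samples, rate, channel_ids)
    list(recording = rec, map = session_channel_map(config), speed = speed,
         ground_truth = ground_truth, config = config)
  })
}
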