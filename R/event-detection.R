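# Immobility segmentation and envelope-threshold event detectors: ripples,
# sharp waves, SWR pairing, burst classification, fast ripples, interictal
# discharges, and per-event/per-session features.

#' Detection parameters
#'
#' All thresholds of the event detectors with their standard defaults:
#' ripples 150-250 Hz, 3 SD for >= 15 ms, boundaries at 1 SD, merge gap
#' 40 ms; sharp waves 4-50 Hz, 2.5 SD, 20-400 ms; bursts chained within
#' 200 ms; fast ripples 250-600 Hz, 5 SD, >= 6 peaks each > 5 SD, with the
#' 75-125 Hz spectral-dominance check; IEDs 60-80 Hz, 5 SD filtered AND
#' 5 SD raw; immobility below 1.5 cm/s for > 20 s with low theta.
#'
#' @param ... overrides for any default listed above (see argument list).
#' @param ripple_band,ripple_thresh_sd,ripple_min_ms,boundary_sd,merge_gap_ms
#'   ripple detector settings.
#' @param spw_band,spw_thresh_sd,spw_min_ms,spw_max_ms sharp-wave settings.
#' @param burst_window_ms peak-to-peak chaining window for bursts.
#' @param fr_band,fr_thresh_sd,fr_min_peaks,fr_peak_sd,fr_ref_band
#'   fast-ripple settings.
#' @param ied_band,ied_filt_sd,ied_raw_sd IED settings.
#' @param immobility_speed_cm_s,immobility_min_s,low_theta_ratio immobility
#'   segmentation settings (theta/delta power ratio must stay below
#'   `low_theta_ratio`).
#' @param immobility_max_gap_s brief criterion violations up to this long
#'   are bridged when building immobility periods (sustained-state
#'   segmentation).
#' @param immobility_ratio_window_s smoothing window for the theta/delta
#'   ratio used in immobility segmentation, seconds.
#' @param ripple_smooth_s,slow_smooth_s Gaussian envelope smoothing sigma in
#'   seconds for fast (ripple/fast-ripple) and slow (SPW/IED/raw) bands.
#' @return a validated `detection_params` list.
#' @export
detection_params <- function(ripple_band = c(150, 250), ripple_thresh_sd = 3,
                             ripple_min_ms = 15, boundary_sd = 1,
                             merge_gap_ms = 40,
                             spw_band = c(4, 50), spw_thresh_sd = 2.5,
                             spw_min_ms = 20, spw_max_ms = 400,
                             burst_window_ms = 200,
                             fr_band = c(250, 600), fr_thresh_sd = 5,
                             fr_min_peaks = 6, fr_peak_sd = 5,
                             fr_ref_band = c(75, 125),
                             ied_band = c(60, 80), ied_filt_sd = 5,
                             ied_raw_sd = 5,
                             immobility_speed_cm_s = 1.5,
                             immobility_min_s = 20, low_theta_ratio = 2,
                             immobility_max_gap_s = 2,
                             immobility_ratio_window_s = 10,
                             ripple_smooth_s = 0.008, slow_smooth_s = 0.010,
                             ...) {
  extra <- list(...)
  if (length(extra))
    stop(sprintf("unknown detection parameter(s): %s",
                 paste(names(extra), collapse = ", ")), call. = FALSE)
  p <- as.list(environment())
  p$extra <- NULL
  for (b in c("ripple_band", "spw_band", "fr_band", "fr_ref_band", "ied_band"))
    if (p[[b]][1] >= p[[b]][2] || p[[b]][1] <= 0)
      stop(sprintf("%s must satisfy 0 < low < high", b), call. = FALSE)
  for (th in c("ripple_thresh_sd", "spw_thresh_sd", "fr_thresh_sd",
               "fr_peak_sd", "ied_filt_sd", "ied_raw_sd", "boundary_sd"))
    if (p[[th]] <= 0) stop(sprintf("%s must be > 0", th), call. = FALSE)
  for (d in c("ripple_min_ms", "spw_min_ms", "spw_max_ms", "immobility_min_s"))
    if (p[[d]] <= 0) stop(sprintf("%s must be > 0", d), call. = FALSE)
  structure(p, class = "detection_params")
}

# immobility periods as a data.frame(start_s, end_s)
empty_periods <- function() data.frame(start_s = numeric(0), end_s = numeric(0))

#' Find immobility periods
#'
#' Maximal intervals in which running speed stays below the immobility
#' threshold and (when a theta/delta ratio is supplied) theta is low, each
#' lasting at least the minimum duration.
#'
#' @param speed a [speed_trace()].
#' @param theta_ratio optional numeric vector of theta/delta power ratios
#'   aligned sample-for-sample with `speed$times_s` (see
#'   [theta_delta_ratio()]); `NULL` skips the low-theta criterion.
#' @param params a [detection_params()].
#' @return data frame with `start_s`, `end_s`, sorted by start.
#' @export
find_immobility_periods <- function(speed, theta_ratio = NULL,
                                    params = detection_params()) {
  if (length(speed$times_s) == 0L)
    stop("empty speed trace", call. = FALSE)
  mask <- speed$speed_cm_s < params$immobility_speed_cm_s
  if (!is.null(theta_ratio)) {
    if (length(theta_ratio) != length(speed$times_s))
      stop("theta_ratio must align with the speed trace", call. = FALSE)
    mask <- mask & (theta_ratio < params$low_theta_ratio)
  }
  # bridge brief criterion violations (sustained-state segmentation)
  max_gap <- round(params$immobility_max_gap_s * speed$frame_rate_hz)
  if (max_gap > 0L && any(mask) && !all(mask)) {
    gaps <- runs_from_mask(!mask)
    for (k in seq_len(nrow(gaps))) {
      len <- gaps[k, "end"] - gaps[k, "start"] + 1L
      interior <- gaps[k, "start"] > 1L && gaps[k, "end"] < length(mask)
      if (interior && len <= max_gap) mask[gaps[k, "start"]:gaps[k, "end"]] <- TRUE
    }
  }
  runs <- runs_from_mask(mask)
  if (nrow(runs) == 0L) return(empty_periods())
  dt <- 1 / speed$frame_rate_hz
  start_s <- speed$times_s[runs[, "start"]]
  end_s <- speed$times_s[runs[, "end"]] + dt
  keep <- (end_s - start_s) >= params$immobility_min_s
  out <- data.frame(start_s = start_s[keep], end_s = end_s[keep])
  out[order(out$start_s), , drop = FALSE]
}

#' Theta/delta power ratio aligned to a time grid
#'
#' Band-passed power (squared signal smoothed over a sliding window) in the
#' theta (6-10 Hz) and delta (1-4 Hz) bands; the ratio is evaluated at
#' `at_times_s` (e.g. the speed-trace frames).
#'
#' @param x single-channel LFP, microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param at_times_s times at which to report the ratio (default: every
#'   sample).
#' @param theta_band,delta_band frequency bands, Hz.
#' @param window_s smoothing window (Gaussian sigma = window/4), seconds.
#' @param t_start_s time of the first sample.
#' @return numeric vector of ratios at `at_times_s`.
#' @export
theta_delta_ratio <- function(x, rate_hz, at_times_s = NULL,
                              theta_band = c(6, 10), delta_band = c(1, 4),
                              window_s = 1, t_start_s = 0) {
  th <- bandpass(x, theta_band, rate_hz)
  de <- bandpass(x, delta_band, rate_hz)
  pw_th <- smooth_gaussian(th ^ 2, window_s / 4, rate_hz)
  pw_de <- smooth_gaussian(de ^ 2, window_s / 4, rate_hz)
  ratio <- pw_th / pmax(pw_de, .Machine$double.eps)
  if (is.null(at_times_s)) return(ratio)
  tt <- t_start_s + (seq_along(x) - 1L) / rate_hz
  stats::approx(tt, ratio, xout = at_times_s, rule = 2)$y
}

periods_to_mask <- function(periods, n, rate_hz, t_start_s = 0) {
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(periods))) {
    i0 <- max(1L, floor((periods$start_s[i] - t_start_s) * rate_hz) + 1L)
    i1 <- min(n, ceiling((periods$end_s[i] - t_start_s) * rate_hz))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

#' Band-limited envelope in baseline-SD units
#'
#' Band-pass filters the signal, takes the magnitude of the analytic
#' signal, smooths it with a Gaussian kernel, and standardizes it by the
#' mean and SD computed over the concatenated baseline periods. The
#' baseline statistics are computed iteratively: a provisional
#' standardization is refined once after excluding samples more than 3
#' provisional SD above baseline, so that the events to be detected do not
#' inflate their own detection units (on an event-free signal the second
#' pass changes almost nothing).
#'
#' @param x single-channel signal.
#' @param band frequency band (pair, Hz) or `NULL` for the raw (unfiltered)
#'   envelope.
#' @param rate_hz sampling rate, Hz.
#' @param baseline_periods data frame (`start_s`, `end_s`) of baseline
#'   intervals (typically the immobility periods).
#' @param smooth_sigma_s Gaussian smoothing sigma, seconds.
#' @param t_start_s time of the first sample.
#' @return list: `filtered` (band-passed signal), `envelope` (SD units,
#'   same length as `x`), `baseline_mean`, `baseline_sd` (microvolts).
#' @export
envelope_sd <- function(x, band, rate_hz, baseline_periods,
                        smooth_sigma_s = 0.004, t_start_s = 0) {
  if (nrow(baseline_periods) == 0L)
    stop("baseline_periods must be non-empty", call. = FALSE)
  flt <- if (is.null(band)) x else bandpass(x, band, rate_hz)
  env <- smooth_gaussian(Mod(analytic_signal(flt)), smooth_sigma_s, rate_hz)
  mask <- periods_to_mask(baseline_periods, length(x), rate_hz, t_start_s)
  if (!any(mask)) stop("baseline periods cover no samples", call. = FALSE)
  m <- mean(env[mask]); s <- stats::sd(env[mask])
  if (!is.finite(s) || s == 0)
    stop("degenerate baseline: zero envelope variance", call. = FALSE)
  keep <- mask & (env - m) / s <= 3
  if (sum(keep) >= 2L) {
    m2 <- mean(env[keep]); s2 <- stats::sd(env[keep])
    if (is.finite(s2) && s2 > 0) { m <- m2; s <- s2 }
  }
  list(filtered = flt, envelope = (env - m) / s, baseline_mean = m,
       baseline_sd = s)
}

# Core run detection within one index range of an SD-unit envelope:
# supra-threshold runs >= min_samples, boundaries extended to boundary_sd
# crossings, events with gaps < merge_gap merged.
detect_in_segment <- function(env, i0, i1, thresh, boundary, min_samples,
                              merge_gap_samples) {
  seg <- env[i0:i1]
  cores <- runs_from_mask(seg > thresh)
  if (nrow(cores) > 0L)
    cores <- cores[(cores[, "end"] - cores[, "start"] + 1L) >= min_samples, ,
                   drop = FALSE]
  if (nrow(cores) == 0L)
    return(cbind(start = integer(0), end = integer(0), core_len = integer(0)))
  above_b <- seg > boundary
  ev <- t(apply(cores, 1L, function(r) {
    a <- r[["start"]]; b <- r[["end"]]
    while (a > 1L && above_b[a - 1L]) a <- a - 1L
    while (b < length(seg) && above_b[b + 1L]) b <- b + 1L
    c(a, b)
  }))
  core_len <- cores[, "end"] - cores[, "start"] + 1L
  # extension can make events overlap or nearly touch: merge gaps < merge_gap
  ord <- order(ev[, 1L])
  ev <- ev[ord, , drop = FALSE]; core_len <- core_len[ord]
  merged <- list(); cur <- ev[1L, ]; cur_core <- core_len[1L]
  if (nrow(ev) > 1L) for (k in 2L:nrow(ev)) {
    gap <- ev[k, 1L] - cur[2L] - 1L
    if (gap < merge_gap_samples) {
      cur[2L] <- max(cur[2L], ev[k, 2L])
      cur_core <- max(cur_core, core_len[k])
    } else {
      merged[[length(merged) + 1L]] <- c(cur, cur_core)
      cur <- ev[k, ]; cur_core <- core_len[k]
    }
  }
  merged[[length(merged) + 1L]] <- c(cur, cur_core)
  out <- do.call(rbind, merged)
  cbind(start = out[, 1L] + i0 - 1L, end = out[, 2L] + i0 - 1L,
        core_len = out[, 3L])
}

segment_indices <- function(periods, n, rate_hz, t_start_s) {
  lapply(seq_len(nrow(periods)), function(i) {
    i0 <- max(1L, floor((periods$start_s[i] - t_start_s) * rate_hz) + 1L)
    i1 <- min(n, ceiling((periods$end_s[i] - t_start_s) * rate_hz))
    c(i0, i1)
  })
}

#' Detect ripple events
#'
#' Ripple candidates are intervals, inside immobility periods, where the
#' smoothed 150-250 Hz envelope exceeds 3 SD above baseline for at least
#' 15 ms; boundaries are extended to the surrounding 1 SD crossings and
#' events closer than 40 ms are combined.
#'
#' @param lfp_pyr single-channel LFP from str. pyramidale, microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param immobility immobility periods (`start_s`, `end_s`); also used as
#'   the envelope baseline.
#' @param params a [detection_params()].
#' @param t_start_s time of the first sample.
#' @return data frame of events: `start_s`, `end_s`, `peak_s`,
#'   `peak_power_sd`, `duration_ms`.
#' @export
detect_ripples <- function(lfp_pyr, rate_hz, immobility,
                           params = detection_params(), t_start_s = 0) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), peak_power_sd = numeric(0),
                      duration_ms = numeric(0))
  if (nrow(immobility) == 0L) {
    warning("no immobility periods: no ripples can be detected")
    return(empty)
  }
  es <- envelope_sd(lfp_pyr, params$ripple_band, rate_hz, immobility,
                    params$ripple_smooth_s, t_start_s)
  detect_events_envelope(es$envelope, rate_hz, immobility,
                         thresh = params$ripple_thresh_sd,
                         boundary = params$boundary_sd,
                         min_ms = params$ripple_min_ms,
                         merge_gap_ms = params$merge_gap_ms,
                         t_start_s = t_start_s)
}

# shared envelope-run detector used by ripple and fast-ripple stages
detect_events_envelope <- function(env, rate_hz, periods, thresh, boundary,
                                   min_ms, merge_gap_ms, t_start_s = 0) {
  min_samples <- max(1L, round(min_ms / 1000 * rate_hz))
  gap_samples <- round(merge_gap_ms / 1000 * rate_hz)
  rows <- list()
  for (si in segment_indices(periods, length(env), rate_hz, t_start_s)) {
    if (si[2L] <= si[1L]) next
    ev <- detect_in_segment(env, si[1L], si[2L], thresh, boundary,
                            min_samples, gap_samples)
    for (k in seq_len(nrow(ev))) {
      a <- ev[k, "start"]; b <- ev[k, "end"]
      pk <- a + which.max(env[a:b]) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = t_start_s + (a - 1L) / rate_hz,
        end_s = t_start_s + b / rate_hz,
        peak_s = t_start_s + (pk - 1L) / rate_hz,
        peak_power_sd = env[pk],
        duration_ms = (b - a + 1L) / rate_hz * 1000)
    }
  }
  if (!length(rows))
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), peak_power_sd = numeric(0),
                      duration_ms = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$start_s), , drop = FALSE]
}

#' Detect sharp-wave events
#'
#' Candidates are supra-threshold spans of the smoothed 4-50 Hz envelope
#' (2.5 SD above baseline) in str. radiatum during immobility whose
#' duration lies in the 20-400 ms window.
#'
#' @param lfp_rad single-channel LFP from str. radiatum, microvolts.
#' @inheritParams detect_ripples
#' @return data frame: `start_s`, `end_s`, `peak_s`, `amplitude_sd`,
#'   `duration_ms`.
#' @export
detect_spws <- function(lfp_rad, rate_hz, immobility,
                        params = detection_params(), t_start_s = 0) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), amplitude_sd = numeric(0),
                      duration_ms = numeric(0))
  if (nrow(immobility) == 0L) {
    warning("no immobility periods: no sharp waves can be detected")
    return(empty)
  }
  es <- envelope_sd(lfp_rad, params$spw_band, rate_hz, immobility,
                    params$slow_smooth_s, t_start_s)
  env <- es$envelope
  rows <- list()
  min_samples <- max(1L, round(params$spw_min_ms / 1000 * rate_hz))
  max_samples <- round(params$spw_max_ms / 1000 * rate_hz)
  for (si in segment_indices(immobility, length(env), rate_hz, t_start_s)) {
    if (si[2L] <= si[1L]) next
    runs <- runs_from_mask(env[si[1L]:si[2L]] > params$spw_thresh_sd)
    for (k in seq_len(nrow(runs))) {
      len <- runs[k, "end"] - runs[k, "start"] + 1L
      if (len < min_samples || len > max_samples) next
      a <- runs[k, "start"] + si[1L] - 1L
      b <- runs[k, "end"] + si[1L] - 1L
      pk <- a + which.max(env[a:b]) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = t_start_s + (a - 1L) / rate_hz,
        end_s = t_start_s + b / rate_hz,
        peak_s = t_start_s + (pk - 1L) / rate_hz,
        amplitude_sd = env[pk],
        duration_ms = len / rate_hz * 1000)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$start_s), , drop = FALSE]
}

interval_overlap <- function(a0, a1, b0, b1) pmax(0, pmin(a1, b1) - pmax(a0, b0))

#' Pair ripples with sharp waves into SWR events
#'
#' A sharp-wave ripple is a ripple (str. pyramidale) whose interval
#' overlaps at least one sharp wave (str. radiatum); ties go to the sharp
#' wave with maximal temporal overlap. Unpaired events on either side are
#' discarded.
#'
#' @param ripples output of [detect_ripples()] (optionally with features).
#' @param spws output of [detect_spws()].
#' @param params a [detection_params()] (unused by the default rule, kept
#'   for interface stability).
#' @return data frame with the ripple columns plus `spw_start_s`,
#'   `spw_end_s`, `spw_amplitude_sd`.
#' @export
pair_swr <- function(ripples, spws, params = detection_params()) {
  if (nrow(ripples) == 0L || nrow(spws) == 0L) {
    out <- ripples[integer(0), , drop = FALSE]
    out$spw_start_s <- numeric(0); out$spw_end_s <- numeric(0)
    out$spw_amplitude_sd <- numeric(0)
    return(out)
  }
  rows <- list()
  for (i in seq_len(nrow(ripples))) {
    ov <- interval_overlap(ripples$start_s[i], ripples$end_s[i],
                           spws$start_s, spws$end_s)
    if (max(ov) <= 0) next
    j <- which.max(ov)
    r <- ripples[i, , drop = FALSE]
    r$spw_start_s <- spws$start_s[j]
    r$spw_end_s <- spws$end_s[j]
    r$spw_amplitude_sd <- spws$amplitude_sd[j]
    rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows)) {
    out <- ripples[integer(0), , drop = FALSE]
    out$spw_start_s <- numeric(0); out$spw_end_s <- numeric(0)
    out$spw_amplitude_sd <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify SWRs into singlets, doublets, triplets and higher-order bursts
#'
#' Events are chained whenever consecutive peak times are within the burst
#' window (200 ms); chain sizes 1/2/3/>3 are labelled singlet, doublet,
#' triplet, higher. Every event belongs to exactly one group.
#'
#' @param swrs data frame with a `peak_s` column, sorted by peak time.
#' @param params a [detection_params()].
#' @return list: `groups` (data frame `group_id`, `kind`, `n_members`,
#'   `first_peak_s`, `last_peak_s`) and `membership` (group id per event).
#' @export
classify_bursts <- function(swrs, params = detection_params()) {
  n <- nrow(swrs)
  if (n == 0L)
    return(list(groups = data.frame(group_id = integer(0), kind = character(0),
                                    n_members = integer(0),
                                    first_peak_s = numeric(0),
                                    last_peak_s = numeric(0)),
                membership = integer(0)))
  peaks <- swrs$peak_s
  if (is.unsorted(peaks)) stop("swrs must be sorted by peak_s", call. = FALSE)
  win <- params$burst_window_ms / 1000
  membership <- integer(n)
  gid <- 1L
  membership[1L] <- gid
  for (i in seq_len(n - 1L)) {
    if (peaks[i + 1L] - peaks[i] > win) gid <- gid + 1L
    membership[i + 1L] <- gid
  }
  sizes <- tabulate(membership)
  kind <- ifelse(sizes == 1L, "singlet",
                 ifelse(sizes == 2L, "doublet",
                        ifelse(sizes == 3L, "triplet", "higher")))
  mf <- factor(membership, levels = seq_along(sizes))
  groups <- data.frame(
    group_id = seq_along(sizes), kind = kind, n_members = sizes,
    first_peak_s = as.numeric(tapply(peaks, mf, min)),
    last_peak_s = as.numeric(tapply(peaks, mf, max)), row.names = NULL,
    stringsAsFactors = FALSE)
  list(groups = groups, membership = membership)
}

#' Per-event ripple features
#'
#' Fills spectral features for each ripple: peak frequency as the argmax of
#' Morlet wavelet power (150-250 Hz bank) at the event peak, and the cycle
#' count as the number of positive band-passed oscillation peaks inside the
#' event exceeding 25% of the event maximum.
#'
#' @param events ripple events from [detect_ripples()].
#' @param lfp_pyr the source channel, microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param params a [detection_params()].
#' @param t_start_s time of the first sample.
#' @param bank_n number of wavelet centres spanning the ripple band
#'   (default 51, a 2 Hz step over 150-250 Hz).
#' @return `events` with `peak_freq_hz` and `n_cycles` columns added.
#' @export
ripple_features <- function(events, lfp_pyr, rate_hz,
                            params = detection_params(), t_start_s = 0,
                            bank_n = 51) {
  events$peak_freq_hz <- rep(NA_real_, nrow(events))
  events$n_cycles <- rep(NA_integer_, nrow(events))
  if (nrow(events) == 0L) return(events)
  bank <- make_bank(params$ripple_band[1], params$ripple_band[2], bank_n,
                    n_cycles = 6, rate_hz = rate_hz)
  flt <- bandpass(lfp_pyr, params$ripple_band, rate_hz)
  pad_s <- 0.25
  n <- length(lfp_pyr)
  for (i in seq_len(nrow(events))) {
    i0 <- floor((events$start_s[i] - t_start_s) * rate_hz) + 1L
    i1 <- ceiling((events$end_s[i] - t_start_s) * rate_hz)
    if (i0 < 1L || i1 > n)
      stop(sprintf("event at %g s lies outside the signal span",
                   events$start_s[i]), call. = FALSE)
    p0 <- max(1L, i0 - round(pad_s * rate_hz))
    p1 <- min(n, i1 + round(pad_s * rate_hz))
    tf <- wavelet_transform(lfp_pyr[p0:p1], bank)
    pk <- round((events$peak_s[i] - t_start_s) * rate_hz) + 1L - p0 + 1L
    pk <- min(max(pk, 1L), ncol(tf$power))
    events$peak_freq_hz[i] <- bank$center_freqs_hz[which.max(tf$power[, pk])]
    seg <- flt[i0:i1]
    events$n_cycles[i] <- count_oscillation_peaks(seg, 0.25)
  }
  events
}

# positive-going local maxima above frac * max(|segment|)
count_oscillation_peaks <- function(seg, frac = 0.25, min_height = NULL) {
  if (length(seg) < 3L) return(0L)
  thr <- if (is.null(min_height)) frac * max(abs(seg)) else min_height
  d <- diff(seg)
  pk <- which(d[-length(d)] > 0 & d[-1L] <= 0) + 1L
  sum(seg[pk] > thr)
}

#' Detect fast ripples (pathological >250 Hz oscillations)
#'
#' Candidates are supra-5 SD spans of the smoothed fast-ripple-band
#' envelope during immobility; an event must contain at least six filtered
#' oscillation peaks each above 5 SD of the band-passed baseline, and its
#' peak spectral power above 200 Hz must exceed the peak power in the
#' 75-125 Hz reference band. The nominal 250-600 Hz band is truncated at
#' 95% of Nyquist when the sampling rate cannot represent it.
#'
#' @inheritParams detect_ripples
#' @param allow_band_truncation permit silently truncating the band upper
#'   edge to 0.95 x Nyquist (default TRUE, with a warning).
#' @return data frame: `start_s`, `end_s`, `peak_s`, `peak_amplitude_sd`,
#'   with attribute `candidates` logging the four criteria per candidate.
#' @export
detect_fast_ripples <- function(lfp_pyr, rate_hz, immobility,
                                params = detection_params(), t_start_s = 0,
                                allow_band_truncation = TRUE) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), peak_amplitude_sd = numeric(0))
  if (nrow(immobility) == 0L) {
    warning("no immobility periods: no fast ripples can be detected")
    return(empty)
  }
  band <- params$fr_band
  if (band[2] >= nyquist(rate_hz)) {
    if (!allow_band_truncation)
      stop(sprintf("fast-ripple band upper edge %g Hz exceeds Nyquist %g Hz",
                   band[2], nyquist(rate_hz)), call. = FALSE)
    band <- c(band[1], 0.95 * nyquist(rate_hz))
    warning(sprintf("fast-ripple band truncated to %g-%g Hz at this rate",
                    band[1], band[2]))
    if (band[2] <= band[1])
      stop("sampling rate too low for any fast-ripple band", call. = FALSE)
  }
  es <- envelope_sd(lfp_pyr, band, rate_hz, immobility,
                    params$ripple_smooth_s, t_start_s)
  # SD units for the filtered trace itself (for the per-peak criterion)
  flt_sd <- es$filtered / stats::sd(
    es$filtered[periods_to_mask(immobility, length(lfp_pyr), rate_hz, t_start_s)])
  cand <- detect_events_envelope(es$envelope, rate_hz, immobility,
                                 thresh = params$fr_thresh_sd,
                                 boundary = params$boundary_sd,
                                 min_ms = 1, merge_gap_ms = 10,
                                 t_start_s = t_start_s)
  log <- list(); rows <- list()
  n <- length(lfp_pyr)
  for (i in seq_len(nrow(cand))) {
    i0 <- max(1L, floor((cand$start_s[i] - t_start_s) * rate_hz) + 1L)
    i1 <- min(n, ceiling((cand$end_s[i] - t_start_s) * rate_hz))
    seg <- flt_sd[i0:i1]
    n_pk <- count_oscillation_peaks(seg, min_height = params$fr_peak_sd)
    # spectral dominance on the raw segment (padded for resolution)
    p0 <- max(1L, i0 - round(0.05 * rate_hz))
    p1 <- min(n, i1 + round(0.05 * rate_hz))
    raw <- lfp_pyr[p0:p1] - mean(lfp_pyr[p0:p1])
    spec <- Mod(stats::fft(raw * hann_window(length(raw)))) ^ 2
    freqs <- (seq_along(spec) - 1L) * rate_hz / length(spec)
    hi <- freqs > 200 & freqs < nyquist(rate_hz)
    ref <- freqs >= params$fr_ref_band[1] & freqs <= params$fr_ref_band[2]
    dom <- any(hi) && any(ref) && max(spec[hi]) > max(spec[ref])
    ok_env <- TRUE   # candidate came from the supra-threshold envelope scan
    ok_pk <- n_pk >= params$fr_min_peaks
    log[[length(log) + 1L]] <- data.frame(
      start_s = cand$start_s[i], envelope_supra = ok_env,
      n_peaks = n_pk, enough_peaks = ok_pk, spectral_dominance = dom)
    if (ok_pk && dom)
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = cand$start_s[i], end_s = cand$end_s[i],
        peak_s = cand$peak_s[i], peak_amplitude_sd = cand$peak_power_sd[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "candidates") <- if (length(log)) do.call(rbind, log) else NULL
  out
}

#' Detect interictal epileptiform discharges (IEDs)
#'
#' Events must satisfy both criteria: the smoothed 60-80 Hz envelope
#' exceeds 5 SD above baseline AND the smoothed raw (unfiltered) envelope
#' exceeds 5 SD above baseline within the event.
#'
#' @inheritParams detect_ripples
#' @return data frame: `start_s`, `end_s`, `peak_s`, `peak_amplitude_sd`
#'   (raw-envelope SD at the peak).
#' @export
detect_ieds <- function(lfp_pyr, rate_hz, immobility,
                        params = detection_params(), t_start_s = 0) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_s = numeric(0), peak_amplitude_sd = numeric(0))
  if (nrow(immobility) == 0L) {
    warning("no immobility periods: no IEDs can be detected")
    return(empty)
  }
  es_f <- envelope_sd(lfp_pyr, params$ied_band, rate_hz, immobility,
                      params$slow_smooth_s, t_start_s)
  es_r <- envelope_sd(lfp_pyr, NULL, rate_hz, immobility,
                      params$slow_smooth_s, t_start_s)
  cand <- detect_events_envelope(es_f$envelope, rate_hz, immobility,
                                 thresh = params$ied_filt_sd,
                                 boundary = params$boundary_sd,
                                 min_ms = 1, merge_gap_ms = 10,
                                 t_start_s = t_start_s)
  rows <- list()
  n <- length(lfp_pyr)
  for (i in seq_len(nrow(cand))) {
    i0 <- max(1L, floor((cand$start_s[i] - t_start_s) * rate_hz) + 1L)
    i1 <- min(n, ceiling((cand$end_s[i] - t_start_s) * rate_hz))
    raw_max <- max(es_r$envelope[i0:i1])
    if (raw_max > params$ied_raw_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = cand$start_s[i], end_s = cand$end_s[i],
        peak_s = cand$peak_s[i], peak_amplitude_sd = raw_max)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' SWR incidence
#'
#' Event count divided by total immobility time.
#'
#' @param swrs paired SWR events.
#' @param immobility immobility periods (`start_s`, `end_s`).
#' @return events per second.
#' @export
swr_incidence <- function(swrs, immobility) {
  total <- sum(immobility$end_s - immobility$start_s)
  if (!is.finite(total) || total <= 0)
    stop("total immobility time must be > 0", call. = FALSE)
  nrow(swrs) / total
}

#' Correlation between sharp-wave amplitude and ripple power
#'
#' Pearson correlation over events of the per-event SPW amplitude (SD) and
#' ripple peak power (SD).
#'
#' @param swrs paired SWR events with `spw_amplitude_sd` and
#'   `peak_power_sd`.
#' @return correlation coefficient in \[-1, 1\].
#' @export
spw_ripple_correlation <- function(swrs) {
  if (nrow(swrs) < 3L)
    stop("need at least 3 SWR events for a correlation", call. = FALSE)
  stats::cor(swrs$spw_amplitude_sd, swrs$peak_power_sd, method = "pearson")
}
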