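# Theta cycle extraction with linear phase interpolation, current source
# density, gamma-amplitude-by-theta-phase profiles, and the theta-gamma
# modulation index.

#' Extract theta cycles with linearly interpolated phase
#'
#' Within each epoch the signal is band-passed broadly (1-40 Hz) and in the
#' theta band (6-10 Hz); zero crossings of the theta-filtered signal anchor
#' alternating peak/trough search windows, extrema of the broad-band signal
#' localize each peak and trough, and phase is interpolated linearly from
#' 0 deg at a cycle-starting peak through 180 deg at the trough to 360 deg
#' at the next peak.
#'
#' @param x single-channel LFP (str. pyramidale reference), microvolts.
#' @param rate_hz sampling rate, Hz.
#' @param epochs theta epochs (`start_s`, `end_s`); cycles never span an
#'   epoch boundary. Epochs shorter than one theta period are skipped.
#' @param broad_band,theta_band filter bands, Hz.
#' @param t_start_s time of the first sample.
#' @return a `theta_cycles` object: `cycles` (data frame `peak_start_s`,
#'   `trough_s`, `peak_end_s`), `phase_deg` (per-sample phase in \[0, 360),
#'   NA outside cycles), `rate_hz`, `t_start_s`, `epochs`.
#' @export
extract_theta_cycles <- function(x, rate_hz, epochs, broad_band = c(1, 40),
                                 theta_band = c(6, 10), t_start_s = 0) {
  broad <- bandpass(x, broad_band, rate_hz)
  theta <- bandpass(x, theta_band, rate_hz)
  n <- length(x)
  phase <- rep(NA_real_, n)
  cyc <- list()
  min_len <- ceiling(rate_hz / theta_band[1])
  for (si in segment_indices(epochs, n, rate_hz, t_start_s)) {
    i0 <- si[1L]; i1 <- si[2L]
    if (i1 - i0 + 1L < min_len) {
      message(sprintf("theta epoch at %.2f s shorter than one theta period: skipped",
                      t_start_s + (i0 - 1L) / rate_hz))
      next
    }
    th <- theta[i0:i1]
    up <- which(th[-length(th)] < 0 & th[-1L] >= 0)
    dn <- which(th[-length(th)] >= 0 & th[-1L] < 0)
    if (length(up) == 0L || length(dn) == 0L) next
    # peaks: broad-band maxima between an up- and the next down-crossing;
    # troughs: minima between a down- and the next up-crossing
    peaks <- integer(0)
    for (u in up) {
      d <- dn[dn > u]
      if (!length(d)) break
      w <- u:d[1L]
      peaks <- c(peaks, w[which.max(broad[i0 + w - 1L])])
    }
    troughs <- integer(0)
    for (d in dn) {
      u <- up[up > d]
      if (!length(u)) break
      w <- d:u[1L]
      troughs <- c(troughs, w[which.min(broad[i0 + w - 1L])])
    }
    if (length(peaks) < 2L || length(troughs) < 1L) next
    for (k in seq_len(length(peaks) - 1L)) {
      tr <- troughs[troughs > peaks[k] & troughs < peaks[k + 1L]]
      if (length(tr) != 1L) next
      p0 <- i0 + peaks[k] - 1L
      tt <- i0 + tr - 1L
      p1 <- i0 + peaks[k + 1L] - 1L
      phase[p0:tt] <- seq(0, 180, length.out = tt - p0 + 1L)
      if (p1 > tt + 1L)
        phase[(tt + 1L):p1] <- seq(180, 360,
                                   length.out = p1 - tt + 1L)[-1L]
      phase[p1] <- 0   # next cycle's start
      cyc[[length(cyc) + 1L]] <- data.frame(
        peak_start_s = t_start_s + (p0 - 1L) / rate_hz,
        trough_s = t_start_s + (tt - 1L) / rate_hz,
        peak_end_s = t_start_s + (p1 - 1L) / rate_hz)
    }
  }
  cycles <- if (length(cyc)) do.call(rbind, cyc) else
    data.frame(peak_start_s = numeric(0), trough_s = numeric(0),
               peak_end_s = numeric(0))
  structure(list(cycles = cycles, phase_deg = phase, rate_hz = rate_hz,
                 t_start_s = t_start_s, epochs = epochs),
            class = "theta_cycles")
}

#' @export
print.theta_cycles <- function(x, ...) {
  cat(sprintf("<theta_cycles> %d cycles over %d epochs\n",
              nrow(x$cycles), nrow(x$epochs)))
  invisible(x)
}

#' Second spatial difference (CSD kernel)
#'
#' CSD(n, t) = (LFP(n-1, t) - 2 LFP(n, t) + LFP(n+1, t)) / distance^2 for
#' the interior contacts of a uniformly spaced laminar profile.
#'
#' @param lfp_mv depth x time numeric matrix, millivolts, depths ordered
#'   and uniformly spaced.
#' @param spacing_mm inter-contact distance, millimetres.
#' @return (depth - 2) x time matrix, mV/mm^2.
#' @export
csd_second_difference <- function(lfp_mv, spacing_mm) {
  if (!is.matrix(lfp_mv) || nrow(lfp_mv) < 3L)
    stop("need at least 3 contiguous depths for a CSD", call. = FALSE)
  if (spacing_mm <= 0) stop("spacing_mm must be > 0", call. = FALSE)
  nd <- nrow(lfp_mv)
  (lfp_mv[1:(nd - 2L), , drop = FALSE] -
     2 * lfp_mv[2:(nd - 1L), , drop = FALSE] +
     lfp_mv[3:nd, , drop = FALSE]) / spacing_mm ^ 2
}

#' Current source density of a laminar recording
#'
#' Applies the second spatial difference along each shank's contiguous
#' depth runs (no spatial smoothing); the first and last depth of each run
#' are excluded. Recording samples in microvolts are converted to
#' millivolts so the output is in mV/mm^2.
#'
#' @param rec an `lfp_recording` (microvolts).
#' @param map matching `channel_map` with uniform spacing per shank.
#' @return a `csd_signal`: `values` (interior channels x time, mV/mm^2),
#'   `channel_ids` (source LFP channel of each CSD row), `layer`, `shank`,
#'   `rate_hz`, `t_start_s`.
#' @export
compute_csd <- function(rec, map) {
  vals <- list(); ids <- character(0); lay <- character(0); shk <- integer(0)
  found_run <- FALSE
  for (s in unique(map$shank)) {
    sub <- map[map$shank == s, , drop = FALSE]
    sub <- sub[order(sub$depth), , drop = FALSE]
    sub <- sub[sub$channel_id %in% rec$channel_ids, , drop = FALSE]
    if (nrow(sub) == 0L) next
    if (length(unique(sub$spacing_mm)) != 1L)
      stop(sprintf("non-uniform contact spacing on shank %d", s),
           call. = FALSE)
    # contiguous depth runs within the remaining channels
    brk <- c(0L, which(diff(sub$depth) != 1L), nrow(sub))
    for (r in seq_len(length(brk) - 1L)) {
      run <- sub[(brk[r] + 1L):brk[r + 1L], , drop = FALSE]
      if (nrow(run) < 3L) next
      found_run <- TRUE
      lfp_mv <- rec$samples[match(run$channel_id, rec$channel_ids), ,
                            drop = FALSE] / 1000
      csd <- csd_second_difference(lfp_mv, run$spacing_mm[1L])
      vals[[length(vals) + 1L]] <- csd
      interior <- run$channel_id[2:(nrow(run) - 1L)]
      ids <- c(ids, interior)
      lay <- c(lay, run$layer[2:(nrow(run) - 1L)])
      shk <- c(shk, rep(s, nrow(run) - 2L))
    }
  }
  if (!found_run)
    stop("no shank has 3 or more contiguous depths: cannot compute a CSD",
         call. = FALSE)
  structure(list(values = do.call(rbind, vals), channel_ids = ids,
                 layer = lay, shank = shk, rate_hz = rec$rate_hz,
                 t_start_s = rec$t_start_s),
            class = "csd_signal")
}

#' Extract one CSD channel
#' @param csd a `csd_signal`.
#' @param channel_id the source LFP channel id of the wanted CSD row.
#' @return numeric vector (mV/mm^2).
#' @export
get_csd_channel <- function(csd, channel_id) {
  i <- match(as.character(channel_id), csd$channel_ids)
  if (is.na(i)) stop(sprintf("no CSD row for channel '%s'", channel_id),
                     call. = FALSE)
  csd$values[i, ]
}

#' Gamma amplitude by theta phase (16-bin cycle-by-cycle profile)
#'
#' Applies the 20-150 Hz Morlet bank to the signal, z-scores the wavelet
#' amplitude per frequency across all in-cycle samples of the session,
#' splits theta phase into 16 bins, and averages the z-scored amplitude per
#' (frequency, bin).
#'
#' @param x single-channel signal (LFP microvolts or CSD mV/mm^2 — the
#'   z-scoring makes the profile scale-free).
#' @param rate_hz sampling rate, Hz.
#' @param cycles an [extract_theta_cycles()] result for the reference
#'   channel.
#' @param bank Morlet bank; default 65 wavelets linearly spaced 20-150 Hz.
#' @param n_bins number of phase bins (default 16).
#' @return a `phase_bin_profile`: `values` (freq x bin mean z-amplitude),
#'   `occupancy` (samples per bin), `bin_edges_deg`, `freqs_hz`.
#' @export
gamma_by_theta_phase <- function(x, rate_hz, cycles, bank = NULL,
                                 n_bins = 16) {
  if (nrow(cycles$cycles) == 0L)
    stop("no theta cycles: cannot build a phase profile", call. = FALSE)
  if (is.null(bank)) bank <- make_bank(20, 150, 65, 6, rate_hz)
  phase <- cycles$phase_deg
  n <- length(x)
  if (length(phase) != n)
    stop("cycles were extracted from a signal of different length",
         call. = FALSE)
  edges <- seq(0, 360, length.out = n_bins + 1L)
  nf <- length(bank$center_freqs_hz)
  sum_bin <- matrix(0, nf, n_bins)
  cnt_bin <- numeric(n_bins)
  tot <- numeric(nf); tot2 <- numeric(nf); n_tot <- 0
  pad <- round(0.25 * rate_hz)
  for (si in segment_indices(cycles$epochs, n, rate_hz, cycles$t_start_s)) {
    p0 <- max(1L, si[1L] - pad); p1 <- min(n, si[2L] + pad)
    in_cyc <- which(!is.na(phase[si[1L]:si[2L]])) + si[1L] - 1L
    if (!length(in_cyc)) next
    tf <- wavelet_transform(x[p0:p1], bank)
    amp <- sqrt(tf$power[, in_cyc - p0 + 1L, drop = FALSE])
    bins <- pmin(n_bins, findInterval(phase[in_cyc], edges,
                                      rightmost.closed = TRUE))
    bins <- pmax(1L, bins)
    for (b in unique(bins)) {
      sel <- bins == b
      sum_bin[, b] <- sum_bin[, b] + rowSums(amp[, sel, drop = FALSE])
      cnt_bin[b] <- cnt_bin[b] + sum(sel)
    }
    tot <- tot + rowSums(amp)
    tot2 <- tot2 + rowSums(amp ^ 2)
    n_tot <- n_tot + ncol(amp)
  }
  if (n_tot == 0) stop("no in-cycle samples inside the epochs", call. = FALSE)
  mu <- tot / n_tot
  sdv <- sqrt(pmax(0, tot2 / n_tot - mu ^ 2) * n_tot / max(1, n_tot - 1))
  vals <- matrix(NA_real_, nf, n_bins)
  nz <- cnt_bin > 0
  vals[, nz] <- sweep(sweep(sum_bin[, nz, drop = FALSE], 2, cnt_bin[nz], "/"),
                      1, mu, "-") / ifelse(sdv > 0, sdv, 1)
  structure(list(values = vals, occupancy = cnt_bin,
                 bin_edges_deg = edges, freqs_hz = bank$center_freqs_hz),
            class = "phase_bin_profile")
}

#' Average a phase profile over a gamma sub-band
#'
#' Mean over bank frequencies whose centres fall in the band (slow gamma
#' 25-55 Hz, mid gamma 65-90 Hz, fast gamma 100 Hz up to the bank maximum),
#' per phase bin.
#'
#' @param profile a [gamma_by_theta_phase()] result.
#' @param band pair (low, high) in Hz; `Inf` upper edge is capped at the
#'   bank maximum.
#' @return numeric vector, one mean z-amplitude per phase bin.
#' @export
band_phase_modulation <- function(profile, band) {
  hi <- min(band[2], max(profile$freqs_hz))
  sel <- profile$freqs_hz >= band[1] & profile$freqs_hz <= hi
  if (!any(sel))
    stop(sprintf("band %g-%g Hz contains no bank frequencies",
                 band[1], band[2]), call. = FALSE)
  colMeans(profile$values[sel, , drop = FALSE])
}

#' Modulation index from a phase-binned amplitude distribution
#'
#' MI = (log N - H) / log N where H is the Shannon entropy of the
#' normalized amplitude-by-phase distribution: 0 for a uniform
#' distribution, 1 when all mass concentrates in a single bin.
#'
#' @param p non-negative amplitude mass per phase bin (any scale; it is
#'   normalized internally).
#' @return MI in \[0, 1\].
#' @export
mi_from_distribution <- function(p) {
  if (any(p < 0) || sum(p) <= 0)
    stop("distribution must be non-negative with positive mass",
         call. = FALSE)
  p <- p / sum(p)
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz]))
  (log(length(p)) - h) / log(length(p))
}

#' Theta-gamma modulation index comodulogram
#'
#' Phase is extracted from the 6-12 Hz band of the phase-providing signal
#' (analytic-signal angle); amplitude from 5 Hz non-overlapping windows
#' between 20 and 200 Hz of the amplitude-providing signal, each window's
#' amplitude taken as the Morlet wavelet amplitude at the window centre
#' (a narrow zero-phase band-pass cannot resolve theta-rate amplitude
#' modulation: its impulse response outlasts a theta cycle, whereas the
#' wavelet's bandwidth scales with frequency). Within theta epochs longer
#' than 1.5 s the amplitude is binned by phase and each window's MI is the
#' normalized entropy deficit of that distribution. Amplitude windows
#' reaching past 95% of Nyquist are truncated with a warning.
#'
#' @param phase_signal,amp_signal single-channel signals (may be the same
#'   vector, or e.g. a CSD channel).
#' @param rate_hz sampling rate, Hz.
#' @param epochs theta epochs (`start_s`, `end_s`).
#' @param phase_band phase-providing band, Hz (default 6-12).
#' @param amp_range,amp_step amplitude window range and width, Hz.
#' @param n_bins number of phase bins (default 18).
#' @param min_epoch_s minimum epoch duration used (default 1.5 s).
#' @param t_start_s time of the first sample.
#' @return a `comodulogram` data frame: `window_low_hz`, `window_high_hz`,
#'   `mi`, `pref_phase_deg` (centre of the maximal-amplitude phase bin,
#'   0 deg = peak of the phase-band oscillation).
#' @export
modulation_index <- function(phase_signal, amp_signal, rate_hz, epochs,
                             phase_band = c(6, 12), amp_range = c(20, 200),
                             amp_step = 5, n_bins = 18, min_epoch_s = 1.5,
                             t_start_s = 0) {
  keep <- (epochs$end_s - epochs$start_s) > min_epoch_s
  epochs <- epochs[keep, , drop = FALSE]
  if (nrow(epochs) == 0L)
    stop(sprintf("no theta epochs longer than %g s", min_epoch_s),
         call. = FALSE)
  n <- length(phase_signal)
  if (length(amp_signal) != n)
    stop("phase and amplitude signals must have equal length", call. = FALSE)
  mask <- periods_to_mask(epochs, n, rate_hz, t_start_s)
  phase <- Arg(analytic_signal(bandpass(phase_signal, phase_band, rate_hz)))[mask]
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  bins <- pmax(1L, pmin(n_bins, findInterval(phase, edges,
                                             rightmost.closed = TRUE)))
  lows <- seq(amp_range[1], amp_range[2] - amp_step, by = amp_step)
  highs <- lows + amp_step
  cap <- 0.95 * nyquist(rate_hz)
  if (any(highs > cap)) {
    warning(sprintf("amplitude windows truncated at %.1f Hz (95%% of Nyquist)",
                    cap))
    keepw <- lows < cap
    lows <- lows[keepw]; highs <- pmin(highs[keepw], cap)
  }
  mi <- numeric(length(lows)); pref <- numeric(length(lows))
  centers_deg <- (edges[-1L] + edges[-length(edges)]) / 2 * 180 / pi
  wbank <- structure(list(center_freqs_hz = (lows + highs) / 2, n_cycles = 6,
                          rate_hz = rate_hz), class = "wavelet_bank")
  tf <- wavelet_transform(amp_signal, wbank)
  for (w in seq_along(lows)) {
    env <- sqrt(tf$power[w, mask])
    means <- as.numeric(tapply(env, factor(bins, levels = seq_len(n_bins)),
                               mean))
    means[is.na(means)] <- 0
    mi[w] <- mi_from_distribution(means)
    pref[w] <- centers_deg[which.max(means)]
  }
  out <- data.frame(window_low_hz = lows, window_high_hz = highs, mi = mi,
                    pref_phase_deg = pref)
  attr(out, "n_bins") <- n_bins
  attr(out, "phase_band") <- phase_band
  class(out) <- c("comodulogram", "data.frame")
  out
}

#' Mean MI over an amplitude band of a comodulogram
#'
#' @param comod a [modulation_index()] result.
#' @param band pair (low, high) in Hz; windows whose centres fall inside
#'   are averaged.
#' @return mean MI.
#' @export
band_mi <- function(comod, band) {
  ctr <- (comod$window_low_hz + comod$window_high_hz) / 2
  sel <- ctr >= band[1] & ctr <= band[2]
  if (!any(sel))
    stop(sprintf("band %g-%g Hz covers no amplitude windows",
                 band[1], band[2]), call. = FALSE)
  mean(comod$mi[sel])
}
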