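# Internal DSP helpers shared by all analysis stages.

nyquist <- function(rate_hz) rate_hz / 2

#' @noRd
check_band <- function(band, rate_hz, what = "band") {
  if (!is.numeric(band) || length(band) != 2L || any(!is.finite(band)))
    stop(sprintf("%s must be a numeric pair (low, high)", what), call. = FALSE)
  if (band[1] <= 0 || band[2] <= band[1])
    stop(sprintf("%s must satisfy 0 < low < high (got %g, %g)",
                 what, band[1], band[2]), call. = FALSE)
  if (band[2] >= nyquist(rate_hz))
    stop(sprintf("%s upper edge %g Hz is at or above the Nyquist frequency %g Hz",
                 what, band[2], nyquist(rate_hz)), call. = FALSE)
  invisible(band)
}

# Butterworth coefficients with a stability guard: very narrow low-frequency
# bands are numerically unstable in transfer-function form (coefficient
# rounding pushes effective poles outside the unit circle), which a pole
# check on the rounded coefficients does not reliably detect. The guard is
# empirical: the impulse response must be finite and decaying; otherwise the
# order is halved.
stable_butter <- function(order, w, type) {
  ord <- as.integer(order)
  repeat {
    flt <- signal::butter(ord, w, type = type)
    h <- signal::filter(flt, c(1, numeric(8191)))
    decays <- all(is.finite(h)) &&
      mean(abs(h[4097:8192])) < mean(abs(h[1:4096])) + 1e-12
    if (decays || ord <= 1L) return(flt)
    ord <- max(1L, ord %/% 2L)
  }
}

#' Zero-phase band-pass filter
#'
#' Forward-backward Butterworth filtering (no group delay), the filter
#' realization used throughout the event detectors and phase analyses.
#'
#' @param x numeric vector, one channel of signal.
#' @param band numeric pair `(low, high)` in Hz, inside (0, rate/2).
#' @param rate_hz sampling rate in Hz.
#' @param order Butterworth order per direction (default 4). Automatically
#'   reduced if the designed filter would be numerically unstable.
#' @return filtered numeric vector, same length as `x`.
#' @export
bandpass <- function(x, band, rate_hz, order = 4) {
  check_band(band, rate_hz)
  flt <- stable_butter(order, band / nyquist(rate_hz), "pass")
  as.numeric(signal::filtfilt(flt, x))
}

#' Zero-phase low-pass filter
#'
#' @inheritParams bandpass
#' @param cutoff_hz cutoff frequency in Hz, inside (0, rate/2).
#' @return filtered numeric vector.
#' @export
lowpass <- function(x, cutoff_hz, rate_hz, order = 4) {
  if (cutoff_hz <= 0 || cutoff_hz >= nyquist(rate_hz))
    stop(sprintf("cutoff %g Hz must lie inside (0, %g) Hz",
                 cutoff_hz, nyquist(rate_hz)), call. = FALSE)
  flt <- stable_butter(order, cutoff_hz / nyquist(rate_hz), "low")
  as.numeric(signal::filtfilt(flt, x))
}

#' Analytic signal via the frequency domain
#'
#' Standard FFT construction: doubles positive frequencies, zeroes negative
#' ones. `Mod()` of the result is the instantaneous amplitude envelope,
#' `Arg()` the instantaneous phase.
#'
#' @param x real numeric vector.
#' @return complex vector, same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Gaussian smoothing of a signal
#'
#' @param x numeric vector.
#' @param sigma_s kernel standard deviation in seconds.
#' @param rate_hz sampling rate in Hz.
#' @return smoothed vector, edges handled by replicate padding.
#' @export
smooth_gaussian <- function(x, sigma_s, rate_hz) {
  sigma <- sigma_s * rate_hz
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  if (half <= 32L) {
    sm <- stats::filter(xp, k, sides = 2)
    return(as.numeric(sm[(half + 1L):(half + n)]))
  }
  # FFT convolution for wide kernels
  np <- length(xp)
  nfft <- stats::nextn(np + length(k) - 1L, 2)
  conv <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - np))) *
                          stats::fft(c(k, numeric(nfft - length(k)))),
                        inverse = TRUE)) / nfft
  # kernel centre sits at offset `half`: sample i of the smoothed padded
  # series is conv[i + half]; drop the padding
  conv[(2L * half + 1L):(2L * half + n)]
}

# TRUE-run extraction: matrix with columns (start, end) of sample indices.
runs_from_mask <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

# Circular helpers (degrees); wrap into (-180, 180].
wrap_deg <- function(x) -(((-x + 180) %% 360) - 180)

circ_mean_deg <- function(x) {
  rad <- x * pi / 180
  wrap_deg(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
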