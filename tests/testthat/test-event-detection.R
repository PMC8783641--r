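# Immobility segmentation, envelope standardization, the ripple/SPW/SWR
# detectors against brute-force oracles, burst chaining, pathological
# events, and session features.

test_that("immobility periods follow the speed, duration and theta rules", {
  params <- detection_params()
  tt <- seq(0, 59.98, by = 0.02)
  sp <- speed_trace(tt, rep(0.5, length(tt)), 50)
  per <- find_immobility_periods(sp, rep(0.5, length(tt)), params)
  expect_equal(nrow(per), 1L)
  expect_equal(per$start_s, 0)
  expect_equal(per$end_s, 60, tolerance = 1e-6)

  # sub-threshold bout lasting only 10 s: rejected
  spd <- rep(5, length(tt)); spd[tt >= 20 & tt < 30] <- 0.5
  per2 <- find_immobility_periods(speed_trace(tt, spd, 50), NULL, params)
  expect_equal(nrow(per2), 0L)

  # constant 2.0 cm/s: never immobile
  per3 <- find_immobility_periods(speed_trace(tt, rep(2, length(tt)), 50),
                                  NULL, params)
  expect_equal(nrow(per3), 0L)

  # high theta vetoes an otherwise immobile stretch
  per4 <- find_immobility_periods(sp, rep(5, length(tt)), params)
  expect_equal(nrow(per4), 0L)

  expect_error(find_immobility_periods(speed_trace(numeric(0), numeric(0)),
                                       NULL, params), "empty speed")
})

test_that("envelope standardization is an identity on its baseline and linear", {
  rate <- 1034
  set.seed(11)
  x <- rnorm(rate * 60)
  base <- data.frame(start_s = 0, end_s = 60)
  es <- envelope_sd(x, c(150, 250), rate, base, 0.008)
  expect_lt(abs(mean(es$envelope)), 0.05)
  expect_lt(abs(sd(es$envelope) - 1), 0.05)

  # scaling the signal outside the baseline scales the envelope linearly
  x2 <- c(x, 2 * x[1:(10 * rate)])
  es2 <- envelope_sd(x2, c(150, 250), rate, base, 0.008)
  seg <- (60 * rate + 500):(69 * rate)
  ref <- es2$envelope[seg - 60 * rate + 500 - 500]
  # envelope in microvolts doubles; in SD units (env*2 - m)/s
  env_uv <- es2$envelope * es2$baseline_sd + es2$baseline_mean
  expect_lt(abs(mean(env_uv[seg]) / mean(env_uv[seg - 60 * rate]) - 2), 0.1)

  # injected 6-SD burst reads back in [5, 7] SD at its centre
  st <- band_env_stats(x, c(150, 250), rate, 0.008)
  xb <- add_at(x, hann_burst(rate, 200, 60, st$m + 6 * st$s), 30, rate)
  esb <- envelope_sd(xb, c(150, 250), rate, base, 0.008)
  ctr <- round(30 * rate) + 1
  expect_gt(max(esb$envelope[(ctr - 30):(ctr + 30)]), 5)
  expect_lt(max(esb$envelope[(ctr - 30):(ctr + 30)]), 7)

  expect_error(envelope_sd(x, c(150, 250), rate, base[0, ], 0.008),
               "non-empty")
  expect_error(envelope_sd(rep(0, rate), c(150, 250), rate,
                           data.frame(start_s = 0, end_s = 1), 0.008),
               "degenerate|variance")
})

test_that("detect_ripples equals the naive sample-wise oracle on 30 s of noise", {
  rate <- 1034
  set.seed(23)
  x <- rnorm(rate * 30)
  imm <- data.frame(start_s = 0, end_s = 30)
  # drop the duration gate so that noise produces candidate events to compare
  params <- detection_params(ripple_thresh_sd = 2.2, ripple_min_ms = 2)
  det <- detect_ripples(x, rate, imm, params)
  es <- envelope_sd(x, params$ripple_band, rate, imm, params$ripple_smooth_s)
  ref <- naive_ripple_detector(es$envelope, rate, imm, thresh = 2.2,
                               boundary = 1, min_ms = 2, merge_ms = 40)
  expect_gt(nrow(det), 3)  # the comparison is not vacuous
  expect_equal(nrow(det), nrow(ref))
  expect_equal(round(det$start_s * rate), ref$start - 1)
  expect_equal(round(det$end_s * rate), ref$end)
})

test_that("merge and duration rules behave at their boundaries", {
  rate <- 1034
  set.seed(31)
  x <- rnorm(rate * 120)
  imm <- data.frame(start_s = 0, end_s = 120)
  # crisp rectangular bursts, no envelope smoothing: exact gap control
  params <- detection_params(ripple_smooth_s = 0)
  st <- band_env_stats(x, c(150, 250), rate, 0)
  amp <- st$m + 8 * st$s

  # two 30 ms bursts with a 30 ms gap -> one event
  x1 <- add_at(x, rect_burst(rate, 200, 30, amp), 10.000, rate)
  x1 <- add_at(x1, rect_burst(rate, 200, 30, amp), 10.060, rate)
  d1 <- detect_ripples(x1, rate, imm, params)
  expect_equal(sum(d1$start_s > 9.9 & d1$start_s < 10.2), 1L)

  # same bursts 50 ms apart -> two events
  x2 <- add_at(x, rect_burst(rate, 200, 30, amp), 20.000, rate)
  x2 <- add_at(x2, rect_burst(rate, 200, 30, amp), 20.080, rate)
  d2 <- detect_ripples(x2, rate, imm, params)
  expect_equal(sum(d2$start_s > 19.9 & d2$start_s < 20.2), 2L)

  # a 10 ms supra-threshold burst fails the 15 ms minimum
  x3 <- add_at(x, rect_burst(rate, 200, 10, amp), 30, rate)
  d3 <- detect_ripples(x3, rate, imm, params)
  expect_equal(sum(d3$start_s > 29.9 & d3$start_s < 30.1), 0L)

  # merge idempotence: no pair of reported events is closer than the gap
  if (nrow(d2) > 1) {
    gaps <- d2$start_s[-1] - d2$end_s[-nrow(d2)]
    expect_true(all(gaps >= 0.040 - 1.5 / rate))
  }
})

test_that("SPW detector enforces the 20-400 ms duration window", {
  rate <- 1034
  set.seed(41)
  x <- rnorm(rate * 150, sd = 5)
  imm <- data.frame(start_s = 0, end_s = 150)
  params <- detection_params()
  st <- band_env_stats(x, c(4, 50), rate, params$slow_smooth_s)
  bump <- function(dur_s) -sin(pi * seq(0, 1, length.out = round(dur_s * rate)))
  # scale each waveform through the band-pass gain of its own shape so the
  # nominal SD value is what the envelope detector sees
  amp100 <- (st$m + 5 * st$s) /
    wave_gain(bump(0.1), c(4, 50), rate, params$slow_smooth_s)
  long_w <- rect_burst(rate, 10, 500, 1)   # in-band, flat 500 ms envelope
  amp500 <- (st$m + 6 * st$s) /
    wave_gain(long_w, c(4, 50), rate, params$slow_smooth_s)
  # 100 ms deflection at ~5 SD -> accepted
  x1 <- add_at(x, amp100 * bump(0.1), 20, rate)
  # 10 ms deflection -> too short
  x1 <- add_at(x1, rect_burst(rate, 25, 10, st$m + 8 * st$s), 40, rate)
  # 500 ms supra-threshold oscillatory deflection -> too long
  x1 <- add_at(x1, amp500 * long_w, 60, rate)
  d <- detect_spws(x1, rate, imm, params)
  covers <- function(t0) sum(d$start_s <= t0 & d$end_s >= t0)
  expect_equal(covers(20), 1L)
  expect_equal(covers(40), 0L)
  expect_equal(covers(60), 0L)
})

test_that("SWR pairing requires overlap and resolves ties by maximal overlap", {
  rip <- data.frame(start_s = c(10.00, 20.00, 30.00),
                    end_s = c(10.06, 20.06, 30.06),
                    peak_s = c(10.03, 20.03, 30.03),
                    peak_power_sd = c(6, 5, 7), duration_ms = 60)
  spw <- data.frame(start_s = c(9.98, 30.02, 30.05), end_s = c(10.10, 30.06, 30.30),
                    peak_s = c(10.04, 30.04, 30.17), amplitude_sd = c(4, 3, 5),
                    duration_ms = c(120, 40, 250))
  sw <- pair_swr(rip, spw)
  # ripple 1 contained -> paired; ripple 2 has no overlap -> dropped
  expect_equal(nrow(sw), 2L)
  expect_true(10.03 %in% sw$peak_s)
  expect_false(20.03 %in% sw$peak_s)
  # ripple 3 overlaps two SPWs (40 ms vs 10 ms) -> the 40 ms one wins
  r3 <- sw[sw$peak_s == 30.03, ]
  expect_equal(r3$spw_amplitude_sd, 3)
  # brute-force check of the max-overlap rule
  ov <- function(a0, a1, b0, b1) max(0, min(a1, b1) - max(a0, b0))
  best <- which.max(c(ov(30, 30.06, 30.02, 30.06), ov(30, 30.06, 30.05, 30.30)))
  expect_equal(best, 1L)
  # empty inputs
  expect_equal(nrow(pair_swr(rip[0, ], spw)), 0L)
  expect_equal(nrow(pair_swr(rip, spw[0, ])), 0L)
})

test_that("burst chaining matches examples and a brute-force oracle", {
  params <- detection_params()
  mk <- function(peaks) data.frame(peak_s = peaks)
  b1 <- classify_bursts(mk(c(0, 0.10)), params)
  expect_equal(b1$groups$kind, "doublet")
  b2 <- classify_bursts(mk(c(0, 0.25, 0.50)), params)
  expect_equal(b2$groups$kind, rep("singlet", 3))
  b3 <- classify_bursts(mk(c(0, 0.15, 0.30)), params)
  expect_equal(b3$groups$kind, "triplet")

  # oracle: chain peaks whenever consecutive gaps <= 200 ms
  naive_chain <- function(peaks, win = 0.2) {
    g <- cumsum(c(1, as.integer(diff(peaks) > win)))
    tabulate(g)
  }
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    peaks <- sort(runif(n, 0, 3))
    got <- classify_bursts(mk(peaks), params)
    sizes <- naive_chain(peaks)
    expect_identical(got$groups$n_members, sizes)
    # partition: every event in exactly one group; sizes sum to n
    expect_identical(sum(got$groups$n_members), n)
    expect_identical(tabulate(got$membership), sizes)
  }
})

test_that("ripple features recover frequency, cycle count and scale linearly", {
  rate <- 1034
  set.seed(51)
  x <- rnorm(rate * 60)
  imm <- data.frame(start_s = 0, end_s = 60)
  params <- detection_params()
  st <- band_env_stats(x, c(150, 250), rate, params$ripple_smooth_s)
  amp <- st$m + 12 * st$s
  x1 <- add_at(x, hann_burst(rate, 200, 50, amp), 30, rate)
  d <- detect_ripples(x1, rate, imm, params)
  d <- d[d$peak_s > 29.9 & d$peak_s < 30.1, ]
  expect_equal(nrow(d), 1L)
  f <- ripple_features(d, x1, rate, params)
  expect_lte(abs(f$peak_freq_hz - 200), 2)        # one bank step (2 Hz)
  expect_true(abs(f$n_cycles - 10) <= 1.5)        # 50 ms x 200 Hz = 10
  expect_equal(f$duration_ms, (f$end_s - f$start_s) * 1000)

  # envelope linearity: doubling the waveform doubles its smoothed
  # envelope exactly in isolation, and within 10% riding on background
  pad <- numeric(round(0.5 * rate))
  e1 <- max(smooth_gaussian(Mod(analytic_signal(
    c(pad, hann_burst(rate, 200, 50, amp), pad))), 0.008, rate))
  e2 <- max(smooth_gaussian(Mod(analytic_signal(
    c(pad, hann_burst(rate, 200, 50, 2 * amp), pad))), 0.008, rate))
  expect_equal(e2 / e1, 2, tolerance = 1e-9)
  x2 <- add_at(x, hann_burst(rate, 200, 50, 2 * amp), 30, rate)
  d2 <- detect_ripples(x2, rate, imm, params)
  d2 <- d2[d2$peak_s > 29.9 & d2$peak_s < 30.1, ]
  z1 <- d$peak_power_sd * st$s + st$m
  z2 <- d2$peak_power_sd * st$s + st$m
  expect_lt(abs(z2 / z1 - 2), 0.2)

  expect_error(ripple_features(data.frame(start_s = -5, end_s = -4.9,
                                          peak_s = -4.95), x1, rate, params),
               "outside")
})

test_that("fast-ripple criteria: peaks, amplitude and spectral dominance", {
  rate <- 1034
  set.seed(61)
  x <- rnorm(rate * 120)
  imm <- data.frame(start_s = 0, end_s = 120)
  params <- detection_params()
  band <- c(250, 0.95 * rate / 2)
  sigf <- sd(bandpass(x, band, rate))

  # flat-top 300 Hz burst, 12 cycles at 8 SD of the filtered trace -> detected
  tw <- seq(0, 1, length.out = round(0.040 * rate))
  tuk <- ifelse(tw < 0.2, 0.5 * (1 + cos(pi * (tw / 0.2 - 1))),
                ifelse(tw > 0.8, 0.5 * (1 + cos(pi * ((1 - tw) / 0.2 - 1))), 1))
  burst <- 8 * sigf * tuk * sin(2 * pi * 300 * (seq_along(tw) - 1) / rate)
  x1 <- add_at(x, burst, 30, rate)
  suppressWarnings(d1 <- detect_fast_ripples(x1, rate, imm, params))
  expect_equal(sum(abs(d1$peak_s - 30) < 0.05), 1L)

  # same burst truncated to 5 cycles -> too few peaks
  short <- 8 * sigf * sin(2 * pi * 300 * (0:(round(5 / 300 * rate))) / rate)
  x2 <- add_at(x, short, 30, rate)
  suppressWarnings(d2 <- detect_fast_ripples(x2, rate, imm, params))
  expect_equal(sum(abs(d2$peak_s - 30) < 0.05), 0L)
  log2 <- attr(d2, "candidates")
  if (!is.null(log2) && nrow(log2)) {
    near <- log2[abs(log2$start_s - 30) < 0.05, ]
    if (nrow(near)) expect_true(all(!near$enough_peaks))
  }

  # strong 100 Hz content beneath the burst defeats spectral dominance
  x3 <- add_at(x, burst, 30, rate)
  x3 <- add_at(x3, hann_burst(rate, 100, 80, 40 * sigf), 30, rate)
  suppressWarnings(d3 <- detect_fast_ripples(x3, rate, imm, params))
  expect_equal(sum(abs(d3$peak_s - 30) < 0.05), 0L)

  # refusing band truncation is an error at this sampling rate
  expect_error(detect_fast_ripples(x1, rate, imm, params,
                                   allow_band_truncation = FALSE),
               "Nyquist")
})

test_that("IEDs require both the filtered and the raw 5 SD criteria", {
  rate <- 1034
  set.seed(71)
  imm <- data.frame(start_s = 0, end_s = 120)
  params <- detection_params()

  # quiet broadband noise: a strong 70 Hz burst passes both criteria
  x <- rnorm(rate * 120, sd = 2)
  str_ <- band_env_stats(x, NULL, rate, params$slow_smooth_s)
  x1 <- add_at(x, hann_burst(rate, 70, 40, str_$m + 9 * str_$s), 30, rate)
  d1 <- detect_ieds(x1, rate, imm, params)
  expect_equal(sum(abs(d1$peak_s - 30) < 0.05), 1L)
  expect_gt(d1$peak_amplitude_sd[abs(d1$peak_s - 30) < 0.05], 5)

  # loud broadband noise: a 70 Hz burst clearing the filtered criterion
  # stays invisible in the raw envelope -> rejected
  y <- rnorm(rate * 120, sd = 60)
  stf <- band_env_stats(y, c(60, 80), rate, params$slow_smooth_s)
  y1 <- add_at(y, hann_burst(rate, 70, 40, stf$m + 7 * stf$s), 30, rate)
  esr <- envelope_sd(y1, NULL, rate, imm, params$slow_smooth_s)
  ctr <- round(30 * rate)
  expect_lt(max(esr$envelope[(ctr - 40):(ctr + 40)]), 5)  # raw criterion fails
  d2 <- detect_ieds(y1, rate, imm, params)
  expect_equal(sum(abs(d2$peak_s - 30) < 0.05), 0L)

  # flat signal with mild noise: nothing
  d3 <- detect_ieds(rnorm(rate * 60), rate,
                    data.frame(start_s = 0, end_s = 60), params)
  expect_equal(nrow(d3), 0L)
})

test_that("incidence and SPW-ripple correlation are the definitional formulas", {
  imm <- data.frame(start_s = c(0, 200), end_s = c(50, 250))
  swrs <- data.frame(peak_s = seq(1, 45, length.out = 45))
  expect_equal(swr_incidence(swrs, imm), 0.45)
  expect_equal(swr_incidence(swrs[0, , drop = FALSE], imm), 0)
  expect_error(swr_incidence(swrs, imm[0, ]), "immobility time")

  ev <- data.frame(spw_amplitude_sd = c(1, 2, 3, 4),
                   peak_power_sd = c(2, 4, 6, 8))
  expect_equal(spw_ripple_correlation(ev), 1)
  ev2 <- ev; ev2$peak_power_sd <- -ev$spw_amplitude_sd + 10
  expect_equal(spw_ripple_correlation(ev2), -1)
  set.seed(3)
  ev3 <- data.frame(spw_amplitude_sd = rnorm(50, 4),
                    peak_power_sd = NA)
  ev3$peak_power_sd <- 2 * ev3$spw_amplitude_sd + rnorm(50, 0, 0.5)
  manual <- {
    a <- ev3$spw_amplitude_sd; b <- ev3$peak_power_sd
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a)) ^ 2) * sum((b - mean(b)) ^ 2))
  }
  expect_equal(spw_ripple_correlation(ev3), manual, tolerance = 1e-12)
  expect_error(spw_ripple_correlation(ev[1:2, ]), "at least 3")
})
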