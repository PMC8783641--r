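# Theta cycle extraction, CSD, phase-binned gamma profiles and the
# modulation index.

test_that("theta phase interpolation pins peaks to 0 and troughs to 180 degrees", {
  rate <- 1034
  t <- (0:(60 * rate - 1)) / rate
  x <- sin(2 * pi * 8 * t)
  ep <- data.frame(start_s = 0.5, end_s = 59.5)
  cy <- extract_theta_cycles(x, rate, ep)
  expect_gt(nrow(cy$cycles), 400)

  # signal minima (troughs of sin at t = (3/4 + k)/8): phase 180 +- 1
  mins <- (3 / 4 + 0:480) / 8
  mins <- mins[mins > 1 & mins < 59]
  ph_min <- cy$phase_deg[round(mins * rate) + 1]
  expect_true(all(!is.na(ph_min)))
  expect_lt(max(abs(ph_min - 180)), 1)

  # signal maxima: phase 0 (cycle start)
  maxs <- (1 / 4 + 0:480) / 8
  maxs <- maxs[maxs > 1 & maxs < 59]
  ph_max <- cy$phase_deg[round(maxs * rate) + 1]
  expect_lt(max(abs(ph_max), na.rm = TRUE), 1)

  # phase stays in [0, 360) and is non-decreasing within a cycle
  expect_true(all(cy$phase_deg >= 0 & cy$phase_deg < 360, na.rm = TRUE))
  c1 <- cy$cycles[10, ]
  i0 <- round(c1$peak_start_s * rate) + 1; i1 <- round(c1$peak_end_s * rate)
  expect_true(all(diff(cy$phase_deg[i0:i1]) >= 0))
})

test_that("cycle count on swept theta matches a zero-crossing peak oracle", {
  rate <- 1034
  dur <- 40
  t <- (0:(dur * rate - 1)) / rate
  finst <- 7 + 2 * t / dur            # 7 -> 9 Hz sweep
  x <- sin(2 * pi * cumsum(finst) / rate)
  ep <- data.frame(start_s = 0.5, end_s = dur - 0.5)
  cy <- extract_theta_cycles(x, rate, ep)
  th <- bandpass(x, c(6, 10), rate)
  d <- diff(th)
  pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1
  pk <- pk[pk > 0.5 * rate & pk < (dur - 0.5) * rate]
  # cycles = consecutive peak pairs inside the epoch
  expect_lt(abs(nrow(cy$cycles) - (length(pk) - 1)), 3)
})

test_that("CSD matches the printed second-difference formula", {
  # linear depth profile maps to exactly zero
  lin <- rbind(rep(1, 10), rep(2, 10), rep(3, 10))
  expect_true(all(csd_second_difference(lin, 0.2) == 0))

  # hand-computed triplet: (0.1 - 0.6 + 0.9) / 0.04 = 10 mV/mm^2
  trip <- cbind(c(0.1, 0.3, 0.9))
  expect_equal(csd_second_difference(matrix(trip, 3), 0.2)[1, 1], 10)

  # superposition to machine precision
  set.seed(9)
  a <- matrix(rnorm(50), 5); b <- matrix(rnorm(50), 5)
  expect_equal(csd_second_difference(2 * a + 3 * b, 0.2),
               2 * csd_second_difference(a, 0.2) +
                 3 * csd_second_difference(b, 0.2),
               tolerance = 1e-12)

  expect_error(csd_second_difference(a[1:2, ], 0.2), "3")
  expect_error(csd_second_difference(a, -1), "spacing")

  # an 8-depth shank yields 6 CSD channels; units flow from microvolts
  rec <- lfp_recording(matrix(rnorm(8 * 100), 8), 1034)
  map <- channel_map(rec$channel_ids, 1, 1:8, 0.2,
                     c("str_oriens", "str_pyramidale", "str_radiatum",
                       "str_radiatum", "str_LM", "dg_moleculare",
                       "dg_granule", "hilus"))
  csd <- compute_csd(rec, map)
  expect_equal(nrow(csd$values), 6L)
  expect_equal(csd$channel_ids, rec$channel_ids[2:7])
  manual <- (rec$samples[1, 1] - 2 * rec$samples[2, 1] + rec$samples[3, 1]) /
    1000 / 0.04
  expect_equal(csd$values[1, 1], manual)

  expect_error(compute_csd(rec, channel_map(rec$channel_ids, 1, 1:8,
                                            c(0.2, rep(0.1, 7)), "unknown")),
               "non-uniform")
})

test_that("gamma-by-phase profile z-scores correctly and finds locked gamma", {
  rate <- 1034
  sco <- synthesize_coupled_oscillation(8, c(75, 85), 0, 1, 90, rate,
                                        seed = 4, theta_amp = 50,
                                        gamma_amp = 10, noise_sd = 2)
  ep <- data.frame(start_s = 1, end_s = 89)
  cy <- extract_theta_cycles(sco$signal, rate, ep)
  prof <- gamma_by_theta_phase(sco$signal, rate, cy)
  expect_equal(dim(prof$values), c(65L, 16L))
  expect_equal(sum(prof$occupancy), sum(!is.na(cy$phase_deg)))

  # occupancy-weighted mean of z-values is 0 per frequency
  wm <- as.numeric(prof$values %*% prof$occupancy) / sum(prof$occupancy)
  expect_lt(max(abs(wm)), 1e-9)

  # 80 Hz gamma locked at the theta peak: band curve maximal at the bin
  # containing 0/360 degrees
  curve <- band_phase_modulation(prof, c(75, 85))
  expect_true(which.max(curve) %in% c(1L, 16L))

  # constant-amplitude gamma: all bins ~0 z
  s0 <- synthesize_coupled_oscillation(8, c(75, 85), 0, 0, 90, rate,
                                       seed = 4, theta_amp = 50,
                                       gamma_amp = 10)
  cy0 <- extract_theta_cycles(s0$signal, rate, ep)
  prof0 <- gamma_by_theta_phase(s0$signal, rate, cy0)
  curve0 <- band_phase_modulation(prof0, c(75, 85))
  expect_lt(max(abs(curve0)), 0.05)

  expect_error(gamma_by_theta_phase(s0$signal, rate,
                                    structure(list(cycles = cy0$cycles[0, ]),
                                              class = "theta_cycles")),
               "no theta cycles")
})

test_that("band curves average exactly the in-band bank frequencies", {
  prof <- structure(list(values = matrix(seq_len(65 * 16), 65, 16),
                         occupancy = rep(10, 16),
                         bin_edges_deg = seq(0, 360, length.out = 17),
                         freqs_hz = seq(20, 150, length.out = 65)),
                    class = "phase_bin_profile")
  centers <- prof$freqs_hz
  sel <- centers >= 65 & centers <= 90
  manual <- colMeans(prof$values[sel, , drop = FALSE])
  expect_equal(band_phase_modulation(prof, c(65, 90)), manual)
  expect_equal(band_phase_modulation(prof, c(20, 150)), colMeans(prof$values))
  # fast gamma band: upper edge capped at the bank maximum
  expect_equal(band_phase_modulation(prof, c(100, Inf)),
               colMeans(prof$values[centers >= 100, ]))
  prof$values[] <- 0
  expect_equal(band_phase_modulation(prof, c(65, 90)), rep(0, 16))
  expect_error(band_phase_modulation(prof, c(151, 200)), "no bank")
})

test_that("MI is the normalized entropy deficit with the right extremes", {
  expect_equal(mi_from_distribution(rep(1, 18)), 0)
  expect_equal(mi_from_distribution(c(5, rep(0, 17))), 1)
  expect_error(mi_from_distribution(c(-1, 1)), "non-negative")
  p <- c(2, 1, 1, 1)
  manual <- (log(4) + sum((p / 5) * log(p / 5))) / log(4)
  expect_equal(mi_from_distribution(p), manual)
})

test_that("modulation index responds to coupling and respects its invariants", {
  rate <- 1034
  ep <- data.frame(start_s = 0, end_s = 90)
  # uniform coupling: MI below 1e-3
  s0 <- synthesize_coupled_oscillation(8, c(75, 85), 0, 0, 90, rate, seed = 3)
  mi0 <- modulation_index(s0$signal, s0$signal, rate, ep)
  expect_lt(band_mi(mi0, c(70, 90)), 1e-3)
  expect_true(all(mi0$mi >= 0 & mi0$mi <= 1))
  # contiguous non-overlapping windows
  expect_equal(mi0$window_low_hz[-1], mi0$window_high_hz[-nrow(mi0)])

  # monotone in depth at 80 Hz with fixed seeds; strong >= 10x control
  mis <- vapply(c(0, 0.3, 0.6, 0.9), function(d) {
    s <- synthesize_coupled_oscillation(8, c(75, 85), 0, d, 90, rate, seed = 3)
    band_mi(modulation_index(s$signal, s$signal, rate, ep), c(75, 85))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
  expect_gt(mis[4], 10 * mis[1])

  # preferred phase recovered within one bin width (22.5 deg target)
  s6 <- synthesize_coupled_oscillation(8, c(75, 85), 60, 0.6, 90, rate,
                                       seed = 3)
  mi6 <- modulation_index(s6$signal, s6$signal, rate, ep)
  pref <- mi6$pref_phase_deg[mi6$window_low_hz == 75]
  dd <- ((pref - 60 + 180) %% 360) - 180
  expect_lt(abs(dd), 22.5)

  # amplitude-scale invariance
  mi_scaled <- modulation_index(s6$signal, 100 * s6$signal, rate, ep)
  expect_equal(mi_scaled$mi, mi6$mi, tolerance = 1e-9)

  # epochs shorter than 1.5 s are insufficient
  expect_error(modulation_index(s6$signal, s6$signal, rate,
                                data.frame(start_s = 0, end_s = 1)),
               "1.5")
})

test_that("phase-profile recovery holds at moderate depth and SNR", {
  rate <- 1034
  sco <- synthesize_coupled_oscillation(8, c(75, 85), 90, 0.4, 120, rate,
                                        seed = 14, theta_amp = 50,
                                        gamma_amp = 10, noise_sd = 10)
  ep <- data.frame(start_s = 1, end_s = 119)
  cy <- extract_theta_cycles(sco$signal, rate, ep)
  prof <- gamma_by_theta_phase(sco$signal, rate, cy)
  curve <- band_phase_modulation(prof, c(70, 90))
  ctr <- (prof$bin_edges_deg[-1] + prof$bin_edges_deg[-17]) / 2
  got <- ctr[which.max(curve)]
  dd <- ((got - 90 + 180) %% 360) - 180
  expect_lte(abs(dd), 22.5)
})
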