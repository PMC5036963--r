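test_that("filterbank construction spans 1-80 Hz with overlapping bands", {
  fb <- build_filterbank()
  expect_equal(nrow(fb), 107)
  expect_equal(fb$center[1], 1)
  expect_equal(fb$center[107], 80)
  expect_true(all(diff(fb$center) > 0))
  # adjacent bands overlap at the default proportional width
  expect_true(all(fb$low[-1] < fb$high[-nrow(fb)]))
  expect_true(all(fb$low > 0))

  fb2 <- build_filterbank(n = 2)
  expect_equal(fb2$center, c(1, 80))
  expect_error(build_filterbank(f_lo = -1), "f_lo")
})

test_that("analytic phase of a sinusoid advances linearly at the band center", {
  fs <- 500; f <- 4
  t <- seq(0, 20, by = 1 / fs)
  s <- sampled_signal(cos(2 * pi * f * t), fs)
  ap <- analytic_phase(s, f / 1.5, f * 1.5)
  mid <- 2000:8000   # away from filter edges
  d <- diff(ap$phase[mid])
  d <- ifelse(d < -pi, d + 2 * pi, ifelse(d > pi, d - 2 * pi, d))
  slope <- mean(d) * fs
  expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.001)
  expect_lt(max(abs(ap$amplitude[mid] - 1)), 0.01)

  # zero-phase filtering: filtered peaks align with raw peaks
  raw_peaks <- which(diff(sign(diff(s$samples))) < 0) + 1L
  fil_peaks <- which(diff(sign(diff(ap$filtered))) < 0) + 1L
  raw_mid <- raw_peaks[raw_peaks > 2000 & raw_peaks < 8000]
  for (p in raw_mid[1:10]) expect_lte(min(abs(fil_peaks - p)), 1)
})

test_that("spike phases follow the cosine convention (peak 0, trough 180)", {
  fs <- 1000
  t <- seq(0, 120, by = 1 / fs)
  s <- sampled_signal(cos(2 * pi * 1 * t), fs)
  ap <- analytic_phase(s, 0.67, 1.5)

  peaks <- spike_train(5:100, epoch = c(0, 120))        # integer s = peaks
  ph <- spike_phases(peaks, ap)
  expect_lt(max(abs(ph)), 0.05)

  troughs <- spike_train(5:100 + 0.5, epoch = c(0, 120))
  ph2 <- spike_phases(troughs, ap)
  expect_lt(max(abs(abs(ph2) - pi)), 0.05)

  # 5 ms jitter on a 1 Hz cycle = 1.8 degrees of circular SD
  set.seed(60)
  jit <- sort(5:100 + rnorm(96, 0, 0.005))
  phj <- spike_phases(spike_train(jit, epoch = c(0, 120)), ap)
  circ_sd_deg <- sqrt(-2 * log(circular_stats(phj)$R)) * 180 / pi
  expect_lt(abs(circ_sd_deg - 1.8), 0.5)

  expect_error(spike_phases(spike_train(130, c(0, 140)), ap), "outside")
})

test_that("ECDF correction is monotone and near-identity for uniform phases", {
  set.seed(61)
  sig <- runif(20000, -pi, pi)
  sp <- runif(200, -pi, pi)
  corrected <- ecdf_phase_correction(sp, sig)
  expect_lt(max(abs(corrected - sp)), 0.1)
  # weakly monotone: sorted by raw phase, corrected phases never decrease
  expect_true(all(diff(corrected[order(sp)]) >= 0))
  expect_error(ecdf_phase_correction(sp, numeric(0)), "empty")
})

test_that("circular statistics match closed forms and the Bessel ratio", {
  expect_equal(circular_stats(rep(1.2, 50))$R, 1)
  expect_lt(circular_stats(c(0, pi / 2, pi, -pi / 2))$R, 1e-12)

  set.seed(62)
  ph <- rvm(2000, mu = 0.5, kappa = 1)
  cs <- circular_stats(ph)
  expect_lt(abs(cs$R - besselI(1, 1) / besselI(1, 0)), 0.05)
  expect_lt(abs(cs$mean_phase - 0.5), 0.1)

  # rotation invariance of R; mean phase shifts by the rotation
  rot <- Arg(exp(1i * (ph + 1)))
  cs2 <- circular_stats(rot)
  expect_equal(cs2$R, cs$R, tolerance = 1e-12)
  expect_lt(abs(Arg(exp(1i * (cs2$mean_phase - cs$mean_phase - 1)))), 1e-9)
})

test_that("Rayleigh test is extreme for perfect locking and calibrated under null", {
  r1 <- rayleigh_test(rep(0.3, 40))
  expect_equal(unname(r1$statistic), 40)
  expect_lt(r1$p_value, 1e-15)

  expect_gt(rayleigh_test(c(0, pi / 2, pi, -pi / 2))$p_value, 0.9)

  set.seed(63)
  rej <- mean(replicate(500, rayleigh_test(runif(40, -pi, pi))$p_value) < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("locking profiles localize modulation in frequency", {
  fb <- build_filterbank(n = 19, f_lo = 0.7, f_hi = 60)
  set.seed(64)
  s <- simulate_field(240, fs = 250,
                      amplitudes = c(slow = 1, spindle = 0.2, gamma = 0.1,
                                     noise = 0.1), seed = 64)
  st <- simulate_locked_train(s, band = c(0.67, 1.5), rate = 4, kappa = 2,
                              seed = 65)
  prof <- locking_profile(st, s, fb)
  expect_true(prof$tested)
  # histogram conservation in every band
  expect_true(all(rowSums(prof$histograms) == length(st$times)))
  # locking concentrated near 1 Hz, absent in gamma
  expect_true(range_locking(prof, c(0.7, 1.6))$locked)
  expect_false(range_locking(prof, gamma_band("figures"))$locked)
  expect_gt(range_locking(prof, c(0.7, 1.6))$mean_R,
            range_locking(prof, c(30, 60))$mean_R)

  # a neuron below the 40-spike criterion is profiled but not tested
  few <- spike_train(seq(10, 200, by = 10), epoch = c(0, 240))
  prof2 <- locking_profile(few, s, fb)
  expect_false(prof2$tested)
  expect_true(all(is.na(prof2$bands$rayleigh_p)))
})

test_that("null spikes on a noise signal produce ~5% significant bands", {
  fb <- build_filterbank(n = 20, f_lo = 1, f_hi = 60)
  set.seed(66)
  hits <- numeric(0)
  for (i in 1:5) {
    s <- simulate_field(120, fs = 250,
                        amplitudes = c(slow = 0, spindle = 0, gamma = 0,
                                       noise = 1), seed = 660 + i)
    st <- simulate_locked_train(s, rate = 2, kappa = 0, seed = 670 + i)
    prof <- locking_profile(st, s, fb)
    hits <- c(hits, prof$bands$rayleigh_p < 0.05)
  }
  expect_lt(mean(hits), 0.2)
})
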