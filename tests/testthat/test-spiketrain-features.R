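periodic_train <- function(isi = 0.1, n = 101, t0 = 0) {
  spike_train(t0 + isi * (0:(n - 1)), epoch = c(t0, t0 + isi * n + 1))
}

poisson_train <- function(n_isi, rate = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- cumsum(rexp(n_isi + 1, rate))
  spike_train(t, epoch = c(0, max(t) + 1))
}

test_that("firing rate is count over epoch duration", {
  st <- spike_train(seq(0.5, 59.5, by = 1), epoch = c(0, 60))
  expect_equal(firing_rate(st), 1)
  expect_equal(firing_rate(spike_train(numeric(0), c(0, 60))), 0)

  set.seed(40)
  st <- simulate_locked_train(simulate_field(300, fs = 250, seed = 40),
                              rate = 10, kappa = 0)
  se <- sqrt(10 / 300)   # Poisson SE of the rate estimate
  expect_lt(abs(firing_rate(st) - 10), 2 * se)
})

test_that("ISI histograms are percent counts with boundary accumulation", {
  h <- isi_histogram(periodic_train())
  expect_equal(sum(h$percent), 100, tolerance = 1e-9)
  expect_equal(max(h$percent), 100)   # all mass in one bin

  h2 <- isi_histogram(periodic_train(t0 = 55))   # same ISIs, shifted train
  expect_equal(h$percent, h2$percent)

  # exponential ISIs follow the analytic per-bin mass
  st <- poisson_train(20000, rate = 5, seed = 41)
  h3 <- isi_histogram(st)
  edges <- h3$edges
  nb <- length(edges) - 1L
  for (k in seq_len(nb)) {
    m <- exp_bin_mass(5, edges[k], edges[k + 1])
    # boundary bins also accumulate the clipped out-of-range mass
    if (k == 1L) m <- m + exp_bin_mass(5, 0, edges[1])
    if (k == nb) m <- m + exp_bin_mass(5, edges[nb + 1], Inf)
    se <- sqrt(m * (1 - m) / 20000)
    expect_lt(abs(h3$percent[k] / 100 - m), 5 * se + 1e-4)
  }
  expect_error(isi_histogram(spike_train(1, c(0, 10))), ">= 2 spikes")
})

test_that("ISI-histogram pair correlations rank firing-pattern similarity", {
  st <- poisson_train(3000, rate = 5, seed = 42)
  h <- isi_histogram(st)
  expect_equal(isi_pair_correlation(h, h), 1)

  # far-shifted unimodal distributions anti-correlate in rank
  fast <- isi_histogram(periodic_train(isi = 0.004, n = 500))
  slow <- isi_histogram(periodic_train(isi = 2, n = 50))
  ha <- isi_histogram(poisson_train(3000, rate = 100, seed = 43))
  hb <- isi_histogram(poisson_train(3000, rate = 0.45, seed = 44))
  expect_lt(isi_pair_correlation(ha, hb), 0)

  # two Poisson trains of the same rate have near-identical histograms
  h1 <- isi_histogram(poisson_train(5000, rate = 5, seed = 45))
  h2 <- isi_histogram(poisson_train(5000, rate = 5, seed = 46))
  expect_gt(isi_pair_correlation(h1, h2), 0.7)

  expect_error(isi_pair_correlation(h1, isi_histogram(st, edges = isi_bin_edges(50))),
               "identical bin edges")
})

test_that("CV2 features match closed forms for regular and alternating trains", {
  cv <- cv2_features(periodic_train())
  expect_true(all(cv$cv2 < 1e-9))         # exact up to float spacing
  expect_lt(cv$cv_isi, 1e-9)
  expect_lt(cv$cv2_mean, 1e-9)

  # alternating ISIs a, 3a: every CV2 = 2*2a/4a = 1
  t <- cumsum(rep(c(0.1, 0.3), 50))
  alt <- spike_train(t, epoch = c(0, max(t) + 1))
  expect_true(all(abs(cv2_features(alt)$cv2 - 1) < 1e-12))

  # dimensionless: invariant to uniform time rescaling
  t2 <- spike_train(t * 7.3, epoch = c(0, max(t) * 7.3 + 1))
  expect_equal(cv2_features(alt)$cv2, cv2_features(t2)$cv2)
  expect_equal(cv2_features(alt)$cv_isi, cv2_features(t2)$cv_isi)

  expect_error(cv2_features(spike_train(c(1, 2), c(0, 10))), ">= 2 ISIs")
})

test_that("Poisson trains give CV2 mean near 1 and CV of ISIs near 1", {
  st <- poisson_train(5000, rate = 5, seed = 47)
  cv <- cv2_features(st)
  expect_lt(abs(cv$cv2_mean - 1), 0.05)
  expect_lt(abs(cv$cv_isi - 1), 0.05)
})

test_that("log ISI percentiles interpolate linearly and stay ordered", {
  expect_equal(log_isi_percentile(periodic_train(0.1), 50), -1)

  st <- poisson_train(500, rate = 3, seed = 48)
  p10 <- log_isi_percentile(st, 10)
  p50 <- log_isi_percentile(st, 50)
  p85 <- log_isi_percentile(st, 85)
  expect_true(p10 <= p50 && p50 <= p85)

  # exponential rate 1: median = ln 2
  st1 <- poisson_train(20000, rate = 1, seed = 49)
  expect_lt(abs(log_isi_percentile(st1, 50) - log10(log(2))), 0.02)
})

test_that("waveform segmentation recovers D1/D2 from construction", {
  fs <- 50000
  tri <- c(rep(0, 30), seq(0, 1, length.out = 16)[-1],   # rise 15 samples = 0.3 ms
           seq(1, 0, length.out = 36)[-1],               # fall 35 samples = 0.7 ms
           rep(0, 10))
  ws <- waveform_segments(tri, fs, n_baseline = 25)
  expect_equal(ws$d1_ms, 0.3)
  expect_equal(ws$d2_ms, 0.7)
  expect_equal(ws$total_ms, 1.0)

  sym <- c(rep(0, 30), seq(0, -1, length.out = 21)[-1],
           seq(-1, 0, length.out = 21)[-1], rep(0, 10))
  wsym <- waveform_segments(sym, fs, n_baseline = 25)
  expect_equal(wsym$d1_ms, wsym$d2_ms)

  # noisy biphasic waveform: segments recovered within one sample period
  set.seed(50)
  wave <- c(rep(0, 40), sin(pi * seq(0, 1, length.out = 26))[-1],
            -0.4 * sin(pi * seq(0, 1, length.out = 41))[-1], rep(0, 20))
  noisy <- wave + rnorm(length(wave), 0, 0.01)
  wn <- waveform_segments(noisy, fs, n_baseline = 35)
  clean <- waveform_segments(wave, fs, n_baseline = 35)
  expect_lt(abs(wn$d1_ms - clean$d1_ms), 1000 / fs + 1e-9)

  # a waveform that never returns to baseline is flagged
  stuck <- c(rep(0, 30), seq(0, 1, length.out = 20), rep(1, 30))
  wstuck <- waveform_segments(stuck, fs, n_baseline = 25)
  expect_false(wstuck$ok)
  expect_true(is.na(wstuck$d2_ms))
})

test_that("feature records collect the clustering parameters", {
  st <- poisson_train(500, rate = 8, seed = 51)
  fr <- feature_record(st)
  expect_equal(names(fr), c("rate", "log_isi_p10", "log_isi_p50", "log_isi_p85",
                            "cv_isi", "cv2_mean", "cv2_ratio"))
  expect_true(fr$log_isi_p10 <= fr$log_isi_p50)
})
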