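sine_trace <- function(freq, dur = 0.5, rate = 25000, amp = 1) {
  t <- seq(0, dur, by = 1 / rate)
  voltage_trace(amp * sin(2 * pi * freq * t), rate)
}

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  # in-band 1 kHz: zero-phase response = |H|^2, within 5% of unity
  f1 <- bandpass(sine_trace(1000))
  mid <- 3000:9000
  expect_equal(max(abs(f1$samples[mid])), 1, tolerance = 0.05)

  # out-of-band 10 Hz: attenuated by more than 90%
  f2 <- bandpass(sine_trace(10))
  expect_lt(max(abs(f2$samples[mid])), 0.1)

  # zero in, zero out
  z <- bandpass(voltage_trace(numeric(1000), 25000))
  expect_equal(z$samples, numeric(1000))

  expect_error(bandpass(sine_trace(1000), low_hz = 2000, high_hz = 100),
               "band edges")
  expect_error(bandpass(sine_trace(1000), high_hz = 20000), "band edges")
})

test_that("spike detection recovers injected deflections and ignores scale", {
  tr <- simulate_trace(4, spike_times = c(0.5, 1.2, 2.0, 3.1),
                       amplitude = 8, noise_sd = 1, seed = 2)
  filt <- bandpass(tr)
  ras <- detect_spikes(filt)
  found <- which(ras$spikes == 1) / ras$rate_hz
  expect_equal(length(found), 4)
  for (t0 in attr(tr, "true_spike_times")) {
    expect_lt(min(abs(found - t0)), 1e-3)   # within 1 ms
  }

  # threshold is SD-relative: positive rescaling changes nothing
  filt2 <- voltage_trace(filt$samples * 13.7, filt$rate_hz)
  expect_equal(detect_spikes(filt2)$spikes, ras$spikes)

  # constant trace: warning, no spikes
  expect_warning(r0 <- detect_spikes(voltage_trace(rep(1, 1000), 25000)),
                 "constant")
  expect_equal(sum(r0$spikes), 0)
})

test_that("false positives on pure noise follow the normal tail", {
  set.seed(14)
  n <- 250000
  x <- voltage_trace(rnorm(n), 25000)
  # at 3 SD the expected below-threshold sample count is n * pnorm(-3);
  # after refractory collapse the event count is smaller but of that order
  ras <- detect_spikes(x, k_sd = 3)
  expected_samples <- n * pnorm(-3)
  expect_gt(sum(ras$spikes), 0.2 * expected_samples)
  expect_lt(sum(ras$spikes), 1.5 * expected_samples)
  # at 5 SD false positives are essentially absent
  expect_lt(sum(detect_spikes(x, k_sd = 5)$spikes), 3)
})

test_that("leaky integrator reproduces its closed forms", {
  rate <- 1000
  tau <- 50
  mk_raster <- function(spikes) {
    structure(list(spikes = spikes, rate_hz = rate, channel_id = "t"),
              class = "spike_raster")
  }
  # impulse response: decays to exp(-1) of the peak exactly tau later
  n <- 1000
  imp <- integer(n)
  imp[100] <- 1L
  y <- leaky_integrate(mk_raster(imp), tau_ms = tau)
  k <- tau / 1000 * rate    # samples per tau
  expect_equal(y[100 + k] / y[100], exp(-1))

  # empty raster -> all zeros
  expect_equal(leaky_integrate(mk_raster(integer(200)), tau),
               rep(0, 200), ignore_attr = TRUE)

  # periodic spikes at interval tau: steady-state peak -> 1 / (1 - e^-1)
  per <- integer(60000)
  per[seq(1, 60000, by = k)] <- 1L
  yp <- leaky_integrate(mk_raster(per), tau_ms = tau)
  peaks <- yp[seq(1, 60000, by = k)]
  expect_equal(tail(peaks, 1), 1 / (1 - exp(-1)), tolerance = 1e-6)

  # linearity: superposition holds exactly
  a <- integer(500); a[c(50, 200)] <- 1L
  b <- integer(500); b[c(120, 300)] <- 1L
  ya <- leaky_integrate(mk_raster(a), tau)
  yb <- leaky_integrate(mk_raster(b), tau)
  yab <- leaky_integrate(mk_raster(a + b), tau)
  expect_equal(as.numeric(yab), as.numeric(ya) + as.numeric(yb))
})

test_that("burst detection finds injected clusters and stays quiet otherwise", {
  # 10 dense clusters in sparse background spiking
  set.seed(6)
  rate <- 1000
  n <- 120000   # 120 s at 1 kHz
  spikes <- integer(n)
  spikes[sample.int(n, 120)] <- 1L   # 1 Hz background
  onsets <- seq(5000, 115000, length.out = 10)
  for (o in onsets) {
    spikes[o + sort(sample.int(500, 100, replace = TRUE))] <- 1L
  }
  ras <- structure(list(spikes = spikes, rate_hz = rate, channel_id = "b"),
                   class = "spike_raster")
  y <- leaky_integrate(ras, 50)
  bursts <- detect_bursts(y, 4)
  expect_equal(nrow(bursts$intervals), 10)
  # each detected onset is near an injected cluster
  for (on in bursts$intervals$onset_sample) {
    expect_lt(min(abs(on - onsets)), 600)
  }
  expect_true(all(bursts$intervals$onset_sample <
                  bursts$intervals$offset_sample))

  # homogeneous sparse raster: no or almost no bursts
  sp <- integer(n)
  sp[sample.int(n, 200)] <- 1L
  y0 <- leaky_integrate(structure(list(spikes = sp, rate_hz = rate,
                                       channel_id = "q"),
                                  class = "spike_raster"), 50)
  expect_lte(nrow(detect_bursts(y0, 4)$intervals), 2)

  # empty raster
  ye <- leaky_integrate(structure(list(spikes = integer(1000),
                                       rate_hz = rate, channel_id = "e"),
                                  class = "spike_raster"), 50)
  expect_equal(nrow(detect_bursts(ye)$intervals), 0)
})

test_that("activity summaries use spikes/sec and bursts/min with SEM", {
  mk <- function(nspk, dur_s, rate = 1000) {
    sp <- integer(dur_s * rate)
    if (nspk > 0) sp[seq_len(nspk)] <- 1L
    structure(list(spikes = sp, rate_hz = rate, channel_id = paste0("ch", nspk)),
              class = "spike_raster")
  }
  mkb <- function(k) {
    structure(list(intervals = data.frame(onset_sample = seq_len(k) * 100,
                                          offset_sample = seq_len(k) * 100 + 10),
                   threshold_used = 1, rate_hz = 1000),
              class = "burst_events")
  }
  one <- summarize_activity(list(mk(600, 60)), list(mkb(0)), 60)
  expect_equal(one$per_channel$spike_rate_hz, 10)

  two <- summarize_activity(list(mk(120, 60), mk(240, 60)),
                            list(mkb(2), mkb(4)), 60)
  expect_equal(two$summary$mean[two$summary$measure == "spike_rate_hz"], 3)
  expect_equal(two$summary$sem[two$summary$measure == "spike_rate_hz"], 1)
  expect_equal(two$summary$mean[two$summary$measure == "burst_rate_min"], 3)
  expect_equal(two$summary$sem[two$summary$measure == "burst_rate_min"], 1)
})

test_that("trace simulation is deterministic and spikes beyond duration error", {
  t1 <- simulate_trace(1, spike_times = 0.5, noise_sd = 0, amplitude = 8,
                       seed = 1)
  expect_equal(max(abs(t1$samples)), 8, tolerance = 1e-9)
  expect_true(all(t1$samples[1:1000] == 0))

  t2 <- simulate_trace(1, spike_times = 0.2, noise_sd = 1, seed = 9)
  t3 <- simulate_trace(1, spike_times = 0.2, noise_sd = 1, seed = 9)
  expect_identical(t2$samples, t3$samples)
  expect_error(simulate_trace(1, spike_times = 2), "beyond")
})

test_that("the full chain recovers injected bursts and all strong spikes", {
  tr <- simulate_trace(60, spike_times = seq(1, 4, by = 0.5),
                       burst_onsets = seq(6, 56, length.out = 10),
                       spikes_per_burst = 50, burst_dur_s = 0.15,
                       amplitude = 8, noise_sd = 1, rate_hz = 25000,
                       seed = 33)
  filt <- bandpass(tr)
  ras <- detect_spikes(filt)
  truth <- attr(tr, "true_spike_times")

  # 100% recall of 8-SD spikes within 1 ms
  found <- which(ras$spikes == 1) / ras$rate_hz
  recall <- mean(vapply(truth, function(t0) {
    any(abs(found - t0) < 1e-3)
  }, logical(1)))
  expect_equal(recall, 1)

  y <- leaky_integrate(ras, tau_ms = 50, decimate_to_hz = 1000)
  bursts <- detect_bursts(y, 4)
  expect_equal(nrow(bursts$intervals), 10)
})
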