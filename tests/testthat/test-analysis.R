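# The analysis functions are simulator-independent: all expectations here
# come from the synthetic fixture generator, whose ground truth is known
# by construction.

test_that("spike detection recovers synthetic spike times", {
  fx <- generate_fixtures("spiketrain", seed = 1)
  sp <- detect_spikes(fx$trace)
  expect_equal(nrow(sp), length(fx$truth$spike_times))
  # threshold crossing within 1 ms of waveform onset, peaks near truth
  expect_true(all(abs(sp$threshold_time - fx$truth$spike_times) < 1))
  # peaks ride on the AHPs of preceding spikes, so allow a few mV
  expect_true(all(abs(sp$peak_v - fx$truth$peak_v) < 8))
  # flat trace: nothing
  flat <- data.frame(time = seq(0, 100, 0.025), v_soma = -80)
  expect_equal(nrow(detect_spikes(flat)), 0)
})

test_that("a pure ramp at the threshold rate yields at most one event", {
  tt <- seq(0, 20, by = 0.025)
  ramp <- data.frame(time = tt, v_soma = -80 + 5 * tt) # exactly 5 mV/ms
  sp <- detect_spikes(ramp, peak_min = -200)
  expect_lte(nrow(sp), 1)
})

test_that("spike metrics reproduce the ISI-based frequency definitions", {
  # ISI set consistent with the reference instantaneous/steady-state pair
  isis <- c(5.68, 6, 7, 7.94, 8)
  times <- cumsum(c(30.3, isis))
  spikes <- data.frame(threshold_time = times, threshold_v = -40,
                       peak_time = times + 0.4, peak_v = 36.7)
  sm <- spike_metrics(spikes, stim_onset = 0)
  expect_equal(sm$first_spike_delay, 30.3)
  expect_equal(sm$instantaneous_frequency, 1000 / 5.68, tolerance = 1e-12)
  expect_equal(sm$steady_state_frequency, 1000 / 7.94, tolerance = 1e-12)
  expect_equal(sm$frequency_ratio, 5.68 / 7.94, tolerance = 1e-12)
  # the printed 176/126 Hz pair implies a ratio within 0.5% of 0.715
  expect_equal(sm$instantaneous_frequency, 176, tolerance = 0.01)
  expect_equal(sm$steady_state_frequency, 126, tolerance = 0.01)
  expect_equal(sm$frequency_ratio, 126 / 176, tolerance = 0.005 * 0.716)
  # identity: ratio == ss/inst by construction
  expect_equal(sm$frequency_ratio,
               sm$steady_state_frequency / sm$instantaneous_frequency,
               tolerance = 1e-12)
})

test_that("spike metrics degrade gracefully with few spikes", {
  one <- data.frame(threshold_time = 10, threshold_v = -40,
                    peak_time = 10.4, peak_v = 30)
  sm <- spike_metrics(one, 0)
  expect_true(is.na(sm$instantaneous_frequency))
  expect_true(is.na(sm$frequency_ratio))
  # uniform ISIs give ratio exactly 1
  times <- seq(10, 60, by = 10)
  u <- data.frame(threshold_time = times, threshold_v = -40,
                  peak_time = times + 0.4, peak_v = 30)
  expect_equal(spike_metrics(u, 0)$frequency_ratio, 1)
})

test_that("sag amplitude matches the synthetic double-exponential truth", {
  fx <- generate_fixtures("sag_trace", seed = 3)
  s <- sag_amplitude(fx$trace)
  expect_equal(s, fx$truth$sag, tolerance = 0.02 * abs(fx$truth$sag))
  expect_lt(s, 0)
  # a monotone RC-like response has no sag
  tt <- seq(0, 1000, 0.05)
  rc <- data.frame(time = tt, v_soma = -80 - 15 * (1 - exp(-tt / 50)))
  attr(rc, "stim_onset") <- 0; attr(rc, "stim_end") <- 1000
  expect_equal(sag_amplitude(rc), 0, tolerance = 1e-6)
})

test_that("tri-exponential fit recovers known amplitudes and time constants", {
  fx <- generate_fixtures("exponential_transient", seed = 2)
  ft <- fit_triexponential(fx$trace, delta_mV = fx$truth$delta_mV)
  expect_equal(ft$tau, fx$truth$tau, tolerance = 0.05)
  expect_equal(ft$A, fx$truth$A, tolerance = 0.05)
  expect_equal(ft$C, fx$truth$C, tolerance = 1e-3)
  expect_equal(ft$c_in_fit_pF, fx$truth$c_in_fit_pF, tolerance = 0.05)
  # taus ordered
  expect_true(all(diff(ft$tau) > 0))
  expect_error(fit_triexponential(fx$trace, delta_mV = 0), "zero")
})

test_that("tri-exponential fit is scale-equivariant in the step amplitude", {
  fx <- generate_fixtures("exponential_transient", seed = 2)
  tr2 <- fx$trace
  tr2$i_clamp <- 2 * tr2$i_clamp
  f1 <- fit_triexponential(fx$trace, delta_mV = -10)
  f2 <- fit_triexponential(tr2, delta_mV = -20)
  expect_equal(f2$A, 2 * f1$A, tolerance = 1e-3)
  expect_equal(f2$tau, f1$tau, tolerance = 1e-3)
  expect_equal(f2$c_in_pF, f1$c_in_pF, tolerance = 1e-3)
})

test_that("LOR metrics recover ramp slope, delay and duration from synthetic traces", {
  fx <- generate_fixtures("lor_like", seed = 4)
  lm_ <- lor_metrics(fx$trace)
  expect_true(lm_$has_lor)
  expect_equal(lm_$spike_count, length(fx$truth$spike_times))
  expect_equal(lm_$delay, fx$truth$delay, tolerance = 1)
  expect_equal(lm_$duration, fx$truth$duration, tolerance = 1.5)
  expect_equal(lm_$ramp_slope, fx$truth$ramp_slope_mV_s,
               tolerance = 0.05 * fx$truth$ramp_slope_mV_s)
  # no spikes: ramp slope still reported, delay undefined
  tt <- seq(0, 2000, 0.05)
  quiet <- data.frame(time = tt, v_soma = -80 + 0.002 * tt)
  attr(quiet, "stim_onset") <- 100; attr(quiet, "stim_end") <- 190
  lmq <- lor_metrics(quiet)
  expect_false(lmq$has_lor)
  expect_true(is.na(lmq$delay))
  expect_equal(lmq$ramp_slope, 2, tolerance = 0.01)
})

test_that("fixtures are deterministic in the seed", {
  a <- generate_fixtures("spiketrain", seed = 7, noise_sd = 0.5)
  b <- generate_fixtures("spiketrain", seed = 7, noise_sd = 0.5)
  expect_identical(a$trace, b$trace)
  d <- generate_fixtures("spiketrain", seed = 8, noise_sd = 0.5)
  expect_false(identical(a$trace, d$trace))
  expect_error(generate_fixtures("nope", 1))
})
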