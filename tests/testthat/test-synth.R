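# synthetic-signal generators: determinism, closed-form waveforms, and
# ground-truth bookkeeping

test_that("generators are pure functions of their seed", {
  a <- gen_psc_trace(5, seed = 11)
  b <- gen_psc_trace(5, seed = 11)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
  c <- gen_psc_trace(5, seed = 12)
  expect_false(identical(a$trace$samples, c$trace$samples))
  l1 <- gen_lfp_trace(20, rate_hz = 2000, seed = 3)
  l2 <- gen_lfp_trace(20, rate_hz = 2000, seed = 3)
  expect_identical(l1$trace$samples, l2$trace$samples)
  d1 <- gen_seizure_diary(4, seed = 5)
  d2 <- gen_seizure_diary(4, seed = 5)
  expect_identical(d1$records, d2$records)
})

test_that("PSC kernel has unit peak and the analytic rise time", {
  k <- psc_kernel(0.5, 5, 20, 10000)
  expect_equal(max(k), 1, tolerance = 1e-3)  # peak between samples
  expect_equal(k[1], 0)
  # closed-form peak time
  tpk <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5)
  expect_equal((which.max(k) - 1) / 10, tpk, tolerance = 0.06)
  expect_error(psc_kernel(5, 0.5), "exceed")
  # analytic 10-90% rise time is recovered by event_metrics on a clean
  # single-event trace (unfiltered)
  g <- gen_psc_trace(1, event_times_s = 0.5, event_amps_pA = 15,
                     noise_sd_pA = 0)
  m <- event_metrics(g$trace, 0.5)
  expect_equal(m$amplitude_pA, 15, tolerance = 0.01)
  expect_equal(m$rise_time_ms, psc_kernel_rise_time(0.5, 5),
               tolerance = 0.06)
})

test_that("PSC generator injects what it reports", {
  # rate 0, noise 0 -> flat baseline
  g0 <- gen_psc_trace(2, event_rate_hz = 0, noise_sd_pA = 0, seed = 1)
  expect_equal(nrow(g0$truth), 0)
  expect_true(all(g0$trace$samples == 0))
  # realized count is the recorded Poisson draw, near rate * duration
  g <- gen_psc_trace(60, event_rate_hz = 2, seed = 42)
  expect_equal(nrow(g$truth), 120, tolerance = 0.25)
  expect_true(all(diff(g$truth$time_s) > 0))
  expect_true(all(g$truth$amp_pA > 0))
  # single noiseless event: peak deviation equals the amplitude at the
  # kernel's analytic peak delay
  g1 <- gen_psc_trace(1, event_times_s = 0.4, event_amps_pA = 12,
                      noise_sd_pA = 0)
  expect_equal(min(g1$trace$samples), -12, tolerance = 0.01)
  tpk <- 0.5 * 5 / (5 - 0.5) * log(5 / 0.5) / 1000
  expect_equal((which.min(g1$trace$samples) - 1) / 10000, 0.4 + tpk,
               tolerance = 2e-4)
  expect_error(gen_psc_trace(1, rise_tau_ms = 5, decay_tau_ms = 0.5),
               "exceed")
})

test_that("LFP generator reproduces amplitude and per-state counts", {
  # clean single discharge: raw peak-to-peak equals the stated amplitude
  g1 <- gen_lfp_trace(10, rate_hz = 2000, discharge_times_s = 5,
                      discharge_amps_uV = 168, mains_amp_uV = 0,
                      noise_sd_uV = 0, pink_sd_uV = 0)
  expect_equal(max(g1$trace$samples) - min(g1$trace$samples), 168,
               tolerance = 1e-9)
  expect_equal(nrow(g1$truth), 1)
  # equal dark/light rates: no systematic state difference
  sch <- stim_schedule("continuous_5s", t_start_s = 35, n_runs = 10)
  g2 <- gen_lfp_trace(435, rate_hz = 1000, schedule = sch,
                      dark_rate_hz = 0.5, light_rate_hz = 0.5, seed = 2)
  expect_true(all(g2$truth$state %in% c("dark", "light")))
  # rates differ: per-state counts recorded in the truth reflect it
  g3 <- gen_lfp_trace(435, rate_hz = 1000, schedule = sch,
                      dark_rate_hz = 0.5, light_rate_hz = 0.45, seed = 3)
  n_light <- sum(g3$truth$state == "light")
  expect_equal(n_light, 0.45 * 50, tolerance = 0.5)  # 10 runs x 5 s
  expect_error(gen_lfp_trace(10, dark_rate_hz = -1), "non-negative")
})

test_that("quasi-regular timing has the requested interval CV", {
  g <- gen_lfp_trace(600, rate_hz = 1000, dark_rate_hz = 0.5,
                     jitter_cv = 0.2, seed = 8)
  iei <- diff(g$truth$time_s)
  expect_equal(mean(iei), 2, tolerance = 0.1)
  expect_equal(stats::sd(iei) / mean(iei), 0.2, tolerance = 0.35)
})

test_that("test-pulse response matches the closed-form RC solution", {
  g <- gen_test_pulse_response(rs_MOhm = 10, rm_MOhm = 500, cm_pF = 100,
                               step_mV = 5, noise_sd_pA = 0)
  on_i <- round(g$step_windows$on_s * g$trace$rate_hz) + 1
  expect_equal(g$trace$samples[on_i], 500)         # instantaneous peak
  ss_i <- round(g$step_windows$off_s * g$trace$rate_hz) - 5
  expect_equal(g$trace$samples[ss_i], 5 / 510 * 1000, tolerance = 1e-6)
  # Cm -> 0: rectangle of height dV / (Rs + Rm)
  g0 <- gen_test_pulse_response(cm_pF = 0, noise_sd_pA = 0)
  mid <- round(mean(unlist(g0$step_windows)) * g0$trace$rate_hz)
  expect_equal(g0$trace$samples[mid], 5 / 510 * 1000, tolerance = 1e-9)
  expect_equal(max(abs(g0$trace$samples)), 5 / 510 * 1000,
               tolerance = 1e-9)
  # doubling Cm doubles the integrated transient charge
  q_of <- function(cm) {
    g <- gen_test_pulse_response(cm_pF = cm, noise_sd_pA = 0)
    i_on <- round(g$step_windows$on_s[1] * g$trace$rate_hz) + 1
    i_off <- round(g$step_windows$off_s[1] * g$trace$rate_hz)
    seg <- g$trace$samples[i_on:i_off] - g$model$ss_pA
    (sum(seg) - (seg[1] + seg[length(seg)]) / 2) / g$trace$rate_hz
  }
  expect_equal(q_of(200) / q_of(100), 2, tolerance = 1e-3)
  expect_error(gen_test_pulse_response(step_dur_ms = 1), "steady state")
})

test_that("AP waveform carries its stated features", {
  tr <- gen_ap_waveform(threshold_mV = -40, peak_mV = 30, width_ms = 1,
                        ahp_depth_mV = 25)
  truth <- attr(tr, "truth")
  expect_equal(truth$amplitude_mV, 70)
  expect_equal(min(tr$samples), -65)               # AHP minimum
  expect_equal(max(tr$samples), 30)
  # crosses threshold exactly twice
  above <- tr$samples > -40
  crossings <- sum(diff(above) != 0)
  expect_equal(crossings, 2)
  expect_error(gen_ap_waveform(width_ms = 0.0001), "3 samples")
  # multiple APs: one pair of crossings each
  tr5 <- gen_ap_waveform(n_aps = 5)
  expect_equal(sum(diff(tr5$samples > -40) != 0), 10)
})

test_that("seizure diary generator matches its Poisson bookkeeping", {
  d0 <- gen_seizure_diary(3, rate_per_hour = 0, seed = 1)
  expect_equal(nrow(d0$records), 0)
  expect_equal(nrow(d0$animals), 3)
  # mean count over many animals approaches rate x window
  d <- gen_seizure_diary(400, days = 7, rate_per_hour = 1 / 12, seed = 2)
  counts <- table(factor(d$records$animal_id,
                         levels = d$animals$animal_id))
  expect_equal(mean(counts), 14, tolerance = 0.05)
  # degenerate severity distribution
  d5 <- gen_seizure_diary(5, severity_probs = c(0, 0, 1), seed = 3)
  expect_true(all(d5$records$severity == 5))
  expect_true(all(d$records$onset_s >= 0 & d$records$onset_s <= d$window_s))
})
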