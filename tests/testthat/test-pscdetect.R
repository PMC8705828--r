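# PSC template-correlation detector and per-cell summaries

test_that("lowpass filter passes DC and attenuates above cutoff", {
  dc <- trace(rep(5, 5000), 10000, "pA")
  expect_equal(lowpass_filter(dc, 400)$samples, rep(5, 5000),
               tolerance = 1e-6)
  t <- (0:49999) / 10000
  s1k <- trace(sin(2 * pi * 1000 * t), 10000, "pA")
  out <- lowpass_filter(s1k, 400)
  atten_db <- 20 * log10(stats::sd(s1k$samples) /
                           stats::sd(out$samples[1000:49000]))
  expect_gt(atten_db, 20)
  # white noise: spectral power above the cutoff drops, below survives
  set.seed(2)
  wn <- trace(rnorm(20000), 10000, "pA")
  fw <- lowpass_filter(wn, 400)
  spec_in <- Mod(stats::fft(wn$samples))^2
  spec_out <- Mod(stats::fft(fw$samples))^2
  f <- (seq_along(spec_in) - 1) / length(spec_in) * 10000
  hi <- f > 600 & f < 5000
  lo <- f > 10 & f < 300
  expect_lt(mean(spec_out[hi]) / mean(spec_in[hi]), 0.01)
  expect_gt(mean(spec_out[lo]) / mean(spec_in[lo]), 0.8)
  expect_error(lowpass_filter(wn, 6000), "Nyquist")
})

test_that("sliding correlation matches the direct per-window oracle", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(300)
    w <- rnorm(20)
    expect_equal(slicephys:::.sliding_correlation(x, w),
                 oracle_sliding_corr(x, w), tolerance = 1e-10)
  }
  expect_error(slicephys:::.sliding_correlation(rnorm(5), rnorm(10)),
               "longer")
})

test_that("noiseless injected events are recovered with exact onsets", {
  set.seed(1)
  times <- sort(sample(seq(0.1, 19.5, by = 0.001), 20))
  times <- times[c(TRUE, diff(times) > 0.05)]
  g <- gen_psc_trace(20, event_times_s = times,
                     event_amps_pA = rep(15, length(times)),
                     noise_sd_pA = 0)
  ev <- detect_pscs(g$trace)
  expect_equal(nrow(ev), nrow(g$truth))
  expect_true(all(abs(ev$time_s - g$truth$time_s) <= 0.001))
  expect_equal(ev$amplitude_pA, rep(15, nrow(ev)), tolerance = 0.05)
  expect_equal(ev$iei_ms[-1], diff(g$truth$time_s) * 1000,
               tolerance = 1e-6)
  expect_true(is.na(ev$iei_ms[1]))
})

test_that("each exclusion rule removes exactly its violating events", {
  # four constructed events, each violating at most one rule:
  #   0.5 s  matched kinetics, 15 pA          -> accepted
  #   1.5 s  matched kinetics,  2 pA          -> amplitude rule
  #   2.3 s  slow kinetics (6.6 ms rise), 15 pA -> rise-time rule
  #   3.2 s  1.5 ms square artifact, 15 pA    -> correlation rule
  # detection uses a mid-speed template so all three kernel shapes clear
  # the 0.6 correlation cutoff while the square artifact does not
  fs <- 10000
  dur <- 4
  set.seed(77)
  mk <- function(t0, amp, tr_ = 0.5, td = 5)
    gen_psc_trace(dur, event_times_s = t0, event_amps_pA = amp,
                  rise_tau_ms = tr_, decay_tau_ms = td,
                  noise_sd_pA = 0)$trace$samples
  y <- mk(0.5, 15) + mk(1.5, 2) + mk(2.3, 15, 6, 30)
  y[(3.2 * fs + 1):(3.2 * fs + 15)] <- -15
  tr <- trace(y + rnorm(dur * fs, 0, 0.3), fs, "pA")
  tpl <- psc_template(2, 12, 40, fs)
  found_at <- function(ev, t0) any(abs(ev$time_s - t0) < 0.02)
  ev <- detect_pscs(tr, tpl)
  expect_true(found_at(ev, 0.5))
  expect_false(found_at(ev, 1.5))
  expect_false(found_at(ev, 2.3))
  expect_false(found_at(ev, 3.2))
  rej <- attr(ev, "rejected")
  expect_true("amplitude" %in%
                rej$reason[abs(rej$time_s - 1.5) < 0.02])
  expect_true("rise_time" %in%
                rej$reason[abs(rej$time_s - 2.3) < 0.02])
  # lowering the amplitude cutoff below 2 pA admits the tiny event only
  ev_a <- detect_pscs(tr, tpl,
                      config = analysis_config(psc_amp_min_pA = 1.5))
  expect_true(found_at(ev_a, 1.5))
  expect_false(found_at(ev_a, 2.3))
  expect_false(found_at(ev_a, 3.2))
  # disabling the rise-time rule admits the slow event only
  ev_r <- detect_pscs(tr, tpl,
                      config = analysis_config(psc_rise_max_ms = Inf))
  expect_true(found_at(ev_r, 2.3))
  expect_false(found_at(ev_r, 1.5))
  expect_false(found_at(ev_r, 3.2))
  # lowering the correlation cutoff admits the square artifact only
  # (amplitude and rise rules stay active)
  ev_c <- detect_pscs(tr, tpl,
                      config = analysis_config(psc_corr_min = 0.2))
  expect_true(found_at(ev_c, 3.2))
  expect_false(found_at(ev_c, 1.5))
  expect_false(found_at(ev_c, 2.3))
})

test_that("amplitude and frequency are recovered within 10% with noise", {
  amp_err <- freq_err <- numeric(10)
  for (s in 1:10) {
    g <- gen_psc_trace(30, event_rate_hz = 1.4, amp_mean_pA = 15,
                       noise_sd_pA = 2, seed = 100 + s)
    ev <- detect_pscs(g$trace)
    amp_err[s] <- abs(stats::median(ev$amplitude_pA) -
                        stats::median(g$truth$amp_pA)) /
      stats::median(g$truth$amp_pA)
    freq_err[s] <- abs(nrow(ev) - nrow(g$truth)) / nrow(g$truth)
  }
  # per-seed recovery stays close; the median across seeds is within 10%
  expect_lt(max(amp_err), 0.15)
  expect_lt(stats::median(amp_err), 0.1)
  expect_lt(max(freq_err), 0.1)
})

test_that("event_metrics flags truncated and unmeasurable events", {
  g <- gen_psc_trace(1, event_times_s = 0.995, event_amps_pA = 15,
                     noise_sd_pA = 0)
  m <- event_metrics(g$trace, 0.995)
  expect_true(m$truncated)
  flat <- trace(rep(0, 10000), 10000, "pA")
  m2 <- event_metrics(flat, 0.5)
  expect_true(is.na(m2$amplitude_pA))
  expect_error(event_metrics(flat, 2), "outside")
})

test_that("summarize_cell computes frequency and medians", {
  ev <- data.frame(time_s = seq(0.5, 6, by = 0.5),
                   peak_time_s = seq(0.5, 6, by = 0.5) + 0.002,
                   amplitude_pA = c(4, 8, 100, rep(8, 9)),
                   rise_time_ms = rep(1, 12), correlation = rep(0.9, 12),
                   iei_ms = c(NA, rep(500, 11)))
  s <- summarize_cell(ev, 10)
  expect_equal(s$frequency_hz, 1.2)
  expect_equal(s$n_events, 12)
  expect_equal(summarize_cell(ev[1:3, ], 10)$median_amplitude_pA, 8)
  empty <- summarize_cell(ev[0, ], 10)
  expect_equal(empty$frequency_hz, 0)
  expect_true(empty$flagged)
  expect_true(is.na(empty$median_amplitude_pA))
})

test_that("equal-n subsampling is deterministic and excludes small cells", {
  set.seed(3)
  cells <- list(
    a = data.frame(amplitude_pA = rnorm(100, 15)),
    b = data.frame(amplitude_pA = rnorm(42, 15)),
    c = data.frame(amplitude_pA = rnorm(30, 15))
  )
  r1 <- equal_n_subsample(cells, n = 42, seed = 9)
  r2 <- equal_n_subsample(cells, n = 42, seed = 9)
  expect_identical(r1$selected, r2$selected)
  expect_equal(r1$excluded, "c")
  expect_equal(nrow(r1$selected$a), 42)
  # a cell with exactly n keeps all its events
  expect_identical(r1$selected$b, cells$b)
  expect_error(equal_n_subsample(cells, n = 0), "positive")
})
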