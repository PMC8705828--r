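# Synthetic-signal generators. Every generator is a pure function of its
# parameters and `seed` and returns the injected ground truth verbatim, so
# downstream detectors can be scored against what was actually put in.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && seed >= 2^31) stop("seed must be < 2^31")
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Synaptic-current kernel (difference of exponentials)
#'
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))` with `A` chosen so the peak
#' magnitude is exactly 1. The peak occurs at
#' `t* = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param rise_tau_ms,decay_tau_ms Kernel time constants (decay > rise).
#' @param window_ms Kernel support length.
#' @param rate_hz Sampling rate.
#' @return Numeric vector of `window_ms * rate_hz / 1000` samples with
#'   unit peak, starting at the kernel onset (value 0).
#' @export
psc_kernel <- function(rise_tau_ms = 0.5, decay_tau_ms = 5,
                       window_ms = 20, rate_hz = 10000) {
  if (decay_tau_ms <= rise_tau_ms)
    stop("decay_tau_ms must exceed rise_tau_ms", call. = FALSE)
  t <- seq(0, by = 1000 / rate_hz, length.out =
             max(2L, round(window_ms * rate_hz / 1000)))
  raw <- exp(-t / decay_tau_ms) - exp(-t / rise_tau_ms)
  tpk <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  peak <- exp(-tpk / decay_tau_ms) - exp(-tpk / rise_tau_ms)
  raw / peak
}

# 10-90% rise time of the difference-of-exponentials kernel, closed form via
# root finding on the analytic expression (used by tests as an oracle too).
#' @rdname psc_kernel
#' @export
psc_kernel_rise_time <- function(rise_tau_ms = 0.5, decay_tau_ms = 5) {
  tpk <- rise_tau_ms * decay_tau_ms / (decay_tau_ms - rise_tau_ms) *
    log(decay_tau_ms / rise_tau_ms)
  peak <- exp(-tpk / decay_tau_ms) - exp(-tpk / rise_tau_ms)
  f <- function(t) (exp(-t / decay_tau_ms) - exp(-t / rise_tau_ms)) / peak
  t10 <- stats::uniroot(function(t) f(t) - 0.1, c(1e-9, tpk))$root
  t90 <- stats::uniroot(function(t) f(t) - 0.9, c(t10, tpk))$root
  t90 - t10
}

#' Simulate a voltage-clamp trace with spontaneous postsynaptic currents
#'
#' Poisson-timed inward (negative) events on a noisy baseline, each event a
#' difference-of-exponentials kernel whose peak magnitude equals the drawn
#' amplitude. The high-chloride internal solution used in the experiments
#' this emulates makes all PSCs inward, hence the single-polarity model.
#'
#' @param duration_s Trace length in seconds.
#' @param rate_hz Sampling rate (default 10 kHz, the acquisition rate).
#' @param event_rate_hz Poisson event rate.
#' @param amp_mean_pA Mean event amplitude (peak magnitude, pA).
#' @param amp_cv Coefficient of variation of amplitudes (lognormal).
#' @param rise_tau_ms,decay_tau_ms Kernel time constants.
#' @param noise_sd_pA Gaussian baseline noise SD.
#' @param baseline_pA Holding-current baseline.
#' @param event_times_s,event_amps_pA Optional explicit events (overrides
#'   the Poisson draw; amplitudes are positive magnitudes).
#' @param seed RNG seed; identical seeds give identical output.
#' @return List with `trace` (units pA) and `truth`, a data.frame with
#'   columns `time_s` (onset) and `amp_pA` of every injected event.
#' @export
gen_psc_trace <- function(duration_s, rate_hz = 10000,
                          event_rate_hz = 1.4, amp_mean_pA = 15,
                          amp_cv = 0.3, rise_tau_ms = 0.5,
                          decay_tau_ms = 5, noise_sd_pA = 2,
                          baseline_pA = 0, event_times_s = NULL,
                          event_amps_pA = NULL, seed = NULL) {
  stopifnot(duration_s > 0, event_rate_hz >= 0)
  if (decay_tau_ms <= rise_tau_ms)
    stop("decay_tau_ms must exceed rise_tau_ms", call. = FALSE)
  .with_seed(seed, {
    n <- round(duration_s * rate_hz)
    if (is.null(event_times_s)) {
      n_ev <- stats::rpois(1L, event_rate_hz * duration_s)
      event_times_s <- sort(stats::runif(n_ev, 0, duration_s))
      sdlog <- sqrt(log(1 + amp_cv^2))
      event_amps_pA <- stats::rlnorm(n_ev, log(amp_mean_pA) - sdlog^2 / 2,
                                     sdlog)
    } else {
      event_times_s <- as.numeric(event_times_s)
      if (is.null(event_amps_pA)) event_amps_pA <-
          rep(amp_mean_pA, length(event_times_s))
      stopifnot(all(diff(event_times_s) > 0), all(event_amps_pA > 0))
    }
    # snap onsets to the sample grid so ground truth is exact
    idx <- round(event_times_s * rate_hz) + 1
    keep <- idx >= 1 & idx <= n
    idx <- idx[keep]; amps <- event_amps_pA[keep]
    event_times_s <- (idx - 1) / rate_hz
    y <- rep(baseline_pA, n)
    if (length(idx)) {
      kern <- psc_kernel(rise_tau_ms, decay_tau_ms,
                         window_ms = 10 * decay_tau_ms, rate_hz = rate_hz)
      for (j in seq_along(idx)) {
        span <- idx[j]:min(n, idx[j] + length(kern) - 1L)
        y[span] <- y[span] - amps[j] * kern[seq_along(span)]
      }
    }
    if (noise_sd_pA > 0) y <- y + stats::rnorm(n, 0, noise_sd_pA)
    list(trace = trace(y, rate_hz, "pA"),
         truth = data.frame(time_s = event_times_s, amp_pA = amps))
  })
}

# Gabor-like biphasic discharge waveform, normalized to unit peak-to-peak.
.discharge_waveform <- function(rate_hz, f_hz = 40, sigma_ms = 8) {
  half <- 3.5 * sigma_ms / 1000
  t <- seq(-half, half, by = 1 / rate_hz)
  w <- exp(-t^2 / (2 * (sigma_ms / 1000)^2)) * sin(2 * pi * f_hz * t)
  list(w = w / (max(w) - min(w)), center = which.min(w))
}

# Quasi-regular event times on [0, duration): a gamma renewal process with
# interval CV `jitter_cv`, time-rescaled so the local rate is
# `light_rate_hz` inside schedule episodes and `dark_rate_hz` outside.
.renewal_times <- function(duration_s, dark_rate_hz, light_rate_hz,
                           schedule = NULL, jitter_cv = 0.2) {
  if (dark_rate_hz < 0 || light_rate_hz < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (is.null(schedule)) {
    breaks <- c(0, duration_s)
    rates <- dark_rate_hz
  } else {
    ep <- schedule$episodes
    ep <- ep[ep$on_s < duration_s, , drop = FALSE]
    breaks <- sort(unique(pmin(c(0, ep$on_s, ep$off_s, duration_s),
                               duration_s)))
    mids <- breaks[-length(breaks)] + diff(breaks) / 2
    rates <- ifelse(light_state(mids, schedule) == "light",
                    light_rate_hz, dark_rate_hz)
  }
  cum <- c(0, cumsum(rates * diff(breaks)))   # integrated intensity
  total <- cum[length(cum)]
  if (total <= 0) return(numeric(0))
  shape <- 1 / jitter_cv^2
  # burn-in in operational time so the process starts near equilibrium
  # (an ordinary renewal start would slightly depress early counts)
  burn <- 20
  s <- numeric(0); acc <- 0
  repeat {
    draw <- stats::rgamma(max(16L, ceiling(total + burn)), shape = shape,
                          rate = shape)
    s <- c(s, acc + cumsum(draw))
    acc <- s[length(s)]
    if (acc > total + burn) break
  }
  s <- s[s >= burn & s < total + burn] - burn
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  breaks[seg] + (s - cum[seg]) / rates[seg]
}

#' Simulate an LFP trace with epileptiform discharges
#'
#' Quasi-regular ("pseudo-regular") sharp biphasic discharges on a 1/f +
#' white background with power-line hum. Discharge timing is a gamma
#' renewal process (interval CV `jitter_cv`) whose local rate switches
#' between `dark_rate_hz` and `light_rate_hz` according to the
#' stimulation schedule, emulating an optogenetic rate effect.
#'
#' @param duration_s Trace length (s).
#' @param rate_hz Sampling rate (default 10 kHz).
#' @param schedule Optional [stim_schedule()]; without one the whole trace
#'   is dark.
#' @param dark_rate_hz,light_rate_hz Discharge rates by illumination state.
#' @param amp_mean_uV Mean discharge peak-to-peak amplitude (uV).
#' @param amp_cv Amplitude coefficient of variation (lognormal).
#' @param jitter_cv Interval CV of the renewal process (0 = clock-like,
#'   1 = Poisson; default 0.2, between the two).
#' @param mains_amp_uV 50 Hz hum amplitude (uV, sine peak).
#' @param mains_hz Power-line fundamental.
#' @param noise_sd_uV White background SD.
#' @param pink_sd_uV 1/f background SD.
#' @param discharge_f_hz,discharge_sigma_ms Waveform carrier frequency and
#'   Gaussian envelope SD (a ~20-50 ms broadband transient).
#' @param discharge_times_s,discharge_amps_uV Optional explicit events
#'   (times are waveform centers).
#' @param seed RNG seed.
#' @return List with `trace` (units uV) and `truth`, a data.frame with
#'   `time_s` (waveform center), `amp_uV`, `state` ("dark"/"light").
#' @export
gen_lfp_trace <- function(duration_s, rate_hz = 10000, schedule = NULL,
                          dark_rate_hz = 0.47, light_rate_hz = 0.47,
                          amp_mean_uV = 168, amp_cv = 0.2,
                          jitter_cv = 0.2, mains_amp_uV = 10,
                          mains_hz = 50, noise_sd_uV = 0.5,
                          pink_sd_uV = 0.5,
                          discharge_f_hz = 40, discharge_sigma_ms = 8,
                          discharge_times_s = NULL,
                          discharge_amps_uV = NULL, seed = NULL) {
  stopifnot(duration_s > 0)
  if (dark_rate_hz < 0 || light_rate_hz < 0)
    stop("rates must be non-negative", call. = FALSE)
  .with_seed(seed, {
    n <- round(duration_s * rate_hz)
    if (is.null(discharge_times_s)) {
      discharge_times_s <- .renewal_times(duration_s, dark_rate_hz,
                                          light_rate_hz, schedule,
                                          jitter_cv)
      sdlog <- sqrt(log(1 + amp_cv^2))
      discharge_amps_uV <- stats::rlnorm(length(discharge_times_s),
                                         log(amp_mean_uV) - sdlog^2 / 2,
                                         sdlog)
    } else if (is.null(discharge_amps_uV)) {
      discharge_amps_uV <- rep(amp_mean_uV, length(discharge_times_s))
    }
    wf <- .discharge_waveform(rate_hz, discharge_f_hz, discharge_sigma_ms)
    y <- numeric(n)
    ctr <- round(discharge_times_s * rate_hz) + 1
    keep <- ctr >= 1 & ctr <= n
    ctr <- ctr[keep]
    amps <- discharge_amps_uV[keep]
    times <- (ctr - 1) / rate_hz
    for (j in seq_along(ctr)) {
      i0 <- ctr[j] - wf$center + 1L
      span <- max(1L, i0):min(n, i0 + length(wf$w) - 1L)
      y[span] <- y[span] + amps[j] * wf$w[span - i0 + 1L]
    }
    if (mains_amp_uV > 0)
      y <- y + mains_amp_uV * sin(2 * pi * mains_hz *
                                    (seq_len(n) - 1) / rate_hz)
    if (noise_sd_uV > 0) y <- y + stats::rnorm(n, 0, noise_sd_uV)
    if (pink_sd_uV > 0) y <- y + .pink_noise(n, pink_sd_uV)
    state <- if (is.null(schedule)) rep("dark", length(times))
             else light_state(times, schedule)
    list(trace = trace(y, rate_hz, "uV"),
         truth = data.frame(time_s = times, amp_uV = amps,
                            state = state))
  })
}

# 1/f ("pink") noise by spectral shaping of white Gaussian noise.
.pink_noise <- function(n, sd) {
  nf <- 2^ceiling(log2(n))
  x <- stats::rnorm(nf)
  X <- stats::fft(x)
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)          # symmetric frequency index
  X <- X / sqrt(f)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  y * sd / stats::sd(y)
}

#' Simulate whole-cell test-pulse current responses
#'
#' Analytic current response of the series-resistance / membrane RC circuit
#' (`Rs` in series with `Rm || Cm`) to repeated voltage steps, the protocol
#' used to estimate passive membrane properties. For a step of `dV`:
#' instantaneous peak `dV / Rs`, steady state `dV / (Rs + Rm)`, relaxation
#' time constant `tau = Cm Rs Rm / (Rs + Rm)`.
#'
#' @param rs_MOhm,rm_MOhm,cm_pF Circuit ground truth (all positive,
#'   `Rs < Rm`).
#' @param vrest_mV Resting potential of the model cell (returned as truth;
#'   the current trace itself is baseline-subtracted pipette current).
#' @param step_mV Test-pulse amplitude (default 5 mV).
#' @param step_dur_ms Step duration (default 100 ms; must exceed ~5 tau so
#'   steady state is reached).
#' @param pre_ms,gap_ms Baseline before the first step and between steps.
#' @param n_pulses Number of repeated pulses.
#' @param rate_hz Sampling rate.
#' @param noise_sd_pA Gaussian noise SD.
#' @param seed RNG seed.
#' @return List with `trace` (pA), `step_windows` (data.frame `on_s`,
#'   `off_s` per pulse) and `model` (the ground-truth parameters).
#' @export
gen_test_pulse_response <- function(rs_MOhm = 10, rm_MOhm = 500,
                                    cm_pF = 100, vrest_mV = -60,
                                    step_mV = 5, step_dur_ms = 100,
                                    pre_ms = 20, gap_ms = 100,
                                    n_pulses = 1, rate_hz = 10000,
                                    noise_sd_pA = 0, seed = NULL) {
  stopifnot(rs_MOhm > 0, rm_MOhm > 0, cm_pF >= 0, rs_MOhm < rm_MOhm)
  tau_ms <- cm_pF * rs_MOhm * rm_MOhm / (rs_MOhm + rm_MOhm) * 1e-3
  if (step_dur_ms < 5 * tau_ms)
    stop("step_dur_ms too short: steady state not reached", call. = FALSE)
  .with_seed(seed, {
    period_ms <- pre_ms + step_dur_ms + gap_ms
    n <- round(period_ms * n_pulses * rate_hz / 1000)
    t_ms <- (seq_len(n) - 1) / rate_hz * 1000
    ipeak <- step_mV / rs_MOhm * 1000          # pA
    iss <- step_mV / (rs_MOhm + rm_MOhm) * 1000
    istep <- function(tm) {                    # response to unit step at 0
      out <- numeric(length(tm))
      on <- tm >= 0
      out[on] <- if (tau_ms > 0)
        iss + (ipeak - iss) * exp(-tm[on] / tau_ms) else iss
      out
    }
    y <- numeric(n)
    on_s <- off_s <- numeric(n_pulses)
    for (p in seq_len(n_pulses)) {
      on_ms <- (p - 1) * period_ms + pre_ms
      off_ms <- on_ms + step_dur_ms
      y <- y + istep(t_ms - on_ms) - istep(t_ms - off_ms)
      on_s[p] <- on_ms / 1000; off_s[p] <- off_ms / 1000
    }
    if (noise_sd_pA > 0) y <- y + stats::rnorm(n, 0, noise_sd_pA)
    list(trace = trace(y, rate_hz, "pA"),
         step_windows = data.frame(on_s = on_s, off_s = off_s),
         model = list(rs_MOhm = rs_MOhm, rm_MOhm = rm_MOhm, cm_pF = cm_pF,
                      vrest_mV = vrest_mV, step_mV = step_mV,
                      tau_ms = tau_ms, peak_pA = ipeak, ss_pA = iss))
  })
}

#' Synthetic action-potential waveform with known features
#'
#' Piecewise-smooth voltage waveform whose true threshold (onset of the
#' fast upstroke), peak, width at threshold and AHP minimum equal the
#' inputs exactly on the sample grid: a slow sub-threshold approach ramp
#' (2 mV/ms, well under any dV/dt criterion), a fast quarter-sine upstroke
#' and downstroke spanning `width_ms` above threshold, then a
#' half-cosine AHP dip and recovery that stays below threshold.
#'
#' @param threshold_mV,peak_mV AP threshold and peak (peak > threshold).
#' @param width_ms Width at threshold (>= 3 samples).
#' @param ahp_depth_mV AHP depth below threshold (> 0); the AHP minimum is
#'   `threshold_mV - ahp_depth_mV`.
#' @param rate_hz Sampling rate.
#' @param n_aps Number of identical APs.
#' @param inter_ms Baseline between APs.
#' @param approach_ms Duration of the sub-threshold approach ramp.
#' @param ahp_ms,recover_ms AHP descent and recovery durations.
#' @return A `trace` (mV) with attribute `truth`: list of the injected
#'   feature values and per-AP threshold-crossing times.
#' @export
gen_ap_waveform <- function(threshold_mV = -40, peak_mV = 30,
                            width_ms = 1, ahp_depth_mV = 20,
                            rate_hz = 10000, n_aps = 1, inter_ms = 50,
                            approach_ms = 5, ahp_ms = 10,
                            recover_ms = 25) {
  stopifnot(peak_mV > threshold_mV, ahp_depth_mV > 0)
  dt_ms <- 1000 / rate_hz
  n_w <- round(width_ms / dt_ms)
  if (n_w < 3) stop("width_ms shorter than 3 samples", call. = FALSE)
  base <- threshold_mV - 10
  n_rise <- max(1L, round(0.4 * n_w)); n_fall <- n_w - n_rise
  seg_base <- rep(base, round(10 / dt_ms))
  seg_appr <- base + (threshold_mV - base) *
    seq_len(round(approach_ms / dt_ms)) / round(approach_ms / dt_ms)
  # last approach sample is exactly the threshold; upstroke continues above
  seg_up <- threshold_mV + (peak_mV - threshold_mV) *
    sin(pi / 2 * seq_len(n_rise) / n_rise)
  seg_down <- threshold_mV + (peak_mV - threshold_mV) *
    cos(pi / 2 * seq_len(n_fall) / n_fall)
  n_ahp <- round(ahp_ms / dt_ms); n_rec <- round(recover_ms / dt_ms)
  seg_ahp <- threshold_mV - ahp_depth_mV * sin(pi / 2 * seq_len(n_ahp) / n_ahp)
  amin <- threshold_mV - ahp_depth_mV
  seg_rec <- base + (amin - base) * cos(pi / 2 * seq_len(n_rec) / n_rec)
  block <- c(seg_appr, seg_up, seg_down, seg_ahp, seg_rec,
             rep(base, round(inter_ms / dt_ms)))
  y <- c(seg_base, rep(block, n_aps), rep(base, round(10 / dt_ms)))
  thr_idx <- length(seg_base) + length(seg_appr) +
    (seq_len(n_aps) - 1) * length(block)
  tr <- trace(y, rate_hz, "mV")
  attr(tr, "truth") <- list(threshold_mV = threshold_mV, peak_mV = peak_mV,
                            amplitude_mV = peak_mV - threshold_mV,
                            width_ms = (n_rise + n_fall) * dt_ms,
                            ahp_mV = ahp_depth_mV,
                            ahp_min_mV = amin,
                            threshold_times_s = (thr_idx - 1) / rate_hz)
  tr
}

#' Simulate a behavioural seizure diary
#'
#' Per-animal Poisson seizure onsets over a continuous monitoring window,
#' exponential durations, severities drawn on the modified Racine grades
#' 3-5 (lower grades are not registered).
#'
#' @param n_animals Number of animals.
#' @param days Monitoring duration (default 7 days of continuous video).
#' @param rate_per_hour Seizure rate per animal.
#' @param mean_dur_s Mean seizure duration (s).
#' @param severity_probs Probabilities for grades 3, 4, 5.
#' @param motor_prob Probability a seizure has a motor component.
#' @param group Group label applied to all animals in this call.
#' @param animal_ids Optional explicit ids (default `A1...`).
#' @param seed RNG seed.
#' @return A `seizure_diary`: list with `records` (data.frame `animal_id`,
#'   `group`, `onset_s`, `duration_s`, `severity`, `motor`), `animals`
#'   (one row per monitored animal, including any with zero seizures) and
#'   `window_s`.
#' @export
gen_seizure_diary <- function(n_animals = 8, days = 7,
                              rate_per_hour = 1 / 12, mean_dur_s = 23,
                              severity_probs = c(0.1, 0.3, 0.6),
                              motor_prob = 1, group = "non_grafted",
                              animal_ids = NULL, seed = NULL) {
  stopifnot(rate_per_hour >= 0, mean_dur_s > 0,
            length(severity_probs) == 3)
  .with_seed(seed, {
    window_s <- days * 86400
    if (is.null(animal_ids))
      animal_ids <- paste0(substr(group, 1, 1), seq_len(n_animals))
    recs <- lapply(seq_len(n_animals), function(i) {
      k <- stats::rpois(1L, rate_per_hour * days * 24)
      if (k == 0) return(NULL)
      data.frame(animal_id = animal_ids[i], group = group,
                 onset_s = sort(stats::runif(k, 0, window_s)),
                 duration_s = stats::rexp(k, 1 / mean_dur_s),
                 severity = sample(3:5, k, replace = TRUE,
                                   prob = severity_probs),
                 motor = stats::runif(k) < motor_prob)
    })
    seizure_diary(do.call(rbind, recs),
                  animals = data.frame(animal_id = animal_ids,
                                       group = group),
                  window_s = window_s)
  })
}
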