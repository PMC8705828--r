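# Passive membrane properties, action-potential features and light-evoked
# response metrics from single-cell recordings.

#' Estimate passive membrane properties from test-pulse responses
#'
#' From the current response to repeated small voltage steps (5 mV,
#' 100 ms): series resistance `Rs = dV / I_peak` from the instantaneous
#' capacitive transient, input resistance `Ri = dV / I_ss - Rs` from the
#' steady-state current, and membrane capacitance by charge integration of
#' the transient, `Cm = (Q / dV) x ((Rs + Ri) / Ri)^2`, where
#' `Q = integral of (I - I_ss)` over the transient. The quadratic factor
#' undoes the attenuation of the capacitive charge by the
#' series-resistance divider (without it the estimate is biased low by
#' `(Ri / (Rs + Ri))^2`). Multiple pulses are aligned and averaged before
#' estimation. The transient is integrated from the step onset until the
#' current first settles within 2 noise-SDs of the steady state.
#'
#' @param x Current `trace` (pA).
#' @param step_windows data.frame with `on_s`, `off_s` per pulse (e.g.
#'   from [gen_test_pulse_response()]).
#' @param step_mV Step amplitude (default 5).
#' @param baseline_ms Pre-step baseline used for the holding current and
#'   the noise SD (default 10).
#' @param steady_ms Portion at the end of the step averaged for the
#'   steady-state current (default 20).
#' @param rmp_mV Resting membrane potential to report: either supplied
#'   directly (e.g. the zero-current voltage reading after break-in) or
#'   via `voltage`, a voltage `trace` at zero injected current whose
#'   median is used.
#' @param voltage Optional zero-current voltage `trace` for the RMP.
#' @return List of class `membrane_props`: `rmp_mV`, `rs_MOhm`, `ri_MOhm`,
#'   `cm_pF`, plus `tau_ms`, `flagged` (TRUE when no transient was
#'   detectable) and `warning` (steady state not reached).
#' @export
estimate_membrane_props <- function(x, step_windows, step_mV = 5,
                                    baseline_ms = 10, steady_ms = 20,
                                    rmp_mV = NA_real_, voltage = NULL) {
  stopifnot(is_trace(x))
  if (x$units != "pA") stop("response must be a current trace in pA",
                            call. = FALSE)
  fs <- x$rate_hz
  dt <- 1 / fs
  n_pre <- round(baseline_ms / 1000 * fs)
  dur <- min(step_windows$off_s - step_windows$on_s)
  n_step <- round(dur * fs)
  # align and average the pulses
  segs <- lapply(seq_len(nrow(step_windows)), function(p) {
    i_on <- round((step_windows$on_s[p] - x$t0_s) * fs) + 1
    lo <- i_on - n_pre; hi <- i_on + n_step - 1L
    if (lo < 1 || hi > length(x$samples))
      stop("step window outside trace", call. = FALSE)
    x$samples[lo:hi]
  })
  avg <- Reduce(`+`, segs) / length(segs)
  base <- avg[seq_len(n_pre)]
  i0 <- stats::median(base)
  noise_sd <- stats::sd(base)
  step <- avg[(n_pre + 1L):length(avg)] - i0
  n_ss <- min(length(step), round(steady_ms / 1000 * fs))
  i_ss <- mean(step[(length(step) - n_ss + 1L):length(step)])
  sgn <- sign(i_ss + sign(step_mV) * 1e-12)
  trans <- sgn * (step - i_ss)             # decaying positive transient
  pk <- which.max(trans)
  i_peak <- abs(step[pk])
  if (!(i_peak > abs(i_ss)) || trans[pk] <= max(3 * noise_sd, 1e-9)) {
    return(structure(list(rmp_mV = .rmp_from(rmp_mV, voltage),
                          rs_MOhm = NA_real_, ri_MOhm = NA_real_,
                          cm_pF = NA_real_, tau_ms = NA_real_,
                          flagged = TRUE, warning = NA_character_),
                     class = "membrane_props"))
  }
  # slope test over the steady window: warn when still relaxing
  ss_seg <- step[(length(step) - n_ss + 1L):length(step)]
  drift <- abs(stats::coef(stats::lm(ss_seg ~ seq_along(ss_seg)))[2]) * n_ss
  warn <- if (drift > max(2 * noise_sd, 0.02 * abs(i_ss)))
    "steady state not reached within the step" else NA_character_
  # integrate the transient until it first settles into the noise band
  band <- max(2 * noise_sd, 1e-4 * trans[pk])
  settled <- which(trans < band)
  settled <- settled[settled > pk]
  i_end <- if (length(settled)) settled[1L] else length(trans)
  # trapezoid rule; the left-Riemann sum overestimates a decaying
  # exponential by ~peak*dt/2 (several percent at 10 kHz)
  q_pA_ms <- (sum(trans[seq_len(i_end)]) -
                (trans[1L] + trans[i_end]) / 2) * dt * 1000  # pA*ms/mV = pF
  rs <- step_mV / i_peak * 1000                   # mV / pA -> GOhm; x1000 = MOhm
  ri <- step_mV / abs(i_ss) * 1000 - rs
  cm_raw <- q_pA_ms / step_mV                     # pA*ms/mV = pF
  cm <- cm_raw * ((rs + ri) / ri)^2
  tau_ms <- cm * rs * ri / (rs + ri) * 1e-3
  structure(list(rmp_mV = .rmp_from(rmp_mV, voltage), rs_MOhm = rs,
                 ri_MOhm = ri, cm_pF = cm, tau_ms = tau_ms,
                 flagged = FALSE, warning = warn),
            class = "membrane_props")
}

.rmp_from <- function(rmp_mV, voltage) {
  if (!is.null(voltage)) {
    stopifnot(is_trace(voltage), voltage$units == "mV")
    stats::median(voltage$samples)
  } else rmp_mV
}

#' @export
print.membrane_props <- function(x, ...) {
  cat(sprintf("RMP %.1f mV | Rs %.2f MOhm | Ri %.1f MOhm | Cm %.1f pF\n",
              x$rmp_mV, x$rs_MOhm, x$ri_MOhm, x$cm_pF))
  invisible(x)
}

#' Action-potential features
#'
#' Threshold is the voltage at the first sample whose forward-difference
#' slope reaches the dV/dt criterion before the first peak; amplitude is
#' threshold to peak; duration is the width at the threshold voltage
#' (sub-sample interpolated crossings around the peak); the AHP amplitude
#' is threshold minus the post-AP minimum, reported positive. All
#' quantities are invariant to a constant voltage offset.
#'
#' @param x Voltage `trace` (mV) containing at least one AP (a peak above
#'   0 mV).
#' @param dvdt_mV_per_ms Slope criterion (default 20 mV/ms).
#' @return List of class `ap_features`: `threshold_mV`, `amplitude_mV`,
#'   `duration_ms`, `ahp_mV`, `peak_mV`, `threshold_time_s`,
#'   `peak_time_s`.
#' @export
ap_features <- function(x, dvdt_mV_per_ms = 20) {
  stopifnot(is_trace(x))
  if (x$units != "mV") stop("AP analysis expects a voltage trace in mV",
                            call. = FALSE)
  v <- x$samples
  fs <- x$rate_hz
  peaks <- .ap_peaks(v, fs)
  if (!length(peaks)) stop("no AP detected", call. = FALSE)
  pk <- peaks[1L]
  dvdt <- diff(v) * fs / 1000                       # mV/ms, forward diff
  cand <- which(dvdt[seq_len(pk - 1L)] >= dvdt_mV_per_ms)
  if (!length(cand)) stop("no AP detected", call. = FALSE)
  thr_i <- cand[1L]
  thr <- v[thr_i]
  # width at threshold: crossings bracketing the peak
  up <- .cross_time(v, thr, thr_i, pk, rising = TRUE)
  dn_end <- if (length(peaks) > 1L) peaks[2L] else length(v)
  dn <- .cross_time(v, thr, pk, dn_end, rising = FALSE)
  # AHP: minimum after the downward crossing, before the next AP
  ahp_lo <- min(length(v), ceiling(dn) + 1L)
  ahp_min <- min(v[ahp_lo:dn_end])
  structure(list(threshold_mV = thr, amplitude_mV = v[pk] - thr,
                 duration_ms = (dn - up) / fs * 1000,
                 ahp_mV = thr - ahp_min, peak_mV = v[pk],
                 threshold_time_s = x$t0_s + (thr_i - 1) / fs,
                 peak_time_s = x$t0_s + (pk - 1) / fs),
            class = "ap_features")
}

#' @export
print.ap_features <- function(x, ...) {
  cat(sprintf("threshold %.1f mV | amplitude %.1f mV | width %.2f ms | AHP %.1f mV\n",
              x$threshold_mV, x$amplitude_mV, x$duration_ms, x$ahp_mV))
  invisible(x)
}

# AP peaks: local maxima above 0 mV with a refractory separation
.ap_peaks <- function(v, fs, refractory_ms = 2) {
  above <- v > 0
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])
  pks <- vapply(seq_len(nrow(reg)), function(i)
    reg[i, 1] + which.max(v[reg[i, 1]:reg[i, 2]]) - 1L, 0L)
  keep <- c(TRUE, diff((pks - 1) / fs * 1000) >= refractory_ms)
  pks[keep]
}

# sub-sample crossing of `level` between samples a..b
.cross_time <- function(v, level, a, b, rising) {
  idx <- a:b
  if (rising) {
    hit <- which(v[idx] >= level)
    if (!length(hit)) return(a)
    i <- idx[hit[1L]]
    if (i == a || v[i] == v[i - 1L]) return(i)
    (i - 1) + (level - v[i - 1L]) / (v[i] - v[i - 1L])
  } else {
    hit <- which(v[idx] <= level)
    if (!length(hit)) return(b)
    i <- idx[hit[1L]]
    if (i == a || v[i] == v[i - 1L]) return(i)
    (i - 1) + (v[i - 1L] - level) / (v[i - 1L] - v[i])
  }
}

#' Count action potentials per current step
#'
#' Counts APs (0 mV-crossing peaks with a refractory rule) inside each
#' step window of a step protocol (e.g. 500 ms steps, -40 to +200 pA in
#' 10 pA increments).
#'
#' @param x Voltage `trace` (mV).
#' @param steps data.frame with `start_s`, `end_s`, `current_pA` per step.
#' @param refractory_ms Minimum peak separation (default 2 ms).
#' @return data.frame `current_pA`, `n_aps`, with attribute
#'   `"onset_current_pA"`: the smallest current with >= 1 AP (NA when the
#'   cell never fires).
#' @export
count_aps <- function(x, steps, refractory_ms = 2) {
  stopifnot(is_trace(x))
  counts <- vapply(seq_len(nrow(steps)), function(i) {
    seg <- slice_trace(x, steps$start_s[i], steps$end_s[i])
    length(.ap_peaks(seg$samples, seg$rate_hz, refractory_ms))
  }, 0L)
  out <- data.frame(current_pA = steps$current_pA, n_aps = counts)
  firing <- out$current_pA[out$n_aps >= 1L]
  attr(out, "onset_current_pA") <- if (length(firing)) min(firing)
                                   else NA_real_
  out
}

#' Light-evoked response metrics
#'
#' For a voltage-clamp current trace aligned to a light pulse: peak
#' current is the maximum baseline deviation within the pulse;
#' steady-state current is the mean deviation over the final
#' `steady_last_ms` of the pulse. When a current-clamp voltage trace is
#' supplied, AP generation and the light-onset-to-threshold latency are
#' measured. The latency to the first delayed synaptic event
#' (`syn_latency_ms`) is measured by PSC detection on the current trace
#' after excluding the direct-response window following light onset.
#'
#' @param current Current `trace` (pA).
#' @param light_on_s,light_dur_s Light pulse onset and duration (s);
#'   defaults describe the 500 ms continuous pulse.
#' @param voltage Optional voltage `trace` (mV) from the same stimulation.
#' @param config An [analysis_config()] (used for PSC detection and the AP
#'   threshold criterion).
#' @param steady_last_ms Steady-state averaging window at the pulse end
#'   (default 100 ms).
#' @param direct_window_ms Direct-response exclusion window after light
#'   onset when searching for delayed synaptic events (default 5 ms).
#' @param baseline_ms Pre-light baseline (default 50 ms).
#' @return List of class `opto_response`: `peak_current_pA`,
#'   `steady_state_current_pA`, `ap_generated`, `ap_onset_ms`,
#'   `syn_latency_ms` (NA when absent).
#' @export
opto_response <- function(current, light_on_s, light_dur_s = 0.5,
                          voltage = NULL, config = analysis_config(),
                          steady_last_ms = 100, direct_window_ms = 5,
                          baseline_ms = 50) {
  stopifnot(is_trace(current))
  fs <- current$rate_hz
  t_end <- current$t0_s + length(current$samples) / fs
  if (light_on_s < current$t0_s || light_on_s + light_dur_s > t_end)
    stop("light pulse outside trace", call. = FALSE)
  i_on <- round((light_on_s - current$t0_s) * fs) + 1
  i_off <- i_on + round(light_dur_s * fs) - 1L
  ib <- max(1L, i_on - round(baseline_ms / 1000 * fs))
  base <- stats::median(current$samples[ib:max(ib, i_on - 1L)])
  dev <- abs(current$samples[i_on:i_off] - base)
  peak <- max(dev)
  n_ss <- min(length(dev), round(steady_last_ms / 1000 * fs))
  ss <- mean(dev[(length(dev) - n_ss + 1L):length(dev)])
  ap_generated <- FALSE
  ap_onset_ms <- NA_real_
  if (!is.null(voltage)) {
    seg <- slice_trace(voltage, light_on_s,
                       min(t_end, light_on_s + light_dur_s + 0.05))
    feat <- tryCatch(ap_features(seg, config$ap_dvdt_mV_per_ms),
                     error = function(e) NULL)
    if (!is.null(feat)) {
      ap_generated <- TRUE
      ap_onset_ms <- (feat$threshold_time_s - light_on_s) * 1000
    }
  }
  syn_latency_ms <- NA_real_
  search_from <- light_on_s + direct_window_ms / 1000
  if (search_from < t_end - 0.05) {
    seg <- slice_trace(current, search_from, t_end)
    ev <- tryCatch(detect_pscs(seg, config = config),
                   error = function(e) NULL)
    if (!is.null(ev) && nrow(ev))
      syn_latency_ms <- (ev$time_s[1L] - light_on_s) * 1000
  }
  structure(list(peak_current_pA = peak, steady_state_current_pA = ss,
                 ap_generated = ap_generated, ap_onset_ms = ap_onset_ms,
                 syn_latency_ms = syn_latency_ms),
            class = "opto_response")
}

#' Correlation of photocurrent amplitude with AP onset latency
#'
#' Spearman rank correlation of the light-onset-to-AP-threshold latency
#' against the peak and the steady-state photocurrent across cells.
#'
#' @param responses data.frame with columns `ap_onset_ms`,
#'   `peak_current_pA`, `steady_state_current_pA` (one row per cell), or a
#'   list of `opto_response` objects.
#' @return data.frame per current measure: `measure`, `rho`, `p_value`,
#'   `n`.
#' @export
latency_correlation <- function(responses) {
  if (is.list(responses) && !is.data.frame(responses))
    responses <- do.call(rbind, lapply(responses, function(r)
      data.frame(ap_onset_ms = r$ap_onset_ms,
                 peak_current_pA = r$peak_current_pA,
                 steady_state_current_pA = r$steady_state_current_pA)))
  out <- lapply(c("peak_current_pA", "steady_state_current_pA"),
                function(m) {
    ok <- is.finite(responses$ap_onset_ms) & is.finite(responses[[m]])
    if (sum(ok) < 5)
      stop("need >= 5 cells with both latency and ", m, call. = FALSE)
    res <- spearman(responses$ap_onset_ms[ok], responses[[m]][ok])
    data.frame(measure = m, rho = res$statistic, p_value = res$p_value,
               n = sum(ok))
  })
  do.call(rbind, out)
}
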