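# Template-correlation detection of spontaneous postsynaptic currents.
#
# The recordings this targets use a high-chloride internal solution that
# makes all PSCs inward: the detector searches negative deflections and
# reports amplitudes as positive magnitudes.

#' PSC detection template
#'
#' Parametric template: the difference-of-exponentials kernel over a fixed
#' window, stored as the inward waveform (peak magnitude 1, negative peak).
#'
#' @param rise_tau_ms,decay_tau_ms Kernel time constants.
#' @param window_ms Template window (also the correlation window).
#' @param rate_hz Sampling rate the template is built for.
#' @return Object of class `psc_template` with fields `kernel` (length-L
#'   inward waveform, min value -1), `source`, `rise_tau_ms`,
#'   `decay_tau_ms`, `rate_hz`.
#' @export
psc_template <- function(rise_tau_ms = 0.5, decay_tau_ms = 5,
                         window_ms = 20, rate_hz = 10000) {
  kern <- -psc_kernel(rise_tau_ms, decay_tau_ms, window_ms, rate_hz)
  if (length(kern) < 10L) stop("template must span >= 10 samples",
                               call. = FALSE)
  structure(list(kernel = kern, source = "parametric",
                 rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 rate_hz = rate_hz),
            class = "psc_template")
}

#' Derive a PSC template from the data
#'
#' Averages the trace windows around high-confidence detections obtained
#' with a parametric seed template, then normalizes to peak magnitude 1.
#' Useful when the parametric kinetics are a poor match for the cell.
#'
#' @param x A `trace` (pA).
#' @param config An [analysis_config()].
#' @param corr_min Correlation cutoff defining "high-confidence" (default
#'   0.8, stricter than the detection cutoff).
#' @param seed_template Optional parametric seed; default from `config`.
#' @return A `psc_template` with `source = "data_derived"`.
#' @export
derive_template <- function(x, config = analysis_config(), corr_min = 0.8,
                            seed_template = NULL) {
  if (is.null(seed_template))
    seed_template <- psc_template(window_ms = config$psc_window_ms,
                                  rate_hz = x$rate_hz)
  ev <- detect_pscs(x, seed_template, config)
  ev <- ev[ev$correlation >= corr_min, , drop = FALSE]
  if (nrow(ev) < 3L)
    stop("too few high-confidence events to derive a template",
         call. = FALSE)
  L <- length(seed_template$kernel)
  idx <- round((ev$time_s - x$t0_s) * x$rate_hz) + 1
  idx <- idx[idx + L - 1 <= length(x$samples)]
  mat <- vapply(idx, function(i) {
    w <- x$samples[i:(i + L - 1)]
    w - stats::median(w[seq_len(max(1L, round(
      config$psc_baseline_ms / 1000 * x$rate_hz / 4)))])
  }, numeric(L))
  avg <- rowMeans(mat)
  structure(list(kernel = avg / max(abs(avg)), source = "data_derived",
                 rise_tau_ms = NA_real_, decay_tau_ms = NA_real_,
                 rate_hz = x$rate_hz),
            class = "psc_template")
}

# zero-phase filtering with odd-reflection padding: suppresses the edge
# transients signal::filtfilt() otherwise leaves (pad covers ~3 time
# constants of the filter's lowest edge frequency)
.zero_phase <- function(bf, x, rate_hz, low_edge_hz) {
  n <- length(x)
  p <- min(n - 1L, max(60L, round(3 * rate_hz / low_edge_hz)))
  head_pad <- 2 * x[1L] - x[(p + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(p + 1L):(p + n)]
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase shift),
#' with reflection padding so edges carry no filter transient; output has
#' the same length and rate as the input.
#'
#' @param x A `trace`.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @return Filtered `trace`.
#' @export
lowpass_filter <- function(x, cutoff_hz = 400) {
  stopifnot(is_trace(x))
  if (cutoff_hz >= x$rate_hz / 2)
    stop("cutoff_hz must be below Nyquist (", x$rate_hz / 2, " Hz)",
         call. = FALSE)
  bf <- signal::butter(4, cutoff_hz / (x$rate_hz / 2), type = "low")
  trace(.zero_phase(bf, x$samples, x$rate_hz, cutoff_hz), x$rate_hz,
        x$units, t0_s = x$t0_s, meta = x$meta)
}

# Sliding Pearson correlation of `w` against every length(w) window of `x`,
# vectorized with running sums; window k starts at sample k.
.sliding_correlation <- function(x, w) {
  n <- length(x); L <- length(w)
  if (L > n) stop("template longer than trace", call. = FALSE)
  mw <- mean(w)
  ssw <- sum((w - mw)^2)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  k <- seq_len(n - L + 1L)
  sx <- cs[k + L] - cs[k]
  sxx <- cs2[k + L] - cs2[k]
  # cross-correlation sum_i x[k+i-1] w[i] via FFT convolution
  # (convolve(type = "filter") slides y over x without reversal)
  dot <- stats::convolve(x, w, type = "filter")
  num <- dot - sx * mw
  den2 <- (sxx - sx^2 / L) * ssw
  r <- numeric(length(k))
  ok <- den2 > 1e-24
  r[ok] <- num[ok] / sqrt(den2[ok])
  pmin(1, pmax(-1, r))
}

#' Per-event amplitude, rise time and peak time
#'
#' Baseline is the median of the pre-onset baseline window; amplitude is
#' the magnitude of the extremum relative to baseline within the event
#' window; rise time is the 10-90% interval on the rising phase (onset to
#' peak), with sub-sample linear interpolation at both crossings.
#'
#' @param x A `trace` (pA for PSC work; any units accepted).
#' @param onset_s Event onset time (s).
#' @param window_ms Event window after onset.
#' @param baseline_ms Pre-onset baseline window.
#' @param direction `"negative"` for inward currents (default) or
#'   `"positive"`.
#' @return List with `amplitude_pA`, `rise_time_ms`, `peak_time_s`,
#'   `truncated` (TRUE when the event window runs past the trace end, in
#'   which case the metrics are NA and the event should be excluded from
#'   summaries).
#' @export
event_metrics <- function(x, onset_s, window_ms = 20, baseline_ms = 5,
                          direction = c("negative", "positive")) {
  stopifnot(is_trace(x))
  direction <- match.arg(direction)
  fs <- x$rate_hz
  i0 <- round((onset_s - x$t0_s) * fs) + 1
  if (i0 < 1 || i0 > length(x$samples))
    stop("onset outside trace", call. = FALSE)
  iw <- i0 + round(window_ms / 1000 * fs) - 1
  if (iw > length(x$samples))
    return(list(amplitude_pA = NA_real_, rise_time_ms = NA_real_,
                peak_time_s = NA_real_, truncated = TRUE))
  sgn <- if (direction == "negative") -1 else 1
  # refine the onset: find the extremum after the mark, then walk back
  # along a lightly smoothed copy to where the deflection started -- a
  # mark that is late (e.g. template/kinetics mismatch) would otherwise
  # put the baseline window onto the rising phase
  pk0 <- i0 - 1L + which.max(sgn * x$samples[i0:iw])
  back <- max(1L, pk0 - round(window_ms / 1000 * fs))
  sm <- stats::filter(sgn * x$samples[back:pk0], rep(1 / 7, 7),
                      sides = 2)
  sm[is.na(sm)] <- sgn * x$samples[back:pk0][is.na(sm)]
  j <- length(sm)
  while (j > 1L && sm[j - 1L] < sm[j]) j <- j - 1L
  i0 <- min(i0, back + j - 1L)
  ib <- max(1L, i0 - round(baseline_ms / 1000 * fs))
  bl <- stats::median(x$samples[ib:max(ib, i0 - 1L)])
  # the measurement segment includes the pre-onset margin so a slightly
  # late detection mark still sees the whole rising phase
  seg <- x$samples[ib:iw]
  if (direction == "negative") seg <- bl - seg else seg <- seg - bl
  off <- i0 - ib                    # samples of pre-onset margin
  pk <- off + which.max(seg[(off + 1L):length(seg)])
  amp <- seg[pk]
  if (!is.finite(amp) || amp <= 0)
    return(list(amplitude_pA = NA_real_, rise_time_ms = NA_real_,
                peak_time_s = NA_real_, truncated = FALSE))
  # 10-90% crossings walking backward from the peak: immune to baseline
  # activity earlier in the margin
  t90 <- .last_crossing(seg, 0.9 * amp, pk)
  t10 <- .last_crossing(seg, 0.1 * amp, ceiling(t90) + 1L)
  list(amplitude_pA = amp,
       rise_time_ms = (t90 - t10) / fs * 1000,
       peak_time_s = x$t0_s + (ib + pk - 2) / fs,
       truncated = FALSE)
}

# last upward crossing of `level` strictly before sample `before`
# (0-based fractional index, linear interpolation; 0 when never below)
.last_crossing <- function(v, level, before) {
  upto <- min(before, length(v))
  below <- which(v[seq_len(upto - 1L)] < level)
  if (!length(below)) return(0)
  i <- below[length(below)]
  frac <- (level - v[i]) / (v[i + 1L] - v[i])
  (i - 1L) + frac
}

#' Detect spontaneous postsynaptic currents
#'
#' Sliding-window Pearson correlation between the inward template and the
#' (400 Hz low-pass filtered) trace; candidate onsets at correlation
#' maxima above `psc_corr_min` with a minimum separation; candidates whose
#' amplitude or 10-90% rise time violate the acceptance rules
#' (amplitude >= 3 pA, rise time <= 5 ms by default) are removed.
#'
#' @param x A `trace` in pA.
#' @param template A [psc_template()]; default parametric at the trace
#'   rate.
#' @param config An [analysis_config()]. Set `psc_corr_min = -1`,
#'   `psc_amp_min_pA = 0` or `psc_rise_max_ms = Inf` to toggle individual
#'   exclusion rules off.
#' @param filter Low-pass filter before detection (default TRUE).
#' @return data.frame with one row per accepted event: `time_s` (onset),
#'   `peak_time_s`, `amplitude_pA`, `rise_time_ms`, `correlation`,
#'   `iei_ms` (NA for the first event). Attribute `"rejected"` holds the
#'   candidates that failed the amplitude/rise rules with a `reason`
#'   column.
#' @export
detect_pscs <- function(x, template = NULL, config = analysis_config(),
                        filter = TRUE) {
  stopifnot(is_trace(x))
  if (x$units != "pA") stop("PSC detection expects a current trace in pA",
                            call. = FALSE)
  if (is.null(template))
    template <- psc_template(window_ms = config$psc_window_ms,
                             rate_hz = x$rate_hz)
  if (!isTRUE(all.equal(template$rate_hz, x$rate_hz)))
    stop("template and trace sampling rates differ", call. = FALSE)
  y <- if (filter && config$psc_lowpass_hz < x$rate_hz / 2)
    lowpass_filter(x, config$psc_lowpass_hz) else x
  r <- .sliding_correlation(y$samples, template$kernel)
  fs <- x$rate_hz
  min_sep <- max(1L, round(config$psc_min_separation_ms / 1000 * fs))
  # candidates: local maxima of the correlation above the cutoff. The
  # correlation of one event stays high along its decay, so plateau
  # wiggles are suppressed by a prominence rule -- a weaker peak is only
  # kept if the correlation dips well below it between it and every
  # stronger accepted peak (a genuine valley separates distinct events,
  # e.g. two PSCs overlapping within the template window).
  is_max <- c(TRUE, diff(r) >= 0) & c(diff(r) < 0, TRUE)
  cand <- which(is_max & r >= config$psc_corr_min)
  if (!length(cand)) return(.empty_psc_events())
  cand <- cand[order(r[cand], decreasing = TRUE)]
  prom <- 0.05
  acc <- integer(0)
  for (i in cand) {
    if (length(acc)) {
      if (any(abs(acc - i) <= min_sep)) next
      left <- acc[acc < i]; right <- acc[acc > i]
      valley_ok <- TRUE
      if (length(left)) {
        j <- max(left)
        if (min(r[j:i]) > r[i] - prom) valley_ok <- FALSE
      }
      if (valley_ok && length(right)) {
        j <- min(right)
        if (min(r[i:j]) > r[i] - prom) valley_ok <- FALSE
      }
      if (!valley_ok) next
    }
    acc <- c(acc, i)
  }
  onsets <- sort(acc)
  met <- lapply(onsets, function(i)
    event_metrics(y, y$t0_s + (i - 1) / fs,
                  window_ms = config$psc_window_ms,
                  baseline_ms = config$psc_baseline_ms))
  ev <- data.frame(
    time_s = x$t0_s + (onsets - 1) / fs,
    peak_time_s = vapply(met, `[[`, 0, "peak_time_s"),
    amplitude_pA = vapply(met, `[[`, 0, "amplitude_pA"),
    rise_time_ms = vapply(met, `[[`, 0, "rise_time_ms"),
    correlation = r[onsets],
    truncated = vapply(met, `[[`, NA, "truncated")
  )
  bad_amp <- !is.na(ev$amplitude_pA) & ev$amplitude_pA < config$psc_amp_min_pA
  bad_rise <- !is.na(ev$rise_time_ms) & ev$rise_time_ms > config$psc_rise_max_ms
  bad_na <- is.na(ev$amplitude_pA) | is.na(ev$rise_time_ms) | ev$truncated
  rejected <- ev[bad_amp | bad_rise | bad_na, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- ifelse(bad_na[bad_amp | bad_rise | bad_na],
                              "unmeasurable",
                       ifelse(bad_amp[bad_amp | bad_rise | bad_na],
                              "amplitude", "rise_time"))
  ev <- ev[!(bad_amp | bad_rise | bad_na), , drop = FALSE]
  ev$truncated <- NULL
  ev$iei_ms <- if (nrow(ev)) c(NA_real_, diff(ev$time_s) * 1000)
               else numeric(0)
  rownames(ev) <- NULL
  attr(ev, "rejected") <- rejected
  ev
}

.empty_psc_events <- function() {
  ev <- data.frame(time_s = numeric(0), peak_time_s = numeric(0),
                   amplitude_pA = numeric(0), rise_time_ms = numeric(0),
                   correlation = numeric(0), iei_ms = numeric(0))
  attr(ev, "rejected") <- ev
  ev
}

#' Per-cell summary of accepted PSC events
#'
#' @param events Event data.frame from [detect_pscs()].
#' @param duration_s Analysed duration (s).
#' @return List with `n_events`, `median_amplitude_pA`,
#'   `median_rise_time_ms`, `frequency_hz` (= n / duration),
#'   `median_iei_ms`, and `flagged` (TRUE when there were no events, in
#'   which case the medians are NA).
#' @export
summarize_cell <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  n <- nrow(events)
  list(
    n_events = n,
    median_amplitude_pA = if (n) stats::median(events$amplitude_pA) else NA_real_,
    median_rise_time_ms = if (n) stats::median(events$rise_time_ms) else NA_real_,
    frequency_hz = n / duration_s,
    median_iei_ms = if (n > 1) stats::median(events$iei_ms, na.rm = TRUE)
                    else NA_real_,
    flagged = n == 0
  )
}

#' Equal-n random subsample of events per cell
#'
#' For distribution comparisons an equal number of events is analysed from
#' every cell. Cells with fewer than `n` accepted events are excluded and
#' reported.
#'
#' @param events_by_cell Named list of event data.frames (one per cell).
#' @param n Events to keep per cell (default 42).
#' @param seed RNG seed (subsampling is deterministic given the seed).
#' @return List with `selected` (named list of n-row data.frames) and
#'   `excluded` (character vector of cell names with < n events).
#' @export
equal_n_subsample <- function(events_by_cell, n = 42, seed = NULL) {
  if (!is.numeric(n) || n <= 0) stop("n must be positive", call. = FALSE)
  counts <- vapply(events_by_cell, nrow, 0L)
  excl <- names(events_by_cell)[counts < n]
  keep <- events_by_cell[counts >= n]
  .with_seed(seed, {
    sel <- lapply(keep, function(ev) {
      idx <- sort(sample.int(nrow(ev), n))
      ev[idx, , drop = FALSE]
    })
    list(selected = sel, excluded = excl)
  })
}
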