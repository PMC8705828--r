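# Detection and scoring of epileptiform discharges in LFP recordings, and
# quantification of paired dark/light stimulation effects.

#' Preprocess an LFP trace
#'
#' In order: zero-phase band-pass (2-400 Hz Butterworth), comb filter
#' (zero-phase notches at the power-line fundamental and its harmonics up
#' to the band's upper edge), anti-aliased integer-factor downsampling to
#' `out_rate_hz`. The band-pass upper edge doubles as the anti-aliasing
#' filter for the downsample.
#'
#' @param x A `trace` (uV).
#' @param band_hz Band-pass edges, default `c(2, 400)`.
#' @param mains_hz Power-line fundamental (default 50 Hz).
#' @param out_rate_hz Output rate (default 1000 Hz); the input rate must be
#'   an integer multiple, and `out_rate_hz` must exceed twice the band's
#'   upper edge.
#' @param notch_halfwidth_hz Half-width of each notch (default 2 Hz).
#' @return Preprocessed `trace` at `out_rate_hz`.
#' @export
preprocess_lfp <- function(x, band_hz = c(2, 400), mains_hz = 50,
                           out_rate_hz = 1000, notch_halfwidth_hz = 2) {
  stopifnot(is_trace(x))
  nyq <- x$rate_hz / 2
  if (band_hz[2] >= nyq)
    stop("band upper edge must be below input Nyquist", call. = FALSE)
  if (out_rate_hz < 2 * band_hz[2])
    stop("out_rate_hz below 2x band upper edge would alias", call. = FALSE)
  factor <- x$rate_hz / out_rate_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop("input rate must be an integer multiple of out_rate_hz",
         call. = FALSE)
  bf <- signal::butter(2, band_hz / nyq, type = "pass")
  y <- .zero_phase(bf, x$samples, x$rate_hz, band_hz[1])
  harmonics <- seq(mains_hz, band_hz[2], by = mains_hz)
  for (h in harmonics) {
    nf <- signal::butter(2, c(h - notch_halfwidth_hz,
                              h + notch_halfwidth_hz) / nyq,
                         type = "stop")
    y <- .zero_phase(nf, y, x$rate_hz, notch_halfwidth_hz * 2)
  }
  idx <- seq(1L, length(y), by = round(factor))
  trace(y[idx], out_rate_hz, x$units, t0_s = x$t0_s, meta = x$meta)
}

#' Sliding-window signal power
#'
#' Power at position `k` is the mean of squared samples in the window of
#' `window_ms` starting at sample `k`, sliding sample-by-sample; the value
#' is assigned to the window's start sample. With `stat = "sum"` the
#' unnormalized sum of squares is returned instead (units uV^2 x samples).
#'
#' @param x A `trace`.
#' @param window_ms Window length (default 50 ms; >= 2 samples).
#' @param stat `"mean"` (default) or `"sum"`.
#' @return Object of class `power_series`: list with `values`
#'   (length `n - window + 1`), `rate_hz`, `window_ms`, `t0_s`, `stat`.
#' @export
sliding_power <- function(x, window_ms = 50, stat = c("mean", "sum")) {
  stopifnot(is_trace(x))
  stat <- match.arg(stat)
  w <- round(window_ms / 1000 * x$rate_hz)
  if (w < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (w > length(x$samples)) stop("window longer than trace", call. = FALSE)
  cs <- c(0, cumsum(x$samples^2))
  k <- seq_len(length(x$samples) - w + 1L)
  v <- cs[k + w] - cs[k]
  if (stat == "mean") v <- v / w
  structure(list(values = pmax(v, 0), rate_hz = x$rate_hz,
                 window_ms = window_ms, t0_s = x$t0_s, stat = stat),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> %d values @ %g Hz, %g ms window (%s of squares)\n",
              length(x$values), x$rate_hz, x$window_ms, x$stat))
  invisible(x)
}

# population moments kurtosis; "pearson" is the non-excess form m4/m2^2
# (Gaussian -> 3), which keeps median x kurtosis a positive scale factor
.kurtosis <- function(v, type = c("pearson", "excess")) {
  type <- match.arg(type)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 <= 0) stop("kurtosis undefined for a constant series",
                    call. = FALSE)
  k <- mean((v - m)^4) / m2^2
  if (type == "excess") k - 3 else k
}

#' Adaptive discharge-detection threshold
#'
#' `threshold = factor x median(power) x kurtosis(power)`; the kurtosis of
#' the power series grows with the prominence of rare high-power events,
#' scaling the threshold to the recording.
#'
#' @param power A [sliding_power()] result.
#' @param factor Multiplier (default 4).
#' @param kurtosis `"pearson"` (non-excess, default) or `"excess"`.
#' @return Threshold in the power units (uV^2 for `stat = "mean"`).
#' @export
detection_threshold <- function(power, factor = 4,
                                kurtosis = c("pearson", "excess")) {
  stopifnot(inherits(power, "power_series"))
  factor * stats::median(power$values) * .kurtosis(power$values, kurtosis)
}

#' Coastline index of a signal segment
#'
#' `(1/N) * sum_{n=1}^{N-1} |y[n+1] - y[n]|` -- the mean absolute
#' sample-to-sample difference, a line-length measure of signal
#' complexity. Note the normalization by `N`, not `N - 1`.
#'
#' @param x A `trace` or numeric vector (N >= 2).
#' @return Coastline in the signal's units.
#' @export
coastline_index <- function(x) {
  v <- if (is_trace(x)) x$samples else as.numeric(x)
  if (length(v) < 2L) stop("coastline needs at least 2 samples",
                           call. = FALSE)
  sum(abs(diff(v))) / length(v)
}

#' Detect epileptiform discharges from a power series
#'
#' Finds contiguous supra-threshold regions of the power series (regions
#' separated by less than `merge_gap_ms` are merged so one biphasic
#' discharge is not marked twice), marks one detection per region at the
#' power maximum, and scores each event on the filtered signal:
#' peak-to-peak amplitude and coastline over a window of `event_window_ms`
#' centred on the mark (or the supra-threshold region if longer), and the
#' region's peak power.
#'
#' @param power A [sliding_power()] result.
#' @param threshold Detection threshold (> 0), e.g. from
#'   [detection_threshold()].
#' @param filtered The preprocessed `trace` the power was computed from.
#' @param event_window_ms Metric window (default 200 ms).
#' @param merge_gap_ms Region merge gap (default 25 ms).
#' @return data.frame with one row per discharge: `time_s`,
#'   `region_start_s`, `region_end_s`, `p2p_uV`, `peak_power_uV2`,
#'   `coastline_uV`. Empty when nothing exceeds the threshold.
#' @export
detect_discharges <- function(power, threshold, filtered,
                              event_window_ms = 200, merge_gap_ms = 25) {
  stopifnot(inherits(power, "power_series"), is_trace(filtered))
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  v <- power$values
  fs <- power$rate_hz
  above <- v > threshold
  if (!any(above)) return(.empty_discharges())
  # run-length regions of supra-threshold power
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])
  gap <- max(0L, round(merge_gap_ms / 1000 * fs))
  if (nrow(reg) > 1L) {
    merged <- reg[1, , drop = FALSE]
    for (i in 2:nrow(reg)) {
      if (reg[i, 1] - merged[nrow(merged), 2] < gap)
        merged[nrow(merged), 2] <- reg[i, 2]
      else merged <- rbind(merged, reg[i, ])
    }
    reg <- merged
  }
  half <- round(event_window_ms / 2000 * fs)
  n_sig <- length(filtered$samples)
  out <- lapply(seq_len(nrow(reg)), function(i) {
    a <- reg[i, 1]; b <- reg[i, 2]
    pk <- a + which.max(v[a:b]) - 1L
    # power index k maps to the window starting at signal sample k
    lo <- min(pk - half, a); hi <- max(pk + half, b)
    lo <- max(1L, lo); hi <- min(n_sig, hi)
    seg <- filtered$samples[lo:hi]
    data.frame(
      time_s = power$t0_s + (pk - 1) / fs,
      region_start_s = power$t0_s + (a - 1) / fs,
      region_end_s = power$t0_s + (b - 1) / fs,
      p2p_uV = max(seg) - min(seg),
      peak_power_uV2 = v[pk],
      coastline_uV = coastline_index(seg)
    )
  })
  do.call(rbind, out)
}

.empty_discharges <- function() {
  data.frame(time_s = numeric(0), region_start_s = numeric(0),
             region_end_s = numeric(0), p2p_uV = numeric(0),
             peak_power_uV2 = numeric(0), coastline_uV = numeric(0))
}

#' Full LFP discharge-detection pipeline
#'
#' Convenience wrapper: [preprocess_lfp()] -> [sliding_power()] ->
#' [detection_threshold()] -> [detect_discharges()], with all constants
#' taken from the configuration.
#'
#' @param x Raw LFP `trace` (uV).
#' @param config An [analysis_config()].
#' @return The event data.frame of [detect_discharges()], with attributes
#'   `"threshold_uV2"` and `"filtered"` (the preprocessed trace).
#' @export
detect_lfp_events <- function(x, config = analysis_config()) {
  filt <- preprocess_lfp(x, band_hz = config$lfp_band_hz,
                         mains_hz = config$mains_hz,
                         out_rate_hz = config$lfp_downsample_hz)
  pw <- sliding_power(filt, window_ms = config$power_window_ms,
                      stat = config$power_stat)
  thr <- detection_threshold(pw, factor = config$threshold_factor,
                             kurtosis = config$kurtosis)
  ev <- detect_discharges(pw, thr, filt,
                          event_window_ms = config$event_window_ms,
                          merge_gap_ms = config$merge_gap_ms)
  attr(ev, "threshold_uV2") <- thr
  attr(ev, "filtered") <- filt
  ev
}

#' Paired dark/light stimulation analysis
#'
#' For each run of the protocol, the event rate and the mean per-event
#' metrics are computed within the light episode and within the paired
#' dark period preceding it. Runs are then averaged per slice, giving one
#' dark and one light value per slice and parameter; their difference
#' (light minus dark) is evaluated across slices with the Wilcoxon
#' signed-rank test. Runs with no events in a state contribute a rate of 0
#' but are excluded from that state's metric average.
#'
#' @param events_by_slice List (one element per slice) of discharge event
#'   data.frames with at least `time_s`; metric columns `p2p_uV`,
#'   `peak_power_uV2`, `coastline_uV` are used when present.
#' @param schedule The [stim_schedule()] shared by all slices.
#' @return Object of class `light_effect`: list with `per_slice`
#'   (data.frame slice x parameter with `dark`, `light`, `diff`) and
#'   `tests` (data.frame per parameter: mean/median difference, Wilcoxon
#'   statistic and p-value, `n_slices`).
#' @export
light_effect_analysis <- function(events_by_slice, schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  ep <- schedule$episodes
  dk <- dark_periods(schedule)
  metrics <- c("p2p_uV", "peak_power_uV2", "coastline_uV")
  state_means <- function(ev, win) {
    len <- win$off_s - win$on_s
    per_run <- lapply(seq_len(nrow(win)), function(r) {
      inside <- ev$time_s >= win$on_s[r] & ev$time_s < win$off_s[r]
      out <- c(rate_hz = sum(inside) / len[r])
      for (m in metrics)
        out[m] <- if (m %in% names(ev) && any(inside))
          mean(ev[[m]][inside]) else NA_real_
      out
    })
    mat <- do.call(rbind, per_run)
    colMeans(mat, na.rm = TRUE)    # run average; all-NA metric -> NaN
  }
  per_slice <- lapply(seq_along(events_by_slice), function(s) {
    ev <- events_by_slice[[s]]
    d <- state_means(ev, dk)
    l <- state_means(ev, data.frame(on_s = ep$on_s, off_s = ep$off_s))
    data.frame(slice = s, parameter = names(d), dark = unname(d),
               light = unname(l), diff = unname(l - d))
  })
  per_slice <- do.call(rbind, per_slice)
  per_slice$dark[is.nan(per_slice$dark)] <- NA
  per_slice$light[is.nan(per_slice$light)] <- NA
  per_slice$diff[is.nan(per_slice$diff)] <- NA
  tests <- lapply(split(per_slice, per_slice$parameter), function(df) {
    d <- df$diff[is.finite(df$diff)]
    res <- if (length(d) >= 2 && any(d != 0))
      wilcoxon_signed_rank(d) else list(statistic = NA_real_,
                                        p_value = NA_real_)
    data.frame(parameter = df$parameter[1],
               mean_diff = mean(d), median_diff = stats::median(d),
               statistic = res$statistic, p_value = res$p_value,
               n_slices = length(d))
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(per_slice = per_slice, tests = tests),
            class = "light_effect")
}

#' @export
print.light_effect <- function(x, ...) {
  cat("Paired dark/light stimulation analysis\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
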