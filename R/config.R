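#' Analysis configuration
#'
#' Collects every tunable constant of the detection pipelines in one place.
#' Defaults follow the published protocol where one is stated; the remainder
#' are package conventions (see the methods vignette for provenance and
#' rationale per field).
#'
#' @param psc_corr_min Minimum Pearson correlation with the PSC template
#'   (protocol value 0.6).
#' @param psc_amp_min_pA Minimum PSC amplitude in pA (protocol value 3).
#' @param psc_rise_max_ms Maximum PSC 10-90% rise time in ms (protocol
#'   value 5).
#' @param psc_lowpass_hz Low-pass cutoff applied before PSC detection
#'   (protocol value 400).
#' @param psc_window_ms PSC template / event-metric window length (package
#'   convention, 20 ms).
#' @param psc_baseline_ms Pre-onset baseline window for PSC amplitude
#'   (package convention, 5 ms; median is used for robustness to
#'   overlapping tails).
#' @param psc_min_separation_ms Minimum separation between accepted PSC
#'   onsets (package convention, 2 ms: the template rise window).
#' @param lfp_band_hz Band-pass edges for LFP preprocessing (protocol value
#'   c(2, 400)).
#' @param lfp_downsample_hz Output rate after downsampling (protocol value
#'   1000).
#' @param power_window_ms Sliding power window (protocol value 50).
#' @param threshold_factor Multiplier in the adaptive detection threshold
#'   `factor x median x kurtosis` (protocol value 4).
#' @param mains_hz Power-line fundamental for the comb filter (50 Hz).
#' @param event_window_ms Window around each discharge mark for
#'   peak-to-peak and coastline metrics (package convention, 200 ms).
#' @param merge_gap_ms Supra-threshold regions closer than this are merged
#'   before marking maxima (package convention, 25 ms).
#' @param kurtosis Kurtosis convention for the threshold: `"pearson"`
#'   (non-excess, Gaussian -> 3; guarantees a positive scale factor) or
#'   `"excess"` for sensitivity analysis.
#' @param power_stat `"mean"` of squares in the window (units uV^2) or
#'   `"sum"` for sensitivity analysis.
#' @param ap_dvdt_mV_per_ms Slope criterion defining the AP threshold
#'   (package convention, 20 mV/ms; 10 and 50 are common alternatives).
#' @param rng_seed Seed recorded with analysis runs.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(psc_corr_min = 0.6,
                            psc_amp_min_pA = 3,
                            psc_rise_max_ms = 5,
                            psc_lowpass_hz = 400,
                            psc_window_ms = 20,
                            psc_baseline_ms = 5,
                            psc_min_separation_ms = 2,
                            lfp_band_hz = c(2, 400),
                            lfp_downsample_hz = 1000,
                            power_window_ms = 50,
                            threshold_factor = 4,
                            mains_hz = 50,
                            event_window_ms = 200,
                            merge_gap_ms = 25,
                            kurtosis = c("pearson", "excess"),
                            power_stat = c("mean", "sum"),
                            ap_dvdt_mV_per_ms = 20,
                            rng_seed = NULL) {
  cfg <- list(
    psc_corr_min = psc_corr_min, psc_amp_min_pA = psc_amp_min_pA,
    psc_rise_max_ms = psc_rise_max_ms, psc_lowpass_hz = psc_lowpass_hz,
    psc_window_ms = psc_window_ms, psc_baseline_ms = psc_baseline_ms,
    psc_min_separation_ms = psc_min_separation_ms,
    lfp_band_hz = lfp_band_hz, lfp_downsample_hz = lfp_downsample_hz,
    power_window_ms = power_window_ms, threshold_factor = threshold_factor,
    mains_hz = mains_hz, event_window_ms = event_window_ms,
    merge_gap_ms = merge_gap_ms, kurtosis = match.arg(kurtosis),
    power_stat = match.arg(power_stat),
    ap_dvdt_mV_per_ms = ap_dvdt_mV_per_ms, rng_seed = rng_seed
  )
  scalars <- c("psc_amp_min_pA", "psc_rise_max_ms", "psc_lowpass_hz",
               "psc_window_ms", "psc_baseline_ms", "psc_min_separation_ms",
               "lfp_downsample_hz", "power_window_ms", "threshold_factor",
               "mains_hz", "event_window_ms", "ap_dvdt_mV_per_ms")
  for (nm in scalars)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be positive", call. = FALSE)
  if (length(cfg$lfp_band_hz) != 2L || any(cfg$lfp_band_hz <= 0) ||
      diff(cfg$lfp_band_hz) <= 0)
    stop("lfp_band_hz must be increasing positive edges", call. = FALSE)
  structure(cfg, class = "analysis_config")
}

#' Light-stimulation schedule
#'
#' Describes when the blue light was on. The three protocols used with
#' slice LFP recordings are: a 5 s continuous pulse repeated 30 times with
#' 35 s dark gaps; a 5 s train of 3 ms pulses at 30 Hz with the same
#' repetition; and a single 3 min 30 Hz train. Episodes are the macroscopic
#' light-on intervals; for train protocols `pulse_width_s` records the
#' within-episode pulse width.
#'
#' @param protocol One of `"continuous_5s"`, `"pulse_train_5s_30hz"`,
#'   `"pulse_train_3min_30hz"`, or `"custom"` (then supply `episodes`).
#' @param t_start_s Start of the first light episode, seconds. For repeated
#'   protocols the first episode is preceded by a full dark gap starting at
#'   `t_start_s - inter_episode_dark_s`.
#' @param n_runs Number of repetitions for the repeated protocols
#'   (default 30).
#' @param light_s Episode length for the repeated protocols (default 5 s).
#' @param inter_episode_dark_s Dark gap between episodes (default 35 s).
#' @param pulse_width_s Pulse width within train episodes (default 3 ms).
#' @param episodes For `protocol = "custom"`: a two-column matrix or
#'   data.frame of (on_s, off_s), strictly increasing and non-overlapping.
#' @return A list of class `stim_schedule` with elements `episodes`
#'   (data.frame `on_s`, `off_s`), `protocol_kind`, `pulse_width_s`,
#'   `inter_episode_dark_s`, `n_runs`.
#' @export
stim_schedule <- function(protocol = c("continuous_5s",
                                       "pulse_train_5s_30hz",
                                       "pulse_train_3min_30hz", "custom"),
                          t_start_s = 35, n_runs = 30, light_s = 5,
                          inter_episode_dark_s = 35, pulse_width_s = 0.003,
                          episodes = NULL) {
  protocol <- match.arg(protocol)
  if (protocol == "custom") {
    if (is.null(episodes)) stop("custom protocol requires episodes",
                                call. = FALSE)
    episodes <- as.data.frame(episodes)
    names(episodes) <- c("on_s", "off_s")
    n_runs <- nrow(episodes)
  } else if (protocol == "pulse_train_3min_30hz") {
    episodes <- data.frame(on_s = t_start_s, off_s = t_start_s + 180)
    n_runs <- 1L
  } else {
    on <- t_start_s + (seq_len(n_runs) - 1) * (light_s + inter_episode_dark_s)
    episodes <- data.frame(on_s = on, off_s = on + light_s)
  }
  if (any(episodes$off_s <= episodes$on_s))
    stop("episodes must have positive length", call. = FALSE)
  if (nrow(episodes) > 1L &&
      any(episodes$on_s[-1L] < episodes$off_s[-nrow(episodes)]))
    stop("episodes must be non-overlapping and increasing", call. = FALSE)
  structure(list(episodes = episodes, protocol_kind = protocol,
                 pulse_width_s = pulse_width_s,
                 inter_episode_dark_s = inter_episode_dark_s,
                 n_runs = n_runs),
            class = "stim_schedule")
}

#' Paired dark periods of a schedule
#'
#' For each light episode, the dark interval immediately preceding it
#' (capped at `inter_episode_dark_s`, or at 120 s of baseline for the
#' single 3-minute train protocol, which is analysed as one light period
#' against the preceding baseline).
#'
#' @param schedule A `stim_schedule`.
#' @return data.frame with columns `on_s`, `off_s`, one row per episode.
#' @export
dark_periods <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  ep <- schedule$episodes
  gap <- if (schedule$protocol_kind == "pulse_train_3min_30hz") 120
         else schedule$inter_episode_dark_s
  prev_off <- c(-Inf, ep$off_s[-nrow(ep)])
  on <- pmax(ep$on_s - gap, prev_off)
  data.frame(on_s = on, off_s = ep$on_s)
}

#' Classify event times as dark or light
#'
#' @param times_s Numeric vector of event times.
#' @param schedule A `stim_schedule`.
#' @return Character vector, `"light"` for times inside any episode
#'   (half-open `[on, off)`), `"dark"` otherwise.
#' @export
light_state <- function(times_s, schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  ep <- schedule$episodes
  inside <- vapply(times_s, function(t)
    any(t >= ep$on_s & t < ep$off_s), NA)
  ifelse(inside, "light", "dark")
}
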