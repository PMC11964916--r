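#' Heart-rate band sets
#'
#' The two studied band layouts: `"wide"` covers relaxed state through
#' tachycardia in four bands (60-82, 82-105, 105-128, 128-150 bpm); `"narrow"`
#' emphasizes subtle mid-range changes (60-80, 80-88, 88-96, 96-150 bpm).
#'
#' @param set `"wide"` or `"narrow"`.
#' @return A tibble with columns `band`, `low_bpm`, `high_bpm`.
#' @export
hr_bands <- function(set = c("wide", "narrow")) {
  set <- match.arg(set)
  if (set == "wide") {
    tibble::tibble(band = paste0("e", 1:4),
                   low_bpm = c(60, 82, 105, 128),
                   high_bpm = c(82, 105, 128, 150))
  } else {
    tibble::tibble(band = paste0("e", 1:4),
                   low_bpm = c(60, 80, 88, 96),
                   high_bpm = c(80, 88, 96, 150))
  }
}

#' Band-pass filter bank configuration
#'
#' Causal Butterworth band-pass filters, one per heart-rate band. Band edges
#' in bpm convert to Hz by division by 60. With `include_boundary = TRUE` two
#' extra filters are added, one band-width below the first band and one above
#' the last, which stabilize decoding at the edges of the covered HR range.
#'
#' @param bands A band table as from [hr_bands()], or `"wide"` / `"narrow"`.
#' @param order Filter order (1, 2 and 4 are the studied values).
#' @param gain Amplification applied after full-wave rectification.
#' @param include_boundary Add the two boundary filters.
#' @return A list of class `filter_bank_config` with a `bands` tibble.
#' @export
filter_bank_config <- function(bands = "wide", order = 2, gain = 8,
                               include_boundary = FALSE) {
  if (is.character(bands)) bands <- hr_bands(bands)
  stopifnot(all(c("band", "low_bpm", "high_bpm") %in% names(bands)))
  if (any(bands$low_bpm <= 0) || any(bands$high_bpm <= bands$low_bpm)) {
    rlang::abort("Band edges must satisfy 0 < low_bpm < high_bpm.")
  }
  if (order < 1 || order != round(order)) rlang::abort("`order` must be a positive integer.")
  if (gain <= 0) rlang::abort("`gain` must be positive.")
  if (include_boundary) {
    w_lo <- bands$high_bpm[1] - bands$low_bpm[1]
    w_hi <- bands$high_bpm[nrow(bands)] - bands$low_bpm[nrow(bands)]
    bands <- dplyr::bind_rows(
      tibble::tibble(band = "b_low",
                     low_bpm = bands$low_bpm[1] - w_lo,
                     high_bpm = bands$low_bpm[1]),
      bands,
      tibble::tibble(band = "b_high",
                     low_bpm = bands$high_bpm[nrow(bands)],
                     high_bpm = bands$high_bpm[nrow(bands)] + w_hi)
    )
  }
  structure(list(bands = bands, order = order, gain = gain,
                 include_boundary = include_boundary),
            class = "filter_bank_config")
}

#' Apply the band-pass filter bank
#'
#' Each band is the causal Butterworth band-pass response of the input at the
#' configured order (applied forward only; no zero-phase filtering, matching
#' a real-time wearable).
#'
#' @param w A waveform.
#' @param cfg A [filter_bank_config()].
#' @return A nested tibble with one row per band: `band`, `low_bpm`,
#'   `high_bpm`, and `signal` (a list column of waveforms).
#' @export
apply_filter_bank <- function(w, cfg) {
  fs <- wf_fs(w)
  nyq <- fs / 2
  if (any(cfg$bands$high_bpm / 60 >= nyq)) {
    rlang::abort("Band edge at or above the Nyquist frequency.")
  }
  out <- cfg$bands
  out$signal <- purrr::pmap(list(out$low_bpm, out$high_bpm), function(lo, hi) {
    bt <- signal::butter(cfg$order, c(lo, hi) / 60 / nyq, type = "pass")
    wf_like(w, as.numeric(signal::filter(bt, w$value)))
  })
  out
}

#' Full-wave rectification and amplification
#'
#' @param w A waveform (one filter-bank channel).
#' @param gain Positive amplification factor.
#' @return A waveform with samples `gain * abs(value)`.
#' @export
rectify_amplify <- function(w, gain = 8) {
  if (gain <= 0) rlang::abort("`gain` must be positive.")
  wf_like(w, gain * abs(w$value))
}

#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics are `dv/dt = (I - v) / tau`: the steady state for a
#' constant current `I` is `v = I`, and a spike is emitted when `v >= v_thr`,
#' after which `v` resets to `v_reset`. For `I > v_thr` the closed-form
#' inter-spike interval is `tau * log(I / (I - v_thr))`.
#'
#' @param tau Membrane time constant in seconds (default 24 ms).
#' @param v_thr Spiking threshold in normalized units (default 1).
#' @param v_reset Reset value (default 0).
#' @param refractory Absolute refractory period in seconds (default 0).
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(tau = 0.024, v_thr = 1, v_reset = 0, refractory = 0) {
  if (tau <= 0) rlang::abort("`tau` must be positive.")
  if (v_thr <= v_reset) rlang::abort("`v_thr` must exceed `v_reset`.")
  if (refractory < 0) rlang::abort("`refractory` must be non-negative.")
  structure(list(tau = tau, v_thr = v_thr, v_reset = v_reset,
                 refractory = refractory),
            class = "lif_params")
}

#' Encode a current waveform as a spike train
#'
#' Integrates the LIF membrane equation with exact exponential stepping at the
#' waveform sampling rate (piecewise-constant input), which removes time-step
#' sensitivity at typical 125-256 Hz biosignal rates.
#'
#' @param w A non-negative current waveform (post-rectification).
#' @param p [lif_params()].
#' @return A tibble of class `spike_train` with column `time` (s, strictly
#'   increasing), carrying the source `fs` and duration as attributes.
#' @export
lif_encode <- function(w, p = lif_params()) {
  times <- lif_encode_cpp(w$value, wf_fs(w), p$tau, p$v_thr, p$v_reset,
                          p$refractory, 0) + w$time[1]
  out <- tibble::tibble(time = times)
  attr(out, "duration") <- wf_duration(w)
  attr(out, "fs") <- wf_fs(w)
  class(out) <- c("spike_train", class(out))
  out
}

#' Standardize a waveform to zero mean and unit variance
#'
#' Emulates the input-range normalization of an analog front end (low-noise
#' amplifier plus programmable-gain stage): downstream gain and threshold
#' settings then refer to a signal of unit RMS regardless of sensor units.
#' With a finite `window` the normalization is adaptive (automatic gain
#' control): mean and RMS are estimated in a centered sliding window, so the
#' local scale stays unit even when the beat rate, and hence signal power,
#' drifts over a long recording.
#'
#' @param w A waveform with nonzero variance.
#' @param window Optional AGC window in seconds; `NULL` normalizes globally.
#' @return A standardized waveform.
#' @export
standardize_waveform <- function(w, window = NULL) {
  if (is.null(window)) {
    s <- stats::sd(w$value)
    if (!is.finite(s) || s == 0) rlang::abort("Cannot standardize a constant waveform.")
    return(wf_like(w, (w$value - mean(w$value)) / s))
  }
  k <- max(2L, round(window * wf_fs(w)))
  mu <- stats::filter(w$value, rep(1 / k, k), sides = 2)
  mu[is.na(mu)] <- mean(w$value)
  v2 <- stats::filter((w$value - mu)^2, rep(1 / k, k), sides = 2)
  v2[is.na(v2)] <- mean((w$value - mu)^2, na.rm = TRUE)
  if (all(v2 <= 0)) rlang::abort("Cannot standardize a constant waveform.")
  wf_like(w, as.numeric((w$value - mu) / sqrt(pmax(v2, 1e-12))))
}

#' Waveform-to-spikes preprocessing pipeline
#'
#' Composition of [standardize_waveform()] (optional), [apply_filter_bank()],
#' [rectify_amplify()] and [lif_encode()]: one spike train per band (plus the
#' two boundary bands when enabled in the config).
#'
#' @param w Input waveform (PPG, ECG, or an accelerometer axis).
#' @param cfg A [filter_bank_config()].
#' @param p [lif_params()].
#' @param normalize Standardize the input before filtering (default `TRUE`).
#' @param agc_window Optional sliding AGC window in seconds for the
#'   standardization (`NULL` = global).
#' @return A tibble of class `spike_raster` with columns `time` and `channel`
#'   (the band label); attribute `duration`.
#' @export
preprocess_pipeline <- function(w, cfg = filter_bank_config(), p = lif_params(),
                                normalize = TRUE, agc_window = NULL) {
  # constant (e.g. all-zero) signals carry no scale: skip normalization
  if (normalize && stats::sd(w$value) > 0) w <- standardize_waveform(w, agc_window)
  chans <- apply_filter_bank(w, cfg)
  events <- purrr::map2_dfr(chans$signal, chans$band, function(sig, band) {
    st <- lif_encode(rectify_amplify(sig, cfg$gain), p)
    tibble::tibble(time = st$time, channel = band)
  })
  events <- dplyr::arrange(events, .data$time)
  attr(events, "duration") <- wf_duration(w)
  attr(events, "channels") <- chans$band
  class(events) <- c("spike_raster", class(events))
  events
}

#' Per-channel spike rates of a preprocessed raster
#'
#' Sliding-window spike counts divided by the window length, per channel.
#'
#' @param raster A `spike_raster` from [preprocess_pipeline()].
#' @param window Window length in seconds.
#' @param step Step between window starts in seconds.
#' @param duration Total duration (defaults to the raster attribute).
#' @return A tibble `time` (window center), `channel`, `rate` (Hz).
#' @export
channel_rates <- function(raster, window = 2, step = 0.5,
                          duration = attr(raster, "duration")) {
  if (window < step || step <= 0) rlang::abort("Require window >= step > 0.")
  channels <- attr(raster, "channels")
  if (is.null(channels)) channels <- unique(raster$channel)
  starts <- seq(0, max(duration - window, 0), by = step)
  grid <- tidyr::expand_grid(start = starts, channel = channels)
  counts <- purrr::map2_int(grid$start, grid$channel, function(s, ch) {
    sum(raster$channel == ch & raster$time >= s & raster$time < s + window)
  })
  tibble::tibble(time = grid$start + window / 2, channel = grid$channel,
                 rate = counts / window)
}
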