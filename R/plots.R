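#' Plot a waveform
#' @param object A waveform.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hr_waveform
#' @export
autoplot.hr_waveform <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a simulation spike raster
#' @param object An `snn_raster`.
#' @param ... Unused.
#' @return A ggplot with one point per spike, rows grouped by population.
#' @method autoplot snn_raster
#' @export
autoplot.snn_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$neuron,
                                       colour = .data$population)) +
    ggplot2::geom_point(shape = ".", alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Plot a preprocessed per-band spike raster
#' @param object A `spike_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spike_raster
#' @export
autoplot.spike_raster <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$channel)) +
    ggplot2::geom_point(shape = "|") +
    ggplot2::labs(x = "time (s)", y = "band") +
    ggplot2::theme_minimal()
}

#' Plot a decoded state trace
#' @param object A `state_trace`.
#' @param ... Unused.
#' @return A ggplot step plot of the active HR band over time.
#' @method autoplot state_trace
#' @export
autoplot.state_trace <- function(object, ...) {
  lv <- c("none", paste0("e", 1:4))
  df <- dplyr::mutate(object, state = factor(.data$state, levels = lv))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$state, group = 1)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = "decoded HR band") +
    ggplot2::theme_minimal()
}

#' Plot a decoded heart-rate series against its target
#'
#' @param hr A tibble from [decode_hr()] (columns `time`, `hr`).
#' @param traj Optional [hr_trajectory()] overlaying the target HR.
#' @return A ggplot.
#' @export
plot_decoded_hr <- function(hr, traj = NULL) {
  p <- ggplot2::ggplot(hr, ggplot2::aes(x = .data$time, y = .data$hr)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "heart rate (bpm)") +
    ggplot2::theme_minimal()
  if (!is.null(traj)) {
    tgt <- tibble::tibble(time = hr$time, hr = hr_at(traj, hr$time))
    p <- p + ggplot2::geom_line(data = tgt, linetype = "dashed")
  }
  p
}

#' Plot a noise-robustness sweep summary
#'
#' @param sweep Result of [noise_sweep()].
#' @return A ggplot of mean RRMSE (with sd error bars) per SNR and color.
#' @export
plot_noise_sweep <- function(sweep) {
  s <- sweep$summary
  s$snr_lab <- ifelse(is.infinite(s$snr_db), "clean", paste0(s$snr_db, " dB"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$snr_lab, y = .data$mean_rrmse,
                                  fill = .data$color)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rrmse - .data$sd_rrmse,
                                        ymax = .data$mean_rrmse + .data$sd_rrmse),
                           position = ggplot2::position_dodge(0.9), width = 0.2,
                           na.rm = TRUE) +
    ggplot2::labs(x = "noise level", y = "state-decoding RRMSE") +
    ggplot2::theme_minimal()
}
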