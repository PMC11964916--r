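#' Configuration of the instantaneous heart-rate decoder
#'
#' The decoder is a layer of LIF neurons whose bpm centers uniformly tile the
#' covered HR range. Each decoder neuron receives every band's spike train,
#' weighted by a Gaussian of the distance (in bpm) between the neuron's center
#' and the band's center, so the layer converts per-band spike rates into a
#' smooth population-rate profile over the bpm axis. With 13 neurons on
#' 60-150 bpm the spacing is 7.5 bpm.
#'
#' @param filter_bank A [filter_bank_config()]; boundary filters are enabled
#'   by default so the profile stays well-formed at the range edges.
#' @param n_neurons Decoder layer size.
#' @param hr_range Covered heart-rate range in bpm.
#' @param sigma_in Gaussian fan-in width in bpm.
#' @param w_scale Total synaptic weight per decoder neuron (rows of the
#'   weight matrix are normalized to sum to `w_scale`).
#' @param kernel_sigma Default off-line smoothing kernel width in bpm.
#' @param agc_window Sliding window (s) of the adaptive input normalization.
#' @param lif Decoder neuron parameters.
#' @param syn_tau Synaptic time constant of the fan-in (s).
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(filter_bank = filter_bank_config(include_boundary = TRUE),
                           n_neurons = 13, hr_range = c(60, 150),
                           sigma_in = 15, w_scale = 0.5, kernel_sigma = 8,
                           agc_window = 10,
                           lif = lif_params(tau = 0.024, refractory = 0.002),
                           syn_tau = 0.1) {
  if (n_neurons < nrow(filter_bank$bands)) {
    rlang::abort("Decoder layer must be at least as large as the band count.")
  }
  centers <- seq(hr_range[1], hr_range[2], length.out = n_neurons)
  structure(list(filter_bank = filter_bank, n_neurons = n_neurons,
                 hr_range = hr_range, centers = centers, sigma_in = sigma_in,
                 w_scale = w_scale, kernel_sigma = kernel_sigma,
                 agc_window = agc_window, lif = lif, syn_tau = syn_tau),
            class = "decoder_config")
}

#' Gaussian fan-in weight matrix of the decoder
#'
#' @param cfg A [decoder_config()].
#' @return A `bands x neurons` matrix; each column (one decoder neuron's
#'   incoming weights) sums to `cfg$w_scale`.
#' @export
decoder_weights <- function(cfg) {
  beta <- (cfg$filter_bank$bands$low_bpm + cfg$filter_bank$bands$high_bpm) / 2
  g <- outer(beta, cfg$centers,
             function(b, c) exp(-(c - b)^2 / (2 * cfg$sigma_in^2)))
  sweep(g, 2, colSums(g) / cfg$w_scale, "/")
}

#' Build the decoder network
#'
#' One single-source input population per filter band, densely wired to the
#' decoder layer with the Gaussian fan-in weights.
#'
#' @param cfg A [decoder_config()].
#' @param mismatch_cv Device-mismatch coefficient of variation.
#' @param seed Seed for mismatch draws.
#' @return A [network_spec()].
#' @export
build_decoder <- function(cfg = decoder_config(), mismatch_cv = 0, seed = 1L) {
  bands <- cfg$filter_bank$bands$band
  g <- decoder_weights(cfg)
  pops <- dplyr::bind_rows(
    purrr::map_dfr(bands, function(b) population(paste0("inp_", b), 1L, "input")),
    population("dec", cfg$n_neurons, "exc")
  )
  cons <- purrr::map_dfr(seq_along(bands), function(j) {
    connection(paste0("inp_", bands[j]), "dec", p = 1, weight = 1,
               tau = cfg$syn_tau, weights = matrix(g[j, ], nrow = 1))
  })
  network_spec(pops, cons, lif = cfg$lif,
               syn_tau = c(slow = cfg$syn_tau, fast = 0.01),
               mismatch_cv = mismatch_cv, seed = seed)
}

#' Decode instantaneous heart rate from decoder-layer activity
#'
#' Per window, the firing-rate profile across the decoder neurons is smoothed
#' with a Gaussian kernel along the bpm axis and the continuous peak position
#' (fine-grid argmax refined by quadratic interpolation) is returned as the
#' decoded HR. Windows with no spikes decode to `NA`.
#'
#' @param raster An `snn_raster` from a [build_decoder()] network.
#' @param cfg The [decoder_config()] used to build the network.
#' @param kernel_sigma Smoothing kernel width in bpm.
#' @param window,step Rate window length and step in seconds.
#' @param calibration Optional [decoder_calibrate()] readout calibration
#'   mapping raw peak positions to bpm.
#' @return A tibble `time`, `hr` (bpm).
#' @export
decode_hr <- function(raster, cfg, kernel_sigma = cfg$kernel_sigma,
                      window = 2, step = 0.5, calibration = NULL) {
  net <- attr(raster, "net")
  duration <- attr(raster, "duration")
  starts <- seq(0, max(duration - window, 0), by = step)
  ids <- net$pop_index$dec
  grid <- seq(cfg$hr_range[1], cfg$hr_range[2], by = 0.1)
  kern <- outer(grid, cfg$centers,
                function(g, c) exp(-(g - c)^2 / (2 * kernel_sigma^2)))
  hr <- purrr::map_dbl(starts, function(s) {
    ev <- raster$neuron[raster$time >= s & raster$time < s + window]
    if (!length(ev)) return(NA_real_)
    r <- tabulate(match(ev, ids), nbins = length(ids)) / window
    smooth_peak(kern %*% r, grid)
  })
  if (!is.null(calibration)) hr <- stats::predict(calibration, hr)
  tibble::tibble(time = starts + window / 2, hr = hr)
}

# Continuous argmax of a profile sampled on a grid: fine-grid maximum refined
# by quadratic interpolation through the three points around the peak.
smooth_peak <- function(p, grid) {
  i <- which.max(p)
  if (i == 1L || i == length(p)) return(grid[i])
  d <- grid[2] - grid[1]
  denom <- p[i - 1] - 2 * p[i] + p[i + 1]
  if (denom >= 0) return(grid[i])
  grid[i] + 0.5 * d * (p[i - 1] - p[i + 1]) / denom
}

#' End-to-end heart-rate decoding of a waveform
#'
#' Convenience composition: preprocess the waveform into per-band spike
#' trains, drive the decoder network with them, and decode the HR series.
#'
#' @param w Input PPG waveform.
#' @param cfg A [decoder_config()].
#' @param window,step Decoding windows (s).
#' @param calibration Optional [decoder_calibrate()] readout calibration.
#' @param mismatch_cv,seed Passed to [build_decoder()] / [simulate_network()].
#' @param dt Simulation step (s).
#' @return A tibble `time`, `hr`.
#' @export
decode_heart_rate <- function(w, cfg = decoder_config(), window = 4,
                              step = 0.5, calibration = NULL,
                              mismatch_cv = 0, seed = 1L, dt = 1e-3) {
  raster <- preprocess_pipeline(w, cfg$filter_bank, cfg$lif,
                                agc_window = cfg$agc_window)
  net <- realize_connectivity(build_decoder(cfg, mismatch_cv = mismatch_cv,
                                            seed = seed))
  inputs <- purrr::map(split(raster$time, raster$channel), identity)
  names(inputs) <- paste0("inp_", names(inputs))
  sim <- simulate_network(net, inputs, duration = wf_duration(w),
                          dt = dt, seed = seed)
  decode_hr(sim, cfg, window = window, step = step,
            calibration = calibration)
}

#' Calibrate the off-line decoder readout
#'
#' The raw statistic returned by [decode_hr()] -- the peak position of the
#' smoothed decoder-rate profile -- is a monotone but not identity function of
#' the true heart rate, because band tuning curves are asymmetric (harmonics,
#' filter skew) and LIF rates are nonlinear in their drive. As in any
#' tuning-curve population decoder, the readout is therefore calibrated once
#' on self-generated clean constant-HR signals: the mean raw peak is measured
#' at each calibration HR, made monotone by isotonic regression, and inverted
#' by piecewise-linear interpolation.
#'
#' @param cfg A [decoder_config()].
#' @param hrs Calibration heart rates in bpm.
#' @param duration Length of each constant-HR calibration signal (s).
#' @param warmup Seconds discarded while filters and neurons settle.
#' @param window Decoding window (s); use the same value when decoding.
#' @param fs Sampling rate of the calibration signals (Hz).
#' @param dt Simulation step (s).
#' @param mismatch_cv Device mismatch of the decoder network; use the same
#'   value (and `seed`) as the network being calibrated, so the calibration
#'   compensates that realization's heterogeneity the way a per-power-on
#'   recalibration would on an analog system.
#' @param seed Seed for the calibration runs.
#' @return An object of class `decoder_calibration`; apply with
#'   `predict(cal, raw_peak)` or pass as `calibration =` to [decode_hr()].
#' @export
decoder_calibrate <- function(cfg = decoder_config(),
                              hrs = seq(cfg$hr_range[1], cfg$hr_range[2],
                                        by = 2.5),
                              duration = 20, warmup = 6, window = 4,
                              fs = 125, dt = 1e-3, mismatch_cv = 0, seed = 1L) {
  raw <- purrr::map_dbl(hrs, function(h) {
    w <- generate_ppg(hr_constant(h, range = cfg$hr_range), fs = fs,
                      duration = duration)
    est <- decode_heart_rate(w, cfg, window = window, seed = seed, dt = dt,
                             mismatch_cv = mismatch_cv)
    mean(est$hr[est$time > warmup], na.rm = TRUE)
  })
  iso <- stats::isoreg(hrs, raw)
  structure(list(knots = tibble::tibble(hr = hrs, raw = iso$yf),
                 window = window, seed = seed),
            class = "decoder_calibration")
}

#' @method predict decoder_calibration
#' @export
predict.decoder_calibration <- function(object, newdata, ...) {
  f <- stats::approxfun(object$knots$raw, object$knots$hr, rule = 2,
                        ties = mean)
  f(newdata)
}

#' @method print decoder_calibration
#' @export
print.decoder_calibration <- function(x, ...) {
  cat(sprintf("<decoder readout calibration: %d knots over %.0f-%.0f bpm>\n",
              nrow(x$knots), min(x$knots$hr), max(x$knots$hr)))
  invisible(x)
}
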