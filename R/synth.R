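#' Two-Gaussian PPG pulse shape
#'
#' Parameters of the circular-phase pulse model: one beat is traced as a point
#' moving on the unit circle with angular velocity `2 * pi * HR / 60`; the PPG
#' amplitude is the sum of two Gaussians in the polar angle `theta`, one for
#' the systolic peak and one for the diastolic shoulder. Defaults are the
#' values fitted to real resting PPG pulses.
#'
#' @param a1,a2 Peak amplitudes (dimensionless).
#' @param b1,b2 Gaussian width parameters (radians); interpreted as the
#'   Gaussian sigma unless `width_is_2b = TRUE`, in which case sigma = 2 b.
#' @param theta1,theta2 Gaussian centers in radians, in (-pi, pi].
#' @param t0 Phase-offset time in seconds.
#' @param width_is_2b Alternative width reading (sigma = 2 b); default `FALSE`.
#' @return A list of class `ppg_pulse_spec`.
#' @export
ppg_pulse_spec <- function(a1 = 0.19, a2 = 0.07, b1 = 0.42, b2 = 0.5,
                           theta1 = -0.7, theta2 = 0.4, t0 = 0.403,
                           width_is_2b = FALSE) {
  if (b1 <= 0 || b2 <= 0) rlang::abort("Width parameters b1, b2 must be positive.")
  if (any(c(theta1, theta2) <= -pi) || any(c(theta1, theta2) > pi)) {
    rlang::abort("Gaussian centers theta1, theta2 must lie in (-pi, pi].")
  }
  structure(
    list(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
         theta1 = theta1, theta2 = theta2, t0 = t0,
         width_is_2b = isTRUE(width_is_2b)),
    class = "ppg_pulse_spec"
  )
}

#' Heart-rate trajectories
#'
#' A trajectory maps time (s) to heart rate (bpm) and declares the admissible
#' HR range. `hr_constant()` is a flat profile, `hr_staircase()` a sequence of
#' equal-duration constant steps, and `hr_trajectory()` interpolates a
#' `(time, bpm)` table (piecewise-constant or linear).
#'
#' @param bpm Heart rate in beats per minute.
#' @param profile Data frame with columns `time` (s) and `bpm`.
#' @param interp `"constant"` (sample-and-hold) or `"linear"`.
#' @param range Admissible HR range in bpm; values outside it are an error.
#' @return A list of class `hr_trajectory` with element `hr(t)`.
#' @export
hr_trajectory <- function(profile, interp = c("constant", "linear"),
                          range = c(60, 150)) {
  interp <- match.arg(interp)
  stopifnot(is.data.frame(profile), all(c("time", "bpm") %in% names(profile)))
  if (any(profile$bpm < range[1] - 1e-9) || any(profile$bpm > range[2] + 1e-9)) {
    rlang::abort(sprintf("HR values outside the declared range [%g, %g] bpm.",
                         range[1], range[2]))
  }
  profile <- dplyr::arrange(profile, .data$time)
  f <- stats::approxfun(profile$time, profile$bpm,
                        method = if (interp == "constant") "constant" else "linear",
                        rule = 2)
  structure(list(hr = f, range = range, profile = tibble::as_tibble(profile),
                 interp = interp),
            class = "hr_trajectory")
}

#' @rdname hr_trajectory
#' @export
hr_constant <- function(bpm, range = c(60, 150)) {
  hr_trajectory(data.frame(time = 0, bpm = bpm), interp = "constant",
                range = range)
}

#' @rdname hr_trajectory
#' @param from,to First and last step values in bpm.
#' @param n_steps Number of constant steps.
#' @param duration Total duration in seconds.
#' @export
hr_staircase <- function(from = 60, to = 150, n_steps = 10, duration = 470,
                         range = c(60, 150)) {
  steps <- seq(from, to, length.out = n_steps)
  hr_trajectory(
    data.frame(time = seq(0, duration, length.out = n_steps + 1)[-(n_steps + 1)],
               bpm = steps),
    interp = "constant", range = range
  )
}

#' Heart rate at given times
#' @param traj An [hr_trajectory()].
#' @param t Time(s) in seconds.
#' @return HR in bpm, vectorized over `t`.
#' @export
hr_at <- function(traj, t) traj$hr(t)

#' Generate a synthetic PPG waveform
#'
#' The beat phase advances as the integral of the instantaneous angular
#' velocity `omega(t) = 2 * pi * hr(t) / 60` (so HR steps do not cause phase
#' discontinuities); the planar position `(x, y) = (cos psi, sin psi)` with
#' `psi = phi(t) - omega(0) * t0 - pi` traces the unit circle, and the PPG
#' sample is the two-Gaussian pulse evaluated at `theta = atan2(y, x)`.
#' For constant HR the output is periodic with period `60 / HR` seconds.
#'
#' @param traj An [hr_trajectory()].
#' @param pulse A [ppg_pulse_spec()].
#' @param fs Sampling rate in Hz (>= 50 to resolve pulse morphology).
#' @param duration Signal duration in seconds (> 0).
#' @return A waveform (see [waveform()]).
#' @export
#' @examples
#' w <- generate_ppg(hr_constant(60), ppg_pulse_spec(), fs = 125, duration = 5)
generate_ppg <- function(traj, pulse = ppg_pulse_spec(), fs = 125, duration) {
  if (duration <= 0) rlang::abort("`duration` must be positive.")
  if (fs < 50) rlang::abort("`fs` must be at least 50 Hz to resolve pulse morphology.")
  n <- round(duration * fs)
  t <- seq_len(n) / fs - 1 / fs
  omega <- 2 * pi * hr_at(traj, t) / 60
  # accumulated phase: trapezoid-free cumulative sum is adequate at >= 50 Hz
  phi <- cumsum(omega) / fs - omega[1] / fs
  psi <- phi - omega[1] * pulse$t0 - pi
  theta <- atan2(sin(psi), cos(psi))
  s1 <- if (pulse$width_is_2b) 2 * pulse$b1 else pulse$b1
  s2 <- if (pulse$width_is_2b) 2 * pulse$b2 else pulse$b2
  z <- pulse$a1 * exp(-(theta - pulse$theta1)^2 / (2 * s1^2)) +
       pulse$a2 * exp(-(theta - pulse$theta2)^2 / (2 * s2^2))
  waveform(z, fs = fs)
}

# Zero-mean unit-power colored noise: white Gaussian noise is shaped in the
# frequency domain by |f|^(alpha/2) (DC bin zeroed), transformed back, then
# renormalized. alpha: white 0, pink -1, brown -2, blue +1, violet +2.
colored_noise <- function(n, color = c("white", "pink", "brown", "blue", "violet")) {
  color <- match.arg(color)
  x <- stats::rnorm(n)
  if (color == "white") return(x / sqrt(mean(x^2)))
  alpha <- c(pink = -1, brown = -2, blue = 1, violet = 2)[[color]]
  xf <- stats::fft(x)
  f <- seq(0, n - 1)
  f <- pmin(f, n - f) # two-sided frequency magnitude, in bins
  shape <- c(0, f[-1]^(alpha / 2))
  y <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  y <- y - mean(y)
  y / sqrt(mean(y^2))
}

#' Add calibrated noise to a waveform
#'
#' Zero-mean noise of the requested spectral color is scaled so its empirical
#' power is exactly `signal_power(w) * 10^(-snr_db / 10)` and added to the
#' signal. Colored noise has spectral density proportional to `f^alpha`
#' (white 0, pink -1, brown -2, blue +1, violet +2). Seeded and reproducible.
#'
#' @param w A waveform with nonzero power.
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @param color Noise color.
#' @param seed Integer seed for the noise draw.
#' @return A waveform `w + noise`.
#' @export
add_noise <- function(w, snr_db, color = c("white", "pink", "brown", "blue", "violet"),
                      seed = 1L) {
  color <- match.arg(color)
  p_sig <- signal_power(w)
  if (p_sig <= 0) rlang::abort("Signal power is zero: SNR is undefined.")
  p_noise <- p_sig * 10^(-snr_db / 10)
  noise <- withr::with_seed(seed, colored_noise(nrow(w), color))
  wf_like(w, w$value + noise * sqrt(p_noise))
}

#' Fit the two-Gaussian pulse model to a recorded pulse
#'
#' Segments the waveform into pulses ("the data points between the midpoints
#' of two consecutive valleys"), then least-squares fits the circular-phase
#' two-Gaussian model to the first complete pulse, using the known constant
#' heart rate to fix the angular velocity.
#'
#' @param w A waveform containing at least one full pulse.
#' @param traj The (constant) HR trajectory that generated/underlies the pulse.
#' @param start Optional starting [ppg_pulse_spec()] for the optimizer.
#' @return An object of class `ppg_pulse_fit`; use [generics::tidy()] /
#'   [generics::glance()] or `$spec` for the fitted [ppg_pulse_spec()].
#' @export
fit_pulse_params <- function(w, traj, start = ppg_pulse_spec()) {
  fs <- wf_fs(w)
  bpm <- hr_at(traj, w$time[1])
  period <- 60 / bpm
  v <- w$value
  if (max(v) - min(v) < 1e-12) {
    rlang::abort("Waveform is flat: no pulses to fit.", class = "hrsnn_fit_failure")
  }
  # valley detection on a lightly smoothed copy (robust to additive noise):
  # local minima separated by at least half a period
  k <- max(3L, round(fs * period / 20))
  vs <- stats::filter(v, rep(1 / k, k), sides = 2)
  vs[is.na(vs)] <- v[is.na(vs)]
  half <- max(3L, floor(period * fs / 2))
  is_min <- which(diff(sign(diff(vs))) > 0) + 1L
  if (length(is_min) < 2L) {
    rlang::abort("No detectable valleys in the waveform.", class = "hrsnn_fit_failure")
  }
  valleys <- is_min[1]
  for (i in is_min[-1]) {
    if (i - valleys[length(valleys)] >= half) valleys <- c(valleys, i)
  }
  if (length(valleys) < 2L) {
    rlang::abort("Fewer than two valleys: no complete pulse.", class = "hrsnn_fit_failure")
  }
  i0 <- valleys[1]; i1 <- valleys[2]
  lo <- max(1L, floor((i0 + i1) / 2) - round(period * fs))
  seg <- seq(lo, min(nrow(w), lo + round(period * fs)))
  tt <- w$time[seg]; zz <- v[seg]

  omega <- 2 * pi * bpm / 60
  model <- function(p, t) {
    psi <- omega * (t - p[["t0"]]) - pi
    th <- atan2(sin(psi), cos(psi))
    p[["a1"]] * exp(-(th - p[["theta1"]])^2 / (2 * p[["b1"]]^2)) +
      p[["a2"]] * exp(-(th - p[["theta2"]])^2 / (2 * p[["b2"]]^2))
  }
  # data-driven refinement of the starting point: peak height sets a1, and
  # the systolic peak time pins the phase offset t0 (theta = theta1 there)
  omega0 <- 2 * pi * bpm / 60
  i_peak <- seg[which.max(zz)]
  t0_init <- w$time[i_peak] - (start$theta1 + pi) / omega0
  t0_init <- t0_init %% period
  p0 <- c(a1 = max(zz), a2 = start$a2, b1 = start$b1, b2 = start$b2,
          theta1 = start$theta1, theta2 = start$theta2, t0 = t0_init)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = p0,
      fn = function(p) zz - model(p, tt),
      lower = c(0, 0, 0.05, 0.05, -pi, -pi, -5),
      upper = c(2, 2, pi, pi, pi, pi, 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) rlang::abort("Pulse fit failed to converge.",
                                     class = "hrsnn_fit_failure", parent = e)
  )
  p <- fit$par
  spec <- ppg_pulse_spec(a1 = p[["a1"]], a2 = p[["a2"]], b1 = p[["b1"]],
                         b2 = p[["b2"]], theta1 = p[["theta1"]],
                         theta2 = p[["theta2"]], t0 = p[["t0"]])
  structure(
    list(spec = spec, rss = sum(fit$fvec^2), n = length(zz),
         convergence = fit$info, bpm = bpm),
    class = "ppg_pulse_fit"
  )
}

#' @export
print.ppg_pulse_fit <- function(x, ...) {
  cat("<two-Gaussian pulse fit>\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy a pulse fit
#' @param x A `ppg_pulse_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @method tidy ppg_pulse_fit
#' @export
tidy.ppg_pulse_fit <- function(x, ...) {
  s <- x$spec
  tibble::tibble(
    term = c("a1", "a2", "b1", "b2", "theta1", "theta2", "t0"),
    estimate = c(s$a1, s$a2, s$b1, s$b2, s$theta1, s$theta2, s$t0)
  )
}

#' @rdname tidy.ppg_pulse_fit
#' @method glance ppg_pulse_fit
#' @export
glance.ppg_pulse_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = x$n, bpm = x$bpm, convergence = x$convergence)
}

#' Align a pulse fit to a reference phase convention
#'
#' The circular-phase pulse model has a continuous gauge freedom: shifting the
#' phase-offset time by `delta` while rotating both Gaussian centers by
#' `-omega * delta` leaves the waveform unchanged, so `t0` and the centers are
#' only identifiable jointly. To compare fitted parameters with a reference
#' parameterization, this helper picks the gauge in which `t0` equals the
#' reference value and rotates the fitted centers accordingly.
#'
#' @param fit A `ppg_pulse_fit` from [fit_pulse_params()].
#' @param t0 Reference phase-offset time in seconds.
#' @return The fit with an aligned `$spec`.
#' @export
align_pulse_fit <- function(fit, t0 = 0.403) {
  s <- fit$spec
  omega <- 2 * pi * fit$bpm / 60
  delta <- t0 - s$t0
  wrap <- function(x) {
    y <- (x + pi) %% (2 * pi) - pi
    ifelse(y <= -pi, y + 2 * pi, y)
  }
  fit$spec <- ppg_pulse_spec(
    a1 = s$a1, a2 = s$a2, b1 = s$b1, b2 = s$b2,
    theta1 = wrap(s$theta1 - omega * delta),
    theta2 = wrap(s$theta2 - omega * delta),
    t0 = t0, width_is_2b = s$width_is_2b
  )
  fit
}
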