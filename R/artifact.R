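#' Band-filtered PPG and accelerometer channel matrix
#'
#' Builds the 16 channels used for motion-artifact removal: the four
#' band-filtered PPG channels plus, per accelerometer axis, the same four
#' band filters (12 accelerometer channels). All channels share the input
#' length and sampling rate.
#'
#' @param ppg PPG waveform.
#' @param accel Named list of accelerometer waveforms (e.g. `x`, `y`, `z`),
#'   time-aligned with the PPG at the same rate.
#' @param cfg A [filter_bank_config()] (the four main bands; boundary filters
#'   are not used here).
#' @return A list of class `channel_matrix` with elements `ppg` (list of 4
#'   waveforms by band) and `accel` (named list of 12 waveforms,
#'   `axis.band`), plus the config.
#' @export
build_channel_matrix <- function(ppg, accel, cfg = filter_bank_config()) {
  if (cfg$include_boundary) {
    rlang::abort("Artifact removal uses the four main bands only.")
  }
  ok <- purrr::every(accel, function(a) {
    nrow(a) == nrow(ppg) && isTRUE(all.equal(wf_fs(a), wf_fs(ppg)))
  })
  if (!ok) rlang::abort("All channels must share length and sampling rate.")
  fb_ppg <- apply_filter_bank(ppg, cfg)
  ppg_ch <- stats::setNames(fb_ppg$signal, fb_ppg$band)
  accel_ch <- purrr::imap(accel, function(a, nm) {
    fb <- apply_filter_bank(a, cfg)
    stats::setNames(fb$signal, paste0(nm, ".", fb$band))
  })
  accel_ch <- purrr::flatten(accel_ch)
  structure(list(ppg = ppg_ch, accel = accel_ch, cfg = cfg),
            class = "channel_matrix")
}

#' ECG-derived reference firing rates
#'
#' The surrogate ground truth for artifact removal: the ECG is pushed through
#' the same preprocessing pipeline and the per-band LIF firing-rate series is
#' returned.
#'
#' @param ecg ECG waveform.
#' @param cfg A [filter_bank_config()].
#' @param p Preprocessing [lif_params()].
#' @param window,step Rate windows in seconds.
#' @return A tibble `time`, `channel`, `rate` (Hz).
#' @export
ecg_reference_rates <- function(ecg, cfg = filter_bank_config(),
                                p = lif_params(), window = 2, step = 0.5) {
  channel_rates(preprocess_pipeline(ecg, cfg, p), window = window, step = step)
}

# Combine the 16 channels with one coefficient vector (4 PPG + 12 accel).
# The combination represents a single cleaned signal split by the filter
# bank, so band b receives only same-band channels:
#   combined_b = w[b] * ppg_b + sum_axis w[axis.b] * accel_{axis.b}
# (cross-band channels are disjoint in frequency and drop out).
combine_channels <- function(wts, ch) {
  stopifnot(length(wts) == 4 + length(ch$accel))
  accel_bands <- sub("^[^.]+\\.", "", names(ch$accel))
  purrr::imap(ch$ppg, function(p, nm) {
    b <- match(nm, names(ch$ppg))
    v <- wts[b] * p$value
    for (j in which(accel_bands == nm)) {
      v <- v + wts[4 + j] * ch$accel[[j]]$value
    }
    wf_like(p, v)
  })
}

#' Artifact-removal objective
#'
#' Combines the channels with the candidate weights, rectifies, amplifies and
#' LIF-encodes the per-band combined signals, and returns the mean over bands
#' of the RRMSE between the resulting firing-rate series and the ECG-derived
#' reference rates.
#'
#' @param wts Numeric vector of 16 combination coefficients (4 PPG + 12
#'   accelerometer).
#' @param ch A [build_channel_matrix()] result.
#' @param ref Reference rates from [ecg_reference_rates()].
#' @param p Preprocessing [lif_params()].
#' @param window,step Rate windows (must match those used for `ref`).
#' @return Mean per-band RRMSE (dimensionless).
#' @export
artifact_objective <- function(wts, ch, ref, p = lif_params(), window = 2,
                               step = 0.5) {
  combined <- combine_channels(wts, ch)
  gain <- ch$cfg$gain
  errs <- purrr::imap_dbl(combined, function(wv, band) {
    st <- lif_encode(rectify_amplify(wv, gain), p)
    attr(st, "channels") <- band
    r <- channel_rates(
      structure(tibble::tibble(time = st$time, channel = band),
                duration = wf_duration(wv), channels = band,
                class = c("spike_raster", "tbl_df", "tbl", "data.frame")),
      window = window, step = step
    )
    target <- ref$rate[ref$channel == band]
    if (all(target == 0)) rlang::abort("All-zero reference rates: RRMSE undefined.")
    rrmse(r$rate, target)
  })
  mean(errs)
}

#' Optimize the channel combination against the ECG reference
#'
#' Derivative-free Nelder-Mead descent of [artifact_objective()] from seeded
#' random initializations (PPG coefficients start at 1, accelerometer
#' coefficients uniform in \[-1, 1\]), `n_iter` simplex iterations per
#' restart; the best vertex over all restarts is returned and is never worse
#' than its own initialization.
#'
#' @param ch A [build_channel_matrix()] result.
#' @param ref Reference rates from [ecg_reference_rates()].
#' @param p Preprocessing [lif_params()].
#' @param n_iter Nelder-Mead iterations per restart (default 20).
#' @param n_restarts Random restarts (best kept).
#' @param seed Seed for the initializations.
#' @param window,step Rate windows (s).
#' @return An object of class `artifact_fit` with elements `weights`,
#'   `objective`, `objective_init`, `mode`, `seed`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
optimize_combination <- function(ch, ref, p = lif_params(), n_iter = 20,
                                 n_restarts = 5, seed = 1L, window = 2,
                                 step = 0.5) {
  n_w <- 4 + length(ch$accel)
  obj <- function(w) artifact_objective(w, ch, ref, p, window, step)
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      w0 <- c(rep(1, 4), stats::runif(n_w - 4, -1, 1))
      f0 <- obj(w0)
      tries <- 0
      while (!is.finite(f0) && tries < 10) {
        w0 <- c(rep(1, 4), stats::runif(n_w - 4, -1, 1))
        f0 <- obj(w0)
        tries <- tries + 1
      }
      if (!is.finite(f0)) {
        rlang::abort("Objective non-finite at every tried initialization.")
      }
      fit <- if (n_iter > 0) {
        stats::optim(w0, obj, method = "Nelder-Mead",
                     control = list(maxit = n_iter))
      } else list(par = w0, value = f0)
      cand <- if (fit$value <= f0) fit else list(par = w0, value = f0)
      if (is.null(best) || cand$value < best$value) {
        best <- c(cand, list(init = f0))
      }
    }
  })
  structure(list(weights = best$par, objective = best$value,
                 objective_init = best$init, n_iter = n_iter,
                 n_restarts = n_restarts, seed = seed,
                 channel_names = c(names(ch$ppg), names(ch$accel))),
            class = "artifact_fit")
}

#' Group-wise artifact-removal optimization
#'
#' Runs [optimize_combination()] either once on pooled data (`mode =
#' "global"`) or independently per group (`mode = "per_subject"` /
#' `"per_exercise"`), mirroring calibration per user or per activity type.
#'
#' @param records A list of lists, each with elements `ch` (channel matrix),
#'   `ref` (reference rates), and grouping labels `subject` / `exercise`.
#' @param mode Optimization mode.
#' @param ... Passed to [optimize_combination()].
#' @return A tibble with one row per optimization unit: `group`, `fit`
#'   (list column), `objective` (mean over the unit's records).
#' @export
optimize_grouped <- function(records,
                             mode = c("global", "per_subject", "per_exercise"),
                             ...) {
  mode <- match.arg(mode)
  key <- switch(mode, global = function(r) "all",
                per_subject = function(r) r$subject,
                per_exercise = function(r) r$exercise)
  groups <- split(records, vapply(records, key, character(1)))
  purrr::imap_dfr(groups, function(recs, g) {
    gfit <- optimize_pooled(recs, ...)
    tibble::tibble(group = g, mode = mode, fit = list(gfit),
                   objective = gfit$objective)
  })
}

# Pooled variant of optimize_combination over several records.
optimize_pooled <- function(recs, p = lif_params(), n_iter = 20,
                            n_restarts = 5, seed = 1L, window = 2, step = 0.5) {
  n_w <- 4 + length(recs[[1]]$ch$accel)
  obj <- function(w) {
    mean(vapply(recs, function(r) {
      artifact_objective(w, r$ch, r$ref, p, window, step)
    }, numeric(1)))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      w0 <- c(rep(1, 4), stats::runif(n_w - 4, -1, 1))
      f0 <- obj(w0)
      if (!is.finite(f0)) next
      fit <- if (n_iter > 0) {
        stats::optim(w0, obj, method = "Nelder-Mead",
                     control = list(maxit = n_iter))
      } else list(par = w0, value = f0)
      cand <- if (fit$value <= f0) fit else list(par = w0, value = f0)
      if (is.null(best) || cand$value < best$value) best <- c(cand, list(init = f0))
    }
  })
  if (is.null(best)) rlang::abort("Objective non-finite at every initialization.")
  structure(list(weights = best$par, objective = best$value,
                 objective_init = best$init, n_iter = n_iter,
                 n_restarts = n_restarts, seed = seed,
                 channel_names = c(names(recs[[1]]$ch$ppg),
                                   names(recs[[1]]$ch$accel))),
            class = "artifact_fit")
}

#' @export
print.artifact_fit <- function(x, ...) {
  cat(sprintf("<artifact fit: objective %.4f (init %.4f), %d iterations x %d restarts>\n",
              x$objective, x$objective_init, x$n_iter, x$n_restarts))
  invisible(x)
}

#' Tidy an artifact-removal fit
#' @param x An `artifact_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @method tidy artifact_fit
#' @export
tidy.artifact_fit <- function(x, ...) {
  tibble::tibble(term = x$channel_names, estimate = x$weights)
}

#' @rdname tidy.artifact_fit
#' @method glance artifact_fit
#' @export
glance.artifact_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, objective_init = x$objective_init,
                 n_iter = x$n_iter, n_restarts = x$n_restarts, seed = x$seed)
}

#' Slope of cleaned-signal rates against the reference rates
#'
#' Least-squares slope of one firing-rate series regressed on another; a unit
#' slope indicates perfect rate agreement. Used to compare raw, globally
#' optimized, subject-specific and exercise-specific combinations.
#'
#' @param rates Rate series of the (cleaned) signal.
#' @param ref_rates Reference (ECG-derived) rate series, same length >= 2.
#' @return Slope (dimensionless).
#' @export
fit_rate_slope <- function(rates, ref_rates) {
  if (length(rates) != length(ref_rates) || length(rates) < 2) {
    rlang::abort("Series must have equal length >= 2.")
  }
  if (stats::var(ref_rates) == 0) {
    rlang::abort("Constant reference series: slope undefined.",
                 class = "hrsnn_degenerate")
  }
  unname(stats::coef(stats::lm(rates ~ ref_rates))[2])
}

#' Synthetic motion-corruption fixture
#'
#' Constructs a controlled artifact-removal problem: a clean synthetic PPG
#' serves as the ECG surrogate; sinusoidal "motion" at a band-interior
#' frequency is recorded by one accelerometer axis and leaks into the PPG with
#' a known coefficient. Recovering the negative of that coefficient removes
#' the corruption exactly.
#'
#' @param traj HR trajectory of the clean pulse signal.
#' @param duration,fs Signal length (s) and sampling rate (Hz).
#' @param leak_coef Leakage coefficient of the motion into the PPG.
#' @param motion_amp Amplitude of the motion component relative to the
#'   unit-RMS clean pulse signal (wrist motion during exercise is comparable
#'   in power to the pulse itself).
#' @param motion_bpm Frequency of the motion component, in bpm units.
#' @param axis Which accelerometer axis carries the motion.
#' @param seed Seed for the accelerometer noise floor.
#' @return A list `ppg` (corrupted), `clean`, `accel` (list x/y/z), `ecg`
#'   (clean surrogate), `leak_coef`, `motion_bpm`.
#' @export
make_motion_fixture <- function(traj = hr_constant(70), duration = 60,
                                fs = 125, leak_coef = 0.5, motion_amp = 1,
                                motion_bpm = 93, axis = "x", seed = 1L) {
  # front-end output scale: unit-variance clean pulse signal
  clean <- standardize_waveform(generate_ppg(traj, fs = fs, duration = duration))
  t <- clean$time
  motion <- sin(2 * pi * motion_bpm / 60 * t) * motion_amp
  withr::with_seed(seed, {
    floor_noise <- function() stats::rnorm(length(t), sd = 0.01)
    accel <- list(x = wf_like(clean, floor_noise()),
                  y = wf_like(clean, floor_noise()),
                  z = wf_like(clean, floor_noise()))
  })
  accel[[axis]]$value <- accel[[axis]]$value + motion
  ppg <- wf_like(clean, clean$value + leak_coef * motion)
  list(ppg = ppg, clean = clean, accel = accel, ecg = clean,
       leak_coef = leak_coef, motion_bpm = motion_bpm, axis = axis)
}
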