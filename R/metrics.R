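#' Relative root-mean-square error
#'
#' RMSE between predicted and observed series divided by the mean of the
#' observed (ground-truth) values; 0 means perfect agreement, and the measure
#' is invariant under a common positive rescaling of both series.
#'
#' @param predicted,actual Equal-length numeric vectors; pairs with `NA` in
#'   either series are dropped when `na.rm = TRUE`.
#' @param na.rm Drop incomplete pairs.
#' @return A single number.
#' @export
#' @examples
#' rrmse(c(2, 2, 2), c(1, 1, 1)) # 1
rrmse <- function(predicted, actual, na.rm = FALSE) {
  if (length(predicted) != length(actual) || !length(actual)) {
    rlang::abort("`predicted` and `actual` must have equal positive length.")
  }
  if (na.rm) {
    ok <- !is.na(predicted) & !is.na(actual)
    predicted <- predicted[ok]; actual <- actual[ok]
  }
  m <- mean(actual)
  if (!is.finite(m) || m == 0) {
    rlang::abort("RRMSE is undefined for zero-mean ground truth.")
  }
  sqrt(mean((predicted - actual)^2)) / m
}

#' Per-operation energy costs of the neuromorphic processor
#'
#' Circuit-level energy estimates (at 1.8 V) for the events that dominate the
#' chip's activity-dependent power: generating a spike, encoding it and
#' appending destinations, broadcasting within a core, routing to another
#' core, and extending the output pulse.
#'
#' @param e_spike,e_enc,e_br,e_rt,e_pulse Energies in joules.
#' @return A named list of class `energy_table`.
#' @export
energy_table <- function(e_spike = 883e-12, e_enc = 883e-12, e_br = 6.84e-9,
                         e_rt = 360e-12, e_pulse = 324e-12) {
  vals <- c(e_spike = e_spike, e_enc = e_enc, e_br = e_br, e_rt = e_rt,
            e_pulse = e_pulse)
  if (any(vals <= 0)) rlang::abort("All energies must be positive.")
  structure(as.list(vals), class = "energy_table")
}

#' Estimate chip power from firing rates and fan-out
#'
#' Sums, over neurons, `r_n * (E_spike + E_enc + N_cores * (E_br + E_rt) +
#' N_cam_match * E_pulse)`: power is linear in the rates and zero when the
#' network is silent.
#'
#' @param rates Per-neuron mean firing rates in Hz (recycled scalars allowed
#'   via `n_neurons`).
#' @param n_cores Destination core count per neuron.
#' @param n_cam_match Postsynaptic neuron count per neuron (fan-out).
#' @param table An [energy_table()].
#' @param n_neurons Optional count to expand scalar `rates`.
#' @return Power in watts.
#' @export
#' @examples
#' estimate_power(1, n_cores = 1, n_cam_match = 0) # 8.966e-9 W
estimate_power <- function(rates, n_cores = 1, n_cam_match = 0,
                           table = energy_table(), n_neurons = NULL) {
  if (!is.null(n_neurons)) rates <- rep_len(rates, n_neurons)
  if (any(rates < 0)) rlang::abort("Firing rates must be non-negative.")
  per_spike <- table$e_spike + table$e_enc + n_cores * (table$e_br + table$e_rt) +
    n_cam_match * table$e_pulse
  sum(rates * per_spike)
}

#' Mean per-neuron rates of a raster, for power estimation
#'
#' Full-trial mean firing rate of every simulated neuron (silent neurons
#' included as 0 Hz).
#'
#' @param raster An `snn_raster`.
#' @return A tibble `neuron`, `population`, `rate`.
#' @export
raster_mean_rates <- function(raster) {
  net <- attr(raster, "net")
  duration <- attr(raster, "duration")
  counts <- tabulate(raster$neuron, nbins = nrow(net$neurons))
  tibble::tibble(neuron = net$neurons$id, population = net$neurons$population,
                 rate = counts / duration)
}

#' Energy from power and duration
#' @param power Power in watts.
#' @param duration Duration in seconds (>= 0).
#' @return Energy in joules.
#' @export
#' @examples
#' energy(13.1e-6, 5) # 65.5e-6 J
energy <- function(power, duration) {
  if (any(duration < 0)) rlang::abort("`duration` must be non-negative.")
  power * duration
}

#' Stored energy of a battery
#' @param voltage Nominal voltage in volts.
#' @param capacity_mah Capacity in mAh.
#' @return Energy in joules (1 V * 1 mAh = 3.6 J).
#' @export
#' @examples
#' battery_energy(3.7, 100) # 1332 J
battery_energy <- function(voltage, capacity_mah) {
  if (voltage <= 0 || capacity_mah <= 0) rlang::abort("Inputs must be positive.")
  voltage * capacity_mah * 3.6
}

#' Fan-out that reconciles a mean rate with a measured power
#'
#' Calibration helper: given a subsystem's mean firing rate, neuron count and
#' a measured total power, returns the per-spike CAM fan-out `n_cam_match`
#' (at the stated `n_cores`) that makes the power model reproduce it.
#'
#' @param power_w Measured power in watts.
#' @param mean_rate Mean per-neuron rate in Hz.
#' @param n_neurons Neuron count.
#' @param n_cores Destination core count per neuron.
#' @param table An [energy_table()].
#' @return Implied `n_cam_match` (real-valued).
#' @export
fanout_for_power <- function(power_w, mean_rate, n_neurons, n_cores = 1,
                             table = energy_table()) {
  base <- table$e_spike + table$e_enc + n_cores * (table$e_br + table$e_rt)
  (power_w / (n_neurons * mean_rate) - base) / table$e_pulse
}

#' Noise-robustness sweep of the state-decoding task
#'
#' For every (SNR, color) cell, generates the synthetic staircase PPG, adds
#' calibrated noise, runs preprocessing and the requested state machine, and
#' scores the decoded state trace against the target HR (band centers vs
#' target, RRMSE). `snr_db = Inf` rows are the clean condition. Repeated for
#' `n_seeds` seed initializations; means are averaged across seeds and the
#' reported sd is the across-seed standard deviation (`NA` for one seed).
#'
#' @param snr_db Vector of SNR levels in dB (`Inf` = clean).
#' @param colors Noise colors.
#' @param n_seeds Number of seed initializations (default 10).
#' @param duration Trial length in seconds.
#' @param arch `"wta"`, `"nnnsm"`, or `"mononsm"`.
#' @param traj HR trajectory of the trial.
#' @param cfg Filter-bank configuration for preprocessing.
#' @param lif Preprocessing LIF parameters.
#' @param mismatch_cv Device mismatch of the state machine.
#' @param dt Simulation step (s).
#' @param seed Base seed; trial seeds are `seed + 1:n_seeds`.
#' @return A list with `trials` (one row per cell and seed) and `summary`
#'   (mean and sd per cell).
#' @export
noise_sweep <- function(snr_db = c(Inf, 20, 10, 5), colors = "white",
                        n_seeds = 10, duration = 100, arch = "wta",
                        traj = hr_staircase(duration = duration),
                        cfg = filter_bank_config(),
                        lif = lif_params(), mismatch_cv = 0.2, dt = 2e-4,
                        seed = 1L) {
  build <- switch(arch, wta = build_wta, nnnsm = build_nnnsm,
                  mononsm = build_mononsm)
  cells <- tidyr::expand_grid(snr_db = snr_db, color = colors,
                              run = seq_len(n_seeds))
  # clean condition is color-independent; keep a single set of clean rows
  cells <- dplyr::distinct(
    dplyr::mutate(cells, color = ifelse(is.infinite(.data$snr_db),
                                        "clean", .data$color)))
  trials <- purrr::pmap_dfr(cells, function(snr_db, color, run) {
    s <- seed + run
    w <- generate_ppg(traj, fs = 125, duration = duration)
    if (is.finite(snr_db)) w <- add_noise(w, snr_db, color, seed = s)
    err <- state_task_rrmse(w, traj, build(mismatch_cv = mismatch_cv, seed = s),
                            cfg = cfg, lif = lif, dt = dt, seed = s)
    tibble::tibble(snr_db = snr_db, color = color, run = run, rrmse = err)
  })
  summary <- dplyr::summarise(
    dplyr::group_by(trials, .data$snr_db, .data$color),
    mean_rrmse = mean(.data$rrmse),
    sd_rrmse = if (dplyr::n() > 1) stats::sd(.data$rrmse) else NA_real_,
    .groups = "drop"
  )
  list(trials = trials, summary = summary)
}

#' Run the state-decoding task on one waveform and score it
#'
#' Preprocesses the waveform, drives the given state machine with the per-band
#' spike trains, decodes the state trace and returns the RRMSE between decoded
#' band centers and the target HR (undecided windows are scored at the
#' across-band mean, a maximally uninformative prediction).
#'
#' @param w Input waveform.
#' @param traj Target HR trajectory.
#' @param spec A state-machine [network_spec()].
#' @param cfg Filter-bank configuration.
#' @param lif Preprocessing LIF parameters.
#' @param window State readout window (s).
#' @param dt,seed Simulation step and Poisson seed.
#' @return RRMSE (dimensionless).
#' @export
state_task_rrmse <- function(w, traj, spec, cfg = filter_bank_config(),
                             lif = lif_params(), window = 0.5, dt = 2e-4,
                             seed = 1L) {
  raster <- preprocess_pipeline(w, cfg, lif)
  inputs <- purrr::map(split(raster$time, raster$channel), identity)
  names(inputs) <- paste0("inp_", names(inputs))
  inputs <- inputs[names(inputs) %in% paste0("inp_e", 1:4)]
  sim <- simulate_network(spec, inputs, duration = wf_duration(w),
                          dt = dt, seed = seed)
  trace <- state_to_bpm(read_state(sim, window = window), cfg$bands)
  target <- hr_at(traj, trace$time)
  centers <- (cfg$bands$low_bpm + cfg$bands$high_bpm) / 2
  pred <- ifelse(is.na(trace$bpm), mean(centers), trace$bpm)
  rrmse(pred, target)
}
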