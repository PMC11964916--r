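#' Read / write multi-channel physiological records
#'
#' Records are delimited text: a comment header stating the sampling rate and
#' optional labels, then a `time_s` column followed by one column per channel
#' (e.g. `ppg`, `ecg`, `accel_x`, `accel_y`, `accel_z`). Channels are returned
#' as waveforms at the file's rate, optionally resampled to a common target
#' rate with a polyphase filter.
#'
#' @param path File path.
#' @param channels Channel names that must be present (`NULL` = all columns
#'   after `time_s`).
#' @param resample_to Optional target sampling rate in Hz.
#' @return A list of class `record_bundle`: `channels` (named waveform list),
#'   `fs`, `subject`, `activity`, `source`.
#' @export
read_record <- function(path, channels = NULL, resample_to = NULL) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("fs=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 2L) rlang::abort("Missing `# fs=...` header line.")
  fs <- as.numeric(m[2])
  lab <- function(key) {
    mm <- regmatches(header, regexec(paste0(key, "=([^ ]+)"), header))[[1]]
    if (length(mm) == 2L) mm[2] else NA_character_
  }
  dat <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  if (names(dat)[1] != "time_s") rlang::abort("First column must be `time_s`.")
  have <- names(dat)[-1]
  if (is.null(channels)) channels <- have
  missing <- setdiff(channels, have)
  if (length(missing)) {
    rlang::abort(sprintf("Record is missing channel(s): %s",
                         paste(missing, collapse = ", ")),
                 class = "hrsnn_schema_error")
  }
  chans <- purrr::map(stats::setNames(channels, channels), function(ch) {
    v <- dat[[ch]]
    if (anyNA(v)) {
      rlang::abort(sprintf("Channel '%s' has missing samples.", ch),
                   class = "hrsnn_schema_error")
    }
    w <- waveform(v, fs = fs, start = dat$time_s[1])
    if (!is.null(resample_to) && resample_to != fs) {
      rs <- resample_waveform(w, resample_to)
      rs
    } else w
  })
  out_fs <- if (is.null(resample_to)) fs else resample_to
  structure(list(channels = chans, fs = out_fs,
                 subject = lab("subject"), activity = lab("activity"),
                 source = path),
            class = "record_bundle")
}

#' @rdname read_record
#' @param bundle A `record_bundle` or named list of waveforms.
#' @param fs Sampling rate (required when `bundle` is a plain list).
#' @param subject,activity Optional labels written into the header.
#' @export
write_record <- function(bundle, path, fs = NULL, subject = NULL,
                         activity = NULL) {
  if (inherits(bundle, "record_bundle")) {
    chans <- bundle$channels; fs <- bundle$fs
    subject <- subject %||% bundle$subject
    activity <- activity %||% bundle$activity
  } else {
    chans <- bundle
    if (is.null(fs)) fs <- wf_fs(chans[[1]])
  }
  n <- nrow(chans[[1]])
  hdr <- sprintf("# fs=%.17g", fs)
  if (!is.null(subject) && !is.na(subject)) hdr <- paste0(hdr, " subject=", subject)
  if (!is.null(activity) && !is.na(activity)) hdr <- paste0(hdr, " activity=", activity)
  mat <- cbind(time_s = chans[[1]]$time,
               do.call(cbind, purrr::map(chans, "value")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(mat), collapse = "\t"), con)
  utils::write.table(format(mat, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Resample a waveform with a polyphase filter
#' @param w A waveform.
#' @param fs_new Target rate in Hz.
#' @return A waveform at `fs_new`.
#' @export
resample_waveform <- function(w, fs_new) {
  fs <- wf_fs(w)
  fr <- as.integer(MASS_fractions(fs_new / fs))
  v <- signal::resample(w$value, fr[1], fr[2])
  waveform(v, fs = fs_new, start = w$time[1])
}

# small rational approximation p/q of a rate ratio
MASS_fractions <- function(x, max_den = 1024L) {
  best <- c(1L, 1L); err <- Inf
  for (q in 1:max_den) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err) { err <- e; best <- c(p, q) }
    if (err == 0) break
  }
  best
}

#' Write / read spike events as delimited text
#'
#' Two-column `time_s`, `id` text; the id column holds the neuron index of a
#' simulation raster or the band label of a preprocessed raster.
#'
#' @param raster A raster tibble (`spike_raster` or `snn_raster`).
#' @param path File path.
#' @return `write_raster()` returns `path` invisibly; `read_raster()` returns
#'   a tibble `time`, `id`.
#' @export
write_raster <- function(raster, path) {
  id <- if ("neuron" %in% names(raster)) raster$neuron else raster$channel
  dur <- attr(raster, "duration")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration=%.17g", dur %||% max(raster$time, 0)), con)
  writeLines("time_s\tid", con)
  writeLines(sprintf("%.8f\t%s", raster$time, id), con)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("duration=([0-9.eE+-]+)", header))[[1]]
  dat <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           colClasses = c("numeric", "character"))
  out <- tibble::tibble(time = dat$time_s, id = dat$id)
  attr(out, "duration") <- as.numeric(m[2])
  out
}

#' Run a reproducible end-to-end experiment
#'
#' Executes synthesize -> preprocess -> decode and/or state machine -> metrics
#' from a single configuration list, writing every artifact (waveform, raster,
#' decoded series, metric table) plus a log with the full configuration, its
#' hash, and every seed, into `out_dir`. Re-running the same configuration
#' reproduces the outputs bit-identically.
#'
#' @param config Named list (or path to a YAML file) with fields `duration`,
#'   `fs`, `hr` (constant bpm or staircase `list(from, to, n_steps)`),
#'   optional `snr_db`/`color`, `arch` (`"decoder"`, `"wta"`, `"nnnsm"`,
#'   `"mononsm"`), `bands`, `order`, `gain`, `seed`, and optional simulation
#'   overrides `dt`, `mismatch_cv`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed results and file paths.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  allowed <- c("duration", "fs", "hr", "snr_db", "color", "arch", "bands",
               "order", "gain", "seed", "dt", "mismatch_cv", "window")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(
    list(duration = 100, fs = 125, hr = list(from = 60, to = 150, n_steps = 5),
         snr_db = Inf, color = "white", arch = "decoder", bands = "wide",
         order = 2, gain = 8, seed = 1L, dt = NULL, mismatch_cv = 0.2,
         window = 2),
    config
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digest <- rlang::hash(cfg)

  traj <- if (is.numeric(cfg$hr)) hr_constant(cfg$hr) else {
    hr_staircase(cfg$hr$from, cfg$hr$to, cfg$hr$n_steps, cfg$duration)
  }
  w <- generate_ppg(traj, fs = cfg$fs, duration = cfg$duration)
  if (is.finite(cfg$snr_db)) w <- add_noise(w, cfg$snr_db, cfg$color, cfg$seed)
  write_waveform(w, file.path(out_dir, "signal.tsv"))

  results <- list(config = cfg, digest = digest)
  if (cfg$arch == "decoder") {
    dcfg <- decoder_config(filter_bank_config(cfg$bands, cfg$order, cfg$gain,
                                              include_boundary = TRUE))
    hr <- decode_heart_rate(w, dcfg, window = cfg$window, seed = cfg$seed,
                            dt = cfg$dt %||% 1e-3)
    hr$target <- hr_at(traj, hr$time)
    utils::write.table(hr, file.path(out_dir, "decoded_hr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$hr <- hr
    results$rrmse <- rrmse(hr$hr, hr$target, na.rm = TRUE)
    results$rmse_bpm <- results$rrmse * mean(hr$target)
  } else {
    build <- switch(cfg$arch, wta = build_wta, nnnsm = build_nnnsm,
                    mononsm = build_mononsm,
                    rlang::abort("Unknown `arch`."))
    fb <- filter_bank_config(cfg$bands, cfg$order, cfg$gain)
    raster <- preprocess_pipeline(w, fb)
    inputs <- purrr::map(split(raster$time, raster$channel), identity)
    names(inputs) <- paste0("inp_", names(inputs))
    sim <- simulate_network(build(mismatch_cv = cfg$mismatch_cv, seed = cfg$seed),
                            inputs, duration = cfg$duration,
                            dt = cfg$dt %||% 2e-4, seed = cfg$seed)
    write_raster(sim, file.path(out_dir, "raster.tsv"))
    trace <- state_to_bpm(read_state(sim), hr_bands(cfg$bands))
    utils::write.table(trace, file.path(out_dir, "state_trace.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$trace <- trace
    target <- hr_at(traj, trace$time)
    pred <- ifelse(is.na(trace$bpm), mean(trace$bpm, na.rm = TRUE), trace$bpm)
    results$rrmse <- rrmse(pred, target)
  }
  log <- c(sprintf("config_digest: %s", digest),
           sprintf("seed: %d", cfg$seed),
           utils::capture.output(utils::str(cfg)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(results)
}
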