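#' Construct a uniformly sampled waveform
#'
#' A waveform is a tibble with columns `time` (seconds) and `value`, plus a
#' sampling-rate attribute. All signal-processing functions in the package
#' take and return waveforms, so calls chain with the pipe.
#'
#' @param value Numeric vector of samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param start Time of the first sample in seconds.
#' @return A tibble of class `hr_waveform` with columns `time`, `value`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * seq(0, 1, by = 1 / 125)), fs = 125)
#' signal_power(w)
waveform <- function(value, fs, start = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    rlang::abort("`fs` must be a single positive number.")
  }
  value <- as.numeric(value)
  out <- tibble::tibble(
    time = start + seq_along(value) / fs - 1 / fs,
    value = value
  )
  attr(out, "fs") <- fs
  class(out) <- c("hr_waveform", class(out))
  out
}

#' Sampling rate of a waveform
#' @param w A waveform (or any object carrying an `fs` attribute).
#' @return Sampling rate in Hz.
#' @export
wf_fs <- function(w) {
  fs <- attr(w, "fs")
  if (is.null(fs)) rlang::abort("Object has no sampling-rate attribute `fs`.")
  fs
}

#' Duration of a waveform in seconds
#' @param w A waveform.
#' @return Duration in seconds (sample count / fs).
#' @export
wf_duration <- function(w) nrow(w) / wf_fs(w)

# Rebuild a waveform from an existing one with new sample values.
wf_like <- function(w, value) {
  waveform(value, fs = wf_fs(w), start = w$time[1])
}

#' Mean power of a waveform
#'
#' The mean of squared samples, the quantity used to calibrate additive noise
#' to a target signal-to-noise ratio.
#'
#' @param w A waveform.
#' @return Mean squared sample value.
#' @export
signal_power <- function(w) {
  if (nrow(w) == 0L) rlang::abort("Cannot compute the power of an empty waveform.")
  mean(w$value^2)
}

#' Write / read a waveform as delimited text
#'
#' The on-disk format is tab-separated `time_s`, `value` with a comment header
#' line stating the sampling rate, so files round-trip losslessly and stay
#' human-readable.
#'
#' @param w A waveform.
#' @param path File path.
#' @return `write_waveform()` returns `path` invisibly; `read_waveform()`
#'   returns a waveform.
#' @export
write_waveform <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g start=%.17g", wf_fs(w), w$time[1]), con)
  writeLines("time_s\tvalue", con)
  writeLines(sprintf("%.10g\t%.17g", w$time, w$value), con)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("fs=([0-9.eE+-]+) start=([0-9.eE+-]+)", header))[[1]]
  if (length(m) != 3L) rlang::abort("Missing `# fs=... start=...` header line.")
  dat <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  waveform(dat$value, fs = as.numeric(m[2]), start = as.numeric(m[3]))
}

#' @export
print.hr_waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz, %.3f s>\n",
              nrow(x), wf_fs(x), wf_duration(x)))
  NextMethod()
}
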