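test_that("constant-HR pulses are periodic at 60/HR seconds", {
  w <- generate_ppg(hr_constant(60), table1_pulse(), fs = 125, duration = 20)
  peaks <- which(diff(sign(diff(w$value))) < 0) + 1L
  peaks <- peaks[w$value[peaks] > 0.15] # systolic peaks only
  expect_equal(mean(diff(w$time[peaks])), 1.000, tolerance = 1e-3)

  # phase conservation: pulse count matches floor(T * HR / 60) +/- 1
  for (h in c(72, 95, 130)) {
    wh <- generate_ppg(hr_constant(h), fs = 125, duration = 30)
    pk <- which(diff(sign(diff(wh$value))) < 0) + 1L
    pk <- pk[wh$value[pk] > 0.15]
    expect_lte(abs(length(pk) - floor(30 * h / 60)), 1)
  }
})

test_that("zero-amplitude pulse spec yields an all-zero waveform", {
  w <- generate_ppg(hr_constant(60), ppg_pulse_spec(a1 = 0, a2 = 0),
                    fs = 125, duration = 5)
  expect_true(all(w$value == 0))
})

test_that("generator matches dense brute-force evaluation of the pulse model", {
  w <- generate_ppg(hr_constant(60), fs = 125, duration = 3)
  dense_t <- seq(1, 2, by = 1e-4)
  dense <- brute_force_pulse(dense_t, 60)
  # peak height agrees within the 1/fs phase resolution of the sampled grid
  seg <- w[w$time >= 1 & w$time <= 2, ]
  expect_lt(abs(max(seg$value) - max(dense)), 1e-3)
  expect_lt(abs(seg$time[which.max(seg$value)] -
                dense_t[which.max(dense)]), 1 / 125 + 1e-9)
  # sample-by-sample agreement on the generator's own grid
  expect_equal(seg$value, brute_force_pulse(seg$time, 60), tolerance = 1e-10)
})

test_that("generator validates its arguments", {
  expect_error(generate_ppg(hr_constant(60), fs = 125, duration = 0), "positive")
  expect_error(generate_ppg(hr_constant(60), fs = 20, duration = 5), "50")
  expect_error(hr_constant(200), "range")
  expect_error(ppg_pulse_spec(b1 = -1), "positive")
})

test_that("time-varying HR accumulates phase without discontinuities", {
  traj <- hr_staircase(60, 150, 3, 30)
  w <- generate_ppg(traj, fs = 125, duration = 30)
  # no sample-to-sample jump can exceed the steepest pulse slope
  expect_lt(max(abs(diff(w$value))), 0.05)
})

test_that("signal power is the mean square", {
  expect_equal(signal_power(waveform(rep(0, 100), 100)), 0)
  expect_equal(signal_power(waveform(rep(3, 100), 100)), 9)
  t <- seq_len(1000) / 100
  expect_equal(signal_power(waveform(sin(2 * pi * t), 100)), 0.5,
               tolerance = 1e-12)
  expect_error(signal_power(waveform(numeric(0), 100)), "empty")
})

test_that("added noise is calibrated exactly to the target SNR", {
  w <- generate_ppg(hr_constant(80), fs = 125, duration = 100)
  p_sig <- signal_power(w)
  for (snr in c(0, 10)) {
    wn <- add_noise(w, snr, "white", seed = 3)
    expect_equal(mean((wn$value - w$value)^2), p_sig * 10^(-snr / 10),
                 tolerance = 1e-12)
  }
  expect_error(add_noise(waveform(rep(0, 10), 10), 10), "undefined")
})

test_that("noise colors have the stated spectral slope and are seeded", {
  # identical seeds give bit-identical noise
  w <- generate_ppg(hr_constant(80), fs = 125, duration = 10)
  expect_identical(add_noise(w, 5, "pink", seed = 9)$value,
                   add_noise(w, 5, "pink", seed = 9)$value)
  expect_false(identical(add_noise(w, 5, "pink", seed = 9)$value,
                         add_noise(w, 5, "pink", seed = 10)$value))
  # periodogram regression recovers the design exponent
  for (col in c("pink", "violet")) {
    alpha <- c(pink = -1, violet = 2)[[col]]
    n <- withr::with_seed(11, hrsnn:::colored_noise(2^17, col))
    sp <- stats::spec.pgram(n, plot = FALSE, taper = 0, detrend = FALSE)
    sel <- sp$freq > 0.01 & sp$freq < 0.1
    slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~
                                            log(sp$freq[sel])))[2])
    expect_equal(slope, alpha, tolerance = 0.08)
  }
})

test_that("pulse parameters are recovered from clean self-generated data", {
  w <- generate_ppg(hr_constant(60), fs = 125, duration = 10)
  fit <- fit_pulse_params(w, hr_constant(60),
                          start = ppg_pulse_spec(a1 = 0.25, a2 = 0.1, b1 = 0.5,
                                                 b2 = 0.55, theta1 = -0.6,
                                                 theta2 = 0.5, t0 = 0.35))
  truth <- ppg_pulse_spec()
  est <- tidy(align_pulse_fit(fit, t0 = truth$t0)) # fix the phase gauge
  for (term in est$term) {
    expect_lt(abs(est$estimate[est$term == term] - truth[[term]]) /
                abs(truth[[term]]), 0.05)
  }
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("degenerate waveforms signal a fit failure", {
  flat <- waveform(rep(0.2, 500), 125)
  expect_error(fit_pulse_params(flat, hr_constant(60)),
               class = "hrsnn_fit_failure")
})

test_that("noisy replicate fits recover the systolic amplitude dispersion", {
  # mean recovered a1 over replicates stays within the reference 0.19 +/- 0.02
  a1s <- purrr::map_dbl(1:10, function(s) {
    w <- add_noise(generate_ppg(hr_constant(60), fs = 125, duration = 8),
                   20, "white", seed = s)
    fit <- fit_pulse_params(w, hr_constant(60))
    fit$spec$a1
  })
  expect_gte(mean(a1s), 0.17)
  expect_lte(mean(a1s), 0.21)
})
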