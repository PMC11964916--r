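test_that("band tables convert bpm edges to the stated Hz edges", {
  wide <- hr_bands("wide")
  expect_equal(wide$low_bpm, c(60, 82, 105, 128))
  expect_equal(wide$high_bpm, c(82, 105, 128, 150))
  expect_equal(wide$low_bpm[1] / 60, 1.0000)
  expect_equal(wide$high_bpm[1] / 60, 1.3667, tolerance = 1e-4)
  narrow <- hr_bands("narrow")
  expect_equal(narrow$low_bpm, c(60, 80, 88, 96))
  expect_equal(narrow$high_bpm, c(80, 88, 96, 150))
})

test_that("boundary filters extend the bank by one band-width on each side", {
  cfg <- filter_bank_config("wide", include_boundary = TRUE)
  expect_equal(nrow(cfg$bands), 6)
  expect_equal(cfg$bands$low_bpm[1], 60 - 22)
  expect_equal(cfg$bands$high_bpm[6], 150 + 22)
})

test_that("filter bank isolates the band containing a pure tone", {
  fs <- 125
  t <- seq_len(60 * fs) / fs
  tone <- waveform(sin(2 * pi * (93.5 / 60) * t), fs) # center of e2
  out <- apply_filter_bank(tone, filter_bank_config("wide", order = 2))
  powers <- purrr::map_dbl(out$signal, function(s) signal_power(s[-(1:1000), ]))
  expect_equal(out$band[which.max(powers)], "e2")
  expect_true(all(powers[out$band != "e2"] < max(powers)))

  zero <- apply_filter_bank(waveform(rep(0, 1000), fs), filter_bank_config())
  expect_true(all(purrr::map_dbl(zero$signal, ~ max(abs(.x$value))) == 0))

  expect_error(
    apply_filter_bank(tone, filter_bank_config(
      tibble::tibble(band = "x", low_bpm = 100, high_bpm = 80 * 60))),
    "Nyquist")
})

test_that("full-wave rectification takes gain * |x|", {
  w <- waveform(c(-1, 2, -3), 10)
  expect_equal(rectify_amplify(w, 1)$value, c(1, 2, 3))
  expect_equal(rectify_amplify(w, 8)$value, 8 * c(1, 2, 3))
  expect_error(rectify_amplify(w, 0), "positive")
  # rectified sinusoid has its fundamental at twice the input frequency
  fs <- 200
  t <- seq_len(40 * fs) / fs
  r <- rectify_amplify(waveform(sin(2 * pi * 2 * t), fs), 1)
  sp <- stats::spec.pgram(r$value - mean(r$value), plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)] * fs, 4, tolerance = 0.05)
})

test_that("LIF encoding matches the closed-form inter-spike interval", {
  # dv/dt = (I - v)/tau: ISI = tau * log(I / (I - v_thr)) for constant I
  fs <- 1000
  p <- lif_params(tau = 0.024, v_thr = 1)
  for (I in c(1.5, 3, 8)) {
    st <- lif_encode(waveform(rep(I, 5 * fs), fs), p)
    isi_pred <- p$tau * log(I / (I - p$v_thr))
    expect_equal(mean(diff(st$time)), isi_pred, tolerance = 1.5 / fs / isi_pred)
  }
  expect_equal(nrow(lif_encode(waveform(rep(0, 1000), fs), p)), 0)
})

test_that("LIF rate is monotone in drive and threshold", {
  fs <- 500
  rate_at <- function(I, v_thr = 1) {
    nrow(lif_encode(waveform(rep(I, 4 * fs), fs), lif_params(v_thr = v_thr))) / 4
  }
  drives <- c(1.2, 2, 4, 8)
  rates <- vapply(drives, rate_at, numeric(1))
  expect_true(all(diff(rates) > 0))
  # higher spiking threshold produces fewer spikes (power saving)
  expect_lt(rate_at(4, v_thr = 1.5), rate_at(4, v_thr = 1))
})

test_that("spike times are strictly increasing and inside the signal support", {
  w <- rectify_amplify(generate_ppg(hr_constant(90), fs = 125, duration = 20), 8)
  st <- lif_encode(standardize_waveform(w), lif_params())
  expect_true(all(diff(st$time) > 0))
  expect_true(all(st$time > 0 & st$time <= 20))
})

test_that("preprocessing pipeline fires fastest in the band containing the HR", {
  for (h in c(65, 90, 115, 140)) {
    w <- generate_ppg(hr_constant(h), fs = 125, duration = 40)
    raster <- preprocess_pipeline(w, filter_bank_config("wide", 2, 8))
    counts <- table(factor(raster$channel, levels = paste0("e", 1:4)))
    expect_equal(unname(which.max(counts)), band_of(h),
                 label = sprintf("HR %d winner", h))
  }
})

test_that("silence in gives zero spikes out on all bands", {
  w <- waveform(rep(0, 125 * 5), 125)
  raster <- preprocess_pipeline(w, filter_bank_config())
  expect_equal(nrow(raster), 0)
})

test_that("channel rates count events in sliding windows", {
  w <- generate_ppg(hr_constant(90), fs = 125, duration = 20)
  raster <- preprocess_pipeline(w, filter_bank_config())
  r <- channel_rates(raster, window = 2, step = 1)
  expect_true(all(c("time", "channel", "rate") %in% names(r)))
  manual <- sum(raster$time >= 0 & raster$time < 2 & raster$channel == "e2") / 2
  expect_equal(r$rate[r$channel == "e2"][1], manual)
})

test_that("decoding quality is stable in the LIF-parameter neighborhood", {
  # the operating point (tau = 24 ms, v_thr = 1) is not a knife edge: nearby
  # settings decode a short staircase with comparable raw error
  traj <- hr_staircase(65, 145, 4, 60)
  w <- generate_ppg(traj, fs = 125, duration = 60)
  rmse_at <- function(tau, v_thr) {
    cfg <- decoder_config(lif = lif_params(tau = tau, v_thr = v_thr,
                                           refractory = 0.002))
    hr <- decode_heart_rate(w, cfg, window = 4, seed = 1)
    tgt <- purrr::map_dbl(hr$time, function(tc) {
      mean(hr_at(traj, seq(tc - 2, tc + 2, by = 0.1)))
    })
    ok <- !is.na(hr$hr)
    sqrt(mean((hr$hr[ok] - tgt[ok])^2))
  }
  base <- rmse_at(0.024, 1)
  expect_lt(rmse_at(0.020, 1), 2 * base + 1)
  expect_lt(rmse_at(0.028, 1.1), 2 * base + 1)
})
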