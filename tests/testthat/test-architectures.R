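test_that("decoder weight matrix is Gaussian in bpm distance and normalized", {
  cfg <- decoder_config()
  g <- decoder_weights(cfg)
  expect_equal(dim(g), c(6, 13))
  expect_equal(unname(colSums(g)), rep(cfg$w_scale, 13), tolerance = 1e-12)
  # narrow-sigma limit: each decoder neuron driven only by its nearest band
  tiny <- decoder_config(sigma_in = 0.5)
  gt <- decoder_weights(tiny)
  beta <- (tiny$filter_bank$bands$low_bpm + tiny$filter_bank$bands$high_bpm) / 2
  for (k in seq_len(13)) {
    d <- abs(beta - tiny$centers[k])
    if (sum(d == min(d)) > 1) next # equidistant centers split the weight
    expect_equal(which.max(gt[, k]), which.min(d))
    expect_equal(max(gt[, k]), tiny$w_scale, tolerance = 1e-6)
  }
  spec <- build_decoder(cfg)
  expect_equal(sum(spec$populations$size[spec$populations$role != "input"]), 13)
})

test_that("profile peak equals the brute-force argmax of the smoothed profile", {
  cfg <- decoder_config()
  r <- exp(-(cfg$centers - 97)^2 / (2 * 12^2)) * 30 # known bump at 97 bpm
  kern_at <- function(g) {
    sum(r * exp(-(g - cfg$centers)^2 / (2 * cfg$kernel_sigma^2)))
  }
  grid <- seq(60, 150, by = 0.001)
  brute <- grid[which.max(vapply(grid, kern_at, numeric(1)))]
  fine <- seq(60, 150, by = 0.1)
  kern <- outer(fine, cfg$centers,
                function(g, c) exp(-(g - c)^2 / (2 * cfg$kernel_sigma^2)))
  expect_equal(hrsnn:::smooth_peak(kern %*% r, fine), brute, tolerance = 0.01)
})

test_that("activity concentrated on one decoder neuron decodes to its center", {
  cfg <- decoder_config()
  net <- realize_connectivity(build_decoder(cfg))
  k <- 5
  ev <- tibble::tibble(time = seq(0.1, 3.9, by = 0.05), neuron = net$pop_index$dec[k])
  raster <- ev
  attr(raster, "duration") <- 4
  attr(raster, "net") <- net
  class(raster) <- c("snn_raster", class(raster))
  hr <- decode_hr(raster, cfg, window = 2, step = 1)
  expect_equal(hr$hr, rep(cfg$centers[k], nrow(hr)), tolerance = 0.05)
  # a window with no spikes decodes to NA
  empty <- raster[0, ]
  attr(empty, "duration") <- 2
  attr(empty, "net") <- net
  class(empty) <- class(raster)
  expect_true(all(is.na(decode_hr(empty, cfg, window = 2, step = 1)$hr)))
})

test_that("the WTA selects and keeps the stimulated band", {
  spec <- build_wta(mismatch_cv = 0.2, seed = 3)
  n_sim <- sum(spec$populations$size[spec$populations$role != "input"])
  expect_equal(n_sim, 4 * 16 + 16)
  r <- simulate_network(spec, list(inp_e2 = 60), duration = 6, dt = 2e-4, seed = 4)
  st <- read_state(r, window = 0.5)
  expect_true(all(st$state[st$time > 2] == "e2"))
  # no input: no sustained winner above background
  r0 <- simulate_network(spec, list(), duration = 3, dt = 2e-4, seed = 4)
  expect_true(all(read_state(r0, window = 0.5)$state == "none"))
})

test_that("spiking WTA winner agrees with the rate-oracle argmax under mismatch", {
  hits <- withr::with_seed(42, {
    purrr::map_lgl(1:12, function(i) {
      dom <- sample(1:4, 1)
      rates <- stats::runif(4, 0, 0.5) * 120
      rates[dom] <- stats::runif(1, 80, 160)
      spec <- build_wta(mismatch_cv = 0.2, seed = i)
      inputs <- stats::setNames(as.list(rates), paste0("inp_e", 1:4))
      r <- simulate_network(spec, inputs, duration = 4, dt = 2e-4, seed = i + 1000)
      st <- read_state(r, window = 1)
      st$state[nrow(st)] == paste0("e", wta_rate_oracle(rates)$winner)
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("nnNSM wiring only gates adjacent bands", {
  spec <- build_nnnsm(seed = 1)
  expect_equal(sum(spec$populations$size[spec$populations$role != "input"]),
               80 + 4 * (16 + 4))
  cons <- spec$connections
  # allowed transition pattern implied by the gate wiring is tridiagonal:
  # block d_j (gating band j+1) is driven only by bands j and j+2 (own)
  gate_src <- cons[grepl("^e", cons$src) & grepl("_exc$", cons$dst), ]
  allowed <- matrix(FALSE, 4, 4)
  diag(allowed) <- TRUE
  for (i in seq_len(nrow(gate_src))) {
    k <- as.integer(substr(gate_src$src[i], 2, 2))
    j <- as.integer(substr(gate_src$dst[i], 2, 2))
    allowed[k, j + 1] <- TRUE # band k enables band j+1
  }
  expect_true(all(allowed == (abs(row(allowed) - col(allowed)) <= 1)))
})

test_that("nnNSM never activates a non-adjacent band directly", {
  spec <- build_nnnsm(mismatch_cv = 0.2, seed = 2)
  r <- simulate_network(spec, list(
    inp_e1 = data.frame(time = c(0, 4), rate = c(100, 0)),
    inp_e3 = data.frame(time = c(0, 4), rate = c(0, 100))),
    duration = 12, dt = 2e-4, seed = 102)
  st <- read_state(r, window = 0.5)
  expect_true(no_band_jump(st$state))
})

test_that("monoNSM progresses monotonically and holds under constant input", {
  spec <- build_mononsm(mismatch_cv = 0.2, seed = 4)
  r <- simulate_network(spec, list(
    inp_e1 = data.frame(time = c(0, 4), rate = c(100, 0)),
    inp_e2 = data.frame(time = c(0, 4, 8), rate = c(0, 100, 0)),
    inp_e3 = data.frame(time = c(0, 8, 12), rate = c(0, 100, 0)),
    inp_e4 = data.frame(time = c(0, 12), rate = c(0, 100))),
    duration = 16, dt = 2e-4, seed = 104)
  st <- read_state(r, window = 0.5)
  expect_true(monotone_states(st$state))
  expect_true(all(paste0("e", 1:4) %in% st$state)) # staircase visits all four
  # absorbing under held input
  r2 <- simulate_network(spec, list(inp_e1 = 100), duration = 8, dt = 2e-4,
                         seed = 204)
  st2 <- read_state(r2, window = 0.5)
  expect_true(all(st2$state[st2$time > 2] == "e1"))
})

test_that("state readout applies the winner margin", {
  ev <- tibble::tibble(time = rep(seq(0.05, 0.95, by = 0.05), 2),
                       neuron = rep(c(1, 17), each = 19))
  raster <- fake_raster(ev, list(e3 = 16L, e4 = 16L))
  # equal rates: margin readout is undecided, pure argmax is not
  expect_equal(read_state(raster, window = 1, margin = 0.1)$state[1], "none")
  expect_true(read_state(raster, window = 1, margin = 0)$state[1] %in%
                c("e3", "e4"))
  only3 <- fake_raster(tibble::tibble(time = seq(0.05, 1.95, by = 0.05),
                                      neuron = 2), list(e3 = 16L))
  expect_true(all(read_state(only3, window = 0.5)$state == "e3"))
})

test_that("transition time is non-increasing in stimulation rate", {
  spec <- build_wta(mismatch_cv = 0.2, seed = 5)
  expect_equal(measure_transition_time(spec, 2, 3, input_rate = 0,
                                       settle = 3, trial = 4, seed = 9), Inf)
  t_lo <- measure_transition_time(spec, 2, 3, input_rate = 60, settle_rate = 60,
                                  settle = 4, trial = 10, seed = 9)
  t_hi <- measure_transition_time(spec, 2, 3, input_rate = 140, settle_rate = 60,
                                  settle = 4, trial = 10, seed = 9)
  expect_gte(t_lo, t_hi)
})
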