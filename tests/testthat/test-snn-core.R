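test_that("connectivity realization follows the Bernoulli wiring law", {
  two_pops <- dplyr::bind_rows(population("a", 4, "exc"), population("b", 4, "exc"))
  full <- realize_connectivity(network_spec(
    two_pops, connection("a", "b", 1.0, 0.1, "slow")))
  expect_equal(nrow(full$edges), 16)
  none <- realize_connectivity(network_spec(
    two_pops, connection("a", "b", 0.0, 0.1, "slow")))
  expect_equal(nrow(none$edges), 0)

  # realized edge counts are binomial: mean over seeds near 0.85 * 256
  pops16 <- dplyr::bind_rows(population("a", 16, "exc"), population("b", 16, "exc"))
  spec <- network_spec(pops16, connection("a", "b", 0.85, 0.1, "slow"))
  counts <- purrr::map_int(1:100, function(s) {
    nrow(realize_connectivity(spec, seed = s)$edges)
  })
  se <- sqrt(256 * 0.85 * 0.15) / sqrt(100)
  expect_lt(abs(mean(counts) - 217.6), 4 * se)
})

test_that("network spec validation catches bad references and signs", {
  pops <- dplyr::bind_rows(population("a", 4, "exc"), population("i", 4, "inh"))
  expect_error(network_spec(pops, connection("a", "zz", 0.5, 0.1)), "unknown")
  expect_error(network_spec(pops, connection("a", "a", 0.5, -0.1)), "positive")
  expect_error(network_spec(pops, connection("i", "a", 0.5, 0.1)), "negative")
})

test_that("a quiescent network emits no events", {
  pops <- population("a", 8, "exc")
  net <- network_spec(pops, connection("a", "a", 0.3, 0.05, "slow"))
  r <- simulate_network(net, list(), duration = 1, dt = 5e-4)
  expect_equal(nrow(r), 0)
})

test_that("a driven neuron reproduces the closed-form LIF rate", {
  # regular high-rate input gives a near-constant synaptic current
  # I = w * R * tau_s; compare against the closed-form LIF rate
  pops <- dplyr::bind_rows(population("drv", 1, "input"),
                           population("n", 1, "exc"))
  spec <- network_spec(pops, connection("drv", "n", 1.0, 0.02, "slow"),
                       lif = lif_params(tau = 0.024, refractory = 0))
  train <- seq(5e-4, 4, by = 1e-3) # 1 kHz regular drive
  r <- simulate_network(spec, list(drv = train), duration = 4, dt = 1e-4)
  I <- 0.02 * 1000 * 0.1
  pred <- 1 / (0.024 * log(I / (I - 1)))
  expect_equal(sum(r$time > 1) / 3, pred, tolerance = 0.05)
})

test_that("excitatory and inhibitory currents approximately cancel at the attractor", {
  # at the winner's operating point the mean recurrent excitatory drive is
  # balanced by inhibition: |<I_exc> + <I_inh>| is small next to <I_exc>
  spec <- build_wta(mismatch_cv = 0.2, seed = 3)
  net <- realize_connectivity(spec)
  r <- simulate_network(net, list(inp_e2 = 60), duration = 6, dt = 2e-4, seed = 4)
  rates <- raster_mean_rates(r)
  rate_of <- function(id) rates$rate[id]
  e2_ids <- net$pop_index$e2
  syn_tau <- net$syn_tau
  cur <- function(edges) {
    if (!nrow(edges)) return(0)
    sum(edges$w * rate_of(edges$pre) * syn_tau[edges$k]) / length(e2_ids)
  }
  rec <- net$edges[net$edges$post %in% e2_ids, ]
  pre_pop <- net$neurons$population[rec$pre]
  ext <- net$ext_edges[net$ext_edges$post %in% e2_ids &
                         net$ext_edges$pre %in% net$input_index$inp_e2, ]
  i_ext <- sum(ext$w * 60 * syn_tau[ext$k]) / length(e2_ids)
  i_exc <- cur(rec[pre_pop != "inh", ]) + i_ext
  i_inh <- cur(rec[pre_pop == "inh", ])
  expect_gt(i_exc, 1)
  expect_lt(abs(i_exc + i_inh), 0.6 * i_exc)
})

test_that("population rates count events per neuron per second", {
  ev <- tidyr::expand_grid(neuron = 1:16, k = 1:25)
  ev$time <- (ev$k - 1) / 25 + 0.01
  raster <- fake_raster(ev[, c("time", "neuron")], list(p = 16L))
  pr <- population_rates(raster, "p", window = 1)
  expect_equal(pr$rate[1], 25)
  # Poisson raster recovers its rate within three standard errors
  lambda <- 40
  tt <- withr::with_seed(5, sort(stats::runif(16 * lambda * 2, 0, 2)))
  pois <- fake_raster(tibble::tibble(time = tt,
                                     neuron = rep(1:16, length.out = length(tt))),
                      list(p = 16L))
  pr2 <- population_rates(pois, "p", window = 2)
  se <- sqrt(16 * lambda * 2) / (2 * 16)
  expect_lt(abs(pr2$rate[1] - lambda), 3 * se)
})

test_that("simulations are bit-identical under a fixed seed", {
  spec <- build_wta(mismatch_cv = 0.2, seed = 7)
  a <- simulate_network(spec, list(inp_e1 = 50), duration = 2, dt = 5e-4, seed = 2)
  b <- simulate_network(spec, list(inp_e1 = 50), duration = 2, dt = 5e-4, seed = 2)
  expect_identical(a$time, b$time)
  expect_identical(a$neuron, b$neuron)
  d <- simulate_network(spec, list(inp_e1 = 50), duration = 2, dt = 5e-4, seed = 3)
  expect_false(identical(a$time, d$time))
  expect_true(all(a$time >= 0 & a$time <= 2))
})

test_that("runaway excitation is signalled instead of silently saturating", {
  pops <- dplyr::bind_rows(population("drv", 4, "input"), population("a", 8, "exc"))
  boom <- network_spec(
    pops,
    dplyr::bind_rows(connection("drv", "a", 1, 2, "slow"),
                     connection("a", "a", 1, 2, "slow")),
    lif = lif_params(tau = 0.024, refractory = 0)
  )
  expect_error(
    simulate_network(boom, list(drv = 200), duration = 2, dt = 5e-4,
                     rate_cap = 500),
    class = "hrsnn_runaway")
})

test_that("the rate oracle selects the largest input and reports ties", {
  res <- wta_rate_oracle(c(1, 3, 2, 0))
  expect_equal(res$winner, 2)
  expect_lt(max(res$rates[-2]), 1e-6 * res$rates[2])
  tie <- wta_rate_oracle(c(2, 2, 1, 0))
  expect_true(tie$tie)
  expect_true(is.na(tie$winner))
  withr::with_seed(21, {
    for (i in 1:100) {
      I <- stats::runif(4, 0, 10)
      expect_equal(wta_rate_oracle(I)$winner, which.max(I))
    }
  })
})
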