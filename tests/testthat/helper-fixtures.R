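# Shared small fixtures; everything is generated in code at test time.

table1_pulse <- function() ppg_pulse_spec()

# dense brute-force evaluation of the two-Gaussian circular-phase model for a
# constant heart rate, independent of generate_ppg()
brute_force_pulse <- function(t, bpm, p = ppg_pulse_spec()) {
  omega <- 2 * pi * bpm / 60
  psi <- omega * (t - p$t0) - pi
  theta <- atan2(sin(psi), cos(psi))
  p$a1 * exp(-(theta - p$theta1)^2 / (2 * p$b1^2)) +
    p$a2 * exp(-(theta - p$theta2)^2 / (2 * p$b2^2))
}

# minimal simulated raster with a hand-written event list, for readout tests
fake_raster <- function(events, pops) {
  pop_tbl <- purrr::imap_dfr(pops, function(sz, nm) population(nm, sz, "exc"))
  spec <- network_spec(pop_tbl,
                       connection(names(pops)[1], names(pops)[1], 0, 0.1, "slow"),
                       seed = 1L)
  net <- realize_connectivity(spec)
  out <- tibble::tibble(
    time = events$time,
    neuron = events$neuron,
    population = net$neurons$population[events$neuron]
  )
  attr(out, "duration") <- max(events$time, 1)
  attr(out, "net") <- net
  class(out) <- c("snn_raster", class(out))
  out
}

# band index (1..4) containing a heart rate, for selectivity checks
band_of <- function(bpm, bands = hr_bands("wide")) {
  which(bpm >= bands$low_bpm & bpm <= bands$high_bpm)[1]
}

no_band_jump <- function(states) {
  s <- states[states != "none"]
  if (length(s) < 2) return(TRUE)
  all(abs(diff(as.integer(substr(s, 2, 2)))) <= 1)
}

monotone_states <- function(states) {
  s <- states[states != "none"]
  if (length(s) < 2) return(TRUE)
  all(diff(as.integer(substr(s, 2, 2))) >= 0)
}
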