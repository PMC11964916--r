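#' Population and connection specifications
#'
#' A network is declared as populations (excitatory, inhibitory, or external
#' input sources) plus probabilistic connections. Each (pre, post) pair of a
#' connection is wired independently with the stated Bernoulli probability
#' when the network is realized, so realized in-degrees are binomial.
#'
#' @param name Population name.
#' @param size Neuron count (>= 1).
#' @param role `"exc"`, `"inh"`, or `"input"` (external spike sources).
#' @return A one-row tibble.
#' @export
population <- function(name, size, role = c("exc", "inh", "input")) {
  role <- match.arg(role)
  if (size < 1) rlang::abort("Population size must be >= 1.")
  tibble::tibble(name = name, size = as.integer(size), role = role)
}

#' @rdname population
#' @param src,dst Source and target population names.
#' @param p Bernoulli wiring probability in `[0, 1]`.
#' @param weight Synaptic efficacy; must be positive for excitatory/input
#'   sources and negative for inhibitory sources.
#' @param tau Synaptic current time constant: `"slow"`, `"fast"`, or seconds.
#' @param weights Optional dense `size(src) x size(dst)` weight matrix; when
#'   given, wiring is deterministic with these weights and `p`/`weight` are
#'   ignored.
#' @export
connection <- function(src, dst, p, weight, tau = "fast", weights = NULL) {
  if (is.null(weights) && (p < 0 || p > 1)) {
    rlang::abort("Connection probability must lie in [0, 1].")
  }
  tibble::tibble(src = src, dst = dst,
                 p = if (is.null(weights)) p else NA_real_,
                 weight = if (is.null(weights)) weight else NA_real_,
                 tau = list(tau), weights = list(weights))
}

#' Declare a recurrent spiking network
#'
#' @param populations Row-bound [population()] tibble.
#' @param connections Row-bound [connection()] tibble.
#' @param lif Neuron parameters shared by all simulated populations
#'   ([lif_params()]); per-neuron heterogeneity comes from `mismatch_cv`.
#' @param syn_tau Named vector of synaptic time constants in seconds; the
#'   defaults map the slow/fast synapse dichotomy of mixed-signal neuromorphic
#'   cores to 100 ms and 10 ms.
#' @param mismatch_cv Coefficient of variation of the multiplicative Gaussian
#'   jitter applied per neuron (membrane tau, threshold) and per synapse
#'   (weight) to emulate analog device mismatch.
#' @param seed Integer seed for connectivity and mismatch draws.
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(populations, connections,
                         lif = lif_params(tau = 0.024, refractory = 0.003),
                         syn_tau = c(slow = 0.1, fast = 0.01),
                         mismatch_cv = 0, seed = 1L) {
  bad <- setdiff(unique(c(connections$src, connections$dst)), populations$name)
  if (length(bad)) {
    rlang::abort(sprintf("Connection references unknown population(s): %s",
                         paste(bad, collapse = ", ")))
  }
  if (any(duplicated(populations$name))) rlang::abort("Duplicated population names.")
  roles <- stats::setNames(populations$role, populations$name)
  for (i in seq_len(nrow(connections))) {
    if (!is.null(connections$weights[[i]])) next
    w <- connections$weight[i]
    r <- roles[[connections$src[i]]]
    if (r %in% c("exc", "input") && w <= 0) {
      rlang::abort("Excitatory/input sources must have positive weights.")
    }
    if (r == "inh" && w >= 0) {
      rlang::abort("Inhibitory sources must have negative weights.")
    }
  }
  structure(list(populations = populations, connections = connections,
                 lif = lif, syn_tau = syn_tau, mismatch_cv = mismatch_cv,
                 seed = as.integer(seed)),
            class = "network_spec")
}

# multiplicative mismatch jitter, truncated away from zero
jitter_cv <- function(x, cv) {
  if (cv <= 0) return(x)
  x * pmax(1 + stats::rnorm(length(x), sd = cv), 0.05)
}

#' Realize the probabilistic connectivity of a network
#'
#' Draws the Bernoulli wiring and the device-mismatch parameter jitter under
#' the spec seed, producing the explicit adjacency the simulator runs on.
#'
#' @param spec A [network_spec()].
#' @param seed Optional seed override.
#' @return A list of class `network` with elements `neurons` (per-neuron
#'   parameter tibble), `edges` (recurrent adjacency), `ext_edges` (input
#'   adjacency), `pop_index` and `input_index` (global index maps).
#' @export
realize_connectivity <- function(spec, seed = spec$seed) {
  pops <- spec$populations
  sim_pops <- pops[pops$role != "input", ]
  inp_pops <- pops[pops$role == "input", ]
  offs <- c(0, cumsum(sim_pops$size))
  pop_index <- purrr::map2(offs[-length(offs)], sim_pops$size,
                           function(o, s) o + seq_len(s))
  names(pop_index) <- sim_pops$name
  ioffs <- c(0, cumsum(inp_pops$size))
  input_index <- purrr::map2(ioffs[-length(ioffs)], inp_pops$size,
                             function(o, s) o + seq_len(s))
  names(input_index) <- inp_pops$name
  n <- sum(sim_pops$size)

  tau_names <- names(spec$syn_tau)
  tau_idx <- function(tau) {
    if (is.character(tau)) {
      k <- match(tau, tau_names)
      if (is.na(k)) rlang::abort(sprintf("Unknown synaptic tau label '%s'.", tau))
      list(k = k, val = NULL)
    } else list(k = NA_integer_, val = as.numeric(tau))
  }

  withr::with_seed(seed, {
    neurons <- tibble::tibble(
      id = seq_len(n),
      population = rep(sim_pops$name, sim_pops$size),
      role = rep(sim_pops$role, sim_pops$size),
      tau_m = jitter_cv(rep(spec$lif$tau, n), spec$mismatch_cv),
      v_thr = jitter_cv(rep(spec$lif$v_thr, n), spec$mismatch_cv),
      v_reset = rep(spec$lif$v_reset, n),
      refractory = rep(spec$lif$refractory, n)
    )

    syn_tau <- spec$syn_tau
    resolve_tau <- function(tau) {
      ti <- tau_idx(tau)
      if (!is.na(ti$k)) return(ti$k)
      k <- match(ti$val, syn_tau)
      if (is.na(k)) {
        syn_tau <<- c(syn_tau, ti$val)
        k <- length(syn_tau)
      }
      k
    }

    make_edges <- function(con) {
      src_input <- con$src %in% names(input_index)
      pre_ids <- if (src_input) input_index[[con$src]] else pop_index[[con$src]]
      post_ids <- pop_index[[con$dst]]
      if (is.null(post_ids)) {
        rlang::abort(sprintf("Cannot target input population '%s'.", con$dst))
      }
      k <- resolve_tau(con$tau[[1]])
      if (!is.null(con$weights[[1]])) {
        wm <- con$weights[[1]]
        stopifnot(nrow(wm) == length(pre_ids), ncol(wm) == length(post_ids))
        idx <- which(wm != 0, arr.ind = TRUE)
        ed <- tibble::tibble(pre = pre_ids[idx[, 1]], post = post_ids[idx[, 2]],
                             w = wm[idx], k = k)
      } else {
        grid <- expand.grid(pre = pre_ids, post = post_ids)
        keep <- stats::runif(nrow(grid)) < con$p
        ed <- tibble::tibble(pre = grid$pre[keep], post = grid$post[keep],
                             w = con$weight, k = k)
      }
      ed$w <- jitter_cv(ed$w, spec$mismatch_cv)
      ed$input <- src_input
      ed
    }

    all_edges <- purrr::map_dfr(seq_len(nrow(spec$connections)),
                                function(i) make_edges(spec$connections[i, ]))
  })

  structure(list(
    spec = spec,
    neurons = neurons,
    edges = all_edges[!all_edges$input, c("pre", "post", "w", "k")],
    ext_edges = all_edges[all_edges$input, c("pre", "post", "w", "k")],
    syn_tau = syn_tau,
    pop_index = pop_index,
    input_index = input_index,
    seed = seed
  ), class = "network")
}

# CSR over presynaptic index (1..n_src); returns 0-based arrays for C++
edges_to_csr <- function(edges, n_src) {
  o <- order(edges$pre)
  counts <- tabulate(edges$pre, nbins = n_src)
  list(ptr = as.integer(c(0, cumsum(counts))),
       post = as.integer(edges$post[o] - 1L),
       w = as.numeric(edges$w[o]),
       k = as.integer(edges$k[o] - 1L))
}

# Draw a Poisson spike train for a piecewise-constant rate profile.
draw_poisson_train <- function(rate_df, duration) {
  t_edges <- c(rate_df$time, duration)
  out <- numeric(0)
  for (i in seq_len(nrow(rate_df))) {
    len <- t_edges[i + 1] - t_edges[i]
    if (len <= 0 || rate_df$rate[i] <= 0) next
    m <- stats::rpois(1, rate_df$rate[i] * len)
    if (m > 0) out <- c(out, sort(stats::runif(m, t_edges[i], t_edges[i + 1])))
  }
  out
}

#' Simulate a realized spiking network
#'
#' Clock-driven integration of every neuron's membrane and synaptic state.
#' External inputs are given per input population as either a constant Poisson
#' rate (Hz per generator), a piecewise-constant rate profile
#' (`data.frame(time, rate)`), or explicit spike times (numeric vector or a
#' `spike_train`), which are then routed through the realized input wiring.
#' Deterministic given the network (already realized with its own seed) and
#' `seed` (Poisson draws).
#'
#' @param net A realized [realize_connectivity()] network (a `network_spec`
#'   is accepted and realized first).
#' @param inputs Named list keyed by input population name; see Details.
#' @param duration Simulation length in seconds (> 0).
#' @param dt Time step in seconds (<= 1 ms; default 0.1 ms).
#' @param seed Seed for the Poisson input draws and replication jitter.
#' @param rate_cap Per-neuron mean rate (Hz) above which the run aborts with a
#'   runaway-excitation error, signalling parameters outside the balanced
#'   regime.
#' @param input_jitter When an explicit spike train is replicated across the
#'   generators of a multi-generator input population, each generator's copy
#'   is delayed by a fixed uniform draw in `[0, input_jitter]` seconds
#'   (seeded). This desynchronizes the copies, emulating independent encoder
#'   lines rather than one perfectly synchronous volley; single-generator
#'   populations are never jittered.
#' @return A tibble of class `snn_raster` with columns `time`, `neuron`,
#'   `population`; attributes `duration` and `net`.
#' @export
simulate_network <- function(net, inputs = list(), duration, dt = 1e-4,
                             seed = 1L, rate_cap = 1000, input_jitter = 0.05) {
  if (inherits(net, "network_spec")) net <- realize_connectivity(net)
  if (duration <= 0) rlang::abort("`duration` must be positive.")
  if (dt > 1e-3) rlang::abort("`dt` must be at most 1 ms.")
  n <- nrow(net$neurons)
  n_ext <- sum(lengths(net$input_index))

  unknown <- setdiff(names(inputs), names(net$input_index))
  if (length(unknown)) {
    rlang::abort(sprintf("Unknown input population(s): %s",
                         paste(unknown, collapse = ", ")))
  }

  ev_time <- list(); ev_src <- list()
  withr::with_seed(seed, {
    for (nm in names(inputs)) {
      gens <- net$input_index[[nm]]
      x <- inputs[[nm]]
      if (inherits(x, "spike_train")) x <- x$time
      if (is.numeric(x) && length(x) == 1L && is.null(dim(x))) {
        x <- data.frame(time = 0, rate = x)
      }
      if (is.data.frame(x)) {
        for (g in gens) {
          tt <- draw_poisson_train(x, duration)
          if (length(tt)) {
            ev_time[[length(ev_time) + 1]] <- tt
            ev_src[[length(ev_src) + 1]] <- rep(g, length(tt))
          }
        }
      } else { # explicit spike times, replicated to every generator
        tt <- as.numeric(x)
        tt <- tt[tt >= 0 & tt < duration]
        delays <- if (length(gens) > 1 && input_jitter > 0) {
          stats::runif(length(gens), 0, input_jitter)
        } else rep(0, length(gens))
        for (gi in seq_along(gens)) {
          tg <- tt + delays[gi]
          tg <- tg[tg < duration]
          ev_time[[length(ev_time) + 1]] <- tg
          ev_src[[length(ev_src) + 1]] <- rep(gens[gi], length(tg))
        }
      }
    }
  })
  ev_time <- unlist(ev_time) %||% numeric(0)
  ev_src <- unlist(ev_src) %||% integer(0)
  o <- order(ev_time)

  csr <- edges_to_csr(net$edges, n)
  ext <- edges_to_csr(net$ext_edges, max(n_ext, 1L))

  res <- simulate_net_cpp(
    net$neurons$tau_m, net$neurons$v_thr, net$neurons$v_reset,
    net$neurons$refractory,
    csr$ptr, csr$post, csr$w, csr$k,
    as.numeric(net$syn_tau),
    ev_time[o], as.integer(ev_src[o] - 1L),
    ext$ptr, ext$post, ext$w, ext$k,
    duration, dt, rate_cap
  )
  if (!isTRUE(res$ok)) {
    rlang::abort("Runaway excitation: mean population rate exceeded `rate_cap`.",
                 class = "hrsnn_runaway")
  }
  out <- tibble::tibble(
    time = res$time,
    neuron = res$neuron,
    population = net$neurons$population[res$neuron]
  )
  attr(out, "duration") <- duration
  attr(out, "net") <- net
  class(out) <- c("snn_raster", class(out))
  out
}

#' Sliding-window population firing rate
#'
#' Event count in a sliding window divided by window length and population
#' size, in Hz per neuron.
#'
#' @param raster An `snn_raster` from [simulate_network()].
#' @param populations Population names (default: all simulated populations).
#' @param window,step Window length and step in seconds (window >= step > 0).
#' @param duration Total duration (defaults to the raster attribute).
#' @return A tibble `time` (window center), `population`, `rate`.
#' @export
population_rates <- function(raster, populations = NULL, window = 0.5,
                             step = window, duration = attr(raster, "duration")) {
  if (!(window >= step && step > 0)) rlang::abort("Require window >= step > 0.")
  net <- attr(raster, "net")
  sizes <- table(net$neurons$population)
  if (is.null(populations)) populations <- names(net$pop_index)
  if (any(!populations %in% names(sizes))) rlang::abort("Unknown population.")
  starts <- seq(0, max(duration - window, 0), by = step)
  purrr::map_dfr(populations, function(pp) {
    tt <- raster$time[raster$population == pp]
    counts <- purrr::map_int(starts, function(s) sum(tt >= s & tt < s + window))
    tibble::tibble(time = starts + window / 2, population = pp,
                   rate = counts / (window * as.integer(sizes[[pp]])))
  })
}

#' Winner-take-all firing-rate oracle
#'
#' Integrates the rate equations
#' `tau * dr_i/dt = -r_i + f(I_i - sum_{j != i} w_ij r_j)` with rectifying
#' `f` and competition weights `w_ij = gamma * Heaviside(r_j - r_i)` to steady
#' state. In the idealized strong-competition regime only the unit with the
#' largest input stays active, so the oracle returns `which.max(I)`; exact
#' ties are reported as ties rather than broken.
#'
#' @param I Input vector.
#' @param gamma Inhibition strength (> 0).
#' @param tau Rate time constant in seconds.
#' @param dt,t_max Integration step and horizon in seconds.
#' @param tol Relative tolerance for declaring a tie in the inputs.
#' @return A list with `winner` (1-based index, `NA` on tie), `rates`
#'   (steady-state vector) and `tie` (logical).
#' @export
wta_rate_oracle <- function(I, gamma = 100, tau = 0.1, dt = 1e-3, t_max = 10,
                            tol = 1e-9) {
  if (gamma <= 0) rlang::abort("`gamma` must be positive.")
  I <- as.numeric(I)
  mx <- max(I)
  if (sum(abs(I - mx) <= tol * max(abs(mx), 1)) > 1L) {
    return(list(winner = NA_integer_, rates = rep(NA_real_, length(I)),
                tie = TRUE))
  }
  r <- pmax(I, 0) * 1e-3 # small input-proportional kick breaks symmetry honestly
  for (s in seq_len(round(t_max / dt))) {
    inh <- vapply(seq_along(r), function(i) {
      sum(gamma * (r[-i] > r[i]) * r[-i])
    }, numeric(1))
    drive <- pmax(I - inh, 0)
    r <- r + dt / tau * (-r + drive)
  }
  list(winner = which.max(r), rates = r, tie = FALSE)
}
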