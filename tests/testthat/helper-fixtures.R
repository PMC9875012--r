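# Shared fixtures. The reference single-neuron run (constant 20 uA, 100 ms,
# dt = 0.01 ms, recorded every step) is reused across several tests; build it
# once per test session.
.fixture_env <- new.env(parent = emptyenv())

single_neuron_traj <- function(dt = 0.01, duration = 100, I = 20) {
  key <- sprintf("sn_%g_%g_%g", dt, duration, I)
  if (is.null(.fixture_env[[key]])) {
    g1 <- directed_graph(1, matrix(integer(0), ncol = 2))
    .fixture_env[[key]] <- simulate_network(
      g1, hh_params(), I, 0,
      sim_settings(dt = dt, duration = duration, record_stride = 1))
  }
  .fixture_env[[key]]
}

empty_graph <- function(n) directed_graph(n, matrix(integer(0), ncol = 2))

# Hand-built spike raster (per-neuron spike time vectors + duration).
make_raster <- function(spike_times, duration) {
  structure(list(spike_times = spike_times, threshold = 0,
                 duration = duration, n = length(spike_times)),
            class = "spike_raster")
}

# Hand-built trajectory object for tests that need exact analytic states.
make_traj <- function(times, V, m, n, h, stimulus, k, graph,
                      params = hh_params()) {
  structure(list(times = times, V = V, m = m, n = n, h = h,
                 stimulus = stimulus, k = k, graph = graph, params = params,
                 dt = if (length(times) > 1) times[2] - times[1] else 1),
            class = "network_trajectory")
}

# Hand-built power decomposition with a prescribed total-rate series.
make_decomp <- function(times, total_rate, n = ncol(total_rate)) {
  z <- matrix(0, nrow(total_rate), n)
  structure(list(times = times, W_I = z, W_ion = z, gap_drive = z,
                 amp_supply = z, total_rate = total_rate,
                 P_nernst = total_rate, P_passive = z, P_nernst_raw = z,
                 stimulus = rep(0, n), k = 0, n = n),
            class = "power_decomposition")
}

# One experimental condition of the family-comparison protocol: generate the
# family graph at the requested scale, draw U[7,30] uA stimuli, simulate an
# energy window and an information window, and reduce to (E_N, alpha, I_N,
# epsilon_N). Mean degree is kept at the connectome's ~7.9 when scaling n.
family_condition <- function(family, n, edges, k, seed,
                             energy_window = 500, info_duration = 1500,
                             alpha_window = 100,
                             noise = noise_spec(FALSE),
                             need_info = TRUE, dt = 0.01) {
  g <- switch(family,
              ER = generate_er(n, edges, seed),
              WS = generate_ws(n, 8, 0.1, seed),
              BA = generate_ba(n, 8, edges, seed))
  stim <- draw_stimulus(n, 7, 30, seed = seed + 1000L)
  etraj <- simulate_network(g, hh_params(), stim, k,
                            sim_settings(dt = dt, duration = energy_window),
                            noise, seed = seed + 2000L)
  d <- power_decomposition(etraj)
  E_N <- network_energy_rate(d, energy_window)$E_N
  alpha <- negative_energy_ratio(d, alpha_window)$alpha
  I_N <- NA_real_
  if (need_info) {
    itraj <- simulate_network(g, hh_params(), stim, k,
                              sim_settings(dt = dt,
                                           duration = info_duration,
                                           record_gates = FALSE),
                              noise, seed = seed + 3000L)
    I_N <- network_information_rate(detect_spikes(itraj), 3, 30)$I_N
  }
  list(E_N = E_N, alpha = alpha, I_N = I_N, epsilon_N = I_N / E_N)
}
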