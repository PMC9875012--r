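#' Hodgkin-Huxley membrane parameters
#'
#' Defaults are the classical squid-axon values used throughout the package:
#' capacitance `C` = 1 uF/cm^2, maximal conductances `g_Na` = 120,
#' `g_K` = 36, `g_l` = 0.3 mS/cm^2, Nernst (reversal) potentials
#' `E_Na` = 50, `E_K` = -77, `E_l` = -54.5 mV, and initial potential
#' `V0` = -65 mV. All per-area quantities assume 1 cm^2 of membrane, so
#' power in mV * uA reads directly as nJ/s.
#'
#' @param C Membrane capacitance, uF/cm^2.
#' @param g_Na,g_K,g_l Maximal conductances, mS/cm^2 (must be positive).
#' @param E_Na,E_K,E_l Reversal potentials, mV.
#' @param V0 Initial membrane potential, mV.
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(C = 1, g_Na = 120, g_K = 36, g_l = 0.3,
                      E_Na = 50, E_K = -77, E_l = -54.5, V0 = -65) {
  stopifnot(C > 0, g_Na > 0, g_K > 0, g_l > 0)
  structure(list(C = C, g_Na = g_Na, g_K = g_K, g_l = g_l,
                 E_Na = E_Na, E_K = E_K, E_l = E_l, V0 = V0),
            class = "hh_params")
}

#' Channel-gate opening/closing rates
#'
#' Evaluates the six voltage-dependent rate functions (1/ms) of the HH model.
#' The removable singularities of `alpha_m` at V = -40 mV and `alpha_n` at
#' V = -55 mV are evaluated by their analytic limits (x/(1 - exp(-x/10)) -> 10
#' as x -> 0), so the rates are continuous everywhere.
#'
#' @param V Membrane potential(s), mV.
#' @return A matrix with columns `alpha_m`, `beta_m`, `alpha_n`, `beta_n`,
#'   `alpha_h`, `beta_h`, one row per element of `V`.
#' @export
gating_rates <- function(V) {
  stopifnot(all(is.finite(V)))
  gating_rates_cpp(as.numeric(V))
}

#' Steady-state gating values at a holding potential
#'
#' `x_inf = alpha_x / (alpha_x + beta_x)` for x in m, n, h. Used to
#' initialize simulations at rest so short energy windows are not dominated
#' by a startup transient.
#'
#' @param V Holding potential, mV.
#' @return Named vector `c(m, n, h)`.
#' @export
gating_steady_state <- function(V) {
  r <- gating_rates(V)[1, ]
  c(m = unname(r["alpha_m"] / (r["alpha_m"] + r["beta_m"])),
    n = unname(r["alpha_n"] / (r["alpha_n"] + r["beta_n"])),
    h = unname(r["alpha_h"] / (r["alpha_h"] + r["beta_h"])))
}

#' Time-derivative of a single-neuron HH state
#'
#' The membrane equation
#' `C dV/dt = -g_Na m^3 h (V - E_Na) - g_K n^4 (V - E_K) - g_l (V - E_l) + I`
#' together with the first-order gate kinetics
#' `dx/dt = alpha_x(V) (1 - x) - beta_x(V) x`.
#'
#' @param state Named vector/list with `V`, `m`, `n`, `h`.
#' @param I_total Total applied current, uA.
#' @param params An [hh_params()] object.
#' @return Named vector `c(dV, dm, dn, dh)` (mV/ms and 1/ms).
#' @export
hh_derivatives <- function(state, I_total, params = hh_params()) {
  V <- state[["V"]]; m <- state[["m"]]; n <- state[["n"]]; h <- state[["h"]]
  r <- gating_rates(V)[1, ]
  i_Na <- params$g_Na * m^3 * h * (V - params$E_Na)
  i_K  <- params$g_K * n^4 * (V - params$E_K)
  i_l  <- params$g_l * (V - params$E_l)
  c(dV = (I_total - i_Na - i_K - i_l) / params$C,
    dm = unname(r["alpha_m"] * (1 - m) - r["beta_m"] * m),
    dn = unname(r["alpha_n"] * (1 - n) - r["beta_n"] * n),
    dh = unname(r["alpha_h"] * (1 - h) - r["beta_h"] * h))
}

#' Gap-junction (electrical synapse) current
#'
#' `I_junction = k (V_i - V_j)`: the current a presynaptic neuron `i` injects
#' into neuron `j` through a gap junction of conductance `k`; positive values
#' depolarize neuron `j`.
#'
#' @param k Coupling conductance, mS/cm^2.
#' @param V_i,V_j Membrane potentials, mV.
#' @return Current in uA (vectorized).
#' @export
gap_junction_current <- function(k, V_i, V_j) k * (V_i - V_j)

#' Simulation settings
#'
#' @param dt Integration step, ms (default 0.01; fixed-step).
#' @param duration Total simulated time, ms.
#' @param integrator `"rk4"` (default) or `"euler"`.
#' @param record_stride Record every this many steps; the default records at
#'   0.1 ms resolution (sufficient for spike detection) regardless of `dt`.
#' @param record_gates Record m, n, h alongside V (needed for energy
#'   accounting; switch off for long information-rate runs to save memory).
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(dt = 0.01, duration = 100, integrator = c("rk4", "euler"),
                         record_stride = NULL, record_gates = TRUE) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, duration >= dt)
  if (is.null(record_stride)) record_stride <- max(1L, round(0.1 / dt))
  structure(list(dt = dt, duration = duration, integrator = integrator,
                 record_stride = as.integer(record_stride),
                 record_gates = isTRUE(record_gates)),
            class = "sim_settings")
}

#' Gaussian white-noise current specification
#'
#' When enabled, an independent draw from N(mean, variance) uA is added to
#' each neuron's stimulus current at every integration step and held constant
#' within the step. This literal per-step discretization is step-size
#' dependent; set `sqrt_dt_scaling = TRUE` for the diffusion-consistent
#' alternative in which the standard deviation is scaled by `1/sqrt(dt)`.
#'
#' @param enabled Logical.
#' @param mean Mean, uA (default 0).
#' @param variance Variance, uA^2 (default 1; must be >= 0).
#' @param sqrt_dt_scaling Use the `1/sqrt(dt)` scaled alternative.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(enabled = FALSE, mean = 0, variance = 1,
                       sqrt_dt_scaling = FALSE) {
  stopifnot(variance >= 0)
  structure(list(enabled = isTRUE(enabled), mean = mean, variance = variance,
                 sqrt_dt_scaling = isTRUE(sqrt_dt_scaling)),
            class = "noise_spec")
}

#' Simulate a gap-junction-coupled Hodgkin-Huxley network
#'
#' Integrates the coupled membrane equations: neuron `j` obeys
#' `C dV_j/dt = I_j - i_Na - i_K - i_l + k * sum_i C_ij (V_i - V_j)`
#' with the sum over presynaptic neurons `i` (directed edges `i -> j` of the
#' adjacency `C`), optional Gaussian white-noise current, fixed-step RK4
#' (default) and steady-state gating initialization at `V0`. A single neuron
#' is the special case of an empty graph with `n = 1`.
#'
#' @param graph A [directed_graph()].
#' @param params An [hh_params()].
#' @param stimulus Numeric vector of per-neuron constant currents, uA
#'   (length `graph$n`), e.g. from [draw_stimulus()].
#' @param k Gap-junction coupling strength, mS/cm^2.
#' @param settings A [sim_settings()].
#' @param noise A [noise_spec()].
#' @param seed Integer seed consumed before integration so noisy runs are
#'   reproducible; ignored for the dynamics when noise is off (the system is
#'   then deterministic).
#' @return An object of class `network_trajectory`: `times` (ms), matrices
#'   `V` (and `m`, `n`, `h` if recorded) of dimension samples x neurons,
#'   plus `stimulus`, `k`, `graph`, `params`, `dt`, `noise`.
#' @export
simulate_network <- function(graph, params = hh_params(), stimulus, k = 0,
                             settings = sim_settings(), noise = noise_spec(),
                             seed = NULL) {
  stopifnot(inherits(graph, "directed_graph"), inherits(params, "hh_params"))
  if (length(stimulus) != graph$n)
    stop("stimulus length (", length(stimulus), ") must equal graph$n (",
         graph$n, ")")
  n <- graph$n
  nsteps <- round(settings$duration / settings$dt)
  stride <- settings$record_stride
  nsteps <- (nsteps %/% stride) * stride  # whole recorded samples only
  g0 <- gating_steady_state(params$V0)
  if (!is.null(seed)) set.seed(seed)
  res <- hh_simulate_cpp(
    n = n,
    edges_from = graph$edges[, 1] - 1L, edges_to = graph$edges[, 2] - 1L,
    I_applied = as.numeric(stimulus), k = k,
    params = c(params$C, params$g_Na, params$g_K, params$g_l,
               params$E_Na, params$E_K, params$E_l),
    V0 = rep(params$V0, n), m0 = rep(g0[["m"]], n),
    n0 = rep(g0[["n"]], n), h0 = rep(g0[["h"]], n),
    dt = settings$dt, nsteps = nsteps, stride = stride,
    euler = settings$integrator == "euler",
    noise_on = noise$enabled, noise_mean = noise$mean,
    noise_sd = sqrt(noise$variance),
    noise_sqrt_dt = noise$sqrt_dt_scaling,
    record_gates = settings$record_gates)
  structure(c(res, list(stimulus = as.numeric(stimulus), k = k, graph = graph,
                        params = params, dt = settings$dt, noise = noise)),
            class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  cat(sprintf("network_trajectory: %d neurons, %d samples over %.1f ms (k = %g)\n",
              ncol(x$V), nrow(x$V), max(x$times), x$k))
  invisible(x)
}

#' Detect spikes by threshold crossing
#'
#' One spike per upward crossing of `threshold` (default 0 mV, which HH
#' action potentials at the default parameters overshoot by tens of mV),
#' with an enforced minimum separation (default 2 ms) so noisy shoulder
#' re-crossings are not double counted. The spike time is the first recorded
#' sample at or above threshold.
#'
#' @param traj A `network_trajectory` recorded at <= 0.1 ms resolution.
#' @param threshold Detection threshold, mV.
#' @param min_separation_ms Minimum inter-spike separation, ms.
#' @return An object of class `spike_raster`: list `spike_times` (per-neuron
#'   sorted numeric vectors, ms), `threshold`, `duration`, `n`.
#' @export
detect_spikes <- function(traj, threshold = 0, min_separation_ms = 2) {
  times <- traj$times
  step <- if (length(times) > 1) times[2] - times[1] else Inf
  if (step > 0.1 + 1e-9)
    warning("trajectory sampled at ", step,
            " ms; spike timing fidelity needs <= 0.1 ms")
  above <- traj$V >= threshold
  spikes <- lapply(seq_len(ncol(above)), function(j) {
    a <- above[, j]
    cross <- which(a & !c(FALSE, a[-length(a)]))
    st <- times[cross]
    if (length(st) > 1) {
      keep <- rep(TRUE, length(st))
      last <- st[1]
      for (i in seq_along(st)[-1]) {
        if (st[i] - last < min_separation_ms) keep[i] <- FALSE else last <- st[i]
      }
      st <- st[keep]
    }
    st
  })
  structure(list(spike_times = spikes, threshold = threshold,
                 duration = max(times), n = ncol(above)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons, %d spikes over %.1f ms\n",
              x$n, sum(lengths(x$spike_times)), x$duration))
  invisible(x)
}

#' Write a spike raster as a two-column CSV
#'
#' Columns `neuron_id` (1-based) and `spike_time_ms`.
#'
#' @param raster A `spike_raster`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  df <- data.frame(
    neuron_id = rep(seq_along(raster$spike_times),
                    lengths(raster$spike_times)),
    spike_time_ms = unlist(raster$spike_times))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
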