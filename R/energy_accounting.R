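# Cumulative / definite trapezoidal integral over the recorded time grid.
# x: times (ms), Y: samples x n matrix. Returns per-column integral in
# (units of Y) * ms.
.trapz <- function(x, Y) {
  nt <- length(x)
  w <- diff(x)
  colSums((Y[-nt, , drop = FALSE] + Y[-1, , drop = FALSE]) * w / 2)
}

.window_index <- function(times, window) {
  if (window > max(times) + 1e-9)
    stop("window (", window, " ms) exceeds trajectory duration (",
         max(times), " ms)")
  which(times <= window + 1e-9)
}

#' Decompose the instantaneous power budget of a simulated network
#'
#' Evaluates, sample-wise from the recorded states, every term of the
#' per-neuron energy rate
#' \deqn{\dot E_j = V_j I_j - g_{Na} m_j^3 h_j (V_j-E_{Na})^2
#'   - g_K n_j^4 (V_j-E_K)^2 - g_l (V_j-E_l)^2
#'   + \sum_i k C_{ij} V_j (V_i - V_j) + \sum_i k C_{ij} V_i (V_i - V_j)}
#' (all in nJ/s for a 1 cm^2 membrane): the stimulus power `W_I = V I`, the
#' ion-channel power `W_ion` (a sum of negated squares, hence pointwise
#' non-positive), the gap-junction drive and amplifier-supply coupling terms,
#' and their sum `total_rate`. Also returns the Nernst-potential power
#' `P_nernst = |i_K E_K| + |i_l E_l| - |i_Na E_Na|` (the ion-pump proxy: the
#' sodium source is storing energy, hence negative) and the passive-transport
#' power `P_passive = V (i_Na + i_K + i_l)`.
#'
#' @param traj A `network_trajectory` recorded with gating variables.
#' @param params Membrane parameters; defaults to those stored in `traj`.
#' @return An object of class `power_decomposition`: `times` plus matrices
#'   (samples x neurons) `W_I`, `W_ion`, `gap_drive`, `amp_supply`,
#'   `total_rate`, `P_nernst`, `P_passive`, `P_nernst_raw`
#'   (`i_Na E_Na + i_K E_K + i_l E_l`, the sign-consistent form used by the
#'   energy-identity oracle).
#' @export
power_decomposition <- function(traj, params = traj$params) {
  if (is.null(traj$m))
    stop("trajectory lacks gating variables; simulate with record_gates = TRUE")
  V <- traj$V
  if (ncol(V) != traj$graph$n)
    stop("graph/trajectory mismatch: ", traj$graph$n, " nodes vs ",
         ncol(V), " recorded neurons")
  i_Na <- params$g_Na * traj$m^3 * traj$h * (V - params$E_Na)
  i_K  <- params$g_K * traj$n^4 * (V - params$E_K)
  i_l  <- params$g_l * (V - params$E_l)
  W_I <- sweep(V, 2, traj$stimulus, "*")
  W_ion <- -(i_Na * (V - params$E_Na) + i_K * (V - params$E_K) +
             i_l * (V - params$E_l))
  C <- adjacency(traj$graph)
  if (nrow(traj$graph$edges) > 0 && traj$k != 0) {
    S <- as.matrix(V %*% C)        # S[t, j] = sum_i C_ij V_i
    Q <- as.matrix((V * V) %*% C)  # Q[t, j] = sum_i C_ij V_i^2
    indeg <- Matrix::colSums(C)
    gap_drive  <- traj$k * (V * S - sweep(V * V, 2, indeg, "*"))
    amp_supply <- traj$k * (Q - S * V)
  } else {
    gap_drive <- amp_supply <- matrix(0, nrow(V), ncol(V))
  }
  structure(list(
    times = traj$times,
    W_I = W_I, W_ion = W_ion,
    gap_drive = gap_drive, amp_supply = amp_supply,
    total_rate = W_I + W_ion + gap_drive + amp_supply,
    P_nernst = abs(i_K * params$E_K) + abs(i_l * params$E_l) -
      abs(i_Na * params$E_Na),
    P_passive = V * (i_Na + i_K + i_l),
    P_nernst_raw = i_Na * params$E_Na + i_K * params$E_K + i_l * params$E_l,
    stimulus = traj$stimulus, k = traj$k, n = ncol(V)),
    class = "power_decomposition")
}

#' @export
print.power_decomposition <- function(x, ...) {
  cat(sprintf("power_decomposition: %d neurons, %d samples (k = %g)\n",
              x$n, length(x$times), x$k))
  invisible(x)
}

#' Peak ion-channel power magnitude
#'
#' Per-neuron maximum over time of `|W_ion|`, the instantaneous
#' electrochemical power dissipated in the ion channels (nJ/s).
#'
#' @param traj A `network_trajectory` (gating recorded).
#' @param params Membrane parameters (default from `traj`).
#' @return Numeric vector, one value per neuron.
#' @export
ion_channel_power_peak <- function(traj, params = traj$params) {
  d <- power_decomposition(traj, params)
  apply(abs(d$W_ion), 2, max)
}

#' Network energy consumption rate
#'
#' Integrates each neuron's total power over `[0, window]` by the
#' trapezoidal rule and flips the sign so consumption is reported positive
#' (the ionic terms are negated squares, so the raw integral is negative).
#' The network rate is the time average
#' `E_N = sum_j E_j / t` with `t` in seconds, hence nJ/s.
#'
#' @param decomp A [power_decomposition()].
#' @param window Averaging window, ms (must not exceed the trajectory).
#' @return An object of class `energy_summary`: `E_j` (per-neuron nJ),
#'   `E_N` (nJ/s), `window_ms`.
#' @export
network_energy_rate <- function(decomp, window = max(decomp$times)) {
  idx <- .window_index(decomp$times, window)
  tsec <- decomp$times[idx[length(idx)]] / 1000
  E_j <- -.trapz(decomp$times[idx], decomp$total_rate[idx, , drop = FALSE]) / 1000
  structure(list(E_j = E_j, E_N = sum(E_j) / tsec, window_ms = window),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, ...) {
  cat(sprintf("energy_summary: E_N = %.1f nJ/s over %g ms (%d neurons)\n",
              x$E_N, x$window_ms, length(x$E_j)))
  invisible(x)
}

#' Nernst-potential vs passive-transport power split
#'
#' Splits the ion-channel power into the power of the Nernst-potential
#' voltage sources (`P_nernst`, the ion-pump proxy with the sodium source
#' counted as storing, i.e. negative) and the power driven by the membrane
#' potential gradient (`P_passive = V (i_Na + i_K + i_l)`).
#'
#' @param traj A `network_trajectory`.
#' @param params Membrane parameters (default from `traj`).
#' @return List of matrices `P_nernst`, `P_passive`, `P_nernst_raw`.
#' @export
nernst_passive_split <- function(traj, params = traj$params) {
  d <- power_decomposition(traj, params)
  list(P_nernst = d$P_nernst, P_passive = d$P_passive,
       P_nernst_raw = d$P_nernst_raw)
}

#' Negative energy ratio (synchronization index)
#'
#' Fraction of the network's integrated power that is negative
#' (energy-storing) over `[0, window]`:
#' `alpha = |E_negative| / (E_positive + |E_negative|) * 100` (percent), with
#' `E_negative = sum_j int P_j 1[P_j < 0] dt` and
#' `E_positive = sum_j int P_j 1[P_j > 0] dt`.
#'
#' The power `P_j(t)` entering the ratio is configurable:
#' \describe{
#'   \item{`"nernst_full"` (default)}{stimulus power + Nernst-source power
#'     (`|i_K E_K| + |i_l E_l| - |i_Na E_Na|`) + both gap-junction coupling
#'     terms.}
#'   \item{`"total"`}{the full energy rate `total_rate` (every term of the
#'     per-neuron budget).}
#'   \item{`"nernst_only"`}{the Nernst-source power alone.}
#' }
#'
#' @param decomp A [power_decomposition()].
#' @param window Window, ms.
#' @param power Which per-neuron power series defines the ratio.
#' @return An object of class `negative_energy_ratio`: `alpha` (percent,
#'   in `[0, 100]`), `E_negative`, `E_positive` (nJ, magnitudes),
#'   `window_ms`.
#' @export
negative_energy_ratio <- function(decomp, window = max(decomp$times),
                                  power = c("nernst_full", "total",
                                            "nernst_only")) {
  power <- match.arg(power)
  P <- switch(power,
              nernst_full = decomp$W_I + decomp$P_nernst + decomp$gap_drive +
                decomp$amp_supply,
              total = decomp$total_rate,
              nernst_only = decomp$P_nernst)
  idx <- .window_index(decomp$times, window)
  tt <- decomp$times[idx]
  P <- P[idx, , drop = FALSE]
  E_neg <- sum(.trapz(tt, P * (P < 0))) / 1000
  E_pos <- sum(.trapz(tt, P * (P > 0))) / 1000
  if (E_neg == 0 && E_pos == 0)
    stop("power series identically zero: negative energy ratio undefined")
  structure(list(alpha = abs(E_neg) / (E_pos + abs(E_neg)) * 100,
                 E_negative = abs(E_neg), E_positive = E_pos,
                 window_ms = window, power = power),
            class = "negative_energy_ratio")
}

#' @export
print.negative_energy_ratio <- function(x, ...) {
  cat(sprintf("negative_energy_ratio: alpha = %.4f%% over %g ms (%s power)\n",
              x$alpha, x$window_ms, x$power))
  invisible(x)
}

#' Energy-identity residual (equivalent-circuit consistency check)
#'
#' Along a recorded single-neuron trajectory, accumulates the source
#' energies `H_ion(t) = int i_ion E_ion dt` (cumulative trapezoid) to form
#' the total circuit energy `E(t) = C V^2 / 2 + H_Na + H_K + H_l`, and
#' compares the central finite difference `dE/dt` against the closed-form
#' energy rate `V I - g_Na m^3 h (V-E_Na)^2 - g_K n^4 (V-E_K)^2 -
#' g_l (V-E_l)^2`. Both are exact restatements of the same circuit, so the
#' residual is pure discretization error, shrinking as O(dt^2).
#'
#' @param traj A single-neuron `network_trajectory` recorded every step
#'   (`record_stride = 1`).
#' @param params Membrane parameters (default from `traj`).
#' @return Max absolute residual divided by max absolute energy rate.
#' @export
energy_identity_residual <- function(traj, params = traj$params) {
  stopifnot(ncol(traj$V) == 1)
  V <- traj$V[, 1]; tt <- traj$times
  src <- traj$stimulus[1]
  d <- power_decomposition(traj, params)
  iE <- d$P_nernst_raw[, 1]                    # i_Na E_Na + i_K E_K + i_l E_l
  h <- diff(tt)
  H <- c(0, cumsum((iE[-length(iE)] + iE[-1]) * h / 2))
  E_total <- params$C * V^2 / 2 + H
  core <- 2:(length(tt) - 1)
  dEdt <- (E_total[core + 1] - E_total[core - 1]) / (tt[core + 1] - tt[core - 1])
  rhs <- d$W_I[, 1] + d$W_ion[, 1]
  max(abs(dEdt - rhs[core])) / max(abs(rhs))
}

#' Power-budget extremes of the sustained firing regime
#'
#' Summarizes a trajectory's repetitive-firing regime: the peak membrane
#' potential, the peak ion-channel power magnitude and the extremes of the
#' stimulus power `W_I = V I`, all taken over samples at or after `settle`
#' ms. The first action potential fired out of the rest initialization
#' overshoots well above the sustained spike amplitude, so the
#' characterization of ongoing activity discards roughly the first two
#' firing cycles.
#'
#' @param traj A `network_trajectory` with gating recorded (single neuron
#'   for the classical figure-style characterization).
#' @param settle Start of the sustained regime, ms (default 20).
#' @param neuron Column to summarize (default 1).
#' @return List: `peak_V` (mV), `W_ion_peak`, `W_I_min_mag`, `W_I_max`
#'   (nJ/s), `n_spikes` over the regime.
#' @export
steady_regime_summary <- function(traj, settle = 20, neuron = 1) {
  d <- power_decomposition(traj)
  keep <- traj$times >= settle
  V <- traj$V[keep, neuron]
  thr_cross <- sum(diff(V >= 0) == 1)
  list(peak_V = max(V),
       W_ion_peak = max(abs(d$W_ion[keep, neuron])),
       W_I_min_mag = abs(min(d$W_I[keep, neuron])),
       W_I_max = max(d$W_I[keep, neuron]),
       n_spikes = thr_cross)
}
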