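test_that("gating rate functions match their closed forms and limits", {
  r <- gating_rates(-65)[1, ]
  expect_equal(r[["beta_m"]], 4)        # exponent vanishes at V = -65
  expect_equal(r[["beta_n"]], 0.125)
  expect_equal(r[["alpha_h"]], 0.07)
  expect_equal(gating_rates(-35)[1, "beta_h"][[1]], 0.5)

  # removable singularities: value at the singular point equals the limit
  expect_equal(gating_rates(-40)[1, "alpha_m"][[1]], 1)
  expect_equal(gating_rates(-55)[1, "alpha_n"][[1]], 0.1)
  for (eps in c(-1e-6, 1e-6)) {
    expect_equal(gating_rates(-40 + eps)[1, "alpha_m"][[1]], 1,
                 tolerance = 1e-6)
    expect_equal(gating_rates(-55 + eps)[1, "alpha_n"][[1]], 0.1,
                 tolerance = 1e-6)
  }

  expect_true(all(gating_rates(seq(-120, 60, by = 0.5)) >= 0))
})

test_that("steady-state gating and derivatives behave at rest", {
  ss <- gating_steady_state(-65)
  expect_equal(ss[["m"]], 0.0529, tolerance = 1e-3)

  st <- c(V = -65, ss)
  d0 <- hh_derivatives(st, I_total = 0)
  expect_equal(d0[["dm"]], 0, tolerance = 1e-12)
  expect_equal(d0[["dn"]], 0, tolerance = 1e-12)
  expect_equal(d0[["dh"]], 0, tolerance = 1e-12)

  # stimulus chosen to cancel the ionic sum zeroes dV/dt
  p <- hh_params()
  i_sum <- p$g_Na * ss[["m"]]^3 * ss[["h"]] * (-65 - p$E_Na) +
    p$g_K * ss[["n"]]^4 * (-65 - p$E_K) + p$g_l * (-65 - p$E_l)
  expect_equal(hh_derivatives(st, i_sum)[["dV"]], 0, tolerance = 1e-12)

  # all channels shut, V at leak reversal, no input: nothing moves V
  d1 <- hh_derivatives(c(V = p$E_l, m = 0, n = 0, h = 0), 0)
  expect_equal(d1[["dV"]], 0)
})

test_that("gap-junction current is linear, zero at equality, antisymmetric", {
  expect_equal(gap_junction_current(1.5, -65, -70), 7.5)
  expect_equal(gap_junction_current(2, -50, -50), 0)
  expect_equal(gap_junction_current(0.7, -40, -60),
               -gap_junction_current(0.7, -60, -40))
})

test_that("a single neuron at 20 uA fires repetitively; at 0 uA it rests", {
  traj <- single_neuron_traj()
  raster <- detect_spikes(traj)
  expect_gt(length(raster$spike_times[[1]]), 5)
  reg <- steady_regime_summary(traj)
  expect_gt(reg$peak_V, 15)              # sustained spikes overshoot 0 mV
  expect_lt(reg$peak_V, 30)
  expect_true(all(diff(raster$spike_times[[1]]) > 2))

  rest <- simulate_network(empty_graph(1), hh_params(), 0, 0,
                           sim_settings(duration = 100))
  expect_length(detect_spikes(rest)$spike_times[[1]], 0)
  expect_lt(max(abs(rest$V[nrow(rest$V), 1] + 65)), 2)
})

test_that("gating variables stay inside [0, 1] along simulated trajectories", {
  g <- generate_er(10, 40, seed = 3)
  traj <- simulate_network(g, hh_params(), draw_stimulus(10, seed = 4), 1.5,
                           sim_settings(duration = 100))
  for (v in c("m", "n", "h")) {
    expect_true(all(traj[[v]] >= 0 & traj[[v]] <= 1))
  }
})

test_that("halving the step leaves spikes and peaks essentially unchanged", {
  t1 <- single_neuron_traj(dt = 0.01)
  t2 <- single_neuron_traj(dt = 0.005)
  s1 <- detect_spikes(t1)$spike_times[[1]]
  s2 <- detect_spikes(t2)$spike_times[[1]]
  expect_length(s2, length(s1))
  expect_lt(max(abs(s1 - s2)), 0.1)
  expect_lt(abs(max(t1$V) - max(t2$V)), 0.5)
})

test_that("symmetric twins stay identical and decoupling reproduces isolation", {
  # two mutually coupled identical neurons: traces coincide for all time
  g2 <- directed_graph(2, rbind(c(1, 2), c(2, 1)))
  tw <- simulate_network(g2, hh_params(), c(15, 15), 1.5,
                         sim_settings(duration = 50))
  expect_equal(tw$V[, 1], tw$V[, 2], tolerance = 1e-12)

  # k = 0: each neuron bit-identical to its isolated run
  g3 <- generate_er(3, 4, seed = 1)
  stim <- c(10, 18, 25)
  net <- simulate_network(g3, hh_params(), stim, 0,
                          sim_settings(duration = 50))
  for (j in 1:3) {
    iso <- simulate_network(empty_graph(1), hh_params(), stim[j], 0,
                            sim_settings(duration = 50))
    expect_identical(net$V[, j], iso$V[, 1])
  }
})

test_that("noise runs are reproducible from their seed and vary across seeds", {
  g <- generate_er(5, 10, seed = 2)
  stim <- draw_stimulus(5, seed = 3)
  args <- list(g, hh_params(), stim, 0.5, sim_settings(duration = 30),
               noise_spec(enabled = TRUE))
  a <- do.call(simulate_network, c(args, seed = 11))
  b <- do.call(simulate_network, c(args, seed = 11))
  c_ <- do.call(simulate_network, c(args, seed = 12))
  expect_identical(a$V, b$V)
  expect_false(identical(a$V, c_$V))
})

test_that("an over-large step triggers the instability error", {
  expect_error(
    simulate_network(empty_graph(1), hh_params(), 20, 0,
                     sim_settings(dt = 1, duration = 50, integrator = "euler",
                                  record_stride = 1)),
    "instability")
})

test_that("spike detection matches peak counting and shifts with its input", {
  traj <- single_neuron_traj()
  V <- traj$V[, 1]
  n_spikes <- length(detect_spikes(traj)$spike_times[[1]])
  # oracle: count of local maxima above 0 mV
  peaks <- which(diff(sign(diff(V))) == -2) + 1
  expect_identical(n_spikes, sum(V[peaks] > 0))

  # constant subthreshold trace: empty raster
  flat <- make_traj(seq(0, 10, 0.1), matrix(-65, 101, 1),
                    matrix(0, 101, 1), matrix(0, 101, 1), matrix(0, 101, 1),
                    0, 0, empty_graph(1))
  expect_length(detect_spikes(flat)$spike_times[[1]], 0)

  # time-shifted copy of a trace: raster shifted by the same lag
  nshift <- 500  # 5 ms at 0.01 ms sampling
  V2 <- cbind(V, c(rep(-65, nshift), V[1:(length(V) - nshift)]))
  sh <- make_traj(traj$times, V2, NULL, NULL, NULL, c(20, 20), 0,
                  empty_graph(2))
  r2 <- detect_spikes(sh)
  s1 <- r2$spike_times[[1]]
  s2 <- r2$spike_times[[2]]
  s1_in <- s1[s1 + 5 <= max(traj$times)]
  expect_equal(s2, s1_in + 5, tolerance = 1e-9)
})
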