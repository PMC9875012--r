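test_that("power terms at the rest state match direct arithmetic", {
  # hand-built one-sample trajectory at V = -65 with steady-state gating
  ss <- gating_steady_state(-65)
  tt <- c(0, 1)
  mk <- function(x) matrix(x, 2, 1)
  traj <- make_traj(tt, mk(-65), mk(ss[["m"]]), mk(ss[["n"]]), mk(ss[["h"]]),
                    stimulus = 20, k = 0, graph = empty_graph(1))
  d <- power_decomposition(traj)
  expect_equal(d$W_I[1, 1], -1300)               # (-65) * 20

  # oracle: direct arithmetic from the channel currents
  p <- hh_params()
  i_Na <- p$g_Na * ss[["m"]]^3 * ss[["h"]] * (-65 - p$E_Na)
  i_K <- p$g_K * ss[["n"]]^4 * (-65 - p$E_K)
  i_l <- p$g_l * (-65 - p$E_l)
  expect_equal(i_l * (-65 - p$E_l), 33.075)      # leak: -0.3 * 10.5^2 negated
  expect_equal(d$W_ion[1, 1],
               -(i_Na * (-65 - p$E_Na) + i_K * (-65 - p$E_K) +
                 i_l * (-65 - p$E_l)))
})

test_that("ion-channel power is pointwise non-positive and terms sum exactly", {
  g <- generate_er(8, 30, seed = 6)
  traj <- simulate_network(g, hh_params(), draw_stimulus(8, seed = 7), 1.2,
                           sim_settings(duration = 80))
  d <- power_decomposition(traj)
  expect_true(all(d$W_ion <= 0))
  recomposed <- d$W_I + d$W_ion + d$gap_drive + d$amp_supply
  expect_lt(max(abs(recomposed - d$total_rate)) /
            max(abs(d$total_rate)), 1e-9)
})

test_that("coupling terms obey the pairwise identity k (V_i^2 - V_j^2)", {
  g2 <- directed_graph(2, rbind(c(1, 2)))     # single edge 1 -> 2
  traj <- simulate_network(g2, hh_params(), c(22, 9), 1.5,
                           sim_settings(duration = 60))
  d <- power_decomposition(traj)
  lhs <- d$gap_drive[, 2] + d$amp_supply[, 2]
  rhs <- 1.5 * (traj$V[, 1]^2 - traj$V[, 2]^2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # neuron 1 has no presynaptic partner: no coupling power
  expect_true(all(d$gap_drive[, 1] == 0 & d$amp_supply[, 1] == 0))
})

test_that("per-channel algebra -g(V-E)^2 = E i - V i holds along trajectories", {
  traj <- single_neuron_traj()
  d <- power_decomposition(traj)
  expect_lt(max(abs(d$W_ion - (d$P_nernst_raw - d$P_passive))) /
            max(abs(d$W_ion)), 1e-9)
})

test_that("Nernst split reduces correctly when the sodium current vanishes", {
  ss <- gating_steady_state(-65)
  mk <- function(x) matrix(x, 2, 1)
  traj <- make_traj(c(0, 1), mk(-60), mk(0), mk(ss[["n"]]), mk(ss[["h"]]),
                    stimulus = 0, k = 0, graph = empty_graph(1))  # m = 0
  sp <- nernst_passive_split(traj)
  p <- hh_params()
  i_K <- p$g_K * ss[["n"]]^4 * (-60 - p$E_K)
  i_l <- p$g_l * (-60 - p$E_l)
  expect_equal(sp$P_nernst[1, 1], abs(i_K * p$E_K) + abs(i_l * p$E_l))

  # integrated raw-split form equals integrated squared-terms form
  tr <- single_neuron_traj()
  d <- power_decomposition(tr)
  h <- diff(tr$times)
  integ <- function(y) sum((y[-length(y)] + y[-1]) * h / 2)
  expect_equal(integ(d$P_nernst_raw[, 1] - d$P_passive[, 1]),
               integ(d$W_ion[, 1]), tolerance = 1e-9)
})

test_that("circuit energy bookkeeping matches the closed-form rate, O(dt^2)", {
  r1 <- energy_identity_residual(single_neuron_traj(dt = 0.01))
  r2 <- energy_identity_residual(single_neuron_traj(dt = 0.005))
  expect_lt(r1, 1e-3)
  expect_lt(r2, r1 / 2.5)   # roughly quadratic shrink
})

test_that("network energy rate: closed forms and the decoupled-sum identity", {
  # constant negative rate -c per neuron over t: E_N = n * c
  tt <- seq(0, 1000, 10)
  dc <- make_decomp(tt, matrix(-42, length(tt), 3))
  en <- network_energy_rate(dc, 1000)
  expect_equal(en$E_N, 3 * 42, tolerance = 1e-12)

  z <- make_decomp(tt, matrix(0, length(tt), 2))
  expect_equal(network_energy_rate(z, 1000)$E_N, 0)
  expect_error(network_energy_rate(dc, 2000), "window")

  # k = 0 network energy equals the sum of isolated-neuron energies
  g <- generate_er(4, 8, seed = 9)
  stim <- c(8, 14, 21, 28)
  net <- simulate_network(g, hh_params(), stim, 0,
                          sim_settings(duration = 100))
  E_net <- network_energy_rate(power_decomposition(net), 100)$E_N
  E_iso <- sum(vapply(1:4, function(j) {
    iso <- simulate_network(empty_graph(1), hh_params(), stim[j], 0,
                            sim_settings(duration = 100))
    network_energy_rate(power_decomposition(iso), 100)$E_N
  }, numeric(1)))
  expect_lt(abs(E_net - E_iso) / abs(E_iso), 1e-9)
})

test_that("negative energy ratio: closed forms, bounds, failure modes", {
  tt <- seq(0, 100, 1)
  pos <- make_decomp(tt, matrix(5, length(tt), 2))
  expect_equal(negative_energy_ratio(pos, 100, power = "total")$alpha, 0)

  # equal time at +c and -c: alpha = 50%
  wave <- matrix(rep(c(3, 3, -3, -3), length.out = length(tt)), ncol = 1)
  aw <- negative_energy_ratio(make_decomp(tt, wave), 100, power = "total")
  expect_equal(aw$alpha, 50, tolerance = 2)  # trapezoid smears transitions
  expect_true(aw$alpha >= 0 && aw$alpha <= 100)

  zero <- make_decomp(tt, matrix(0, length(tt), 1))
  expect_error(negative_energy_ratio(zero, 100, power = "total"),
               "undefined")

  # the three power variants give ratios in [0, 100] on a real run
  traj <- simulate_network(generate_er(6, 20, seed = 2), hh_params(),
                           draw_stimulus(6, seed = 3), 1.5,
                           sim_settings(duration = 100))
  d <- power_decomposition(traj)
  for (pw in c("nernst_full", "total", "nernst_only")) {
    a <- negative_energy_ratio(d, 100, power = pw)$alpha
    expect_true(a >= 0 && a <= 100)
  }
})
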