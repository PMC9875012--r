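---
title: "Energy efficiency of gap-junction-coupled Hodgkin-Huxley networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy efficiency of gap-junction-coupled Hodgkin-Huxley networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Nervous systems pay a steep metabolic price for signalling: most of the
cortical energy budget goes into restoring the ionic gradients that action
potentials dissipate. If metabolic energy is a binding constraint, the
wiring diagram of a neural network should be shaped by *energy efficiency*
— the information transmitted per unit of energy consumed. `neuroenergy`
makes that quantity computable for networks of Hodgkin-Huxley (HH) neurons
coupled by gap junctions (electrical synapses), and compares the classical
graph families — Erdős–Rényi (ER), Watts–Strogatz (WS) and Barabási–Albert
(BA) — at the scale of the *C. elegans* connectome (297 neurons, about
2,345 directed edges).

## The model

Each neuron follows the classical HH equations. Neuron $j$ of the network
obeys

$$C \dot V_j = I_j - i_{Na} - i_K - i_l + \sum_i k\, C_{ij} (V_i - V_j),$$

with $i_{Na} = g_{Na} m^3 h (V - E_{Na})$, $i_K = g_K n^4 (V - E_K)$,
$i_l = g_l (V - E_l)$, first-order kinetics for the gates $m, n, h$, and
the binary directed adjacency $C_{ij}$ (an edge $i \to j$ influences $j$
only). The gap-junction current $k (V_i - V_j)$ uses the coupling
conductance $k$ in mS/cm². Parameters default to the squid-axon values
($C = 1\,\mu F/cm^2$, $g_{Na} = 120$, $g_K = 36$, $g_l = 0.3$ mS/cm²,
$E_{Na} = 50$, $E_K = -77$, $E_l = -54.5$ mV, $V_0 = -65$ mV). All
per-area quantities assume 1 cm² of membrane, so mV·µA products read
directly as nJ/s.

### The energy budget

Treating the membrane as its equivalent circuit, the total electrical
energy is $E = \tfrac12 C V^2 + H_{Na} + H_K + H_l$, where each $H$
accumulates the energy of one ionic battery at rate $i_{ion} E_{ion}$.
Differentiating and substituting the membrane equation yields the
per-neuron energy rate

$$\dot E_j = V_j I_j - g_{Na} m^3 h (V_j - E_{Na})^2
 - g_K n^4 (V_j - E_K)^2 - g_l (V_j - E_l)^2
 + \sum_i k C_{ij} V_j (V_i - V_j) + \sum_i k C_{ij} V_i (V_i - V_j),$$

whose terms `power_decomposition()` reports separately: the stimulus power
$W_I = V I$, the ion-channel power $W_{ion}$ (a sum of negated squares,
hence pointwise non-positive), and the two coupling terms (gap-junction
drive and the power supplied by the unity-gain amplifier that sources the
junction current). Because the derivation is an algebraic identity, the
package carries its own regression oracle: `energy_identity_residual()`
re-accumulates $E(t)$ numerically and checks that its finite-difference
derivative matches the closed form, with residual shrinking as $O(dt^2)$.

The network consumption rate is $E_N = \langle \sum_j E_j \rangle_t$
(consumption reported positive, i.e. $E_j = -\int \dot E_j\,dt$, since the
dominant ionic terms are negative squares), computed by `network_energy_rate()`
with trapezoidal integration on the recorded grid.

### The negative-energy ratio

The synchronization index $\alpha$ is the fraction of integrated power
that is negative (energy-storing):
$\alpha = |E_{neg}| / (E_{pos} + |E_{neg}|) \times 100\%$. As typeset in
the source derivations, the negative-part integral is itself negative
while reported ratios are positive percentages; the package therefore uses
magnitudes, the only reading that yields values in $[0, 100]$. The power
entering $\alpha$ replaces the ionic block by the Nernst-source power
$P = |i_K E_K| + |i_l E_l| - |i_{Na} E_{Na}|$ (the sodium battery is
storing, the others consuming — the ion-pump proxy) plus the stimulus and
coupling terms. Whether the stimulus/coupling terms belong in $\alpha$ is
genuinely ambiguous in the source material, so `negative_energy_ratio()`
exposes the choice (`"nernst_full"` default, `"total"` and `"nernst_only"`
alternatives) rather than asserting one as canonical.

### Information rate and efficiency

Spike trains (upward crossings of 0 mV with a 2 ms refractory guard —
HH spikes at these parameters overshoot 0 mV by tens of mV, so the
threshold is uncritical) are binarized into $\Delta t$-wide bins, tiled by
non-overlapping windows of length $T$ into words of $l = T/\Delta t$
binary characters, and the plug-in Shannon entropy of the word
distribution gives the per-neuron entropy rate $H_T = -\tfrac1T \sum_w
p(w) \log_2 p(w)$ in bits/s ($T$ converted to seconds; the standard
positive entropy). The network information rate $I_N$ sums per-neuron
rates — words are per-neuron, not joint. Energy efficiency is
$\varepsilon_N = I_N / E_N$, bits per nJ.

The canonical protocol uses $\Delta t = 3$ ms, $T = 30$ ms ($l = 10$) and
a 9,000 ms record, i.e. 300 words per neuron. With up to $2^{10}$
possible words, 300 samples make the plug-in estimator noticeably biased
downward; the package documents and demonstrates the bias on synthetic
Bernoulli trains (where the analytic rate $l\,h(p)/T$ is known) but
deliberately applies no correction, since the protocol it implements uses
the raw plug-in estimate. Comparisons across families at matched settings
share the same bias and remain meaningful.

## Design choices in the gaps

Several ingredients are not pinned down by the source material; the
package fixes them once, as follows.

* **Integrator.** Fixed-step RK4 at `dt = 0.01` ms (Euler available for
  cross-checks). Halving `dt` moves spike times by < 0.1 ms and peaks by
  < 0.5 mV, which the suite asserts. Long qualitative sweeps in the tests
  use 0.02 ms, inside the convergence plateau.
* **Initialization.** $V_0 = -65$ mV with gates at their steady state
  $x_\infty(V_0)$. The first action potential fired out of this rest
  state still overshoots anomalously (≈ 41 mV vs ≈ 25 mV sustained), so
  figure-style single-neuron summaries (`steady_regime_summary()`)
  discard the first 20 ms — about two firing cycles — and characterize
  the sustained regime.
* **Rate-function singularities.** $\alpha_m$ and $\alpha_n$ are evaluated
  by their analytic limits within $10^{-7}$ mV of $V = -40$ and $-55$.
* **Graph orientation.** The classical generators are undirected; the
  connectome adjacency is directed. ER is drawn directly as a directed
  $G(n, m)$ (exact edge budget, no extra variance). BA grows an
  undirected preferential-attachment skeleton (`attach = 8`, matching the
  target mean degree), orients each edge uniformly at random, then
  adds/deletes uniform random edges to hit the budget exactly. WS keeps
  the rewired ring lattice (`neighbors = 8`, `rewire_prob = 0.1`, the
  canonical small-world regime) and symmetrizes — both directions per
  lattice edge — giving $297 \times 8 = 2376$ directed edges, within 1.5%
  of the 2,345 target.
* **Noise.** "Unit-variance Gaussian white noise current" is discretized
  as one $N(0, 1)$ µA draw per neuron per step, held constant within the
  step. This literal reading is step-size dependent; the
  diffusion-consistent $1/\sqrt{dt}$ scaling sits behind
  `sqrt_dt_scaling = TRUE`. Seeding goes through R's RNG, so every run is
  reproducible from its seed.
* **Windows.** 1,000 ms for $E_N$, 100 ms for $\alpha$, 9,000 ms for
  $I_N$ (1,500 ms in the noise preset), all configurable in
  `sweep_spec()`.
* **Stimulus.** Constant per neuron per run, drawn once from U[7, 30] µA
  and reused across the `k` grid within a (family, repeat) so coupling is
  the only moving variable.
* **Bin-width sweeps** hold $l = 10$ and size the record as
  `words` × $T$ per bin width; one simulation of the longest record is
  truncated for the shorter ones, so every $\Delta t$ sees the same spike
  train.

## What the synthetic generators do and do not emulate

The generators reproduce the *scale* and *density* of the measured
connectome (297 nodes, ~2,345 directed edges), the stimulus protocol and
the noise model. They do not reproduce the connectome's actual wiring:
its degree correlations, community structure, or the identity of hub
neurons. Consequently the tests establish the *family-level* claims —
ER/WS consumption falling with coupling, the scale-free information and
efficiency advantage, bin-width monotonicity, noise robustness of the
ordering — as majority-over-seeds properties of the generated ensembles,
not point reproductions of any measured curve. A user with a real
adjacency can load it (`load_connectome()`, edge-list or 0/1 CSV,
self-loops dropped) and run the identical pipeline via the `"file"`
family.

## Problem sizes used by the test suite

Deterministic checks (single-neuron budget, energy identity, word
arithmetic) run at full resolution. The negative-energy-ratio band check
runs at the full 297-neuron scale with 100 ms windows. For the
stochastic family comparisons the suite uses 5 seeds with majority
verdicts, 500 ms energy / 1,500 ms information windows, the full
297-node scale for the scale-free comparisons (at 0.02 ms steps) and 60
nodes (density-matched, 474 edges) for the coupling-trend and bin-width
legs — sizes chosen so the ensemble properties are well resolved while a
complete run of the suite stays convenient on a laptop. Enlarging any of
them is a one-line change in the corresponding `sweep_spec()`.

## Known limitations

* The plug-in entropy estimator is biased at 300 words; rates are
  comparative, not absolute (no Miller–Madow/NSB correction by design).
* The per-step noise discretization ties the effective noise bandwidth to
  `dt`.
* Energy integration happens on the recorded 0.1 ms grid (trapezoid,
  $O(dt^2)$); recording every step tightens it when needed.
* Chemical synapses, synaptic weights and ATP stoichiometry are out of
  scope; the 3 Na⁺ / 2 K⁺ pump enters only through the Nernst-source
  interpretation of $P$.

## A minimal session

```{r, eval = FALSE}
library(neuroenergy)

g <- generate_ba(297, attach = 8, target_edges = 2345, seed = 1)
stim <- draw_stimulus(297, 7, 30, seed = 2)
traj <- simulate_network(g, hh_params(), stim, k = 1.5,
                         sim_settings(duration = 1000))
decomp <- power_decomposition(traj)
network_energy_rate(decomp, window = 1000)
negative_energy_ratio(decomp, window = 100)

itraj <- simulate_network(g, hh_params(), stim, k = 1.5,
                          sim_settings(duration = 9000,
                                       record_gates = FALSE))
info <- network_information_rate(detect_spikes(itraj), dt_bin = 3, T_ms = 30)
energy_efficiency(info$I_N, network_energy_rate(decomp, 1000)$E_N)
```

Whole protocols — coupling sweeps, bin-width sweeps, noisy repeats with
mean/sd summaries — go through `sweep_spec()` / `run_sweep()` /
`run_bin_length_sweep()` and export to tidy CSV with `write_results()`.
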