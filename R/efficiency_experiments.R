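#' Specification of a coupling-strength sweep
#'
#' Bundles every knob of the standard experiment: for each graph family and
#' repeat, generate (or load) a directed graph, draw per-neuron stimulus
#' currents from U(`stim_lo`, `stim_hi`) uA, and for each coupling strength
#' `k` simulate twice — a short run for the energy consumption rate `E_N`
#' (window `energy_window`, also providing the negative-energy-ratio window
#' `alpha_window`) and a long run for the information rate `I_N` (duration
#' `info_duration`) — then combine into the efficiency `epsilon_N`.
#' The same stimulus vector is reused across `k` within a (family, repeat)
#' so the coupling strength is the only moving variable.
#'
#' @param families Character subset of `c("BA", "ER", "WS", "file")`.
#' @param k_grid Coupling strengths, mS/cm^2 (default 20 points on
#'   `[0.1, 2]`).
#' @param n Node count (default 297, the C. elegans scale).
#' @param target_edges Directed edge budget (default 2345).
#' @param energy_window E_N window, ms (default 1000).
#' @param alpha_window Negative-energy-ratio window, ms (default 100).
#' @param info_duration Information-rate record, ms (default 9000, i.e.
#'   300 words of 30 ms; the noise preset in the literature uses 1500).
#' @param dt_bin,T_ms Binning and word windows, ms (defaults 3 and 30, so
#'   word length l = 10).
#' @param stim_lo,stim_hi Stimulus range, uA (defaults 7 and 30).
#' @param noise A [noise_spec()].
#' @param repeats Repeats per condition (>= 1); summaries with standard
#'   deviations are produced when `repeats >= 2`.
#' @param base_seed Integer; the whole sweep is a pure function of the spec
#'   including this seed.
#' @param dt Integration step, ms.
#' @param ws_neighbors,ws_rewire_prob,ba_attach Family parameters.
#' @param connectome_path,connectome_format Required when `"file"` is among
#'   the families.
#' @param new_graph_per_repeat Regenerate the graph for each repeat
#'   (default TRUE); when FALSE only stimulus/noise vary across repeats.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(families = c("BA", "ER", "WS"),
                       k_grid = seq(0.1, 2, length.out = 20),
                       n = 297, target_edges = 2345,
                       energy_window = 1000, alpha_window = 100,
                       info_duration = 9000, dt_bin = 3, T_ms = 30,
                       stim_lo = 7, stim_hi = 30,
                       noise = noise_spec(FALSE), repeats = 1,
                       base_seed = 1L, dt = 0.01,
                       ws_neighbors = 8, ws_rewire_prob = 0.1, ba_attach = 8,
                       connectome_path = NULL,
                       connectome_format = "edge_list",
                       new_graph_per_repeat = TRUE) {
  families <- match.arg(families, c("BA", "ER", "WS", "file"),
                        several.ok = TRUE)
  stopifnot(length(k_grid) >= 1, all(k_grid >= 0), repeats >= 1,
            alpha_window <= energy_window)
  if ("file" %in% families && is.null(connectome_path))
    stop("family 'file' requires a connectome_path")
  structure(as.list(environment()), class = "sweep_spec")
}

# Deterministic sub-seed table: one stream of seeds < 2^31 derived from
# base_seed, indexed by (family, repeat, purpose[, k]).
.seed_table <- function(base_seed, n_needed) {
  set.seed(base_seed)
  sample.int(.Machine$integer.max, n_needed)
}

.make_graph <- function(spec, family, seed) {
  switch(family,
         ER = generate_er(spec$n, spec$target_edges, seed),
         WS = generate_ws(spec$n, spec$ws_neighbors, spec$ws_rewire_prob, seed),
         BA = generate_ba(spec$n, spec$ba_attach, spec$target_edges, seed),
         file = load_connectome(spec$connectome_path, spec$connectome_format))
}

#' Run a coupling-strength sweep
#'
#' Executes the full pipeline for every (family, repeat, k) combination of a
#' [sweep_spec()]: graph generation, stimulus draw, network simulation,
#' energy accounting (`E_N`, `alpha`), information rate (`I_N`) and
#' efficiency (`epsilon_N`). Fully reproducible from `base_seed`.
#'
#' @param spec A [sweep_spec()].
#' @param verbose Print per-condition progress lines.
#' @return An object of class `sweep_result`: `rows` (a tidy data.frame with
#'   columns family, repeat_id, graph_seed, k, noise, E_N, I_N, epsilon_N,
#'   alpha, energy_window_ms, info_duration_ms) and, when `repeats >= 2`,
#'   `summary` (mean and sd of each metric per family x k).
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  nf <- length(spec$families); nr <- spec$repeats; nk <- length(spec$k_grid)
  seeds <- .seed_table(spec$base_seed, nf * nr * (2 + 2 * nk))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  rows <- vector("list", nf * nr * nk)
  ri <- 0L
  for (family in spec$families) {
    graph <- NULL
    for (r in seq_len(nr)) {
      gseed <- next_seed()
      if (is.null(graph) || spec$new_graph_per_repeat)
        graph <- .make_graph(spec, family, gseed)
      stim <- draw_stimulus(graph$n, spec$stim_lo, spec$stim_hi, next_seed())
      for (k in spec$k_grid) {
        e_seed <- next_seed(); i_seed <- next_seed()
        res <- .run_condition(graph, stim, k, spec, e_seed, i_seed)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          family = family, repeat_id = r, graph_seed = gseed, k = k,
          noise = spec$noise$enabled, E_N = res$E_N, I_N = res$I_N,
          epsilon_N = res$epsilon_N, alpha = res$alpha,
          energy_window_ms = spec$energy_window,
          info_duration_ms = spec$info_duration)
        if (verbose)
          message(sprintf("%s r%d k=%.2f: E_N=%.0f I_N=%.0f eps=%.4g alpha=%.3f",
                          family, r, k, res$E_N, res$I_N, res$epsilon_N,
                          res$alpha))
      }
    }
  }
  rows <- do.call(rbind, rows[seq_len(ri)])
  out <- list(rows = rows, spec = spec)
  if (nr >= 2) {
    agg <- function(f) stats::aggregate(
      cbind(E_N, I_N, epsilon_N, alpha) ~ family + k, data = rows, FUN = f)
    mu <- agg(mean); s <- agg(sd)
    names(mu)[3:6] <- paste0(names(mu)[3:6], "_mean")
    names(s)[3:6] <- paste0(names(s)[3:6], "_sd")
    out$summary <- merge(mu, s, by = c("family", "k"))
  }
  structure(out, class = "sweep_result")
}

# One (graph, stimulus, k) condition: energy run + information run.
.run_condition <- function(graph, stim, k, spec, e_seed, i_seed) {
  etraj <- simulate_network(
    graph, hh_params(), stim, k,
    sim_settings(dt = spec$dt, duration = spec$energy_window),
    spec$noise, seed = e_seed)
  decomp <- power_decomposition(etraj)
  en <- network_energy_rate(decomp, spec$energy_window)
  alpha <- negative_energy_ratio(decomp, spec$alpha_window)$alpha
  itraj <- simulate_network(
    graph, hh_params(), stim, k,
    sim_settings(dt = spec$dt, duration = spec$info_duration,
                 record_gates = FALSE),
    spec$noise, seed = i_seed)
  raster <- detect_spikes(itraj)
  info <- network_information_rate(raster, spec$dt_bin, spec$T_ms)
  list(E_N = en$E_N, I_N = info$I_N,
       epsilon_N = if (en$E_N > 0) info$I_N / en$E_N else NA_real_,
       alpha = alpha)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d rows (%s; k in [%g, %g])\n",
              nrow(x$rows), paste(unique(x$rows$family), collapse = ", "),
              min(x$rows$k), max(x$rows$k)))
  invisible(x)
}

#' Run a bin-width sweep of the information rate
#'
#' Holds the word length at `l` characters while the bin width `dt_bin`
#' varies (window `T = l * dt_bin`), and sizes the record so each bin width
#' yields exactly `words` words (duration `words * T`). One simulation of
#' the longest required duration is run per family and truncated for the
#' shorter records, so every bin width sees the same spike train.
#'
#' @param spec A [sweep_spec()]; its `k_grid[1]` is the (single) coupling
#'   strength used (the canonical choice is k = 1.5).
#' @param dt_grid Bin widths, ms (default 1:10).
#' @param l Word length in characters (default 10).
#' @param words Words per record (default 300).
#' @return An object of class `sweep_result` whose rows have columns
#'   family, repeat_id, dt_bin, T_ms, k, I_N.
#' @export
run_bin_length_sweep <- function(spec, dt_grid = 1:10, l = 10, words = 300) {
  stopifnot(inherits(spec, "sweep_spec"))
  k <- spec$k_grid[1]
  max_dur <- words * l * max(dt_grid)
  nf <- length(spec$families); nr <- spec$repeats
  seeds <- .seed_table(spec$base_seed, nf * nr * 3)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  rows <- list()
  for (family in spec$families) {
    for (r in seq_len(nr)) {
      gseed <- next_seed()
      graph <- .make_graph(spec, family, gseed)
      stim <- draw_stimulus(graph$n, spec$stim_lo, spec$stim_hi, next_seed())
      traj <- simulate_network(
        graph, hh_params(), stim, k,
        sim_settings(dt = spec$dt, duration = max_dur, record_gates = FALSE),
        spec$noise, seed = next_seed())
      raster <- detect_spikes(traj)
      for (db in dt_grid) {
        T_ms <- l * db
        info <- network_information_rate(raster, db, T_ms,
                                         duration = words * T_ms)
        rows[[length(rows) + 1L]] <- data.frame(
          family = family, repeat_id = r, dt_bin = db, T_ms = T_ms, k = k,
          I_N = info$I_N)
      }
    }
  }
  structure(list(rows = do.call(rbind, rows), spec = spec),
            class = "sweep_result")
}

#' Write sweep results to a tidy CSV
#'
#' Prepends `#`-comment header lines recording the base seed, families and
#' package version, then the row table. [read_results()] restores the rows
#' losslessly.
#'
#' @param result A `sweep_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# neuroenergy sweep results"),
    sprintf("# package_version: %s",
            as.character(utils::packageVersion("neuroenergy"))),
    sprintf("# base_seed: %d", result$spec$base_seed),
    sprintf("# families: %s", paste(result$spec$families, collapse = ","))),
    con)
  write.csv(result$rows, con, row.names = FALSE)
  invisible(path)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param path File path.
#' @return The rows data.frame.
#' @export
read_results <- function(path) {
  read.csv(path, comment.char = "#")
}
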