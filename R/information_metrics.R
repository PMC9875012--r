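#' Binarize a spike raster into fixed-width time bins
#'
#' Each neuron's spike train becomes a 0/1 sequence: bin `b` (half-open
#' interval `[(b-1) dt_bin, b dt_bin)` ms) is 1 iff at least one spike falls
#' in it. A duration that is not a multiple of `dt_bin` is truncated to the
#' last whole bin with a warning.
#'
#' @param raster A `spike_raster` (or a list of per-neuron spike-time
#'   vectors plus `duration`).
#' @param dt_bin Bin width, ms (> 0).
#' @param duration Record length, ms; defaults to the raster's duration.
#' @return An object of class `binned_spikes`: `bits` (neurons x bins 0/1
#'   matrix), `dt_bin`, `duration`.
#' @export
binarize <- function(raster, dt_bin, duration = raster$duration) {
  stopifnot(dt_bin > 0)
  nbins <- floor(duration / dt_bin + 1e-9)
  if (abs(nbins * dt_bin - duration) > 1e-9)
    warning("duration not a multiple of dt_bin; truncating to ",
            nbins * dt_bin, " ms")
  spikes <- raster$spike_times
  bits <- matrix(0L, length(spikes), nbins)
  for (j in seq_along(spikes)) {
    b <- floor(spikes[[j]] / dt_bin) + 1L
    b <- b[b >= 1L & b <= nbins]
    bits[j, b] <- 1L
  }
  structure(list(bits = bits, dt_bin = dt_bin, duration = nbins * dt_bin),
            class = "binned_spikes")
}

#' Group binary bins into non-overlapping words
#'
#' A window of length `T_ms` tiles the binned record into words of
#' `l = T_ms / dt_bin` binary characters; a trailing partial window is
#' dropped with a warning. Words are encoded as integers (first bin =
#' most significant bit), which is lossless for `l <= 30`.
#'
#' @param binned A [binarize()] result.
#' @param T_ms Word window, ms; must be a multiple of `dt_bin` and >= it.
#' @return An object of class `word_sequence`: `words` (neurons x n_words
#'   integer matrix), `l`, `T_ms`, `n_words`.
#' @export
build_words <- function(binned, T_ms) {
  dt_bin <- binned$dt_bin
  if (T_ms < dt_bin) stop("word window T_ms must be >= dt_bin")
  l <- as.integer(round(T_ms / dt_bin))
  if (abs(l * dt_bin - T_ms) > 1e-9)
    stop("T_ms must be a multiple of dt_bin")
  if (l > 30) stop("word length l > 30 not supported")
  nbins <- ncol(binned$bits)
  n_words <- as.integer(nbins %/% l)
  if (n_words < 1) stop("record shorter than one word window")
  if (n_words * l < nbins)
    warning("trailing partial window of ", (nbins - n_words * l) * dt_bin,
            " ms dropped")
  weights <- 2^((l - 1):0)
  words <- matrix(0, nrow(binned$bits), n_words)
  for (j in seq_len(nrow(binned$bits))) {
    blk <- matrix(binned$bits[j, seq_len(n_words * l)], nrow = l)
    words[j, ] <- as.vector(weights %*% blk)
  }
  structure(list(words = words, l = l, T_ms = T_ms, n_words = n_words),
            class = "word_sequence")
}

#' Entropy rate of a word sequence
#'
#' Plug-in (maximum-likelihood) Shannon entropy of the empirical word
#' distribution, divided by the window length in seconds:
#' `H_T = -(1/T) sum_w p(w) log2 p(w)` in bits/s. Bounded by `l / T`.
#' No bias correction is applied; with few words relative to the `2^l`
#' possible symbols the estimate is biased downward.
#'
#' @param words Integer vector of word codes for one neuron (order is
#'   irrelevant: only counts matter).
#' @param T_ms Word window, ms.
#' @return Entropy rate, bits per second.
#' @export
entropy_rate <- function(words, T_ms) {
  if (length(words) == 0) stop("empty word sequence")
  p <- tabulate(match(words, unique(words)))
  p <- p / sum(p)
  H_bits <- -sum(p * log2(p))
  H_bits / (T_ms / 1000)
}

#' Network information rate
#'
#' Bins a raster (width `dt_bin`), tiles it into words (window `T_ms`) and
#' sums the per-neuron entropy rates: the information transmitted by the
#' network per second, `I_N` (bits/s).
#'
#' @param raster A `spike_raster`.
#' @param dt_bin Bin width, ms.
#' @param T_ms Word window, ms.
#' @param duration Record length, ms (default: the raster's duration).
#' @return List: `I_N` (bits/s), `per_neuron` (bits/s each), `l`, `n_words`.
#' @export
network_information_rate <- function(raster, dt_bin = 3, T_ms = 30,
                                     duration = raster$duration) {
  bw <- build_words(binarize(raster, dt_bin, duration), T_ms)
  per <- apply(bw$words, 1, entropy_rate, T_ms = T_ms)
  list(I_N = sum(per), per_neuron = per, l = bw$l, n_words = bw$n_words)
}

#' Energy efficiency of a network
#'
#' `epsilon_N = I_N / E_N`: bits transmitted per nJ consumed.
#'
#' @param I_N Network information rate, bits/s.
#' @param E_N Network energy consumption rate, nJ/s (must be positive).
#' @return List of class `efficiency_result`: `I_N`, `E_N`, `epsilon_N`.
#' @export
energy_efficiency <- function(I_N, E_N) {
  if (E_N <= 0) stop("efficiency undefined: E_N must be positive")
  structure(list(I_N = I_N, E_N = E_N, epsilon_N = I_N / E_N),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("efficiency: I_N = %.1f bits/s, E_N = %.1f nJ/s, epsilon_N = %.4g bits/nJ\n",
              x$I_N, x$E_N, x$epsilon_N))
  invisible(x)
}
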