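# AWGN and multi-node interference channel models.

#' Additive white Gaussian noise channel
#'
#' Adds i.i.d. Gaussian noise with per-dimension variance
#' `signal_power / SNR_linear`, where `SNR_linear = 10^(snr_db / 10)`. For an
#' integer superposition of `V` bipolar vectors the per-dimension signal
#' power is `V`; for a single bipolar vector it is 1.
#'
#' @param x Transmitted vector.
#' @param snr_db Signal-to-noise ratio in dB; `Inf` returns `x` unchanged.
#' @param signal_power Per-dimension signal power (> 0).
#' @param seed Optional seed for the noise realization; `NULL` uses the
#'   ambient RNG.
#' @return The received vector `y = x + n`.
#' @export
awgn <- function(x, snr_db, signal_power = 1, seed = NULL) {
  if (signal_power <= 0) stop("`signal_power` must be > 0")
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  sd_n <- sqrt(signal_power / 10^(snr_db / 10))
  x + with_seed_or_not(seed, stats::rnorm(length(x), sd = sd_n))
}

#' Energy per information bit over noise floor
#'
#' `Eb/N0 = SNR / (2 r)` in the linear domain, returned in dB.
#'
#' @param snr_db SNR in dB.
#' @param r Code throughput in bits per channel use (> 0).
#' @return `Eb/N0` in dB.
#' @export
ebn0_from_snr <- function(snr_db, r) {
  if (r <= 0) stop("throughput `r` must be > 0")
  snr_db - 10 * log10(2 * r)
}

#' Symbol-synchronous interference from unrelated transmitting nodes
#'
#' Superposes `n_interferers` equal-power bipolar vectors, each produced by
#' an independent node with its own random codebook, onto the transmitted
#' vector. By default each interfering node contributes a fresh random
#' bipolar vector (statistically identical to an unrelated node's encoded
#' output); pass `encoder` to generate interferers through a specific
#' encoding pipeline.
#'
#' @param x Transmitted bipolar vector.
#' @param n_interferers Number of interfering nodes J (>= 0).
#' @param encoder Optional `function(seed)` returning one interfering node's
#'   bipolar vector of the same dimension.
#' @param seed Seed controlling the interferer realizations.
#' @return `y = x + sum_j x_j`.
#' @export
add_interference <- function(x, n_interferers, encoder = NULL, seed = 0L) {
  if (n_interferers < 0) stop("`n_interferers` must be >= 0")
  if (n_interferers == 0) return(x)
  y <- x
  for (j in seq_len(n_interferers)) {
    node_seed <- derive_seed(seed, paste0("interferer-", j))
    xj <- if (is.null(encoder)) {
      random_bipolar(length(x), seed = node_seed)
    } else {
      encoder(node_seed)
    }
    if (length(xj) != length(x)) stop("interferer dimension mismatch")
    y <- y + xj
  }
  y
}
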