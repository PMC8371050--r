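# Simulation harnesses: BER/iteration sweeps over SNR, retrieval/capacity
# sweeps over (N, V), classification robustness grids over (SNR, J), and
# reconstruction grids over (D, SNR). Every record carries the full
# parameter set that produced it, so any row can be re-run bit-identically.

wilson_half_width <- function(p_hat, n, z = 1.96) {
  denom <- 1 + z^2 / n
  z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
}

#' Bit-error-rate sweep over an SNR grid
#'
#' For each SNR point, encodes `n_blocks` random bit-strings, transmits them
#' through the AWGN channel with per-dimension noise variance `V / SNR`, and
#' decodes with the configured feedback decoder, recording the bit error
#' rate, mean decoder iterations, and a 95% Wilson half-width on the BER.
#'
#' @param config A [code_config()].
#' @param dconfig A [decoder_config()].
#' @param snr_grid SNR points in dB.
#' @param n_blocks Codewords per SNR point.
#' @param seed Master seed.
#' @return A data.frame, one row per SNR point.
#' @export
run_ber_sweep <- function(config, dconfig = decoder_config("unit"),
                          snr_grid, n_blocks = 1000L, seed = 0L) {
  cb <- hdm_codebook(config)
  cache <- am_cache(cb$im)
  V <- config$n_superposed
  k <- config$total_bits
  r <- hdm_throughput(config)
  out <- lapply(snr_grid, function(snr_db) {
    bit_errors <- 0L
    iters <- numeric(n_blocks)
    block_seed <- derive_seed(seed, paste0("snr", snr_db))
    withr::with_seed(block_seed, {
      for (b in seq_len(n_blocks)) {
        u <- sample(0:1, k, replace = TRUE)
        x <- hdm_encode(u, cb$im, cb$perms, config)
        y <- awgn(x, snr_db, signal_power = V)
        dec <- hdm_decode(y, cb$im, cb$perms, config, dconfig, cache = cache)
        bit_errors <- bit_errors + sum(dec$bits != u)
        iters[b] <- dec$iterations
      }
    })
    ber <- bit_errors / (n_blocks * k)
    data.frame(snr_db = snr_db, ebn0_db = ebn0_from_snr(snr_db, r),
               dim = config$dim, im_size = config$im_size, n_superposed = V,
               feedback = dconfig$feedback, n_blocks = n_blocks,
               bit_errors = bit_errors, ber = ber,
               ber_ci_half_width = wilson_half_width(ber, n_blocks * k),
               mean_iterations = mean(iters), seed = seed)
  })
  do.call(rbind, out)
}

#' Retrieval accuracy and capacity sweep over (N, V)
#'
#' At fixed dimension, for every item-memory size and superposition count in
#' the grids, measures the probability of correct position retrieval from
#' noise-free symbol superpositions (no sign/rotation encoding) and converts
#' it to operational capacity. Readouts: standard AM or trained MMSE;
#' optional unit/soft feedback.
#'
#' @param dim Dimension D.
#' @param n_grid Item-memory sizes to test.
#' @param v_grid Superposition counts to test.
#' @param readout `"am"` or `"mmse"`.
#' @param feedback `"none"`, `"unit"` or `"soft"`.
#' @param trials Test superpositions per grid point.
#' @param train_samples MMSE training-set size (default `20 * dim`).
#' @param seed Master seed.
#' @return A data.frame with columns `readout, feedback, N, V, accuracy,
#'   capacity_bits_per_dim, trials, seed`.
#' @export
run_retrieval_sweep <- function(dim, n_grid, v_grid,
                                readout = c("am", "mmse"),
                                feedback = c("none", "unit", "soft"),
                                trials = 200L, train_samples = NULL,
                                seed = 0L) {
  readout <- match.arg(readout)
  feedback <- match.arg(feedback)
  if (is.null(train_samples)) train_samples <- 20L * dim
  out <- list()
  for (N in n_grid) {
    im <- item_memory(N, dim, seed = derive_seed(seed, paste0("im", N)))
    for (V in v_grid) {
      perms <- permutation_set(V, dim,
                               seed = derive_seed(seed, paste0("p", N, "_", V)))
      ro <- NULL
      if (readout == "mmse") {
        tr <- superpose_symbols(train_samples, im, perms, V,
                                seed = derive_seed(seed,
                                                   paste0("tr", N, "_", V)))
        ro <- train_mmse(tr$x, tr$symbols, n_items = N)
      }
      te <- superpose_symbols(trials, im, perms, V,
                              seed = derive_seed(seed,
                                                 paste0("te", N, "_", V)))
      res <- decode_iterative(te$x, im, perms, V, readout = ro,
                              feedback = feedback, truth = te$symbols)
      out[[length(out) + 1]] <- data.frame(
        readout = readout, feedback = feedback, dim = dim, N = N, V = V,
        accuracy = res$accuracy, capacity_bits_per_dim = res$capacity,
        trials = trials, seed = seed)
    }
  }
  do.call(rbind, out)
}

# Largest V (within [1, v_max]) at which retrieval accuracy is exactly 1,
# located by a monotone bisection over the accuracy corner, then confirmed
# by stepping. Used by the capacity studies.
find_retrieval_corner <- function(dim, N, readout = c("am", "mmse"),
                                  feedback = c("none", "unit", "soft"),
                                  trials = 200L, v_max = 300L,
                                  train_samples = NULL, seed = 0L) {
  readout <- match.arg(readout)
  feedback <- match.arg(feedback)
  acc_at <- function(V) {
    run_retrieval_sweep(dim, N, V, readout, feedback, trials,
                        train_samples, seed)$accuracy
  }
  lo <- 1L
  hi <- as.integer(v_max)
  if (acc_at(hi) == 1) return(hi)
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (acc_at(mid) == 1) lo <- mid else hi <- mid
  }
  lo
}

#' Classification robustness grid over SNR and interferer counts
#'
#' Evaluates a trained near-channel classifier on a test stream for every
#' (SNR, number of interfering nodes) cell, recording the accuracy and a
#' 95% Wilson half-width.
#'
#' @param model A trained [ncc_model()].
#' @param features,labels,trials Test stream.
#' @param snr_grid SNR points in dB (may include `Inf`).
#' @param interferer_grid Interferer counts (default 0).
#' @param bipolarize_query Sign-threshold queries before the AM search.
#' @param seed Master seed.
#' @return A data.frame, one row per cell.
#' @export
run_ncc_grid <- function(model, features, labels, trials = NULL,
                         snr_grid = Inf, interferer_grid = 0L,
                         bipolarize_query = FALSE, seed = 0L) {
  out <- list()
  for (J in interferer_grid) {
    for (snr_db in snr_grid) {
      pred <- ncc_predict(model, features, trials, snr_db = snr_db,
                          n_interferers = J,
                          bipolarize_query = bipolarize_query,
                          seed = derive_seed(seed,
                                             paste0("cell", snr_db, "_", J)))
      truth <- as.character(labels)[pred$frame]
      acc <- mean(pred$predicted == truth)
      out[[length(out) + 1]] <- data.frame(
        dim = model$dim, snr_db = snr_db, n_interferers = J,
        bipolarize_query = bipolarize_query,
        n_decisions = length(truth), accuracy = acc,
        ci_half_width = wilson_half_width(acc, length(truth)), seed = seed)
    }
  }
  do.call(rbind, out)
}

#' Feature-reconstruction grid over dimension and SNR
#'
#' Spatially encodes a feature stream at each dimension, transmits the
#' integer superpositions through AWGN (per-dimension signal power equal to
#' the channel count), reconstructs with each requested feedback mode, and
#' records the reconstruction MSE in dB against the original features.
#'
#' @param features `T x n_channels` feature matrix in `[0, 1]`.
#' @param d_grid Dimensions to test.
#' @param snr_grid SNR points in dB (may include `Inf`).
#' @param feedback_modes Subset of `c("none", "unit", "soft")`.
#' @param n_levels Quantization levels (default 128).
#' @param seed Master seed.
#' @return A data.frame, one row per (D, SNR, feedback) cell.
#' @export
run_reconstruction_grid <- function(features, d_grid, snr_grid,
                                    feedback_modes = c("none", "soft"),
                                    n_levels = 128L, seed = 0L) {
  nch <- ncol(features)
  out <- list()
  for (D in d_grid) {
    cim <- continuous_item_memory(n_levels, D,
                                  seed = derive_seed(seed, paste0("cim", D)))
    lev <- t(quantize_features(features, n_levels))
    X <- spatial_encode_stream(lev, cim)
    for (snr_db in snr_grid) {
      Y <- if (is.infinite(snr_db)) X else {
        noise_seed <- derive_seed(seed, paste0("n", D, "_", snr_db))
        X + with_seed_or_not(noise_seed,
                             matrix(stats::rnorm(length(X),
                                                 sd = sqrt(nch / 10^(snr_db / 10))),
                                    nrow = D))
      }
      for (fb in feedback_modes) {
        rec <- reconstruct_features(Y, cim, decoder_config(fb),
                                    n_channels = nch)
        out[[length(out) + 1]] <- data.frame(
          dim = D, snr_db = snr_db, feedback = fb,
          n_frames = ncol(X),
          mse_db = mse_db(rec, features), seed = seed)
      }
    }
  }
  do.call(rbind, out)
}
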