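# Hybrid near-channel pipeline for 64-channel surface EMG: band-limited
# feature extraction, level quantization, spatial encoding through a
# continuous item memory with per-channel cyclic rotations, temporal n-gram
# binding, prototype-based gesture classification of the received vector,
# and feature reconstruction through the iterative feedback decoder.

#' Near-channel classification model configuration
#'
#' Assembles the shared encoder state: the continuous item memory (level
#' dictionary), the fixed random permutations used by the temporal n-gram,
#' and the deterministic tie-breaker used wherever an integer vector is
#' bipolarized. Classification and transmission modes share this one spatial
#' encoder.
#'
#' @param dim Vector dimension D.
#' @param seed Master seed.
#' @param n_levels Quantization levels L (default 128).
#' @param n_channels Number of electrode channels (default 64).
#' @param ngram_size Temporal n-gram length (default 5 frames = 500 ms at
#'   10 frames/s).
#' @return An object of class `ncc_model`; prototypes are added by
#'   [ncc_train()].
#' @export
ncc_model <- function(dim, seed = 0L, n_levels = 128L, n_channels = 64L,
                      ngram_size = 5L) {
  stopifnot(ngram_size >= 1, n_channels >= 1)
  cim <- continuous_item_memory(n_levels, dim,
                                seed = derive_seed(seed, "cim"))
  perms <- if (ngram_size > 1) {
    permutation_set(ngram_size - 1L, dim,
                    seed = derive_seed(seed, "ngram"))
  } else NULL
  structure(list(dim = as.integer(dim), n_levels = as.integer(n_levels),
                 n_channels = as.integer(n_channels),
                 ngram_size = as.integer(ngram_size),
                 seed = seed, cim = cim, ngram_perms = perms,
                 tie_breaker = random_bipolar(dim,
                                              seed = derive_seed(seed, "tie")),
                 prototypes = NULL),
            class = "ncc_model")
}

#' @export
print.ncc_model <- function(x, ...) {
  cat(sprintf(
    "<ncc_model> D = %d, L = %d levels, %d channels, %d-gram%s\n",
    x$dim, x$n_levels, x$n_channels, x$ngram_size,
    if (is.null(x$prototypes)) " (untrained)" else
      sprintf(", %d classes", ncol(x$prototypes$prototypes))))
  invisible(x)
}

# ---- preprocessing ---------------------------------------------------------

# 60 Hz biquad notch (audio-EQ-cookbook coefficients) at Q = 50.
notch_coefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  list(b = c(1, -2 * cos(w0), 1) / (1 + alpha),
       a = c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha)))
}

emg_filter_chain <- function(raw, fs = 1000, decimate = 100L) {
  if (!is.matrix(raw)) raw <- matrix(raw, ncol = 1)
  nc <- notch_coefficients(60, fs, 50)
  bp <- signal::butter(4, c(1, 200) / (fs / 2), type = "pass")
  taps <- decimate
  out <- apply(raw, 2, function(x) {
    x <- signal::filter(signal::Arma(b = nc$b, a = nc$a), x)
    x <- signal::filter(bp, x)
    x <- abs(x)
    x <- stats::filter(x, rep(1 / taps, taps), sides = 1)
    x[is.na(x)] <- 0
    x[seq(decimate, length(x), by = decimate)]
  })
  if (!is.matrix(out)) out <- matrix(out, ncol = ncol(raw))
  out
}

#' Per-channel reference quantiles for feature normalization
#'
#' Runs the filter chain on training-set raw data and returns the per-channel
#' 95% quantile of the unnormalized envelope features; these are the fixed
#' normalizers used by [preprocess_emg()] so that normalized features lie in
#' `[0, 1]` with 95% probability on the training set.
#'
#' @param raw `T x n_channels` matrix of raw EMG at `fs` samples/s.
#' @param fs Sampling rate (default 1000).
#' @param prob Quantile level (default 0.95).
#' @return Numeric vector of per-channel quantiles.
#' @export
emg_reference_quantiles <- function(raw, fs = 1000, prob = 0.95) {
  feats <- emg_filter_chain(raw, fs)
  apply(feats, 2, stats::quantile, probs = prob, names = FALSE)
}

#' Preprocess raw multichannel EMG into feature frames
#'
#' Each channel passes through a 60 Hz notch filter (Q = 50), an 8th-order
#' Butterworth band-pass (1-200 Hz), rectification, a 100-tap moving
#' average, and 100x decimation, yielding ten frames per second; frames are
#' then divided by the stored per-channel training-set quantiles.
#'
#' @param raw `T x n_channels` matrix of raw EMG at `fs` samples/s.
#' @param quantiles Per-channel normalizers from [emg_reference_quantiles()];
#'   required.
#' @param fs Sampling rate (default 1000 samples/s).
#' @return `n_frames x n_channels` matrix of features, nominally in
#'   `[0, 1]`.
#' @export
preprocess_emg <- function(raw, quantiles, fs = 1000) {
  if (missing(quantiles) || is.null(quantiles)) {
    stop("per-channel normalization quantiles are required; ",
         "compute them on training data with emg_reference_quantiles()")
  }
  if (!is.matrix(raw)) raw <- matrix(raw, ncol = 1)
  if (length(quantiles) != ncol(raw)) stop("one quantile per channel needed")
  feats <- emg_filter_chain(raw, fs)
  sweep(feats, 2, pmax(quantiles, .Machine$double.eps), "/")
}

# ---- encoding --------------------------------------------------------------

#' Quantize feature values to discrete levels
#'
#' Uniform quantizer on `[0, 1]`: `level = clamp(floor(f * L) + 1, 1, L)`.
#' Values below 0 map to level 1 and above 1 to level L (the 95%-quantile
#' normalization leaves ~5% overshoot, which is clamped here).
#'
#' @param f Numeric vector/matrix of features.
#' @param L Number of levels (>= 2), default 128.
#' @return Integer levels in `[1, L]`, same shape as `f`.
#' @export
quantize_features <- function(f, L = 128L) {
  stopifnot(L >= 2)
  lev <- floor(f * L) + 1
  lev <- pmin(pmax(lev, 1), L)
  out <- as.integer(lev)
  if (is.matrix(f)) dim(out) <- dim(f)
  out
}

# Linear gather index such that column ch of the result is the level vector
# of channel ch rotated by (ch - 1) positions.
spatial_rot_index <- function(D, n_channels) {
  i <- seq_len(D) - 1L
  idx <- matrix(0L, nrow = D, ncol = n_channels)
  for (ch in seq_len(n_channels)) {
    idx[, ch] <- (ch - 1L) * D + ((i - (ch - 1L)) %% D) + 1L
  }
  idx
}

#' Spatially encode one quantized frame
#'
#' Maps each channel's level to its continuous-item-memory vector, rotates
#' it cyclically by the 0-based channel index, and superposes:
#' `x = sum_ch rotate(cim[level_ch], ch)`.
#'
#' @param levels Integer vector of per-channel levels in `[1, L]`.
#' @param cim A [continuous_item_memory()].
#' @return Integer-valued superposition of length `D`.
#' @export
spatial_encode <- function(levels, cim) {
  nch <- length(levels)
  M <- cim$levels[, levels, drop = FALSE]
  idx <- spatial_rot_index(cim$dim, nch)
  rowSums(matrix(M[idx], nrow = cim$dim))
}

# Batched spatial encoding: levels is n_channels x T; returns D x T.
spatial_encode_stream <- function(levels, cim) {
  D <- cim$dim
  nch <- nrow(levels)
  Tn <- ncol(levels)
  X <- matrix(0, nrow = D, ncol = Tn)
  i <- seq_len(D) - 1L
  for (ch in seq_len(nch)) {
    rot <- ((i - (ch - 1L)) %% D) + 1L
    X <- X + cim$levels[, levels[ch, ], drop = FALSE][rot, , drop = FALSE]
  }
  X
}

#' Temporally encode consecutive frames as an n-gram
#'
#' Bipolarizes each spatial superposition, applies the identity to the newest
#' frame and a distinct fixed random permutation to each older frame, and
#' binds all by element-wise multiplication. The result is always bipolar.
#'
#' @param frames List of `ngram_size` spatial superpositions ordered oldest
#'   to newest.
#' @param model An [ncc_model()] supplying the permutations and tie-breaker.
#' @return Bipolar vector of dimension `D`.
#' @export
temporal_encode <- function(frames, model) {
  n <- model$ngram_size
  if (length(frames) != n) {
    stop(sprintf("expected %d frames, got %d", n, length(frames)))
  }
  out <- hv_bipolarize(frames[[n]], model$tie_breaker) # newest, unpermuted
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      # frame n-k is k steps in the past -> permutation k
      b <- hv_bipolarize(frames[[n - k]], model$tie_breaker)
      out <- out * hv_permute(b, model$ngram_perms, k)
    }
  }
  out
}

# N-gram encodings for every frame of a stream that has a full n-gram of
# history within its own trial. `spatial` is D x T; `trials` an integer
# vector of trial ids per frame (NULL = one continuous trial).
# Returns list(encoded = D x M, frame = emitted frame indices).
ngram_stream <- function(spatial, model, trials = NULL) {
  D <- nrow(spatial)
  Tn <- ncol(spatial)
  n <- model$ngram_size
  if (is.null(trials)) trials <- rep(1L, Tn)
  B <- sign(spatial)
  zero <- B == 0
  if (any(zero)) B[zero] <- matrix(model$tie_breaker,
                                   nrow = D, ncol = Tn)[zero]
  # pre-permuted past frames: P[[k]] = perm_k(B) column-wise
  out_frames <- which(vapply(seq_len(Tn), function(t) {
    t >= n && all(trials[(t - n + 1):t] == trials[t])
  }, logical(1)))
  if (length(out_frames) == 0) {
    return(list(encoded = matrix(0, D, 0), frame = integer(0)))
  }
  enc <- B[, out_frames, drop = FALSE]
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      past <- B[model$ngram_perms$forward[, k], out_frames - k, drop = FALSE]
      enc <- enc * past
    }
  }
  list(encoded = enc, frame = out_frames)
}

# ---- classification --------------------------------------------------------

#' Train per-class prototypes from encoded vectors
#'
#' Accumulates all encoded training vectors of each class element-wise and
#' bipolarizes the sums with the model tie-breaker.
#'
#' @param encoded `D x M` matrix of bipolar n-gram encodings (or list of
#'   vectors).
#' @param labels Class label per encoding (character or factor).
#' @param tie_breaker Bipolar tie-breaking vector.
#' @return An object of class `class_prototypes`: list with `prototypes`
#'   (`D x K` bipolar matrix, columns named by class) and `classes`.
#' @export
train_prototypes <- function(encoded, labels, tie_breaker) {
  if (is.list(encoded)) encoded <- do.call(cbind, encoded)
  labels <- as.character(labels)
  if (length(labels) != ncol(encoded)) stop("one label per encoding needed")
  classes <- unique(labels)
  if (any(table(labels) < 1)) stop("every class needs at least one sample")
  P <- vapply(classes, function(cl) {
    hv_bipolarize(rowSums(encoded[, labels == cl, drop = FALSE]),
                  tie_breaker)
  }, numeric(nrow(encoded)))
  structure(list(prototypes = P, classes = classes),
            class = "class_prototypes")
}

#' Classify received vectors against the class prototypes
#'
#' Picks the class whose prototype has the highest cosine similarity to the
#' query; with `bipolarize_query = TRUE` the query is sign-thresholded first,
#' making the search equivalent to a Hamming-distance comparison. Ties go to
#' the smallest class index.
#'
#' @param y Query vector, or `D x T` matrix of queries.
#' @param prototypes A [train_prototypes()] object.
#' @param bipolarize_query Sign-threshold queries before the search.
#' @param tie_breaker Tie-breaker used when bipolarizing (defaults to +1 at
#'   exact zeros).
#' @return Character vector of predicted class labels.
#' @export
ncc_classify <- function(y, prototypes, bipolarize_query = FALSE,
                         tie_breaker = NULL) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  if (nrow(y) != nrow(prototypes$prototypes)) stop("dimension mismatch")
  if (bipolarize_query) {
    tb <- if (is.null(tie_breaker)) rep(1, nrow(y)) else tie_breaker
    y <- apply(y, 2, hv_bipolarize, tie_breaker = tb)
    if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  }
  # cosine ranking: prototype norms are equal (bipolar), so normalize queries
  scores <- crossprod(prototypes$prototypes, y) # K x T
  norms <- sqrt(colSums(y^2))
  norms[norms == 0] <- 1
  scores <- sweep(scores, 2, norms, "/")
  prototypes$classes[max.col(t(scores), ties.method = "first")]
}

#' Train the near-channel classifier on a feature stream
#'
#' Quantizes and spatially encodes every frame, forms n-grams within trials,
#' and learns one bipolar prototype per class.
#'
#' @param features `T x n_channels` feature matrix in `[0, 1]`.
#' @param labels Class label per frame.
#' @param model An [ncc_model()].
#' @param trials Optional trial id per frame; n-grams never span trials.
#' @return The model with `prototypes` filled in.
#' @export
ncc_train <- function(features, labels, model, trials = NULL) {
  lev <- t(quantize_features(features, model$n_levels)) # channels x T
  spatial <- spatial_encode_stream(lev, model$cim)
  ng <- ngram_stream(spatial, model, trials)
  model$prototypes <- train_prototypes(ng$encoded,
                                       as.character(labels)[ng$frame],
                                       model$tie_breaker)
  model
}

#' Classify a feature stream with a trained model, optionally over a channel
#'
#' Encodes the stream exactly as [ncc_train()], transmits each n-gram over
#' an optional AWGN / interference channel, and classifies the received
#' vectors. One decision is made per frame that has full n-gram history
#' within its trial.
#'
#' @param model Trained [ncc_model()].
#' @param features,trials Test stream (same conventions as [ncc_train()]).
#' @param snr_db Channel SNR in dB (`Inf` = noise-free). The transmitted
#'   n-gram is bipolar, so the per-dimension signal power is 1.
#' @param n_interferers Number of interfering nodes (see
#'   [add_interference()]).
#' @param bipolarize_query Sign-threshold received vectors before the AM
#'   search.
#' @param seed Seed for channel noise and interferers.
#' @return List with `predicted` (labels), `frame` (frame indices of the
#'   decisions).
#' @export
ncc_predict <- function(model, features, trials = NULL, snr_db = Inf,
                        n_interferers = 0, bipolarize_query = FALSE,
                        seed = 0L) {
  if (is.null(model$prototypes)) stop("model has no trained prototypes")
  lev <- t(quantize_features(features, model$n_levels))
  spatial <- spatial_encode_stream(lev, model$cim)
  ng <- ngram_stream(spatial, model, trials)
  Y <- ng$encoded
  if (n_interferers > 0) {
    for (t in seq_len(ncol(Y))) {
      Y[, t] <- add_interference(Y[, t], n_interferers,
                                 seed = derive_seed(seed,
                                                    paste0("intf-", t)))
    }
  }
  if (is.finite(snr_db)) {
    Y <- Y + with_seed_or_not(derive_seed(seed, "awgn"),
                              matrix(stats::rnorm(length(Y),
                                                  sd = sqrt(10^(-snr_db / 10))),
                                     nrow = nrow(Y)))
  }
  list(predicted = ncc_classify(Y, model$prototypes, bipolarize_query,
                                model$tie_breaker),
       frame = ng$frame)
}

# ---- reconstruction --------------------------------------------------------

#' Reconstruct quantized features from a received spatial superposition
#'
#' For every channel, searches the rotation-aligned received vector against
#' the L levels of the continuous item memory (no rotation or sign search),
#' then iterates interference-cancelling feedback across channels exactly as
#' the codec decoder does across blocks: unit feedback subtracts the other
#' channels' re-encoded level estimates at full scale, soft feedback scales
#' each by its confidence clipped to one. Estimated levels map back to bin
#' centers `(l - 0.5) / L`.
#'
#' @param y Received vector of dimension `D` (a possibly noisy spatial
#'   superposition), or a `D x T` matrix of frames.
#' @param cim The [continuous_item_memory()] used by the encoder.
#' @param dconfig A [decoder_config()]; only `feedback` and `max_iterations`
#'   are used.
#' @param n_channels Number of channels encoded in `y` (default 64).
#' @return Matrix `T x n_channels` of reconstructed feature values in
#'   `(0, 1)` (a vector input returns a 1-row matrix).
#' @export
reconstruct_features <- function(y, cim, dconfig = decoder_config("soft"),
                                 n_channels = 64L) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1)
  D <- cim$dim
  L <- cim$n_levels
  Tn <- ncol(y)
  nch <- as.integer(n_channels)
  i0 <- seq_len(D) - 1L
  # rotation index per channel: align channel ch by rotating y by -(ch-1)
  unrot <- lapply(seq_len(nch), function(ch) ((i0 + (ch - 1L)) %% D) + 1L)
  rot <- lapply(seq_len(nch), function(ch) ((i0 - (ch - 1L)) %% D) + 1L)

  lev_hat <- matrix(1L, nrow = nch, ncol = Tn)
  scales <- matrix(0, nrow = nch, ncol = Tn)
  S <- matrix(0, nrow = D, ncol = Tn)
  max_iter <- if (dconfig$feedback == "none") 1L else dconfig$max_iterations
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    lev_new <- lev_hat
    for (ch in seq_len(nch)) {
      fb_ch <- if (iter == 1L) 0 else
        cim$levels[, lev_hat[ch, ], drop = FALSE][rot[[ch]], , drop = FALSE] *
          rep(scales[ch, ], each = D)
      Ych <- y - S + fb_ch
      W <- Ych[unrot[[ch]], , drop = FALSE]
      scores <- crossprod(cim$levels, W) / D # L x T
      lh <- max.col(t(scores), ties.method = "first")
      lev_new[ch, ] <- lh
      conf <- abs(scores[cbind(lh, seq_len(Tn))])
      scales[ch, ] <- switch(dconfig$feedback,
                             none = 0, unit = 1, soft = pmin(conf, 1))
    }
    if (dconfig$feedback != "none") {
      S <- matrix(0, nrow = D, ncol = Tn)
      for (ch in seq_len(nch)) {
        S <- S + cim$levels[, lev_new[ch, ], drop = FALSE][rot[[ch]], ,
                                                           drop = FALSE] *
          rep(scales[ch, ], each = D)
      }
    }
    if (!is.null(prev) && identical(lev_new, prev)) {
      lev_hat <- lev_new
      break
    }
    prev <- lev_new
    lev_hat <- lev_new
  }
  t((lev_hat - 0.5) / L)
}

#' Throughput of the EMG spatiotemporal encoding
#'
#' `r = (64 channels * 7 bits * 5 gram) / D = 2240 / D` bits per channel
#' use; values above 1 mean the encoding compresses.
#'
#' @param D Vector dimension (> 0).
#' @return Throughput in bits per channel use.
#' @export
emg_throughput <- function(D) {
  if (any(D <= 0)) stop("`D` must be positive")
  64 * 7 * 5 / D
}

#' Mean-squared error between feature streams, in dB
#'
#' `10 * log10(mean((reconstructed - original)^2))` over all channels and
#' frames; identical inputs return `-Inf`.
#'
#' @param reconstructed,original Equal-shape feature matrices.
#' @return MSE in dB.
#' @export
mse_db <- function(reconstructed, original) {
  if (length(reconstructed) == 0) stop("empty input")
  if (!all(dim(as.matrix(reconstructed)) == dim(as.matrix(original)))) {
    stop("shape mismatch")
  }
  mse <- mean((reconstructed - original)^2)
  if (mse == 0) -Inf else 10 * log10(mse)
}
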