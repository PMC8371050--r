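# Integer hyperdimensional modulation: bit-strings are split into blocks,
# each block is mapped to (dictionary index q, cyclic-shift index r, sign s),
# materialized as a signed rotated dictionary entry, permuted with a
# block-specific random permutation, and superposed. Decoding is an iterative
# associative-memory search with interference-cancelling feedback.

#' Integer-HDM code configuration
#'
#' Fixes the code geometry: dimension `D`, item-memory size `N` (both powers
#' of two) and the number of superposed blocks `V`. Each block carries
#' `log2(N)` dictionary bits, `log2(D)` rotation bits and 1 sign bit, so the
#' codeword carries `k = V * (log2(N) + log2(D) + 1)` information bits in `D`
#' channel uses.
#'
#' @param dim Vector dimension D (power of two).
#' @param im_size Item-memory size N (power of two).
#' @param n_superposed Number of superposed blocks V (>= 1).
#' @param seed Master seed for the dictionary, permutations and tie-breaker.
#' @return An object of class `code_config` with derived fields `k_q`, `k_r`,
#'   `k_s`, `block_bits` and `total_bits`.
#' @export
code_config <- function(dim, im_size, n_superposed, seed = 0L) {
  is_pow2 <- function(n) n >= 1 && abs(log2(n) - round(log2(n))) < 1e-9
  if (!is_pow2(dim)) stop("`dim` must be a power of two")
  if (!is_pow2(im_size)) stop("`im_size` must be a power of two")
  if (n_superposed < 1) stop("`n_superposed` must be >= 1")
  k_q <- as.integer(round(log2(im_size)))
  k_r <- as.integer(round(log2(dim)))
  structure(list(dim = as.integer(dim), im_size = as.integer(im_size),
                 n_superposed = as.integer(n_superposed), seed = seed,
                 k_q = k_q, k_r = k_r, k_s = 1L,
                 block_bits = k_q + k_r + 1L,
                 total_bits = as.integer(n_superposed) * (k_q + k_r + 1L)),
            class = "code_config")
}

#' @export
print.code_config <- function(x, ...) {
  cat(sprintf(
    "<code_config> D = %d, N = %d, V = %d, k = %d bits, r = %.4f\n",
    x$dim, x$im_size, x$n_superposed, x$total_bits, hdm_throughput(x)))
  invisible(x)
}

#' Build the codebook (dictionary, permutations, tie-breaker) for a code
#'
#' All three components are derived deterministically from the configuration
#' seed via independent streams.
#'
#' @param config A [code_config()].
#' @return A list with `im` ([item_memory()]), `perms` ([permutation_set()])
#'   and `tie_breaker` (bipolar vector), of class `hdm_codebook`.
#' @export
hdm_codebook <- function(config) {
  stopifnot(inherits(config, "code_config"))
  structure(list(
    im = item_memory(config$im_size, config$dim,
                     seed = derive_seed(config$seed, "im")),
    perms = permutation_set(config$n_superposed, config$dim,
                            seed = derive_seed(config$seed, "perms")),
    tie_breaker = random_bipolar(config$dim,
                                 seed = derive_seed(config$seed, "tie")),
    config = config), class = "hdm_codebook")
}

#' Decoder configuration
#'
#' @param feedback Feedback strategy: `"unit"` subtracts each block's
#'   re-encoded estimate at full scale, `"soft"` scales it by the estimate's
#'   confidence clipped to at most one, `"none"` performs a single
#'   non-iterative estimation pass.
#' @param max_iterations Iteration cap (>= 1); decoding stops earlier when the
#'   estimated indexes of all blocks are unchanged between consecutive
#'   iterations.
#' @param readout_levels Optional odd/even integer `V'`: queries are quantized
#'   to the noise-free value grid `{-V', -V'+2, ..., V'}` before each
#'   associative-memory search.
#' @param fixed_point Optional `c(m, q)`: every decoder value (received
#'   vector, cleaned queries, feedback scales) is quantized to fixed point
#'   with `m` integer and `q` fractional bits.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(feedback = c("unit", "soft", "none"),
                           max_iterations = 10L,
                           readout_levels = NULL,
                           fixed_point = NULL) {
  feedback <- match.arg(feedback)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1")
  if (!is.null(readout_levels) && readout_levels < 1) {
    stop("`readout_levels` must be >= 1")
  }
  if (!is.null(fixed_point)) {
    stopifnot(length(fixed_point) == 2, fixed_point[1] >= 1,
              fixed_point[2] >= 0)
  }
  structure(list(feedback = feedback,
                 max_iterations = as.integer(max_iterations),
                 readout_levels = readout_levels,
                 fixed_point = fixed_point),
            class = "decoder_config")
}

# ---- bit-string helpers ----------------------------------------------------

#' Convert between bit representations
#'
#' Bit-strings are accepted either as a single character string of 0/1 or as
#' a numeric/integer vector of 0s and 1s; `as_bits()` normalizes to an
#' integer vector, `bits_to_string()` renders back to text.
#'
#' @param bits A bit-string in either representation.
#' @return `as_bits()`: integer vector of 0/1; `bits_to_string()`: character.
#' @export
as_bits <- function(bits) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1)
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  if (any(is.na(bits)) || !all(bits %in% c(0, 1))) {
    stop("bit-strings may only contain 0 and 1")
  }
  as.integer(bits)
}

#' @rdname as_bits
#' @export
bits_to_string <- function(bits) paste(as_bits(bits), collapse = "")

bits_to_int <- function(bits) {
  # MSB first
  sum(bits * 2^((length(bits) - 1):0))
}

int_to_bits <- function(n, width) {
  as.integer(rev((n %/% 2^(0:(width - 1))) %% 2))
}

# ---- bit-to-index mapping --------------------------------------------------

#' Map one block's bit-string to (dictionary, rotation, sign) indexes
#'
#' The block is sliced in the order (q | r | s); each slice is read as an
#' unsigned integer, most-significant bit first. `q` is a 0-based dictionary
#' index in `[0, N-1]`, `r` a rotation in `[0, D-1]`, and the sign bit maps
#' to `s = 2*bit - 1`.
#'
#' @param u_block Bit-string of length `block_bits`.
#' @param config A [code_config()].
#' @return A list with integer fields `q`, `r` and `s`.
#' @export
bits_to_indexes <- function(u_block, config) {
  bits <- as_bits(u_block)
  if (length(bits) != config$block_bits) {
    stop(sprintf("block must have %d bits, got %d",
                 config$block_bits, length(bits)))
  }
  kq <- config$k_q
  kr <- config$k_r
  list(q = as.integer(bits_to_int(bits[seq_len(kq)])),
       r = as.integer(bits_to_int(bits[kq + seq_len(kr)])),
       s = as.integer(2L * bits[kq + kr + 1L] - 1L))
}

#' Map (dictionary, rotation, sign) indexes back to a block bit-string
#'
#' Exact inverse of [bits_to_indexes()].
#'
#' @param idx List with fields `q`, `r`, `s`.
#' @param config A [code_config()].
#' @return Integer vector of 0/1 of length `block_bits`.
#' @export
indexes_to_bits <- function(idx, config) {
  if (idx$q < 0 || idx$q >= config$im_size) stop("`q` out of range")
  if (idx$r < 0 || idx$r >= config$dim) stop("`r` out of range")
  if (!idx$s %in% c(-1L, 1L)) stop("`s` must be -1 or +1")
  c(int_to_bits(idx$q, config$k_q),
    int_to_bits(idx$r, config$k_r),
    as.integer((idx$s + 1L) / 2L))
}

# ---- encoder ---------------------------------------------------------------

#' Encode a bit-string as an integer-valued HD superposition
#'
#' Each of the `V` blocks is mapped to indexes, materialized as
#' `s * rotate(e_q, r)` from the shared dictionary, permuted with its
#' block-specific permutation and superposed by addition:
#' `x = sum_v perm_v(s_v * rotate(e_{q_v}, r_v))`.
#'
#' @param u Bit-string of length `total_bits` (character or 0/1 vector).
#' @param im The shared [item_memory()] of size `(N, D)`.
#' @param perms A [permutation_set()] with `V` permutations, or `NULL` for
#'   identity permutations on all blocks.
#' @param config A [code_config()].
#' @return Integer-valued numeric vector of length `D`.
#' @export
hdm_encode <- function(u, im, perms, config) {
  bits <- as_bits(u)
  if (length(bits) != config$total_bits) {
    stop(sprintf("expected %d bits, got %d", config$total_bits, length(bits)))
  }
  stopifnot(im$n_items == config$im_size, im$dim == config$dim)
  V <- config$n_superposed
  bb <- config$block_bits
  x <- numeric(config$dim)
  for (v in seq_len(V)) {
    idx <- bits_to_indexes(bits[(v - 1) * bb + seq_len(bb)], config)
    xv <- idx$s * hv_rotate(im$entries[, idx$q + 1L], idx$r)
    if (!is.null(perms)) xv <- hv_permute(xv, perms, v)
    x <- x + xv
  }
  x
}

#' Code throughput in bits per channel use
#'
#' `r = V * (log2(N) + log2(D) + 1) / D`.
#'
#' @param config A [code_config()].
#' @return The throughput as an exact double.
#' @export
hdm_throughput <- function(config) {
  config$total_bits / config$dim
}

# ---- associative-memory search ---------------------------------------------

# Conjugated column-wise DFT of the dictionary; reused across searches.
am_cache <- function(im) {
  structure(list(ehat_conj = Conj(stats::mvfft(im$entries)),
                 dim = im$dim, n_items = im$n_items),
            class = "hdm_am_cache")
}

# Correlation table c[r+1, q+1] = (1/D) <rot(w, -r), e_q> for all (q, r),
# computed for several query columns W at once via circular cross-correlation
# in the frequency domain. Returns a D x (N * ncol(W)) real matrix whose
# column block v holds the table for query v.
#
# Queries are real, so each table is the real inverse transform of a
# Hermitian product; two queries ride through one complex transform, one in
# the real and one in the imaginary part.
am_correlations <- function(W, cache) {
  D <- cache$dim
  N <- cache$n_items
  nq <- ncol(W)
  Z <- matrix(0, nrow = D, ncol = N * nq)
  j <- 1L
  while (j <= nq) {
    if (j + 1L <= nq) {
      f <- stats::fft(complex(real = W[, j], imaginary = W[, j + 1L]))
      z <- stats::mvfft(cache$ehat_conj * f, inverse = TRUE)
      Z[, (j - 1L) * N + seq_len(N)] <- Re(z)
      Z[, j * N + seq_len(N)] <- Im(z)
      j <- j + 2L
    } else {
      f <- stats::fft(W[, j])
      z <- stats::mvfft(cache$ehat_conj * f, inverse = TRUE)
      Z[, (j - 1L) * N + seq_len(N)] <- Re(z)
      j <- j + 1L
    }
  }
  Z / (D * D)
}

# Argmax of |c| over the D x N table with lexicographic (q, then r) ties.
am_pick <- function(Cv, D) {
  k <- which.max(abs(Cv)) # column-major: smallest q first, then smallest r
  conf <- Cv[k]
  list(q = as.integer((k - 1) %/% D),
       r = as.integer((k - 1) %% D),
       s = if (conf >= 0) 1L else -1L,
       confidence = abs(conf))
}

#' Associative-memory search over dictionary and rotation indexes
#'
#' Computes the normalized inner products
#' `c[q, r] = (1/D) * <rotate(y_v, -r), e_q>` for all `N * D` index pairs and
#' returns the pair maximizing `|c|`, the sign of the maximizing entry, and
#' the confidence `|c|` itself. Ties are broken lexicographically (smallest
#' `q`, then smallest `r`). The query must already be inverse-permuted for
#' its block.
#'
#' The full table is evaluated through circular cross-correlation in the
#' frequency domain, which is algebraically identical to the direct scan;
#' `method = "direct"` evaluates the scan literally (useful for small
#' problems and cross-checks).
#'
#' @param y_v Query vector of dimension `D`.
#' @param im An [item_memory()].
#' @param cache Optional pre-computed [am_cache] (internal) to amortize the
#'   dictionary transform across calls.
#' @param method `"fft"` (default) or `"direct"`.
#' @return A list with `q` (0-based), `r`, `s`, `confidence`.
#' @export
am_search <- function(y_v, im, cache = NULL, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (length(y_v) != im$dim) stop("dimension mismatch")
  D <- im$dim
  if (method == "fft") {
    if (is.null(cache)) cache <- am_cache(im)
    Cv <- am_correlations(matrix(y_v, ncol = 1), cache)
  } else {
    # rows: rotations r = 0..D-1 of the query by -r; columns: dictionary
    rot <- matrix(0, nrow = D, ncol = D)
    base <- seq_len(D) - 1L
    for (r in base) rot[r + 1L, ] <- y_v[((base + r) %% D) + 1L]
    Cv <- rot %*% im$entries / D
  }
  am_pick(Cv, D)
}

# ---- decoder ---------------------------------------------------------------

#' Decode a received vector with the iterative feedback decoder
#'
#' Every iteration estimates all `V` blocks in parallel: block `v` is
#' estimated by an associative-memory search on the cleaned query
#' `y - sum_{j != v} fb_j`, where `fb_j` is the re-encoded estimate of block
#' `j` from the previous iteration (all zero initially), scaled by 1 for unit
#' feedback or by `min(|c_j|, 1)` for soft feedback. Decoding stops when all
#' estimated indexes are unchanged between consecutive iterations, or at the
#' iteration cap. A single block (`V = 1`) needs no interference cancellation
#' and terminates after one iteration.
#'
#' @param y Received vector of dimension `D`.
#' @param im,perms,config The codebook components used by [hdm_encode()].
#' @param dconfig A [decoder_config()].
#' @param cache Optional [am_cache] for the dictionary.
#' @return An object of class `hdm_decode_result`: list with `bits`
#'   (integer 0/1 vector of length `k`), `indexes` (data.frame `q`, `r`, `s`),
#'   `iterations`, `converged`, `confidences`.
#' @export
hdm_decode <- function(y, im, perms, config, dconfig = decoder_config(),
                       cache = NULL) {
  D <- config$dim
  N <- config$im_size
  V <- config$n_superposed
  if (length(y) != D) stop("dimension mismatch")
  if (is.null(cache)) cache <- am_cache(im)
  fp <- dconfig$fixed_point
  if (!is.null(fp)) y <- quantize_fixed_point(y, fp[1], fp[2])

  feedback <- matrix(0, nrow = D, ncol = V)
  xhat <- matrix(0, nrow = D, ncol = V)
  q_idx <- integer(V); r_idx <- integer(V); s_idx <- integer(V)
  confs <- numeric(V)
  prev <- NULL
  converged <- FALSE
  max_iter <- if (V == 1 || dconfig$feedback == "none") 1L else
    dconfig$max_iterations
  iterations <- 0L

  for (iter in seq_len(max_iter)) {
    iterations <- iter
    resid <- y - rowSums(feedback)
    # cleaned, inverse-permuted query for each block
    W <- matrix(0, nrow = D, ncol = V)
    for (v in seq_len(V)) {
      yv <- resid + feedback[, v]
      if (!is.null(perms)) yv <- yv[perms$inverse[, v]]
      W[, v] <- yv
    }
    if (!is.null(dconfig$readout_levels)) {
      W <- quantize_readout(W, dconfig$readout_levels)
    }
    if (!is.null(fp)) W <- quantize_fixed_point(W, fp[1], fp[2])
    picks <- am_search_batch_cpp(W, cache$ehat_conj)
    for (v in seq_len(V)) {
      q_idx[v] <- picks$q[v]; r_idx[v] <- picks$r[v]; s_idx[v] <- picks$s[v]
      confs[v] <- picks$confidence[v]
      xv <- picks$s[v] * hv_rotate(im$entries[, picks$q[v] + 1L], picks$r[v])
      if (!is.null(perms)) xv <- hv_permute(xv, perms, v)
      xhat[, v] <- xv
      scale <- switch(dconfig$feedback,
                      unit = 1,
                      soft = min(confs[v], 1),
                      none = 0)
      if (!is.null(fp)) scale <- quantize_fixed_point(scale, fp[1], fp[2])
      feedback[, v] <- scale * xv
    }
    cur <- c(q_idx, r_idx, s_idx)
    if (!is.null(prev) && identical(cur, prev)) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  if (V == 1 || dconfig$feedback == "none") converged <- TRUE

  bits <- unlist(lapply(seq_len(V), function(v) {
    indexes_to_bits(list(q = q_idx[v], r = r_idx[v], s = s_idx[v]), config)
  }))
  structure(list(bits = as.integer(bits),
                 indexes = data.frame(q = q_idx, r = r_idx, s = s_idx),
                 iterations = iterations,
                 converged = converged,
                 confidences = confs),
            class = "hdm_decode_result")
}

#' @export
print.hdm_decode_result <- function(x, ...) {
  cat(sprintf("<hdm_decode_result> %d bits, %d iteration(s), converged: %s\n",
              length(x$bits), x$iterations, x$converged))
  invisible(x)
}

# ---- quantizers ------------------------------------------------------------

#' Quantize a query to the noise-free superposition value grid
#'
#' Maps every element to the nearest value in `{-V', -V'+2, ..., V'-2, V'}`
#' (the values an exact superposition of `V'` bipolar vectors can take);
#' halfway ties go to the smaller magnitude.
#'
#' @param y Numeric vector or matrix.
#' @param v_max Grid extreme `V'` (>= 1).
#' @return The quantized object, same shape as `y`.
#' @export
quantize_readout <- function(y, v_max) {
  if (v_max < 1) stop("`v_max` must be >= 1")
  jf <- (y + v_max) / 2
  lo <- floor(jf)
  frac <- jf - lo
  j <- lo + (frac > 0.5)
  tie <- abs(frac - 0.5) < 1e-12
  if (any(tie)) {
    l_lo <- -v_max + 2 * lo[tie]
    j[tie] <- lo[tie] + (abs(l_lo + 2) < abs(l_lo))
  }
  j <- pmin(pmax(j, 0), v_max)
  out <- -v_max + 2 * j
  if (is.matrix(y)) dim(out) <- dim(y)
  out
}

#' Fixed-point quantization with m integer and q fractional bits
#'
#' Round-to-nearest on the grid of step `2^-q` with symmetric clipping to
#' `+/- (2^m - 2^-q)`; halfway ties round away from zero.
#'
#' @param x Numeric vector or matrix.
#' @param m Integer (magnitude) bits, >= 1.
#' @param q Fractional bits, >= 0.
#' @return The quantized object, same shape as `x`.
#' @export
quantize_fixed_point <- function(x, m, q) {
  if (m < 1 || q < 0) stop("need m >= 1 and q >= 0")
  step <- 2^(-q)
  lim <- 2^m - step
  out <- sign(x) * floor(abs(x) / step + 0.5) * step
  out <- pmin(pmax(out, -lim), lim)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}
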