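# Learned MMSE readout for superposition retrieval, iterative retrieval with
# dictionary feedback, and the operational-capacity statistic. In this
# setting a superposition carries V plain (unsigned, unrotated) dictionary
# entries, each under its block permutation: x = sum_v perm_v(e_{q_v}) with
# symbol indexes q_v in 1..N.

#' Generate random symbol superpositions for retrieval experiments
#'
#' @param n_samples Number of superpositions to draw.
#' @param im An [item_memory()].
#' @param perms A [permutation_set()] with at least `V` permutations, or
#'   `NULL` for identity permutations.
#' @param n_superposed Number of superposed symbols V.
#' @param seed Seed for the symbol draws.
#' @return List with `x` (`D x n_samples` matrix of superpositions) and
#'   `symbols` (`V x n_samples` matrix of 1-based dictionary indexes).
#' @export
superpose_symbols <- function(n_samples, im, perms, n_superposed, seed = 0L) {
  D <- im$dim
  N <- im$n_items
  V <- as.integer(n_superposed)
  Q <- with_seed_or_not(seed,
    matrix(sample.int(N, V * n_samples, replace = TRUE),
           nrow = V, ncol = n_samples))
  X <- matrix(0, nrow = D, ncol = n_samples)
  for (v in seq_len(V)) {
    term <- im$entries[, Q[v, ], drop = FALSE]
    if (!is.null(perms)) term <- term[perms$forward[, v], , drop = FALSE]
    X <- X + term
  }
  list(x = X, symbols = Q)
}

#' Train per-position MMSE readout matrices
#'
#' Fits, for every superposed position `v`, the matrix `F_v` minimizing the
#' mean squared error between the one-hot symbol vector `c_v` and the linear
#' readout `F_v' x` over the training pairs. Training touches only the
#' `(x, c_v)` pairs: it needs neither the dictionary nor the permutations.
#' The objective is convex, so the closed-form least-squares solution
#' (`method = "ls"`, via ridge-stabilized normal equations) and converged
#' gradient descent (`method = "gd"`) coincide.
#'
#' @param superpositions `D x R` matrix of training superpositions (or a list
#'   of length-`D` vectors).
#' @param truths `V x R` matrix of 1-based symbol indexes (or a list of
#'   length-`V` index vectors).
#' @param n_items Dictionary size N (range of the symbol indexes).
#' @param method `"ls"` (default) or `"gd"`.
#' @param ridge Ridge stabilizer added to the Gram diagonal, as a fraction of
#'   its mean; only regularizes rank-deficient training Grams.
#' @param gd_steps,gd_tol Gradient-descent controls (only for
#'   `method = "gd"`).
#' @return An object of class `mmse_readout`: list with `matrices` (list of
#'   `V` `D x N` matrices), `n_items`, `dim`, `n_superposed`.
#' @export
train_mmse <- function(superpositions, truths, n_items,
                       method = c("ls", "gd"), ridge = 1e-8,
                       gd_steps = 300L, gd_tol = 0) {
  method <- match.arg(method)
  if (is.list(superpositions)) {
    superpositions <- do.call(cbind, superpositions)
  }
  if (is.list(truths)) truths <- do.call(cbind, truths)
  if (!is.matrix(truths)) truths <- matrix(truths, nrow = 1)
  X <- superpositions
  R <- ncol(X)
  D <- nrow(X)
  if (ncol(truths) != R) stop("superpositions and truths must be paired")
  V <- nrow(truths)
  N <- as.integer(n_items)

  # one-hot targets stacked over positions: R x (N * V)
  Call <- matrix(0, nrow = R, ncol = N * V)
  for (v in seq_len(V)) {
    Call[cbind(seq_len(R), (v - 1) * N + truths[v, ])] <- 1
  }

  if (method == "ls") {
    G <- tcrossprod(X) # D x D, shared across positions
    diag(G) <- diag(G) + ridge * mean(diag(G)) * D
    Fall <- solve(G, X %*% Call) # D x (N*V)
  } else {
    # full-batch gradient descent on the same convex objective
    Fall <- matrix(0, nrow = D, ncol = N * V)
    G <- tcrossprod(X)
    lmax <- max(abs(eigen(G, symmetric = TRUE, only.values = TRUE)$values))
    step <- R / (2 * lmax) * 1.9
    for (i in seq_len(gd_steps)) {
      grad <- (2 / R) * (X %*% (crossprod(X, Fall) - Call))
      Fall <- Fall - step * grad
      if (gd_tol > 0 && max(abs(grad)) < gd_tol) break
    }
  }
  matrices <- lapply(seq_len(V), function(v) {
    Fall[, (v - 1) * N + seq_len(N), drop = FALSE]
  })
  structure(list(matrices = matrices, n_items = N, dim = D,
                 n_superposed = V),
            class = "mmse_readout")
}

#' @export
print.mmse_readout <- function(x, ...) {
  cat(sprintf("<mmse_readout> V = %d positions, D = %d, N = %d\n",
              x$n_superposed, x$dim, x$n_items))
  invisible(x)
}

#' Estimate one position's symbol with a trained MMSE readout
#'
#' `argmax_q (F_v' x)[q]`, ties to the smallest index.
#'
#' @param x Superposition vector of dimension `D`.
#' @param readout A trained [train_mmse()] object.
#' @param v Position index, `1 <= v <= V`.
#' @return 1-based estimated symbol index.
#' @export
mmse_estimate <- function(x, readout, v) {
  if (!inherits(readout, "mmse_readout")) stop("readout is not trained")
  if (v < 1 || v > readout$n_superposed) stop("position `v` out of range")
  scores <- drop(crossprod(readout$matrices[[v]], x))
  which.max(scores)
}

#' Iterative retrieval of symbol superpositions
#'
#' Decomposes plain symbol superpositions (no sign or rotation encoding)
#' with either the standard associative-memory readout
#' `c_v = E' perm_v^{-1}(x) / D` or trained MMSE readouts, optionally with
#' iterative interference-cancelling feedback. Feedback re-encodes the
#' current estimates through the true dictionary and permutations and
#' subtracts them from the other positions' queries, at full scale (`unit`)
#' or scaled by the estimate's confidence clipped to one (`soft`).
#'
#' @param x Superposition vector, or `D x T` matrix of superpositions
#'   (columns are independent trials).
#' @param im An [item_memory()] (used for the AM readout and for feedback
#'   re-encoding).
#' @param perms [permutation_set()] or `NULL` for identity permutations.
#' @param n_superposed Number of superposed positions V.
#' @param readout `NULL` for the AM readout, or a trained [train_mmse()]
#'   object.
#' @param feedback `"none"`, `"unit"`, or `"soft"`.
#' @param max_iterations Iteration cap for the feedback loop.
#' @param truth Optional `V x T` matrix of true symbol indexes; enables the
#'   accuracy and capacity fields.
#' @return An object of class `retrieval_result`: list with `symbols`
#'   (`V x T` matrix of estimates), `iterations`, and, when `truth` is given,
#'   `accuracy` (fraction of correctly retrieved positions pooled over
#'   trials) and `capacity` (bits/dimension, via [retrieval_capacity()]).
#' @export
decode_iterative <- function(x, im, perms = NULL, n_superposed,
                             readout = NULL,
                             feedback = c("none", "unit", "soft"),
                             max_iterations = 10L, truth = NULL) {
  feedback <- match.arg(feedback)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  D <- nrow(x)
  Tn <- ncol(x)
  V <- as.integer(n_superposed)
  N <- im$n_items
  E <- im$entries
  use_mmse <- !is.null(readout)
  if (use_mmse) stopifnot(inherits(readout, "mmse_readout"),
                          readout$n_superposed >= V)

  # forward-permuted entries for feedback re-encoding:
  # perm_v(e_q)[i] = e_q[forward[i, v]]
  Eperm <- lapply(seq_len(V), function(v) {
    if (is.null(perms)) E else E[perms$forward[, v], , drop = FALSE]
  })

  Q <- matrix(1L, nrow = V, ncol = Tn)
  scales <- matrix(0, nrow = V, ncol = Tn)
  S <- matrix(0, nrow = D, ncol = Tn) # running sum of scaled feedback
  max_iter <- if (feedback == "none" || V == 1) 1L else
    as.integer(max_iterations)
  iterations <- 0L

  for (iter in seq_len(max_iter)) {
    iterations <- iter
    Qnew <- Q
    for (v in seq_len(V)) {
      fb_v <- if (iter == 1L) 0 else
        Eperm[[v]][, Q[v, ], drop = FALSE] *
          rep(scales[v, ], each = D)
      Xv <- x - S + fb_v
      if (use_mmse) {
        scores <- crossprod(readout$matrices[[v]], Xv) # N x T
      } else {
        W <- if (is.null(perms)) Xv else Xv[perms$inverse[, v], , drop = FALSE]
        scores <- crossprod(E, W) / D
      }
      q_hat <- max.col(t(scores), ties.method = "first")
      Qnew[v, ] <- q_hat
      conf <- abs(scores[cbind(q_hat, seq_len(Tn))])
      scales[v, ] <- switch(feedback,
                            none = 0,
                            unit = 1,
                            soft = pmin(conf, 1))
    }
    if (feedback != "none") {
      S <- matrix(0, nrow = D, ncol = Tn)
      for (v in seq_len(V)) {
        S <- S + Eperm[[v]][, Qnew[v, ], drop = FALSE] *
          rep(scales[v, ], each = D)
      }
    }
    if (identical(Qnew, Q) && iter > 1L) {
      Q <- Qnew
      break
    }
    Q <- Qnew
  }

  out <- list(symbols = Q, iterations = iterations)
  if (!is.null(truth)) {
    if (!is.matrix(truth)) truth <- matrix(truth, ncol = 1)
    acc <- mean(Q == truth[seq_len(V), , drop = FALSE])
    out$accuracy <- acc
    out$capacity <- retrieval_capacity(acc, V, D, N)
  }
  structure(out, class = "retrieval_result")
}

#' Operational capacity of a superposition at retrieval probability p_c
#'
#' `Capacity(p_c) = (V/D) * (p_c * log2(p_c N) +
#'   (1 - p_c) * log2(N/(N-1) * (1 - p_c)))` bits per dimension; the second
#' term is taken as 0 at `p_c = 1`, and the whole expression vanishes
#' algebraically at chance level `p_c = 1/N`.
#'
#' @param p_c Probability of correct retrieval, in `[0, 1]`.
#' @param V Number of superposed vectors.
#' @param D Vector dimension.
#' @param N Dictionary size (>= 2).
#' @return Capacity in bits per dimension.
#' @export
retrieval_capacity <- function(p_c, V, D, N) {
  if (any(p_c < 0 | p_c > 1)) stop("`p_c` must lie in [0, 1]")
  if (N < 2) stop("`N` must be >= 2")
  term1 <- ifelse(p_c == 0, 0, p_c * log2(p_c * N))
  term2 <- ifelse(p_c == 1, 0,
                  (1 - p_c) * log2(N / (N - 1) * (1 - p_c)))
  (V / D) * (term1 + term2)
}
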