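#' Random bipolar (Rademacher) vector
#'
#' @param dim Dimension D.
#' @param seed Optional seed; `NULL` uses the ambient RNG.
#' @return Numeric vector of -1/+1 values.
#' @export
random_bipolar <- function(dim, seed = NULL) {
  stopifnot(dim >= 1)
  with_seed_or_not(seed, sample(c(-1, 1), dim, replace = TRUE))
}

#' Item memory: a fixed random dictionary of bipolar vectors
#'
#' Builds `n_items` quasi-orthogonal bipolar vectors of dimension `dim`,
#' stored as columns of a `dim x n_items` matrix. By default each entry is
#' exactly balanced: a fixed half-and-half template of +1/-1 is shuffled per
#' entry, so every column has an equal number of each sign (for odd `dim` the
#' counts differ by one). With `balanced = FALSE` entries are i.i.d.
#' Rademacher draws instead.
#'
#' @param n_items Number of dictionary entries N (>= 1).
#' @param dim Vector dimension D (>= 2).
#' @param seed Integer seed; entries are deterministic given
#'   `(n_items, dim, seed)`.
#' @param balanced Enforce exact sign balance per entry (default `TRUE`).
#' @return An object of class `item_memory` with fields `entries`
#'   (`dim x n_items` matrix), `n_items`, `dim`, `seed`.
#' @export
item_memory <- function(n_items, dim, seed = 0L, balanced = TRUE) {
  if (!is.numeric(n_items) || length(n_items) != 1 || n_items < 1) {
    stop("`n_items` must be a positive integer")
  }
  if (!is.numeric(dim) || length(dim) != 1 || dim < 2) {
    stop("`dim` must be an integer >= 2")
  }
  n_items <- as.integer(n_items)
  dim <- as.integer(dim)
  template <- c(rep(1, dim %/% 2), rep(-1, dim - dim %/% 2))
  entries <- withr::with_seed(derive_seed(seed, "item_memory"), {
    if (balanced) {
      vapply(seq_len(n_items), function(i) sample(template),
             numeric(dim))
    } else {
      matrix(sample(c(-1, 1), dim * n_items, replace = TRUE),
             nrow = dim, ncol = n_items)
    }
  })
  structure(list(entries = entries, n_items = n_items, dim = dim,
                 seed = seed, balanced = balanced),
            class = "item_memory")
}

#' @export
print.item_memory <- function(x, ...) {
  cat(sprintf("<item_memory> N = %d entries, D = %d, seed = %s\n",
              x$n_items, x$dim, format(x$seed)))
  invisible(x)
}

#' Continuous item memory (level dictionary)
#'
#' A distance-preserving dictionary for scalar levels: a random bipolar seed
#' vector represents level 1, and successive levels flip a growing, nested set
#' of randomly chosen positions until exactly `dim/2` positions are flipped at
#' the top level, which makes the extreme levels orthogonal. The cumulative
#' number of flips at level l is `round((l-1)/(L-1) * dim/2)`, so
#' `cosine(level 1, level l)` decreases linearly from 1 to 0.
#'
#' @param n_levels Number of levels L (>= 2).
#' @param dim Vector dimension D; must be even so that level L can be exactly
#'   orthogonal to level 1.
#' @param seed Integer seed.
#' @return An object of class `continuous_item_memory` with fields `levels`
#'   (`dim x n_levels` matrix), `n_levels`, `dim`, `seed`.
#' @export
continuous_item_memory <- function(n_levels, dim, seed = 0L) {
  if (!is.numeric(n_levels) || n_levels < 2) {
    stop("`n_levels` must be an integer >= 2")
  }
  if (!is.numeric(dim) || dim < 2 || dim %% 2 != 0) {
    stop("`dim` must be an even integer >= 2")
  }
  n_levels <- as.integer(n_levels)
  dim <- as.integer(dim)
  built <- withr::with_seed(derive_seed(seed, "cim"), {
    base <- sample(c(-1, 1), dim, replace = TRUE)
    flip_order <- sample.int(dim) # single permutation => nested flip sets
    list(base = base, flip_order = flip_order)
  })
  cum_flips <- round((seq_len(n_levels) - 1) / (n_levels - 1) * dim / 2)
  levels <- matrix(built$base, nrow = dim, ncol = n_levels)
  for (l in seq_len(n_levels)[-1]) {
    idx <- built$flip_order[seq_len(cum_flips[l])]
    levels[idx, l] <- -built$base[idx]
  }
  structure(list(levels = levels, n_levels = n_levels, dim = dim,
                 seed = seed),
            class = "continuous_item_memory")
}

#' @export
print.continuous_item_memory <- function(x, ...) {
  cat(sprintf("<continuous_item_memory> L = %d levels, D = %d, seed = %s\n",
              x$n_levels, x$dim, format(x$seed)))
  invisible(x)
}

#' Set of distinct random permutations
#'
#' `n_perms` distinct random reorderings of `dim` positions, used to keep the
#' superposed blocks of a codeword (or the frames of an n-gram)
#' distinguishable. Forward application of permutation v maps element i to
#' position i of the output via `x[perm[i]]`; the inverse undoes it exactly.
#'
#' @param n_perms Number of permutations V (>= 1).
#' @param dim Dimension D.
#' @param seed Integer seed.
#' @return An object of class `permutation_set` with fields `forward` and
#'   `inverse` (`dim x n_perms` integer matrices), `n_perms`, `dim`, `seed`.
#' @export
permutation_set <- function(n_perms, dim, seed = 0L) {
  stopifnot(n_perms >= 1, dim >= 2)
  n_perms <- as.integer(n_perms)
  dim <- as.integer(dim)
  forward <- withr::with_seed(derive_seed(seed, "permutation_set"), {
    seen <- character(0)
    out <- matrix(0L, nrow = dim, ncol = n_perms)
    for (v in seq_len(n_perms)) {
      repeat {
        p <- sample.int(dim)
        key <- paste(p, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[, v] <- p
          break
        }
      }
    }
    out
  })
  inverse <- apply(forward, 2, order)
  structure(list(forward = forward, inverse = inverse,
                 n_perms = n_perms, dim = dim, seed = seed),
            class = "permutation_set")
}

#' Cosine similarity between two vectors
#'
#' Inner product normalized by the product of Euclidean norms; reflects the
#' angle between the vectors and ignores their lengths.
#'
#' @param x,y Numeric vectors of equal dimension; neither may be all-zero.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_sim <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for zero-norm input")
  sum(x * y) / (nx * ny)
}

#' Cyclic rotation of a vector
#'
#' Right cyclic shift by `r` positions: `rotate(x, r)[i] = x[(i - r) mod D]`
#' (0-based). `hv_rotate(x, -r)` is the exact inverse, and rotations compose
#' additively mod D.
#'
#' @param x Numeric vector.
#' @param r Integer shift (reduced mod `length(x)`).
#' @return The rotated vector.
#' @export
hv_rotate <- function(x, r) {
  d <- length(x)
  r <- ((r %% d) + d) %% d
  if (r == 0) return(x)
  x[((seq_len(d) - 1 - r) %% d) + 1]
}

#' Apply (or invert) one permutation from a permutation set
#'
#' @param x Numeric vector of dimension matching `pset`.
#' @param pset A [permutation_set()].
#' @param v Which permutation to apply, `1 <= v <= n_perms`.
#' @param inverse Apply the inverse permutation instead.
#' @return The reordered vector.
#' @export
hv_permute <- function(x, pset, v, inverse = FALSE) {
  stopifnot(inherits(pset, "permutation_set"))
  if (v < 1 || v > pset$n_perms) stop("permutation index `v` out of range")
  if (length(x) != pset$dim) stop("dimension mismatch")
  if (inverse) x[pset$inverse[, v]] else x[pset$forward[, v]]
}

#' Bundle (superpose) vectors by element-wise addition
#'
#' @param xs Non-empty list of equal-dimension numeric vectors.
#' @return The element-wise sum; an integer-valued vector when inputs are
#'   bipolar.
#' @export
hv_bundle <- function(xs) {
  if (!is.list(xs) || length(xs) == 0) stop("`xs` must be a non-empty list")
  d <- length(xs[[1]])
  if (any(vapply(xs, length, integer(1)) != d)) stop("dimension mismatch")
  Reduce(`+`, xs)
}

#' Bind two bipolar vectors by element-wise multiplication
#'
#' Binding produces a vector dissimilar to both inputs and is self-inverse
#' for bipolar vectors: `hv_bind(hv_bind(x, y), y) == x`.
#'
#' @param x,y Bipolar vectors of equal dimension.
#' @return Their element-wise product.
#' @export
hv_bind <- function(x, y) {
  if (length(x) != length(y)) stop("dimension mismatch")
  x * y
}

#' Bipolarize an integer vector
#'
#' Element-wise sign thresholding: negative values map to -1, positive to +1,
#' and exact zeros take the sign of the deterministic tie-breaker vector at
#' that position. Superpositions of an odd number of bipolar vectors contain
#' no zeros, so the tie-breaker only matters for even superpositions.
#'
#' @param x Integer-valued vector.
#' @param tie_breaker Bipolar vector of the same dimension.
#' @return A bipolar vector.
#' @export
hv_bipolarize <- function(x, tie_breaker) {
  if (length(x) != length(tie_breaker)) stop("dimension mismatch")
  out <- sign(x)
  zero <- out == 0
  if (any(zero)) out[zero] <- tie_breaker[zero]
  out
}
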