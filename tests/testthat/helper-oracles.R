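# Independent oracles used to cross-check the fast implementation paths.

# Literal double-loop evaluation of the associative-memory scan:
# c[q, r] = (1/D) <rotate(y, -r), e_q>, argmax of |c| with lexicographic
# (q, then r) tie-break. Written without any shared code with am_search().
brute_force_am <- function(y, entries) {
  D <- length(y)
  N <- ncol(entries)
  best <- list(q = NA, r = NA, s = NA, confidence = -1)
  for (q in 0:(N - 1)) {
    for (r in 0:(D - 1)) {
      # rotate(y, -r)[i] = y[(i + r) mod D]   (0-based)
      rot <- y[((seq_len(D) - 1 + r) %% D) + 1]
      c_qr <- sum(rot * entries[, q + 1]) / D
      if (abs(c_qr) > best$confidence + 1e-12) {
        best <- list(q = q, r = r, s = if (c_qr >= 0) 1L else -1L,
                     confidence = abs(c_qr))
      }
    }
  }
  best
}

# Closed-form expected cosine between level 1 and level l of a nested-flip
# level dictionary: 1 - 2 * flips / D.
cim_expected_cosine <- function(l, L, D) {
  1 - 2 * round((l - 1) / (L - 1) * D / 2) / D
}

random_bits <- function(k) sample(0:1, k, replace = TRUE)
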