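// Batched associative-memory search over (dictionary entry, cyclic rotation)
// pairs via frequency-domain circular cross-correlation. Queries are real,
// so two query columns share one complex transform: one rides in the real
// part, one in the imaginary part, and the two correlation tables come back
// as Re/Im of the inverse transform.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// W: D x nq real query matrix (each column already inverse-permuted).
// EhatConj: D x N, conjugated column-wise DFT of the dictionary.
// Returns per query: 0-based q and r maximizing |c[q, r]|, the sign s of the
// maximizing entry and the confidence |c|, with c = <rot(w, -r), e_q> / D.
// The scan runs q-major then r-ascending, and strict inequality keeps the
// first maximum, so ties resolve to the lexicographically smallest (q, r).
// [[Rcpp::export]]
List am_search_batch_cpp(const arma::mat& W, const arma::cx_mat& EhatConj) {
  const arma::uword D = W.n_rows;
  const arma::uword N = EhatConj.n_cols;
  const arma::uword nq = W.n_cols;
  const double inv_d = 1.0 / static_cast<double>(D);

  IntegerVector q_out(nq), r_out(nq), s_out(nq);
  NumericVector conf_out(nq);

  arma::vec zeros(D, arma::fill::zeros);
  for (arma::uword j = 0; j < nq; j += 2) {
    const bool paired = (j + 1 < nq);
    arma::cx_vec w = paired
      ? arma::cx_vec(W.col(j), W.col(j + 1))
      : arma::cx_vec(W.col(j), zeros);
    arma::cx_vec f = arma::fft(w);

    double best_a = -1.0, best_b = -1.0, val_a = 0.0, val_b = 0.0;
    arma::uword qa = 0, ra = 0, qb = 0, rb = 0;
    for (arma::uword qq = 0; qq < N; ++qq) {
      arma::cx_vec z = arma::ifft(arma::cx_vec(EhatConj.col(qq) % f));
      const std::complex<double>* zp = z.memptr();
      for (arma::uword rr = 0; rr < D; ++rr) {
        const double za = zp[rr].real();
        const double aa = std::fabs(za);
        if (aa > best_a) { best_a = aa; val_a = za; qa = qq; ra = rr; }
        if (paired) {
          const double zb = zp[rr].imag();
          const double ab = std::fabs(zb);
          if (ab > best_b) { best_b = ab; val_b = zb; qb = qq; rb = rr; }
        }
      }
    }
    q_out[j] = static_cast<int>(qa);
    r_out[j] = static_cast<int>(ra);
    s_out[j] = (val_a >= 0.0) ? 1 : -1;
    conf_out[j] = best_a * inv_d;
    if (paired) {
      q_out[j + 1] = static_cast<int>(qb);
      r_out[j + 1] = static_cast<int>(rb);
      s_out[j + 1] = (val_b >= 0.0) ? 1 : -1;
      conf_out[j + 1] = best_b * inv_d;
    }
  }
  return List::create(_["q"] = q_out, _["r"] = r_out, _["s"] = s_out,
                      _["confidence"] = conf_out);
}
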