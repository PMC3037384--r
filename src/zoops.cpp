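#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ZOOPS forward pass over all sequences of an equal-length set.
//
// seqs     : N x L integer matrix, base codes 0..3 (A,C,G,T)
// logPwm   : 4 x w log letter probabilities, columns = motif positions
// logFlank : length-4 log probabilities of the order-0 flanking model
// logT     : length-(L-w+1) log positional prior over site starts
// p_occ    : P(c = 1), probability that a sequence carries a site
// sw       : probability that the site lies on the forward strand
//
// Returns per-sequence log-likelihood under the ZOOPS mixture plus the
// posterior responsibilities of the no-site component (r0) and of every
// (start, strand) site component (r_fwd, r_rev), which are exactly
// P(c=0|x) and P(c=1, u, strand | x).
// [[Rcpp::export]]
List zoops_forward_cpp(IntegerMatrix seqs, NumericMatrix logPwm,
                       NumericVector logFlank, NumericVector logT,
                       double p_occ, double sw) {
  const int N = seqs.nrow(), L = seqs.ncol(), w = logPwm.ncol();
  const int S = L - w + 1;
  if (logT.size() != S) stop("logT length does not match L - w + 1");
  NumericVector loglik(N), r0(N);
  NumericMatrix rF(N, S), rR(N, S);
  const double log_po = (p_occ > 0.0) ? std::log(p_occ) : R_NegInf;
  const double log_qo = (p_occ < 1.0) ? std::log1p(-p_occ) : R_NegInf;
  const double log_sf = (sw > 0.0) ? std::log(sw) : R_NegInf;
  const double log_sr = (sw < 1.0) ? std::log1p(-sw) : R_NegInf;

  std::vector<double> comp(2 * S + 1);
  std::vector<double> cumF(L + 1);
  for (int i = 0; i < N; ++i) {
    cumF[0] = 0.0;
    for (int l = 0; l < L; ++l) cumF[l + 1] = cumF[l] + logFlank[seqs(i, l)];
    comp[0] = log_qo + cumF[L];
    double m = comp[0];
    for (int u = 0; u < S; ++u) {
      double sF = 0.0, sR = 0.0;
      for (int j = 0; j < w; ++j) {
        const int b = seqs(i, u + j);
        sF += logPwm(b, j);
        sR += logPwm(3 - b, w - 1 - j);  // reverse-complement strand
      }
      const double flank = cumF[u] + (cumF[L] - cumF[u + w]);
      const double base = log_po + logT[u] + flank;
      const double cF = base + log_sf + sF;
      const double cR = base + log_sr + sR;
      comp[1 + u] = cF;
      comp[1 + S + u] = cR;
      if (cF > m) m = cF;
      if (cR > m) m = cR;
    }
    double tot = 0.0;
    for (int k = 0; k < 2 * S + 1; ++k) tot += std::exp(comp[k] - m);
    const double ll = m + std::log(tot);
    loglik[i] = ll;
    r0[i] = std::exp(comp[0] - ll);
    for (int u = 0; u < S; ++u) {
      rF(i, u) = std::exp(comp[1 + u] - ll);
      rR(i, u) = std::exp(comp[1 + S + u] - ll);
    }
  }
  return List::create(_["loglik"] = loglik, _["r0"] = r0,
                      _["r_fwd"] = rF, _["r_rev"] = rR);
}

// Accumulates gradient sufficient statistics of the ZOOPS log-likelihood
// with respect to log PWM entries (G_M) and log flanking probabilities
// (G_F), given externally weighted responsibilities (weights may be
// negative: discriminative learning multiplies them by y_i - P(fg|x_i)).
// [[Rcpp::export]]
List zoops_grad_counts_cpp(IntegerMatrix seqs, NumericMatrix wrF,
                           NumericMatrix wrR, NumericVector wr0, int w) {
  const int N = seqs.nrow(), L = seqs.ncol();
  const int S = L - w + 1;
  NumericMatrix GM(4, w);
  NumericVector GF(4);
  for (int i = 0; i < N; ++i) {
    double tw = 0.0;
    for (int u = 0; u < S; ++u) tw += wrF(i, u) + wrR(i, u);
    const double wfull = wr0[i] + tw;  // whole-sequence flanking counts
    for (int l = 0; l < L; ++l) GF[seqs(i, l)] += wfull;
    for (int u = 0; u < S; ++u) {
      const double rf = wrF(i, u), rr = wrR(i, u);
      if (rf == 0.0 && rr == 0.0) continue;
      const double rs = rf + rr;
      for (int j = 0; j < w; ++j) {
        const int b = seqs(i, u + j);
        GF[b] -= rs;  // site window is emitted by the PWM, not the flank
        GM(b, j) += rf;
        GM(3 - b, w - 1 - j) += rr;
      }
    }
  }
  return List::create(_["G_M"] = GM, _["G_F"] = GF);
}

// Per-sequence transition counts of a homogeneous order-d Markov model
// with ascending-order start conditionals. The parameter cells are laid
// out block-wise: order-0 block (4 cells, position 1), order-1 block
// (16 cells, position 2), ..., order-(d-1) block, then the main order-d
// block (4^d * 4 cells, positions d+1..L). Within a block, cell index is
// context * 4 + letter with the most recent context letter at the lowest
// digit.
// [[Rcpp::export]]
NumericMatrix markov_count_matrix_cpp(IntegerMatrix seqs, int d) {
  const int N = seqs.nrow(), L = seqs.ncol();
  if (d >= L) stop("Markov order must be smaller than sequence length");
  int ncell = 0;
  std::vector<int> offset(d + 1);
  for (int k = 0; k <= d; ++k) {
    offset[k] = ncell;
    int sz = 4;
    for (int j = 0; j < k; ++j) sz *= 4;
    ncell += sz;
  }
  NumericMatrix C(N, ncell);
  for (int i = 0; i < N; ++i) {
    for (int l = 0; l < L; ++l) {
      const int k = (l < d) ? l : d;  // order used at this position
      int ctx = 0, pw = 1;
      for (int j = 1; j <= k; ++j) {
        ctx += seqs(i, l - j) * pw;
        pw *= 4;
      }
      C(i, offset[k] + ctx * 4 + seqs(i, l)) += 1.0;
    }
  }
  return C;
}
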