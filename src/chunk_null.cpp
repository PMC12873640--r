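// Chunk-shuffle null for activation-strength cross-correlograms.
//
// The observed CCG at lag L (in bins) is sum_t a[t] * b[t+L] over bin pairs
// that lie in the same NREM segment, normalized by the number of valid pairs.
// The null permutes 2-s chunks of trace b. Because the lag range (<= 5 bins)
// is much smaller than the chunk length (100 bins), every product either
// pairs a chunk slot with the chunk occupying the same slot (internal term)
// or with the chunk in the adjacent slot (edge term). Both reduce to lookups
// in chunk-pair Gram matrices computed once per pair via BLAS, making each
// shuffle an O(K) gather rather than an O(n) recompute.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// a_chunks, b_chunks: K x C (row = chunk), already standardized traces.
// seg_of_chunk: segment id per chunk slot (edge terms only within a segment).
// perms: n_shuffles x K, 1-based permutation of b chunks per shuffle.
// Returns observed normalized CCG over lags -max_lag..max_lag and the null
// peak (max over lags) per shuffle.
// [[Rcpp::export]]
List chunk_null_cpp(const arma::mat& a_chunks, const arma::mat& b_chunks,
                    const arma::ivec& seg_of_chunk, int max_lag,
                    const arma::imat& perms) {
  const int K = a_chunks.n_rows, C = a_chunks.n_cols;
  const int S = perms.n_rows;
  const int n_lags = 2 * max_lag + 1;

  // adjacent same-segment slot pairs (i, i+1)
  std::vector<int> adj;
  for (int i = 0; i + 1 < K; ++i)
    if (seg_of_chunk[i] == seg_of_chunk[i + 1]) adj.push_back(i);
  const double n_adj = (double)adj.size();

  arma::vec obs(n_lags, arma::fill::zeros);
  arma::mat null_raw(S, n_lags, arma::fill::zeros);
  arma::vec n_valid(n_lags);
  for (int L = 0; L <= max_lag; ++L) {
    n_valid[max_lag + L] = (double)K * (C - L) + n_adj * L;
    n_valid[max_lag - L] = n_valid[max_lag + L];
  }

  arma::mat M;  // K x K work matrix
  for (int L = 0; L <= max_lag; ++L) {
    // internal, +L: a cols 0..C-1-L vs b cols L..C-1
    M = a_chunks.cols(0, C - 1 - L) * b_chunks.cols(L, C - 1).t();
    for (int i = 0; i < K; ++i) obs[max_lag + L] += M(i, i);
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int i = 0; i < K; ++i) acc += M(i, perms(s, i) - 1);
      null_raw(s, max_lag + L) += acc;
    }
    if (L > 0) {
      // internal, -L: a cols L..C-1 vs b cols 0..C-1-L
      M = a_chunks.cols(L, C - 1) * b_chunks.cols(0, C - 1 - L).t();
      for (int i = 0; i < K; ++i) obs[max_lag - L] += M(i, i);
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int i = 0; i < K; ++i) acc += M(i, perms(s, i) - 1);
        null_raw(s, max_lag - L) += acc;
      }
      // edge, +L: tail of a slot i vs head of b chunk in slot i+1
      M = a_chunks.cols(C - L, C - 1) * b_chunks.cols(0, L - 1).t();
      for (size_t k = 0; k < adj.size(); ++k) {
        int i = adj[k];
        obs[max_lag + L] += M(i, i + 1);
        for (int s = 0; s < S; ++s)
          null_raw(s, max_lag + L) += M(i, perms(s, i + 1) - 1);
      }
      // edge, -L: head of a slot i+1 vs tail of b chunk in slot i
      M = a_chunks.cols(0, L - 1) * b_chunks.cols(C - L, C - 1).t();
      for (size_t k = 0; k < adj.size(); ++k) {
        int i = adj[k];
        obs[max_lag - L] += M(i + 1, i);
        for (int s = 0; s < S; ++s)
          null_raw(s, max_lag - L) += M(i + 1, perms(s, i) - 1);
      }
    }
  }

  obs /= n_valid;
  arma::vec peaks(S);
  for (int s = 0; s < S; ++s) {
    double best = -arma::datum::inf;
    for (int l = 0; l < n_lags; ++l) {
      double v = null_raw(s, l) / n_valid[l];
      if (v > best) best = v;
    }
    peaks[s] = best;
  }
  return List::create(_["observed_ccg"] = obs, _["null_peaks"] = peaks);
}
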