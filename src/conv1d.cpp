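// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// 1D same-padding convolution over a batch of sequences stacked
// sample-major into a (B*L) x C activation matrix. The kernel is held in
// offset-concatenated layout Wcat (C x k*F): one GEMM P = A * Wcat, then k
// shifted block additions assemble Z[r, ] = sum_j A[r + o_j, ] W_j.

// [[Rcpp::export]]
Rcpp::List conv1d_fwd(const arma::mat& A, const arma::mat& Wcat,
                      const arma::vec& b, const arma::ivec& offsets,
                      int B, int L) {
  const int F = Wcat.n_cols / offsets.n_elem;
  const arma::mat P = A * Wcat;
  arma::mat Z(A.n_rows, F);
  Z.each_row() = b.t();
  for (arma::uword j = 0; j < offsets.n_elem; ++j) {
    const int o = offsets[j];
    const int lo = std::max(0, -o), hi = std::min(L - 1, L - 1 - o);
    if (lo > hi) continue;
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      Z.rows(base + lo, base + hi) +=
        P.submat(base + lo + o, j * F, base + hi + o, (j + 1) * F - 1);
    }
  }
  arma::mat out = Z;
  out.elem(arma::find(Z <= 0)).zeros();
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("Z") = Z);
}

// Backward pass: dZ = dA_out masked by Z > 0; dP_j[r + o_j, ] = dZ[r, ];
// dWcat = A_in' dPcat; dA_prev = dPcat Wcat'.

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::mat& dA_out, const arma::mat& Z,
                      const arma::mat& A_in, const arma::mat& Wcat,
                      const arma::ivec& offsets, int B, int L) {
  const int F = Wcat.n_cols / offsets.n_elem;
  arma::mat dZ = dA_out;
  dZ.elem(arma::find(Z <= 0)).zeros();
  arma::mat dPcat(A_in.n_rows, Wcat.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < offsets.n_elem; ++j) {
    const int o = offsets[j];
    const int lo = std::max(0, -o), hi = std::min(L - 1, L - 1 - o);
    if (lo > hi) continue;
    for (int s = 0; s < B; ++s) {
      const int base = s * L;
      dPcat.submat(base + lo + o, j * F, base + hi + o, (j + 1) * F - 1) =
        dZ.rows(base + lo, base + hi);
    }
  }
  arma::mat dWcat = A_in.t() * dPcat;
  arma::vec db = arma::sum(dZ, 0).t();
  arma::mat dA_prev = dPcat * Wcat.t();
  return Rcpp::List::create(Rcpp::Named("dWcat") = dWcat,
                            Rcpp::Named("db") = db,
                            Rcpp::Named("dA_prev") = dA_prev);
}
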