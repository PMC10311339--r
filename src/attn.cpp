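// Multi-head additive attention, forward and backward. This is the inner
// loop of training; the R reference implementations (attn_forward_r /
// attn_backward_r) define the semantics and are checked against these in
// the test suite. The (m*k) x d tanh tensor is streamed key-by-key and
// recomputed in the backward pass instead of being stored.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export(name = ".attn_forward_cpp")]]
List attn_forward_cpp(const arma::mat& Q0, const arma::mat& K0,
                      const arma::mat& Wq, const arma::mat& Wk,
                      const arma::mat& Wv, const arma::mat& w, int heads) {
  const int m = Q0.n_rows, k = K0.n_rows, d = Wq.n_cols;
  const int dh = d / heads;
  arma::mat Qp = Q0 * Wq;
  arma::mat Kp = K0 * Wk;
  arma::mat Vp = K0 * Wv;
  arma::mat W_big(d, heads, arma::fill::zeros);
  for (int t = 0; t < heads; ++t)
    W_big.submat(t * dh, t, t * dh + dh - 1, t) = w.col(t);
  arma::mat Z(m * k, heads);
  arma::mat Tblock(m, d);
  for (int j = 0; j < k; ++j) {
    Tblock = arma::tanh(Qp.each_row() + Kp.row(j));
    Z.rows(j * m, j * m + m - 1) = Tblock * W_big;
  }
  Z = arma::exp(Z - Z.max());   // scores bounded by ||w||_1; keep exp <= 1
  arma::cube A(m, k, heads);
  arma::mat O(m, d);
  for (int t = 0; t < heads; ++t) {
    arma::mat ez(Z.colptr(t), m, k);
    arma::vec rs = arma::sum(ez, 1);
    arma::mat At = ez.each_col() / rs;
    A.slice(t) = At;
    O.cols(t * dh, t * dh + dh - 1) = At * Vp.cols(t * dh, t * dh + dh - 1);
  }
  return List::create(_["O"] = O, _["A"] = A, _["Qp"] = Qp, _["Kp"] = Kp,
                      _["Vp"] = Vp, _["W_big"] = W_big,
                      _["m"] = m, _["k"] = k, _["dh"] = dh);
}

// [[Rcpp::export(name = ".attn_backward_cpp")]]
List attn_backward_cpp(const arma::mat& dO, SEXP dA_extra,
                       const arma::cube& A, const arma::mat& Qp,
                       const arma::mat& Kp, const arma::mat& Vp,
                       const arma::mat& W_big,
                       const arma::mat& Q0, const arma::mat& K0,
                       const arma::mat& Wq, const arma::mat& Wk,
                       const arma::mat& Wv, int heads) {
  const int m = A.n_rows, k = A.n_cols;
  const int d = Wq.n_cols, dh = d / heads;
  const bool has_extra = !Rf_isNull(dA_extra);
  arma::cube extra;
  if (has_extra) extra = as<arma::cube>(dA_extra);
  arma::mat dZ(m * k, heads);
  arma::mat dVp(k, d, arma::fill::zeros);
  for (int t = 0; t < heads; ++t) {
    const arma::mat& At = A.slice(t);
    arma::mat dOt = dO.cols(t * dh, t * dh + dh - 1);
    arma::mat dAt = dOt * Vp.cols(t * dh, t * dh + dh - 1).t();
    if (has_extra) dAt += extra.slice(t);
    dVp.cols(t * dh, t * dh + dh - 1) = At.t() * dOt;
    arma::vec rowdot = arma::sum(At % dAt, 1);
    arma::mat dz = At % (dAt.each_col() - rowdot);
    dZ.col(t) = arma::vectorise(dz);
  }
  arma::mat dwfull(d, heads, arma::fill::zeros);
  arma::mat dQp(m, d, arma::fill::zeros);
  arma::mat dKp(k, d);
  arma::mat Tblock(m, d), dTblock(m, d);
  for (int j = 0; j < k; ++j) {
    Tblock = arma::tanh(Qp.each_row() + Kp.row(j));
    const arma::mat dZblock = dZ.rows(j * m, j * m + m - 1);
    dwfull += Tblock.t() * dZblock;
    dTblock = (dZblock * W_big.t()) % (1.0 - Tblock % Tblock);
    dQp += dTblock;
    dKp.row(j) = arma::sum(dTblock, 0);
  }
  arma::mat dw(dh, heads);
  for (int t = 0; t < heads; ++t)
    dw.col(t) = dwfull.submat(t * dh, t, t * dh + dh - 1, t);
  return List::create(_["dQ0"] = dQp * Wq.t(),
                      _["dK0"] = dKp * Wk.t() + dVp * Wv.t(),
                      _["dWq"] = Q0.t() * dQp, _["dWk"] = K0.t() * dKp,
                      _["dWv"] = K0.t() * dVp, _["dw"] = dw);
}
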