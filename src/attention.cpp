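// Batched linear-algebra kernels for the transformer encoder--decoder.
// Layout conventions: activations travel through R as (B*T) x d matrices
// with row index (b-1)*T + t; attention works on cubes with one slice per
// (batch, head) pair, slice index (b-1)*H + h.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// (B*T) x d  ->  cube(T, dk, B*H)
// [[Rcpp::export(name = ".to_heads")]]
arma::cube to_heads(const arma::mat& X, int T, int B, int H) {
  const int d = X.n_cols, dk = d / H;
  cube out(T, dk, B * H);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      out.slice(b * H + h) = X.rows(b * T, b * T + T - 1)
                              .cols(h * dk, h * dk + dk - 1);
    }
  }
  return out;
}

// cube(T, dk, B*H) -> (B*T) x d
// [[Rcpp::export(name = ".from_heads")]]
arma::mat from_heads(const arma::cube& C, int T, int B, int H) {
  const int dk = C.n_cols, d = dk * H;
  mat out(B * T, d);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      out.submat(b * T, h * dk, b * T + T - 1, h * dk + dk - 1) =
          C.slice(b * H + h);
    }
  }
  return out;
}

// Scaled dot-product attention forward over all (batch, head) slices.
// mask is additive (0 or -inf), one slice per batch element (shared across
// heads): mask slice index b, dims Tq x Tk.
// [[Rcpp::export(name = ".attn_fwd")]]
Rcpp::List attn_fwd(const arma::cube& Q, const arma::cube& K,
                    const arma::cube& V, const arma::cube& mask,
                    double scale, int H) {
  const int S = Q.n_slices, Tq = Q.n_rows, Tk = K.n_rows, dv = V.n_cols;
  cube P(Tq, Tk, S), out(Tq, dv, S);
  for (int s = 0; s < S; ++s) {
    mat sc = scale * (Q.slice(s) * K.slice(s).t()) + mask.slice(s / H);
    sc.each_col() -= max(sc, 1);
    mat e = exp(sc);
    vec z = sum(e, 1);
    e.each_col() /= z;
    P.slice(s) = e;
    out.slice(s) = e * V.slice(s);
  }
  return Rcpp::List::create(Rcpp::_["out"] = out, Rcpp::_["P"] = P);
}

// Backward pass of the same attention.
// [[Rcpp::export(name = ".attn_bwd")]]
Rcpp::List attn_bwd(const arma::cube& dOut, const arma::cube& Q,
                    const arma::cube& K, const arma::cube& V,
                    const arma::cube& P, double scale) {
  const int S = Q.n_slices;
  cube dQ(size(Q)), dK(size(K)), dV(size(V));
  for (int s = 0; s < S; ++s) {
    dV.slice(s) = P.slice(s).t() * dOut.slice(s);
    mat dP = dOut.slice(s) * V.slice(s).t();
    vec rs = sum(dP % P.slice(s), 1);
    mat dS = P.slice(s) % (dP - repmat(rs, 1, P.n_cols));
    dQ.slice(s) = scale * (dS * K.slice(s));
    dK.slice(s) = scale * (dS.t() * Q.slice(s));
  }
  return Rcpp::List::create(Rcpp::_["dQ"] = dQ, Rcpp::_["dK"] = dK,
                            Rcpp::_["dV"] = dV);
}

// row-wise layer normalisation, forward
// [[Rcpp::export(name = ".ln_fwd_cpp")]]
Rcpp::List ln_fwd_cpp(const arma::mat& X, const arma::vec& g,
                      const arma::vec& b, double eps) {
  mat xc = X.each_col() - mean(X, 1);
  vec inv = 1.0 / sqrt(mean(xc % xc, 1) + eps);
  mat xhat = xc.each_col() % inv;
  mat Y = (xhat.each_row() % g.t()).each_row() + b.t();
  return Rcpp::List::create(Rcpp::_["Y"] = Y, Rcpp::_["xhat"] = xhat,
                            Rcpp::_["inv"] = inv);
}

// row-wise layer normalisation, backward
// [[Rcpp::export(name = ".ln_bwd_cpp")]]
Rcpp::List ln_bwd_cpp(const arma::mat& dY, const arma::mat& xhat,
                      const arma::vec& inv, const arma::vec& g) {
  mat dxhat = dY.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat tmp = dxhat.each_col() - m1;
  tmp -= xhat.each_col() % m2;
  mat dX = tmp.each_col() % inv;
  rowvec dg = sum(dY % xhat, 0);
  rowvec db = sum(dY, 0);
  return Rcpp::List::create(Rcpp::_["dX"] = dX, Rcpp::_["dg"] = dg.t(),
                            Rcpp::_["db"] = db.t());
}

// X + row-broadcast bias
// [[Rcpp::export(name = ".add_bias")]]
arma::mat add_bias(const arma::mat& X, const arma::vec& b) {
  return X.each_row() + b.t();
}
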