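// Triple-propagation (value, d/dt, d2/dt2) passes for the tanh multilayer
// perceptron used by the time-domain physics-informed trainer. The math
// mirrors the reference implementation in R/nn.R exactly (samples in rows,
// weights input x output); the compiled and reference paths are
// cross-checked in the tests.
//
// The gradient kernel recomputes the forward activations internally so no
// large cache crosses the C++/R boundary: the loss seeds (which depend on
// the equation-of-motion residual, evaluated in R) are the only per-sample
// quantities exchanged.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;

// outputs only: q-hat and its first/second time derivatives
// [[Rcpp::export(name = ".mlp_out3_cpp")]]
List mlp_out3_cpp(List W, List b, const arma::mat& Z0,
                  const arma::mat& Z1, const arma::mat& Z2) {
  int L = W.size();
  mat A = Z0, A1 = Z1, A2 = Z2;
  for (int k = 0; k < L - 1; ++k) {
    mat Wk = as<mat>(W[k]);
    arma::rowvec bk = as<arma::rowvec>(b[k]);
    mat P = A * Wk;
    P.each_row() += bk;
    mat P1 = A1 * Wk;
    mat P2 = A2 * Wk;
    mat H = arma::tanh(P);
    mat S = 1.0 - arma::square(H);
    mat H1 = S % P1;
    mat H2 = S % P2 - 2.0 * (H % S % arma::square(P1));
    A = H; A1 = H1; A2 = H2;
  }
  mat WL = as<mat>(W[L - 1]);
  arma::rowvec bL = as<arma::rowvec>(b[L - 1]);
  mat out = A * WL;
  out.each_row() += bL;
  return List::create(_["out"] = out, _["out1"] = A1 * WL,
                      _["out2"] = A2 * WL);
}

// fused forward + reverse pass; G0, G1, G2 are the loss adjoints of
// (out, out1, out2)
// [[Rcpp::export(name = ".mlp_grad3_cpp")]]
List mlp_grad3_cpp(List W, List b, const arma::mat& Z0,
                   const arma::mat& Z1, const arma::mat& Z2,
                   const arma::mat& G0, const arma::mat& G1,
                   const arma::mat& G2) {
  int L = W.size();
  std::vector<mat> As(L), A1s(L), A2s(L), P1s(L), P2s(L), Hs(L), Ss(L);
  mat A = Z0, A1 = Z1, A2 = Z2;
  for (int k = 0; k < L - 1; ++k) {
    mat Wk = as<mat>(W[k]);
    arma::rowvec bk = as<arma::rowvec>(b[k]);
    As[k] = A; A1s[k] = A1; A2s[k] = A2;
    mat P = A * Wk;
    P.each_row() += bk;
    P1s[k] = A1 * Wk;
    P2s[k] = A2 * Wk;
    Hs[k] = arma::tanh(P);
    Ss[k] = 1.0 - arma::square(Hs[k]);
    mat H1 = Ss[k] % P1s[k];
    mat H2 = Ss[k] % P2s[k] - 2.0 * (Hs[k] % Ss[k] % arma::square(P1s[k]));
    A = Hs[k]; A1 = H1; A2 = H2;
  }
  As[L - 1] = A; A1s[L - 1] = A1; A2s[L - 1] = A2;

  List gW(L), gb(L);
  mat Pb = G0, P1b = G1, P2b = G2;
  for (int k = L - 1; k >= 0; --k) {
    gW[k] = wrap(mat(As[k].t() * Pb + A1s[k].t() * P1b + A2s[k].t() * P2b));
    gb[k] = wrap(arma::vec(arma::sum(Pb, 0).t()));
    if (k > 0) {
      mat Wk = as<mat>(W[k]);
      mat Hb = Pb * Wk.t();
      mat H1b = P1b * Wk.t();
      mat H2b = P2b * Wk.t();
      const mat& H = Hs[k - 1];
      const mat& S = Ss[k - 1];
      const mat& P1 = P1s[k - 1];
      const mat& P2 = P2s[k - 1];
      // adjoints of h = tanh(p), h1 = s*p1, h2 = s*p2 - 2*h*s*p1^2
      Pb = Hb % S - 2.0 * (H1b % (H % S % P1)) -
        H2b % (2.0 * (H % S % P2) +
               2.0 * (S % (S - 2.0 * arma::square(H)) % arma::square(P1)));
      P1b = H1b % S - 4.0 * (H2b % (H % S % P1));
      P2b = H2b % S;
    }
  }
  return List::create(_["W"] = gW, _["b"] = gb);
}
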