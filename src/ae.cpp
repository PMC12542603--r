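// Full-batch Adam training loop for the three-layer autoencoder.
// Weight initialisation and all RNG live on the R side; this loop is
// deterministic given its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {
constexpr double BETA1 = 0.9, BETA2 = 0.999, EPS = 1e-8;

template <typename T>
void adam_step(T& w, const T& g, T& m, T& v, double lr, double bc1, double bc2) {
  m = BETA1 * m + (1.0 - BETA1) * g;
  v = BETA2 * v + (1.0 - BETA2) * square(g);
  w -= lr * (m / bc1) / (sqrt(v / bc2) + EPS);
}
}  // namespace

// [[Rcpp::export(name = ".ae_train_adam")]]
Rcpp::List ae_train_adam(const arma::mat& X, arma::mat W1, arma::rowvec b1,
                         arma::mat W2, arma::rowvec b2, int epochs,
                         double lr, bool tanh_act) {
  const double n = X.n_rows, p = X.n_cols;
  const double cc = 2.0 / (n * p);

  mat mW1(size(W1), fill::zeros), vW1(size(W1), fill::zeros);
  mat mW2(size(W2), fill::zeros), vW2(size(W2), fill::zeros);
  rowvec mb1(size(b1), fill::zeros), vb1(size(b1), fill::zeros);
  rowvec mb2(size(b2), fill::zeros), vb2(size(b2), fill::zeros);
  vec loss_log(epochs);

  mat H, R, gH, gW1, gW2;
  rowvec gb1, gb2;
  for (int e = 1; e <= epochs; ++e) {
    H = X * W1;
    H.each_row() += b1;
    if (tanh_act) H = tanh(H);
    R = H * W2;
    R.each_row() += b2;
    R -= X;
    const double loss = accu(square(R)) / (n * p);
    if (!std::isfinite(loss))
      Rcpp::stop("non-finite reconstruction loss at epoch %d", e);
    loss_log(e - 1) = loss;

    gW2 = cc * (H.t() * R);
    gb2 = cc * sum(R, 0);
    gH = R * W2.t();
    if (tanh_act) gH %= (1.0 - square(H));
    gW1 = cc * (X.t() * gH);
    gb1 = cc * sum(gH, 0);

    const double bc1 = 1.0 - std::pow(BETA1, e);
    const double bc2 = 1.0 - std::pow(BETA2, e);
    adam_step(W1, gW1, mW1, vW1, lr, bc1, bc2);
    adam_step(b1, gb1, mb1, vb1, lr, bc1, bc2);
    adam_step(W2, gW2, mW2, vW2, lr, bc1, bc2);
    adam_step(b2, gb2, mb2, vb2, lr, bc1, bc2);

    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
      Rcpp::Named("W2") = W2, Rcpp::Named("b2") = b2,
      Rcpp::Named("loss") = loss_log);
}
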