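// Convolution primitives and the tied-weight convolutional autoencoder core.
//
// Index convention: conv_valid/conv_full are CROSS-CORRELATIONS,
//   valid: out(i,j) = sum_{p,q} A(i+p, j+q) * B(p,q)
// and conv_full is the zero-padded extension so that every overlap offset of
// B over A contributes. The decoder applies the explicit double flip of the
// kernel, so the reconstruction formula y = sigma(sum_k h^k *full* flip(W^k) + c)
// holds regardless of convention.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat conv_valid_core(const arma::mat& A, const arma::mat& B) {
  const int outR = (int)A.n_rows - (int)B.n_rows + 1;
  const int outC = (int)A.n_cols - (int)B.n_cols + 1;
  arma::mat out(outR, outC);
  for (int i = 0; i < outR; ++i) {
    for (int j = 0; j < outC; ++j) {
      double s = 0.0;
      for (int p = 0; p < (int)B.n_rows; ++p)
        for (int q = 0; q < (int)B.n_cols; ++q)
          s += A(i + p, j + q) * B(p, q);
      out(i, j) = s;
    }
  }
  return out;
}

static arma::mat pad_zeros(const arma::mat& A, int pr, int pc) {
  arma::mat P(A.n_rows + 2 * pr, A.n_cols + 2 * pc, arma::fill::zeros);
  P.submat(pr, pc, pr + A.n_rows - 1, pc + A.n_cols - 1) = A;
  return P;
}

static arma::mat conv_full_core(const arma::mat& A, const arma::mat& B) {
  return conv_valid_core(pad_zeros(A, (int)B.n_rows - 1, (int)B.n_cols - 1), B);
}

static arma::mat flip2(const arma::mat& W) {
  return arma::fliplr(arma::flipud(W));
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

static arma::mat activate(const arma::mat& Z, bool linear) {
  if (linear) return Z;
  arma::mat out(Z.n_rows, Z.n_cols);
  for (arma::uword i = 0; i < Z.n_elem; ++i) out(i) = sigmoid(Z(i));
  return out;
}

// derivative expressed through the activated value a = sigma(z)
static arma::mat act_prime(const arma::mat& A, bool linear) {
  if (linear) return arma::ones<arma::mat>(A.n_rows, A.n_cols);
  return A % (1.0 - A);
}

// [[Rcpp::export]]
arma::mat conv_valid_cpp(const arma::mat& A, const arma::mat& B) {
  if (B.n_rows > A.n_rows || B.n_cols > A.n_cols)
    stop("kernel larger than input (n > m)");
  return conv_valid_core(A, B);
}

// [[Rcpp::export]]
arma::mat conv_full_cpp(const arma::mat& A, const arma::mat& B) {
  return conv_full_core(A, B);
}

// [[Rcpp::export]]
arma::cube cae_encode_cpp(const arma::mat& x, const arma::cube& W,
                          const arma::vec& b, bool linear) {
  const int K = (int)W.n_slices;
  const int hr = (int)x.n_rows - (int)W.n_rows + 1;
  const int hc = (int)x.n_cols - (int)W.n_cols + 1;
  arma::cube h(hr, hc, K);
  for (int k = 0; k < K; ++k)
    h.slice(k) = activate(conv_valid_core(x, W.slice(k)) + b(k), linear);
  return h;
}

// [[Rcpp::export]]
arma::mat cae_decode_cpp(const arma::cube& h, const arma::cube& W, double c,
                         bool linear) {
  const int K = (int)W.n_slices;
  arma::mat z = conv_full_core(h.slice(0), flip2(W.slice(0)));
  for (int k = 1; k < K; ++k)
    z += conv_full_core(h.slice(k), flip2(W.slice(k)));
  return activate(z + c, linear);
}

// Full forward + backward pass for one signal.
// E = (1/(2N)) sum (x - y)^2 with N = number of elements of x.
// dE/dW^k = conv_valid(x, dh^k) + conv_valid(dy, h^k)   (tied decoder weights)
// dE/db^k = sum(dh^k),  dE/dc = sum(dy)
// where dy = (y - x)/N .* sigma'(z) and dh^k = conv_valid(dy, W^k) .* sigma'(a^k).
// [[Rcpp::export]]
List cae_grad_cpp(const arma::mat& x, const arma::cube& W, const arma::vec& b,
                  double c, bool linear,
                  Rcpp::Nullable<Rcpp::NumericMatrix> target = R_NilValue) {
  const int K = (int)W.n_slices;
  const double N = (double)x.n_elem;

  arma::cube h = cae_encode_cpp(x, W, b, linear);
  arma::mat y = cae_decode_cpp(h, W, c, linear);

  // reconstruction target defaults to the input (plain autoencoding); a
  // separate target is a test hook for residual-linearity checks
  arma::mat tgt = target.isNotNull() ? as<arma::mat>(target.get()) : x;
  arma::mat resid = y - tgt;
  double E = arma::accu(arma::square(resid)) / (2.0 * N);

  arma::mat dy = (resid / N) % act_prime(y, linear);
  double dc = arma::accu(dy);

  arma::cube dW(W.n_rows, W.n_cols, K);
  arma::vec db(K);
  for (int k = 0; k < K; ++k) {
    arma::mat dh = conv_valid_core(dy, W.slice(k)) % act_prime(h.slice(k), linear);
    db(k) = arma::accu(dh);
    dW.slice(k) = conv_valid_core(x, dh) + conv_valid_core(dy, h.slice(k));
  }

  return List::create(_["E"] = E, _["y"] = y, _["h"] = h, _["dW"] = dW,
                      _["db"] = db, _["dc"] = dc);
}

// Mean-pool the latent maps of many signals: returns n_signals x K matrix.
// [[Rcpp::export]]
arma::mat cae_pool_cpp(const List& signals, const arma::cube& W,
                       const arma::vec& b, bool linear) {
  const int n = signals.size();
  const int K = (int)W.n_slices;
  arma::mat out(n, K);
  for (int i = 0; i < n; ++i) {
    arma::mat x = as<arma::mat>(signals[i]);
    arma::cube h = cae_encode_cpp(x, W, b, linear);
    for (int k = 0; k < K; ++k) out(i, k) = arma::mean(arma::mean(h.slice(k)));
  }
  return out;
}
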