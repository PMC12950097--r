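// Fully-connected detection head: forward pass, backprop, Adam, early
// stopping. All randomness (weight init, per-epoch balanced index draws)
// happens on the R side, so this loop is deterministic given its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Single-pass Adam step over one parameter array (fused to avoid repeated
// memory sweeps; this update, not the GEMMs, dominates small-batch training).
static inline void adam_update(double* w, const double* g, double* m,
                               double* v, size_t n, double lr, double beta1,
                               double beta2, double eps, double bc1,
                               double bc2) {
  for (size_t i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

static arma::mat forward_all(const std::vector<arma::mat>& W,
                             const std::vector<arma::rowvec>& b,
                             const arma::mat& X) {
  arma::mat A = X;
  const size_t nl = W.size();
  for (size_t l = 0; l < nl; ++l) {
    A = A * W[l];
    A.each_row() += b[l];
    if (l + 1 < nl) {
      A = arma::clamp(A, 0.0, arma::datum::inf); // ReLU
    } else {
      A = 1.0 / (1.0 + arma::exp(-A));           // sigmoid
    }
  }
  return A;
}

// [[Rcpp::export]]
arma::mat mlp_forward_cpp(List W_, List b_, const arma::mat& X) {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
  for (int l = 0; l < W_.size(); ++l) {
    W.push_back(as<arma::mat>(W_[l]));
    b.push_back(as<arma::rowvec>(b_[l]));
  }
  return forward_all(W, b, X);
}

// [[Rcpp::export]]
List mlp_train_cpp(List W_, List b_,
                   const arma::mat& X, const arma::mat& Y,
                   const arma::mat& Xval, const arma::mat& Yval,
                   List epoch_idx, double lr, double l2,
                   IntegerVector l2_layers, int batch_size, int patience) {
  const int nl = W_.size();
  std::vector<arma::mat> W(nl);
  std::vector<arma::rowvec> b(nl);
  for (int l = 0; l < nl; ++l) {
    W[l] = as<arma::mat>(W_[l]);
    b[l] = as<arma::rowvec>(b_[l]);
  }
  std::vector<bool> reg(nl, false);
  for (int i = 0; i < l2_layers.size(); ++i) {
    int l = l2_layers[i] - 1;
    if (l >= 0 && l < nl) reg[l] = true;
  }

  // Adam state
  std::vector<arma::mat> mW(nl), vW(nl);
  std::vector<arma::rowvec> mb(nl), vb(nl);
  for (int l = 0; l < nl; ++l) {
    mW[l] = arma::zeros(arma::size(W[l])); vW[l] = mW[l];
    mb[l] = arma::zeros<arma::rowvec>(b[l].n_elem); vb[l] = mb[l];
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long long step = 0;

  const int max_epochs = epoch_idx.size();
  const int K = Y.n_cols;
  std::vector<double> tr_hist, val_hist;
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<arma::mat> bestW = W;
  std::vector<arma::rowvec> bestb = b;

  std::vector<arma::mat> A(nl + 1), D(nl);

  for (int e = 0; e < max_epochs; ++e) {
    arma::uvec idx = as<arma::uvec>(epoch_idx[e]) - 1; // 1-based from R
    const int ne = idx.n_elem;
    double sq_sum = 0.0;
    for (int start = 0; start < ne; start += batch_size) {
      const int stop = std::min(start + batch_size, ne) - 1;
      arma::uvec bi = idx.subvec(start, stop);
      const int nb = bi.n_elem;
      A[0] = X.rows(bi);
      for (int l = 0; l < nl; ++l) {
        A[l + 1] = A[l] * W[l];
        A[l + 1].each_row() += b[l];
        if (l + 1 < nl) A[l + 1] = arma::clamp(A[l + 1], 0.0, arma::datum::inf);
        else A[l + 1] = 1.0 / (1.0 + arma::exp(-A[l + 1]));
      }
      arma::mat Yb = Y.rows(bi);
      arma::mat diff = A[nl] - Yb;
      sq_sum += arma::accu(arma::square(diff));
      // MSE over all elements of the batch; sigmoid derivative at output
      arma::mat delta = diff % A[nl] % (1.0 - A[nl]) * (2.0 / (nb * K));
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, (double)step);
      const double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (int l = nl - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (reg[l]) gW += 2.0 * l2 * W[l];
        if (l > 0) {
          delta = delta * W[l].t();
          delta.elem(arma::find(A[l] <= 0.0)).zeros(); // ReLU gradient
        }
        adam_update(W[l].memptr(), gW.memptr(), mW[l].memptr(),
                    vW[l].memptr(), W[l].n_elem, lr, beta1, beta2, eps,
                    bc1, bc2);
        adam_update(b[l].memptr(), gb.memptr(), mb[l].memptr(),
                    vb[l].memptr(), b[l].n_elem, lr, beta1, beta2, eps,
                    bc1, bc2);
      }
    }
    const double tr_loss = sq_sum / ((double)ne * K);
    arma::mat Pv = forward_all(W, b, Xval);
    const double val_loss = arma::accu(arma::square(Pv - Yval)) /
      ((double)Yval.n_rows * K);
    tr_hist.push_back(tr_loss);
    val_hist.push_back(val_loss);
    epochs_run = e + 1;
    if (val_loss < best_val) {
      best_val = val_loss;
      best_epoch = e + 1;
      bestW = W; bestb = b;
      wait = 0;
    } else {
      ++wait;
      if (wait >= patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  List Wout(nl), bout(nl);
  for (int l = 0; l < nl; ++l) { Wout[l] = bestW[l]; bout[l] = bestb[l]; }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["train_loss"] = tr_hist, _["val_loss"] = val_hist,
                      _["best_epoch"] = best_epoch,
                      _["epochs_run"] = epochs_run,
                      _["best_val_loss"] = best_val);
}
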