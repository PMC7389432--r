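#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Fully-connected net: ReLU between hidden layers, sigmoid output.
// Weights[l]: d_{l-1} x d_l, biases[l]: d_l. Output layer has 1 unit.

static std::vector<mat> as_mat_list(Rcpp::List W) {
  std::vector<mat> out;
  for (int i = 0; i < W.size(); ++i)
    out.push_back(Rcpp::as<mat>(W[i]));
  return out;
}

static std::vector<rowvec> as_row_list(Rcpp::List b) {
  std::vector<rowvec> out;
  for (int i = 0; i < b.size(); ++i)
    out.push_back(Rcpp::as<rowvec>(b[i]));
  return out;
}

static mat forward_probs(const mat& X, const std::vector<mat>& W,
                         const std::vector<rowvec>& b) {
  mat A = X;
  size_t L = W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    A = A * W[l];
    A.each_row() += b[l];
    A = clamp(A, 0.0, datum::inf);  // ReLU
  }
  mat Z = A * W[L - 1];
  Z.each_row() += b[L - 1];
  return 1.0 / (1.0 + exp(-Z));
}

// [[Rcpp::export(name = ".mlp_forward_cpp")]]
arma::vec mlp_forward_cpp(const arma::mat& X, Rcpp::List weights,
                          Rcpp::List biases) {
  std::vector<mat> W = as_mat_list(weights);
  std::vector<rowvec> b = as_row_list(biases);
  return vectorise(forward_probs(X, W, b));
}

// Plain-SGD training with binary cross-entropy, chronological-tail
// validation split, and early stopping on validation accuracy.
// val_start: 0-based row where the validation block begins (rows
// [val_start, n) are validation; rows [0, val_start) are training).
// [[Rcpp::export(name = ".mlp_train_cpp")]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::vec& y,
                         Rcpp::List weights0, Rcpp::List biases0,
                         double lr, int max_epochs, int batch_size,
                         int patience, int val_start, double threshold,
                         int seed) {
  std::vector<mat> W = as_mat_list(weights0);
  std::vector<rowvec> b = as_row_list(biases0);
  const size_t L = W.size();
  const uword n_train = (uword)val_start;
  const mat Xtr = X.rows(0, n_train - 1);
  const vec ytr = y.subvec(0, n_train - 1);
  const mat Xval = X.rows(n_train, X.n_rows - 1);
  const vec yval = y.subvec(n_train, X.n_rows - 1);

  std::mt19937 rng((unsigned)seed);
  std::vector<uword> order(n_train);
  for (uword i = 0; i < n_train; ++i) order[i] = i;

  std::vector<mat> bestW = W;
  std::vector<rowvec> bestb = b;
  double best_acc = -1.0;
  int best_epoch = 0, stall = 0, epochs_run = 0;
  std::vector<double> loss_hist, acc_hist;

  std::vector<mat> A(L);       // post-activation per layer input
  std::vector<mat> Z(L);       // pre-activation (hidden only)

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0.0;
    uword seen = 0;
    for (uword start = 0; start < n_train; start += (uword)batch_size) {
      uword end = std::min(n_train, start + (uword)batch_size);
      uvec idx(end - start);
      for (uword k = start; k < end; ++k) idx[k - start] = order[k];
      mat Xb = Xtr.rows(idx);
      vec yb = ytr.elem(idx);
      double m = (double)Xb.n_rows;

      // forward, caching activations
      mat cur = Xb;
      for (size_t l = 0; l + 1 < L; ++l) {
        A[l] = cur;
        Z[l] = cur * W[l];
        Z[l].each_row() += b[l];
        cur = clamp(Z[l], 0.0, datum::inf);
      }
      A[L - 1] = cur;
      mat zo = cur * W[L - 1];
      zo.each_row() += b[L - 1];
      vec p = 1.0 / (1.0 + exp(-vectorise(zo)));

      vec pc = clamp(p, 1e-12, 1.0 - 1e-12);
      loss_sum += accu(-yb % log(pc) - (1.0 - yb) % log(1.0 - pc));
      seen += Xb.n_rows;

      // backward: sigmoid + BCE gives delta = p - y at the output
      mat delta = (p - yb) / m;           // m x 1
      for (int l = (int)L - 1; l >= 0; --l) {
        mat gW = A[l].t() * delta;
        rowvec gb = sum(delta, 0);
        if (l > 0) {
          delta = delta * W[l].t();
          delta %= conv_to<mat>::from(Z[l - 1] > 0.0);  // ReLU'
        }
        W[l] -= lr * gW;
        b[l] -= lr * gb;
      }
    }
    epochs_run = epoch;
    loss_hist.push_back(loss_sum / (double)seen);

    vec pv = vectorise(forward_probs(Xval, W, b));
    vec predv = conv_to<vec>::from(pv > threshold);
    double acc = accu(predv == yval) / (double)yval.n_elem;
    acc_hist.push_back(acc);

    if (acc > best_acc) {            // strict: "did not increase" resets
      best_acc = acc;
      best_epoch = epoch;
      bestW = W;
      bestb = b;
      stall = 0;
    } else if (++stall >= patience) {
      break;
    }
  }

  Rcpp::List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = bestW[l];
    bout[l] = bestb[l];
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = Wout,
      Rcpp::Named("biases") = bout,
      Rcpp::Named("best_epoch") = best_epoch,
      Rcpp::Named("best_val_accuracy") = best_acc,
      Rcpp::Named("epochs_run") = epochs_run,
      Rcpp::Named("train_loss") = loss_hist,
      Rcpp::Named("val_accuracy") = acc_hist);
}
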