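// Fully connected feed-forward regressor used as the reflectance surrogate:
// leaky-ReLU hidden layers, sigmoid output, MSE loss, AdamW updates with
// decoupled weight decay, and halve-on-plateau learning-rate scheduling.
// Training runs in 32-bit floats; weights are exchanged with R as doubles.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

#include <cstdint>
#include <random>

using namespace Rcpp;

typedef std::vector<arma::fmat> WList;
typedef std::vector<arma::frowvec> BList;

static void forward_pass(const arma::fmat &X, const WList &W, const BList &b,
                         float slope, std::vector<arma::fmat> &acts) {
  // acts[0] = input, acts[k] = activation after layer k
  size_t nl = W.size();
  acts.resize(nl + 1);
  acts[0] = X;
  for (size_t k = 0; k < nl; ++k) {
    arma::fmat Z = acts[k] * W[k];
    Z.each_row() += b[k];
    if (k + 1 < nl) {
      // leaky ReLU
      acts[k + 1] = arma::max(Z, slope * Z);
    } else {
      acts[k + 1] = 1.0f / (1.0f + arma::exp(-Z));  // sigmoid output
    }
  }
}

static arma::fvec predict_f(const arma::fmat &X, const WList &W,
                            const BList &b, float slope) {
  std::vector<arma::fmat> acts;
  forward_pass(X, W, b, slope, acts);
  return acts.back().col(0);
}

static void r_to_net(const List &weights, const List &biases, WList &W,
                     BList &b) {
  int nl = weights.size();
  W.resize(nl);
  b.resize(nl);
  for (int k = 0; k < nl; ++k) {
    W[k] = arma::conv_to<arma::fmat>::from(
        as<arma::mat>(weights[k]));
    b[k] = arma::conv_to<arma::frowvec>::from(
        as<arma::rowvec>(biases[k]));
  }
}

// [[Rcpp::export]]
NumericVector mlp_predict_cpp(NumericMatrix X, List weights, List biases,
                              double slope) {
  WList W;
  BList b;
  r_to_net(weights, biases, W, b);
  arma::fmat Xf = arma::conv_to<arma::fmat>::from(as<arma::mat>(X));
  arma::fvec y = predict_f(Xf, W, b, static_cast<float>(slope));
  return wrap(arma::conv_to<arma::vec>::from(y));
}

// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix X, NumericVector y, NumericMatrix Xval,
                   NumericVector yval, List weights0, List biases0,
                   double slope, double lr0, double weight_decay,
                   int batch_size, int max_epochs, int plateau_patience,
                   double lr_factor, double min_lr, int seed) {
  WList W, mW, vW;
  BList b, mB, vB;
  r_to_net(weights0, biases0, W, b);
  const size_t nl = W.size();
  mW.resize(nl);
  vW.resize(nl);
  mB.resize(nl);
  vB.resize(nl);
  for (size_t k = 0; k < nl; ++k) {
    mW[k].zeros(W[k].n_rows, W[k].n_cols);
    vW[k].zeros(W[k].n_rows, W[k].n_cols);
    mB[k].zeros(b[k].n_elem);
    vB[k].zeros(b[k].n_elem);
  }

  arma::fmat Xf = arma::conv_to<arma::fmat>::from(as<arma::mat>(X));
  arma::fvec yf = arma::conv_to<arma::fvec>::from(as<arma::vec>(y));
  arma::fmat Xvf = arma::conv_to<arma::fmat>::from(as<arma::mat>(Xval));
  arma::fvec yvf = arma::conv_to<arma::fvec>::from(as<arma::vec>(yval));

  const float sl = static_cast<float>(slope);
  const float beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  double lr = lr0;
  const arma::uword n = Xf.n_rows;
  std::mt19937_64 rng(static_cast<uint64_t>(static_cast<uint32_t>(seed)) *
                          0x9E3779B97F4A7C15ULL +
                      1ULL);

  std::vector<arma::uword> order(n);
  for (arma::uword i = 0; i < n; ++i) order[i] = i;

  std::vector<double> val_history;
  double best_val = R_PosInf;
  int since_improve = 0;
  long step = 0;
  int epochs_run = 0;

  std::vector<arma::fmat> acts;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (arma::uword start = 0; start < n;
         start += static_cast<arma::uword>(batch_size)) {
      arma::uword end = std::min(n, start + static_cast<arma::uword>(batch_size));
      arma::uvec idx(end - start);
      for (arma::uword i = start; i < end; ++i) idx[i - start] = order[i];
      arma::fmat Xb = Xf.rows(idx);
      arma::fvec yb = yf.elem(idx);
      const float bsz = static_cast<float>(Xb.n_rows);

      forward_pass(Xb, W, b, sl, acts);
      // MSE loss: dL/dpred = 2 (pred - y) / batch
      arma::fvec pred = acts[nl].col(0);
      arma::fmat delta = (2.0f / bsz) * (pred - yb);
      // through sigmoid
      delta %= pred % (1.0f - pred);

      ++step;
      const float lrf = static_cast<float>(lr);
      const float bc1 = 1.0f - std::pow(beta1, static_cast<float>(step));
      const float bc2 = 1.0f - std::pow(beta2, static_cast<float>(step));
      const float wdf = static_cast<float>(weight_decay);

      for (int k = static_cast<int>(nl) - 1; k >= 0; --k) {
        arma::fmat gW = acts[k].t() * delta;
        arma::frowvec gB = arma::sum(delta, 0);
        if (k > 0) {
          arma::fmat back = delta * W[k].t();
          // derivative of leaky ReLU at the stored activation
          arma::fmat dact =
              arma::conv_to<arma::fmat>::from(acts[k] > 0.0f) * (1.0f - sl) +
              sl;
          delta = back % dact;
        }
        // AdamW with decoupled weight decay (decay on weights only)
        mW[k] = beta1 * mW[k] + (1.0f - beta1) * gW;
        vW[k] = beta2 * vW[k] + (1.0f - beta2) * (gW % gW);
        W[k] -= lrf * ((mW[k] / bc1) / (arma::sqrt(vW[k] / bc2) + eps) +
                       wdf * W[k]);
        mB[k] = beta1 * mB[k] + (1.0f - beta1) * gB;
        vB[k] = beta2 * vB[k] + (1.0f - beta2) * (gB % gB);
        b[k] -= lrf * (mB[k] / bc1) / (arma::sqrt(vB[k] / bc2) + eps);
      }
    }
    ++epochs_run;

    arma::fvec pv = predict_f(Xvf, W, b, sl);
    double vloss = arma::mean(arma::square(
        arma::conv_to<arma::vec>::from(pv - yvf)));
    val_history.push_back(vloss);
    if (!std::isfinite(vloss)) {
      stop("validation loss became non-finite at epoch %d (lr=%g)", epoch + 1,
           lr);
    }
    if (vloss < best_val * (1.0 - 1e-4)) {
      best_val = vloss;
      since_improve = 0;
    } else if (++since_improve >= plateau_patience) {
      lr = std::max(min_lr, lr * lr_factor);  // halve on validation plateau
      since_improve = 0;
    }
  }

  List Wout(nl), Bout(nl);
  for (size_t k = 0; k < nl; ++k) {
    Wout[k] = wrap(arma::conv_to<arma::mat>::from(W[k]));
    Bout[k] = wrap(arma::conv_to<arma::rowvec>::from(b[k]));
  }
  return List::create(_["weights"] = Wout, _["biases"] = Bout,
                      _["val_loss"] = wrap(val_history),
                      _["epochs"] = epochs_run, _["final_lr"] = lr,
                      _["final_val_loss"] = val_history.back());
}

// Exact nearest neighbour under mean-absolute-error distance.
// Returns 1-based index of the closest row of B for every row of A, with the
// distance; ties break to the lowest index (strict < comparison).
// [[Rcpp::export]]
List nn_mae_cpp(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow(), k = A.ncol();
  IntegerVector idx(na);
  NumericVector dist(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    int besti = -1;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int c = 0; c < k; ++c) {
        s += std::fabs(A(i, c) - B(j, c));
        if (s >= best * k) break;  // partial sums only grow
      }
      double d = s / k;
      if (d < best) {
        best = d;
        besti = j;
      }
    }
    idx[i] = besti + 1;
    dist[i] = best;
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
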