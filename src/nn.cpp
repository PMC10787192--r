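// Dense feed-forward networks used by the response predictor (linear output,
// MSE loss) and the contribution-score explainer (softmax output, KL loss).
// Single-threaded, fully deterministic given the seed: weight initialization,
// minibatch shuffling and dropout masks all draw from one std::mt19937_64.

#include <RcppArmadillo.h>
#include <random>
#include <vector>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Net {
  std::vector<arma::mat> W;   // W[l]: d_l x d_{l+1}
  std::vector<arma::rowvec> b;
};

Net net_from_list(const List& weights, const List& biases) {
  Net net;
  for (int l = 0; l < weights.size(); ++l) {
    net.W.push_back(as<arma::mat>(weights[l]));
    arma::vec bv = as<arma::vec>(biases[l]);
    net.b.push_back(bv.t());
  }
  return net;
}

List net_to_list(const Net& net, List& weights, List& biases) {
  for (size_t l = 0; l < net.W.size(); ++l) {
    weights[l] = net.W[l];
    biases[l] = arma::vec(net.b[l].t());
  }
  return List::create(Named("weights") = weights, Named("biases") = biases);
}

arma::mat softmax_rows(const arma::mat& Z) {
  arma::vec m = arma::max(Z, 1);
  arma::mat E = arma::exp(Z.each_col() - m);
  arma::vec s = arma::sum(E, 1);
  return E.each_col() / s;
}

// Forward pass storing post-activation values A[0] = X, ..., A[L] = output.
// output_type: 0 linear, 1 softmax (row-wise).
void forward_full(const Net& net, const arma::mat& X, int output_type,
                  std::vector<arma::mat>& A) {
  const size_t L = net.W.size();
  A.resize(L + 1);
  A[0] = X;
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = A[l] * net.W[l];
    Z.each_row() += net.b[l];
    if (l + 1 < L) {
      A[l + 1] = arma::clamp(Z, 0.0, arma::datum::inf);  // ReLU
    } else {
      A[l + 1] = (output_type == 1) ? softmax_rows(Z) : Z;
    }
  }
}

const double KL_EPS = 1e-8;

// Mean loss over the batch. MSE averages over all output elements; KL is the
// per-sample divergence sum_i t_i * (log t_i - log p_i), averaged over rows.
double loss_value(const arma::mat& pred, const arma::mat& Y, int output_type) {
  if (output_type == 1) {
    arma::mat lt = arma::log(Y + KL_EPS);
    arma::mat lp = arma::log(pred + KL_EPS);
    return arma::accu(Y % (lt - lp)) / static_cast<double>(Y.n_rows);
  }
  return arma::accu(arma::square(pred - Y)) /
         static_cast<double>(Y.n_rows * Y.n_cols);
}

struct Adam {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::rowvec> mb, vb;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net& net) {
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW.push_back(arma::zeros<arma::mat>(net.W[l].n_rows, net.W[l].n_cols));
      vW.push_back(arma::zeros<arma::mat>(net.W[l].n_rows, net.W[l].n_cols));
      mb.push_back(arma::zeros<arma::rowvec>(net.b[l].n_cols));
      vb.push_back(arma::zeros<arma::rowvec>(net.b[l].n_cols));
    }
  }
  void step(Net& net, const std::vector<arma::mat>& gW,
            const std::vector<arma::rowvec>& gb, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, t);
    const double c2 = 1.0 - std::pow(b2, t);
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW[l] = b1 * mW[l] + (1 - b1) * gW[l];
      vW[l] = b2 * vW[l] + (1 - b2) * arma::square(gW[l]);
      net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      mb[l] = b1 * mb[l] + (1 - b1) * gb[l];
      vb[l] = b2 * vb[l] + (1 - b2) * arma::square(gb[l]);
      net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".nn_init")]]
List nn_init(IntegerVector layer_sizes, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  const int L = layer_sizes.size() - 1;
  List weights(L), biases(L);
  for (int l = 0; l < L; ++l) {
    const int din = layer_sizes[l], dout = layer_sizes[l + 1];
    arma::mat W(din, dout);
    const double sd = std::sqrt(2.0 / static_cast<double>(din));  // He init
    for (int i = 0; i < din; ++i)
      for (int j = 0; j < dout; ++j) W(i, j) = sd * gauss(rng);
    weights[l] = W;
    biases[l] = arma::vec(dout, arma::fill::zeros);
  }
  return List::create(Named("weights") = weights, Named("biases") = biases);
}

// [[Rcpp::export(name = ".nn_forward")]]
arma::mat nn_forward(List weights, List biases, const arma::mat& X,
                     int output_type) {
  Net net = net_from_list(weights, biases);
  std::vector<arma::mat> A;
  forward_full(net, X, output_type, A);
  return A.back();
}

// [[Rcpp::export(name = ".nn_hidden")]]
arma::mat nn_hidden(List weights, List biases, const arma::mat& X) {
  Net net = net_from_list(weights, biases);
  std::vector<arma::mat> A;
  forward_full(net, X, 0, A);
  return A[A.size() - 2];  // last hidden, post-ReLU, pre-dropout
}

// Minibatch Adam training with optional inverted dropout on the last hidden
// layer and optional early stopping on a validation set (falls back to the
// training loss when no validation data are supplied). patience <= 0 disables
// early stopping; the best-loss weights are restored on return.
// [[Rcpp::export(name = ".nn_train")]]
List nn_train(const arma::mat& X, const arma::mat& Y, List init_weights,
              List init_biases, int output_type, double dropout_p, double lr,
              int batch_size, int max_epochs, int patience,
              Nullable<NumericMatrix> Xval, Nullable<NumericMatrix> Yval,
              int seed) {
  Net net = net_from_list(init_weights, init_biases);
  const size_t L = net.W.size();
  const arma::uword n = X.n_rows;
  if (Y.n_rows != n) stop("X and Y row counts differ");
  if (batch_size < 1) stop("batch_size must be >= 1");

  bool has_val = Xval.isNotNull() && Yval.isNotNull();
  arma::mat Xv, Yv;
  if (has_val) {
    Xv = as<arma::mat>(Xval.get());
    Yv = as<arma::mat>(Yval.get());
  }

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  Adam opt;
  opt.init(net);

  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> train_hist, val_hist;
  double best = arma::datum::inf;
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  Net best_net = net;

  std::vector<arma::mat> A;
  std::vector<arma::mat> gW(L);
  std::vector<arma::rowvec> gb(L);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (arma::uword start = 0; start < n; start += batch_size) {
      arma::uword end = std::min<arma::uword>(start + batch_size, n) - 1;
      arma::uvec rows(end - start + 1);
      for (arma::uword k = start; k <= end; ++k) rows[k - start] = idx[k];
      arma::mat Xb = X.rows(rows), Yb = Y.rows(rows);
      const double nb = static_cast<double>(Xb.n_rows);

      // forward with dropout on the last hidden layer
      A.resize(L + 1);
      A[0] = Xb;
      arma::mat drop_mask;
      for (size_t l = 0; l < L; ++l) {
        arma::mat Z = A[l] * net.W[l];
        Z.each_row() += net.b[l];
        if (l + 1 < L) {
          A[l + 1] = arma::clamp(Z, 0.0, arma::datum::inf);
          if (dropout_p > 0.0 && l + 2 == L) {  // hidden layer feeding output
            drop_mask.set_size(Z.n_rows, Z.n_cols);
            const double keep = 1.0 - dropout_p;
            for (arma::uword i = 0; i < Z.n_rows; ++i)
              for (arma::uword j = 0; j < Z.n_cols; ++j)
                drop_mask(i, j) = (unif(rng) < keep) ? 1.0 / keep : 0.0;
            A[l + 1] %= drop_mask;
          }
        } else {
          A[l + 1] = (output_type == 1) ? softmax_rows(Z) : Z;
        }
      }

      // backward
      arma::mat dZ;
      if (output_type == 1) {
        dZ = (A[L] - Yb) / nb;  // softmax + KL(target || pred)
      } else {
        dZ = 2.0 * (A[L] - Yb) / (nb * static_cast<double>(Yb.n_cols));
      }
      for (size_t l = L; l-- > 0;) {
        gW[l] = A[l].t() * dZ;
        gb[l] = arma::sum(dZ, 0);
        if (l > 0) {
          arma::mat dA = dZ * net.W[l].t();
          if (dropout_p > 0.0 && l + 1 == L) dA %= drop_mask;
          dZ = dA % (A[l] > 0);
        }
      }
      if (!gW[0].is_finite()) stop("non-finite gradient at epoch %d", epoch);
      opt.step(net, gW, gb, lr);
    }

    std::vector<arma::mat> Af;
    forward_full(net, X, output_type, Af);
    double tr_loss = loss_value(Af.back(), Y, output_type);
    if (!std::isfinite(tr_loss)) stop("non-finite loss at epoch %d", epoch);
    train_hist.push_back(tr_loss);
    double monitored = tr_loss;
    if (has_val) {
      forward_full(net, Xv, output_type, Af);
      double v = loss_value(Af.back(), Yv, output_type);
      val_hist.push_back(v);
      monitored = v;
    }
    epochs_run = epoch;
    if (monitored < best) {
      best = monitored;
      best_epoch = epoch;
      since_best = 0;
      if (patience > 0) best_net = net;
    } else {
      ++since_best;
    }
    if (patience > 0 && since_best >= patience) break;
  }

  if (patience > 0) net = best_net;
  List weights(L), biases(L);
  net_to_list(net, weights, biases);
  return List::create(
      Named("weights") = weights, Named("biases") = biases,
      Named("train_loss") = train_hist, Named("val_loss") = val_hist,
      Named("best_epoch") = best_epoch, Named("epochs_run") = epochs_run,
      Named("best_loss") = best);
}

// Loss and analytic gradients at the supplied weights (no dropout, full
// batch) — used to validate backpropagation against finite differences.
// [[Rcpp::export(name = ".nn_loss_grad")]]
List nn_loss_grad(List weights, List biases, const arma::mat& X,
                  const arma::mat& Y, int output_type) {
  Net net = net_from_list(weights, biases);
  const size_t L = net.W.size();
  std::vector<arma::mat> A;
  forward_full(net, X, output_type, A);
  const double nb = static_cast<double>(X.n_rows);
  double loss = loss_value(A.back(), Y, output_type);
  arma::mat dZ;
  if (output_type == 1) {
    dZ = (A[L] - Y) / nb;
  } else {
    dZ = 2.0 * (A[L] - Y) / (nb * static_cast<double>(Y.n_cols));
  }
  List gW(L), gb(L);
  for (size_t l = L; l-- > 0;) {
    gW[l] = arma::mat(A[l].t() * dZ);
    gb[l] = arma::vec(arma::sum(dZ, 0).t());
    if (l > 0) dZ = (dZ * net.W[l].t()) % (A[l] > 0);
  }
  return List::create(Named("loss") = loss, Named("gradWeights") = gW,
                      Named("gradBiases") = gb);
}
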