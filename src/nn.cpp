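#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Forward pass for one probe. weights[l] is (n_{l+1} x (n_l + bias)).
// Returns activations for every layer (input layer = the probe itself).
static std::vector<std::vector<double>> forward_one(
    const std::vector<NumericMatrix>& W, const double* x, int n_in,
    bool bias) {
  std::vector<std::vector<double>> act(W.size() + 1);
  act[0].assign(x, x + n_in);
  for (size_t l = 0; l < W.size(); ++l) {
    const NumericMatrix& w = W[l];
    int n_out = w.nrow();
    int n_src = act[l].size();
    std::vector<double> out(n_out);
    for (int i = 0; i < n_out; ++i) {
      double z = 0.0;
      for (int j = 0; j < n_src; ++j) z += w(i, j) * act[l][j];
      if (bias) z += w(i, n_src);  // constant-unit input, activation 1
      out[i] = sigm(z);
    }
    act[l + 1] = out;
  }
  return act;
}

// [[Rcpp::export]]
NumericMatrix cpp_nn_forward(List weights, NumericMatrix X, bool bias) {
  std::vector<NumericMatrix> W(weights.size());
  for (int l = 0; l < weights.size(); ++l) W[l] = as<NumericMatrix>(weights[l]);
  int n = X.nrow(), p = X.ncol();
  int n_out = W.back().nrow();
  NumericMatrix out(n, n_out);
  std::vector<double> x(p);
  for (int r = 0; r < n; ++r) {
    for (int j = 0; j < p; ++j) x[j] = X(r, j);
    std::vector<std::vector<double>> act = forward_one(W, x.data(), p, bias);
    for (int i = 0; i < n_out; ++i) out(r, i) = act.back()[i];
  }
  return out;
}

// Online (per-probe) backpropagation training with sigmoid activations and
// squared-error/2 objective. All weight deltas for a probe are computed
// from the pre-update weights, then applied. `orders` holds one shuffled
// 1-based probe order per epoch (n x epochs), drawn in R so the weight
// trajectory is identical to repeated R-level update steps under the same
// RNG state.
// [[Rcpp::export]]
List cpp_nn_train(List weights, NumericMatrix X, NumericMatrix Y,
                  double alpha, int epochs, double tol, bool bias,
                  IntegerMatrix orders) {
  int n = X.nrow(), p = X.ncol(), q = Y.ncol();
  int L = weights.size();
  std::vector<NumericMatrix> W(L);
  for (int l = 0; l < L; ++l) W[l] = clone(as<NumericMatrix>(weights[l]));

  std::vector<double> loss_trace;
  loss_trace.reserve(epochs);
  double prev_loss = R_PosInf;
  long long iters = 0;
  int epochs_run = 0;
  std::vector<double> x(p), y(q);

  if (orders.nrow() != n || orders.ncol() < epochs)
    stop("orders must be an n x epochs matrix of probe indices");
  for (int e = 0; e < epochs; ++e) {
    double loss = 0.0;
    for (int s = 0; s < n; ++s) {
      int r = orders(s, e) - 1;
      for (int j = 0; j < p; ++j) x[j] = X(r, j);
      for (int i = 0; i < q; ++i) y[i] = Y(r, i);
      std::vector<std::vector<double>> act = forward_one(W, x.data(), p, bias);

      // deltas, output layer first
      std::vector<std::vector<double>> delta(L + 1);
      delta[L].resize(q);
      for (int i = 0; i < q; ++i) {
        double eps = y[i] - act[L][i];
        loss += 0.5 * eps * eps;
        delta[L][i] = eps * act[L][i] * (1.0 - act[L][i]);
      }
      for (int l = L - 1; l >= 1; --l) {
        int nl = act[l].size();
        delta[l].assign(nl, 0.0);
        const NumericMatrix& w = W[l];
        for (int j = 0; j < nl; ++j) {
          double acc = 0.0;
          for (size_t i = 0; i < delta[l + 1].size(); ++i)
            acc += delta[l + 1][i] * w(i, j);
          delta[l][j] = acc * act[l][j] * (1.0 - act[l][j]);
        }
      }
      // apply updates (all deltas used pre-update weights)
      for (int l = 0; l < L; ++l) {
        NumericMatrix& w = W[l];
        int n_src = act[l].size();
        for (size_t i = 0; i < delta[l + 1].size(); ++i) {
          double d = alpha * delta[l + 1][i];
          for (int j = 0; j < n_src; ++j) w(i, j) += d * act[l][j];
          if (bias) w(i, n_src) += d;
        }
      }
      ++iters;
    }
    if (!R_finite(loss)) stop("non-finite training loss at epoch %d", e + 1);
    loss_trace.push_back(loss);
    ++epochs_run;
    if (std::fabs(prev_loss - loss) < tol) break;
    prev_loss = loss;
  }

  List Wout(L);
  for (int l = 0; l < L; ++l) Wout[l] = W[l];
  return List::create(_["weights"] = Wout,
                      _["loss_trace"] = NumericVector(loss_trace.begin(),
                                                      loss_trace.end()),
                      _["epochs_run"] = epochs_run,
                      _["iterations"] = (double)iters);
}
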