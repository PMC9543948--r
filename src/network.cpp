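// Feed-forward inverse-control network: forward pass, backpropagation and a
// seeded mini-batch training loop (Adam / RMSprop) with optional persistent
// binary masks (applied in both the forward pass and the gradient update)
// and optional per-epoch manual re-zeroing of the smallest-magnitude kernel
// weights. Hidden activation: arctangent; output activation: identity.
// Loss: mean of squared errors over all samples and outputs jointly.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

typedef std::vector<arma::mat> MatList;
typedef std::vector<arma::vec> VecList;

static MatList as_matlist(const List& x) {
  MatList out;
  for (int i = 0; i < x.size(); ++i)
    out.push_back(as<arma::mat>(x[i]));
  return out;
}

static VecList as_veclist(const List& x) {
  VecList out;
  for (int i = 0; i < x.size(); ++i)
    out.push_back(as<arma::vec>(x[i]));
  return out;
}

// forward pass on columns-as-samples input; returns activations per layer
// (A[0] = input). Z caches pre-activations for backprop.
static void fwd(const MatList& W, const VecList& b, const arma::mat& A0,
                MatList& A, MatList& Z) {
  const size_t L = W.size();
  A.assign(L + 1, arma::mat());
  Z.assign(L, arma::mat());
  A[0] = A0;
  for (size_t l = 0; l < L; ++l) {
    Z[l] = W[l] * A[l];
    Z[l].each_col() += b[l];
    A[l + 1] = (l + 1 < L) ? arma::atan(Z[l]) : Z[l];
  }
}

static double loss_of(const MatList& W, const VecList& b,
                      const arma::mat& X, const arma::mat& Y) {
  const size_t L = W.size();
  arma::mat A = X;
  for (size_t l = 0; l < L; ++l) {
    arma::mat Z = W[l] * A;
    Z.each_col() += b[l];
    A = (l + 1 < L) ? arma::atan(Z) : Z;
  }
  const arma::mat D = A - Y;
  return arma::accu(D % D) / D.n_elem;
}

// backprop; fills dW/db, returns batch loss
static double backprop(const MatList& W, const VecList& b,
                       const arma::mat& Xb, const arma::mat& Yb,
                       MatList& dW, VecList& db) {
  const size_t L = W.size();
  MatList A, Z;
  fwd(W, b, Xb, A, Z);
  const arma::mat D = A[L] - Yb;
  const double loss = arma::accu(D % D) / D.n_elem;
  arma::mat dZ = (2.0 / D.n_elem) * D;
  for (size_t l = L; l-- > 0;) {
    dW[l] = dZ * A[l].t();
    db[l] = arma::sum(dZ, 1);
    if (l > 0) {
      arma::mat dA = W[l].t() * dZ;
      dZ = dA % (1.0 / (1.0 + arma::square(Z[l - 1])));
    }
  }
  return loss;
}

// zero the n_zero smallest-|w| kernel entries across all layers,
// ties broken by (layer, row, column)
static void rezero_smallest(MatList& W, int n_zero) {
  if (n_zero <= 0) return;
  struct Ent { double mag; int layer; int row; int col; };
  std::vector<Ent> ents;
  size_t total = 0;
  for (size_t l = 0; l < W.size(); ++l) total += W[l].n_elem;
  ents.reserve(total);
  for (size_t l = 0; l < W.size(); ++l)
    for (arma::uword c = 0; c < W[l].n_cols; ++c)
      for (arma::uword r = 0; r < W[l].n_rows; ++r)
        ents.push_back({std::fabs(W[l](r, c)), (int)l, (int)r, (int)c});
  if ((size_t)n_zero > ents.size()) n_zero = (int)ents.size();
  auto cmp = [](const Ent& a, const Ent& b) {
    if (a.mag != b.mag) return a.mag < b.mag;
    if (a.layer != b.layer) return a.layer < b.layer;
    if (a.row != b.row) return a.row < b.row;
    return a.col < b.col;
  };
  std::partial_sort(ents.begin(), ents.begin() + n_zero, ents.end(), cmp);
  for (int i = 0; i < n_zero; ++i)
    W[ents[i].layer](ents[i].row, ents[i].col) = 0.0;
}

//' @noRd
// [[Rcpp::export(name = ".forward_mlp_cpp")]]
NumericMatrix forward_mlp_cpp(List weights, List biases,
                              Nullable<List> masks, NumericMatrix X) {
  MatList W = as_matlist(weights);
  VecList b = as_veclist(biases);
  if (masks.isNotNull()) {
    MatList M = as_matlist(masks.get());
    for (size_t l = 0; l < W.size(); ++l) W[l] %= M[l];
  }
  arma::mat Xt = as<arma::mat>(X).t();
  MatList A, Z;
  fwd(W, b, Xt, A, Z);
  return wrap(arma::mat(A[W.size()].t()));
}

//' @noRd
// [[Rcpp::export(name = ".grad_mlp_cpp")]]
List grad_mlp_cpp(List weights, List biases, Nullable<List> masks,
                  NumericMatrix X, NumericMatrix Y) {
  MatList W = as_matlist(weights);
  VecList b = as_veclist(biases);
  bool masked = masks.isNotNull();
  MatList M;
  if (masked) {
    M = as_matlist(masks.get());
    for (size_t l = 0; l < W.size(); ++l) W[l] %= M[l];
  }
  arma::mat Xt = as<arma::mat>(X).t();
  arma::mat Yt = as<arma::mat>(Y).t();
  MatList dW(W.size());
  VecList db(W.size());
  double loss = backprop(W, b, Xt, Yt, dW, db);
  if (masked)
    for (size_t l = 0; l < W.size(); ++l) dW[l] %= M[l];
  List dWl(W.size()), dbl(W.size());
  for (size_t l = 0; l < W.size(); ++l) {
    dWl[l] = wrap(dW[l]);
    dbl[l] = wrap(db[l]);
  }
  return List::create(_["loss"] = loss, _["dW"] = dWl, _["db"] = dbl);
}

//' @noRd
// [[Rcpp::export(name = ".train_mlp_cpp")]]
List train_mlp_cpp(List weights, List biases, Nullable<List> masks_,
                   NumericMatrix X, NumericMatrix Y,
                   Nullable<NumericMatrix> Xval_, Nullable<NumericMatrix> Yval_,
                   std::string optimizer, double lr, int batch_size,
                   int max_epochs, double min_delta, int patience,
                   int eval_every, int monitor_cap, int seed, int rezero_n) {
  MatList W = as_matlist(weights);
  VecList b = as_veclist(biases);
  const size_t L = W.size();
  const bool masked = masks_.isNotNull();
  MatList M;
  if (masked) {
    M = as_matlist(masks_.get());
    for (size_t l = 0; l < L; ++l) W[l] %= M[l];
  }

  arma::mat Xt = as<arma::mat>(X).t();  // features x samples
  arma::mat Yt = as<arma::mat>(Y).t();
  const int n = (int)Xt.n_cols;

  // monitored set: validation when supplied, else an evenly spaced
  // training subsample of at most monitor_cap rows
  arma::mat Xm, Ym;
  if (Xval_.isNotNull()) {
    Xm = as<arma::mat>(Xval_.get()).t();
    Ym = as<arma::mat>(Yval_.get()).t();
  } else if (monitor_cap > 0 && n > monitor_cap) {
    arma::uvec idx(monitor_cap);
    for (int i = 0; i < monitor_cap; ++i)
      idx(i) = (arma::uword)(((long long)i * n) / monitor_cap);
    Xm = Xt.cols(idx);
    Ym = Yt.cols(idx);
  } else {
    Xm = Xt;
    Ym = Yt;
  }

  // optimizer state
  MatList mW(L), vW(L), dW(L);
  VecList mb(L), vb(L), db(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  const bool adam = (optimizer == "adam");
  const double b1 = 0.9, b2 = 0.999, rho = 0.9, eps = 1e-8;
  long long t_adam = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> hist_batch, hist_loss;
  double best = loss_of(W, b, Xm, Ym);
  hist_batch.push_back(0.0);
  hist_loss.push_back(best);
  int since_improve = 0;
  long long batch_count = 0;
  bool stop_now = false, diverged = false;

  for (int epoch = 0; epoch < max_epochs && !stop_now; ++epoch) {
    if (rezero_n > 0) rezero_smallest(W, rezero_n);
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n && !stop_now; start += batch_size) {
      const int m = std::min(batch_size, n - start);
      arma::uvec idx(m);
      for (int i = 0; i < m; ++i) idx(i) = (arma::uword)order[start + i];
      arma::mat Xb = Xt.cols(idx), Yb = Yt.cols(idx);
      double bl = backprop(W, b, Xb, Yb, dW, db);
      if (!std::isfinite(bl)) { diverged = true; stop_now = true; break; }
      if (masked)
        for (size_t l = 0; l < L; ++l) dW[l] %= M[l];
      ++t_adam;
      for (size_t l = 0; l < L; ++l) {
        if (adam) {
          mW[l] = b1 * mW[l] + (1 - b1) * dW[l];
          vW[l] = b2 * vW[l] + (1 - b2) * arma::square(dW[l]);
          mb[l] = b1 * mb[l] + (1 - b1) * db[l];
          vb[l] = b2 * vb[l] + (1 - b2) * arma::square(db[l]);
          const double c1 = 1.0 - std::pow(b1, (double)t_adam);
          const double c2 = 1.0 - std::pow(b2, (double)t_adam);
          W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
          b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
        } else {  // rmsprop
          vW[l] = rho * vW[l] + (1 - rho) * arma::square(dW[l]);
          vb[l] = rho * vb[l] + (1 - rho) * arma::square(db[l]);
          W[l] -= lr * dW[l] / (arma::sqrt(vW[l]) + eps);
          b[l] -= lr * db[l] / (arma::sqrt(vb[l]) + eps);
        }
        if (masked) W[l] %= M[l];  // keep pruned weights bit-exact zero
      }
      ++batch_count;
      if (batch_count % eval_every == 0) {
        const double mon = loss_of(W, b, Xm, Ym);
        hist_batch.push_back((double)batch_count);
        hist_loss.push_back(mon);
        if (!std::isfinite(mon)) { diverged = true; stop_now = true; break; }
        if (mon < best - min_delta) {
          best = mon;
          since_improve = 0;
        } else {
          since_improve += eval_every;
          if (since_improve >= patience) stop_now = true;
        }
        if (mon < best) best = mon;  // track best even below min_delta
      }
    }
  }

  if (rezero_n > 0) rezero_smallest(W, rezero_n);  // final zeroing state

  List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) {
    Wl[l] = wrap(W[l]);
    bl[l] = wrap(b[l]);
  }
  arma::mat hist(hist_batch.size(), 2);
  for (size_t i = 0; i < hist_batch.size(); ++i) {
    hist(i, 0) = hist_batch[i];
    hist(i, 1) = hist_loss[i];
  }
  const double fin = loss_of(W, b, Xm, Ym);
  return List::create(_["weights"] = Wl, _["biases"] = bl,
                      _["history"] = wrap(hist),
                      _["batches"] = (double)batch_count,
                      _["monitored_loss"] = fin,
                      _["best_loss"] = best,
                      _["diverged"] = diverged);
}
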