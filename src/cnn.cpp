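// Minimal multi-task 1D CNN trainer used for the simulation study:
// 3 same-padded conv layers (ReLU) -> global max pool -> 2 ReLU hidden
// layers -> linear 2-task output, trained with Adam on an MSE loss.
// Written against column-major Armadillo; activations are stored as
// (channels x batch*length) so im2col columns are contiguous.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>

using namespace Rcpp;
using namespace arma;

namespace {

struct Hyper {
  int K, F, H1, H2, L;
  double lr;
  int batch, max_epochs, patience;
};

// first conv layer applied straight to integer base codes (1..4): the
// input is one-hot, so the convolution is a gather of weight columns.
// Wt is the transposed weight matrix (F x K*4); columns are contiguous.
void conv_codes_forward(const Mat<int>& X, const std::vector<uword>& idx,
                        const mat& Wt, const vec& b, int K, mat& A) {
  const int L = X.n_cols, pad = K / 2, F = Wt.n_rows;
  for (uword s = 0; s < idx.size(); ++s) {
    const uword r = idx[s];
    for (int p = 0; p < L; ++p) {
      double* dst = A.colptr(s * L + p);
      std::memcpy(dst, b.memptr(), F * sizeof(double));
      for (int k = 0; k < K; ++k) {
        const int q = p + k - pad;
        if (q < 0 || q >= L) continue;
        const double* wc = Wt.colptr((uword)k * 4 + (X(r, q) - 1));
        for (int f = 0; f < F; ++f) dst[f] += wc[f];
      }
    }
  }
}

// gradient of the first conv layer's weights, same gather pattern
void conv_codes_backward(const Mat<int>& X, const std::vector<uword>& idx,
                         const mat& dZ, int K, mat& dWt) {
  const int L = X.n_cols, pad = K / 2, F = dZ.n_rows;
  dWt.zeros();
  for (uword s = 0; s < idx.size(); ++s) {
    const uword r = idx[s];
    for (int p = 0; p < L; ++p) {
      const double* src = dZ.colptr(s * L + p);
      for (int k = 0; k < K; ++k) {
        const int q = p + k - pad;
        if (q < 0 || q >= L) continue;
        double* wc = dWt.colptr((uword)k * 4 + (X(r, q) - 1));
        for (int f = 0; f < F; ++f) wc[f] += src[f];
      }
    }
  }
}

void im2col_feat(const mat& A, int B, int L, int K, mat& M) {
  const int C = A.n_rows, pad = K / 2;
  M.zeros();
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < L; ++p) {
      double* dst = M.colptr((uword)b * L + p);
      for (int k = 0; k < K; ++k) {
        const int q = p + k - pad;
        if (q >= 0 && q < L)
          std::memcpy(dst + (uword)k * C, A.colptr((uword)b * L + q),
                      C * sizeof(double));
      }
    }
}

void col2im_feat(const mat& dM, int B, int L, int K, mat& dA) {
  const int C = dA.n_rows, pad = K / 2;
  dA.zeros();
  for (int b = 0; b < B; ++b)
    for (int p = 0; p < L; ++p) {
      const double* src = dM.colptr((uword)b * L + p);
      for (int k = 0; k < K; ++k) {
        const int q = p + k - pad;
        if (q < 0 || q >= L) continue;
        double* dst = dA.colptr((uword)b * L + q);
        for (int c = 0; c < C; ++c) dst[c] += src[(uword)k * C + c];
      }
    }
}

struct Cache {
  mat W1t;                    // transposed first-layer weights (F x K*4)
  mat A1, M2, A2, M3, A3;     // conv stages, (channels x B*L)
  Mat<uword> amax;            // pool argmax, B x F
  mat H, A4, A5, out;         // pooled + dense stages, row-per-sample
  int B;
};

void forward(const std::vector<mat>& P, const Mat<int>& X,
             const std::vector<uword>& idx, const Hyper& h, Cache& C) {
  const int B = (int)idx.size(), L = h.L, F = h.F, K = h.K;
  const uword BL = (uword)B * L;
  C.B = B;
  C.W1t = P[0].t();
  C.A1.set_size(F, BL);
  conv_codes_forward(X, idx, C.W1t, P[1].col(0), K, C.A1);
  C.A1.transform([](double v) { return v > 0 ? v : 0.0; });

  C.M2.set_size((uword)K * F, BL);
  im2col_feat(C.A1, B, L, K, C.M2);
  C.A2 = P[2].t() * C.M2;
  C.A2.each_col() += P[3].col(0);
  C.A2.transform([](double v) { return v > 0 ? v : 0.0; });

  C.M3.set_size((uword)K * F, BL);
  im2col_feat(C.A2, B, L, K, C.M3);
  C.A3 = P[4].t() * C.M3;
  C.A3.each_col() += P[5].col(0);
  C.A3.transform([](double v) { return v > 0 ? v : 0.0; });

  // global max pool over positions
  C.H.set_size(B, F);
  C.amax.set_size(B, F);
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      double best = -datum::inf;
      uword barg = 0;
      for (int p = 0; p < L; ++p) {
        const double v = C.A3(f, (uword)b * L + p);
        if (v > best) { best = v; barg = p; }
      }
      C.H(b, f) = best;
      C.amax(b, f) = barg;
    }
  }

  C.A4 = C.H * P[6];
  C.A4.each_row() += P[7].row(0);
  C.A4.transform([](double v) { return v > 0 ? v : 0.0; });
  C.A5 = C.A4 * P[8];
  C.A5.each_row() += P[9].row(0);
  C.A5.transform([](double v) { return v > 0 ? v : 0.0; });
  C.out = C.A5 * P[10];
  C.out.each_row() += P[11].row(0);
}

void backward(const std::vector<mat>& P, const Cache& C, const mat& Yb,
              const Mat<int>& X, const std::vector<uword>& idx,
              const Hyper& h, std::vector<mat>& g) {
  const int B = C.B, L = h.L, F = h.F;
  mat G = (C.out - Yb) * (2.0 / (B * C.out.n_cols));

  g[10] = C.A5.t() * G;
  g[11] = sum(G, 0);
  mat dZ5 = (G * P[10].t()) % (C.A5 > 0);
  g[8] = C.A4.t() * dZ5;
  g[9] = sum(dZ5, 0);
  mat dZ4 = (dZ5 * P[8].t()) % (C.A4 > 0);
  g[6] = C.H.t() * dZ4;
  g[7] = sum(dZ4, 0);
  mat dH = dZ4 * P[6].t(); // B x F

  mat dA3((uword)F, (uword)B * L, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int f = 0; f < F; ++f)
      dA3(f, (uword)b * L + C.amax(b, f)) += dH(b, f);

  mat dZ3 = dA3 % (C.A3 > 0);
  g[4] = C.M3 * dZ3.t();
  g[5] = sum(dZ3, 1);
  mat dA2(F, (uword)B * L);
  col2im_feat(P[4] * dZ3, B, L, h.K, dA2);

  mat dZ2 = dA2 % (C.A2 > 0);
  g[2] = C.M2 * dZ2.t();
  g[3] = sum(dZ2, 1);
  mat dA1(F, (uword)B * L);
  col2im_feat(P[2] * dZ2, B, L, h.K, dA1);

  mat dZ1 = dA1 % (C.A1 > 0);
  mat dW1t(h.F, (uword)h.K * 4);
  conv_codes_backward(X, idx, dZ1, h.K, dW1t);
  g[0] = dW1t.t();
  g[1] = sum(dZ1, 1);
}

mat predict_all(const std::vector<mat>& P, const Mat<int>& X, const Hyper& h,
                int chunk = 512) {
  const int n = X.n_rows;
  mat out(n, 2);
  Cache C;
  for (int lo = 0; lo < n; lo += chunk) {
    const int hi = std::min(n, lo + chunk);
    std::vector<uword> idx;
    for (int i = lo; i < hi; ++i) idx.push_back(i);
    forward(P, X, idx, h, C);
    out.rows(lo, hi - 1) = C.out;
  }
  return out;
}

double mse(const mat& pred, const mat& y) {
  return accu(square(pred - y)) / pred.n_elem;
}

void he_init(mat& W, double sd, std::mt19937& gen) {
  std::normal_distribution<double> N(0.0, sd);
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i) W(i, j) = N(gen);
}

Hyper read_hyper(const List& hyper, int L) {
  Hyper h;
  h.K = as<int>(hyper["filter_width"]);
  h.F = as<int>(hyper["filters"]);
  h.H1 = as<int>(hyper["h1"]);
  h.H2 = as<int>(hyper["h2"]);
  h.lr = as<double>(hyper["lr"]);
  h.batch = as<int>(hyper["batch_size"]);
  h.max_epochs = as<int>(hyper["max_epochs"]);
  h.patience = as<int>(hyper["patience"]);
  h.L = L;
  return h;
}

std::vector<mat> weights_from_list(const List& W) {
  std::vector<mat> P;
  for (int i = 0; i < W.size(); ++i) P.push_back(as<mat>(W[i]));
  return P;
}

} // namespace

// [[Rcpp::export]]
List cnn_train_cpp(IntegerMatrix Xr, NumericMatrix Yr,
                   IntegerMatrix Xvr, NumericMatrix Yvr,
                   List hyper, int seed) {
  Mat<int> X = as<Mat<int>>(Xr), Xv = as<Mat<int>>(Xvr);
  mat Y = as<mat>(Yr), Yv = as<mat>(Yvr);
  Hyper h = read_hyper(hyper, X.n_cols);
  const int n = X.n_rows;

  std::mt19937 gen(seed);
  std::vector<mat> P(12);
  P[0].set_size((uword)h.K * 4, h.F);
  he_init(P[0], std::sqrt(2.0 / (h.K * 4)), gen);
  P[1] = mat(h.F, 1, fill::zeros);
  P[2].set_size((uword)h.K * h.F, h.F);
  he_init(P[2], std::sqrt(2.0 / (h.K * h.F)), gen);
  P[3] = mat(h.F, 1, fill::zeros);
  P[4].set_size((uword)h.K * h.F, h.F);
  he_init(P[4], std::sqrt(2.0 / (h.K * h.F)), gen);
  P[5] = mat(h.F, 1, fill::zeros);
  P[6].set_size(h.F, h.H1);
  he_init(P[6], std::sqrt(2.0 / h.F), gen);
  P[7] = mat(1, h.H1, fill::zeros);
  P[8].set_size(h.H1, h.H2);
  he_init(P[8], std::sqrt(2.0 / h.H1), gen);
  P[9] = mat(1, h.H2, fill::zeros);
  P[10].set_size(h.H2, 2);
  he_init(P[10], std::sqrt(1.0 / h.H2), gen);
  P[11] = mean(Y, 0); // start the output at the target means

  std::vector<mat> m(12), v(12), g(12);
  for (int k = 0; k < 12; ++k) {
    m[k] = mat(size(P[k]), fill::zeros);
    v[k] = mat(size(P[k]), fill::zeros);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;

  std::vector<uword> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  std::vector<mat> bestP = P;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  std::vector<double> tr_hist, val_hist;
  Cache C;

  for (int epoch = 1; epoch <= h.max_epochs; ++epoch) {
    std::shuffle(perm.begin(), perm.end(), gen);
    double tr_loss = 0;
    long tr_n = 0;
    for (int lo = 0; lo < n; lo += h.batch) {
      const int hi = std::min(n, lo + h.batch);
      std::vector<uword> idx(perm.begin() + lo, perm.begin() + hi);
      forward(P, X, idx, h, C);
      mat Yb = Y.rows(uvec(idx));
      const double l = mse(C.out, Yb);
      if (!std::isfinite(l))
        stop("non-finite training loss at epoch %d", epoch);
      tr_loss += l * idx.size();
      tr_n += idx.size();
      backward(P, C, Yb, X, idx, h, g);
      ++t;
      const double c1 = 1.0 - std::pow(b1, (double)t);
      const double c2 = 1.0 - std::pow(b2, (double)t);
      for (int k = 0; k < 12; ++k) {
        m[k] = b1 * m[k] + (1 - b1) * g[k];
        v[k] = b2 * v[k] + (1 - b2) * square(g[k]);
        P[k] -= h.lr * (m[k] / c1) / (sqrt(v[k] / c2) + eps);
      }
    }
    tr_hist.push_back(tr_loss / tr_n);
    const double val = mse(predict_all(P, Xv, h), Yv);
    val_hist.push_back(val);
    epochs_run = epoch;
    if (val < best_val - 1e-7) {
      best_val = val;
      best_epoch = epoch;
      bestP = P;
      wait = 0;
    } else if (++wait >= h.patience) break;
  }

  List W(12);
  for (int k = 0; k < 12; ++k) W[k] = wrap(bestP[k]);
  return List::create(_["weights"] = W,
                      _["epochs_run"] = epochs_run,
                      _["best_epoch"] = best_epoch,
                      _["best_val_mse"] = best_val,
                      _["train_mse"] = wrap(tr_hist),
                      _["val_mse"] = wrap(val_hist));
}

// [[Rcpp::export]]
NumericMatrix cnn_forward_cpp(List weights, IntegerMatrix Xr) {
  std::vector<mat> P = weights_from_list(weights);
  Mat<int> X = as<Mat<int>>(Xr);
  Hyper h;
  h.K = P[0].n_rows / 4;
  h.F = P[0].n_cols;
  h.H1 = P[6].n_cols;
  h.H2 = P[8].n_cols;
  h.L = X.n_cols;
  return wrap(predict_all(P, X, h));
}
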