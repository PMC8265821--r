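// Compact two-convolutional-layer network for 13-class monomer-orientation
// classification: conv(F1@3x3)+ReLU+2x2 maxpool, conv(F2@3x3)+ReLU, flatten,
// dense softmax, categorical cross-entropy, Adam.  Written from scratch: the
// network is small enough (tens of thousands of parameters, 25x25 inputs)
// that plain scalar loops train in minutes on one CPU.
//
// Weight layouts (R matrices, column-major):
//   W1: (9, F1)       column f = 3x3 kernel of filter f, k = i + 3*j
//   W2: (9*F1, F2)    column g, index = ch*9 + i + 3*j
//   W3: (F, C)        column k = class, F = h2*w2*F2 flattened conv2 output
// Activation layouts (flat buffers): a[r + h*c + h*w*f].

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Shape {
  int H, W, F1, F2, C;
  int h1, w1, hp, wp, h2, w2, F;
  Shape(int H_, int W_, int F1_, int F2_, int C_)
      : H(H_), W(W_), F1(F1_), F2(F2_), C(C_) {
    h1 = H - 2; w1 = W - 2;
    hp = h1 / 2; wp = w1 / 2;
    h2 = hp - 2; w2 = wp - 2;
    F = h2 * w2 * F2;
  }
};

struct Buffers {
  std::vector<double> x, z1, pool, z2, flat, probs;
  std::vector<int> argmax1;  // pooled-from index into z1
  explicit Buffers(const Shape& s)
      : x(s.H * s.W), z1(s.h1 * s.w1 * s.F1), pool(s.hp * s.wp * s.F1),
        z2(s.F), flat(s.F), probs(s.C), argmax1(s.hp * s.wp * s.F1) {}
};

// forward pass; returns cross-entropy loss if y >= 0, else 0
double forward(const Shape& s, Buffers& B,
               const double* W1, const double* b1,
               const double* W2, const double* b2,
               const double* W3, const double* b3, int y) {
  // conv1 (valid 3x3) + ReLU
  for (int f = 0; f < s.F1; ++f) {
    const double* w = W1 + 9 * f;
    for (int c = 0; c < s.w1; ++c) {
      for (int r = 0; r < s.h1; ++r) {
        double acc = b1[f];
        for (int j = 0; j < 3; ++j)
          for (int i = 0; i < 3; ++i)
            acc += B.x[(r + i) + s.H * (c + j)] * w[i + 3 * j];
        B.z1[r + s.h1 * c + s.h1 * s.w1 * f] = acc > 0 ? acc : 0;
      }
    }
  }
  // 2x2 max pool
  for (int f = 0; f < s.F1; ++f) {
    const int off = s.h1 * s.w1 * f;
    for (int c = 0; c < s.wp; ++c) {
      for (int r = 0; r < s.hp; ++r) {
        int best = off + 2 * r + s.h1 * 2 * c;
        double bv = B.z1[best];
        const int cand[3] = {off + 2 * r + 1 + s.h1 * 2 * c,
                             off + 2 * r + s.h1 * (2 * c + 1),
                             off + 2 * r + 1 + s.h1 * (2 * c + 1)};
        for (int t = 0; t < 3; ++t)
          if (B.z1[cand[t]] > bv) { bv = B.z1[cand[t]]; best = cand[t]; }
        const int pi = r + s.hp * c + s.hp * s.wp * f;
        B.pool[pi] = bv;
        B.argmax1[pi] = best;
      }
    }
  }
  // conv2 (valid 3x3 over F1 channels) + ReLU, flatten
  for (int g = 0; g < s.F2; ++g) {
    const double* w = W2 + 9 * s.F1 * g;
    for (int c = 0; c < s.w2; ++c) {
      for (int r = 0; r < s.h2; ++r) {
        double acc = b2[g];
        for (int ch = 0; ch < s.F1; ++ch) {
          const double* wc = w + 9 * ch;
          const int poff = s.hp * s.wp * ch;
          for (int j = 0; j < 3; ++j)
            for (int i = 0; i < 3; ++i)
              acc += B.pool[poff + (r + i) + s.hp * (c + j)] * wc[i + 3 * j];
        }
        const int zi = r + s.h2 * c + s.h2 * s.w2 * g;
        B.z2[zi] = acc > 0 ? acc : 0;
        B.flat[zi] = B.z2[zi];
      }
    }
  }
  // dense + softmax
  double mx = -1e300;
  for (int k = 0; k < s.C; ++k) {
    double acc = b3[k];
    const double* w = W3 + s.F * k;
    for (int t = 0; t < s.F; ++t) acc += B.flat[t] * w[t];
    B.probs[k] = acc;
    if (acc > mx) mx = acc;
  }
  double Z = 0;
  for (int k = 0; k < s.C; ++k) { B.probs[k] = std::exp(B.probs[k] - mx); Z += B.probs[k]; }
  for (int k = 0; k < s.C; ++k) B.probs[k] /= Z;
  return y >= 0 ? -std::log(std::max(B.probs[y], 1e-300)) : 0.0;
}

struct Grads {
  std::vector<double> W1, b1, W2, b2, W3, b3;
  explicit Grads(const Shape& s)
      : W1(9 * s.F1), b1(s.F1), W2(9 * s.F1 * s.F2), b2(s.F2),
        W3(s.F * s.C), b3(s.C) {}
  void zero() {
    std::fill(W1.begin(), W1.end(), 0); std::fill(b1.begin(), b1.end(), 0);
    std::fill(W2.begin(), W2.end(), 0); std::fill(b2.begin(), b2.end(), 0);
    std::fill(W3.begin(), W3.end(), 0); std::fill(b3.begin(), b3.end(), 0);
  }
};

void backward(const Shape& s, const Buffers& B,
              const double* W2, const double* W3, int y, Grads& G,
              std::vector<double>& dflat, std::vector<double>& dpool,
              std::vector<double>& dz1) {
  std::vector<double> dlog(B.probs);
  dlog[y] -= 1.0;
  // dense
  for (int k = 0; k < s.C; ++k) {
    double* gw = G.W3.data() + s.F * k;
    const double d = dlog[k];
    for (int t = 0; t < s.F; ++t) gw[t] += B.flat[t] * d;
    G.b3[k] += d;
  }
  for (int t = 0; t < s.F; ++t) {
    double acc = 0;
    for (int k = 0; k < s.C; ++k) acc += W3[s.F * k + t] * dlog[k];
    dflat[t] = B.z2[t] > 0 ? acc : 0;   // through ReLU of conv2
  }
  // conv2 grads and dpool
  std::fill(dpool.begin(), dpool.end(), 0);
  for (int g = 0; g < s.F2; ++g) {
    double* gw = G.W2.data() + 9 * s.F1 * g;
    const double* w = W2 + 9 * s.F1 * g;
    for (int c = 0; c < s.w2; ++c) {
      for (int r = 0; r < s.h2; ++r) {
        const double d = dflat[r + s.h2 * c + s.h2 * s.w2 * g];
        if (d == 0) continue;
        G.b2[g] += d;
        for (int ch = 0; ch < s.F1; ++ch) {
          const int poff = s.hp * s.wp * ch;
          double* gwc = gw + 9 * ch;
          const double* wc = w + 9 * ch;
          for (int j = 0; j < 3; ++j) {
            for (int i = 0; i < 3; ++i) {
              const int pi = poff + (r + i) + s.hp * (c + j);
              gwc[i + 3 * j] += B.pool[pi] * d;
              dpool[pi] += wc[i + 3 * j] * d;
            }
          }
        }
      }
    }
  }
  // unpool into dz1 (ReLU of conv1 already applied in z1; gradient only
  // where the pooled activation was positive)
  std::fill(dz1.begin(), dz1.end(), 0);
  for (size_t pi = 0; pi < B.argmax1.size(); ++pi) {
    if (B.pool[pi] > 0) dz1[B.argmax1[pi]] += dpool[pi];
  }
  // conv1 grads
  for (int f = 0; f < s.F1; ++f) {
    double* gw = G.W1.data() + 9 * f;
    const int off = s.h1 * s.w1 * f;
    for (int c = 0; c < s.w1; ++c) {
      for (int r = 0; r < s.h1; ++r) {
        const double d = dz1[off + r + s.h1 * c];
        if (d == 0) continue;
        G.b1[f] += d;
        for (int j = 0; j < 3; ++j)
          for (int i = 0; i < 3; ++i)
            gw[i + 3 * j] += B.x[(r + i) + s.H * (c + j)] * d;
      }
    }
  }
}

struct Adam {
  std::vector<double> m, v;
  explicit Adam(size_t n) : m(n, 0.0), v(n, 0.0) {}
  void step(double* w, const double* g, size_t n, double scale, double lr,
            double b1, double b2, double eps, double b1t, double b2t) {
    for (size_t i = 0; i < n; ++i) {
      const double gi = g[i] * scale;
      m[i] = b1 * m[i] + (1 - b1) * gi;
      v[i] = b2 * v[i] + (1 - b2) * gi * gi;
      const double mh = m[i] / (1 - b1t);
      const double vh = v[i] / (1 - b2t);
      w[i] -= lr * mh / (std::sqrt(vh) + eps);
    }
  }
};

void load_sample(const NumericMatrix& X, int i, std::vector<double>& x) {
  for (size_t j = 0; j < x.size(); ++j) x[j] = X(i, j);
}

}  // namespace

// [[Rcpp::export]]
List cnn_train_cpp(NumericMatrix X, IntegerVector y,
                   NumericMatrix W1, NumericVector b1,
                   NumericMatrix W2, NumericVector b2,
                   NumericMatrix W3, NumericVector b3,
                   int H, int W, int F1, int F2, int C,
                   IntegerMatrix perm, int batch_size, double lr,
                   double beta1, double beta2, double eps) {
  const Shape s(H, W, F1, F2, C);
  const int n = X.nrow();
  const int epochs = perm.ncol();
  if (X.ncol() != H * W) stop("input size does not match H*W");
  if (W3.nrow() != s.F) stop("W3 rows do not match the flattened conv2 size");

  // mutable copies of the weights
  std::vector<double> w1(W1.begin(), W1.end()), bb1(b1.begin(), b1.end());
  std::vector<double> w2(W2.begin(), W2.end()), bb2(b2.begin(), b2.end());
  std::vector<double> w3(W3.begin(), W3.end()), bb3(b3.begin(), b3.end());

  Buffers B(s);
  Grads G(s);
  std::vector<double> dflat(s.F), dpool(s.hp * s.wp * s.F1),
      dz1(s.h1 * s.w1 * s.F1);
  Adam aW1(w1.size()), ab1(bb1.size()), aW2(w2.size()), ab2(bb2.size()),
      aW3(w3.size()), ab3(bb3.size());

  NumericVector ep_loss(epochs), ep_acc(epochs);
  double b1t = 1.0, b2t = 1.0;
  for (int e = 0; e < epochs; ++e) {
    double loss_sum = 0;
    int correct = 0;
    int done = 0;
    while (done < n) {
      const int bs = std::min(batch_size, n - done);
      G.zero();
      for (int b = 0; b < bs; ++b) {
        const int i = perm(done + b, e);
        load_sample(X, i, B.x);
        const int yi = y[i];
        loss_sum += forward(s, B, w1.data(), bb1.data(), w2.data(),
                            bb2.data(), w3.data(), bb3.data(), yi);
        int pred = 0;
        for (int k = 1; k < s.C; ++k) if (B.probs[k] > B.probs[pred]) pred = k;
        if (pred == yi) ++correct;
        backward(s, B, w2.data(), w3.data(), yi, G, dflat, dpool, dz1);
      }
      b1t *= beta1; b2t *= beta2;
      const double scale = 1.0 / bs;
      aW1.step(w1.data(), G.W1.data(), w1.size(), scale, lr, beta1, beta2, eps, b1t, b2t);
      ab1.step(bb1.data(), G.b1.data(), bb1.size(), scale, lr, beta1, beta2, eps, b1t, b2t);
      aW2.step(w2.data(), G.W2.data(), w2.size(), scale, lr, beta1, beta2, eps, b1t, b2t);
      ab2.step(bb2.data(), G.b2.data(), bb2.size(), scale, lr, beta1, beta2, eps, b1t, b2t);
      aW3.step(w3.data(), G.W3.data(), w3.size(), scale, lr, beta1, beta2, eps, b1t, b2t);
      ab3.step(bb3.data(), G.b3.data(), bb3.size(), scale, lr, beta1, beta2, eps, b1t, b2t);
      done += bs;
      if (done % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    ep_loss[e] = loss_sum / n;
    ep_acc[e] = double(correct) / n;
  }

  NumericMatrix oW1(9, F1), oW2(9 * F1, F2), oW3(s.F, C);
  std::copy(w1.begin(), w1.end(), oW1.begin());
  std::copy(w2.begin(), w2.end(), oW2.begin());
  std::copy(w3.begin(), w3.end(), oW3.begin());
  return List::create(
      _["W1"] = oW1, _["b1"] = NumericVector(bb1.begin(), bb1.end()),
      _["W2"] = oW2, _["b2"] = NumericVector(bb2.begin(), bb2.end()),
      _["W3"] = oW3, _["b3"] = NumericVector(bb3.begin(), bb3.end()),
      _["loss"] = ep_loss, _["accuracy"] = ep_acc);
}

// [[Rcpp::export]]
NumericMatrix cnn_predict_cpp(NumericMatrix X,
                              NumericMatrix W1, NumericVector b1,
                              NumericMatrix W2, NumericVector b2,
                              NumericMatrix W3, NumericVector b3,
                              int H, int W, int F1, int F2, int C) {
  const Shape s(H, W, F1, F2, C);
  const int n = X.nrow();
  if (X.ncol() != H * W) stop("input size does not match H*W");
  Buffers B(s);
  NumericMatrix out(n, C);
  for (int i = 0; i < n; ++i) {
    load_sample(X, i, B.x);
    forward(s, B, REAL(W1), REAL(b1), REAL(W2), REAL(b2), REAL(W3), REAL(b3),
            -1);
    for (int k = 0; k < C; ++k) out(i, k) = B.probs[k];
    if (i % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
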