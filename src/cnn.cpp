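// Inner loops of the one-convolutional-layer classifier.
//
// The convolution is computed as a single GEMM on the precomputed
// kernel-column ("im2col") matrix built in R; this file holds the
// forward pass, backpropagation and RMSprop updates. All randomness
// (initial weights, epoch permutations) is generated in R and passed in,
// so results are reproducible from the R seed alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Params {
  mat W, W1, W2;
  vec b, b1, b2;
};

static Params read_params(const Rcpp::List& p) {
  Params out;
  out.W  = Rcpp::as<mat>(p["W"]);
  out.b  = Rcpp::as<vec>(p["b"]);
  out.W1 = Rcpp::as<mat>(p["W1"]);
  out.b1 = Rcpp::as<vec>(p["b1"]);
  out.W2 = Rcpp::as<mat>(p["W2"]);
  out.b2 = Rcpp::as<vec>(p["b2"]);
  return out;
}

// forward to pooled activations; P is Fn x (f*B) with per-sample blocks of
// f columns; AM records the within-window argmax for unpooling
static void forward_pool(const Params& par, const mat& K, int p, int B,
                         int pw, mat& Z, mat& P, umat& AM) {
  const int f = (p + pw - 1) / pw;
  const int Fn = par.W.n_rows;
  Z = par.W * K;
  Z.each_col() += par.b;
  P.set_size(Fn, f * B);
  AM.set_size(Fn, f * B);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < f; ++j) {
      const int lo = j * pw;
      const int hi = std::min(p, lo + pw);
      for (int r = 0; r < Fn; ++r) {
        double best = 0.0;  // relu floor: activations below 0 clamp to 0
        int arg = lo;
        for (int t = lo; t < hi; ++t) {
          const double v = Z.at(r, b * p + t);
          if (v > best) { best = v; arg = t; }
        }
        P.at(r, b * f + j) = best;
        AM.at(r, b * f + j) = arg;
      }
    }
  }
}

static void dense_forward(const Params& par, const mat& P, int B,
                          mat& V, mat& H, mat& S) {
  V = reshape(P, par.W1.n_cols, B);
  H = par.W1 * V;
  H.each_col() += par.b1;
  H.transform([](double x) { return x > 0 ? x : 0.0; });
  S = par.W2 * H;
  S.each_col() += par.b2;
  S.each_row() -= max(S, 0);
  S = exp(S);
  S.each_row() /= sum(S, 0);
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(const arma::mat& Kall, const arma::ivec& labels,
                         int p, Rcpp::List params0, const arma::imat& perms,
                         int batch_size, double lr, double rho, double eps,
                         int pool_window) {
  const int n = labels.n_elem;
  const int epochs = perms.n_cols;
  const int pw = pool_window;
  const int f = (p + pw - 1) / pw;
  Params par = read_params(params0);
  const int Fn = par.W.n_rows;
  Params cache;
  cache.W = zeros(size(par.W));   cache.b = zeros(size(par.b));
  cache.W1 = zeros(size(par.W1)); cache.b1 = zeros(size(par.b1));
  cache.W2 = zeros(size(par.W2)); cache.b2 = zeros(size(par.b2));
  vec history(epochs, fill::zeros);

  mat K, Z, P, V, H, S;
  umat AM;
  auto rms = [&](mat& w, mat& c, const mat& g) {
    c = rho * c + (1 - rho) * square(g);
    w -= lr * g / (sqrt(c) + eps);
  };
  auto rmsv = [&](vec& w, vec& c, const vec& g) {
    c = rho * c + (1 - rho) * square(g);
    w -= lr * g / (sqrt(c) + eps);
  };

  for (int ep = 0; ep < epochs; ++ep) {
    double eloss = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      uvec cols(p * B);
      ivec ylab(B);
      for (int b = 0; b < B; ++b) {
        const int s = perms.at(start + b, ep) - 1;  // 1-based from R
        ylab[b] = labels[s];
        for (int t = 0; t < p; ++t) cols[b * p + t] = s * p + t;
      }
      K = Kall.cols(cols);
      forward_pool(par, K, p, B, pw, Z, P, AM);
      dense_forward(par, P, B, V, H, S);
      double loss = 0.0;
      for (int b = 0; b < B; ++b) {
        loss -= std::log(std::max(S.at(ylab[b], b), 1e-12));
      }
      eloss += loss / B;
      ++nb;

      // backward
      mat dO = S;
      for (int b = 0; b < B; ++b) dO.at(ylab[b], b) -= 1.0;
      dO /= B;
      mat gW2 = dO * H.t();
      vec gb2 = sum(dO, 1);
      mat dH = par.W2.t() * dO;
      dH.elem(find(H <= 0)).zeros();
      mat gW1 = dH * V.t();
      vec gb1 = sum(dH, 1);
      mat dV = par.W1.t() * dH;
      // unpool dV (Ff x B) back onto conv positions, relu-gated by Z > 0
      mat dZ(Fn, p * B, fill::zeros);
      for (int b = 0; b < B; ++b) {
        for (int j = 0; j < f; ++j) {
          for (int r = 0; r < Fn; ++r) {
            const double g = dV.at(j * Fn + r, b);
            if (g == 0.0) continue;
            const uword t = AM.at(r, b * f + j);
            if (Z.at(r, b * p + t) > 0) dZ.at(r, b * p + t) = g;
          }
        }
      }
      mat gW = dZ * K.t();
      vec gb = sum(dZ, 1);

      rms(par.W, cache.W, gW);   rmsv(par.b, cache.b, gb);
      rms(par.W1, cache.W1, gW1); rmsv(par.b1, cache.b1, gb1);
      rms(par.W2, cache.W2, gW2); rmsv(par.b2, cache.b2, gb2);
    }
    history[ep] = eloss / nb;
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::List::create(
          Rcpp::Named("W") = par.W, Rcpp::Named("b") = par.b,
          Rcpp::Named("W1") = par.W1, Rcpp::Named("b1") = par.b1,
          Rcpp::Named("W2") = par.W2, Rcpp::Named("b2") = par.b2),
      Rcpp::Named("history") = history);
}

// [[Rcpp::export(name = ".cnn_forward_cpp")]]
Rcpp::List cnn_forward_cpp(const arma::mat& K, Rcpp::List params, int p,
                           int B, int pool_window, bool want_probs) {
  Params par = read_params(params);
  mat Z, P;
  umat AM;
  forward_pool(par, K, p, B, pool_window, Z, P, AM);
  if (!want_probs) {
    return Rcpp::List::create(Rcpp::Named("pooled") = P);
  }
  mat V, H, S;
  dense_forward(par, P, B, V, H, S);
  return Rcpp::List::create(Rcpp::Named("probs") = S,
                            Rcpp::Named("pooled") = P);
}
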