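// Batched LSTM trainer for binary sequence classification.
//
// Sequences are padded to a common length and masked: at padded timesteps the
// hidden and cell states carry over unchanged, and the gradient flows through
// the carry. The final-valid-timestep hidden state of the top layer feeds a
// dense layer with 2-way softmax; loss is mean cross-entropy. Optimizer is
// Adam. All randomness (weight init, epoch permutations, holdout split) is
// supplied by the caller, so training is a pure function of its arguments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct Layer {
  mat W, U;  // 4H x Din, 4H x H (gate order: input, forget, cell, output)
  vec b;     // 4H
};

struct Grads {
  mat dW, dU;
  vec db;
};

struct AdamState {
  mat mW, vW, mU, vU;
  vec mb, vb;
};

// Forward one layer over a padded batch, caching gate activations.
// In: Din x B x T cube (slice t = inputs at time t); M: B x T mask.
static void layer_forward(const Layer& L, const cube& In, const mat& M,
                          cube& Ig, cube& Fg, cube& Gg, cube& Og,
                          cube& C, cube& H) {
  const uword H4 = L.W.n_rows, Hh = H4 / 4, B = In.n_cols, T = In.n_slices;
  mat h_prev(Hh, B, fill::zeros), c_prev(Hh, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat A = L.W * In.slice(t) + L.U * h_prev;
    A.each_col() += L.b;
    mat i = sigmoid(A.rows(0, Hh - 1));
    mat f = sigmoid(A.rows(Hh, 2 * Hh - 1));
    mat g = tanh(A.rows(2 * Hh, 3 * Hh - 1));
    mat o = sigmoid(A.rows(3 * Hh, 4 * Hh - 1));
    mat c_new = f % c_prev + i % g;
    mat h_new = o % tanh(c_new);
    rowvec m = M.col(t).t();
    rowvec im = 1.0 - m;
    mat c_t = c_new.each_row() % m;
    c_t += c_prev.each_row() % im;
    mat h_t = h_new.each_row() % m;
    h_t += h_prev.each_row() % im;
    Ig.slice(t) = i; Fg.slice(t) = f; Gg.slice(t) = g; Og.slice(t) = o;
    C.slice(t) = c_t; H.slice(t) = h_t;
    h_prev = h_t; c_prev = c_t;
  }
}

// Backward through one layer. dHout: gradient wrt the layer's masked h_t
// (H x B x T). Returns gradient wrt the layer inputs via dIn.
static void layer_backward(const Layer& L, const cube& In, const mat& M,
                           const cube& Ig, const cube& Fg, const cube& Gg,
                           const cube& Og, const cube& C, const cube& H,
                           const cube& dHout, Grads& G, cube& dIn) {
  const uword Hh = L.U.n_cols, B = In.n_cols, T = In.n_slices;
  G.dW.zeros(L.W.n_rows, L.W.n_cols);
  G.dU.zeros(L.U.n_rows, L.U.n_cols);
  G.db.zeros(L.b.n_elem);
  mat dh_rec(Hh, B, fill::zeros), dc_rec(Hh, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    rowvec m = M.col(t).t();
    rowvec im = 1.0 - m;
    mat dh_total = dHout.slice(t) + dh_rec;
    mat dc_total = dc_rec;
    mat dhm = dh_total.each_row() % m;
    mat dcm = dc_total.each_row() % m;
    mat dh_pass = dh_total.each_row() % im;
    mat dc_pass = dc_total.each_row() % im;

    mat tc = tanh(C.slice(t));
    const mat& i = Ig.slice(t);
    const mat& f = Fg.slice(t);
    const mat& g = Gg.slice(t);
    const mat& o = Og.slice(t);
    mat c_prev = (t > 0) ? C.slice(t - 1) : mat(Hh, B, fill::zeros);
    mat h_prev = (t > 0) ? H.slice(t - 1) : mat(Hh, B, fill::zeros);

    mat do_ = dhm % tc;
    mat dct = dcm + dhm % o % (1.0 - tc % tc);
    mat di = dct % g;
    mat dg = dct % i;
    mat df = dct % c_prev;

    mat A4 = join_cols(join_cols(di % i % (1.0 - i), df % f % (1.0 - f)),
                       join_cols(dg % (1.0 - g % g), do_ % o % (1.0 - o)));
    G.dW += A4 * In.slice(t).t();
    G.dU += A4 * h_prev.t();
    G.db += sum(A4, 1);
    dIn.slice(t) = L.W.t() * A4;
    dh_rec = dh_pass + L.U.t() * A4;
    dc_rec = dc_pass + dct % f;
  }
}

static std::vector<Layer> unpack_layers(const Rcpp::List& weights, int depth) {
  std::vector<Layer> layers(depth);
  for (int l = 0; l < depth; ++l) {
    layers[l].W = Rcpp::as<mat>(weights["W" + std::to_string(l + 1)]);
    layers[l].U = Rcpp::as<mat>(weights["U" + std::to_string(l + 1)]);
    layers[l].b = Rcpp::as<vec>(weights["b" + std::to_string(l + 1)]);
  }
  return layers;
}

// Gather a batch into per-timestep slices plus its mask.
static void gather_batch(const cube& X, const ivec& len, const uvec& idx,
                         cube& Xb, mat& M) {
  const uword D = X.n_rows, B = idx.n_elem;
  uword Tmax = 0;
  for (uword b = 0; b < B; ++b)
    Tmax = std::max(Tmax, (uword)len(idx(b)));
  Xb.set_size(D, B, Tmax);
  Xb.zeros();
  M.set_size(B, Tmax);
  M.zeros();
  for (uword b = 0; b < B; ++b) {
    uword Tb = len(idx(b));
    for (uword t = 0; t < Tb; ++t)
      Xb.slice(t).col(b) = X.slice(idx(b)).col(t);
    M.submat(b, 0, b, Tb - 1).ones();
  }
}

// [[Rcpp::export(name = ".lstm_probs_cpp")]]
arma::mat lstm_probs_cpp(const Rcpp::List& weights, const arma::cube& X,
                         const arma::ivec& len, int depth) {
  std::vector<Layer> layers = unpack_layers(weights, depth);
  mat Wout = Rcpp::as<mat>(weights["Wout"]);
  vec bout = Rcpp::as<vec>(weights["bout"]);
  const uword N = X.n_slices;
  uvec idx = regspace<uvec>(0, N - 1);
  cube Xb; mat M;
  gather_batch(X, len, idx, Xb, M);
  const uword B = Xb.n_cols, T = Xb.n_slices;
  cube In = Xb;
  for (size_t l = 0; l < layers.size(); ++l) {
    const Layer& L = layers[l];
    const uword Hh = L.U.n_cols;
    cube Hout(Hh, B, T);
    mat h_prev(Hh, B, fill::zeros), c_prev(Hh, B, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      mat A = L.W * In.slice(t) + L.U * h_prev;
      A.each_col() += L.b;
      mat i = sigmoid(A.rows(0, Hh - 1));
      mat f = sigmoid(A.rows(Hh, 2 * Hh - 1));
      mat g = tanh(A.rows(2 * Hh, 3 * Hh - 1));
      mat o = sigmoid(A.rows(3 * Hh, 4 * Hh - 1));
      mat c_new = f % c_prev + i % g;
      mat h_new = o % tanh(c_new);
      rowvec m = M.col(t).t();
      rowvec im = 1.0 - m;
      mat c_t = c_new.each_row() % m;
      c_t += c_prev.each_row() % im;
      mat h_t = h_new.each_row() % m;
      h_t += h_prev.each_row() % im;
      Hout.slice(t) = h_t;
      h_prev = h_t; c_prev = c_t;
    }
    In = Hout;
  }
  mat hlast(layers.back().U.n_cols, B);
  for (uword b = 0; b < B; ++b)
    hlast.col(b) = In.slice(len(b) - 1).col(b);
  mat logits = Wout * hlast;
  logits.each_col() += bout;
  logits.each_row() -= max(logits, 0);
  mat e = exp(logits);
  mat probs = e.each_row() / sum(e, 0);
  return probs.t();  // N x 2
}

static double val_accuracy(const Rcpp::List& weights, const cube& Xv,
                           const ivec& lenv, const ivec& yv, int depth) {
  mat probs = lstm_probs_cpp(weights, Xv, lenv, depth);
  uword correct = 0;
  for (uword j = 0; j < probs.n_rows; ++j) {
    int pred = probs(j, 1) >= probs(j, 0) ? 1 : 0;
    if (pred == yv(j)) ++correct;
  }
  return (double)correct / probs.n_rows;
}

static void adam_step(mat& P, const mat& G, mat& m, mat& v, double lr,
                      double b1, double b2, double eps, double t) {
  m = b1 * m + (1 - b1) * G;
  v = b2 * v + (1 - b2) * (G % G);
  mat mh = m / (1 - std::pow(b1, t));
  mat vh = v / (1 - std::pow(b2, t));
  P -= lr * mh / (sqrt(vh) + eps);
}

static void adam_step_vec(vec& P, const vec& G, vec& m, vec& v, double lr,
                          double b1, double b2, double eps, double t) {
  m = b1 * m + (1 - b1) * G;
  v = b2 * v + (1 - b2) * (G % G);
  vec mh = m / (1 - std::pow(b1, t));
  vec vh = v / (1 - std::pow(b2, t));
  P -= lr * mh / (sqrt(vh) + eps);
}

// [[Rcpp::export(name = ".lstm_train_cpp")]]
Rcpp::List lstm_train_cpp(Rcpp::List weights, const arma::cube& Xtr,
                          const arma::ivec& len_tr, const arma::ivec& y_tr,
                          const arma::cube& Xval, const arma::ivec& len_val,
                          const arma::ivec& y_val, int depth, double lr,
                          int epochs, int batch_size,
                          const arma::imat& perms, int val_every) {
  std::vector<Layer> layers = unpack_layers(weights, depth);
  mat Wout = Rcpp::as<mat>(weights["Wout"]);
  vec bout = Rcpp::as<vec>(weights["bout"]);
  const uword N = Xtr.n_slices;
  const bool has_val = Xval.n_slices > 0;

  std::vector<AdamState> st(depth);
  for (int l = 0; l < depth; ++l) {
    st[l].mW.zeros(size(layers[l].W)); st[l].vW.zeros(size(layers[l].W));
    st[l].mU.zeros(size(layers[l].U)); st[l].vU.zeros(size(layers[l].U));
    st[l].mb.zeros(layers[l].b.n_elem); st[l].vb.zeros(layers[l].b.n_elem);
  }
  mat mWout(size(Wout), fill::zeros), vWout(size(Wout), fill::zeros);
  vec mbout(bout.n_elem, fill::zeros), vbout(bout.n_elem, fill::zeros);

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double adam_t = 0;
  long iter = 0;
  std::vector<double> losses;
  std::vector<double> val_acc;
  std::vector<double> val_iter;

  auto pack_weights = [&]() {
    Rcpp::List w = Rcpp::clone(weights);
    for (int l = 0; l < depth; ++l) {
      w["W" + std::to_string(l + 1)] = layers[l].W;
      w["U" + std::to_string(l + 1)] = layers[l].U;
      w["b" + std::to_string(l + 1)] = layers[l].b;
    }
    w["Wout"] = Wout;
    w["bout"] = bout;
    return w;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    for (uword start = 0; start < N; start += batch_size) {
      uword stop = std::min<uword>(start + batch_size, N) - 1;
      uvec idx(stop - start + 1);
      for (uword k = 0; k < idx.n_elem; ++k)
        idx(k) = (uword)perms(start + k, ep);
      const uword B = idx.n_elem;

      cube Xb; mat M;
      gather_batch(Xtr, len_tr, idx, Xb, M);
      const uword T = Xb.n_slices;
      ivec blen(B);
      for (uword b = 0; b < B; ++b) blen(b) = len_tr(idx(b));

      // forward with caches
      std::vector<cube> Ins(depth + 1);
      Ins[0] = Xb;
      std::vector<cube> Ig(depth), Fg(depth), Gg(depth), Og(depth),
                        C(depth), Hc(depth);
      for (int l = 0; l < depth; ++l) {
        uword Hh = layers[l].U.n_cols;
        Ig[l].set_size(Hh, B, T); Fg[l].set_size(Hh, B, T);
        Gg[l].set_size(Hh, B, T); Og[l].set_size(Hh, B, T);
        C[l].set_size(Hh, B, T);  Hc[l].set_size(Hh, B, T);
        layer_forward(layers[l], Ins[l], M, Ig[l], Fg[l], Gg[l], Og[l],
                      C[l], Hc[l]);
        Ins[l + 1] = Hc[l];
      }
      uword Htop = layers[depth - 1].U.n_cols;
      mat hlast(Htop, B);
      for (uword b = 0; b < B; ++b)
        hlast.col(b) = Hc[depth - 1].slice(blen(b) - 1).col(b);
      mat logits = Wout * hlast;
      logits.each_col() += bout;
      logits.each_row() -= max(logits, 0);
      mat e = exp(logits);
      mat probs = e.each_row() / sum(e, 0);

      double loss = 0;
      mat dlogits = probs;
      for (uword b = 0; b < B; ++b) {
        loss -= std::log(std::max(probs(y_tr(idx(b)), b), 1e-12));
        dlogits(y_tr(idx(b)), b) -= 1.0;
      }
      loss /= B;
      dlogits /= B;
      losses.push_back(loss);

      mat dWout = dlogits * hlast.t();
      vec dbout = sum(dlogits, 1);
      mat dhlast = Wout.t() * dlogits;

      cube dHout(Htop, B, T, fill::zeros);
      for (uword b = 0; b < B; ++b)
        dHout.slice(blen(b) - 1).col(b) += dhlast.col(b);

      std::vector<Grads> grads(depth);
      for (int l = depth - 1; l >= 0; --l) {
        cube dIn(Ins[l].n_rows, B, T);
        layer_backward(layers[l], Ins[l], M, Ig[l], Fg[l], Gg[l], Og[l],
                       C[l], Hc[l], dHout, grads[l], dIn);
        if (l > 0) dHout = dIn;
      }

      adam_t += 1;
      for (int l = 0; l < depth; ++l) {
        adam_step(layers[l].W, grads[l].dW, st[l].mW, st[l].vW, lr, b1, b2, eps, adam_t);
        adam_step(layers[l].U, grads[l].dU, st[l].mU, st[l].vU, lr, b1, b2, eps, adam_t);
        adam_step_vec(layers[l].b, grads[l].db, st[l].mb, st[l].vb, lr, b1, b2, eps, adam_t);
      }
      adam_step(Wout, dWout, mWout, vWout, lr, b1, b2, eps, adam_t);
      adam_step_vec(bout, dbout, mbout, vbout, lr, b1, b2, eps, adam_t);

      ++iter;
      if (has_val && val_every > 0 && iter % val_every == 0) {
        double acc = val_accuracy(pack_weights(), Xval, len_val, y_val, depth);
        val_iter.push_back((double)iter);
        val_acc.push_back(acc);
      }
    }
  }
  if (has_val) {
    double acc = val_accuracy(pack_weights(), Xval, len_val, y_val, depth);
    val_iter.push_back((double)iter);
    val_acc.push_back(acc);
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = pack_weights(),
      Rcpp::Named("loss") = losses,
      Rcpp::Named("val_iter") = val_iter,
      Rcpp::Named("val_acc") = val_acc);
}
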