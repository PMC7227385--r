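// Encoder-decoder LSTM core: forward pass, backpropagation through time,
// and Adam training loop. Gate order in the fused weight matrices is
// [input | forget | cell | output], each block `units` columns wide.
// Cell input/output activation is tanh or ReLU; gates are always logistic.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static inline mat act_apply(const mat& x, int code) {
  if (code == 0) return tanh(x);
  mat r = x;
  r.elem(find(r < 0)).zeros();
  return r;
}

// derivative of the activation expressed through the activated value
static inline mat act_grad_from_out(const mat& a, int code) {
  if (code == 0) return 1.0 - square(a);
  return conv_to<mat>::from(a > 0.0);
}

struct LstmCache {
  std::vector<mat> x, hprev, cprev, gi, gf, gg, go, c, hc;
};

struct LstmGrads {
  mat dWx, dWh;
  rowvec db;
  std::vector<mat> dX;
  mat dh0, dc0;
};

// Forward over T steps; inputs[t] is B x n_in. Returns outputs per step.
static std::vector<mat> lstm_forward(const std::vector<mat>& inputs,
                                     const mat& Wx, const mat& Wh,
                                     const rowvec& b, int act,
                                     LstmCache* cache) {
  const uword T = inputs.size();
  const uword B = inputs[0].n_rows;
  const uword U = Wh.n_rows;
  mat h(B, U, fill::zeros), c(B, U, fill::zeros);
  std::vector<mat> out(T);
  for (uword t = 0; t < T; ++t) {
    mat Z = inputs[t] * Wx + h * Wh;
    Z.each_row() += b;
    mat gi = sigmoid(Z.cols(0, U - 1));
    mat gf = sigmoid(Z.cols(U, 2 * U - 1));
    mat gg = act_apply(Z.cols(2 * U, 3 * U - 1), act);
    mat go = sigmoid(Z.cols(3 * U, 4 * U - 1));
    mat cnew = gf % c + gi % gg;
    mat hc = act_apply(cnew, act);
    mat hnew = go % hc;
    if (cache) {
      cache->x.push_back(inputs[t]);
      cache->hprev.push_back(h);
      cache->cprev.push_back(c);
      cache->gi.push_back(gi); cache->gf.push_back(gf);
      cache->gg.push_back(gg); cache->go.push_back(go);
      cache->c.push_back(cnew); cache->hc.push_back(hc);
    }
    h = hnew; c = cnew;
    out[t] = h;
  }
  return out;
}

// dh_ext[t] is the external gradient on the step-t output (may be empty);
// dh_last adds to the final step only.
static LstmGrads lstm_backward(const LstmCache& cache, const mat& Wx,
                               const mat& Wh, int act,
                               const std::vector<mat>& dh_ext,
                               const mat& dh_last) {
  const uword T = cache.x.size();
  const uword B = cache.x[0].n_rows;
  const uword U = Wh.n_rows;
  LstmGrads g;
  g.dWx.zeros(Wx.n_rows, Wx.n_cols);
  g.dWh.zeros(Wh.n_rows, Wh.n_cols);
  g.db.zeros(Wx.n_cols);
  g.dX.resize(T);
  mat dh_carry(B, U, fill::zeros), dc_carry(B, U, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    mat dh = dh_carry;
    if (!dh_ext.empty() && dh_ext[ti].n_elem > 0) dh += dh_ext[ti];
    if (ti == T - 1 && dh_last.n_elem > 0) dh += dh_last;
    const mat& gi = cache.gi[ti];
    const mat& gf = cache.gf[ti];
    const mat& gg = cache.gg[ti];
    const mat& go = cache.go[ti];
    mat da_o = (dh % cache.hc[ti]) % go % (1.0 - go);
    mat dc = dc_carry + dh % go % act_grad_from_out(cache.hc[ti], act);
    mat da_f = (dc % cache.cprev[ti]) % gf % (1.0 - gf);
    mat da_i = (dc % gg) % gi % (1.0 - gi);
    mat da_g = (dc % gi) % act_grad_from_out(gg, act);
    mat dZ = join_rows(join_rows(da_i, da_f), join_rows(da_g, da_o));
    g.dWx += cache.x[ti].t() * dZ;
    g.dWh += cache.hprev[ti].t() * dZ;
    g.db += sum(dZ, 0);
    g.dX[ti] = dZ * Wx.t();
    dh_carry = dZ * Wh.t();
    dc_carry = dc % gf;
  }
  g.dh0 = dh_carry;
  g.dc0 = dc_carry;
  return g;
}

struct Params {
  mat enc_Wx, enc_Wh, dec_Wx, dec_Wh, out_W;
  rowvec enc_b, dec_b, out_b;
};

static Params params_from_list(const Rcpp::List& p) {
  Params q;
  q.enc_Wx = Rcpp::as<mat>(p["enc_Wx"]);
  q.enc_Wh = Rcpp::as<mat>(p["enc_Wh"]);
  q.enc_b  = Rcpp::as<rowvec>(p["enc_b"]);
  q.dec_Wx = Rcpp::as<mat>(p["dec_Wx"]);
  q.dec_Wh = Rcpp::as<mat>(p["dec_Wh"]);
  q.dec_b  = Rcpp::as<rowvec>(p["dec_b"]);
  q.out_W  = Rcpp::as<mat>(p["out_W"]);
  q.out_b  = Rcpp::as<rowvec>(p["out_b"]);
  return q;
}

static Rcpp::List params_to_list(const Params& q) {
  return Rcpp::List::create(
    Rcpp::Named("enc_Wx") = q.enc_Wx, Rcpp::Named("enc_Wh") = q.enc_Wh,
    Rcpp::Named("enc_b") = q.enc_b, Rcpp::Named("dec_Wx") = q.dec_Wx,
    Rcpp::Named("dec_Wh") = q.dec_Wh, Rcpp::Named("dec_b") = q.dec_b,
    Rcpp::Named("out_W") = q.out_W, Rcpp::Named("out_b") = q.out_b);
}

// slices of X are time steps (B x F each)
static std::vector<mat> cube_to_steps(const cube& X) {
  std::vector<mat> v(X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t) v[t] = X.slice(t);
  return v;
}

// Forward through the whole model; optionally fills caches and per-step
// decoder hidden states for the backward pass.
static cube model_forward(const Params& q, const std::vector<mat>& xsteps,
                          int act, uword w_out,
                          LstmCache* enc_cache, LstmCache* dec_cache,
                          std::vector<mat>* dec_h_out) {
  const uword B = xsteps[0].n_rows;
  const uword F = q.out_W.n_cols;
  std::vector<mat> enc_out =
      lstm_forward(xsteps, q.enc_Wx, q.enc_Wh, q.enc_b, act, enc_cache);
  const mat& code = enc_out.back();
  std::vector<mat> dec_in(w_out, code);  // repeat-vector adapter
  std::vector<mat> dec_out =
      lstm_forward(dec_in, q.dec_Wx, q.dec_Wh, q.dec_b, act, dec_cache);
  cube Y(B, F, w_out);
  for (uword t = 0; t < w_out; ++t) {
    mat yt = dec_out[t] * q.out_W;
    yt.each_row() += q.out_b;
    Y.slice(t) = yt;
  }
  if (dec_h_out) *dec_h_out = dec_out;
  return Y;
}

// MAE loss and full gradient for one batch
static double loss_and_grads(const Params& q, const cube& X, const cube& Tg,
                             int act, Params& grads) {
  std::vector<mat> xsteps = cube_to_steps(X);
  const uword w_out = Tg.n_slices;
  LstmCache enc_cache, dec_cache;
  std::vector<mat> dec_h;
  cube Y = model_forward(q, xsteps, act, w_out, &enc_cache, &dec_cache, &dec_h);

  const double denom = (double)Y.n_elem;
  double loss = 0.0;
  grads.out_W.zeros(q.out_W.n_rows, q.out_W.n_cols);
  grads.out_b.zeros(q.out_b.n_elem);
  std::vector<mat> dh_dec(w_out);
  for (uword t = 0; t < w_out; ++t) {
    mat err = Y.slice(t) - Tg.slice(t);
    loss += accu(abs(err));
    mat dY = sign(err) / denom;
    grads.out_W += dec_h[t].t() * dY;
    grads.out_b += sum(dY, 0);
    dh_dec[t] = dY * q.out_W.t();
  }
  loss /= denom;

  LstmGrads gdec = lstm_backward(dec_cache, q.dec_Wx, q.dec_Wh, act,
                                 dh_dec, mat());
  // gradient on the repeated encoding accumulates over decoder steps
  mat d_code = gdec.dX[0];
  for (uword t = 1; t < w_out; ++t) d_code += gdec.dX[t];
  LstmGrads genc = lstm_backward(enc_cache, q.enc_Wx, q.enc_Wh, act,
                                 std::vector<mat>(), d_code);
  grads.enc_Wx = genc.dWx; grads.enc_Wh = genc.dWh; grads.enc_b = genc.db;
  grads.dec_Wx = gdec.dWx; grads.dec_Wh = gdec.dWh; grads.dec_b = gdec.db;
  return loss;
}

// [[Rcpp::export]]
arma::cube cpp_predict(Rcpp::List params, arma::cube X, int w_out,
                       std::string activation) {
  int act = (activation == "tanh") ? 0 : 1;
  Params q = params_from_list(params);
  std::vector<mat> xsteps = cube_to_steps(X);
  return model_forward(q, xsteps, act, (uword)w_out, nullptr, nullptr, nullptr);
}

// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(Rcpp::List params, arma::cube X, arma::cube Tg,
                         std::string activation) {
  int act = (activation == "tanh") ? 0 : 1;
  Params q = params_from_list(params);
  Params g;
  double loss = loss_and_grads(q, X, Tg, act, g);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = params_to_list(g));
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, arma::cube X, arma::cube Tg,
                     int epochs, int batch_windows, double lr, double beta1,
                     double beta2, double eps, double clipnorm,
                     std::string activation, int seed, bool shuffle) {
  int act = (activation == "tanh") ? 0 : 1;
  Params q = params_from_list(params);
  const uword N = X.n_rows;
  const uword B = std::min<uword>((uword)batch_windows, N);

  // Adam state, one slot per parameter array
  std::vector<mat*> slots = {&q.enc_Wx, &q.enc_Wh, &q.dec_Wx, &q.dec_Wh,
                             &q.out_W};
  std::vector<rowvec*> vslots = {&q.enc_b, &q.dec_b, &q.out_b};
  std::vector<mat> m_m(slots.size()), v_m(slots.size());
  std::vector<rowvec> m_v(vslots.size()), v_v(vslots.size());
  for (size_t k = 0; k < slots.size(); ++k) {
    m_m[k].zeros(slots[k]->n_rows, slots[k]->n_cols);
    v_m[k].zeros(slots[k]->n_rows, slots[k]->n_cols);
  }
  for (size_t k = 0; k < vslots.size(); ++k) {
    m_v[k].zeros(vslots[k]->n_elem);
    v_v[k].zeros(vslots[k]->n_elem);
  }
  long adam_t = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  Rcpp::NumericVector history(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) std::shuffle(order.begin(), order.end(), rng);
    double ep_abs = 0.0;
    double ep_n = 0.0;
    for (uword start = 0; start < N; start += B) {
      uword stop = std::min(start + B - 1, N - 1);
      uvec idx(stop - start + 1);
      for (uword i = 0; i < idx.n_elem; ++i) idx[i] = order[start + i];
      cube Xb(idx.n_elem, X.n_cols, X.n_slices);
      cube Tb(idx.n_elem, Tg.n_cols, Tg.n_slices);
      for (uword t = 0; t < X.n_slices; ++t) Xb.slice(t) = X.slice(t).rows(idx);
      for (uword t = 0; t < Tg.n_slices; ++t) Tb.slice(t) = Tg.slice(t).rows(idx);

      Params g;
      double loss = loss_and_grads(q, Xb, Tb, act, g);
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged: non-finite loss at epoch %d", ep + 1);
      double nelem = (double)Tb.n_elem;
      ep_abs += loss * nelem;
      ep_n += nelem;

      std::vector<mat*> gm = {&g.enc_Wx, &g.enc_Wh, &g.dec_Wx, &g.dec_Wh,
                              &g.out_W};
      std::vector<rowvec*> gv = {&g.enc_b, &g.dec_b, &g.out_b};

      if (std::isfinite(clipnorm)) {
        double sq = 0.0;
        for (auto* gp : gm) sq += accu(square(*gp));
        for (auto* gp : gv) sq += accu(square(*gp));
        double nrm = std::sqrt(sq);
        if (nrm > clipnorm && nrm > 0) {
          double sc = clipnorm / nrm;
          for (auto* gp : gm) *gp *= sc;
          for (auto* gp : gv) *gp *= sc;
        }
      }

      ++adam_t;
      double bc1 = 1.0 - std::pow(beta1, (double)adam_t);
      double bc2 = 1.0 - std::pow(beta2, (double)adam_t);
      for (size_t k = 0; k < slots.size(); ++k) {
        m_m[k] = beta1 * m_m[k] + (1.0 - beta1) * (*gm[k]);
        v_m[k] = beta2 * v_m[k] + (1.0 - beta2) * square(*gm[k]);
        *slots[k] -= lr * (m_m[k] / bc1) / (sqrt(v_m[k] / bc2) + eps);
      }
      for (size_t k = 0; k < vslots.size(); ++k) {
        m_v[k] = beta1 * m_v[k] + (1.0 - beta1) * (*gv[k]);
        v_v[k] = beta2 * v_v[k] + (1.0 - beta2) * square(*gv[k]);
        *vslots[k] -= lr * (m_v[k] / bc1) / (sqrt(v_v[k] / bc2) + eps);
      }
    }
    history[ep] = ep_abs / ep_n;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(q),
                            Rcpp::Named("history") = history);
}
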