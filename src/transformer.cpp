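// Encoder-only self-attention classifier over diagnosis-code sequences,
// with sinusoidal positional and days-to-diagnosis encodings, static
// demographic/survey branches and a weighted binary cross-entropy loss.
// Forward and analytic backward passes; padded positions are sliced out
// of the encoder entirely, so they can neither attend nor be attended to
// and receive exactly zero attention weight.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uvec;

static const double LN_EPS = 1e-5;

struct Config {
  int d_model, n_heads, n_layers, d_ff, demo_hidden, survey_hidden;
  double dropout, time_scale;
  explicit Config(const List& cfg)
      : d_model(as<int>(cfg["d_model"])),
        n_heads(as<int>(cfg["n_heads"])),
        n_layers(as<int>(cfg["n_layers"])),
        d_ff(as<int>(cfg["d_ff"])),
        demo_hidden(as<int>(cfg["demo_hidden"])),
        survey_hidden(as<int>(cfg["survey_hidden"])),
        dropout(as<double>(cfg["dropout"])),
        time_scale(as<double>(cfg["time_scale"])) {}
};

// sinusoidal encoding of a scalar value (position index or day offset)
static rowvec sinusoid(double value, int d) {
  rowvec out(d, arma::fill::zeros);
  for (int i = 0; 2 * i < d; ++i) {
    double freq = std::pow(10000.0, -2.0 * i / d);
    out(2 * i) = std::sin(value * freq);
    if (2 * i + 1 < d) out(2 * i + 1) = std::cos(value * freq);
  }
  return out;
}

struct LNCache {
  mat xhat;
  vec inv_sd;
};

static mat layernorm_fwd(const mat& x, const rowvec& g, const rowvec& b,
                         LNCache& cache) {
  vec mu = arma::mean(x, 1);
  mat centered = x.each_col() - mu;
  vec v = arma::mean(arma::square(centered), 1);
  cache.inv_sd = 1.0 / arma::sqrt(v + LN_EPS);
  cache.xhat = centered.each_col() % cache.inv_sd;
  mat y = cache.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat layernorm_bwd(const mat& dy, const rowvec& g, const LNCache& cache,
                         rowvec& dg, rowvec& db) {
  mat dxhat = dy.each_row() % g;
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % cache.xhat, 1);
  mat dx = dxhat.each_col() - m1;
  dx -= cache.xhat.each_col() % m2;
  dx.each_col() %= cache.inv_sd;
  dg += arma::sum(dy % cache.xhat, 0);
  db += arma::sum(dy, 0);
  return dx;
}

struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

struct Params {
  mat emb;
  std::vector<LayerParams> layers;
  mat demo_W, survey_W, head_W;
  rowvec demo_b, survey_b;
  double head_b;
};

static rowvec as_rowvec(const List& p, const std::string& nm) {
  NumericMatrix x = p[nm];
  rowvec out(x.ncol());
  for (int j = 0; j < x.ncol(); ++j) out(j) = x(0, j);
  return out;
}

static Params load_params(const List& p, const Config& cfg) {
  Params P;
  P.emb = as<mat>(p["emb"]);
  for (int l = 1; l <= cfg.n_layers; ++l) {
    std::string pre = "l" + std::to_string(l) + "_";
    LayerParams L;
    L.Wq = as<mat>(p[pre + "Wq"]); L.bq = as_rowvec(p, pre + "bq");
    L.Wk = as<mat>(p[pre + "Wk"]); L.bk = as_rowvec(p, pre + "bk");
    L.Wv = as<mat>(p[pre + "Wv"]); L.bv = as_rowvec(p, pre + "bv");
    L.Wo = as<mat>(p[pre + "Wo"]); L.bo = as_rowvec(p, pre + "bo");
    L.W1 = as<mat>(p[pre + "W1"]); L.b1 = as_rowvec(p, pre + "b1");
    L.W2 = as<mat>(p[pre + "W2"]); L.b2 = as_rowvec(p, pre + "b2");
    L.ln1_g = as_rowvec(p, pre + "ln1_g"); L.ln1_b = as_rowvec(p, pre + "ln1_b");
    L.ln2_g = as_rowvec(p, pre + "ln2_g"); L.ln2_b = as_rowvec(p, pre + "ln2_b");
    P.layers.push_back(L);
  }
  P.demo_W = as<mat>(p["demo_W"]); P.demo_b = as_rowvec(p, "demo_b");
  P.survey_W = as<mat>(p["survey_W"]); P.survey_b = as_rowvec(p, "survey_b");
  P.head_W = as<mat>(p["head_W"]);
  NumericMatrix hb = p["head_b"];
  P.head_b = hb(0, 0);
  return P;
}

struct Grads {
  mat emb;
  std::vector<LayerParams> layers;  // reuse struct for gradient storage
  mat demo_W, survey_W, head_W;
  rowvec demo_b, survey_b;
  double head_b;
};

static Grads zero_grads(const Params& P) {
  Grads G;
  G.emb = arma::zeros<mat>(P.emb.n_rows, P.emb.n_cols);
  for (size_t l = 0; l < P.layers.size(); ++l) {
    const LayerParams& L = P.layers[l];
    LayerParams Z;
    Z.Wq = arma::zeros<mat>(arma::size(L.Wq)); Z.bq = arma::zeros<rowvec>(L.bq.n_elem);
    Z.Wk = arma::zeros<mat>(arma::size(L.Wk)); Z.bk = arma::zeros<rowvec>(L.bk.n_elem);
    Z.Wv = arma::zeros<mat>(arma::size(L.Wv)); Z.bv = arma::zeros<rowvec>(L.bv.n_elem);
    Z.Wo = arma::zeros<mat>(arma::size(L.Wo)); Z.bo = arma::zeros<rowvec>(L.bo.n_elem);
    Z.W1 = arma::zeros<mat>(arma::size(L.W1)); Z.b1 = arma::zeros<rowvec>(L.b1.n_elem);
    Z.W2 = arma::zeros<mat>(arma::size(L.W2)); Z.b2 = arma::zeros<rowvec>(L.b2.n_elem);
    Z.ln1_g = arma::zeros<rowvec>(L.ln1_g.n_elem);
    Z.ln1_b = arma::zeros<rowvec>(L.ln1_b.n_elem);
    Z.ln2_g = arma::zeros<rowvec>(L.ln2_g.n_elem);
    Z.ln2_b = arma::zeros<rowvec>(L.ln2_b.n_elem);
    G.layers.push_back(Z);
  }
  G.demo_W = arma::zeros<mat>(arma::size(P.demo_W));
  G.demo_b = arma::zeros<rowvec>(P.demo_b.n_elem);
  G.survey_W = arma::zeros<mat>(arma::size(P.survey_W));
  G.survey_b = arma::zeros<rowvec>(P.survey_b.n_elem);
  G.head_W = arma::zeros<mat>(arma::size(P.head_W));
  G.head_b = 0.0;
  return G;
}

// per-layer forward cache for one sample
struct LayerCache {
  mat X_in, Q, K, V, H, O, X1, Z1, F1, F2;
  std::vector<mat> A;        // attention per head (m x m), pre-dropout
  std::vector<mat> Adrop;    // attention after dropout (training only)
  std::vector<mat> dropA;    // inverted-dropout masks on attention probs
  mat drop1, drop2;          // inverted-dropout masks on sublayer outputs
  LNCache ln1, ln2;
};

// fast RNG for dropout masks; seeded once per training call from R's
// RNG stream, so results stay reproducible under set.seed()
struct MaskRng {
  uint64_t s;
  explicit MaskRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  double next() {
    // splitmix64
    s += 0x9e3779b97f4a7c15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    z = z ^ (z >> 31);
    return (z >> 11) * (1.0 / 9007199254740992.0);
  }
};

static mat dropout_mask(int m, int d, double p, MaskRng& rng) {
  mat mask(m, d);
  double keep = 1.0 - p;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < d; ++j)
      mask(i, j) = (rng.next() < keep) ? 1.0 / keep : 0.0;
  return mask;
}

// encoder forward over the real (unmasked) positions of one sequence
static mat encoder_forward(const Params& P, const Config& cfg, mat X,
                           bool training, std::vector<LayerCache>* caches,
                           std::vector<std::vector<mat>>* attn_out,
                           MaskRng* rng = nullptr) {
  const int m = X.n_rows;
  const int dh = cfg.d_model / cfg.n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int l = 0; l < cfg.n_layers; ++l) {
    const LayerParams& L = P.layers[l];
    LayerCache C;
    C.X_in = X;
    C.Q = X * L.Wq; C.Q.each_row() += L.bq;
    C.K = X * L.Wk; C.K.each_row() += L.bk;
    C.V = X * L.Wv; C.V.each_row() += L.bv;
    C.H.set_size(m, cfg.d_model);
    if (attn_out) (*attn_out).push_back(std::vector<mat>());
    for (int h = 0; h < cfg.n_heads; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      mat S = C.Q.cols(cols) * C.K.cols(cols).t() * scale;
      // row-wise softmax, vectorized
      S.each_col() -= arma::max(S, 1);
      S = arma::exp(S);
      S.each_col() /= arma::sum(S, 1);
      C.A.push_back(S);
      if (attn_out) (*attn_out)[l].push_back(S);
      if (training && cfg.dropout > 0) {
        // dropout on the attention probabilities, as in the standard
        // transformer encoder layer
        mat M = dropout_mask(m, m, cfg.dropout, *rng);
        C.dropA.push_back(M);
        C.Adrop.push_back(S % M);
        C.H.cols(cols) = C.Adrop.back() * C.V.cols(cols);
      } else {
        C.H.cols(cols) = S * C.V.cols(cols);
      }
    }
    C.O = C.H * L.Wo; C.O.each_row() += L.bo;
    mat Od = C.O;
    if (training && cfg.dropout > 0) {
      C.drop1 = dropout_mask(m, cfg.d_model, cfg.dropout, *rng);
      Od %= C.drop1;
    }
    mat res1 = C.X_in + Od;
    C.X1 = layernorm_fwd(res1, L.ln1_g, L.ln1_b, C.ln1);
    C.Z1 = C.X1 * L.W1; C.Z1.each_row() += L.b1;
    C.F1 = arma::clamp(C.Z1, 0.0, arma::datum::inf);
    C.F2 = C.F1 * L.W2; C.F2.each_row() += L.b2;
    mat Fd = C.F2;
    if (training && cfg.dropout > 0) {
      C.drop2 = dropout_mask(m, cfg.d_model, cfg.dropout, *rng);
      Fd %= C.drop2;
    }
    mat res2 = C.X1 + Fd;
    X = layernorm_fwd(res2, L.ln2_g, L.ln2_b, C.ln2);
    if (caches) caches->push_back(std::move(C));
  }
  return X;
}

// backward through the encoder; returns gradient w.r.t. the input rows
static mat encoder_backward(const Params& P, const Config& cfg,
                            const std::vector<LayerCache>& caches,
                            mat dX, Grads& G, bool training) {
  const int dh = cfg.d_model / cfg.n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  for (int l = cfg.n_layers - 1; l >= 0; --l) {
    const LayerParams& L = P.layers[l];
    const LayerCache& C = caches[l];
    LayerParams& g = G.layers[l];
    // LN2
    mat dres2 = layernorm_bwd(dX, L.ln2_g, C.ln2, g.ln2_g, g.ln2_b);
    mat dF2 = dres2;
    if (training && cfg.dropout > 0) dF2 %= C.drop2;
    mat dX1 = dres2;
    // FFN
    g.W2 += C.F1.t() * dF2;
    g.b2 += arma::sum(dF2, 0);
    mat dF1 = dF2 * L.W2.t();
    mat dZ1 = dF1 % arma::conv_to<mat>::from(C.Z1 > 0);
    g.W1 += C.X1.t() * dZ1;
    g.b1 += arma::sum(dZ1, 0);
    dX1 += dZ1 * L.W1.t();
    // LN1
    mat dres1 = layernorm_bwd(dX1, L.ln1_g, C.ln1, g.ln1_g, g.ln1_b);
    mat dO = dres1;
    if (training && cfg.dropout > 0) dO %= C.drop1;
    mat dXin = dres1;
    // output projection
    g.Wo += C.H.t() * dO;
    g.bo += arma::sum(dO, 0);
    mat dH = dO * L.Wo.t();
    // attention heads
    mat dQ(arma::size(C.Q), arma::fill::zeros);
    mat dK(arma::size(C.K), arma::fill::zeros);
    mat dV(arma::size(C.V), arma::fill::zeros);
    bool attn_drop = training && cfg.dropout > 0;
    for (int h = 0; h < cfg.n_heads; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      const mat& A = C.A[h];
      const mat& Aused = attn_drop ? C.Adrop[h] : A;
      mat dHh = dH.cols(cols);
      mat dAused = dHh * C.V.cols(cols).t();
      dV.cols(cols) = Aused.t() * dHh;
      mat dA = attn_drop ? mat(dAused % C.dropA[h]) : dAused;
      vec rs = arma::sum(dA % A, 1);
      mat dS = A % (dA.each_col() - rs);
      dS *= scale;
      dQ.cols(cols) = dS * C.K.cols(cols);
      dK.cols(cols) = dS.t() * C.Q.cols(cols);
    }
    g.Wq += C.X_in.t() * dQ; g.bq += arma::sum(dQ, 0);
    g.Wk += C.X_in.t() * dK; g.bk += arma::sum(dK, 0);
    g.Wv += C.X_in.t() * dV; g.bv += arma::sum(dV, 0);
    dXin += dQ * L.Wq.t() + dK * L.Wk.t() + dV * L.Wv.t();
    dX = dXin;
  }
  return dX;
}

static List grads_to_list(const Grads& G, const Config& cfg) {
  List out;
  out["emb"] = wrap(G.emb);
  for (int l = 1; l <= cfg.n_layers; ++l) {
    const LayerParams& g = G.layers[l - 1];
    std::string pre = "l" + std::to_string(l) + "_";
    out[pre + "Wq"] = wrap(g.Wq); out[pre + "bq"] = wrap(mat(g.bq));
    out[pre + "Wk"] = wrap(g.Wk); out[pre + "bk"] = wrap(mat(g.bk));
    out[pre + "Wv"] = wrap(g.Wv); out[pre + "bv"] = wrap(mat(g.bv));
    out[pre + "Wo"] = wrap(g.Wo); out[pre + "bo"] = wrap(mat(g.bo));
    out[pre + "ln1_g"] = wrap(mat(g.ln1_g)); out[pre + "ln1_b"] = wrap(mat(g.ln1_b));
    out[pre + "W1"] = wrap(g.W1); out[pre + "b1"] = wrap(mat(g.b1));
    out[pre + "W2"] = wrap(g.W2); out[pre + "b2"] = wrap(mat(g.b2));
    out[pre + "ln2_g"] = wrap(mat(g.ln2_g)); out[pre + "ln2_b"] = wrap(mat(g.ln2_b));
  }
  out["demo_W"] = wrap(G.demo_W); out["demo_b"] = wrap(mat(G.demo_b));
  out["survey_W"] = wrap(G.survey_W); out["survey_b"] = wrap(mat(G.survey_b));
  out["head_W"] = wrap(G.head_W);
  mat hb(1, 1); hb(0, 0) = G.head_b;
  out["head_b"] = wrap(hb);
  return out;
}

// [[Rcpp::export(name = ".cpp_model_run")]]
List cpp_model_run(List params, List cfg_list, IntegerMatrix tokens,
                   NumericMatrix timestamps, LogicalMatrix mask,
                   NumericMatrix demo, NumericMatrix survey,
                   NumericVector labels, double pos_weight,
                   bool training, bool want_grads) {
  Config cfg(cfg_list);
  Params P = load_params(params, cfg);
  const int B = tokens.nrow(), Lm = tokens.ncol();
  const int d = cfg.d_model;
  const bool has_labels = labels.size() == B;
  if (want_grads && !has_labels) stop("gradients require labels");

  NumericVector probs(B);
  double loss = 0.0;
  Grads G;
  if (want_grads) G = zero_grads(P);
  MaskRng rng(training && cfg.dropout > 0
                  ? (uint64_t)(unif_rand() * 9007199254740992.0)
                  : 0ULL);

  for (int b = 0; b < B; ++b) {
    // real positions
    std::vector<int> idx;
    for (int j = 0; j < Lm; ++j) if (mask(b, j)) idx.push_back(j);
    const int m = (int)idx.size();

    mat X0(m, d);
    for (int j = 0; j < m; ++j) {
      int tok = tokens(b, idx[j]);
      if (tok < 0 || tok >= (int)P.emb.n_rows)
        stop("token id out of vocabulary range");
      X0.row(j) = P.emb.row(tok) * std::sqrt((double)d) +
                  sinusoid((double)idx[j], d) +
                  sinusoid(timestamps(b, idx[j]) / cfg.time_scale, d);
    }

    std::vector<LayerCache> caches;
    mat Xf;
    rowvec s(d, arma::fill::zeros);
    mat drop0;
    if (m > 0) {
      if (training && cfg.dropout > 0) {
        // dropout on the summed embeddings + encodings (input dropout),
        // as in the original transformer
        drop0 = dropout_mask(m, d, cfg.dropout, rng);
        X0 %= drop0;
      }
      Xf = encoder_forward(P, cfg, X0, training, want_grads ? &caches : nullptr,
                           nullptr, &rng);
      s = arma::mean(Xf, 0);
    }

    rowvec demo_row(demo.ncol()), survey_row(survey.ncol());
    for (int j = 0; j < demo.ncol(); ++j) demo_row(j) = demo(b, j);
    for (int j = 0; j < survey.ncol(); ++j) survey_row(j) = survey(b, j);
    rowvec hd_pre = demo_row * P.demo_W + P.demo_b;
    rowvec hd = arma::clamp(hd_pre, 0.0, arma::datum::inf);
    rowvec hs_pre = survey_row * P.survey_W + P.survey_b;
    rowvec hs = arma::clamp(hs_pre, 0.0, arma::datum::inf);
    rowvec c = arma::join_rows(s, arma::join_rows(hd, hs));
    double z = arma::dot(c, P.head_W.col(0)) + P.head_b;
    double p = 1.0 / (1.0 + std::exp(-z));
    probs[b] = p;

    if (has_labels) {
      double y = labels[b];
      double pc = std::min(std::max(p, 1e-7), 1.0 - 1e-7);
      loss += -(pos_weight * y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
    }

    if (want_grads) {
      double y = labels[b];
      double gz = (p * (pos_weight * y + 1.0 - y) - pos_weight * y) / B;
      // head
      G.head_W += c.t() * gz;
      G.head_b += gz;
      rowvec dc = gz * P.head_W.col(0).t();
      rowvec ds = dc.subvec(0, d - 1);
      rowvec dhd = dc.subvec(d, d + cfg.demo_hidden - 1);
      rowvec dhs = dc.subvec(d + cfg.demo_hidden,
                             d + cfg.demo_hidden + cfg.survey_hidden - 1);
      rowvec dhd_pre = dhd % arma::conv_to<rowvec>::from(hd_pre > 0);
      rowvec dhs_pre = dhs % arma::conv_to<rowvec>::from(hs_pre > 0);
      G.demo_W += demo_row.t() * dhd_pre;
      G.demo_b += dhd_pre;
      G.survey_W += survey_row.t() * dhs_pre;
      G.survey_b += dhs_pre;
      if (m > 0) {
        mat dXf(m, d);
        for (int i = 0; i < m; ++i) dXf.row(i) = ds / m;
        mat dX0 = encoder_backward(P, cfg, caches, dXf, G, training);
        if (training && cfg.dropout > 0) dX0 %= drop0;
        double esc = std::sqrt((double)d);
        for (int j = 0; j < m; ++j) {
          G.emb.row(tokens(b, idx[j])) += dX0.row(j) * esc;
        }
      }
    }
  }

  List out;
  out["probs"] = probs;
  if (has_labels) out["loss"] = loss / B;
  if (want_grads) {
    G.emb.row(0).zeros();  // PAD embedding stays fixed at zero
    out["grads"] = grads_to_list(G, cfg);
  }
  return out;
}

// pooled encoder outputs (mean over unmasked positions), evaluation mode;
// the static branches and head can then be applied cheaply outside
// [[Rcpp::export(name = ".cpp_pooled")]]
NumericMatrix cpp_pooled(List params, List cfg_list, IntegerMatrix tokens,
                         NumericMatrix timestamps, LogicalMatrix mask) {
  Config cfg(cfg_list);
  Params P = load_params(params, cfg);
  const int B = tokens.nrow(), Lm = tokens.ncol();
  const int d = cfg.d_model;
  mat pooled(B, d, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    std::vector<int> idx;
    for (int j = 0; j < Lm; ++j) if (mask(b, j)) idx.push_back(j);
    const int m = (int)idx.size();
    if (m == 0) continue;
    mat X0(m, d);
    for (int j = 0; j < m; ++j) {
      int tok = tokens(b, idx[j]);
      if (tok < 0 || tok >= (int)P.emb.n_rows)
        stop("token id out of vocabulary range");
      X0.row(j) = P.emb.row(tok) * std::sqrt((double)d) +
                  sinusoid((double)idx[j], d) +
                  sinusoid(timestamps(b, idx[j]) / cfg.time_scale, d);
    }
    mat Xf = encoder_forward(P, cfg, X0, false, nullptr, nullptr);
    pooled.row(b) = arma::mean(Xf, 0);
  }
  return wrap(pooled);
}

// [[Rcpp::export(name = ".cpp_attention")]]
List cpp_attention(List params, List cfg_list, IntegerVector tokens,
                   NumericVector timestamps, LogicalVector mask) {
  Config cfg(cfg_list);
  Params P = load_params(params, cfg);
  const int Lm = tokens.size();
  const int d = cfg.d_model;
  std::vector<int> idx;
  for (int j = 0; j < Lm; ++j) if (mask[j]) idx.push_back(j);
  const int m = (int)idx.size();

  std::vector<std::vector<mat>> attn;
  if (m > 0) {
    mat X0(m, d);
    for (int j = 0; j < m; ++j) {
      X0.row(j) = P.emb.row(tokens[idx[j]]) * std::sqrt((double)d) +
                  sinusoid((double)idx[j], d) +
                  sinusoid(timestamps[idx[j]] / cfg.time_scale, d);
    }
    encoder_forward(P, cfg, X0, false, nullptr, &attn);
  }

  List layers(cfg.n_layers);
  for (int l = 0; l < cfg.n_layers; ++l) {
    List heads(cfg.n_heads);
    for (int h = 0; h < cfg.n_heads; ++h) {
      mat full(Lm, Lm, arma::fill::zeros);  // padded keys/queries: exactly 0
      if (m > 0) {
        for (int i = 0; i < m; ++i)
          for (int j = 0; j < m; ++j)
            full(idx[i], idx[j]) = attn[l][h](i, j);
      }
      heads[h] = wrap(full);
    }
    layers[l] = heads;
  }
  return layers;
}

// [[Rcpp::export(name = ".cpp_embed")]]
NumericMatrix cpp_embed(List params, List cfg_list, IntegerVector tokens,
                        NumericVector timestamps, int component) {
  Config cfg(cfg_list);
  Params P = load_params(params, cfg);
  const int Lm = tokens.size();
  const int d = cfg.d_model;
  mat out(Lm, d, arma::fill::zeros);
  for (int j = 0; j < Lm; ++j) {
    rowvec tok = P.emb.row(tokens[j]) * std::sqrt((double)d);
    rowvec pos = sinusoid((double)j, d);
    rowvec tim = sinusoid(timestamps[j] / cfg.time_scale, d);
    switch (component) {
      case 0: out.row(j) = tok + pos + tim; break;
      case 1: out.row(j) = tok; break;
      case 2: out.row(j) = pos; break;
      case 3: out.row(j) = tim; break;
      default: stop("component must be 0..3");
    }
  }
  return wrap(out);
}
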