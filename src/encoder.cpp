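// Fused training-step kernels for the rotary-embedding encoder.
//
// These mirror the reference R implementation (R/model.R, R/train.R,
// R/finetune.R) operation for operation: token embedding lookup, rotary
// rotation of queries/keys, per-sequence masked softmax attention,
// post-layer normalization, GELU feed-forward, residuals, and the exact
// backward passes. The R path stays canonical for readability and
// gradient tests; these kernels only remove interpreter overhead.
//
// Dropout masks are drawn from R's RNG (RNGScope), so runs remain
// reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static const double LN_EPS = 1e-5;
static const double GELU_C = 0.7978845608028654;  // sqrt(2/pi)

namespace {

struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  rowvec bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

struct LayerCache {
  mat X, Q, K, V, O, Xn, H1, Gt, G, xhat1, xhat2, dmask1, dmask2;
  vec inv1, inv2;
  std::vector<mat> A;  // one T x T attention matrix per (sequence, head)
  bool has_drop = false;
};

inline NumericVector as_rvec(const vec& v) {
  return NumericVector(v.begin(), v.end());
}
inline NumericVector as_rvec(const rowvec& v) {
  return NumericVector(v.begin(), v.end());
}

LayerParams read_layer(const List& lp) {
  LayerParams p;
  p.Wq = as<mat>(lp["Wq"]); p.Wk = as<mat>(lp["Wk"]);
  p.Wv = as<mat>(lp["Wv"]); p.Wo = as<mat>(lp["Wo"]);
  p.W1 = as<mat>(lp["W1"]); p.W2 = as<mat>(lp["W2"]);
  p.bq = as<rowvec>(lp["bq"]); p.bk = as<rowvec>(lp["bk"]);
  p.bv = as<rowvec>(lp["bv"]); p.bo = as<rowvec>(lp["bo"]);
  p.b1 = as<rowvec>(lp["b1"]); p.b2 = as<rowvec>(lp["b2"]);
  p.ln1_g = as<rowvec>(lp["ln1_g"]); p.ln1_b = as<rowvec>(lp["ln1_b"]);
  p.ln2_g = as<rowvec>(lp["ln2_g"]); p.ln2_b = as<rowvec>(lp["ln2_b"]);
  return p;
}

// rotary cos/sin tables, rows x hidden
void rope_tables(const vec& positions, int heads, int head_dim, mat& C, mat& S) {
  int half = head_dim / 2;
  rowvec colfreq(heads * head_dim);
  for (int h = 0; h < heads; ++h) {
    for (int i = 0; i < half; ++i) {
      double theta = std::pow(10000.0, -2.0 * i / head_dim);
      colfreq(h * head_dim + 2 * i) = theta;
      colfreq(h * head_dim + 2 * i + 1) = theta;
    }
  }
  mat ang = positions * colfreq;  // outer product
  C = arma::cos(ang);
  S = arma::sin(ang);
}

mat rope_swapsign(const mat& M) {
  mat out(M.n_rows, M.n_cols);
  for (arma::uword j = 0; j < M.n_cols; j += 2) {
    out.col(j) = -M.col(j + 1);
    out.col(j + 1) = M.col(j);
  }
  return out;
}

inline mat rope_apply(const mat& M, const mat& C, const mat& S, double dir) {
  return M % C + dir * (rope_swapsign(M) % S);
}

void ln_forward(const mat& X, const rowvec& g, const rowvec& b,
                mat& y, mat& xhat, vec& inv) {
  vec mu = arma::mean(X, 1);
  mat Xc = X.each_col() - mu;
  vec v = arma::mean(arma::square(Xc), 1);
  inv = 1.0 / arma::sqrt(v + LN_EPS);
  xhat = Xc.each_col() % inv;
  y = xhat.each_row() % g;
  y.each_row() += b;
}

void ln_backward(const mat& dY, const mat& xhat, const vec& inv, const rowvec& g,
                 mat& dX, rowvec& dg, rowvec& db) {
  mat dxhat = dY.each_row() % g;
  dg = arma::sum(dY % xhat, 0);
  db = arma::sum(dY, 0);
  vec rs1 = arma::mean(dxhat, 1);
  vec rs2 = arma::mean(dxhat % xhat, 1);
  dX = dxhat;
  dX.each_col() -= rs1;
  dX -= xhat.each_col() % rs2;
  dX.each_col() %= inv;
}

mat softmax_rows(mat M) {
  vec mx = arma::max(M, 1);
  M.each_col() -= mx;
  M = arma::exp(M);
  vec rs = arma::sum(M, 1);
  M.each_col() /= rs;
  return M;
}

mat dropout_mask(arma::uword r, arma::uword c, double rate) {
  NumericVector u = runif(r * c);
  mat m(r, c);
  double scale = 1.0 / (1.0 - rate);
  for (arma::uword j = 0; j < c; ++j)
    for (arma::uword i = 0; i < r; ++i)
      m(i, j) = u[j * r + i] >= rate ? scale : 0.0;
  return m;
}

// Full encoder forward; fills caches for the backward pass.
mat forward_pass(const List& params, const IntegerMatrix& ids,
                 const IntegerMatrix& att, int heads, double dropout,
                 std::vector<LayerParams>& lps, std::vector<LayerCache>& caches,
                 mat& C, mat& S, arma::uvec& idx) {
  const mat tok_emb = as<mat>(params["tok_emb"]);
  List layers = params["layers"];
  int L = layers.size();
  int B = ids.nrow(), T = ids.ncol();
  int H = tok_emb.n_cols;
  int dh = H / heads;
  double isq = 1.0 / std::sqrt((double)dh);

  idx.set_size(B * T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) idx(b * T + t) = ids(b, t);
  mat X(B * T, H);
  for (arma::uword r = 0; r < idx.n_elem; ++r) X.row(r) = tok_emb.row(idx(r));

  vec positions(B * T);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) positions(b * T + t) = t;
  rope_tables(positions, heads, dh, C, S);

  lps.resize(L);
  caches.resize(L);
  for (int l = 0; l < L; ++l) {
    lps[l] = read_layer(layers[l]);
    LayerParams& p = lps[l];
    LayerCache& ca = caches[l];
    ca.X = X;
    mat Qp = X * p.Wq; Qp.each_row() += p.bq;
    mat Kp = X * p.Wk; Kp.each_row() += p.bk;
    ca.Q = rope_apply(Qp, C, S, 1.0);
    ca.K = rope_apply(Kp, C, S, 1.0);
    ca.V = X * p.Wv; ca.V.each_row() += p.bv;
    ca.O.set_size(B * T, H);
    ca.A.resize(B * heads);
    for (int b = 0; b < B; ++b) {
      rowvec keymask(T);
      for (int t = 0; t < T; ++t) keymask(t) = att(b, t) == 1 ? 0.0 : -1e30;
      arma::uword r0 = b * T, r1 = (b + 1) * T - 1;
      for (int h = 0; h < heads; ++h) {
        arma::uword c0 = h * dh, c1 = (h + 1) * dh - 1;
        mat Sc = ca.Q.submat(r0, c0, r1, c1) * ca.K.submat(r0, c0, r1, c1).t() * isq;
        Sc.each_row() += keymask;
        mat A = softmax_rows(Sc);
        ca.A[b * heads + h] = A;
        ca.O.submat(r0, c0, r1, c1) = A * ca.V.submat(r0, c0, r1, c1);
      }
    }
    mat attn_out = ca.O * p.Wo; attn_out.each_row() += p.bo;
    if (dropout > 0) {
      ca.has_drop = true;
      ca.dmask1 = dropout_mask(attn_out.n_rows, attn_out.n_cols, dropout);
      attn_out %= ca.dmask1;
    }
    ln_forward(X + attn_out, p.ln1_g, p.ln1_b, ca.Xn, ca.xhat1, ca.inv1);
    ca.H1 = ca.Xn * p.W1; ca.H1.each_row() += p.b1;
    ca.Gt = arma::tanh(GELU_C * (ca.H1 + 0.044715 * arma::pow(ca.H1, 3)));
    ca.G = 0.5 * ca.H1 % (1.0 + ca.Gt);
    mat ffn_out = ca.G * p.W2; ffn_out.each_row() += p.b2;
    if (dropout > 0) {
      ca.dmask2 = dropout_mask(ffn_out.n_rows, ffn_out.n_cols, dropout);
      ffn_out %= ca.dmask2;
    }
    mat y2, xhat2; vec inv2;
    ln_forward(ca.Xn + ffn_out, p.ln2_g, p.ln2_b, y2, ca.xhat2, ca.inv2);
    X = y2;
  }
  return X;
}

// Backward through all layers; returns gradients as a named flat list and
// accumulates the token-embedding gradient.
void backward_pass(mat dX, const std::vector<LayerParams>& lps,
                   const std::vector<LayerCache>& caches, const mat& C,
                   const mat& S, const arma::uvec& idx, int heads,
                   int vocab_rows, List& out) {
  int L = lps.size();
  int H = dX.n_cols;
  arma::uword BT = dX.n_rows;
  int T = caches[0].A[0].n_rows;
  int B = BT / T;
  int dh = H / heads;
  double isq = 1.0 / std::sqrt((double)dh);

  for (int l = L - 1; l >= 0; --l) {
    const LayerParams& p = lps[l];
    const LayerCache& ca = caches[l];
    std::string pre = "layers" + std::to_string(l + 1) + ".";
    mat dXn_ln2; rowvec dg2, db2;
    ln_backward(dX, ca.xhat2, ca.inv2, p.ln2_g, dXn_ln2, dg2, db2);
    out[pre + "ln2_g"] = as_rvec(dg2);
    out[pre + "ln2_b"] = as_rvec(db2);
    mat dffn = dXn_ln2;
    if (ca.has_drop) dffn %= ca.dmask2;
    out[pre + "W2"] = ca.G.t() * dffn;
    out[pre + "b2"] = as_rvec(rowvec(arma::sum(dffn, 0)));
    mat dG = dffn * p.W2.t();
    mat gg = 0.5 * (1.0 + ca.Gt) +
      0.5 * ca.H1 % (1.0 - arma::square(ca.Gt)) % (GELU_C * (1.0 + 3 * 0.044715 * arma::square(ca.H1)));
    mat dH1 = dG % gg;
    out[pre + "W1"] = ca.Xn.t() * dH1;
    out[pre + "b1"] = as_rvec(rowvec(arma::sum(dH1, 0)));
    mat dXn = dXn_ln2 + dH1 * p.W1.t();
    mat dattn; rowvec dg1, db1;
    ln_backward(dXn, ca.xhat1, ca.inv1, p.ln1_g, dattn, dg1, db1);
    out[pre + "ln1_g"] = as_rvec(dg1);
    out[pre + "ln1_b"] = as_rvec(db1);
    if (ca.has_drop) dattn %= ca.dmask1;
    out[pre + "Wo"] = ca.O.t() * dattn;
    out[pre + "bo"] = as_rvec(rowvec(arma::sum(dattn, 0)));
    mat dO = dattn * p.Wo.t();
    mat dQ(BT, H, arma::fill::zeros), dK(BT, H, arma::fill::zeros),
        dV(BT, H, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      arma::uword r0 = (arma::uword)b * T, r1 = (arma::uword)(b + 1) * T - 1;
      for (int h = 0; h < heads; ++h) {
        arma::uword c0 = h * dh, c1 = (h + 1) * dh - 1;
        const mat& A = ca.A[b * heads + h];
        mat dOb = dO.submat(r0, c0, r1, c1);
        mat dA = dOb * ca.V.submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = A.t() * dOb;
        vec rs = arma::sum(dA % A, 1);
        mat dS = A % (dA.each_col() - rs);
        dQ.submat(r0, c0, r1, c1) = dS * ca.K.submat(r0, c0, r1, c1) * isq;
        dK.submat(r0, c0, r1, c1) = dS.t() * ca.Q.submat(r0, c0, r1, c1) * isq;
      }
    }
    dQ = rope_apply(dQ, C, S, -1.0);
    dK = rope_apply(dK, C, S, -1.0);
    out[pre + "Wq"] = ca.X.t() * dQ;
    out[pre + "bq"] = as_rvec(rowvec(arma::sum(dQ, 0)));
    out[pre + "Wk"] = ca.X.t() * dK;
    out[pre + "bk"] = as_rvec(rowvec(arma::sum(dK, 0)));
    out[pre + "Wv"] = ca.X.t() * dV;
    out[pre + "bv"] = as_rvec(rowvec(arma::sum(dV, 0)));
    dX = dattn + dQ * p.Wq.t() + dK * p.Wk.t() + dV * p.Wv.t();
  }
  mat demb(vocab_rows, H, arma::fill::zeros);
  for (arma::uword r = 0; r < BT; ++r) demb.row(idx(r)) += dX.row(r);
  out["tok_emb"] = demb;
}

}  // namespace

// Inference forward: final hidden states, (B*T) x H, sequence-major rows.
// [[Rcpp::export(name = ".cpp_encoder_hidden")]]
NumericMatrix cpp_encoder_hidden(List params, IntegerMatrix ids,
                                 IntegerMatrix att, int heads) {
  std::vector<LayerParams> lps;
  std::vector<LayerCache> caches;
  mat C, S;
  arma::uvec idx;
  mat X = forward_pass(params, ids, att, heads, 0.0, lps, caches, C, S, idx);
  return wrap(X);
}

// One masked-language-model step: cross-entropy at label positions
// (mean-normalized) and gradients for every parameter.
// [[Rcpp::export(name = ".cpp_mlm_step")]]
List cpp_mlm_step(List params, IntegerMatrix ids, IntegerMatrix att,
                  IntegerMatrix labels, int heads, double dropout) {
  RNGScope scope;
  std::vector<LayerParams> lps;
  std::vector<LayerCache> caches;
  mat C, S;
  arma::uvec idx;
  mat X = forward_pass(params, ids, att, heads, dropout, lps, caches, C, S, idx);
  const mat lm_W = as<mat>(params["lm_W"]);
  const rowvec lm_b = as<rowvec>(params["lm_b"]);
  int B = ids.nrow(), T = ids.ncol();
  std::vector<arma::uword> rows;
  std::vector<int> tgt;
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t)
      if (labels(b, t) >= 0) {
        rows.push_back((arma::uword)b * T + t);
        tgt.push_back(labels(b, t));
      }
  List out;
  int n = rows.size();
  if (n == 0) {
    out["loss_sum"] = 0.0;
    out["n"] = 0;
    return out;
  }
  arma::uvec ridx(n);
  for (int i = 0; i < n; ++i) ridx(i) = rows[i];
  mat Hsub = X.rows(ridx);
  mat logits = Hsub * lm_W; logits.each_row() += lm_b;
  mat P = softmax_rows(logits);
  double loss = 0;
  for (int i = 0; i < n; ++i) {
    double pi = std::max(P(i, tgt[i]), 1e-12);
    loss -= std::log(pi);
    P(i, tgt[i]) -= 1.0;
  }
  P /= n;
  out["loss_sum"] = loss;
  out["n"] = n;
  out["lm_W"] = Hsub.t() * P;
  out["lm_b"] = as_rvec(rowvec(arma::sum(P, 0)));
  mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  dX.rows(ridx) = P * lm_W.t();
  int vocab_rows = as<mat>(params["tok_emb"]).n_rows;
  backward_pass(dX, lps, caches, C, S, idx, heads, vocab_rows, out);
  return out;
}

// One regression step: mean-pooled hidden states (content positions only,
// token ids >= 5) through a linear head, squared-error loss, gradients for
// head and encoder.
// [[Rcpp::export(name = ".cpp_reg_step")]]
List cpp_reg_step(List params, NumericVector head_w, double head_b,
                  IntegerMatrix ids, IntegerMatrix att, NumericVector y,
                  int heads, double dropout) {
  RNGScope scope;
  std::vector<LayerParams> lps;
  std::vector<LayerCache> caches;
  mat C, S;
  arma::uvec idx;
  mat X = forward_pass(params, ids, att, heads, dropout, lps, caches, C, S, idx);
  int B = ids.nrow(), T = ids.ncol();
  int H = X.n_cols;
  vec w = as<vec>(head_w);
  mat pooled(B, H, arma::fill::zeros);
  vec counts(B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int t = 0; t < T; ++t)
      if (ids(b, t) >= 5) {
        pooled.row(b) += X.row((arma::uword)b * T + t);
        counts(b) += 1;
      }
    if (counts(b) < 1) counts(b) = 1;
    pooled.row(b) /= counts(b);
  }
  vec pred = pooled * w + head_b;
  vec err = pred - as<vec>(y);
  vec dpred = 2.0 * err / B;
  List out;
  out["pred"] = as_rvec(pred);
  out["loss"] = arma::mean(arma::square(err));
  out["head.w"] = as_rvec(vec(pooled.t() * dpred));
  out["head.b"] = arma::sum(dpred);
  mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    rowvec g = (dpred(b) / counts(b)) * w.t();
    for (int t = 0; t < T; ++t)
      if (ids(b, t) >= 5) dX.row((arma::uword)b * T + t) = g;
  }
  int vocab_rows = as<mat>(params["tok_emb"]).n_rows;
  backward_pass(dX, lps, caches, C, S, idx, heads, vocab_rows, out);
  return out;
}
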