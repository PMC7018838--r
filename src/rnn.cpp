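// Stacked (optionally bidirectional) GRU sequence classifier: forward pass,
// full backpropagation through time, and the combined cross-entropy +
// generalized Dice loss. Parameters live in a named R list of matrices;
// the R side owns initialization and the Adam update loop.
//
// Layout conventions:
//   - a batch is a cube X of size (d x B x T); flattening slices gives a
//     (d x B*T) matrix whose column index is b + B*t
//   - GRU gate matrices stack the reset/update/candidate blocks row-wise
//     ([r; z; n], h rows each): Wx (3h x in), Wh (3h x h), bx, bh (3h)
//   - candidate uses n = tanh(Wx_n x + bx_n + r % (Wh_n h + bh_n))

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static mat sigmoid_m(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruCache {
  cube r, z, nb, ghn, hs;  // each h x B x T; hs holds h_t
};

// forward one direction of one GRU layer; X is (in x B x T) in time order
static cube gru_forward(const mat& Wx, const mat& Wh,
                        const vec& bx, const vec& bh,
                        const cube& X, GruCache& c) {
  const uword in = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword h = Wh.n_cols;
  mat Xf(const_cast<double*>(X.memptr()), in, B * T, false, true);
  mat GX = Wx * Xf;              // 3h x B*T
  GX.each_col() += bx;
  c.r.set_size(h, B, T); c.z.set_size(h, B, T);
  c.nb.set_size(h, B, T); c.ghn.set_size(h, B, T);
  c.hs.set_size(h, B, T);
  mat hprev(h, B, fill::zeros);
  mat gh(3 * h, B);
  for (uword t = 0; t < T; ++t) {
    const mat gx(GX.colptr(B * t), 3 * h, B, false, true);
    // aliases into the cache slices: computed in place, no copies
    mat r(c.r.slice_memptr(t), h, B, false, true);
    mat z(c.z.slice_memptr(t), h, B, false, true);
    mat nb(c.nb.slice_memptr(t), h, B, false, true);
    mat ghn(c.ghn.slice_memptr(t), h, B, false, true);
    mat hnew(c.hs.slice_memptr(t), h, B, false, true);
    gh = Wh * hprev;
    gh.each_col() += bh;
    r = sigmoid_m(gx.rows(0, h - 1) + gh.rows(0, h - 1));
    z = sigmoid_m(gx.rows(h, 2 * h - 1) + gh.rows(h, 2 * h - 1));
    ghn = gh.rows(2 * h, 3 * h - 1);
    nb = tanh(gx.rows(2 * h, 3 * h - 1) + r % ghn);
    hnew = (1.0 - z) % nb + z % hprev;
    hprev = hnew;
  }
  return c.hs;
}

// backward for one direction; dH is (h x B x T); fills dX and grads
static void gru_backward(const mat& Wx, const mat& Wh,
                         const cube& X, const GruCache& c, const cube& dH,
                         cube& dX, mat& dWx, mat& dWh, vec& dbx, vec& dbh) {
  const uword in = X.n_rows, B = X.n_cols, T = X.n_slices;
  const uword h = Wh.n_cols;
  mat dGX(3 * h, B * T, fill::zeros);
  dWh.zeros(3 * h, h);
  dbh.zeros(3 * h);
  mat dh(h, B, fill::zeros);
  mat dgh(3 * h, B);
  const mat zero_h(h, B, fill::zeros);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    const mat r(const_cast<double*>(c.r.slice_memptr(t)), h, B, false, true);
    const mat z(const_cast<double*>(c.z.slice_memptr(t)), h, B, false, true);
    const mat nb(const_cast<double*>(c.nb.slice_memptr(t)), h, B, false, true);
    const mat ghn(const_cast<double*>(c.ghn.slice_memptr(t)), h, B, false, true);
    const mat hprev = (t == 0)
      ? zero_h
      : mat(const_cast<double*>(c.hs.slice_memptr(t - 1)), h, B, false, true);
    mat dgx(dGX.colptr(B * t), 3 * h, B, false, true);
    mat dan = (dh % (1.0 - z)) % (1.0 - nb % nb);   // pre-tanh candidate
    dgh.rows(0, h - 1) = (dan % ghn) % r % (1.0 - r);
    dgh.rows(h, 2 * h - 1) = (dh % (hprev - nb)) % z % (1.0 - z);
    dgh.rows(2 * h, 3 * h - 1) = dan % r;
    dWh += dgh * hprev.t();
    dbh += sum(dgh, 1);
    dgx.rows(0, 2 * h - 1) = dgh.rows(0, 2 * h - 1);
    dgx.rows(2 * h, 3 * h - 1) = dan;
    dh = dh % z + Wh.t() * dgh;
  }
  mat Xf(const_cast<double*>(X.memptr()), in, B * T, false, true);
  dWx = dGX * Xf.t();
  dbx = sum(dGX, 1);
  mat dXf = Wx.t() * dGX;
  dX.set_size(in, B, T);
  std::memcpy(dX.memptr(), dXf.memptr(), sizeof(double) * in * B * T);
}

static cube reverse_time(const cube& X) {
  cube Y(X.n_rows, X.n_cols, X.n_slices);
  for (uword t = 0; t < X.n_slices; ++t)
    Y.slice(t) = X.slice(X.n_slices - 1 - t);
  return Y;
}

static mat dropout_mask(uword nr, uword nc, double p) {
  mat m(nr, nc);
  for (uword j = 0; j < nc; ++j)
    for (uword i = 0; i < nr; ++i)
      m(i, j) = (R::unif_rand() < p) ? 0.0 : 1.0 / (1.0 - p);
  return m;
}

struct NetCache {
  std::vector<mat> fc_pre;       // pre-activation of each FC layer
  std::vector<mat> fc_out;       // post-ReLU (after dropout where applied)
  std::vector<mat> fc_dropm;
  std::vector<GruCache> gf, gb;  // per layer, forward / backward direction
  std::vector<cube> layer_in;    // input cube to each GRU layer
  std::vector<mat> gru_dropm;
  mat hcat;                      // final concatenated hidden (hd x B*T)
  mat probs;                     // 3 x B*T
};

// full forward pass; returns logits (3 x B*T)
static mat net_forward(const List& params, const cube& X, int k, int h,
                       bool bidir, double dropout, bool train, NetCache& nc) {
  const uword d = X.n_rows, B = X.n_cols, T = X.n_slices;
  mat cur(const_cast<double*>(X.memptr()), d, B * T, false, true);
  mat curc = cur;                // copy: FC chain operates on 2-D view
  // FC feature extractor
  for (int l = 0; l < k; ++l) {
    mat W = params["fc_W" + std::to_string(l + 1)];
    vec b = Rcpp::as<vec>(params["fc_b" + std::to_string(l + 1)]);
    mat pre = W * curc;
    pre.each_col() += b;
    nc.fc_pre.push_back(pre);
    mat out = clamp(pre, 0.0, datum::inf);   // ReLU
    if (train && dropout > 0) {
      mat dm = dropout_mask(out.n_rows, out.n_cols, dropout);
      out %= dm;
      nc.fc_dropm.push_back(dm);
    } else {
      nc.fc_dropm.push_back(mat());
    }
    nc.fc_out.push_back(out);
    curc = out;
  }
  // GRU stack
  cube cin(curc.memptr(), curc.n_rows, B, T);
  nc.gf.resize(k); nc.gb.resize(k);
  for (int l = 0; l < k; ++l) {
    nc.layer_in.push_back(cin);
    std::string p = "gru" + std::to_string(l + 1) + "_";
    cube hf = gru_forward(params[p + "f_Wx"], params[p + "f_Wh"],
                          Rcpp::as<vec>(params[p + "f_bx"]),
                          Rcpp::as<vec>(params[p + "f_bh"]), cin, nc.gf[l]);
    cube hout;
    if (bidir) {
      cube rin = reverse_time(cin);
      cube hb = gru_forward(params[p + "b_Wx"], params[p + "b_Wh"],
                            Rcpp::as<vec>(params[p + "b_bx"]),
                            Rcpp::as<vec>(params[p + "b_bh"]), rin, nc.gb[l]);
      cube hbr = reverse_time(hb);
      hout.set_size(2 * h, B, T);
      hout.tube(0, 0, h - 1, B - 1) = hf;
      hout.tube(h, 0, 2 * h - 1, B - 1) = hbr;
    } else {
      hout = hf;
    }
    mat hflat(hout.memptr(), hout.n_rows, B * T);
    if (train && dropout > 0 && l < k - 1) {
      mat dm = dropout_mask(hflat.n_rows, hflat.n_cols, dropout);
      hflat %= dm;
      nc.gru_dropm.push_back(dm);
    } else {
      nc.gru_dropm.push_back(mat());
    }
    cin = cube(hflat.memptr(), hflat.n_rows, B, T);
  }
  nc.hcat = mat(cin.memptr(), cin.n_rows, B * T);
  mat Wo = params["out_W"];
  vec bo = Rcpp::as<vec>(params["out_b"]);
  mat logits = Wo * nc.hcat;
  logits.each_col() += bo;
  return logits;
}

// softmax columns
static mat softmax_cols(const mat& logits) {
  mat m = logits.each_row() - max(logits, 0);
  m = exp(m);
  m.each_row() /= sum(m, 0);
  return m;
}

// combined CE + generalized-Dice loss and gradient w.r.t. logits.
// y: class index 0..C-1, or negative for ignored samples; w: sample weight
static double loss_and_dlogits(const mat& probs, const ivec& y, const vec& w,
                               double lambda_dice, mat& dlogits,
                               double* ce_out, double* dice_out) {
  const uword C = probs.n_rows, N = probs.n_cols;
  uvec valid = find(y >= 0);
  double wsum = 0.0;
  for (uword ii = 0; ii < valid.n_elem; ++ii) wsum += w(valid(ii));
  if (wsum <= 0) { dlogits.zeros(C, N); *ce_out = 0; *dice_out = 0; return 0; }
  // cross-entropy
  double ce = 0.0;
  mat dp(C, N, fill::zeros);     // dL/dp for the dice part accumulates here
  mat dl(C, N, fill::zeros);     // CE contributes directly to dlogits
  for (uword ii = 0; ii < valid.n_elem; ++ii) {
    uword n = valid(ii);
    uword c = (uword)y(n);
    double p = std::max(probs(c, n), 1e-12);
    ce += -w(n) * std::log(p);
    for (uword cc = 0; cc < C; ++cc)
      dl(cc, n) = w(n) * (probs(cc, n) - (cc == c ? 1.0 : 0.0)) / wsum;
  }
  ce /= wsum;
  // generalized Dice over valid samples (unweighted)
  vec gsum(C, fill::zeros), inter(C, fill::zeros), psum(C, fill::zeros);
  for (uword ii = 0; ii < valid.n_elem; ++ii) {
    uword n = valid(ii);
    uword c = (uword)y(n);
    gsum(c) += 1.0;
    inter(c) += probs(c, n);
    for (uword cc = 0; cc < C; ++cc) psum(cc) += probs(cc, n);
  }
  vec wc(C);
  for (uword c = 0; c < C; ++c)
    wc(c) = gsum(c) > 0 ? 1.0 / (gsum(c) * gsum(c)) : 0.0;
  double Nnum = dot(wc, inter);
  double Dden = dot(wc, psum + gsum);
  double dice = (Dden > 0) ? 1.0 - 2.0 * Nnum / Dden : 0.0;
  if (Dden > 0) {
    for (uword ii = 0; ii < valid.n_elem; ++ii) {
      uword n = valid(ii);
      uword c = (uword)y(n);
      for (uword cc = 0; cc < C; ++cc) {
        double dnum = (cc == c) ? wc(cc) : 0.0;     // d inter / d p
        double dden = wc(cc);                        // d psum / d p
        dp(cc, n) += lambda_dice *
          (-2.0) * (dnum * Dden - Nnum * dden) / (Dden * Dden);
      }
    }
  }
  // chain dice dL/dp through softmax: dl_k = p_k (dp_k - sum_c p_c dp_c)
  rowvec s = sum(probs % dp, 0);
  mat dice_dl = probs % (dp.each_row() - s);
  dlogits = dl + dice_dl;
  *ce_out = ce;
  *dice_out = dice;
  return ce + lambda_dice * dice;
}

// backward through the whole net given dlogits; returns named grads
static List net_backward(const List& params, const cube& X, int k, int h,
                         bool bidir, const NetCache& nc, const mat& dlogits) {
  const uword d = X.n_rows, B = X.n_cols, T = X.n_slices;
  List g;
  mat Wo = params["out_W"];
  g["out_W"] = mat(dlogits * nc.hcat.t());
  g["out_b"] = vec(sum(dlogits, 1));
  mat dh = Wo.t() * dlogits;    // hd x B*T
  for (int l = k - 1; l >= 0; --l) {
    if (!nc.gru_dropm[l].is_empty()) dh %= nc.gru_dropm[l];
    std::string p = "gru" + std::to_string(l + 1) + "_";
    cube dhc(dh.memptr(), dh.n_rows, B, T);
    cube dxf, dxb;
    mat dWx, dWh; vec dbx, dbh;
    if (bidir) {
      cube dhf = dhc.tube(0, 0, h - 1, B - 1);
      cube dhb = dhc.tube(h, 0, 2 * h - 1, B - 1);
      gru_backward(params[p + "f_Wx"], params[p + "f_Wh"],
                   nc.layer_in[l], nc.gf[l], dhf, dxf, dWx, dWh, dbx, dbh);
      g[p + "f_Wx"] = dWx; g[p + "f_Wh"] = dWh;
      g[p + "f_bx"] = dbx; g[p + "f_bh"] = dbh;
      cube rin = reverse_time(nc.layer_in[l]);
      cube dhbr = reverse_time(dhb);
      cube dxb_r;
      gru_backward(params[p + "b_Wx"], params[p + "b_Wh"],
                   rin, nc.gb[l], dhbr, dxb_r, dWx, dWh, dbx, dbh);
      g[p + "b_Wx"] = dWx; g[p + "b_Wh"] = dWh;
      g[p + "b_bx"] = dbx; g[p + "b_bh"] = dbh;
      dxb = reverse_time(dxb_r);
      cube dX = dxf + dxb;
      dh = mat(dX.memptr(), dX.n_rows, B * T);
    } else {
      gru_backward(params[p + "f_Wx"], params[p + "f_Wh"],
                   nc.layer_in[l], nc.gf[l], dhc, dxf, dWx, dWh, dbx, dbh);
      g[p + "f_Wx"] = dWx; g[p + "f_Wh"] = dWh;
      g[p + "f_bx"] = dbx; g[p + "f_bh"] = dbh;
      dh = mat(dxf.memptr(), dxf.n_rows, B * T);
    }
  }
  // FC chain backward
  for (int l = k - 1; l >= 0; --l) {
    if (!nc.fc_dropm[l].is_empty()) dh %= nc.fc_dropm[l];
    dh %= conv_to<mat>::from(nc.fc_pre[l] > 0);   // ReLU
    mat below = (l == 0)
      ? mat(const_cast<double*>(X.memptr()), d, B * T, false, true)
      : nc.fc_out[l - 1];
    std::string nm = std::to_string(l + 1);
    mat W = params["fc_W" + nm];
    g["fc_W" + nm] = mat(dh * below.t());
    g["fc_b" + nm] = vec(sum(dh, 1));
    dh = W.t() * dh;
  }
  return g;
}

// [[Rcpp::export]]
List rnn_grad_cpp(List params, arma::cube X, arma::ivec y, arma::vec w,
                  int k, int h, bool bidir, double dropout, bool train,
                  double lambda_dice) {
  Rcpp::RNGScope rng;            // dropout draws from R's RNG stream
  NetCache nc;
  mat logits = net_forward(params, X, k, h, bidir, dropout, train, nc);
  mat probs = softmax_cols(logits);
  mat dlogits;
  double ce, dice;
  double loss = loss_and_dlogits(probs, y, w, lambda_dice, dlogits, &ce, &dice);
  List grads = net_backward(params, X, k, h, bidir, nc, dlogits);
  return List::create(Named("loss") = loss, Named("ce") = ce,
                      Named("dice") = dice, Named("grads") = grads);
}

// [[Rcpp::export]]
arma::mat rnn_predict_cpp(List params, arma::cube X, int k, int h, bool bidir) {
  NetCache nc;
  mat logits = net_forward(params, X, k, h, bidir, 0.0, false, nc);
  return softmax_cols(logits);   // 3 x (B*T), column index = b + B*t
}
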