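// Single-layer LSTM kernel: batched forward pass and full
// backpropagation-through-time for a masked squared-error loss.
//
// Shapes: X is a T x D x S cube (T months, D predictors, S sites); the
// recurrence is vectorized across sites, so states are H x S matrices.
// Gate weights are packed column-wise in the order
//   [input | forget | cell-candidate | output],
// i.e. Wx is D x 4H, Wh is H x 4H, b is 4H. The output layer is a single
// linear unit (Wy: H, by: scalar). `drop` is an inverted-dropout mask on the
// hidden-to-output connection (all ones at prediction time). Initial hidden
// and cell states are zero.
//
// For speed the input projection Wx' * x_t is lifted out of the time loop
// into one GEMM over all (t, s) columns, the gate nonlinearities run as
// hand-written loops over raw buffers, and the weight gradients are
// accumulated as single GEMMs over the stored per-timestep gate deltas.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static void check_shapes(const cube& X, const mat& Wx, const mat& Wh,
                         const vec& b, const vec& Wy, const vec& drop) {
  const uword D = X.n_cols, H = Wh.n_rows;
  if (Wx.n_rows != D || Wx.n_cols != 4 * H || Wh.n_cols != 4 * H ||
      b.n_elem != 4 * H || Wy.n_elem != H || drop.n_elem != H)
    Rcpp::stop("lstm kernel: weight shapes inconsistent with inputs");
}

// X (T x D x S) flattened to D x (S*T), column t*S + s
static mat flatten_inputs(const cube& X) {
  const uword T = X.n_rows, D = X.n_cols, S = X.n_slices;
  mat out(D, S * T);
  for (uword s = 0; s < S; ++s) {
    const mat& sl = X.slice(s);
    for (uword t = 0; t < T; ++t)
      out.col(t * S + s) = sl.row(t).t();
  }
  return out;
}

// [[Rcpp::export]]
arma::mat lstm_forward_cpp(const arma::cube& X,
                           const arma::mat& Wx, const arma::mat& Wh,
                           const arma::vec& b, const arma::vec& Wy,
                           double by, const arma::vec& drop) {
  check_shapes(X, Wx, Wh, b, Wy, drop);
  const uword T = X.n_rows, S = X.n_slices, H = Wh.n_rows;
  const mat WhT = Wh.t();
  const vec Wyd = Wy % drop;

  const mat Xall = flatten_inputs(X);
  const mat Ax = Wx.t() * Xall;            // 4H x S*T

  mat preds(T, S);
  mat h(H, S, fill::zeros), c(H, S, fill::zeros), a(4 * H, S);
  const double* bp = b.memptr();
  for (uword t = 0; t < T; ++t) {
    a = Ax.cols(t * S, t * S + S - 1) + WhT * h;
    double* ap = a.memptr();
    double* hp = h.memptr();
    double* cp = c.memptr();
    for (uword s = 0; s < S; ++s) {
      const double* ac = ap + s * 4 * H;
      double* hc = hp + s * H;
      double* cc = cp + s * H;
      for (uword k = 0; k < H; ++k) {
        const double iv = sig(ac[k] + bp[k]);
        const double fv = sig(ac[H + k] + bp[H + k]);
        const double gv = std::tanh(ac[2 * H + k] + bp[2 * H + k]);
        const double ov = sig(ac[3 * H + k] + bp[3 * H + k]);
        cc[k] = fv * cc[k] + iv * gv;
        hc[k] = ov * std::tanh(cc[k]);
      }
    }
    preds.row(t) = Wyd.t() * h + by;
  }
  return preds;
}

// [[Rcpp::export]]
Rcpp::List lstm_loss_grad_cpp(const arma::cube& X, const arma::mat& y,
                              const arma::umat& mask,
                              const arma::mat& Wx, const arma::mat& Wh,
                              const arma::vec& b, const arma::vec& Wy,
                              double by, const arma::vec& drop) {
  check_shapes(X, Wx, Wh, b, Wy, drop);
  const uword T = X.n_rows, S = X.n_slices, H = Wh.n_rows;
  if (y.n_rows != T || y.n_cols != S || mask.n_rows != T || mask.n_cols != S)
    Rcpp::stop("lstm kernel: target/mask shapes inconsistent with X");
  const double M = accu(mask);
  if (M < 1) Rcpp::stop("lstm kernel: mask has no observed entries");

  const mat WhT = Wh.t();
  const vec Wyd = Wy % drop;
  const mat Xall = flatten_inputs(X);
  const mat Ax = Wx.t() * Xall;

  // caches over all (t, s) columns: gates, cell, tanh(cell), hidden
  mat Ica(H, S * T), Fca(H, S * T), Gca(H, S * T), Oca(H, S * T),
      Cca(H, S * T), TCa(H, S * T), Hall(H, S * T);
  mat h(H, S, fill::zeros), c(H, S, fill::zeros), a(4 * H, S);
  mat resid(T, S, fill::zeros);
  double loss = 0.0;
  const double* bp = b.memptr();
  for (uword t = 0; t < T; ++t) {
    a = Ax.cols(t * S, t * S + S - 1) + WhT * h;
    const double* ap = a.memptr();
    double* hp = h.memptr();
    double* cp = c.memptr();
    for (uword s = 0; s < S; ++s) {
      const uword col = t * S + s;
      const double* ac = ap + s * 4 * H;
      double* hc = hp + s * H;
      double* cc = cp + s * H;
      double* Ip = Ica.colptr(col); double* Fp = Fca.colptr(col);
      double* Gp = Gca.colptr(col); double* Op = Oca.colptr(col);
      double* Cp = Cca.colptr(col); double* Tp = TCa.colptr(col);
      double* Hp = Hall.colptr(col);
      for (uword k = 0; k < H; ++k) {
        const double iv = sig(ac[k] + bp[k]);
        const double fv = sig(ac[H + k] + bp[H + k]);
        const double gv = std::tanh(ac[2 * H + k] + bp[2 * H + k]);
        const double ov = sig(ac[3 * H + k] + bp[3 * H + k]);
        const double cv = fv * cc[k] + iv * gv;
        const double tv = std::tanh(cv);
        Ip[k] = iv; Fp[k] = fv; Gp[k] = gv; Op[k] = ov;
        Cp[k] = cv; Tp[k] = tv;
        cc[k] = cv;
        hc[k] = ov * tv;
        Hp[k] = hc[k];
      }
    }
    const rowvec pred = Wyd.t() * h + by;
    for (uword s = 0; s < S; ++s) {
      if (mask(t, s)) {
        const double e = pred(s) - y(t, s);
        loss += e * e / M;
        resid(t, s) = 2.0 * e / M;
      }
    }
  }

  // backward sweep: per-timestep gate deltas stored column-wise, then the
  // weight gradients fall out as single GEMMs
  mat DAall(4 * H, S * T), HPall(H, S * T);
  mat dh(H, S), da(4 * H, S);
  mat dh_next(H, S, fill::zeros);
  vec dc_next_buf(H * S, fill::zeros);
  for (uword tt = T; tt-- > 0;) {
    const rowvec r = resid.row(tt);
    dh = Wyd * r + dh_next;
    const double* dhp = dh.memptr();
    double* dap = da.memptr();
    double* dcn = dc_next_buf.memptr();
    for (uword s = 0; s < S; ++s) {
      const uword col = tt * S + s;
      const double* Ip = Ica.colptr(col); const double* Fp = Fca.colptr(col);
      const double* Gp = Gca.colptr(col); const double* Op = Oca.colptr(col);
      const double* Tp = TCa.colptr(col);
      const double* cprev = (tt > 0) ? Cca.colptr(col - S) : nullptr;
      const double* hprev = (tt > 0) ? Hall.colptr(col - S) : nullptr;
      double* hpcol = HPall.colptr(col);
      const double* dhc = dhp + s * H;
      double* dac = dap + s * 4 * H;
      double* dcc = dcn + s * H;
      for (uword k = 0; k < H; ++k) {
        const double tv = Tp[k], ov = Op[k], iv = Ip[k], fv = Fp[k],
                     gv = Gp[k];
        const double dov = dhc[k] * tv;
        const double dcv = dhc[k] * ov * (1.0 - tv * tv) + dcc[k];
        const double cpv = cprev ? cprev[k] : 0.0;
        dac[k]         = dcv * gv * iv * (1.0 - iv);
        dac[H + k]     = dcv * cpv * fv * (1.0 - fv);
        dac[2 * H + k] = dcv * iv * (1.0 - gv * gv);
        dac[3 * H + k] = dov * ov * (1.0 - ov);
        dcc[k] = dcv * fv;
        hpcol[k] = hprev ? hprev[k] : 0.0;
      }
    }
    DAall.cols(tt * S, tt * S + S - 1) = da;
    dh_next = Wh * da;
  }

  // flatten residuals to match the (t*S + s) column layout
  vec rflat(S * T);
  for (uword t = 0; t < T; ++t)
    for (uword s = 0; s < S; ++s) rflat(t * S + s) = resid(t, s);

  const mat dWx = Xall * DAall.t();
  const mat dWh = HPall * DAall.t();
  const vec db = sum(DAall, 1);
  const vec dWy = (Hall.each_col() % drop) * rflat;
  const double dby = accu(rflat);

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("dWx") = dWx, Rcpp::Named("dWh") = dWh,
    Rcpp::Named("db") = db, Rcpp::Named("dWy") = dWy,
    Rcpp::Named("dby") = dby);
}
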