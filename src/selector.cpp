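// Core of the attention-based feature selector: per-feature tokenization,
// pre-norm multi-head self-attention encoder block(s) with feed-forward
// sublayer and residual connections, CLS classification head, and the joint
// objective L_total = L_cls + lambda1 * L_stat + lambda2 * R, where L_stat is
// the negative mean per-feature ridge-regularized Hotelling T^2 between
// outcome groups and R is the mean squared norm of the input token
// embeddings. Gradients are hand-derived and validated against finite
// differences in the test suite.
//
// Conventions: tokens are row vectors; a linear map is x -> x * W + b.
// The batch is held as one big (n*t) x d matrix whose row i*t + a is token a
// of sample i (token 0 = CLS, token j = feature j, 1-based j-1 in R).
// Parameter vector layout (column-major for matrices), with t = p + 1,
// dff = 4*d:
//   for each feature j: affine -> w_j (d), b_j (d); categorical -> Emb_j (d x K_j)
//   cls (d)
//   per layer: ln1_g, ln1_b (d each); Wq (d x d), bq (d); Wk, bk; Wv, bv;
//              Wo (d x d), bo (d); ln2_g, ln2_b; W1 (d x dff), b1 (dff);
//              W2 (dff x d), b2 (d)
//   head_w (d), head_b (1)

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static const double LN_EPS = 1e-5;

struct LayerP {
  vec ln1_g, ln1_b, bq, bk, bv, bo, ln2_g, ln2_b, b1, b2;
  mat Wq, Wk, Wv, Wo, W1, W2;
};

struct Params {
  std::vector<mat> tokA;   // affine features: d x 2 (col 0 = w, col 1 = b)
  std::vector<mat> tokE;   // categorical features: d x K
  vec cls;
  std::vector<LayerP> layers;
  vec head_w;
  double head_b;
};

struct Cursor {
  const double* p;
  size_t off;
  vec getv(int len) { vec v(p + off, len); off += len; return v; }
  mat getm(int r, int c) { mat m(p + off, r, c); off += (size_t)r * c; return m; }
  double gets() { return p[off++]; }
};

struct GCursor {
  double* p;
  size_t off;
  void addv(const vec& v) { for (uword i = 0; i < v.n_elem; ++i) p[off + i] += v(i); off += v.n_elem; }
  void addm(const mat& m) { for (uword i = 0; i < m.n_elem; ++i) p[off + i] += m(i); off += m.n_elem; }
  void adds(double s) { p[off++] += s; }
};

static Params read_params(const double* ptr, const Rcpp::IntegerVector& kinds,
                          const Rcpp::IntegerVector& ncat, int d, int L) {
  Params P;
  Cursor c{ptr, 0};
  int p = kinds.size();
  P.tokA.resize(p);
  P.tokE.resize(p);
  for (int j = 0; j < p; ++j) {
    if (kinds[j] == 0) P.tokA[j] = c.getm(d, 2);
    else P.tokE[j] = c.getm(d, ncat[j]);
  }
  P.cls = c.getv(d);
  int dff = 4 * d;
  P.layers.resize(L);
  for (int l = 0; l < L; ++l) {
    LayerP& q = P.layers[l];
    q.ln1_g = c.getv(d); q.ln1_b = c.getv(d);
    q.Wq = c.getm(d, d); q.bq = c.getv(d);
    q.Wk = c.getm(d, d); q.bk = c.getv(d);
    q.Wv = c.getm(d, d); q.bv = c.getv(d);
    q.Wo = c.getm(d, d); q.bo = c.getv(d);
    q.ln2_g = c.getv(d); q.ln2_b = c.getv(d);
    q.W1 = c.getm(d, dff); q.b1 = c.getv(dff);
    q.W2 = c.getm(dff, d); q.b2 = c.getv(d);
  }
  P.head_w = c.getv(d);
  P.head_b = c.gets();
  return P;
}

// layer norm forward on rows of X; returns output, caches xhat and 1/sigma
static mat layernorm_fwd(const mat& X, const vec& g, const vec& b,
                         mat& xhat, vec& inv_sigma) {
  vec mu = mean(X, 1);
  mat C = X.each_col() - mu;
  vec v = mean(square(C), 1);
  inv_sigma = 1.0 / sqrt(v + LN_EPS);
  xhat = C.each_col() % inv_sigma;
  mat Y = xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat layernorm_bwd(const mat& gY, const mat& xhat, const vec& inv_sigma,
                         const vec& g, vec& gGamma, vec& gBeta) {
  gGamma += sum(gY % xhat, 0).t();
  gBeta += sum(gY, 0).t();
  mat Gx = gY.each_row() % g.t();
  vec m1 = mean(Gx, 1);
  vec m2 = mean(Gx % xhat, 1);
  mat gX = Gx.each_col() - m1;
  gX -= xhat.each_col() % m2;
  gX.each_col() %= inv_sigma;
  return gX;
}

struct LayerCache {
  mat A, xhat1, Q, K, V, O, Bn, xhat2, Hn;
  vec is1, is2;
  cube Pc;  // t x t x (n*H); slice i*H+h, column a = attention weights of query a
};

static void copy_rows_out(const mat& big, uword r0, int t, mat& dst) {
  // rows r0..r0+t-1 of each column are contiguous in the col-major big matrix
  for (uword c = 0; c < big.n_cols; ++c)
    std::memcpy(dst.colptr(c), big.colptr(c) + r0, t * sizeof(double));
}

static void copy_rows_in(mat& big, uword r0, int t, const mat& src) {
  for (uword c = 0; c < big.n_cols; ++c)
    std::memcpy(big.colptr(c) + r0, src.colptr(c), t * sizeof(double));
}

// fast exp for non-positive arguments (range-reduced degree-9 polynomial,
// ~1e-12 relative accuracy); the same function is used in every forward
// pass, so analytic gradients are exact for the computed objective
static inline double fast_exp(double x) {
  if (x < -708.0) return 0.0;
  double n = std::nearbyint(x * 1.4426950408889634);
  double r = x - n * 0.693147180559945286;
  r -= n * 2.3190468138462996e-17;
  double p = 1.0 + r * (1.0 + r * (1.0 / 2 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320 + r * (1.0 / 362880)))))))));
  union { double d; uint64_t u; } v;
  v.d = p;
  v.u += (uint64_t)((int64_t)n) << 52;
  return v.d;
}

// direct BLAS wrapper for the small per-head products, avoiding any
// expression-template temporaries
#include <R_ext/BLAS.h>
static inline void dgemm_(char ta, char tb, int m, int n, int k, double alpha,
                          const double* A, int lda, const double* B, int ldb,
                          double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta,
                  C, &ldc FCONE FCONE);
}

// column-wise softmax in place (contiguous memory per column)
static void softmax_cols(mat& S) {
  for (uword a = 0; a < S.n_cols; ++a) {
    double* col = S.colptr(a);
    double mx = col[0];
    for (uword b = 1; b < S.n_rows; ++b) mx = std::max(mx, col[b]);
    double acc = 0.0;
    for (uword b = 0; b < S.n_rows; ++b) { col[b] = fast_exp(col[b] - mx); acc += col[b]; }
    double inv = 1.0 / acc;
    for (uword b = 0; b < S.n_rows; ++b) col[b] *= inv;
  }
}

// forward through one pre-norm block; X is the big (n*t) x d matrix
static mat block_fwd(const mat& X, const LayerP& q, int n, int t, int H,
                     LayerCache& C) {
  int d = X.n_cols;
  int dh = d / H;
  double scale = 1.0 / std::sqrt((double)dh);
  C.A = layernorm_fwd(X, q.ln1_g, q.ln1_b, C.xhat1, C.is1);
  C.Q = C.A * q.Wq; C.Q.each_row() += q.bq.t();
  C.K = C.A * q.Wk; C.K.each_row() += q.bk.t();
  C.V = C.A * q.Wv; C.V.each_row() += q.bv.t();
  C.O.set_size(n * t, d);
  C.Pc.set_size(t, t, (size_t)n * H);
  mat Qi(t, d), Ki(t, d), Vi(t, d), Oi(t, d);
  for (int i = 0; i < n; ++i) {
    uword r0 = (uword)i * t;
    copy_rows_out(C.Q, r0, t, Qi);
    copy_rows_out(C.K, r0, t, Ki);
    copy_rows_out(C.V, r0, t, Vi);
    for (int h = 0; h < H; ++h) {
      uword c0 = (uword)h * dh;
      // Pt(b, a) = scale * <K_b, Q_a>: column a holds query a's scores
      mat Pt(C.Pc.slice_memptr((size_t)i * H + h), t, t, false, true);
      dgemm_('N', 'T', t, t, dh, scale, Ki.colptr(c0), t, Qi.colptr(c0), t,
             0.0, Pt.memptr(), t);
      softmax_cols(Pt);
      // O_a = sum_b P(b, a) V_b
      dgemm_('T', 'N', t, dh, t, 1.0, Pt.memptr(), t, Vi.colptr(c0), t,
             0.0, Oi.colptr(c0), t);
    }
    copy_rows_in(C.O, r0, t, Oi);
  }
  mat M = C.O * q.Wo; M.each_row() += q.bo.t();
  mat U = X + M;
  C.Bn = layernorm_fwd(U, q.ln2_g, q.ln2_b, C.xhat2, C.is2);
  mat Z1 = C.Bn * q.W1; Z1.each_row() += q.b1.t();
  C.Hn = clamp(Z1, 0.0, datum::inf);
  mat F = C.Hn * q.W2; F.each_row() += q.b2.t();
  return U + F;
}

// backward through one block; gOut is dL/d(block output); returns dL/dX and
// accumulates parameter gradients into gc (must be called in layout order)
static mat block_bwd(const mat& gOut, const LayerP& q, const LayerCache& C,
                     int n, int t, int H,
                     vec& g_ln1_g, vec& g_ln1_b, mat& gWq, vec& gbq,
                     mat& gWk, vec& gbk, mat& gWv, vec& gbv,
                     mat& gWo, vec& gbo, vec& g_ln2_g, vec& g_ln2_b,
                     mat& gW1, vec& gb1, mat& gW2, vec& gb2) {
  int d = gOut.n_cols;
  int dh = d / H;
  double scale = 1.0 / std::sqrt((double)dh);
  // F = Hn*W2 + b2 ; out = U + F
  mat gF = gOut;
  gW2 += C.Hn.t() * gF;
  gb2 += sum(gF, 0).t();
  mat gHn = gF * q.W2.t();
  mat gZ1 = gHn % conv_to<mat>::from(C.Hn > 0);
  gW1 += C.Bn.t() * gZ1;
  gb1 += sum(gZ1, 0).t();
  mat gBn = gZ1 * q.W1.t();
  mat gU = gOut + layernorm_bwd(gBn, C.xhat2, C.is2, q.ln2_g, g_ln2_g, g_ln2_b);
  // M = O*Wo + bo ; U = X + M
  gWo += C.O.t() * gU;
  gbo += sum(gU, 0).t();
  mat gO = gU * q.Wo.t();
  mat gQ(size(gO)), gK(size(gO)), gV(size(gO));
  {
    mat Qi(t, d), Ki(t, d), Vi(t, d), gOi(t, d), gQi(t, d), gKi(t, d),
        gVi(t, d), gPt(t, t), gSt(t, t);
    for (int i = 0; i < n; ++i) {
      uword r0 = (uword)i * t;
      copy_rows_out(C.Q, r0, t, Qi);
      copy_rows_out(C.K, r0, t, Ki);
      copy_rows_out(C.V, r0, t, Vi);
      copy_rows_out(gO, r0, t, gOi);
      for (int h = 0; h < H; ++h) {
        uword c0 = (uword)h * dh;
        const double* Pt = C.Pc.slice_memptr((size_t)i * H + h);  // (b, a)
        // O_a = sum_b Pt(b,a) V_b
        dgemm_('N', 'T', t, t, dh, 1.0, Vi.colptr(c0), t, gOi.colptr(c0), t,
               0.0, gPt.memptr(), t);
        dgemm_('N', 'N', t, dh, t, 1.0, Pt, t, gOi.colptr(c0), t,
               0.0, gVi.colptr(c0), t);
        // softmax backward per query column a
        for (int a = 0; a < t; ++a) {
          const double* pc = Pt + (size_t)a * t;
          double* gp = gPt.colptr(a);
          double* gs = gSt.colptr(a);
          double dotv = 0.0;
          for (int b = 0; b < t; ++b) dotv += gp[b] * pc[b];
          for (int b = 0; b < t; ++b) gs[b] = pc[b] * (gp[b] - dotv);
        }
        // Pt pre-softmax was scale * <K_b, Q_a>
        dgemm_('T', 'N', t, dh, t, scale, gSt.memptr(), t, Ki.colptr(c0), t,
               0.0, gQi.colptr(c0), t);
        dgemm_('N', 'N', t, dh, t, scale, gSt.memptr(), t, Qi.colptr(c0), t,
               0.0, gKi.colptr(c0), t);
      }
      copy_rows_in(gQ, r0, t, gQi);
      copy_rows_in(gK, r0, t, gKi);
      copy_rows_in(gV, r0, t, gVi);
    }
  }
  gWq += C.A.t() * gQ; gbq += sum(gQ, 0).t();
  gWk += C.A.t() * gK; gbk += sum(gK, 0).t();
  gWv += C.A.t() * gV; gbv += sum(gV, 0).t();
  mat gA = gQ * q.Wq.t() + gK * q.Wk.t() + gV * q.Wv.t();
  mat gX = gU + layernorm_bwd(gA, C.xhat1, C.is1, q.ln1_g, g_ln1_g, g_ln1_b);
  return gX;
}

static mat tokenize_big(const mat& X, const Params& P,
                        const Rcpp::IntegerVector& kinds, int d) {
  int n = X.n_rows, p = X.n_cols, t = p + 1;
  mat T0((uword)n * t, d);
  for (int i = 0; i < n; ++i) {
    T0.row((uword)i * t) = P.cls.t();
    for (int j = 0; j < p; ++j) {
      if (kinds[j] == 0) {
        T0.row((uword)i * t + j + 1) =
          (X(i, j) * P.tokA[j].col(0) + P.tokA[j].col(1)).t();
      } else {
        int k = (int)std::lround(X(i, j));
        T0.row((uword)i * t + j + 1) = P.tokE[j].col(k).t();
      }
    }
  }
  return T0;
}

// big (n*t) x d matrix  ->  R array (n, t, d)
static Rcpp::NumericVector bigmat_to_array(const mat& E, int n, int t, int d) {
  Rcpp::NumericVector out((R_xlen_t)n * t * d);
  out.attr("dim") = Rcpp::IntegerVector::create(n, t, d);
  double* o = out.begin();
  for (int c = 0; c < d; ++c)
    for (int a = 0; a < t; ++a)
      for (int i = 0; i < n; ++i)
        o[i + (R_xlen_t)a * n + (R_xlen_t)c * n * t] = E((uword)i * t + a, c);
  return out;
}

static mat array_to_bigmat(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector dm = arr.attr("dim");
  int n = dm[0], t = dm[1], d = dm[2];
  mat E((uword)n * t, d);
  const double* a = arr.begin();
  for (int c = 0; c < d; ++c)
    for (int tk = 0; tk < t; ++tk)
      for (int i = 0; i < n; ++i)
        E((uword)i * t + tk, c) = a[i + (R_xlen_t)tk * n + (R_xlen_t)c * n * t];
  return E;
}

// per-feature ridge T^2 on the encoded big matrix; optionally accumulates
// d(lambda1 * L_stat)/dE into gE.  L_stat = -(1/p) * sum_j T2_j.
static double stat_loss(const mat& E, const Rcpp::IntegerVector& y, int n,
                        int t, int p, double ridge, vec& t2_out,
                        mat* gE, double lambda1) {
  int d = E.n_cols;
  uvec i0, i1;
  {
    std::vector<uword> v0, v1;
    for (int i = 0; i < n; ++i) (y[i] == 1 ? v1 : v0).push_back(i);
    i0 = uvec(v0); i1 = uvec(v1);
  }
  double n0 = i0.n_elem, n1 = i1.n_elem;
  if (n0 < 2 || n1 < 2)
    Rcpp::stop("statistical loss needs >= 2 samples in each outcome class");
  double k = n0 * n1 / (n0 + n1);
  double denom = n0 + n1 - 2.0;
  double acc = 0.0;
  mat Ej(n, d);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) Ej.row(i) = E.row((uword)i * t + j + 1);
    mat E0 = Ej.rows(i0), E1 = Ej.rows(i1);
    rowvec m0 = mean(E0, 0), m1 = mean(E1, 0);
    vec delta = (m1 - m0).t();
    mat C0 = E0.each_row() - m0;
    mat C1 = E1.each_row() - m1;
    mat M = (C0.t() * C0 + C1.t() * C1) / denom;
    M.diag() += ridge;
    vec a;
    bool ok = solve(a, M, delta, solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok) a = pinv(M) * delta;
    double t2 = k * dot(delta, a);
    t2_out(j) = t2;
    acc += t2;
    if (gE != nullptr && lambda1 != 0.0) {
      double coef = -lambda1 / p;   // dL/dT2_j
      // dT2/de_i = (2k * s_i / n_g) a - (2k/denom) * dot(a, e_i - m_g) * a
      vec c0v = C0 * a, c1v = C1 * a;
      rowvec at = a.t();
      for (uword r = 0; r < i0.n_elem; ++r) {
        double s = coef * 2.0 * k * (-1.0 / n0) - coef * (2.0 * k / denom) * c0v(r);
        gE->row((uword)i0(r) * t + j + 1) += s * at;
      }
      for (uword r = 0; r < i1.n_elem; ++r) {
        double s = coef * 2.0 * k * (1.0 / n1) - coef * (2.0 * k / denom) * c1v(r);
        gE->row((uword)i1(r) * t + j + 1) += s * at;
      }
    }
  }
  return -acc / p;
}

// [[Rcpp::export]]
Rcpp::List sel_eval(Rcpp::NumericVector par, Rcpp::NumericMatrix Xr,
                    Rcpp::IntegerVector kinds, Rcpp::IntegerVector ncat,
                    Rcpp::IntegerVector y, int d, int H, int L,
                    double lambda1, double lambda2, double ridge,
                    bool want_grad, bool want_encoded) {
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  int n = X.n_rows, p = X.n_cols, t = p + 1;
  Params P = read_params(par.begin(), kinds, ncat, d, L);
  bool have_y = (y.size() == n);

  mat T0 = tokenize_big(X, P, kinds, d);
  std::vector<LayerCache> caches(L);
  mat E = T0;
  for (int l = 0; l < L; ++l) E = block_fwd(E, P.layers[l], n, t, H, caches[l]);

  // classification head on CLS rows
  vec logits(n), gz(n, fill::zeros);
  double l_cls = 0.0;
  if (have_y) {
    for (int i = 0; i < n; ++i) {
      double z = dot(E.row((uword)i * t), P.head_w) + P.head_b;
      logits(i) = z;
      double yl = (double)y[i];
      // numerically stable BCE with logits
      l_cls += (z > 0 ? z * (1.0 - yl) + std::log1p(std::exp(-z))
                      : -yl * z + std::log1p(std::exp(z)));
      double sig = 1.0 / (1.0 + std::exp(-z));
      gz(i) = (sig - yl) / n;
    }
    l_cls /= n;
  }

  // embedding-norm regularizer on the input tokens
  double l_reg = accu(T0 % T0) / n;

  vec t2(p, fill::zeros);
  double l_stat = 0.0;
  mat gE;
  if (want_grad) gE.zeros(size(E));
  if (have_y) {
    l_stat = stat_loss(E, y, n, t, p, ridge, t2,
                       want_grad ? &gE : nullptr, lambda1);
  }
  double total = l_cls + lambda1 * l_stat + lambda2 * l_reg;
  if (!std::isfinite(total))
    Rcpp::stop("non-finite loss encountered");

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = total,
    Rcpp::Named("l_cls") = l_cls,
    Rcpp::Named("l_stat") = l_stat,
    Rcpp::Named("l_reg") = l_reg,
    Rcpp::Named("logits") = Rcpp::NumericVector(logits.begin(), logits.end()),
    Rcpp::Named("t2") = Rcpp::NumericVector(t2.begin(), t2.end()));
  if (want_encoded)
    out["encoded"] = bigmat_to_array(E, n, t, d);

  if (!want_grad) return out;

  // ---- backward ----
  vec ghw(d, fill::zeros);
  double ghb = 0.0;
  if (have_y) {
    for (int i = 0; i < n; ++i) {
      gE.row((uword)i * t) += gz(i) * P.head_w.t();
      ghw += gz(i) * E.row((uword)i * t).t();
      ghb += gz(i);
    }
  }

  int dff = 4 * d;
  std::vector<vec> g_ln1_g(L), g_ln1_b(L), gbq(L), gbk(L), gbv(L), gbo(L),
      g_ln2_g(L), g_ln2_b(L), gb1(L), gb2(L);
  std::vector<mat> gWq(L), gWk(L), gWv(L), gWo(L), gW1(L), gW2(L);
  for (int l = 0; l < L; ++l) {
    g_ln1_g[l].zeros(d); g_ln1_b[l].zeros(d);
    gWq[l].zeros(d, d); gbq[l].zeros(d);
    gWk[l].zeros(d, d); gbk[l].zeros(d);
    gWv[l].zeros(d, d); gbv[l].zeros(d);
    gWo[l].zeros(d, d); gbo[l].zeros(d);
    g_ln2_g[l].zeros(d); g_ln2_b[l].zeros(d);
    gW1[l].zeros(d, dff); gb1[l].zeros(dff);
    gW2[l].zeros(dff, d); gb2[l].zeros(d);
  }
  mat g = gE;
  for (int l = L - 1; l >= 0; --l) {
    g = block_bwd(g, P.layers[l], caches[l], n, t, H,
                  g_ln1_g[l], g_ln1_b[l], gWq[l], gbq[l], gWk[l], gbk[l],
                  gWv[l], gbv[l], gWo[l], gbo[l], g_ln2_g[l], g_ln2_b[l],
                  gW1[l], gb1[l], gW2[l], gb2[l]);
  }
  // token regularizer
  g += (2.0 * lambda2 / n) * T0;

  // tokenizer gradients
  Rcpp::NumericVector grad(par.size());
  GCursor gc{grad.begin(), 0};
  for (int j = 0; j < p; ++j) {
    if (kinds[j] == 0) {
      vec gw(d, fill::zeros), gb(d, fill::zeros);
      for (int i = 0; i < n; ++i) {
        rowvec gr = g.row((uword)i * t + j + 1);
        gw += X(i, j) * gr.t();
        gb += gr.t();
      }
      mat gm(d, 2);
      gm.col(0) = gw; gm.col(1) = gb;
      gc.addm(gm);
    } else {
      mat gEmb(d, ncat[j], fill::zeros);
      for (int i = 0; i < n; ++i) {
        int k = (int)std::lround(X(i, j));
        gEmb.col(k) += g.row((uword)i * t + j + 1).t();
      }
      gc.addm(gEmb);
    }
  }
  vec gcls(d, fill::zeros);
  for (int i = 0; i < n; ++i) gcls += g.row((uword)i * t).t();
  gc.addv(gcls);
  for (int l = 0; l < L; ++l) {
    gc.addv(g_ln1_g[l]); gc.addv(g_ln1_b[l]);
    gc.addm(gWq[l]); gc.addv(gbq[l]);
    gc.addm(gWk[l]); gc.addv(gbk[l]);
    gc.addm(gWv[l]); gc.addv(gbv[l]);
    gc.addm(gWo[l]); gc.addv(gbo[l]);
    gc.addv(g_ln2_g[l]); gc.addv(g_ln2_b[l]);
    gc.addm(gW1[l]); gc.addv(gb1[l]);
    gc.addm(gW2[l]); gc.addv(gb2[l]);
  }
  gc.addv(ghw);
  gc.adds(ghb);
  out["grad"] = grad;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector sel_tokenize(Rcpp::NumericVector par, Rcpp::NumericMatrix Xr,
                                 Rcpp::IntegerVector kinds,
                                 Rcpp::IntegerVector ncat, int d, int L) {
  mat X(Xr.begin(), Xr.nrow(), Xr.ncol(), false);
  Params P = read_params(par.begin(), kinds, ncat, d, L);
  mat T0 = tokenize_big(X, P, kinds, d);
  return bigmat_to_array(T0, X.n_rows, X.n_cols + 1, d);
}

// [[Rcpp::export]]
Rcpp::NumericVector sel_encode(Rcpp::NumericVector par, Rcpp::NumericVector tokens,
                               Rcpp::IntegerVector kinds,
                               Rcpp::IntegerVector ncat, int d, int H, int L) {
  Rcpp::IntegerVector dm = tokens.attr("dim");
  int n = dm[0], t = dm[1];
  Params P = read_params(par.begin(), kinds, ncat, d, L);
  mat E = array_to_bigmat(tokens);
  std::vector<LayerCache> caches(L);
  for (int l = 0; l < L; ++l) E = block_fwd(E, P.layers[l], n, t, H, caches[l]);
  return bigmat_to_array(E, n, t, d);
}
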