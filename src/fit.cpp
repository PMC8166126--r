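// MAP fitting of the per-SNP beta-binomial allelic-preference model.
//
// The objective is the log posterior of (pi, delta, phi, theta) given paired
// tumor/normal A-allele counts at heterozygous samples.  Optimization runs in
// unconstrained transformed coordinates (scaled logit for pi, delta, phi and
// for log theta) through R's own L-BFGS-B routine, with an analytic gradient.
// The permutation null requires ~1e5 refits, hence the compiled loop.

#include <Rcpp.h>
#include <R_ext/Applic.h>
#include <array>
#include <cstring>
#include <limits>
#include <vector>

using namespace Rcpp;

// prior families: 0 = uniform, 1 = beta(a, b) (unnormalized, truncated),
// 2 = log-uniform.  One row per parameter: family, a, b, lower, upper.
struct PriorSpec {
  int family;
  double a, b, lo, hi;
};

struct SnpData {
  std::vector<double> kt, nt; // tumor A counts, totals (het samples)
  std::vector<double> kn, nn; // normal A counts, totals
  double lchoose_const;       // sum of log binomial coefficients (param-free)
};

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// B-allele share after the error-mixing matrix E(delta) and the mapping-bias
// matrix M(phi) act on the allele-fraction vector (1-f, f).
static inline double distort(double f, double del, double phi) {
  double a1 = (1.0 - f) * (1.0 - del) + f * del;
  double b1 = (1.0 - f) * del + f * (1.0 - del);
  double a2 = 2.0 * (1.0 - phi) * a1;
  double b2 = 2.0 * phi * b1;
  return b2 / (a2 + b2);
}

// Beta-binomial log likelihood of one tissue group sharing the A-side mean mu
// and precision theta; optionally accumulates d/dmu and d/dtheta.
static double bb_group(const std::vector<double>& k, const std::vector<double>& n,
                       double mu, double th, bool grad, double* dmu, double* dth) {
  const int m = (int)k.size();
  if (m == 0) { if (grad) { *dmu = 0.0; *dth = 0.0; } return 0.0; }
  const double a = mu * th, b = (1.0 - mu) * th;
  double ll = m * (R::lgammafn(th) - R::lgammafn(a) - R::lgammafn(b));
  double Sa = 0.0, Sb = 0.0, St = 0.0;
  for (int i = 0; i < m; ++i) {
    ll += R::lgammafn(k[i] + a) + R::lgammafn(n[i] - k[i] + b) - R::lgammafn(n[i] + th);
    if (grad) {
      Sa += R::digamma(k[i] + a);
      Sb += R::digamma(n[i] - k[i] + b);
      St -= R::digamma(n[i] + th);
    }
  }
  if (grad) {
    Sa -= m * R::digamma(a);
    Sb -= m * R::digamma(b);
    St += m * R::digamma(th);
    *dmu = th * (Sa - Sb);
    *dth = mu * Sa + (1.0 - mu) * Sb + St;
  }
  return ll;
}

static inline double prior_logdens(const PriorSpec& pr, double v, bool grad, double* dv) {
  if (grad) *dv = 0.0;
  switch (pr.family) {
  case 1:
    if (grad) *dv = (pr.a - 1.0) / v - (pr.b - 1.0) / (1.0 - v);
    return (pr.a - 1.0) * std::log(v) + (pr.b - 1.0) * std::log1p(-v);
  case 2:
    if (grad) *dv = -1.0 / v;
    return -std::log(v);
  default:
    return 0.0;
  }
}

// Log posterior in natural coordinates v = (pi, delta, phi, theta);
// gnat receives the natural-scale gradient when grad is true.
static double log_post_nat(const SnpData& d, const double v[4], const PriorSpec pr[4],
                           bool grad, double gnat[4]) {
  const double pi = v[0], del = v[1], phi = v[2], th = v[3];
  const double pt = distort(pi, del, phi);  // tumor B share
  const double pn = distort(0.5, del, phi); // normal B share
  const double mut = 1.0 - pt, mun = 1.0 - pn;

  double dmut = 0, dtht = 0, dmun = 0, dthn = 0;
  double lp = bb_group(d.kt, d.nt, mut, th, grad, &dmut, &dtht) +
              bb_group(d.kn, d.nn, mun, th, grad, &dmun, &dthn) +
              d.lchoose_const;

  double dprior[4] = {0, 0, 0, 0};
  for (int j = 0; j < 4; ++j) {
    double dv = 0.0;
    lp += prior_logdens(pr[j], v[j], grad, &dv);
    dprior[j] = dv;
  }

  if (grad) {
    // Jacobian of (pt, pn) wrt (pi, delta, phi) by central differences: the
    // distortion map is O(1) and smooth, so this costs nothing relative to
    // the data terms and avoids a page of rational-function algebra.
    const double h = 1e-7;
    double dpt_dpi = (distort(pi + h, del, phi) - distort(pi - h, del, phi)) / (2 * h);
    double dpt_ddel = (distort(pi, del + h, phi) - distort(pi, del - h, phi)) / (2 * h);
    double dpt_dphi = (distort(pi, del, phi + h) - distort(pi, del, phi - h)) / (2 * h);
    double dpn_ddel = (distort(0.5, del + h, phi) - distort(0.5, del - h, phi)) / (2 * h);
    double dpn_dphi = (distort(0.5, del, phi + h) - distort(0.5, del, phi - h)) / (2 * h);
    gnat[0] = -dmut * dpt_dpi + dprior[0];
    gnat[1] = -dmut * dpt_ddel - dmun * dpn_ddel + dprior[1];
    gnat[2] = -dmut * dpt_dphi - dmun * dpn_dphi + dprior[2];
    gnat[3] = dtht + dthn + dprior[3];
  }
  return lp;
}

// ---- transformed coordinates -------------------------------------------------
// j = 0..2: v = lo + (hi - lo) * sigmoid(x)
// j = 3:    log v = log lo + (log hi - log lo) * sigmoid(x)

struct OptCtx {
  const SnpData* d;
  const PriorSpec* pr;
  double lo[4], hi[4];
  // cache: fn computes value and gradient together; gr reuses it
  double x_cache[4];
  double g_cache[4];
  bool have_cache;
};

static void x_to_nat(const OptCtx* c, const double x[4], double v[4], double dvdx[4]) {
  for (int j = 0; j < 3; ++j) {
    double s = sigmoid(x[j]);
    v[j] = c->lo[j] + (c->hi[j] - c->lo[j]) * s;
    dvdx[j] = (c->hi[j] - c->lo[j]) * s * (1.0 - s);
  }
  double s = sigmoid(x[3]);
  double llo = std::log(c->lo[3]), lhi = std::log(c->hi[3]);
  v[3] = std::exp(llo + (lhi - llo) * s);
  dvdx[3] = v[3] * (lhi - llo) * s * (1.0 - s);
}

static double nat_to_x(double v, double lo, double hi) {
  double u = (v - lo) / (hi - lo);
  u = std::min(std::max(u, 1e-9), 1.0 - 1e-9);
  return std::log(u / (1.0 - u));
}

static double opt_fn(int n, double* x, void* ex) {
  OptCtx* c = (OptCtx*)ex;
  double v[4], dvdx[4], gnat[4];
  x_to_nat(c, x, v, dvdx);
  double lp = log_post_nat(*c->d, v, c->pr, true, gnat);
  for (int j = 0; j < 4; ++j) c->g_cache[j] = -gnat[j] * dvdx[j];
  std::memcpy(c->x_cache, x, 4 * sizeof(double));
  c->have_cache = true;
  if (!R_finite(lp)) return 1e300;
  return -lp;
}

static void opt_gr(int n, double* x, double* g, void* ex) {
  OptCtx* c = (OptCtx*)ex;
  if (!c->have_cache || std::memcmp(c->x_cache, x, 4 * sizeof(double)) != 0)
    (void)opt_fn(n, x, ex);
  std::memcpy(g, c->g_cache, 4 * sizeof(double));
}

struct FitResult {
  double v[4];
  double logpost;
  bool converged;
  int niter;
};

static FitResult fit_one(const SnpData& d, const PriorSpec pr[4],
                         const std::vector<std::array<double, 4> >& starts,
                         double factr, double pgtol, int maxit) {
  OptCtx ctx;
  ctx.d = &d;
  ctx.pr = pr;
  for (int j = 0; j < 4; ++j) { ctx.lo[j] = pr[j].lo; ctx.hi[j] = pr[j].hi; }

  FitResult best;
  best.logpost = -std::numeric_limits<double>::infinity();
  best.converged = false;
  best.niter = 0;
  for (int j = 0; j < 4; ++j) best.v[j] = NA_REAL;

  // Keep the logit coordinates away from saturation; sigmoid(12) differs from
  // 1 by ~6e-6 of the parameter range, well inside the prior box.
  double l[4] = {-12, -12, -12, -12}, u[4] = {12, 12, 12, 12};
  int nbd[4] = {2, 2, 2, 2};

  for (size_t s = 0; s < starts.size(); ++s) {
    double x[4];
    x[0] = nat_to_x(starts[s][0], ctx.lo[0], ctx.hi[0]);
    x[1] = nat_to_x(starts[s][1], ctx.lo[1], ctx.hi[1]);
    x[2] = nat_to_x(starts[s][2], ctx.lo[2], ctx.hi[2]);
    x[3] = nat_to_x(std::log(starts[s][3]), std::log(ctx.lo[3]), std::log(ctx.hi[3]));
    for (int j = 0; j < 4; ++j) x[j] = std::min(std::max(x[j], -12.0), 12.0);

    ctx.have_cache = false;
    double Fmin = 0.0;
    int fail = 0, fncount = 0, grcount = 0;
    char msg[256];
    lbfgsb(4, 5, x, l, u, nbd, &Fmin, opt_fn, opt_gr, &fail, (void*)&ctx,
           factr, pgtol, &fncount, &grcount, maxit, msg, 0, 10);

    double v[4], dvdx[4];
    x_to_nat(&ctx, x, v, dvdx);
    double lp = -Fmin;
    bool conv = (fail == 0);
    // best objective wins; near-ties break toward pi closest to 0.5
    bool take = false;
    if (lp > best.logpost + 1e-9) take = true;
    else if (std::abs(lp - best.logpost) <= 1e-9 && R_finite(best.v[0]) &&
             std::abs(v[0] - 0.5) < std::abs(best.v[0] - 0.5)) take = true;
    if (take) {
      std::memcpy(best.v, v, 4 * sizeof(double));
      best.logpost = lp;
      best.converged = conv;
      best.niter = fncount;
    }
  }
  return best;
}

static void parse_priors(const NumericMatrix& spec, PriorSpec pr[4]) {
  if (spec.nrow() != 4 || spec.ncol() != 5)
    stop("prior specification must be a 4 x 5 matrix");
  for (int j = 0; j < 4; ++j) {
    pr[j].family = (int)spec(j, 0);
    pr[j].a = spec(j, 1);
    pr[j].b = spec(j, 2);
    pr[j].lo = spec(j, 3);
    pr[j].hi = spec(j, 4);
    if (!(pr[j].lo < pr[j].hi)) stop("prior bounds must satisfy lower < upper");
  }
}

// Gather one SNP's het-sample counts from matrix row i; entries with missing
// or zero totals are skipped.
static int gather_snp(const NumericMatrix& ta, const NumericMatrix& tn,
                      const NumericMatrix& na, const NumericMatrix& nn,
                      int i, SnpData& d) {
  const int ns = ta.ncol();
  d.kt.clear(); d.nt.clear(); d.kn.clear(); d.nn.clear();
  d.lchoose_const = 0.0;
  int m = 0;
  for (int s = 0; s < ns; ++s) {
    double t_tot = tn(i, s), n_tot = nn(i, s);
    if (ISNAN(t_tot) || ISNAN(n_tot) || t_tot <= 0 || n_tot <= 0) continue;
    double t_a = ta(i, s), n_a = na(i, s);
    if (ISNAN(t_a) || ISNAN(n_a)) continue;
    d.kt.push_back(t_a); d.nt.push_back(t_tot);
    d.kn.push_back(n_a); d.nn.push_back(n_tot);
    d.lchoose_const += R::lchoose(t_tot, t_a) + R::lchoose(n_tot, n_a);
    ++m;
  }
  return m;
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_fit_cohort(NumericMatrix tumor_a, NumericMatrix tumor_tot,
                             NumericMatrix normal_a, NumericMatrix normal_tot,
                             NumericMatrix prior_spec, NumericMatrix starts,
                             Nullable<NumericMatrix> warm_starts,
                             double factr, double pgtol, int maxit, int min_het) {
  PriorSpec pr[4];
  parse_priors(prior_spec, pr);
  const int nsnp = tumor_a.nrow();
  if (tumor_tot.nrow() != nsnp || normal_a.nrow() != nsnp || normal_tot.nrow() != nsnp)
    stop("count matrices must share dimensions");
  if (starts.ncol() != 4) stop("starts must have 4 columns");

  NumericMatrix warm;
  bool has_warm = warm_starts.isNotNull();
  if (has_warm) {
    warm = NumericMatrix(warm_starts);
    if (warm.nrow() != nsnp || warm.ncol() != 4)
      stop("warm_starts must be an n_snp x 4 matrix");
  }

  NumericMatrix out(nsnp, 8);
  colnames(out) = CharacterVector::create("pi", "delta", "phi", "theta",
                                          "log_posterior", "converged",
                                          "n_iter", "n_het");
  SnpData d;
  std::vector<std::array<double, 4> > st;
  for (int i = 0; i < nsnp; ++i) {
    int m = gather_snp(tumor_a, tumor_tot, normal_a, normal_tot, i, d);
    out(i, 7) = m;
    if (m < std::max(min_het, 1)) {
      for (int j = 0; j < 5; ++j) out(i, j) = NA_REAL;
      out(i, 5) = 0; out(i, 6) = 0;
      continue;
    }
    st.clear();
    if (has_warm && R_finite(warm(i, 0))) {
      std::array<double, 4> w = {{warm(i, 0), warm(i, 1), warm(i, 2), warm(i, 3)}};
      st.push_back(w);
    }
    for (int s = 0; s < starts.nrow(); ++s) {
      std::array<double, 4> w = {{starts(s, 0), starts(s, 1), starts(s, 2), starts(s, 3)}};
      st.push_back(w);
    }
    FitResult r = fit_one(d, pr, st, factr, pgtol, maxit);
    for (int j = 0; j < 4; ++j) out(i, j) = r.v[j];
    out(i, 4) = r.logpost;
    out(i, 5) = r.converged ? 1 : 0;
    out(i, 6) = r.niter;
    if ((i & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
double cpp_log_posterior(NumericVector params, NumericVector tumor_a,
                         NumericVector tumor_tot, NumericVector normal_a,
                         NumericVector normal_tot, NumericMatrix prior_spec) {
  PriorSpec pr[4];
  parse_priors(prior_spec, pr);
  if (params.size() != 4) stop("params must be length 4 (pi, delta, phi, theta)");
  SnpData d;
  d.lchoose_const = 0.0;
  for (int i = 0; i < tumor_a.size(); ++i) {
    d.kt.push_back(tumor_a[i]); d.nt.push_back(tumor_tot[i]);
    d.kn.push_back(normal_a[i]); d.nn.push_back(normal_tot[i]);
    d.lchoose_const += R::lchoose(tumor_tot[i], tumor_a[i]) +
                       R::lchoose(normal_tot[i], normal_a[i]);
  }
  double v[4] = {params[0], params[1], params[2], params[3]};
  for (int j = 0; j < 4; ++j)
    if (v[j] < pr[j].lo || v[j] > pr[j].hi) return R_NegInf;
  double gnat[4];
  return log_post_nat(d, v, pr, false, gnat);
}
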