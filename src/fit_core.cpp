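#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Nine-peak triglyceride proton spectrum. Shifts in ppm; proton counts are
// linear in (ndb, nmidb, cl). Total protons = 6*cl - 2*ndb + 2.
static const int NPEAK = 9;
static const double SHIFT_PPM[NPEAK] =
    {5.3, 5.2, 4.2, 2.75, 2.2, 2.0, 1.6, 1.3, 0.9};
static const double GAMMA_MHZ_PER_T = 42.577;

static inline void peak_protons(double ndb, double nmidb, double cl,
                                double *a) {
  a[0] = 2.0 * ndb;                                // olefinic CH=CH
  a[1] = 1.0;                                      // glycerol CH
  a[2] = 4.0;                                      // glycerol CH2
  a[3] = 2.0 * nmidb;                              // diallylic CH2
  a[4] = 6.0;                                      // alpha-carboxyl CH2
  a[5] = 4.0 * (ndb - nmidb);                      // allylic CH2
  a[6] = 6.0;                                      // beta-carboxyl CH2
  a[7] = 6.0 * (cl - 4.0) - 8.0 * ndb + 2.0 * nmidb; // bulk methylene
  a[8] = 9.0;                                      // terminal methyl
}

struct FitContext {
  int nte;
  std::vector<double> te_s;        // echo times in seconds
  std::vector<double> cre, cim;    // cos/sin(2*pi*f_p*te), nte x NPEAK
  double cl;
};

// Complex fat modulation c(te) for a given ndb (nmidb tied as 0.093*ndb^2).
static inline void fat_mod(const FitContext &ctx, double ndb, int ite,
                           double &re, double &im) {
  double a[NPEAK];
  double nmidb = 0.093 * ndb * ndb;
  peak_protons(ndb, nmidb, ctx.cl, a);
  double tot = 0.0, sre = 0.0, sim = 0.0;
  for (int p = 0; p < NPEAK; ++p) {
    tot += a[p];
    sre += a[p] * ctx.cre[ite * NPEAK + p];
    sim += a[p] * ctx.cim[ite * NPEAK + p];
  }
  re = sre / tot;
  im = sim / tot;
}

// Magnitude signal model: |W + F*c(te)| * exp(-r2s * te)
static void model_eval(const FitContext &ctx, const double *th, double *m) {
  double W = th[0], F = th[1], ndb = th[2], r2s = th[3];
  for (int i = 0; i < ctx.nte; ++i) {
    double re, im;
    fat_mod(ctx, ndb, i, re, im);
    double xr = W + F * re;
    double xi = F * im;
    m[i] = std::sqrt(xr * xr + xi * xi) * std::exp(-r2s * ctx.te_s[i]);
  }
}

static double sse(const FitContext &ctx, const double *th, const double *y,
                  double *work) {
  model_eval(ctx, th, work);
  double s = 0.0;
  for (int i = 0; i < ctx.nte; ++i) {
    double r = work[i] - y[i];
    s += r * r;
  }
  return s;
}

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Solve (A + lambda*diag(A)) x = b for a 4x4 system, Gaussian elimination
// with partial pivoting. Returns false on (near-)singularity.
static bool solve4(double A[4][4], double lambda, const double *b,
                   double *x) {
  double M[4][5];
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j < 4; ++j) M[i][j] = A[i][j];
    M[i][i] += lambda * (A[i][i] > 1e-300 ? A[i][i] : 1e-300);
    M[i][4] = b[i];
  }
  for (int c = 0; c < 4; ++c) {
    int piv = c;
    for (int r = c + 1; r < 4; ++r)
      if (std::fabs(M[r][c]) > std::fabs(M[piv][c])) piv = r;
    if (std::fabs(M[piv][c]) < 1e-300) return false;
    if (piv != c)
      for (int j = c; j < 5; ++j) std::swap(M[piv][j], M[c][j]);
    for (int r = c + 1; r < 4; ++r) {
      double f = M[r][c] / M[c][c];
      for (int j = c; j < 5; ++j) M[r][j] -= f * M[c][j];
    }
  }
  for (int r = 3; r >= 0; --r) {
    double s = M[r][4];
    for (int j = r + 1; j < 4; ++j) s -= M[r][j] * x[j];
    x[r] = s / M[r][r];
  }
  return true;
}

// Projected Levenberg-Marquardt for one voxel from one start.
// theta = (water, fat, ndb, r2star). Box bounds enforced by clamping.
static double lm_fit(const FitContext &ctx, const double *y,
                     const double *lower, const double *upper, double *theta,
                     bool *converged, int max_eval = 500,
                     double ftol = 1e-10) {
  const int n = ctx.nte;
  std::vector<double> m(n), mh(n), J(n * 4), r(n);
  double th[4];
  for (int k = 0; k < 4; ++k) th[k] = clampd(theta[k], lower[k], upper[k]);
  double cur = sse(ctx, th, y, m.data());
  double lambda = 1e-3;
  int evals = 1;
  *converged = false;
  for (int it = 0; it < 200 && evals < max_eval; ++it) {
    // residuals and forward-difference Jacobian
    for (int i = 0; i < n; ++i) r[i] = y[i] - m[i];
    for (int k = 0; k < 4; ++k) {
      double h = 1e-6 * std::max(1.0, std::fabs(th[k]));
      double thh[4] = {th[0], th[1], th[2], th[3]};
      if (th[k] + h > upper[k]) h = -h;  // one-sided at the bound
      thh[k] = th[k] + h;
      model_eval(ctx, thh, mh.data());
      ++evals;
      for (int i = 0; i < n; ++i) J[i * 4 + k] = (mh[i] - m[i]) / h;
    }
    double A[4][4], g[4];
    for (int a2 = 0; a2 < 4; ++a2) {
      g[a2] = 0.0;
      for (int b2 = 0; b2 < 4; ++b2) A[a2][b2] = 0.0;
    }
    for (int i = 0; i < n; ++i)
      for (int a2 = 0; a2 < 4; ++a2) {
        g[a2] += J[i * 4 + a2] * r[i];
        for (int b2 = a2; b2 < 4; ++b2)
          A[a2][b2] += J[i * 4 + a2] * J[i * 4 + b2];
      }
    for (int a2 = 0; a2 < 4; ++a2)
      for (int b2 = 0; b2 < a2; ++b2) A[a2][b2] = A[b2][a2];

    bool improved = false;
    for (int tries = 0; tries < 12 && evals < max_eval; ++tries) {
      double step[4];
      if (!solve4(A, lambda, g, step)) {
        lambda *= 10.0;
        continue;
      }
      double cand[4];
      for (int k = 0; k < 4; ++k)
        cand[k] = clampd(th[k] + step[k], lower[k], upper[k]);
      double s = sse(ctx, cand, y, mh.data());
      ++evals;
      if (s < cur) {
        double drop = cur - s;
        for (int k = 0; k < 4; ++k) th[k] = cand[k];
        cur = s;
        std::copy(mh.begin(), mh.end(), m.begin());
        lambda = std::max(lambda * 0.3, 1e-12);
        improved = true;
        if (drop < ftol * (cur + ftol)) {
          *converged = true;
          it = 1000;  // break outer
        }
        break;
      }
      lambda *= 10.0;
    }
    if (!improved) {
      *converged = true;  // stuck: local minimum (possibly at a bound)
      break;
    }
  }
  for (int k = 0; k < 4; ++k) theta[k] = th[k];
  return cur;
}

static FitContext make_context(const NumericVector &te_ms, double field,
                               double water_ppm, double cl) {
  FitContext ctx;
  ctx.nte = te_ms.size();
  ctx.cl = cl;
  ctx.te_s.resize(ctx.nte);
  ctx.cre.resize(ctx.nte * NPEAK);
  ctx.cim.resize(ctx.nte * NPEAK);
  for (int i = 0; i < ctx.nte; ++i) {
    ctx.te_s[i] = te_ms[i] / 1000.0;
    for (int p = 0; p < NPEAK; ++p) {
      double f_hz = (SHIFT_PPM[p] - water_ppm) * GAMMA_MHZ_PER_T * field;
      double ph = 2.0 * M_PI * f_hz * ctx.te_s[i];
      ctx.cre[i * NPEAK + p] = std::cos(ph);
      ctx.cim[i * NPEAK + p] = std::sin(ph);
    }
  }
  return ctx;
}

// [[Rcpp::export]]
NumericMatrix cpp_fit_voxels(NumericMatrix y, NumericVector te_ms,
                             double field, double water_ppm, double cl,
                             NumericVector lower, NumericVector upper,
                             NumericMatrix starts, int max_eval = 500,
                             double ftol = 1e-10) {
  const int nvox = y.nrow();
  if (y.ncol() != te_ms.size())
    stop("signal matrix and echo-time vector disagree");
  FitContext ctx = make_context(te_ms, field, water_ppm, cl);
  NumericMatrix out(nvox, 6);
  colnames(out) = CharacterVector::create("water", "fat", "ndb", "r2star",
                                          "rss", "converged");
  std::vector<double> yv(ctx.nte);
  const double lo[4] = {lower[0], lower[1], lower[2], lower[3]};
  const double up[4] = {upper[0], upper[1], upper[2], upper[3]};
  for (int v = 0; v < nvox; ++v) {
    for (int i = 0; i < ctx.nte; ++i) yv[i] = y(v, i);
    double best[4] = {NA_REAL, NA_REAL, NA_REAL, NA_REAL};
    double best_rss = R_PosInf;
    bool best_conv = false;
    double ymax = 0.0;
    for (int i = 0; i < ctx.nte; ++i) ymax = std::max(ymax, yv[i]);
    // Dixon-style split of the first two echoes (near out-of-phase /
    // in-phase at 1.5 T) as the default amplitude initialisation.
    double w0 = std::max((yv[1] + yv[0]) / 2.0, 1e-3);
    double f0 = std::max((yv[1] - yv[0]) / 2.0, 0.02 * (ymax + 1e-3));
    for (int s = 0; s < starts.nrow(); ++s) {
      bool dixon = ISNA(starts(s, 0)) && ISNA(starts(s, 1));
      // the two-point split cannot tell water from fat: try both
      // assignments when the amplitudes are data-initialised
      for (int swap = 0; swap < (dixon ? 2 : 1); ++swap) {
        double th[4] = {starts(s, 0), starts(s, 1), starts(s, 2),
                        starts(s, 3)};
        if (ISNA(th[0])) th[0] = swap ? f0 : w0;
        if (ISNA(th[1])) th[1] = swap ? w0 : f0;
        bool conv = false;
        double rss =
            lm_fit(ctx, yv.data(), lo, up, th, &conv, max_eval, ftol);
        // keep lowest residual; ties broken by lowest ndb
        if (rss < best_rss - 1e-12 ||
            (std::fabs(rss - best_rss) <= 1e-12 && th[2] < best[2])) {
          best_rss = rss;
          best_conv = conv;
          for (int k = 0; k < 4; ++k) best[k] = th[k];
        }
      }
    }
    out(v, 0) = best[0];
    out(v, 1) = best[1];
    out(v, 2) = best[2];
    out(v, 3) = best[3];
    out(v, 4) = best_rss;
    out(v, 5) = best_conv ? 1.0 : 0.0;
  }
  return out;
}

// Forward model for a block of voxels (used by the phantom renderer).
// params: nvox x 4 matrix (water, fat, ndb, r2star); returns nvox x nte.
// [[Rcpp::export]]
NumericMatrix cpp_forward_signal(NumericMatrix params, NumericVector te_ms,
                                 double field, double water_ppm, double cl) {
  FitContext ctx = make_context(te_ms, field, water_ppm, cl);
  const int nvox = params.nrow();
  NumericMatrix out(nvox, ctx.nte);
  std::vector<double> m(ctx.nte);
  for (int v = 0; v < nvox; ++v) {
    double th[4] = {params(v, 0), params(v, 1), params(v, 2), params(v, 3)};
    model_eval(ctx, th, m.data());
    for (int i = 0; i < ctx.nte; ++i) out(v, i) = m[i];
  }
  return out;
}
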