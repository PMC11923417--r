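#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Profiled bounded least squares for the nonlinear candidate families.
//
// Data enter in sufficient-statistic form: distinct covariate levels x,
// per-level observation counts w, per-level response means ybar.  For any
// value of the nonlinear coefficient(s) nu the intercept b0 and slope b1
// are profiled out in closed form (weighted simple regression of ybar on
// g(x; nu)), so the optimization runs over 1 or 2 dimensions only.
//
// family codes: 1 emax, 2 exponential, 3 sigemax, 4 beta (fixed scale).

namespace {

struct Prob {
  const double* x;
  const double* w;
  const double* ybar;
  int nlev;
  int fam;
  double scal;
  double W, Sy;  // precomputed totals
};

inline double gfun(int fam, double x, const double* nu, double scal) {
  switch (fam) {
    case 1: return x / (nu[0] + x);
    case 2: return std::exp(x / nu[0]) - 1.0;
    case 3: {
      double h = nu[1];
      double xh = std::pow(x, h);
      return xh / (std::pow(nu[0], h) + xh);
    }
    case 4: {
      double d1 = nu[0], d2 = nu[1];
      double z = x / scal;
      if (z <= 0.0) return 0.0;
      if (z >= 1.0) z = 1.0;
      double bnorm = std::pow(d1 + d2, d1 + d2) /
                     (std::pow(d1, d1) * std::pow(d2, d2));
      return bnorm * std::pow(z, d1) * std::pow(1.0 - z, d2);
    }
  }
  return NA_REAL;
}

// profiled between-level RSS at nu; fills b0/b1 when requested
double prss(const Prob& p, const double* nu, double* b0out, double* b1out) {
  double Sg = 0.0, Sgg = 0.0, Sgy = 0.0;
  std::vector<double> g(p.nlev);
  for (int i = 0; i < p.nlev; ++i) {
    double gi = gfun(p.fam, p.x[i], nu, p.scal);
    if (!std::isfinite(gi)) return R_PosInf;
    g[i] = gi;
    Sg += p.w[i] * gi;
    Sgg += p.w[i] * gi * gi;
    Sgy += p.w[i] * gi * p.ybar[i];
  }
  double den = p.W * Sgg - Sg * Sg;
  double b0, b1;
  if (den <= 1e-12 * (p.W * Sgg + 1e-300)) {  // g effectively constant
    b1 = 0.0;
    b0 = p.Sy / p.W;
  } else {
    b1 = (p.W * Sgy - Sg * p.Sy) / den;
    b0 = (p.Sy - b1 * Sg) / p.W;
  }
  double rss = 0.0;
  for (int i = 0; i < p.nlev; ++i) {
    double r = p.ybar[i] - b0 - b1 * g[i];
    rss += p.w[i] * r * r;
  }
  if (b0out) { *b0out = b0; *b1out = b1; }
  return rss;
}

// golden-section minimization of prss along one log-scaled coordinate
double golden1(const Prob& p, double la, double lb, int coord,
               double* nu, double tol) {
  const double gr = 0.6180339887498949;
  double a = la, b = lb;
  double c = b - gr * (b - a);
  double d = a + gr * (b - a);
  double nuc[2] = {nu[0], nu[1]};
  double nud[2] = {nu[0], nu[1]};
  nuc[coord] = std::exp(c);
  nud[coord] = std::exp(d);
  double fc = prss(p, nuc, nullptr, nullptr);
  double fd = prss(p, nud, nullptr, nullptr);
  for (int it = 0; it < 120 && (b - a) > tol; ++it) {
    if (fc < fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      nuc[coord] = std::exp(c);
      fc = prss(p, nuc, nullptr, nullptr);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      nud[coord] = std::exp(d);
      fd = prss(p, nud, nullptr, nullptr);
    }
  }
  return 0.5 * (a + b);
}

}  // namespace

// [[Rcpp::export]]
List fit_profiled_cpp(NumericVector x, NumericVector w, NumericVector ybar,
                      int fam, NumericVector lower, NumericVector upper,
                      double scal, int ngrid) {
  int nlev = x.size();
  Prob p;
  p.x = x.begin(); p.w = w.begin(); p.ybar = ybar.begin();
  p.nlev = nlev; p.fam = fam; p.scal = scal;
  p.W = 0.0; p.Sy = 0.0;
  for (int i = 0; i < nlev; ++i) { p.W += w[i]; p.Sy += w[i] * ybar[i]; }

  int dim = lower.size();
  std::vector<double> llo(dim), lhi(dim);
  for (int k = 0; k < dim; ++k) {
    llo[k] = std::log(lower[k]);
    lhi[k] = std::log(upper[k]);
  }

  double best = R_PosInf;
  double nu[2] = {0.0, 0.0};

  if (dim == 1) {
    int ib = 0;
    for (int i = 0; i < ngrid; ++i) {
      double lv = llo[0] + (lhi[0] - llo[0]) * i / (ngrid - 1.0);
      double cand[2] = {std::exp(lv), 0.0};
      double f = prss(p, cand, nullptr, nullptr);
      if (f < best) { best = f; ib = i; }
    }
    double step = (lhi[0] - llo[0]) / (ngrid - 1.0);
    double la = std::max(llo[0], llo[0] + step * (ib - 1));
    double lb = std::min(lhi[0], llo[0] + step * (ib + 1));
    double lopt = golden1(p, la, lb, 0, nu, 1e-10);
    nu[0] = std::exp(lopt);
  } else {
    // lattice scan then cyclic coordinate refinement
    int ibi = 0, ibj = 0;
    for (int i = 0; i < ngrid; ++i) {
      double l1 = llo[0] + (lhi[0] - llo[0]) * i / (ngrid - 1.0);
      for (int j = 0; j < ngrid; ++j) {
        double l2 = llo[1] + (lhi[1] - llo[1]) * j / (ngrid - 1.0);
        double cand[2] = {std::exp(l1), std::exp(l2)};
        double f = prss(p, cand, nullptr, nullptr);
        if (f < best) { best = f; ibi = i; ibj = j; }
      }
    }
    double s1 = (lhi[0] - llo[0]) / (ngrid - 1.0);
    double s2 = (lhi[1] - llo[1]) / (ngrid - 1.0);
    nu[0] = std::exp(llo[0] + s1 * ibi);
    nu[1] = std::exp(llo[1] + s2 * ibj);
    double w1 = 1.5 * s1, w2 = 1.5 * s2;  // shrinking search windows
    for (int sweep = 0; sweep < 10; ++sweep) {
      double l1 = std::log(nu[0]);
      double a1 = std::max(llo[0], l1 - w1), b1 = std::min(lhi[0], l1 + w1);
      nu[0] = std::exp(golden1(p, a1, b1, 0, nu, 1e-11));
      double l2 = std::log(nu[1]);
      double a2 = std::max(llo[1], l2 - w2), b2 = std::min(lhi[1], l2 + w2);
      nu[1] = std::exp(golden1(p, a2, b2, 1, nu, 1e-11));
      w1 *= 0.6; w2 *= 0.6;
    }
  }

  double b0 = 0.0, b1c = 0.0;
  double rss = prss(p, nu, &b0, &b1c);
  NumericVector nuout(dim);
  for (int k = 0; k < dim; ++k) nuout[k] = nu[k];
  return List::create(_["nu"] = nuout, _["b0"] = b0, _["b1"] = b1c,
                      _["rss_between"] = rss,
                      _["converged"] = std::isfinite(rss));
}
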