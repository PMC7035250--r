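// Overdamped Langevin dynamics in CV space under a well-tempered
// metadynamics bias with lower-wall restraints.
//
// The bias is accumulated on a regular grid: hill deposition adds the
// Gaussian exactly at every node within 6 sigma, and the per-step bias
// value/gradient are linearly interpolated between nodes.  Grid nodes
// therefore agree with direct hill summation to the truncation error
// (~1e-8 kJ/mol); interpolation error only perturbs the dynamics, not
// the recorded hills.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// model potentials: id 1 harmonic, 2 double well (1D), 3 three-basin
// Gaussian surface with confining bowl (2D)
static inline double pot_energy(int id, const NumericVector& par,
                                const double* s) {
  if (id == 1) {
    return 0.5 * par[0] * s[0] * s[0];
  } else if (id == 2) {
    double q = s[0] * s[0] - 1.0;
    return par[0] * q * q + par[1] * s[0];
  } else {
    // par: ngauss, then per gaussian (depth, x, y, w), then bowl b, r0b
    int ng = (int)par[0];
    double u = 0.0;
    for (int g = 0; g < ng; ++g) {
      double D = par[1 + 4 * g], xc = par[2 + 4 * g],
             yc = par[3 + 4 * g], w = par[4 + 4 * g];
      double dx = s[0] - xc, dy = s[1] - yc;
      u -= D * std::exp(-(dx * dx + dy * dy) / (2.0 * w * w));
    }
    double b = par[1 + 4 * ng], r0 = par[2 + 4 * ng];
    double r2 = (s[0] * s[0] + s[1] * s[1]) / (r0 * r0);
    u += b * r2 * r2 * r2;
    return u;
  }
}

static inline void pot_grad(int id, const NumericVector& par,
                            const double* s, double* g) {
  if (id == 1) {
    g[0] = par[0] * s[0];
  } else if (id == 2) {
    double q = s[0] * s[0] - 1.0;
    g[0] = 4.0 * par[0] * q * s[0] + par[1];
  } else {
    int ng = (int)par[0];
    g[0] = 0.0; g[1] = 0.0;
    for (int gg = 0; gg < ng; ++gg) {
      double D = par[1 + 4 * gg], xc = par[2 + 4 * gg],
             yc = par[3 + 4 * gg], w = par[4 + 4 * gg];
      double dx = s[0] - xc, dy = s[1] - yc;
      double e = D * std::exp(-(dx * dx + dy * dy) / (2.0 * w * w)) /
                 (w * w);
      g[0] += e * dx;
      g[1] += e * dy;
    }
    double b = par[1 + 4 * ng], r0 = par[2 + 4 * ng];
    double r2 = (s[0] * s[0] + s[1] * s[1]) / (r0 * r0);
    double pref = 6.0 * b * r2 * r2 / (r0 * r0);
    g[0] += pref * s[0];
    g[1] += pref * s[1];
  }
}

// [[Rcpp::export]]
List cpp_run_wtmetad(int pot_id, NumericVector pot_par, NumericVector s0,
                     double n_steps_d, double dt, double friction,
                     double kT, double w0, NumericVector sigma,
                     double gamma, int pace_steps, int out_stride,
                     NumericVector gmin, NumericVector gmax,
                     IntegerVector gn, NumericMatrix wallm) {
  const int d = s0.size();
  const long n_steps = (long)n_steps_d;
  const bool do_bias = w0 > 0.0;

  std::vector<double> dx(d), s(d);
  for (int i = 0; i < d; ++i) {
    dx[i] = (gmax[i] - gmin[i]) / (gn[i] - 1);
    s[i] = s0[i];
  }
  const long ntot = (d == 1) ? gn[0] : (long)gn[0] * gn[1];
  std::vector<double> V(ntot, 0.0);

  // linear interpolation of V and its gradient on the grid
  auto bias_eval = [&](const double* p, double* grad) -> double {
    if (!do_bias) { for (int i = 0; i < d; ++i) grad[i] = 0.0; return 0.0; }
    if (d == 1) {
      double u = (p[0] - gmin[0]) / dx[0];
      long i0 = (long)std::floor(u);
      if (i0 < 0) i0 = 0;
      if (i0 > gn[0] - 2) i0 = gn[0] - 2;
      double f = u - i0;
      grad[0] = (V[i0 + 1] - V[i0]) / dx[0];
      return V[i0] * (1.0 - f) + V[i0 + 1] * f;
    }
    double u = (p[0] - gmin[0]) / dx[0], v = (p[1] - gmin[1]) / dx[1];
    long i0 = (long)std::floor(u), j0 = (long)std::floor(v);
    if (i0 < 0) i0 = 0;
    if (i0 > gn[0] - 2) i0 = gn[0] - 2;
    if (j0 < 0) j0 = 0;
    if (j0 > gn[1] - 2) j0 = gn[1] - 2;
    double fu = u - i0, fv = v - j0;
    double v00 = V[i0 + gn[0] * j0], v10 = V[i0 + 1 + gn[0] * j0];
    double v01 = V[i0 + gn[0] * (j0 + 1)],
           v11 = V[i0 + 1 + gn[0] * (j0 + 1)];
    grad[0] = ((v10 - v00) * (1.0 - fv) + (v11 - v01) * fv) / dx[0];
    grad[1] = ((v01 - v00) * (1.0 - fu) + (v11 - v10) * fu) / dx[1];
    return v00 * (1.0 - fu) * (1.0 - fv) + v10 * fu * (1.0 - fv) +
           v01 * (1.0 - fu) * fv + v11 * fu * fv;
  };

  auto add_hill = [&](const double* c, double h) {
    if (d == 1) {
      double lo = c[0] - 6.0 * sigma[0], hi = c[0] + 6.0 * sigma[0];
      long i0 = std::max(0L, (long)std::ceil((lo - gmin[0]) / dx[0]));
      long i1 = std::min((long)gn[0] - 1,
                         (long)std::floor((hi - gmin[0]) / dx[0]));
      for (long i = i0; i <= i1; ++i) {
        double z = (gmin[0] + i * dx[0] - c[0]) / sigma[0];
        V[i] += h * std::exp(-0.5 * z * z);
      }
    } else {
      long i0 = std::max(0L, (long)std::ceil(
                  (c[0] - 6.0 * sigma[0] - gmin[0]) / dx[0]));
      long i1 = std::min((long)gn[0] - 1, (long)std::floor(
                  (c[0] + 6.0 * sigma[0] - gmin[0]) / dx[0]));
      long j0 = std::max(0L, (long)std::ceil(
                  (c[1] - 6.0 * sigma[1] - gmin[1]) / dx[1]));
      long j1 = std::min((long)gn[1] - 1, (long)std::floor(
                  (c[1] + 6.0 * sigma[1] - gmin[1]) / dx[1]));
      for (long j = j0; j <= j1; ++j) {
        double zy = (gmin[1] + j * dx[1] - c[1]) / sigma[1];
        double ey = std::exp(-0.5 * zy * zy);
        for (long i = i0; i <= i1; ++i) {
          double zx = (gmin[0] + i * dx[0] - c[0]) / sigma[0];
          V[i + gn[0] * j] += h * ey * std::exp(-0.5 * zx * zx);
        }
      }
    }
  };

  const long n_out = n_steps / out_stride + 1;
  const long n_hills_max = do_bias ? n_steps / pace_steps + 1 : 0;
  NumericMatrix colvar(n_out, d + 2);
  NumericMatrix hillrec(n_hills_max, 2 * d + 2);
  long n_rec = 0, n_hill = 0;

  const double noise_pref = std::sqrt(2.0 * kT * dt / friction);
  std::vector<double> gU(d), gV(d), gtot(d);

  RNGScope scope;

  // record initial point
  {
    double b = bias_eval(s.data(), gV.data());
    colvar(n_rec, 0) = 0.0;
    for (int i = 0; i < d; ++i) colvar(n_rec, 1 + i) = s[i];
    colvar(n_rec, d + 1) = b;
    ++n_rec;
  }

  for (long step = 1; step <= n_steps; ++step) {
    pot_grad(pot_id, pot_par, s.data(), gU.data());
    bias_eval(s.data(), gV.data());
    for (int i = 0; i < d; ++i) gtot[i] = gU[i] + gV[i];
    // lower walls
    for (int wi = 0; wi < wallm.nrow(); ++wi) {
      int cvi = (int)wallm(wi, 0) - 1;
      double thr = wallm(wi, 1), kap = wallm(wi, 2);
      int ex = (int)wallm(wi, 3);
      if (s[cvi] < thr) {
        double gap = thr - s[cvi];
        gtot[cvi] += -kap * ex * std::pow(gap, ex - 1);
      }
    }
    for (int i = 0; i < d; ++i) {
      s[i] += -gtot[i] * dt / friction + noise_pref * R::norm_rand();
      // reflect at grid bounds
      if (s[i] < gmin[i]) s[i] = 2.0 * gmin[i] - s[i];
      if (s[i] > gmax[i]) s[i] = 2.0 * gmax[i] - s[i];
      if (s[i] < gmin[i]) s[i] = gmin[i];  // pathological overshoot
      if (!std::isfinite(s[i]))
        stop("Langevin dynamics diverged at step %ld", step);
    }
    if (do_bias && step % pace_steps == 0) {
      double Vhere = bias_eval(s.data(), gV.data());
      double h = w0 * std::exp(-Vhere / ((gamma - 1.0) * kT));
      add_hill(s.data(), h);
      hillrec(n_hill, 0) = step * dt;
      for (int i = 0; i < d; ++i) {
        hillrec(n_hill, 1 + i) = s[i];
        hillrec(n_hill, 1 + d + i) = sigma[i];
      }
      hillrec(n_hill, 2 * d + 1) = h;
      ++n_hill;
    }
    if (step % out_stride == 0) {
      double b = bias_eval(s.data(), gV.data());
      colvar(n_rec, 0) = step * dt;
      for (int i = 0; i < d; ++i) colvar(n_rec, 1 + i) = s[i];
      colvar(n_rec, d + 1) = b;
      ++n_rec;
    }
  }

  NumericMatrix hills_out(n_hill, 2 * d + 2);
  for (long k = 0; k < n_hill; ++k)
    for (int j = 0; j < 2 * d + 2; ++j) hills_out(k, j) = hillrec(k, j);
  NumericMatrix colvar_out(n_rec, d + 2);
  for (long k = 0; k < n_rec; ++k)
    for (int j = 0; j < d + 2; ++j) colvar_out(k, j) = colvar(k, j);

  return List::create(_["colvar"] = colvar_out, _["hills"] = hills_out,
                      _["grid"] = NumericVector(V.begin(), V.end()));
}
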