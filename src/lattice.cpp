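#include <Rcpp.h>
using namespace Rcpp;

// Exponentially weighted adaptive lattice structures for source-tract
// deconstruction.  All recursions share the same guard: denominators are
// offset by eps (a small fraction of the input power) so no division by
// zero can occur, and every reflection/ladder coefficient is a ratio of a
// cross product to a half-sum of squares, which keeps |k| < 1 by the
// AM-GM inequality applied term by term.

// Radiation compensation: a first-order prediction lattice tracks the
// lag-0/lag-1 autocorrelation of the input with forgetting lambda.  The
// normalised coefficient k is read as the lag-1 moment of an MA(1)
// radiation model x = (1 - z0 B) s with locally flat s, k = -z0/(1+z0^2);
// the zero estimate z0 is inverted with a leaky pole min(z0, rho_max)
// (leaky integration), and a DC blocker removes residual drift.
// [[Rcpp::export]]
List st_radiation_cpp(NumericVector x, double lambda, double eps_rel,
                      double rho_max, double dc_pole) {
  int n = x.size();
  NumericVector y(n), ktraj(n);
  if (n == 0) return List::create(_["y"] = y, _["k"] = ktraj);
  double msx = 0.0;
  for (int i = 0; i < n; ++i) msx += x[i] * x[i];
  msx /= n;
  double eps = eps_rel * msx + 1e-300;

  double r1 = 0.0, r0 = 0.0, k = 0.0;
  double yprev = 0.0, dprev = 0.0, oprev = 0.0;
  for (int i = 0; i < n; ++i) {
    double xp = (i > 0) ? x[i - 1] : 0.0;
    r1 = lambda * r1 + x[i] * xp;
    r0 = lambda * r0 + x[i] * x[i];
    k = r1 / (r0 + eps);
    ktraj[i] = k;
    // Radiation-zero estimate from the MA(1) moment relation
    // k = -z0/(1+z0^2), using the saturating linear surrogate
    // z0 ~ min(1, -2k): exact at the physical z0 = 1 limit and free of
    // the unbounded sensitivity of the exact inverse there.
    double rho = 0.0;
    if (k < 0.0) {
      double z0 = -2.0 * k;
      rho = (z0 < rho_max) ? z0 : rho_max;
    }
    double yi = x[i] + rho * yprev;   // leaky integration
    yprev = yi;
    // DC blocker: y(n) - y(n-1) + dc_pole * out(n-1)
    double oi = yi - dprev + dc_pole * oprev;
    dprev = yi;
    oprev = oi;
    y[i] = oi;
  }
  return List::create(_["y"] = y, _["k"] = ktraj);
}

// k-order prediction-error lattice with Burg-type exponentially weighted
// error-product recursions.  Returns the final-stage forward error
// (residual), the per-sample reflection-coefficient trajectories and the
// per-sample backward prediction errors of every stage (needed by the
// joint-process ladder).
// [[Rcpp::export]]
List st_lattice_cpp(NumericVector x, int order, double lambda,
                    double eps_rel, bool keep_backward) {
  int n = x.size();
  NumericVector resid(n);
  NumericMatrix ktraj(order, n);
  NumericMatrix bmat = keep_backward ? NumericMatrix(order + 1, n)
                                     : NumericMatrix(0, 0);
  if (n == 0)
    return List::create(_["residual"] = resid, _["parcor"] = ktraj,
                        _["backward"] = bmat);
  double msx = 0.0;
  for (int i = 0; i < n; ++i) msx += x[i] * x[i];
  msx /= n;
  double eps = eps_rel * msx + 1e-300;

  std::vector<double> C(order, 0.0), D(order, 0.0);
  std::vector<double> bprev(order + 1, 0.0), bcur(order + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double f = x[i];
    bcur[0] = x[i];
    for (int m = 1; m <= order; ++m) {
      double bp = bprev[m - 1];
      C[m - 1] = lambda * C[m - 1] + f * bp;
      D[m - 1] = lambda * D[m - 1] + 0.5 * (f * f + bp * bp);
      double k = C[m - 1] / (D[m - 1] + eps);
      double fn = f - k * bp;
      bcur[m] = bp - k * f;
      f = fn;
      ktraj(m - 1, i) = k;
    }
    resid[i] = f;
    if (keep_backward)
      for (int m = 0; m <= order; ++m) bmat(m, i) = bcur[m];
    std::swap(bprev, bcur);
  }
  return List::create(_["residual"] = resid, _["parcor"] = ktraj,
                      _["backward"] = bmat);
}

// Joint-process estimation: a lattice orthogonalises the reference signal
// into backward prediction errors b_0..b_k; ladder coefficients regress
// the desired signal on them with the same forgetting factor.  The
// joint-process estimate and its error decompose the desired signal
// additively (est + err = d exactly).
// [[Rcpp::export]]
List st_jpe_cpp(NumericVector ref, NumericVector d, int order, double lambda,
                double eps_rel, int n_sweeps) {
  int n = ref.size();
  NumericVector est(n), err(n);
  NumericMatrix ktraj(order, n);
  if (n == 0)
    return List::create(_["estimate"] = est, _["error"] = err,
                        _["parcor"] = ktraj);
  double msx = 0.0;
  for (int i = 0; i < n; ++i) msx += ref[i] * ref[i];
  msx /= n;
  double eps = eps_rel * msx + 1e-300;
  double msd = 0.0;
  for (int i = 0; i < n; ++i) msd += d[i] * d[i];
  msd /= n;
  double epsd = eps_rel * msd + 1e-300;
  if (n_sweeps < 1) n_sweeps = 1;

  std::vector<double> C(order, 0.0), D(order, 0.0);
  // one ladder (gain + normaliser) per refinement sweep
  std::vector< std::vector<double> > G(n_sweeps), P(n_sweeps);
  for (int s = 0; s < n_sweeps; ++s) {
    G[s].assign(order + 1, 0.0);
    P[s].assign(order + 1, 0.0);
  }
  std::vector<double> bprev(order + 1, 0.0), bcur(order + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    double f = ref[i];
    bcur[0] = ref[i];
    for (int m = 1; m <= order; ++m) {
      double bp = bprev[m - 1];
      C[m - 1] = lambda * C[m - 1] + f * bp;
      D[m - 1] = lambda * D[m - 1] + 0.5 * (f * f + bp * bp);
      double k = C[m - 1] / (D[m - 1] + eps);
      double fn = f - k * bp;
      bcur[m] = bp - k * f;
      f = fn;
      ktraj(m - 1, i) = k;
    }
    // ladder: each sweep regresses the remaining estimation error on
    // the full set of backward errors; the second sweep compensates
    // their residual (non-ideal) correlation
    double target = d[i];
    for (int s = 0; s < n_sweeps; ++s) {
      double ys = 0.0;
      for (int m = 0; m <= order; ++m) {
        G[s][m] = lambda * G[s][m] + target * bcur[m];
        P[s][m] = lambda * P[s][m] + bcur[m] * bcur[m];
        ys += (G[s][m] / (P[s][m] + epsd)) * bcur[m];
      }
      target -= ys;
    }
    est[i] = d[i] - target;
    err[i] = target;
    std::swap(bprev, bcur);
  }
  return List::create(_["estimate"] = est, _["error"] = err,
                      _["parcor"] = ktraj);
}
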