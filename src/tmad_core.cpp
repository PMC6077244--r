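#include <Rcpp.h>
using namespace Rcpp;

// Thomas algorithm for a tridiagonal system.
// lower[0] and upper[n-1] are ignored. Overwrites work arrays cp/dp.
static void thomas(int n, const double* lower, const double* diag,
                   const double* upper, const double* rhs,
                   double* x, double* cp, double* dp) {
  if (diag[0] == 0.0) stop("zero pivot in tridiagonal solve (row 1)");
  cp[0] = upper[0] / diag[0];
  dp[0] = rhs[0] / diag[0];
  for (int i = 1; i < n; ++i) {
    double m = diag[i] - lower[i] * cp[i - 1];
    if (m == 0.0) stop("zero pivot in tridiagonal solve (row %d)", i + 1);
    cp[i] = upper[i] / m;
    dp[i] = (rhs[i] - lower[i] * dp[i - 1]) / m;
  }
  x[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = dp[i] - cp[i] * x[i + 1];
}

// [[Rcpp::export]]
NumericVector cpp_thomas(NumericVector lower, NumericVector diag,
                         NumericVector upper, NumericVector rhs) {
  int n = diag.size();
  if (lower.size() != n || upper.size() != n || rhs.size() != n)
    stop("tridiagonal bands and rhs must have equal length");
  NumericVector x(n);
  std::vector<double> cp(n), dp(n);
  thomas(n, lower.begin(), diag.begin(), upper.begin(), rhs.begin(),
         x.begin(), cp.data(), dp.data());
  return x;
}

// One backward-Euler step of the trumpet mass balance, written as
// finite-volume rows (volume cap*dz per node, no flux through outer faces,
// advection upwinded by flow sign).  Bands are filled in place.
static void assemble(int n, const double* C, const double* cap,
                     const double* area_face, // n-1 face-averaged airway areas
                     const double* w_aw, const double* w_alv,
                     double dz, double dt, double flow, int dirichlet,
                     double ambient, double J_aw, double D_aw, double J_A,
                     double D_A, double D_gas,
                     double* a, double* b, double* c, double* d) {
  for (int i = 0; i < n; ++i) {
    double v = cap[i] * dz;
    a[i] = 0.0;
    c[i] = 0.0;
    b[i] = v / dt + dz * (w_aw[i] * D_aw + w_alv[i] * D_A);
    d[i] = v / dt * C[i] + dz * (w_aw[i] * J_aw + w_alv[i] * J_A);
    if (D_gas > 0.0) {
      if (i > 0) {
        double fl = D_gas * area_face[i - 1] / dz;
        a[i] -= fl;
        b[i] += fl;
      }
      if (i < n - 1) {
        double fr = D_gas * area_face[i] / dz;
        c[i] -= fr;
        b[i] += fr;
      }
    }
    if (flow > 0.0 && i > 0) { // inhalation: upwind neighbour is i-1
      b[i] += flow;
      a[i] -= flow;
    } else if (flow < 0.0 && i < n - 1) { // exhalation: upwind is i+1
      b[i] -= flow;
      c[i] += flow;
    }
  }
  if (dirichlet) { // mouth pinned to ambient during inhalation
    a[0] = 0.0;
    b[0] = 1.0;
    c[0] = 0.0;
    d[0] = ambient;
  }
}

// [[Rcpp::export]]
List cpp_tmad_assemble(NumericVector C, NumericVector cap,
                       NumericVector area_face, NumericVector w_aw,
                       NumericVector w_alv, double dz, double dt, double flow,
                       int dirichlet, double ambient, double J_aw, double D_aw,
                       double J_A, double D_A, double D_gas) {
  int n = C.size();
  NumericVector a(n), b(n), c(n), d(n);
  assemble(n, C.begin(), cap.begin(), area_face.begin(), w_aw.begin(),
           w_alv.begin(), dz, dt, flow, dirichlet, ambient, J_aw, D_aw, J_A,
           D_A, D_gas, a.begin(), b.begin(), c.begin(), d.begin());
  return List::create(_["lower"] = a, _["diag"] = b, _["upper"] = c,
                      _["rhs"] = d);
}

// Run nsteps backward-Euler steps; flow / dirichlet / ambient are per-step.
// Records the mouth-node concentration after every step and full axial
// snapshots after the steps listed in snap_at (1-based).
// [[Rcpp::export]]
List cpp_tmad_run(NumericVector C0, NumericVector cap, NumericVector area_face,
                  NumericVector w_aw, NumericVector w_alv, double dz, double dt,
                  NumericVector flow, IntegerVector dirichlet,
                  NumericVector ambient, double J_aw, double D_aw, double J_A,
                  double D_A, double D_gas, IntegerVector snap_at,
                  double neg_tol) {
  int n = C0.size();
  int nsteps = flow.size();
  if (dirichlet.size() != nsteps || ambient.size() != nsteps)
    stop("flow, dirichlet and ambient must have one value per step");
  if (cap.size() != n || w_aw.size() != n || w_alv.size() != n)
    stop("grid vectors must match the state length");
  if (area_face.size() != n - 1) stop("need n-1 face areas");

  std::vector<double> C(C0.begin(), C0.end());
  std::vector<double> a(n), b(n), c(n), d(n), x(n), cp(n), dp(n);
  NumericVector mouth(nsteps);
  NumericMatrix snaps(n, snap_at.size());
  int nsnap = 0, nclip = 0;

  for (int k = 0; k < nsteps; ++k) {
    assemble(n, C.data(), cap.begin(), area_face.begin(), w_aw.begin(),
             w_alv.begin(), dz, dt, flow[k], dirichlet[k], ambient[k], J_aw,
             D_aw, J_A, D_A, D_gas, a.data(), b.data(), c.data(), d.data());
    thomas(n, a.data(), b.data(), c.data(), d.data(), x.data(), cp.data(),
           dp.data());
    for (int i = 0; i < n; ++i) {
      if (x[i] < 0.0) {
        if (x[i] < -neg_tol)
          stop("negative concentration %g ppb at node %d, step %d", x[i],
               i + 1, k + 1);
        x[i] = 0.0;
        ++nclip;
      }
      C[i] = x[i];
    }
    mouth[k] = C[0];
    if (nsnap < snap_at.size() && snap_at[nsnap] == k + 1) {
      for (int i = 0; i < n; ++i) snaps(i, nsnap) = C[i];
      ++nsnap;
    }
  }
  return List::create(_["mouth"] = mouth,
                      _["state"] = NumericVector(C.begin(), C.end()),
                      _["snapshots"] = snaps, _["n_clipped"] = nclip);
}
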