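#include <Rcpp.h>
using namespace Rcpp;

// Backward-Euler march of the coupled system in boundary-fixed coordinates,
//   dC_i/dt = (D / L^2(t)) d2C_i/dxi2 - (sigma(t) + k_i) C_i
//             + m k_{i-1} C_{i-1},
// on xi in [0, 1] with zero-flux (ghost-point Neumann) closure at both ends.
// Diffusion and reaction are implicit at the new time level; the coupling
// source uses the already-updated density of the previous generation, so
// each step reduces to one tridiagonal solve per generation.
//
// C0:        nodes x G initial densities
// Lsq_new:   L^2 at t = s*dt, s = 1..nsteps (new time level)
// sigma_new: sigma at t = s*dt
// save_step: 1-based step indices at which to store the state
// Returns a nodes x G x nsave array.
// [[Rcpp::export]]
NumericVector fd_march(NumericMatrix C0, double D, double dxi, double dt,
                       NumericVector Lsq_new, NumericVector sigma_new,
                       NumericVector k, double m, IntegerVector save_step) {
  const int n = C0.nrow();
  const int G = C0.ncol();
  const int nsteps = Lsq_new.size();
  const int nsave = save_step.size();

  NumericVector out(Dimension(n, G, nsave));
  std::vector<double> C(n * G), Cnew(n * G);
  for (int g = 0; g < G; ++g)
    for (int j = 0; j < n; ++j) C[g * n + j] = C0(j, g);

  std::vector<double> cp(n), dp(n), rhs(n);
  int isave = 0;
  // step 0 requested (t = 0): store the initial state
  while (isave < nsave && save_step[isave] == 0) {
    for (int g = 0; g < G; ++g)
      for (int j = 0; j < n; ++j) out[isave * n * G + g * n + j] = C[g * n + j];
    ++isave;
  }

  for (int s = 0; s < nsteps; ++s) {
    const double lam = D * dt / (Lsq_new[s] * dxi * dxi);
    const double sig = sigma_new[s];
    for (int g = 0; g < G; ++g) {
      const double diag = 1.0 + 2.0 * lam + dt * (sig + k[g]);
      double *Cg = &C[g * n];
      double *Ng = &Cnew[g * n];
      if (g == 0) {
        for (int j = 0; j < n; ++j) rhs[j] = Cg[j];
      } else {
        const double src = dt * m * k[g - 1];
        const double *Pg = &Cnew[(g - 1) * n];
        for (int j = 0; j < n; ++j) rhs[j] = Cg[j] + src * Pg[j];
      }
      // Thomas algorithm; ghost points double the off-diagonal in rows 0, n-1
      cp[0] = -2.0 * lam / diag;
      dp[0] = rhs[0] / diag;
      for (int j = 1; j < n - 1; ++j) {
        const double w = diag - lam * (-cp[j - 1]);
        cp[j] = -lam / w;
        dp[j] = (rhs[j] + lam * dp[j - 1]) / w;
      }
      {
        const double w = diag - 2.0 * lam * (-cp[n - 2]);
        dp[n - 1] = (rhs[n - 1] + 2.0 * lam * dp[n - 2]) / w;
      }
      Ng[n - 1] = dp[n - 1];
      for (int j = n - 2; j >= 0; --j) Ng[j] = dp[j] - cp[j] * Ng[j + 1];
    }
    std::swap(C, Cnew);

    while (isave < nsave && save_step[isave] == s + 1) {
      for (int g = 0; g < G; ++g)
        for (int j = 0; j < n; ++j) out[isave * n * G + g * n + j] = C[g * n + j];
      ++isave;
    }
  }

  for (int j = 0; j < n * G; ++j)
    if (!R_finite(C[j]))
      stop("finite-difference solution became non-finite; reduce `dt`");
  return out;
}
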