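#include <Rcpp.h>
using namespace Rcpp;

// Explicit-Euler integrator for the two-variable excitable-media model on a
// labelled 2-D grid: 5-point Laplacian with per-face conductances (harmonic
// mean of the two cell diffusivities; zero on outer faces and wherever either
// side is non-conducting), cubic reaction u(u - theta)(alpha - u) - u2 in
// active cells, recovery du2 = eps (beta u - gamma u2 - delta).
//
// Per recorded frame it stores: u1 at point probes, lead-field projections
// (weighted sums of the instantaneous diffusive current over cardiac cells),
// and per-region means and absolute maxima of u1.
//
// [[Rcpp::export]]
List fhn_run_cpp(NumericMatrix u1_, NumericMatrix u2_,
                 NumericMatrix Gr_, NumericMatrix Gd_,
                 NumericMatrix eps_, IntegerMatrix active_,
                 NumericMatrix theta_, IntegerMatrix labels,
                 double alpha, double beta, double gamma, double delta,
                 double h, double dt, double t0, int nsteps, int record_every,
                 IntegerVector stim_idx, double stim_amp,
                 double stim_start, double stim_period, double stim_width,
                 IntegerVector probe_idx, int nregions,
                 IntegerVector card_idx, NumericMatrix W) {
  const int nr = u1_.nrow(), nc = u1_.ncol(), n = nr * nc;
  std::vector<double> u1(u1_.begin(), u1_.end());
  std::vector<double> u2(u2_.begin(), u2_.end());
  std::vector<double> nu1(n), nu2(n);
  // face conductances aligned per cell: gN couples k with k-1, gS with k+1,
  // gW with k-nr, gE with k+nr; zero entries double as the no-flux mask
  std::vector<double> gN(n, 0.0), gS(n, 0.0), gW(n, 0.0), gE(n, 0.0);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++) {
      int k = i + j * nr;
      if (i > 0)      gN[k] = Gd_(i - 1, j);
      if (i < nr - 1) gS[k] = Gd_(i, j);
      if (j > 0)      gW[k] = Gr_(i, j - 1);
      if (j < nc - 1) gE[k] = Gr_(i, j);
    }
  std::vector<double> eps(n), theta(n);
  std::vector<int> active(n);
  for (int k = 0; k < n; k++) {
    eps[k] = eps_[k]; theta[k] = theta_[k]; active[k] = active_[k];
  }
  const double ih2 = 1.0 / (h * h);
  const int nrec = record_every > 0 ? nsteps / record_every : 0;
  const int np = probe_idx.size();
  const int ncard = card_idx.size(), nw = W.ncol();
  NumericMatrix probes(nrec, np), probes_phi(nrec, nw);
  NumericMatrix rmeans(nrec, nregions), rmax(nrec, nregions);
  NumericVector rec_times(nrec);
  std::vector<int> rcount(nregions, 0);
  for (int k = 0; k < n; k++) rcount[labels[k] - 1]++;
  int irec = 0;
  for (int s = 0; s < nsteps; s++) {
    double t = t0 + s * dt;
    bool stim_on = false;
    if (stim_amp > 0 && t >= stim_start) {
      double tt = t - stim_start;
      double ph = tt - std::floor(tt / stim_period) * stim_period;
      stim_on = (ph < stim_width);
    }
    const double *pu1 = u1.data(), *pu2 = u2.data();
    double *q1 = nu1.data(), *q2 = nu2.data();
    for (int k = 0; k < n; k++) {
      double u = pu1[k];
      double flux = 0.0;
      if (gN[k] != 0.0) flux += gN[k] * (pu1[k - 1]  - u);
      if (gS[k] != 0.0) flux += gS[k] * (pu1[k + 1]  - u);
      if (gW[k] != 0.0) flux += gW[k] * (pu1[k - nr] - u);
      if (gE[k] != 0.0) flux += gE[k] * (pu1[k + nr] - u);
      double du1 = flux * ih2;
      double v2 = pu2[k];
      if (active[k]) {
        du1 += u * (u - theta[k]) * (alpha - u) - v2;
        q2[k] = v2 + dt * eps[k] * (beta * u - gamma * v2 - delta);
      } else q2[k] = v2;
      q1[k] = u + dt * du1;
    }
    if (stim_on)
      for (int q = 0; q < stim_idx.size(); q++) q1[stim_idx[q]] += dt * stim_amp;
    std::swap(u1, nu1);
    std::swap(u2, nu2);
    if (record_every > 0 && (s + 1) % record_every == 0) {
      rec_times[irec] = t0 + (s + 1) * dt;
      for (int q = 0; q < np; q++) probes(irec, q) = u1[probe_idx[q]];
      for (int q = 0; q < nw; q++) {
        double acc = 0.0;
        for (int c = 0; c < ncard; c++) {
          int k = card_idx[c];
          double u = u1[k], flux = 0.0;
          if (gN[k] != 0.0) flux += gN[k] * (u1[k - 1]  - u);
          if (gS[k] != 0.0) flux += gS[k] * (u1[k + 1]  - u);
          if (gW[k] != 0.0) flux += gW[k] * (u1[k - nr] - u);
          if (gE[k] != 0.0) flux += gE[k] * (u1[k + nr] - u);
          acc += W(c, q) * flux * ih2;
        }
        probes_phi(irec, q) = acc;
      }
      std::vector<double> rsum(nregions, 0.0), rmx(nregions, 0.0);
      for (int k = 0; k < n; k++) {
        int r = labels[k] - 1;
        rsum[r] += u1[k];
        double a = std::fabs(u1[k]);
        if (a > rmx[r]) rmx[r] = a;
      }
      for (int r = 0; r < nregions; r++) {
        rmeans(irec, r) = rcount[r] > 0 ? rsum[r] / rcount[r] : NA_REAL;
        rmax(irec, r)   = rcount[r] > 0 ? rmx[r] : NA_REAL;
      }
      irec++;
    }
  }
  NumericMatrix u1o(nr, nc), u2o(nr, nc);
  std::copy(u1.begin(), u1.end(), u1o.begin());
  std::copy(u2.begin(), u2.end(), u2o.begin());
  return List::create(_["u1"] = u1o, _["u2"] = u2o,
                      _["t"] = t0 + nsteps * dt, _["times"] = rec_times,
                      _["probes"] = probes, _["probes_phi"] = probes_phi,
                      _["region_means"] = rmeans, _["region_max"] = rmax);
}
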