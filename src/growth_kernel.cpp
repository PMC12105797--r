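#include <Rcpp.h>
using namespace Rcpp;

// Explicit forward-Euler integration of the coupled two-species
// reaction-diffusion system on the brain-mask voxels.
//
// Diffusion uses a conservative flux form with arithmetic face averaging of
// the (stress-damped) diffusion coefficient; faces whose neighbour lies
// outside the brain mask carry zero flux, which enforces the zero-flux
// boundary condition and conserves total mass exactly when the reaction
// terms vanish. Because the diffusion fields are fixed for the duration of
// one call (they are refreshed with the daily mechanics solve), the face
// transmissibilities are precomputed once and the substep loop is
// branch-free: boundary faces carry zero transmissibility and point at the
// centre voxel. The logistic-competition reactions read
//   kpE * NE * (1 - (NE + betaNE * NN) / thetaE)
//   kpN * NN * (1 - (NN + betaEN * NE) / thetaN)
// and the state is clipped to [0, theta_j] after each substep (clips are
// counted and reported).
//
// nb: 6 x n neighbour table over mask voxels (0 = face on the boundary),
// rows ordered -x,+x,-y,+y,-z,+z; inv_h2: 1/dx^2, 1/dy^2, 1/dz^2.
// [[Rcpp::export]]
List cpp_growth(NumericVector ne, NumericVector nn,
                NumericVector de, NumericVector dn,
                NumericVector kpe, NumericVector kpn,
                double betaNE, double betaEN,
                double thetaE, double thetaN,
                IntegerMatrix nb, NumericVector inv_h2,
                double dt, int nsteps) {
  const int n = ne.size();
  NumericVector outE(n), outN(n);
  std::vector<double> uE(ne.begin(), ne.end()), uN(nn.begin(), nn.end());
  std::vector<double> vE(n), vN(n);
  std::vector<double> TE(6 * n), TN(6 * n), rsE(n), rsN(n);
  std::vector<int> J(6 * n);
  const int *nbp = nb.begin();  // column-major: entry f of voxel i at 6*i+f

  for (int i = 0; i < n; ++i) {
    double se = 0.0, sn = 0.0;
    for (int f = 0; f < 6; ++f) {
      const int idx = 6 * i + f;
      const int j = nbp[idx];
      if (j == 0) { J[idx] = i; TE[idx] = 0.0; TN[idx] = 0.0; continue; }
      const double w = inv_h2[f / 2];
      J[idx] = j - 1;
      TE[idx] = 0.5 * (de[i] + de[j - 1]) * w;
      TN[idx] = 0.5 * (dn[i] + dn[j - 1]) * w;
      se += TE[idx]; sn += TN[idx];
    }
    rsE[i] = se; rsN[i] = sn;
  }

  long clipped = 0;
  const double iTE = 1.0 / thetaE, iTN = 1.0 / thetaN;
  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      const int b = 6 * i;
      const double uEi = uE[i], uNi = uN[i];
      double lapE = -rsE[i] * uEi, lapN = -rsN[i] * uNi;
      lapE += TE[b] * uE[J[b]] + TE[b + 1] * uE[J[b + 1]] +
        TE[b + 2] * uE[J[b + 2]] + TE[b + 3] * uE[J[b + 3]] +
        TE[b + 4] * uE[J[b + 4]] + TE[b + 5] * uE[J[b + 5]];
      lapN += TN[b] * uN[J[b]] + TN[b + 1] * uN[J[b + 1]] +
        TN[b + 2] * uN[J[b + 2]] + TN[b + 3] * uN[J[b + 3]] +
        TN[b + 4] * uN[J[b + 4]] + TN[b + 5] * uN[J[b + 5]];
      double wE = uEi + dt * (lapE + kpe[i] * uEi *
                              (1.0 - (uEi + betaNE * uNi) * iTE));
      double wN = uNi + dt * (lapN + kpn[i] * uNi *
                              (1.0 - (uNi + betaEN * uEi) * iTN));
      if (wE < 0.0) { wE = 0.0; ++clipped; }
      else if (wE > thetaE) { wE = thetaE; ++clipped; }
      if (wN < 0.0) { wN = 0.0; ++clipped; }
      else if (wN > thetaN) { wN = thetaN; ++clipped; }
      vE[i] = wE; vN[i] = wN;
    }
    uE.swap(vE); uN.swap(vN);
  }
  std::copy(uE.begin(), uE.end(), outE.begin());
  std::copy(uN.begin(), uN.end(), outN.begin());
  return List::create(_["NE"] = outE, _["NN"] = outN,
                      _["clipped"] = (double)clipped);
}
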