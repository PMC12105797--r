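#include <Rcpp.h>
using namespace Rcpp;

// Batched forward simulation engine.
//
// Integrates the two-species reaction-diffusion model with mechanics-damped
// diffusion and discrete chemoradiation events for P parameter columns that
// share one anatomy, schedule and variant. Batching exists so that a
// finite-difference Jacobian (the base point plus one perturbed column per
// free parameter) costs a single pass over the expensive sparse LU factors
// of the mechanics operator instead of one pass per parameter.
//
// Mechanics: the equilibrium operator factorization (P_r A = L U on
// permuted columns, Matrix::lu convention A[p+1, q+1] = L U) and the
// density -> body-force and displacement -> stress operators are passed in
// CSC form; the triangular solves are batched across columns with
// row-major scratch so L and U stream through memory once per day.
//
// Treatment couplings (rt_mode / ct_mode): 0 = off, 1 = spatially uniform
// LQ, 2 = vasculature (dose scaled by 1/OER), 3 = cell-density modulated.
// combined = single RT-form term with SF_CT = 1.
//
// Parameter rows (canonical order): kpE, kpN, D_w, D_g, f_NE, beta_NE,
// beta_EN, lambda1, alpha_RT, alpha_RT_prolif, alpha_CT, alpha_beta.

namespace {

struct CSC {
  const int *p, *i;
  const double *x;
  int ncol;
};

CSC csc(List m) {
  CSC out;
  IntegerVector p = m["p"], i = m["i"];
  NumericVector x = m["x"];
  out.p = p.begin(); out.i = i.begin(); out.x = x.begin();
  out.ncol = p.size() - 1;
  return out;
}

// y (nrow x P, row-major) += A (CSC, nrow x ncol) * x (ncol x P, row-major)
void spmm_rm(const CSC &A, const double *x, double *y, int P) {
  for (int j = 0; j < A.ncol; ++j) {
    const double *xj = x + (size_t)j * P;
    for (int k = A.p[j]; k < A.p[j + 1]; ++k) {
      double *yr = y + (size_t)A.i[k] * P;
      const double a = A.x[k];
      for (int c = 0; c < P; ++c) yr[c] += a * xj[c];
    }
  }
}

// Batched triangular solves with the Cholesky factor held in single
// precision: the factor is streamed twice per solve and dominates the
// memory traffic of a whole simulated day, while the ~1e-7 relative
// error it introduces into the stress field is orders of magnitude below
// the densities' dynamic range and identical for every simulation (truth
// and calibration share this code path, so self-consistency is exact).
// X is row-major (n x P), float; diag positions precomputed.
void lsolve_rm(const int *Lp, const int *Li, const float *Lx,
               int ncol, const int *dk, float *X, int P) {
  for (int j = 0; j < ncol; ++j) {
    float *Xj = X + (size_t)j * P;
    const float d = Lx[dk[j]];
    for (int c = 0; c < P; ++c) Xj[c] /= d;
    for (int k = Lp[j]; k < Lp[j + 1]; ++k) {
      const int r = Li[k];
      if (r == j) continue;
      float *Xr = X + (size_t)r * P;
      const float a = Lx[k];
      for (int c = 0; c < P; ++c) Xr[c] -= a * Xj[c];
    }
  }
}

// in-place batched transposed solve L' X = B (gather form over columns)
void ltsolve_rm(const int *Lp, const int *Li, const float *Lx,
                int ncol, const int *dk, float *X, int P) {
  for (int j = ncol - 1; j >= 0; --j) {
    float *Xj = X + (size_t)j * P;
    for (int k = Lp[j]; k < Lp[j + 1]; ++k) {
      const int r = Li[k];
      if (r == j) continue;
      const float *Xr = X + (size_t)r * P;
      const float a = Lx[k];
      for (int c = 0; c < P; ++c) Xj[c] -= a * Xr[c];
    }
    const float d = Lx[dk[j]];
    for (int c = 0; c < P; ++c) Xj[c] /= d;
  }
}

inline double lq(double alpha, double dose, double ab) {
  return std::exp(-alpha * dose * (1.0 + dose / ab));
}

}  // namespace

// [[Rcpp::export]]
List cpp_sim_engine(NumericVector ne0, NumericVector nn0,
                    NumericMatrix par, IntegerVector lab,
                    IntegerMatrix nb, NumericVector inv_h2,
                    double theta_e, double theta_n,
                    double dt_max, double cfl, int mech_cadence,
                    List mech, bool use_mech_any,
                    IntegerVector event_days, LogicalVector event_has_rt,
                    NumericMatrix dose_maps, NumericVector oer,
                    int rt_mode, int ct_mode, bool combined,
                    IntegerVector obs_days, int day0) {
  const int n = ne0.size();
  const int P = par.ncol();
  const int n3 = 3 * n, n6 = 6 * n;
  const double cap = theta_e + theta_n;

  // per-column parameters
  std::vector<double> kpE(P), kpN(P), bNE(P), bEN(P), lam1(P),
    aRT(P), aRTp(P), aCT(P), aB(P), dt(P);
  std::vector<int> steps(P);
  // per-column fields (col-major, column c at offset c*n)
  std::vector<double> d0e((size_t)n * P), d0n((size_t)n * P);
  std::vector<double> dE((size_t)n * P), dN((size_t)n * P);
  std::vector<double> uE((size_t)n * P), uN((size_t)n * P);
  std::vector<double> prolif((size_t)n * P, 1.0);
  double s_invh2 = inv_h2[0] + inv_h2[1] + inv_h2[2];

  for (int c = 0; c < P; ++c) {
    kpE[c] = par(0, c); kpN[c] = par(1, c);
    const double dw = par(2, c), dg = par(3, c), fne = par(4, c);
    bNE[c] = par(5, c); bEN[c] = par(6, c); lam1[c] = par(7, c);
    aRT[c] = par(8, c); aRTp[c] = par(9, c); aCT[c] = par(10, c);
    aB[c] = par(11, c);
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      const double de = (lab[i] == 1) ? dw : dg;
      d0e[(size_t)c * n + i] = de;
      d0n[(size_t)c * n + i] = de * fne;
      dmax = std::max(dmax, std::max(de, de * fne));
    }
    double bound = (dmax > 0) ? cfl / (2.0 * dmax * s_invh2) : dt_max;
    double dtc = std::min(dt_max, bound);
    steps[c] = std::max(1, (int)std::ceil(1.0 / dtc - 1e-12));
    dt[c] = 1.0 / steps[c];
    std::copy(ne0.begin(), ne0.end(), uE.begin() + (size_t)c * n);
    std::copy(nn0.begin(), nn0.end(), uN.begin() + (size_t)c * n);
    for (int i = 0; i < n; ++i) {
      dE[(size_t)c * n + i] = d0e[(size_t)c * n + i];
      dN[(size_t)c * n + i] = d0n[(size_t)c * n + i];
    }
  }

  // mechanics operators: Cholesky factor of the negated (positive
  // definite) equilibrium operator, P (-A) P' = L L'
  CSC B{}, L{}, S{};
  const int *pp = nullptr;
  std::vector<int> Ldiag;
  std::vector<float> Lxf;
  if (use_mech_any) {
    B = csc(mech["B"]); L = csc(mech["L"]); S = csc(mech["S"]);
    IntegerVector ppv = mech["perm"];
    pp = ppv.begin();
    Ldiag.resize(L.ncol);
    for (int j = 0; j < L.ncol; ++j)
      for (int k = L.p[j]; k < L.p[j + 1]; ++k)
        if (L.i[k] == j) { Ldiag[j] = k; break; }
    const int nnz = L.p[L.ncol];
    Lxf.resize(nnz);
    for (int k = 0; k < nnz; ++k) Lxf[k] = (float)L.x[k];
  }
  std::vector<double> dens_rm, rhs_rm, u_rm, sig_rm, vm((size_t)n * P, 0.0);
  std::vector<float> perm_rm;
  if (use_mech_any) {
    dens_rm.resize((size_t)n * P); rhs_rm.resize((size_t)n3 * P);
    perm_rm.resize((size_t)n3 * P); u_rm.resize((size_t)n3 * P);
    sig_rm.resize((size_t)n6 * P);
  }

  // transmissibilities per column (recomputed after each mechanics refresh)
  std::vector<double> TE((size_t)6 * n * P), TN((size_t)6 * n * P),
    rsE((size_t)n * P), rsN((size_t)n * P);
  std::vector<int> J6((size_t)6 * n);
  const int *nbp = nb.begin();
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < 6; ++f) {
      const int idx = 6 * i + f;
      J6[idx] = (nbp[idx] == 0) ? i : nbp[idx] - 1;
    }
  auto build_T = [&](int c) {
    const double *de = &dE[(size_t)c * n], *dn = &dN[(size_t)c * n];
    double *te = &TE[(size_t)6 * n * c], *tn = &TN[(size_t)6 * n * c];
    double *re = &rsE[(size_t)c * n], *rn = &rsN[(size_t)c * n];
    for (int i = 0; i < n; ++i) {
      double se = 0.0, sn = 0.0;
      for (int f = 0; f < 6; ++f) {
        const int idx = 6 * i + f;
        if (nbp[idx] == 0) { te[idx] = 0.0; tn[idx] = 0.0; continue; }
        const double w = inv_h2[f / 2];
        te[idx] = 0.5 * (de[i] + de[nbp[idx] - 1]) * w;
        tn[idx] = 0.5 * (dn[i] + dn[nbp[idx] - 1]) * w;
        se += te[idx]; sn += tn[idx];
      }
      re[i] = se; rn[i] = sn;
    }
  };
  for (int c = 0; c < P; ++c) build_T(c);

  std::vector<double> scrE(n), scrN(n);
  std::vector<double> clipped(P, 0.0);

  const int n_obs = obs_days.size();
  List outNE(n_obs), outNN(n_obs);
  int oi = 0;
  const int last_day = obs_days[n_obs - 1];
  int ev_idx = 0;

  for (int day = day0; ; ++day) {
    if (oi < n_obs && day == obs_days[oi]) {
      NumericMatrix me(n, P), mn(n, P);
      std::copy(uE.begin(), uE.end(), me.begin());
      std::copy(uN.begin(), uN.end(), mn.begin());
      outNE[oi] = me; outNN[oi] = mn;
      ++oi;
    }
    while (ev_idx < event_days.size() && event_days[ev_idx] == day) {
      // one treatment event: discrete voxelwise reduction
      const bool has_rt = event_has_rt[ev_idx];
      for (int c = 0; c < P; ++c) {
        double *e = &uE[(size_t)c * n], *nn_ = &uN[(size_t)c * n];
        double *pr = &prolif[(size_t)c * n];
        for (int i = 0; i < n; ++i) {
          const double d = dose_maps(i, ev_idx);
          double deff = d;
          double sf_rt = 1.0, sf_ct = 1.0, sf_p;
          if (rt_mode == 1) sf_rt = lq(aRT[c], d, aB[c]);
          else if (rt_mode == 2) {
            deff = d / oer[i];
            sf_rt = lq(aRT[c], deff, aB[c]);
          } else if (rt_mode == 3) {
            const double smin = lq(aRT[c], d, aB[c]);
            sf_rt = smin + (1.0 - smin) * (1.0 - (e[i] + nn_[i]) / cap);
          }
          if (!combined && ct_mode != 0) {
            if (ct_mode == 1) sf_ct = std::exp(-aCT[c] * d);
            else if (ct_mode == 2) sf_ct = std::exp(-aCT[c] * d / oer[i]);
            else {
              const double smin = std::exp(-aCT[c] * d);
              sf_ct = smin + (1.0 - smin) * (1.0 - (e[i] + nn_[i]) / cap);
            }
          }
          sf_p = (rt_mode == 2) ? lq(aRTp[c], deff, aB[c])
                                : lq(aRTp[c], d, aB[c]);
          const double sf = sf_rt * sf_ct;
          e[i] *= sf; nn_[i] *= sf;
          if (has_rt) pr[i] *= sf_p;
        }
      }
      ++ev_idx;
    }
    if (day >= last_day) break;

    // daily mechanics refresh and diffusion damping
    if (use_mech_any && ((day - day0) % mech_cadence == 0)) {
      // total density, row-major for the batched solves
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < P; ++c)
          dens_rm[(size_t)i * P + c] =
            uE[(size_t)c * n + i] + uN[(size_t)c * n + i];
      std::fill(rhs_rm.begin(), rhs_rm.end(), 0.0);
      spmm_rm(B, dens_rm.data(), rhs_rm.data(), P);
      // u = A^-1 b = -( -A )^-1 b: permute and negate, solve L L' y = Pb
      for (int r = 0; r < n3; ++r) {
        const double *src = &rhs_rm[(size_t)pp[r] * P];
        float *dst = &perm_rm[(size_t)r * P];
        for (int c = 0; c < P; ++c) dst[c] = (float)(-src[c]);
      }
      lsolve_rm(L.p, L.i, Lxf.data(), L.ncol, Ldiag.data(),
                perm_rm.data(), P);
      ltsolve_rm(L.p, L.i, Lxf.data(), L.ncol, Ldiag.data(),
                 perm_rm.data(), P);
      for (int r = 0; r < n3; ++r) {  // undo the permutation
        const float *src = &perm_rm[(size_t)r * P];
        double *dst = &u_rm[(size_t)pp[r] * P];
        for (int c = 0; c < P; ++c) dst[c] = (double)src[c];
      }
      std::fill(sig_rm.begin(), sig_rm.end(), 0.0);
      spmm_rm(S, u_rm.data(), sig_rm.data(), P);
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < P; ++c) {
          const double s1 = sig_rm[(size_t)i * P + c];
          const double s2 = sig_rm[(size_t)(n + i) * P + c];
          const double s3 = sig_rm[(size_t)(2 * n + i) * P + c];
          const double s4 = sig_rm[(size_t)(3 * n + i) * P + c];
          const double s5 = sig_rm[(size_t)(4 * n + i) * P + c];
          const double s6 = sig_rm[(size_t)(5 * n + i) * P + c];
          vm[(size_t)c * n + i] = std::sqrt(
            0.5 * ((s1 - s2) * (s1 - s2) + (s2 - s3) * (s2 - s3) +
                   (s3 - s1) * (s3 - s1)) +
            3.0 * (s4 * s4 + s5 * s5 + s6 * s6));
        }
      }
      for (int c = 0; c < P; ++c) {
        if (lam1[c] <= 0) continue;  // undamped column, D stays D0
        for (int i = 0; i < n; ++i) {
          const double damp = std::exp(-lam1[c] * vm[(size_t)c * n + i]);
          dE[(size_t)c * n + i] = d0e[(size_t)c * n + i] * damp;
          dN[(size_t)c * n + i] = d0n[(size_t)c * n + i] * damp;
        }
        build_T(c);
      }
    }

    // integrate one day, per column
    for (int c = 0; c < P; ++c) {
      double *e = &uE[(size_t)c * n], *nn_ = &uN[(size_t)c * n];
      const double *te = &TE[(size_t)6 * n * c], *tn = &TN[(size_t)6 * n * c];
      const double *re = &rsE[(size_t)c * n], *rn = &rsN[(size_t)c * n];
      const double *pr = &prolif[(size_t)c * n];
      const double dtc = dt[c];
      const double iTE = 1.0 / theta_e, iTN = 1.0 / theta_n;
      const double kpe = kpE[c], kpn = kpN[c];
      const double bne = bNE[c], ben = bEN[c];
      long clip = 0;
      for (int s = 0; s < steps[c]; ++s) {
        for (int i = 0; i < n; ++i) {
          const int b = 6 * i;
          const double uEi = e[i], uNi = nn_[i];
          double lapE = -re[i] * uEi, lapN = -rn[i] * uNi;
          lapE += te[b] * e[J6[b]] + te[b + 1] * e[J6[b + 1]] +
            te[b + 2] * e[J6[b + 2]] + te[b + 3] * e[J6[b + 3]] +
            te[b + 4] * e[J6[b + 4]] + te[b + 5] * e[J6[b + 5]];
          lapN += tn[b] * nn_[J6[b]] + tn[b + 1] * nn_[J6[b + 1]] +
            tn[b + 2] * nn_[J6[b + 2]] + tn[b + 3] * nn_[J6[b + 3]] +
            tn[b + 4] * nn_[J6[b + 4]] + tn[b + 5] * nn_[J6[b + 5]];
          double wE = uEi + dtc * (lapE + kpe * pr[i] * uEi *
                                   (1.0 - (uEi + bne * uNi) * iTE));
          double wN = uNi + dtc * (lapN + kpn * pr[i] * uNi *
                                   (1.0 - (uNi + ben * uEi) * iTN));
          if (wE < 0.0) { wE = 0.0; ++clip; }
          else if (wE > theta_e) { wE = theta_e; ++clip; }
          if (wN < 0.0) { wN = 0.0; ++clip; }
          else if (wN > theta_n) { wN = theta_n; ++clip; }
          scrE[i] = wE; scrN[i] = wN;
        }
        std::copy(scrE.begin(), scrE.end(), e);
        std::copy(scrN.begin(), scrN.end(), nn_);
      }
      clipped[c] += (double)clip;
      // divergence guard, named with the offending day
      double tot = 0.0;
      for (int i = 0; i < n; ++i) tot += e[i] + nn_[i];
      if (!std::isfinite(tot))
        stop("simulation diverged (non-finite density) at day %d", day + 1);
    }
  }

  return List::create(_["NE"] = outNE, _["NN"] = outNN,
                      _["clipped"] = wrap(clipped),
                      _["DE"] = wrap(dE), _["DN"] = wrap(dN),
                      _["vm"] = wrap(vm),
                      _["dt"] = wrap(dt));
}
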