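// Exact stochastic simulation (Gillespie direct method) of the CBSD
// reaction network in molecule counts.
//
// The reaction list mirrors build_reaction_network() in R, in the same
// order, so the two representations can be cross-checked reaction by
// reaction. Concentration rate laws (µM/h) are converted to
// propensities (events/h) with the system size Omega (molecules/µM):
// zeroth-order k -> k*Omega, first-order k*x -> k*count, Hill-modulated
// terms are evaluated at concentration count/Omega and scaled by Omega.
//
// R's RNG (unif_rand) is used so runs are reproducible via set.seed()
// and bit-identical to the reference R implementation of the direct
// method.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  double k0_s, ks1, J1s, n1s, kd_s, kS_tl, JS_34, nS_34, kd_S;
  double k0_3, k3, J1_3, n1_3, J2_3, n2_3, kd_3;
  double k0_z, kz, Jz, nz, kd_z, kZ_tl, JZ_200, nZ_200, kd_Z;
  double k0_2, k2, J1_2, n1_2, J2_2, n2_2, kd_2;
  double k0_T, kT, JT, nT, kd_T;
  double kE1, J1E, n1E, kE2, J2E, n2E, kd_E;
  double kN1, J1N, n1N, kN2, J2N, n2N, kd_N;
  double tgf_unit_scale;
  double ks2, J2s, n2s, k0_d, kd1, J1d, n1d, kd2, J2d, n2d, kd_dm,
      kD_tl, kd_D;
};

double getp(const NumericVector& p, const char* nm) {
  CharacterVector nms = p.names();
  for (int i = 0; i < p.size(); ++i) {
    if (std::strcmp(nms[i], nm) == 0) return p[i];
  }
  stop("parameter '%s' missing", nm);
  return NA_REAL;
}

Pars load_pars(const NumericVector& p) {
  Pars q;
#define G(f) q.f = getp(p, #f)
  G(k0_s); G(ks1); G(J1s); G(n1s); G(kd_s); G(kS_tl); G(JS_34); G(nS_34);
  G(kd_S); G(k0_3); G(k3); G(J1_3); G(n1_3); G(J2_3); G(n2_3); G(kd_3);
  G(k0_z); G(kz); G(Jz); G(nz); G(kd_z); G(kZ_tl); G(JZ_200); G(nZ_200);
  G(kd_Z); G(k0_2); G(k2); G(J1_2); G(n1_2); G(J2_2); G(n2_2); G(kd_2);
  G(k0_T); G(kT); G(JT); G(nT); G(kd_T); G(kE1); G(J1E); G(n1E); G(kE2);
  G(J2E); G(n2E); G(kd_E); G(kN1); G(J1N); G(n1N); G(kN2); G(J2N); G(n2N);
  G(kd_N); G(tgf_unit_scale); G(ks2); G(J2s); G(n2s); G(k0_d); G(kd1);
  G(J1d); G(n1d); G(kd2); G(J2d); G(n2d); G(kd_dm); G(kD_tl); G(kd_D);
#undef G
  return q;
}

inline double ha(double x, double J, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x / J, n);
  return xn / (1.0 + xn);
}
inline double hr(double x, double J, double n) {
  if (x <= 0.0) return 1.0;
  return 1.0 / (1.0 + std::pow(x / J, n));
}
inline double hr2(double x1, double J1, double n1, double x2, double J2,
                  double n2) {
  double a = x1 > 0 ? std::pow(x1 / J1, n1) : 0.0;
  double b = x2 > 0 ? std::pow(x2 / J2, n2) : 0.0;
  return 1.0 / (1.0 + a + b);
}

// species indices (canonical order of cbsd_species())
enum { iS_m = 0, iS = 1, iR3 = 2, iZ_m = 3, iZ = 4, iR2 = 5, iE = 6,
       iN = 7, iT = 8, iD_m = 9, iD = 10 };
const int NSPEC = 11;
const int NREAC = 32;

// single-reaction propensity, in the order of
// build_reaction_network(); counts are molecule numbers, result events/h
double prop_one(int r, const Pars& q, double kdfac, double tgf_ex,
                const double* n, double omega) {
  const double S = n[iS] / omega, R3 = n[iR3] / omega, Z = n[iZ] / omega,
               R2 = n[iR2] / omega, Tt = n[iT] / omega + tgf_ex,
               D = n[iD] / omega;
  switch (r) {
    case 0: return q.k0_s * omega;
    case 1: return q.ks1 * ha(Tt, q.J1s, q.n1s) * omega;
    case 2: return q.ks2 * ha(D, q.J2s, q.n2s) * omega;
    case 3: return q.kd_s * n[iS_m];
    case 4: return q.kS_tl * n[iS_m] * hr(R3, q.JS_34, q.nS_34);
    case 5: return q.kd_S * n[iS];
    case 6: return q.k0_3 * omega;
    case 7: return q.k3 * hr2(S, q.J1_3, q.n1_3, Z, q.J2_3, q.n2_3) * omega;
    case 8: return q.kd_3 * n[iR3];
    case 9: return q.k0_z * omega;
    case 10: return q.kz * ha(S, q.Jz, q.nz) * omega;
    case 11: return q.kd_z * n[iZ_m];
    case 12: return q.kZ_tl * n[iZ_m] * hr(R2, q.JZ_200, q.nZ_200);
    case 13: return q.kd_Z * n[iZ];
    case 14: return q.k0_2 * omega;
    case 15: return q.k2 * hr2(S, q.J1_2, q.n1_2, Z, q.J2_2, q.n2_2) * omega;
    case 16: return q.kd_2 * n[iR2];
    case 17: return q.kE1 * hr(S, q.J1E, q.n1E) * omega;
    case 18: return q.kE2 * hr(Z, q.J2E, q.n2E) * omega;
    case 19: return q.kd_E * n[iE];
    case 20: return q.kN1 * ha(S, q.J1N, q.n1N) * omega;
    case 21: return q.kN2 * ha(Z, q.J2N, q.n2N) * omega;
    case 22: return q.kd_N * n[iN];
    case 23: return q.k0_T * omega;
    case 24: return q.kT * hr(R2, q.JT, q.nT) * omega;
    case 25: return q.kd_T * n[iT];
    case 26: return kdfac * q.k0_d * omega;
    case 27: return kdfac * q.kd1 * ha(Tt, q.J1d, q.n1d) * omega;
    case 28: return kdfac * q.kd2 * ha(Z, q.J2d, q.n2d) * omega;
    case 29: return q.kd_dm * n[iD_m];
    case 30: return q.kD_tl * n[iD_m];
    case 31: return q.kd_D * n[iD];
  }
  return 0.0;
}

void propensities(const Pars& q, double kdfac, double tgf_ex,
                  const double* n, double omega, double* a) {
  for (int r = 0; r < NREAC; ++r) a[r] = prop_one(r, q, kdfac, tgf_ex, n, omega);
}

// species changed (+1 on production, -1 on degradation) per reaction
const int r_spec[NREAC] = {iS_m, iS_m, iS_m, iS_m, iS, iS, iR3, iR3, iR3,
                           iZ_m, iZ_m, iZ_m, iZ, iZ, iR2, iR2, iR2, iE,
                           iE, iE, iN, iN, iN, iT, iT, iT, iD_m, iD_m,
                           iD_m, iD_m, iD, iD};
const int r_sign[NREAC] = {1, 1, 1, -1, 1, -1, 1, 1, -1, 1, 1, -1, 1, -1,
                           1, 1, -1, 1, 1, -1, 1, 1, -1, 1, 1, -1, 1, 1,
                           1, -1, 1, -1};

}  // namespace

//' @rdname ssa_run
//' @keywords internal
// [[Rcpp::export(name = ".ssa_propensities_cpp")]]
NumericVector ssa_propensities_cpp(NumericVector params, double tgf0,
                                   bool knockdown, double k_knockdown,
                                   NumericVector counts, double omega) {
  Pars q = load_pars(params);
  double kdfac = knockdown ? 1.0 - k_knockdown : 1.0;
  double tgf_ex = q.tgf_unit_scale * tgf0;
  std::vector<double> n(NSPEC);
  for (int i = 0; i < NSPEC; ++i) n[i] = counts[i];
  NumericVector a(NREAC);
  propensities(q, kdfac, tgf_ex, n.data(), omega, &a[0]);
  return a;
}

//' @rdname ssa_run
//' @keywords internal
// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(NumericVector params, double tgf0, bool knockdown,
                 double k_knockdown, NumericVector counts0, double omega,
                 NumericVector t_grid) {
  Pars q = load_pars(params);
  double kdfac = knockdown ? 1.0 - k_knockdown : 1.0;
  double tgf_ex = q.tgf_unit_scale * tgf0;
  int ng = t_grid.size();
  NumericMatrix out(ng, NSPEC);
  std::vector<double> n(NSPEC);
  for (int i = 0; i < NSPEC; ++i) n[i] = std::floor(counts0[i] + 0.5);
  double a[NREAC];
  double t = t_grid[0];
  int gi = 0;
  bool absorbed = false;
  long long nevents = 0;
  // reactions whose propensity depends on each species (dependency
  // graph of the direct method; only these are re-evaluated after an
  // event changes one species)
  static const std::vector<int> dep[NSPEC] = {
      {3, 4}, {5, 7, 10, 15, 17, 20}, {4, 8}, {11, 12},
      {7, 13, 15, 18, 21, 28}, {12, 16, 24}, {19}, {22},
      {1, 25, 27}, {29, 30}, {2, 31}};
  RNGScope scope;
  propensities(q, kdfac, tgf_ex, n.data(), omega, a);
  double a0 = 0.0;
  for (int r = 0; r < NREAC; ++r) a0 += a[r];
  while (gi < ng) {
    if ((nevents & 0xFFFF) == 0) {  // periodic full refresh vs FP drift
      propensities(q, kdfac, tgf_ex, n.data(), omega, a);
      a0 = 0.0;
      for (int r = 0; r < NREAC; ++r) a0 += a[r];
    }
    double tnext;
    if (a0 <= 0.0) {
      absorbed = true;
      tnext = R_PosInf;
    } else {
      tnext = t + ::Rf_rexp(1.0 / a0);
    }
    while (gi < ng && t_grid[gi] <= tnext) {
      for (int i = 0; i < NSPEC; ++i) out(gi, i) = n[i];
      ++gi;
    }
    if (gi >= ng || absorbed) break;
    double u = ::unif_rand() * a0;
    int r = 0;
    double acc = a[0];
    while (acc < u && r < NREAC - 1) acc += a[++r];
    int sp = r_spec[r];
    n[sp] += r_sign[r];
    if (n[sp] < 0) n[sp] = 0;
    // delta-update the propensities touched by this species change
    for (int di : dep[sp]) {
      double anew = prop_one(di, q, kdfac, tgf_ex, n.data(), omega);
      a0 += anew - a[di];
      a[di] = anew;
    }
    t = tnext;
    ++nevents;
    if ((nevents & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (absorbed) {
    for (; gi < ng; ++gi)
      for (int i = 0; i < NSPEC; ++i) out(gi, i) = n[i];
  }
  return List::create(_["state"] = out, _["absorbed"] = absorbed,
                      _["n_events"] = (double)nevents);
}
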