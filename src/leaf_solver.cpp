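// Coupled biochemical photosynthesis / stomatal conductance leaf solver.
//
// For each environment the net assimilation rate A is found as the root of
// a monotone residual: given a trial A, the stomatal submodel and the CO2
// diffusion chain determine the CO2 level at the carboxylation sites, whose
// biochemical rate must equal the trial value.  Each limitation branch
// (Rubisco / electron transport) is solved to consistency by guarded
// bisection and the lower A is returned, following the minimum rule.

#include <Rcpp.h>
using namespace Rcpp;

static const double RGAS = 8.314;
static const double BIG = 1e8;

struct Pars {
  int family; // 0 = C3, 1 = C4 / CCM
  double phi2LL, r2_1, theta, f_cyc, f_pseudo, f_Q, h, alpha_bs, x_atp,
      phi_ccm;
  double T_opt, Omega, gamma_star25, K_mC25, K_mO25;
  double chi_Vcmax25, chi_Jmax25, chi_epsp25, chi_Rd25, Rm_factor;
  double g0, a1, b1, chi_gm25, chi_gbs25, u_oc25;
  double E_gamma_star, E_Vcmax, E_KmC, E_KmO, E_Rd;
  double E_Jmax, D_Jmax, S_Jmax, E_epsp, D_epsp, S_epsp;
  double E_gm, D_gm, S_gm, E_gbs, D_gbs, S_gbs, E_uoc;
  bool cs_star_alt;
};

// operative values at one leaf temperature / nitrogen level
struct LeafT {
  double Vcmax, Jmax, Rd, Rm, KmC, KmO, gstar, gm, gbs, epsp, uoc;
  double J2, fv, g0s, z;
};

struct State {
  double gs, Ci, Cc, Cs, O_umol, Vp, L;
};

static double num(const List& par, const char* nm) {
  return as<double>(par[nm]);
}

static Pars unpack(const List& par) {
  Pars p;
  std::string fam = as<std::string>(par["model_family"]);
  p.family = (fam == "C3") ? 0 : 1;
  p.phi2LL = num(par, "phi2LL");
  p.r2_1 = num(par, "r2_1");
  p.theta = num(par, "theta");
  p.f_cyc = num(par, "f_cyc");
  p.f_pseudo = num(par, "f_pseudo");
  p.f_Q = num(par, "f_Q");
  p.h = num(par, "h");
  p.alpha_bs = num(par, "alpha_bs");
  p.x_atp = num(par, "x_atp");
  p.phi_ccm = num(par, "phi_ccm");
  p.T_opt = num(par, "T_opt");
  p.Omega = num(par, "Omega");
  p.gamma_star25 = num(par, "gamma_star25");
  p.K_mC25 = num(par, "K_mC25");
  p.K_mO25 = num(par, "K_mO25");
  p.chi_Vcmax25 = num(par, "chi_Vcmax25");
  p.chi_Jmax25 = num(par, "chi_Jmax25");
  p.chi_epsp25 = num(par, "chi_epsp25");
  p.chi_Rd25 = num(par, "chi_Rd25");
  p.Rm_factor = num(par, "Rm_factor");
  p.g0 = num(par, "g0");
  p.a1 = num(par, "a1");
  p.b1 = num(par, "b1");
  p.chi_gm25 = num(par, "chi_gm25");
  p.chi_gbs25 = num(par, "chi_gbs25");
  p.u_oc25 = num(par, "u_oc25");
  p.E_gamma_star = num(par, "E_gamma_star");
  p.E_Vcmax = num(par, "E_Vcmax");
  p.E_KmC = num(par, "E_KmC");
  p.E_KmO = num(par, "E_KmO");
  p.E_Rd = num(par, "E_Rd");
  p.E_Jmax = num(par, "E_Jmax");
  p.D_Jmax = num(par, "D_Jmax");
  p.S_Jmax = num(par, "S_Jmax");
  p.E_epsp = num(par, "E_epsp");
  p.D_epsp = num(par, "D_epsp");
  p.S_epsp = num(par, "S_epsp");
  p.E_gm = num(par, "E_gm");
  p.D_gm = num(par, "D_gm");
  p.S_gm = num(par, "S_gm");
  p.E_gbs = num(par, "E_gbs");
  p.D_gbs = num(par, "D_gbs");
  p.S_gbs = num(par, "S_gbs");
  p.E_uoc = num(par, "E_uoc");
  p.cs_star_alt = as<bool>(par["cs_star_alt"]);
  return p;
}

static double arrh(double p25, double E, double Tl) {
  return p25 * std::exp((1.0 / 298.0 - 1.0 / (273.0 + Tl)) * E / RGAS);
}

static double stable_log1pexp(double x) {
  return (x > 35.0) ? x : std::log1p(std::exp(x));
}

static double parrh(double p25, double E, double D, double S, double Tl) {
  double a = (S - D / 298.0) / RGAS;
  double b = (S - D / (273.0 + Tl)) / RGAS;
  return arrh(p25, E, Tl) * std::exp(stable_log1pexp(a) - stable_log1pexp(b));
}

static LeafT leaf_at_T(const Pars& p, double Tl, double np, double I_abs,
                       double VPD, double g0_scale) {
  LeafT t;
  t.Vcmax = arrh(p.chi_Vcmax25 * np, p.E_Vcmax, Tl);
  t.Jmax = parrh(p.chi_Jmax25 * np, p.E_Jmax, p.D_Jmax, p.S_Jmax, Tl);
  t.Rd = arrh(p.chi_Rd25 * np, p.E_Rd, Tl);
  t.KmC = arrh(p.K_mC25, p.E_KmC, Tl);
  t.KmO = arrh(p.K_mO25, p.E_KmO, Tl);
  t.gstar = arrh(p.gamma_star25, p.E_gamma_star, Tl);
  if (p.family == 0) {
    t.gm = parrh(p.chi_gm25 * np, p.E_gm, p.D_gm, p.S_gm, Tl);
    t.Rm = 0.0;
    t.gbs = t.epsp = t.uoc = t.z = 0.0;
  } else {
    t.gm = 0.0;
    t.Rm = p.Rm_factor * t.Rd;
    t.gbs = parrh(p.chi_gbs25 * np, p.E_gbs, p.D_gbs, p.S_gbs, Tl);
    t.epsp = parrh(p.chi_epsp25 * np, p.E_epsp, p.D_epsp, p.S_epsp, Tl);
    t.uoc = arrh(p.u_oc25, p.E_uoc, Tl);
    t.z = (2.0 + p.f_Q - p.f_cyc) / (p.h * (1.0 - p.f_cyc));
  }
  double d = (Tl - p.T_opt) / p.Omega;
  double phi2 = p.phi2LL * std::exp(-d * d);
  double a2 = phi2 * (1.0 - p.f_cyc) / (1.0 - p.f_cyc + p.r2_1);
  double ai = a2 * I_abs;
  if (p.theta < 1e-12) {
    t.J2 = (ai + t.Jmax > 0) ? ai * t.Jmax / (ai + t.Jmax) : 0.0;
  } else {
    double s = ai + t.Jmax;
    double disc = s * s - 4.0 * p.theta * t.Jmax * ai;
    if (disc < 0) disc = 0;
    t.J2 = (s - std::sqrt(disc)) / (2.0 * p.theta);
  }
  double r = p.a1 - p.b1 * VPD;
  if (r < 0.01) r = 0.01;
  t.fv = 1.0 / (1.0 / r - 1.0);
  t.g0s = p.g0 * g0_scale;
  return t;
}

// ---- C3 residual: A - A_biochem(A) for one limitation branch -------------

static double resid_c3(double A, double x1, double x2, double GammaStar,
                       double Ci_star, const LeafT& t, double Ca, double gb,
                       double gs_fix, bool use_gs_fix, State* st) {
  double gs, Ci;
  double ApR = A + t.Rd;
  if (use_gs_fix) {
    gs = gs_fix;
    Ci = Ca - A * (1.0 / gb + 1.0 / gs);
  } else if (std::fabs(ApR) < 1e-13) {
    gs = t.g0s;
    Ci = Ca - A * (1.0 / gb + 1.0 / gs);
  } else {
    // combine the stomatal submodel with the supply function: quadratic in
    // u = Ci - Ci_star
    double w = Ci_star - Ca + A / gb;
    double aq = t.g0s, bq = ApR * t.fv + t.g0s * w + A, cq = ApR * t.fv * w;
    double u;
    if (aq < 1e-12) {
      if (std::fabs(bq) < 1e-14) return (ApR > 0) ? BIG : -BIG;
      u = -cq / bq;
    } else {
      double disc = bq * bq - 4.0 * aq * cq;
      if (disc < 0) return (ApR > 0) ? BIG : -BIG;
      u = (-bq + std::sqrt(disc)) / (2.0 * aq);
    }
    if (u <= 0) return (ApR > 0) ? BIG : -BIG;
    gs = t.g0s + ApR * t.fv / u;
    if (gs <= 1e-7) return -BIG;
    Ci = Ci_star + u;
  }
  double Cc = Ci - A / t.gm;
  if (Cc <= 1e-9 || Ci <= 0) return BIG;
  double Ab = (Cc - GammaStar) * x1 / (Cc + x2) - t.Rd;
  if (st) {
    st->gs = gs;
    st->Ci = Ci;
    st->Cc = Cc;
    st->Cs = Ca - A / gb;
    st->O_umol = NA_REAL;
    st->Vp = NA_REAL;
    st->L = NA_REAL;
  }
  return A - Ab;
}

// ---- C4/CCM residual ------------------------------------------------------

static double resid_c4(double A, int branch, double x1j, double Vp_e,
                       double Cs_star, const Pars& p, const LeafT& t,
                       double Ca, double gb, double Oi_umol, double gs_fix,
                       bool use_gs_fix, State* st) {
  double Cs = Ca - A / gb;
  double gs;
  double ApR = A + t.Rd;
  if (use_gs_fix) {
    gs = gs_fix;
  } else if (std::fabs(ApR) < 1e-13) {
    gs = t.g0s;
  } else {
    double den = Cs - Cs_star;
    if (den <= 1e-9) return BIG;
    gs = t.g0s + ApR * t.fv / den;
    if (gs <= 1e-7) return -BIG;
  }
  double Ci = Cs - A / gs;
  if (Ci <= 0) return BIG;
  double O_umol = p.alpha_bs * A / (t.uoc * t.gbs) + Oi_umol;
  if (O_umol < 1.0) O_umol = 1.0;
  double Vp_enz = t.epsp * Ci;
  double a, b;
  if (Vp_enz <= Vp_e) {
    a = 1.0 + t.epsp / t.gbs;
    b = 0.0;
  } else {
    a = 1.0;
    b = Vp_e;
  }
  double Cc = a * Ci + (b - A - t.Rm) / t.gbs;
  if (Cc <= 1e-9) return BIG;
  double Ab;
  if (branch == 0) {
    Ab = (Cc - t.gstar * O_umol) * t.Vcmax /
             (Cc + t.KmC * (O_umol / 1000.0) / t.KmO + t.KmC) -
         t.Rd;
  } else {
    Ab = (Cc - t.gstar * O_umol) * x1j / (Cc + 2.0 * t.gstar * O_umol) - t.Rd;
  }
  if (st) {
    st->gs = gs;
    st->Ci = Ci;
    st->Cc = Cc;
    st->Cs = Cs;
    st->O_umol = O_umol;
    st->Vp = std::min(Vp_enz, Vp_e);
    st->L = t.gbs * (Cc - Ci);
  }
  return A - Ab;
}

// Bisection on a monotone-increasing residual; res(lo) <= 0 <= res(hi)
// is established by the callers' bracket choices and the signed guards.
template <typename F>
static double bisect(F f, double lo, double hi) {
  double rl = f(lo);
  if (rl >= 0) return lo;
  double rh = f(hi);
  int guard = 0;
  while (rh < 0 && guard++ < 8) {
    hi = hi * 2.0 + 5.0;
    rh = f(hi);
  }
  for (int it = 0; it < 80; ++it) {
    double mid = 0.5 * (lo + hi);
    double rm = f(mid);
    if (rm < 0)
      lo = mid;
    else
      hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
List leaf_solve_cpp(List par, NumericVector I_abs, NumericVector Ca,
                    NumericVector Oi_mmol, NumericVector Tl,
                    NumericVector VPD, NumericVector gb, NumericVector np,
                    NumericVector g0_scale,
                    Nullable<NumericVector> gs_fixed = R_NilValue) {
  Pars p = unpack(par);
  int n = I_abs.size();
  bool use_fix = gs_fixed.isNotNull();
  NumericVector gsf;
  if (use_fix) gsf = gs_fixed.get();
  NumericVector A(n), gs(n), Ci(n), Cc(n), Cs(n), Obs(n), Vp(n), L(n), J2(n),
      Rd(n);
  IntegerVector lim(n);

  for (int i = 0; i < n; ++i) {
    LeafT t = leaf_at_T(p, Tl[i], np[i] > 0 ? np[i] : 0.0, I_abs[i], VPD[i],
                        g0_scale[i]);
    double Oi_umol = Oi_mmol[i] * 1000.0;
    Rd[i] = t.Rd;
    J2[i] = t.J2;
    if (np[i] <= 0) { // no photosynthetic machinery
      A[i] = -t.Rd;
      gs[i] = use_fix ? gsf[i] : t.g0s;
      Ci[i] = Cc[i] = Cs[i] = Ca[i];
      Obs[i] = Oi_mmol[i];
      Vp[i] = L[i] = NA_REAL;
      lim[i] = NA_INTEGER;
      continue;
    }
    double gfx = use_fix ? gsf[i] : 0.0;
    double Abest = 0, A0, A1;
    State sb;
    int limi = NA_INTEGER;
    if (p.family == 0) {
      if (t.gm <= 1e-12)
        stop("mesophyll conductance is zero at positive leaf nitrogen");
      double GammaStar = t.gstar * Oi_umol;
      double Ci_star = GammaStar - t.Rd / t.gm;
      double x1c = t.Vcmax;
      double x2c = t.KmC * (1.0 + Oi_mmol[i] / t.KmO);
      double x1j = (1.0 - p.f_pseudo / (1.0 - p.f_cyc)) * t.J2 / 4.0;
      double x2j = 2.0 * Oi_umol * t.gstar;
      auto fc = [&](double A_) {
        return resid_c3(A_, x1c, x2c, GammaStar, Ci_star, t, Ca[i], gb[i],
                        gfx, use_fix, nullptr);
      };
      auto fj = [&](double A_) {
        return resid_c3(A_, x1j, x2j, GammaStar, Ci_star, t, Ca[i], gb[i],
                        gfx, use_fix, nullptr);
      };
      double loc = -t.Rd - GammaStar * x1c / std::max(x2c, 1e-9) - 1.0;
      double loj = -t.Rd - 0.5 * x1j - 1.0;
      A0 = (x1c > 0) ? bisect(fc, loc, t.Vcmax - t.Rd) : -t.Rd;
      A1 = (x1j > 0) ? bisect(fj, loj, x1j - t.Rd) : -t.Rd;
      if (A0 <= A1) {
        Abest = A0;
        limi = 1;
        resid_c3(Abest, x1c, x2c, GammaStar, Ci_star, t, Ca[i], gb[i], gfx,
                 use_fix, &sb);
      } else {
        Abest = A1;
        limi = 2;
        resid_c3(Abest, x1j, x2j, GammaStar, Ci_star, t, Ca[i], gb[i], gfx,
                 use_fix, &sb);
      }
    } else {
      if (t.gbs <= 1e-12 || t.uoc <= 1e-12)
        stop("bundle-sheath parameters are zero at positive leaf nitrogen");
      double Vp_e =
          (p.phi_ccm > 0) ? p.x_atp * t.J2 * t.z / p.phi_ccm : BIG;
      double csnum;
      if (p.cs_star_alt) {
        csnum = t.gbs * t.gstar * Oi_umol -
                (1.0 + t.gstar * p.alpha_bs / t.uoc) * (t.Rd - t.Rm);
      } else {
        csnum = t.gbs * t.gstar * Oi_umol -
                (1.0 + t.gstar * p.alpha_bs / t.uoc) * t.Rd + t.Rm;
      }
      double Cs_star = csnum / (t.gbs + t.epsp);
      double x1j = (1.0 - p.f_pseudo / (1.0 - p.f_cyc)) * t.J2 / 4.0;
      auto fe = [&](double A_) {
        return resid_c4(A_, 0, x1j, Vp_e, Cs_star, p, t, Ca[i], gb[i],
                        Oi_umol, gfx, use_fix, nullptr);
      };
      auto fj = [&](double A_) {
        return resid_c4(A_, 1, x1j, Vp_e, Cs_star, p, t, Ca[i], gb[i],
                        Oi_umol, gfx, use_fix, nullptr);
      };
      double x2e = t.KmC * (Oi_mmol[i] / t.KmO) + t.KmC;
      double loe = -t.Rd - 2.0 * t.gstar * Oi_umol * t.Vcmax /
                       std::max(x2e, 1e-9) - 2.0;
      double loj = -t.Rd - 0.5 * x1j - 2.0;
      A0 = (t.Vcmax > 0) ? bisect(fe, loe, t.Vcmax - t.Rd) : -t.Rd;
      A1 = (x1j > 0) ? bisect(fj, loj, x1j - t.Rd) : -t.Rd;
      if (A0 <= A1) {
        Abest = A0;
        limi = 1;
        resid_c4(Abest, 0, x1j, Vp_e, Cs_star, p, t, Ca[i], gb[i], Oi_umol,
                 gfx, use_fix, &sb);
      } else {
        Abest = A1;
        limi = 2;
        resid_c4(Abest, 1, x1j, Vp_e, Cs_star, p, t, Ca[i], gb[i], Oi_umol,
                 gfx, use_fix, &sb);
      }
    }
    A[i] = Abest;
    gs[i] = sb.gs;
    Ci[i] = sb.Ci;
    Cc[i] = sb.Cc;
    Cs[i] = sb.Cs;
    Obs[i] = (p.family == 0) ? Oi_mmol[i] : sb.O_umol / 1000.0;
    Vp[i] = sb.Vp;
    L[i] = sb.L;
    lim[i] = limi;
  }
  return List::create(
      _["A"] = A, _["gs"] = gs, _["Ci"] = Ci, _["Cc"] = Cc, _["Cs"] = Cs,
      _["O_bs"] = Obs, _["Vp"] = Vp, _["L"] = L, _["J2"] = J2, _["Rd"] = Rd,
      _["limitation"] = lim);
}
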