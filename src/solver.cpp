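// Nonlinear 1D blood-flow solver on a bifurcating network.
//
// Conservative variables (A, Q) per axial node, tube law
// P = Pd + (beta/Ad)(sqrt(A) - sqrt(Ad)), advanced with the two-step
// Richtmyer Lax-Wendroff scheme (2nd order). Boundaries are handled with
// Riemann invariants W_{f,b} = u +/- 4c: prescribed inflow with an
// absorbed outgoing characteristic at the root, Newton-coupled junctions
// conserving mass and total pressure, and implicit three-element
// Windkessel outlets.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Segment {
  int n;                 // nodes
  double dx;
  std::vector<double> Ad, beta, b;   // b = beta/Ad
  std::vector<double> A, Q;
  std::vector<double> Am, Qm;        // midpoint (half-step) states
  std::vector<double> hcorr, fcorr;  // well-balancing source corrections
  std::vector<double> gb, gsAd, gcd;  // d/dx of b, sqrt(Ad), c_d at nodes
  int parent;                        // segment index, -1 for root
  std::vector<int> children;
  int terminal;                      // index into wk arrays, -1 if none
};

static inline double wavec(double A, double b, double rho) {
  return std::sqrt(b / (2.0 * rho)) * std::sqrt(std::sqrt(A));
}
static inline double ptube(double A, double Ad, double b, double Pd) {
  return Pd + b * (std::sqrt(A) - std::sqrt(Ad));
}

// small dense linear solve (Gaussian elimination, partial pivoting)
static bool lin_solve(double* M, double* r, int n) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double mx = std::fabs(M[k * n + k]);
    for (int i = k + 1; i < n; ++i)
      if (std::fabs(M[i * n + k]) > mx) { mx = std::fabs(M[i * n + k]); piv = i; }
    if (mx < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(M[k * n + j], M[piv * n + j]);
      std::swap(r[k], r[piv]);
    }
    for (int i = k + 1; i < n; ++i) {
      double f = M[i * n + k] / M[k * n + k];
      for (int j = k; j < n; ++j) M[i * n + j] -= f * M[k * n + j];
      r[i] -= f * r[k];
    }
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = r[i];
    for (int j = i + 1; j < n; ++j) s -= M[i * n + j] * r[j];
    r[i] = s / M[i * n + i];
  }
  return true;
}

// [[Rcpp::export]]
List solve_1d_cpp(List segments, IntegerVector parent_idx, List children_idx,
                  IntegerVector terminal_of, NumericMatrix wk,
                  NumericVector inflow_vals, double inflow_t0,
                  double period, double rho, double mu, double zeta,
                  double Pd, double dt, int min_cycles, int max_cycles,
                  double tol_periodicity, IntegerMatrix planes,
                  int monitor_plane) {
  const int ns = segments.size();
  std::vector<Segment> seg(ns);
  for (int s = 0; s < ns; ++s) {
    List L = segments[s];
    Segment& S = seg[s];
    S.n = as<int>(L["n"]);
    S.dx = as<double>(L["dx"]);
    NumericVector Ad = L["Ad"], beta = L["beta"];
    S.Ad.assign(Ad.begin(), Ad.end());
    S.beta.assign(beta.begin(), beta.end());
    S.b.resize(S.n);
    for (int i = 0; i < S.n; ++i) S.b[i] = S.beta[i] / S.Ad[i];
    S.A = S.Ad;                      // start at diastolic area, zero flow
    S.Q.assign(S.n, 0.0);
    S.Am.assign(S.n - 1, 0.0);
    S.Qm.assign(S.n - 1, 0.0);
    S.parent = parent_idx[s];
    IntegerVector ch = children_idx[s];
    S.children.assign(ch.begin(), ch.end());
    S.terminal = terminal_of[s];
  }

  const double fcoef = 2.0 * (zeta + 2.0) * M_PI * mu / rho; // friction

  for (int s = 0; s < ns; ++s) {
    Segment& S = seg[s];
    S.gb.assign(S.n, 0.0);
    S.gsAd.assign(S.n, 0.0);
    S.gcd.assign(S.n, 0.0);
    auto der = [&](std::vector<double> f, int i) {
      int n = S.n;
      if (i == 0)
        return (-3.0 * f[0] + 4.0 * f[1] - f[2]) / (2.0 * S.dx);
      if (i == n - 1)
        return (3.0 * f[n - 1] - 4.0 * f[n - 2] + f[n - 3]) / (2.0 * S.dx);
      return (f[i + 1] - f[i - 1]) / (2.0 * S.dx);
    };
    std::vector<double> sAd(S.n), cdv(S.n);
    for (int i = 0; i < S.n; ++i) {
      sAd[i] = std::sqrt(S.Ad[i]);
      cdv[i] = wavec(S.Ad[i], S.b[i], rho);
    }
    for (int i = 0; i < S.n; ++i) {
      S.gb[i] = der(S.b, i);
      S.gsAd[i] = der(sAd, i);
      S.gcd[i] = der(cdv, i);
    }
  }

  // geometry source at midpoint i of segment S for state (A, Q)
  auto srcm = [&](const Segment& S, int i, double A, double Q) {
    double Adm = 0.5 * (S.Ad[i] + S.Ad[i + 1]);
    double bm = 0.5 * (S.b[i] + S.b[i + 1]);
    double dbdx = (S.b[i + 1] - S.b[i]) / S.dx;
    double dAddx = (S.Ad[i + 1] - S.Ad[i]) / S.dx;
    return -fcoef * Q / A +
      (dbdx / rho) * (A * std::sqrt(Adm) - (2.0 / 3.0) * (A * std::sqrt(A))) +
      (A * bm / (2.0 * rho * std::sqrt(Adm))) * dAddx;
  };
  // well-balancing corrections: make the diastolic rest state (A = Ad,
  // Q = 0) an exact discrete equilibrium of both scheme stages, so tapered
  // segments neither drift at rest nor bias the cycle-mean flux
  for (int s = 0; s < ns; ++s) {
    Segment& S = seg[s];
    S.hcorr.assign(S.n - 1, 0.0);
    S.fcorr.assign(S.n, 0.0);
    auto F2n = [&](int i, double A) {
      return S.b[i] * (A * std::sqrt(A)) / (3.0 * rho);
    };
    for (int i = 0; i < S.n - 1; ++i) {
      double Adm = 0.5 * (S.Ad[i] + S.Ad[i + 1]);
      S.hcorr[i] = (F2n(i + 1, S.Ad[i + 1]) - F2n(i, S.Ad[i])) / S.dx -
        srcm(S, i, Adm, 0.0);
    }
    for (int i = 1; i < S.n - 1; ++i) {
      double AdmL = 0.5 * (S.Ad[i - 1] + S.Ad[i]);
      double AdmR = 0.5 * (S.Ad[i] + S.Ad[i + 1]);
      double bmL = 0.5 * (S.b[i - 1] + S.b[i]);
      double bmR = 0.5 * (S.b[i] + S.b[i + 1]);
      double F2L = bmL * (AdmL * std::sqrt(AdmL)) / (3.0 * rho);
      double F2R = bmR * (AdmR * std::sqrt(AdmR)) / (3.0 * rho);
      S.fcorr[i] = (F2R - F2L) / S.dx -
        0.5 * (srcm(S, i - 1, AdmL, 0.0) + srcm(S, i, AdmR, 0.0));
    }
  }
  int root = -1;
  for (int s = 0; s < ns; ++s) if (seg[s].parent < 0) root = s;

  const int nwk = wk.nrow();
  std::vector<double> Pc(nwk, Pd);   // compliance-node pressures

  const int ntab = inflow_vals.size();
  const double dtab = period / ntab;
  auto qin_at = [&](double t) {
    double z = (t - inflow_t0) / period;
    double tau = (z - std::floor(z)) * period;
    double x = tau / dtab;
    int i = (int)std::floor(x);
    double w = x - i;
    int i1 = (i + 1) % ntab;
    return inflow_vals[i % ntab] * (1.0 - w) + inflow_vals[i1] * w;
  };

  const int steps_per_cycle = (int)std::llround(period / dt);
  const double dt_eff = period / steps_per_cycle;

  const int np = planes.nrow();
  // per-plane traces for the running cycle
  std::vector<std::vector<double>> trP(np), trQ(np), trA(np);
  for (int p = 0; p < np; ++p) {
    trP[p].assign(steps_per_cycle, 0.0);
    trQ[p].assign(steps_per_cycle, 0.0);
    trA[p].assign(steps_per_cycle, 0.0);
  }
  std::vector<double> mon_prev(steps_per_cycle, 0.0);
  std::vector<double> conv;            // per-cycle periodicity metric
  double max_junc_residual = 0.0;
  double peak_inflow = 0.0;
  for (int i = 0; i < ntab; ++i)
    peak_inflow = std::max(peak_inflow, std::fabs(inflow_vals[i]));

  double vol_in = 0.0;
  std::vector<double> vol_out(nwk, 0.0);
  std::vector<std::vector<double>> A_cycle_start(ns);
  std::vector<std::vector<double>> Anew(ns), Qnew(ns);
  for (int s = 0; s < ns; ++s) { Anew[s] = seg[s].A; Qnew[s] = seg[s].Q; }

  double t = 0.0;
  int cycle = 0;
  bool converged = false;
  std::string errmsg = "";

  for (cycle = 0; cycle < max_cycles && !converged; ++cycle) {
    vol_in = 0.0;
    std::fill(vol_out.begin(), vol_out.end(), 0.0);
    for (int s = 0; s < ns; ++s) A_cycle_start[s] = seg[s].A;

    for (int k = 0; k < steps_per_cycle; ++k) {
      const double tn1 = t + dt_eff;

      // ---- CFL / positivity guard ----
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        for (int i = 0; i < S.n; ++i) {
          if (!(S.A[i] > 0.0)) { errmsg = "negative area"; goto failed; }
          double u = S.Q[i] / S.A[i];
          double c = wavec(S.A[i], S.b[i], rho);
          if ((std::fabs(u) + c) * dt_eff > S.dx) {
            errmsg = "CFL violation"; goto failed;
          }
        }
      }

      // ---- half step: midpoint states ----
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        for (int i = 0; i < S.n - 1; ++i) {
          double A0 = S.A[i], A1 = S.A[i + 1], Q0 = S.Q[i], Q1 = S.Q[i + 1];
          double F20 = Q0 * Q0 / A0 +
            S.b[i] * (A0 * std::sqrt(A0)) / (3.0 * rho);
          double F21 = Q1 * Q1 / A1 +
            S.b[i + 1] * (A1 * std::sqrt(A1)) / (3.0 * rho);
          double Aa = 0.5 * (A0 + A1), Qa = 0.5 * (Q0 + Q1);
          double src = srcm(S, i, Aa, Qa) + S.hcorr[i];
          S.Am[i] = Aa - 0.5 * dt_eff / S.dx * (Q1 - Q0);
          S.Qm[i] = Qa - 0.5 * dt_eff / S.dx * (F21 - F20) +
            0.5 * dt_eff * src;
          if (!(S.Am[i] > 0.0)) { errmsg = "negative area"; goto failed; }
        }
      }

      // ---- full step: interior nodes ----
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        Anew[s] = S.A; Qnew[s] = S.Q;
        for (int i = 1; i < S.n - 1; ++i) {
          double AdmL = 0.5 * (S.Ad[i - 1] + S.Ad[i]);
          double AdmR = 0.5 * (S.Ad[i] + S.Ad[i + 1]);
          double bmL = 0.5 * (S.b[i - 1] + S.b[i]);
          double bmR = 0.5 * (S.b[i] + S.b[i + 1]);
          double F2L = S.Qm[i - 1] * S.Qm[i - 1] / S.Am[i - 1] +
            bmL * (S.Am[i - 1] * std::sqrt(S.Am[i - 1])) / (3.0 * rho);
          double F2R = S.Qm[i] * S.Qm[i] / S.Am[i] +
            bmR * (S.Am[i] * std::sqrt(S.Am[i])) / (3.0 * rho);
          double srcL = srcm(S, i - 1, S.Am[i - 1], S.Qm[i - 1]);
          double srcR = srcm(S, i, S.Am[i], S.Qm[i]);
          Anew[s][i] = S.A[i] - dt_eff / S.dx * (S.Qm[i] - S.Qm[i - 1]);
          Qnew[s][i] = S.Q[i] - dt_eff / S.dx * (F2R - F2L) +
            dt_eff * (0.5 * (srcL + srcR) + S.fcorr[i]);
        }
      }

      // ---- characteristic extrapolation helpers (old state) ----
      // Invariants are referenced to the local diastolic state,
      // V+- = u +- 4(c - c_d(x)), which vanish at rest. Along the
      // characteristics dx/dt = u +- c they obey
      //   dV/dt = -G - f u/A +- (u +- c) (2 c b'/b - 4 c_d')
      // with G = [b'(sqrt(A) - sqrt(Ad)) - b (sqrt(Ad))'] / rho.
      // The foot value and the source are interpolated quadratically over
      // the three nodes nearest the boundary: in strongly tapered or
      // stiffness-graded vessels the linear variant leaves an O(dx^2)
      // rectified flux bias with a large constant.
      auto nodeV = [&](const Segment& S, int i, int sgn) {
        double u = S.Q[i] / S.A[i];
        double c = wavec(S.A[i], S.b[i], rho);
        double cd = wavec(S.Ad[i], S.b[i], rho);
        return u + sgn * 4.0 * (c - cd);
      };
      auto nodeSig = [&](const Segment& S, int i, int sgn) {
        double A = S.A[i], u = S.Q[i] / A;
        double c = wavec(A, S.b[i], rho);
        double G = (S.gb[i] * (std::sqrt(A) - std::sqrt(S.Ad[i])) -
                    S.b[i] * S.gsAd[i]) / rho;
        return -G - fcoef * u / A +
          sgn * (u + sgn * c) * (2.0 * c * S.gb[i] / S.b[i] -
                                 4.0 * S.gcd[i]);
      };
      auto quad = [](double v0, double v1, double v2, double s) {
        return v0 + s * (-1.5 * v0 + 2.0 * v1 - 0.5 * v2) +
          s * s * (0.5 * v0 - v1 + 0.5 * v2);
      };
      auto Wf_out = [&](const Segment& S) {  // forward invariant at x = L
        int n = S.n;
        double u = S.Q[n - 1] / S.A[n - 1];
        double c = wavec(S.A[n - 1], S.b[n - 1], rho);
        double s = std::min(1.0, std::max(0.0, (u + c) * dt_eff / S.dx));
        double V = quad(nodeV(S, n - 1, +1), nodeV(S, n - 2, +1),
                        nodeV(S, n - 3, +1), s);
        double sig = quad(nodeSig(S, n - 1, +1), nodeSig(S, n - 2, +1),
                          nodeSig(S, n - 3, +1), s);
        return V + dt_eff * sig;
      };
      auto Wb_in = [&](const Segment& S) {   // backward invariant at x = 0
        double u = S.Q[0] / S.A[0];
        double c = wavec(S.A[0], S.b[0], rho);
        double s = std::min(1.0, std::max(0.0, (c - u) * dt_eff / S.dx));
        double V = quad(nodeV(S, 0, -1), nodeV(S, 1, -1), nodeV(S, 2, -1),
                        s);
        double sig = quad(nodeSig(S, 0, -1), nodeSig(S, 1, -1),
                          nodeSig(S, 2, -1), s);
        return V + dt_eff * sig;
      };

      // ---- root inlet: prescribed Q, absorb outgoing characteristic ----
      {
        Segment& S = seg[root];
        double Wb = Wb_in(S);
        double Qb = qin_at(tn1);
        double A = S.A[0];
        double cd0 = wavec(S.Ad[0], S.b[0], rho);
        for (int it = 0; it < 60; ++it) {
          double c = wavec(A, S.b[0], rho);
          double g = Qb / A - 4.0 * (c - cd0) - Wb;
          double dg = -Qb / (A * A) - c / A;  // d(4c)/dA = c/A
          double step = g / dg;
          A -= step;
          if (!(A > 0.0)) A = 0.5 * (A + step + 1e-12);
          if (std::fabs(step) < 1e-14 * S.Ad[0] + 1e-18) break;
        }
        if (!(A > 0.0)) { errmsg = "inlet Newton failed"; goto failed; }
        Anew[root][0] = A; Qnew[root][0] = Qb;
      }

      // ---- junctions ----
      for (int s = 0; s < ns; ++s) {
        Segment& P = seg[s];
        const int nc = (int)P.children.size();
        if (nc == 0) continue;
        double Wfp = Wf_out(P);
        std::vector<double> Wbc(nc);
        for (int c = 0; c < nc; ++c) Wbc[c] = Wb_in(seg[P.children[c]]);
        const int nun = 2 + 2 * nc;
        double x[8];
        x[0] = P.A[P.n - 1];
        x[1] = P.Q[P.n - 1] / P.A[P.n - 1];
        for (int c = 0; c < nc; ++c) {
          const Segment& Ch = seg[P.children[c]];
          x[2 + 2 * c] = Ch.A[0];
          x[3 + 2 * c] = Ch.Q[0] / Ch.A[0];
        }
        double bp = P.b[P.n - 1], Adp = P.Ad[P.n - 1];
        double cdp = wavec(Adp, bp, rho);
        bool ok = false;
        for (int it = 0; it < 50; ++it) {
          double r[8], J[64];
          for (int i = 0; i < nun; ++i) r[i] = 0.0;
          for (int i = 0; i < nun * nun; ++i) J[i] = 0.0;
          double Ap = x[0], up = x[1];
          double cp = wavec(Ap, bp, rho);
          // eq 0: parent forward characteristic
          r[0] = up + 4.0 * (cp - cdp) - Wfp;
          J[0 * nun + 0] = cp / Ap;
          J[0 * nun + 1] = 1.0;
          // eq 1: mass
          r[1] = Ap * up;
          J[1 * nun + 0] = up;
          J[1 * nun + 1] = Ap;
          double Pp = ptube(Ap, Adp, bp, Pd) + 0.5 * rho * up * up;
          for (int c = 0; c < nc; ++c) {
            const Segment& Ch = seg[P.children[c]];
            double Ac = x[2 + 2 * c], uc = x[3 + 2 * c];
            double bc = Ch.b[0], Adc = Ch.Ad[0];
            double cc = wavec(Ac, bc, rho);
            r[1] -= Ac * uc;
            J[1 * nun + 2 + 2 * c] = -uc;
            J[1 * nun + 3 + 2 * c] = -Ac;
            // child backward characteristic
            int e = 2 + 2 * c;
            double cdc = wavec(Adc, bc, rho);
            r[e] = uc - 4.0 * (cc - cdc) - Wbc[c];
            J[e * nun + 2 + 2 * c] = -cc / Ac;
            J[e * nun + 3 + 2 * c] = 1.0;
            // total-pressure continuity parent-child
            e = 3 + 2 * c;
            double Pc2 = ptube(Ac, Adc, bc, Pd) + 0.5 * rho * uc * uc;
            r[e] = Pp - Pc2;
            J[e * nun + 0] = bp / (2.0 * std::sqrt(Ap));
            J[e * nun + 1] = rho * up;
            J[e * nun + 2 + 2 * c] = -bc / (2.0 * std::sqrt(Ac));
            J[e * nun + 3 + 2 * c] = -rho * uc;
          }
          double rn = 0.0;
          for (int i = 0; i < nun; ++i) rn = std::max(rn, std::fabs(r[i]));
          if (!lin_solve(J, r, nun)) { break; }
          double sn = 0.0;
          for (int i = 0; i < nun; ++i) { x[i] -= r[i]; sn = std::max(sn, std::fabs(r[i])); }
          if (x[0] <= 0.0) { break; }
          bool bad = false;
          for (int c = 0; c < nc; ++c) if (x[2 + 2 * c] <= 0.0) bad = true;
          if (bad) break;
          if (sn < 1e-12 * std::sqrt(Adp) + 1e-16) { ok = true; break; }
          if (it == 49) ok = true;   // accept last iterate if still sane
        }
        if (!ok) { errmsg = "junction Newton failed"; goto failed; }
        Anew[s][P.n - 1] = x[0];
        Qnew[s][P.n - 1] = x[0] * x[1];
        double qsum = 0.0;
        for (int c = 0; c < nc; ++c) {
          int cs = P.children[c];
          Anew[cs][0] = x[2 + 2 * c];
          Qnew[cs][0] = x[2 + 2 * c] * x[3 + 2 * c];
          qsum += Qnew[cs][0];
        }
        double res = std::fabs(Qnew[s][P.n - 1] - qsum);
        if (peak_inflow > 0.0)
          max_junc_residual = std::max(max_junc_residual, res / peak_inflow);
      }

      // ---- Windkessel outlets ----
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        if (S.terminal < 0) continue;
        const int j = S.terminal;
        const double R1 = wk(j, 0), R2 = wk(j, 1), Cw = wk(j, 2),
          Pout = wk(j, 3);
        double Wf = Wf_out(S);
        double bn = S.b[S.n - 1], Adn = S.Ad[S.n - 1];
        double a = dt_eff / (R2 * Cw);
        double cdn = wavec(Adn, bn, rho);
        double A = S.A[S.n - 1];
        for (int it = 0; it < 60; ++it) {
          double c = wavec(A, bn, rho);
          double u = Wf - 4.0 * (c - cdn);
          double Q = A * u;
          double Pcn = (Pc[j] + dt_eff * Q / Cw + a * Pout) / (1.0 + a);
          double g = ptube(A, Adn, bn, Pd) - Pcn - Q * R1;
          double du = -c / A;                    // d u / dA
          double dQ = u + A * du;
          double dPcn = dt_eff * dQ / Cw / (1.0 + a);
          double dg = bn / (2.0 * std::sqrt(A)) - dPcn - dQ * R1;
          double step = g / dg;
          A -= step;
          if (!(A > 0.0)) { A += 0.5 * step; }
          if (std::fabs(step) < 1e-14 * Adn + 1e-18) break;
        }
        if (!(A > 0.0)) { errmsg = "outlet Newton failed"; goto failed; }
        double c = wavec(A, bn, rho);
        double u = Wf - 4.0 * (c - cdn);
        double Q = A * u;
        Pc[j] = (Pc[j] + dt_eff * Q / Cw + a * Pout) / (1.0 + a);
        Anew[s][S.n - 1] = A;
        Qnew[s][S.n - 1] = Q;
        vol_out[j] += Q * dt_eff;
      }

      vol_in += qin_at(tn1) * dt_eff;

      for (int s = 0; s < ns; ++s) { seg[s].A = Anew[s]; seg[s].Q = Qnew[s]; }
      t = tn1;

      // ---- record plane traces ----
      for (int p = 0; p < np; ++p) {
        const Segment& S = seg[planes(p, 0)];
        int i = planes(p, 1);
        trA[p][k] = S.A[i];
        trQ[p][k] = S.Q[i];
        trP[p][k] = ptube(S.A[i], S.Ad[i], S.b[i], Pd);
      }
    }

    // ---- periodicity check on the monitor plane pressure ----
    {
      double num = 0.0, den = 0.0;
      for (int k = 0; k < steps_per_cycle; ++k) {
        double d = trP[monitor_plane][k] - mon_prev[k];
        num += d * d;
        den += trP[monitor_plane][k] * trP[monitor_plane][k];
      }
      double metric = (cycle == 0) ? 1.0 : std::sqrt(num / std::max(den, 1e-300));
      conv.push_back(metric);
      mon_prev = trP[monitor_plane];
      if (cycle + 1 >= min_cycles && metric < tol_periodicity)
        converged = true;
    }
  }

  goto done;
failed:
  {
    return List::create(_["ok"] = false, _["error"] = errmsg,
                        _["time"] = t);
  }
done:
  // net stored volume over the last cycle
  double stored = 0.0;
  for (int s = 0; s < ns; ++s)
    for (int i = 0; i < seg[s].n - 1; ++i)
      stored += 0.5 * ((seg[s].A[i] - A_cycle_start[s][i]) +
                       (seg[s].A[i + 1] - A_cycle_start[s][i + 1])) *
        seg[s].dx;

  NumericVector tout(steps_per_cycle);
  for (int k = 0; k < steps_per_cycle; ++k) tout[k] = (k + 1) * dt_eff;
  List Pl(np), Ql(np), Al(np);
  for (int p = 0; p < np; ++p) {
    Pl[p] = NumericVector(trP[p].begin(), trP[p].end());
    Ql[p] = NumericVector(trQ[p].begin(), trQ[p].end());
    Al[p] = NumericVector(trA[p].begin(), trA[p].end());
  }
  return List::create(
    _["ok"] = true,
    _["t"] = tout,
    _["P"] = Pl, _["Q"] = Ql, _["A"] = Al,
    _["cycles"] = cycle,
    _["converged"] = converged,
    _["convergence"] = NumericVector(conv.begin(), conv.end()),
    _["max_junction_residual"] = max_junc_residual,
    _["volume_in"] = vol_in,
    _["volume_out"] = NumericVector(vol_out.begin(), vol_out.end()),
    _["volume_stored"] = stored,
    _["dt"] = dt_eff);
}
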