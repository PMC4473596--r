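// Compiled hot paths: rate-network integration, the RLS/FORCE training
// loop, and closed-loop crossbar programming. Semantics mirror the R
// reference operations (step_network, update_P, weight_increment,
// program_to_target); the test suite cross-checks the two paths.

#define USE_FC_LEN_T
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double clampG(double g, double gmin, double gmax) {
  return std::min(std::max(g, gmin), gmax);
}

// choose which device to modulate; returns false when no headroom
static inline bool plan_dev(double G1, double G2, double err,
                            double Gmin, double Gmax, int &dev, int &dir) {
  double h1, h2;
  int d1, d2;
  if (err > 0) {            // increase w: depress m1 or potentiate m2
    h1 = G1 - Gmin; h2 = Gmax - G2; d1 = -1; d2 = +1;
  } else {                  // decrease w: potentiate m1 or depress m2
    h1 = Gmax - G1; h2 = G2 - Gmin; d1 = +1; d2 = -1;
  }
  if (h1 <= 0.0 && h2 <= 0.0) return false;
  if (h2 >= h1) { dev = 2; dir = d2; } else { dev = 1; dir = d1; }
  return true;
}

static inline double coarse_step(double G, int dir, double Gmin, double Gmax,
                                 double ep, double ed) {
  double g = (dir > 0) ? G + ep * (Gmax - G) : G - ed * (G - Gmin);
  return clampG(g, Gmin, Gmax);
}

static inline double fine_step(double G, int dir, double Gmin, double Gmax,
                               double dR) {
  double r = 1.0 / G - dir * dR;
  double g = (r <= 0.0) ? Gmax : 1.0 / r;
  return clampG(g, Gmin, Gmax);
}

// closed-loop coarse/fine programming of one differential synapse;
// returns 0 on success, 1 when the target is missed beyond tolerance
static int program_pair(double &G1, double &G2, double wt, double Rf,
                        double Gmin, double Gmax, double ep, double ed,
                        double dR, double tol, double coarse_frac,
                        int maxit, long long &nc, long long &nf) {
  const double wmax = Rf * (Gmax - Gmin);
  const double full = 2.0 * wmax;
  const double tol_abs = tol * full;
  const double band = coarse_frac * full;
  // below half the smallest representable fine step no pulse can improve
  if (std::fabs(wt + Rf * (G1 - G2)) < 0.5 * Rf * Gmin * Gmin * dR)
    return 0;
  // refresh: when both devices have ratcheted into the high-conductance
  // half, erase toward the floor (the array is isolated during the
  // modulation stage, so the transient weight excursion is unseen) and
  // re-program; the pair then sits near the high-resistance end, where
  // the differential step -- and hence the residual -- is finest
  if (G1 > Gmin + 0.4 * (Gmax - Gmin) && G2 > Gmin + 0.4 * (Gmax - Gmin)) {
    int guard = 0;
    while (G1 > Gmin + 1e-8 && ++guard < 400) { G1 = coarse_step(G1, -1, Gmin, Gmax, ep, ed); ++nc; }
    guard = 0;
    while (G2 > Gmin + 1e-8 && ++guard < 400) { G2 = coarse_step(G2, -1, Gmin, Gmax, ep, ed); ++nc; }
  }
  for (int it = 0; it < maxit; ++it) {
    double err = wt + Rf * (G1 - G2);    // wt - w,  w = -Rf (G1 - G2)
    if (std::fabs(err) <= 1e-15) return 0;
    int dev, dir;
    if (!plan_dev(G1, G2, err, Gmin, Gmax, dev, dir)) break;
    if (std::fabs(err) > band) {
      if (dev == 1) G1 = coarse_step(G1, dir, Gmin, Gmax, ep, ed);
      else          G2 = coarse_step(G2, dir, Gmin, Gmax, ep, ed);
      ++nc;
    } else {
      double g1 = G1, g2 = G2;
      if (dev == 1) g1 = fine_step(G1, dir, Gmin, Gmax, dR);
      else          g2 = fine_step(G2, dir, Gmin, Gmax, dR);
      double err2 = wt + Rf * (g1 - g2);
      if (std::fabs(err2) < std::fabs(err) - 1e-18) {
        G1 = g1; G2 = g2; ++nf;
      } else {
        // the planned device's step overshoots: the complementary device
        // (whose step size differs with its conductance state) may still
        // improve -- use it in the next modulation stage
        g1 = G1; g2 = G2;
        if (dev == 1) g2 = fine_step(G2, (err > 0) ? +1 : -1, Gmin, Gmax, dR);
        else          g1 = fine_step(G1, (err > 0) ? -1 : +1, Gmin, Gmax, dR);
        err2 = wt + Rf * (g1 - g2);
        if (std::fabs(err2) < std::fabs(err) - 1e-18) {
          G1 = g1; G2 = g2; ++nf;
        } else {
          // composition: same-polarity pairs on both devices (two
          // modulation stages) give a net step equal to the *difference*
          // of the two devices' fine steps -- much finer than either
          double p1 = fine_step(G1, +1, Gmin, Gmax, dR);
          double p2 = fine_step(G2, +1, Gmin, Gmax, dR);
          double d1 = fine_step(G1, -1, Gmin, Gmax, dR);
          double d2 = fine_step(G2, -1, Gmin, Gmax, dR);
          double e_pp = wt + Rf * (p1 - p2);
          double e_dd = wt + Rf * (d1 - d2);
          if (std::fabs(e_pp) < std::fabs(err) - 1e-18) {
            G1 = p1; G2 = p2; nf += 2;
          } else if (std::fabs(e_dd) < std::fabs(err) - 1e-18) {
            G1 = d1; G2 = d2; nf += 2;
          } else break;
        }
      }
    }
  }
  return (std::fabs(wt + Rf * (G1 - G2)) > tol_abs) ? 1 : 0;
}

// [[Rcpp::export]]
List program_matrix_cpp(arma::mat G1, arma::mat G2, const arma::mat &W,
                        double Rf, double Gmin, double Gmax,
                        double eta_p, double eta_d, double dR,
                        double tol, double coarse_frac, int maxit) {
  long long nc = 0, nf = 0;
  long long failed = -1;
  for (arma::uword k = 0; k < G1.n_elem; ++k) {
    double g1 = G1(k), g2 = G2(k);
    if (program_pair(g1, g2, W(k), Rf, Gmin, Gmax, eta_p, eta_d, dR,
                     tol, coarse_frac, maxit, nc, nf)) {
      failed = (long long)k;
      break;
    }
    G1(k) = g1; G2(k) = g2;
  }
  return List::create(_["G1"] = G1, _["G2"] = G2,
                      _["n_coarse"] = (double)nc, _["n_fine"] = (double)nf,
                      _["failed"] = (double)failed);
}

// [[Rcpp::export]]
List run_network_cpp(const arma::mat &WNN, const arma::mat &WNI,
                     const arma::mat &WZN, const arma::vec &x0,
                     double g, double dt_over_tau, const arma::mat &I,
                     int n_steps, bool record_r) {
  const arma::uword N = WNN.n_rows;
  arma::vec x = x0, r = arma::tanh(x0);
  arma::mat Z(n_steps, WZN.n_rows);
  arma::mat R;
  if (record_r) R.set_size(n_steps, N);
  const bool has_in = WNI.n_cols > 0;
  for (int t = 0; t < n_steps; ++t) {
    arma::vec drive = g * (WNN * r);
    if (has_in) drive += WNI * I.row(t).t();
    x += dt_over_tau * (-x + drive);
    r = arma::tanh(x);
    Z.row(t) = (WZN * r).t();
    if (record_r) R.row(t) = r.t();
    if ((t & 255) == 0 && !x.is_finite())
      stop("network state diverged (non-finite) at step %d", t + 1);
  }
  List out = List::create(_["z"] = Z, _["x"] = x);
  if (record_r) out["r"] = R;
  return out;
}

// [[Rcpp::export]]
List force_train_cpp(arma::mat WNN, const arma::mat &WNI, arma::mat WZN,
                     const arma::mat &mask, const arma::vec &x0,
                     double g, double dt_over_tau,
                     const arma::mat &f, const arma::mat &ctrl,
                     int n_steps, double alpha, int update_every,
                     const arma::ivec &part, int row_mode,
                     const arma::vec &fb,
                     bool train_internal, bool train_readout,
                     bool crossbar, arma::mat G1, arma::mat G2, double Rf,
                     double Gmin, double Gmax, double eta_p, double eta_d,
                     double dR, double tol, double coarse_frac,
                     const IntegerMatrix &tracked) {
  const arma::uword N = WNN.n_rows;
  const arma::uword n_out = WZN.n_rows;
  const arma::uword n_pat = f.n_rows;
  const bool has_in = WNI.n_cols > 0;
  const double wmax = Rf * (Gmax - Gmin);
  const int n_tr = tracked.nrow();

  // In crossbar mode the RLS increments accumulate on continuous *target*
  // registers (WtNN/WtZN); the devices are programmed toward the target at
  // each modulation stage and the network dynamics always use the realised
  // (quantised) weights WNN/WZN. Without the target registers, increments
  // below the fine programming step would be discarded and learning stalls.
  arma::mat WtNN, WtZN;
  if (crossbar) { WtNN = WNN; WtZN = WZN; }
  arma::mat &UNN = crossbar ? WtNN : WNN;
  arma::mat &UZN = crossbar ? WtZN : WZN;

  arma::vec x = x0, r = arma::tanh(x0);
  arma::mat P = arma::eye(N, N) / alpha;   // only the upper triangle is
  arma::vec Pr(N), e_rows(N);              // maintained (dsymv/dsyr below)
  arma::mat Z(n_steps, n_out), E(n_steps, n_out);
  arma::mat GJ(n_steps, n_tr);
  long long nc = 0, nf = 0;
  const int maxit = 10000;
  const bool full_mask = (mask.min() >= 1.0);
  const int ni = (int)N, none = 1, nout_i = (int)n_out;
  const double d_one = 1.0, d_zero = 0.0, d_m1 = -1.0;

  for (int t = 0; t < n_steps; ++t) {
    arma::uword pr = (arma::uword)(t % (long long)n_pat);
    arma::vec drive = g * (WNN * r);
    if (has_in) drive += WNI * ctrl.row(pr).t();
    x += dt_over_tau * (-x + drive);
    r = arma::tanh(x);
    arma::vec z = WZN * r;
    arma::vec e = z - f.row(pr).t();
    Z.row(t) = z.t();
    E.row(t) = e.t();
    if ((t & 255) == 0 && !x.is_finite())
      stop("network state diverged (non-finite) at step %d", t + 1);

    if (update_every > 0 && ((t + 1) % update_every) == 0) {
      // Pr = P r (symmetric, stored in the upper triangle)
      F77_CALL(dsymv)("U", &ni, &d_one, P.memptr(), &ni, r.memptr(), &none,
                      &d_zero, Pr.memptr(), &none FCONE);
      double den = 1.0 + arma::dot(r, Pr);
      if (!(den > 0.0))
        stop("RLS denominator <= 0 at step %d", t + 1);
      double c = 1.0 / den;
      double negc = -c;
      // P <- P - c Pr Pr^T (rank-1, upper triangle)
      F77_CALL(dsyr)("U", &ni, &negc, Pr.memptr(), &none,
                     P.memptr(), &ni FCONE);
      arma::vec dw = c * Pr;                   // = P_new * r
      if (train_readout && n_out > 0)
        F77_CALL(dger)(&nout_i, &ni, &d_m1, e.memptr(), &none,
                       dw.memptr(), &none, UZN.memptr(), &nout_i);
      if (train_internal) {
        if (row_mode == 1) {                   // partition (feedback-scaled)
          for (arma::uword i = 0; i < N; ++i)
            e_rows(i) = fb(i) * e((arma::uword)part(i));
        } else if (row_mode == 2) {            // feedback-scaled
          e_rows = fb * e(0);
        } else {                               // identical
          e_rows.fill(arma::mean(e));
        }
        if (full_mask)
          F77_CALL(dger)(&ni, &ni, &d_m1, e_rows.memptr(), &none,
                         dw.memptr(), &none, UNN.memptr(), &ni);
        else
          UNN -= (e_rows * dw.t()) % mask;
      }
      if (crossbar) {
        // modulation stage: program every synapse to its new target
        for (arma::uword j = 0; j < N; ++j) {
          for (arma::uword i = 0; i < N; ++i) {
            if (mask(i, j) == 0.0) continue;
            double wt = WtNN(i, j);
            wt = std::min(std::max(wt, -wmax), wmax);
            double g1 = G1(i, j), g2 = G2(i, j);
            if (program_pair(g1, g2, wt, Rf, Gmin, Gmax, eta_p, eta_d, dR,
                             tol, coarse_frac, maxit, nc, nf))
              stop("programming failure at synapse (%d, %d), step %d",
                   (int)i + 1, (int)j + 1, t + 1);
            G1(i, j) = g1; G2(i, j) = g2;
            WNN(i, j) = -Rf * (g1 - g2);
          }
          for (arma::uword k = 0; k < n_out; ++k) {
            double wt = WtZN(k, j);
            wt = std::min(std::max(wt, -wmax), wmax);
            double g1 = G1(N + k, j), g2 = G2(N + k, j);
            if (program_pair(g1, g2, wt, Rf, Gmin, Gmax, eta_p, eta_d, dR,
                             tol, coarse_frac, maxit, nc, nf))
              stop("programming failure at readout synapse (%d, %d), step %d",
                   (int)k + 1, (int)j + 1, t + 1);
            G1(N + k, j) = g1; G2(N + k, j) = g2;
            WZN(k, j) = -Rf * (g1 - g2);
          }
        }
      }
    }

    for (int q = 0; q < n_tr; ++q) {
      int m = tracked(q, 0), i = tracked(q, 1) - 1, j = tracked(q, 2) - 1;
      if (crossbar) {
        arma::uword row = (m == 0) ? (arma::uword)i : N + (arma::uword)i;
        GJ(t, q) = G1(row, (arma::uword)j) - G2(row, (arma::uword)j);
      } else {
        double w = (m == 0) ? WNN((arma::uword)i, (arma::uword)j)
                            : WZN((arma::uword)i, (arma::uword)j);
        GJ(t, q) = -w / Rf;                    // implied joint conductance
      }
    }
  }

  P = arma::symmatu(P);
  return List::create(
    _["WNN"] = WNN, _["WZN"] = WZN, _["G1"] = G1, _["G2"] = G2,
    _["P"] = P, _["x"] = x, _["Z"] = Z, _["E"] = E, _["Gjoint"] = GJ,
    _["n_coarse"] = (double)nc, _["n_fine"] = (double)nf);
}
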