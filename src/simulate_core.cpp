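// Core integrator for the junctional binding/unbinding dynamics.
//
// State: concentration u on directed half-edges (F-end in the owning
// cell).  The opposite half-edge of mu carries the opposite-polarity
// concentration v seen from mu's cell.  Per half-edge mu (owner i,
// facing j):
//
//   du/dt = kappa * f_i * g_j * (1 + A_mu) - gamma * u_mu * (1 + B_mu)/(1 + A_mu)
//         + cue_mu(t)
//
// where A_mu (B_mu) is the cell-averaged cooperative up(down)regulation
// input of the junction (see drift_eval), and f_i, g_j are the unbound
// pools (total minus perimeter-averaged bound amount, clipped at zero).  Integration: classical RK4 on the drift, then an
// additive Euler-Maruyama noise increment eta0*sqrt(dt)*N(0,1) per
// half-edge, then reflection at zero by clipping.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: fast, reproducible across
// platforms independently of the C++ standard library.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Box-Muller, one at a time (cache the spare)
  bool has_spare = false;
  double spare = 0.0;
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586476925 * u2;
    spare = r * std::sin(th); has_spare = true;
    return r * std::cos(th);
  }
};

struct Sys {
  int n_he, n_cells;
  const int *own, *opp, *neigh, *cell_start, *he_pos;
  const double *len, *P, *Wup, *Wdn;
  const int *woff;                    // per-cell offset into Wup/Wdn
  const double *f0, *g0, *alpha, *beta;
  double kappa, gamma;
};

// drift evaluation; scratch vectors supplied by caller.  The cooperative
// input of a junction averages the channels of its two cells (both
// species' messengers regulate the shared junction, keeping F and G on an
// equal footing): per half-edge h (owner i, facing j),
//   Ku_eff = (alpha_i (Wup_i u)_h + alpha_j (Wup_j u~)_opp(h)) / 2
// and analogously for the opposite-polarity input, with u~ the
// opposite-polarity state.
static void drift_eval(const Sys &S, const double *u, double *du,
                       double *fubd, double *gubd,
                       double *buu, double *buv, double *bdu, double *bdv,
                       double *uopp, const double *cue_s, double cue_amp) {
  const int nc = S.n_cells, n = S.n_he;
  for (int h = 0; h < n; h++) uopp[h] = u[S.opp[h]];
  for (int c = 0; c < nc; c++) {
    double sb = 0.0, tb = 0.0;
    for (int h = S.cell_start[c]; h < S.cell_start[c + 1]; h++) {
      sb += u[h] * S.len[h];
      tb += uopp[h] * S.len[h];
    }
    double f = S.f0[c] - sb / S.P[c];
    double g = S.g0[c] - tb / S.P[c];
    fubd[c] = f > 0.0 ? f : 0.0;
    gubd[c] = g > 0.0 ? g : 0.0;
  }
  const bool shared_w = (S.Wup == S.Wdn);
  for (int c = 0; c < nc; c++) {
    int h0 = S.cell_start[c], m = S.cell_start[c + 1] - h0;
    const double *Wu = S.Wup + S.woff[c];
    const double *uu = u + h0, *uo = uopp + h0;
    for (int r = 0; r < m; r++) {
      double au = 0.0, av = 0.0;
      const double *w = Wu + (size_t)r * m;
      for (int q = 0; q < m; q++) {
        au += w[q] * uu[q];
        av += w[q] * uo[q];
      }
      buu[h0 + r] = au;
      buv[h0 + r] = av;
    }
    if (!shared_w) {
      const double *Wd = S.Wdn + S.woff[c];
      for (int r = 0; r < m; r++) {
        double au = 0.0, av = 0.0;
        const double *w = Wd + (size_t)r * m;
        for (int q = 0; q < m; q++) {
          au += w[q] * uu[q];
          av += w[q] * uo[q];
        }
        bdu[h0 + r] = au;
        bdv[h0 + r] = av;
      }
    }
  }
  if (shared_w) { bdu = buu; bdv = buv; }
  for (int h = 0; h < n; h++) {
    int i = S.own[h], j = S.neigh[h], o = S.opp[h];
    double up = 1.0 + 0.5 * (S.alpha[i] * buu[h] + S.alpha[j] * buv[o]);
    double dn = 1.0 + 0.5 * (S.beta[i] * bdv[h] + S.beta[j] * bdu[o]);
    du[h] = S.kappa * fubd[i] * gubd[j] * up - S.gamma * u[h] * dn / up;
  }
  if (cue_amp != 0.0)
    for (int h = 0; h < n; h++) du[h] += cue_amp * cue_s[h];
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector u0,
                   IntegerVector own, IntegerVector opp, IntegerVector neigh,
                   NumericVector len, IntegerVector cell_start,
                   NumericVector Wup, NumericVector Wdn, IntegerVector woff,
                   NumericVector Pcell,
                   NumericVector f0, NumericVector g0,
                   NumericVector alpha, NumericVector beta,
                   double kappa, double gamma,
                   double eta0, double dt, double t0,
                   int nsteps, int record_stride,
                   NumericVector cue_s, double cueM, double cue_tau,
                   IntegerVector clamp_idx, NumericVector clamp_val,
                   NumericMatrix nhat, IntegerVector dip_cell,
                   double rngseed,
                   bool check_steady, double steady_window, double steady_tol) {
  const int n = u0.size(), nc = Pcell.size();
  Sys S;
  S.n_he = n; S.n_cells = nc;
  S.own = own.begin(); S.opp = opp.begin(); S.neigh = neigh.begin();
  S.cell_start = cell_start.begin(); S.he_pos = nullptr;
  S.len = len.begin(); S.P = Pcell.begin();
  S.Wup = Wup.begin(); S.Wdn = Wdn.begin(); S.woff = woff.begin();
  S.f0 = f0.begin(); S.g0 = g0.begin();
  S.alpha = alpha.begin(); S.beta = beta.begin();
  S.kappa = kappa; S.gamma = gamma;

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), ut(n);
  std::vector<double> fub(nc), gub(nc), buu(n), buv(n), bdu(n), bdv(n), uopp(n);
  Xoshiro rng((uint64_t)rngseed);
  const double sqdt = eta0 * std::sqrt(dt);

  int max_rec = nsteps / record_stride + 2;
  NumericMatrix U(max_rec, n);
  NumericVector times(max_rec);
  std::vector<double> Qs, Os;
  int nrec = 0;
  bool steady = false;
  double t_steady = NA_REAL;

  auto record = [&](double tnow) {
    for (int h = 0; h < n; h++) U(nrec, h) = u[h];
    times[nrec] = tnow;
    // order parameters for the stopping rule
    double px_sum = 0, py_sum = 0, q_sum = 0;
    std::vector<double> Px(nc, 0.0), Py(nc, 0.0);
    for (int h = 0; h < n; h++) {
      double d = u[h] - u[S.opp[h]];
      Px[S.own[h]] += d * nhat(h, 0);
      Py[S.own[h]] += d * nhat(h, 1);
    }
    for (int c = 0; c < nc; c++) {
      px_sum += Px[c]; py_sum += Py[c];
      q_sum += std::sqrt(Px[c] * Px[c] + Py[c] * Py[c]);
    }
    double Q = q_sum / nc;
    double P = std::sqrt(px_sum * px_sum + py_sum * py_sum) / nc;
    Qs.push_back(Q);
    Os.push_back(Q > 1e-14 ? P / Q : 0.0);
    nrec++;
  };

  record(t0);
  const int nclamp = clamp_idx.size();
  for (int c = 0; c < nclamp; c++) u[clamp_idx[c]] = clamp_val[c];

  double rec_dt = record_stride * dt;
  int win = check_steady ? std::max(2, (int)std::round(steady_window / rec_dt)) : 0;

  for (int s = 1; s <= nsteps; s++) {
    double tnow = t0 + (s - 1) * dt;
    double amp1 = 0.0, amp2 = 0.0, amp3 = 0.0;
    if (cueM != 0.0) {
      if (R_finite(cue_tau)) {
        amp1 = cueM * std::exp(-tnow / cue_tau);
        amp2 = cueM * std::exp(-(tnow + 0.5 * dt) / cue_tau);
        amp3 = cueM * std::exp(-(tnow + dt) / cue_tau);
      } else amp1 = amp2 = amp3 = cueM;
    }
    drift_eval(S, u.data(), k1.data(), fub.data(), gub.data(), buu.data(), buv.data(), bdu.data(), bdv.data(), uopp.data(), cue_s.begin(), amp1);
    for (int h = 0; h < n; h++) ut[h] = u[h] + 0.5 * dt * k1[h];
    drift_eval(S, ut.data(), k2.data(), fub.data(), gub.data(), buu.data(), buv.data(), bdu.data(), bdv.data(), uopp.data(), cue_s.begin(), amp2);
    for (int h = 0; h < n; h++) ut[h] = u[h] + 0.5 * dt * k2[h];
    drift_eval(S, ut.data(), k3.data(), fub.data(), gub.data(), buu.data(), buv.data(), bdu.data(), bdv.data(), uopp.data(), cue_s.begin(), amp2);
    for (int h = 0; h < n; h++) ut[h] = u[h] + dt * k3[h];
    drift_eval(S, ut.data(), k4.data(), fub.data(), gub.data(), buu.data(), buv.data(), bdu.data(), bdv.data(), uopp.data(), cue_s.begin(), amp3);
    if (eta0 > 0.0) {
      for (int h = 0; h < n; h++) {
        double v = u[h] + dt / 6.0 * (k1[h] + 2.0 * k2[h] + 2.0 * k3[h] + k4[h])
                 + sqdt * rng.norm();
        u[h] = v > 0.0 ? v : 0.0;
      }
    } else {
      for (int h = 0; h < n; h++) {
        double v = u[h] + dt / 6.0 * (k1[h] + 2.0 * k2[h] + 2.0 * k3[h] + k4[h]);
        u[h] = v > 0.0 ? v : 0.0;
      }
    }
    for (int c = 0; c < nclamp; c++) u[clamp_idx[c]] = clamp_val[c];
    if (!std::isfinite(u[0])) {
      bool bad = false;
      for (int h = 0; h < n; h++) if (!std::isfinite(u[h])) { bad = true; break; }
      if (bad) stop("non-finite state at t = %f", t0 + s * dt);
    }
    if (s % record_stride == 0) {
      record(t0 + s * dt);
      // steady when the change of the window-averaged order parameters
      // between two consecutive windows is below tolerance or within the
      // noise standard error of the window (stochastic runs fluctuate
      // forever; only the systematic drift should keep the run alive)
      if (check_steady && nrec >= 3 * win + 1) {
        auto wstat = [&](const std::vector<double> &x, int from, int to,
                         double &mean, double &var) {
          double m = 0.0;
          for (int k = from; k < to; k++) m += x[k];
          m /= (to - from);
          double v = 0.0;
          for (int k = from; k < to; k++) v += (x[k] - m) * (x[k] - m);
          mean = m; var = v / std::max(1, to - from - 1);
        };
        // three consecutive windows must agree pairwise and end-to-end,
        // so a slow monotone drift (coarsening) does not pass as steady
        double q1, q2, q3, o1, o2, o3, vq, vo, dum;
        wstat(Qs, nrec - 3 * win, nrec - 2 * win, q1, dum);
        wstat(Qs, nrec - 2 * win, nrec - win, q2, dum);
        wstat(Qs, nrec - win, nrec, q3, vq);
        wstat(Os, nrec - 3 * win, nrec - 2 * win, o1, dum);
        wstat(Os, nrec - 2 * win, nrec - win, o2, dum);
        wstat(Os, nrec - win, nrec, o3, vo);
        double se_q = 2.0 * std::sqrt(vq / win), se_o = 2.0 * std::sqrt(vo / win);
        double qref = std::fabs(q3) + 1e-12;
        double dq = std::max(std::fabs(q3 - q2), std::fabs(q3 - q1));
        double do_ = std::max(std::fabs(o3 - o2), std::fabs(o3 - o1));
        bool q_ok = dq < std::max(steady_tol * qref, se_q);
        bool o_ok = do_ < std::max(steady_tol, se_o);
        if (q_ok && o_ok) {
          steady = true;
          t_steady = t0 + s * dt;
          break;
        }
      }
    }
  }

  NumericMatrix Uout(nrec, n);
  NumericVector tout(nrec), Qout(nrec), Oout(nrec);
  for (int r = 0; r < nrec; r++) {
    tout[r] = times[r]; Qout[r] = Qs[r]; Oout[r] = Os[r];
    for (int h = 0; h < n; h++) Uout(r, h) = U(r, h);
  }
  return List::create(_["times"] = tout, _["U"] = Uout,
                      _["Qbar"] = Qout, _["O"] = Oout,
                      _["steady"] = steady, _["t_steady"] = t_steady);
}
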