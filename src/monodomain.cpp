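// Explicit finite-difference monodomain solver on a regular 2D grid with
// per-node longitudinal diffusion (x direction), a uniform transverse-to-
// longitudinal ratio, no-flux boundaries, and heterogeneous membrane kinetics
// (epicardial / midmyocardial myocytes, fibroblast nodes). Edge diffusion is
// the harmonic mean of the two node coefficients; any edge touching a
// fibroblast node is divided by 3 (reduced myocyte-fibroblast coupling).

#include <Rcpp.h>
#include "ord.h"

using namespace Rcpp;

struct Stim {
  int r0, r1, c0, c1;   // 0-based inclusive node ranges
  double t0, dur, period, amp;
  int npulses;
  bool active(double t) const {
    if (t < t0) return false;
    if (period <= 0.0) return t < t0 + dur;
    double k = std::floor((t - t0) / period);
    if (k >= npulses) return false;
    double ph = t - t0 - k * period;
    return ph < dur;
  }
};

// [[Rcpp::export]]
List monodomain_cpp(IntegerMatrix celltype, NumericMatrix DL, double ratio,
                    double dx, double dt, double duration, List stims,
                    NumericVector init_epi, NumericVector init_mid,
                    NumericVector init_fib,
                    Nullable<NumericMatrix> init_full_,
                    double meas_start, double trace_dt, double upcross_bin,
                    double upcross_level, bool return_state, bool ina_tp06,
                    double quiet_stop, double quiet_after) {
  const int ny = celltype.nrow(), nx = celltype.ncol();
  const int nn = ny * nx;
  if (DL.nrow() != ny || DL.ncol() != nx) stop("DL shape mismatch");
  if (ratio <= 0 || ratio > 1) stop("anisotropy ratio must be in (0, 1]");
  if (dx <= 0 || dt <= 0) stop("dx and dt must be positive");

  // membrane state
  std::vector<double> S((size_t)nn * ORD_NSTATE);
  std::vector<double> V(nn);
  std::vector<int> ct(nn);
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r < ny; ++r) ct[c * ny + r] = celltype(r, c);

  if (init_full_.isNotNull()) {
    NumericMatrix F(init_full_);
    if (F.nrow() != nn || F.ncol() != ORD_NSTATE) stop("init_full shape");
    for (int k = 0; k < nn; ++k)
      for (int j = 0; j < ORD_NSTATE; ++j) S[(size_t)k * ORD_NSTATE + j] = F(k, j);
  } else {
    if (init_epi.size() != ORD_NSTATE || init_mid.size() != ORD_NSTATE)
      stop("myocyte init state length");
    if (init_fib.size() != FIB_NSTATE) stop("fibroblast init state length");
    for (int k = 0; k < nn; ++k) {
      double *X = &S[(size_t)k * ORD_NSTATE];
      if (ct[k] == CT_FIB) {
        for (int j = 0; j < FIB_NSTATE; ++j) X[j] = init_fib[j];
      } else {
        const NumericVector &ini = (ct[k] == CT_MID) ? init_mid : init_epi;
        for (int j = 0; j < ORD_NSTATE; ++j) X[j] = ini[j];
      }
    }
  }
  for (int k = 0; k < nn; ++k) V[k] = S[(size_t)k * ORD_NSTATE];

  // edge conductances (1/ms)
  const double inv_dx2 = 1.0 / (dx * dx);
  std::vector<double> gx((size_t)std::max(0, nx - 1) * ny, 0.0);
  std::vector<double> gy((size_t)std::max(0, ny - 1) * nx, 0.0);
  for (int c = 0; c + 1 < nx; ++c)
    for (int r = 0; r < ny; ++r) {
      double a = DL(r, c), b = DL(r, c + 1);
      double g = 2.0 * a * b / (a + b) * inv_dx2;
      if (ct[c * ny + r] == CT_FIB || ct[(c + 1) * ny + r] == CT_FIB) g /= 3.0;
      gx[(size_t)c * ny + r] = g;
    }
  for (int c = 0; c < nx; ++c)
    for (int r = 0; r + 1 < ny; ++r) {
      double a = ratio * DL(r, c), b = ratio * DL(r + 1, c);
      double g = 2.0 * a * b / (a + b) * inv_dx2;
      if (ct[c * ny + r] == CT_FIB || ct[c * ny + r + 1] == CT_FIB) g /= 3.0;
      gy[(size_t)c * (ny - 1) + r] = g;
    }

  // stimuli
  std::vector<Stim> st;
  for (int i = 0; i < stims.size(); ++i) {
    NumericVector s(stims[i]);
    if (s.size() != 9) stop("each stimulus needs 9 entries");
    Stim q;
    q.r0 = (int)s[0] - 1; q.r1 = (int)s[1] - 1;
    q.c0 = (int)s[2] - 1; q.c1 = (int)s[3] - 1;
    q.t0 = s[4]; q.dur = s[5]; q.period = s[6];
    q.npulses = (int)s[7]; q.amp = s[8];
    if (q.r0 < 0 || q.r1 >= ny || q.c0 < 0 || q.c1 >= nx || q.r0 > q.r1 ||
        q.c0 > q.c1)
      stop("stimulus region outside grid");
    st.push_back(q);
  }
  std::vector<double> stim_now(nn, 0.0);
  std::vector<char> stim_state(st.size(), 0);

  OrdTab Tepi(CT_EPI, dt, ina_tp06), Tmid(CT_MID, dt, ina_tp06);

  const long nstep = (long)std::llround(duration / dt);

  // per-node measurement bookkeeping
  std::vector<double> vrest(nn, NA_REAL), dvdtmax(nn, 0.0),
      act(nn, NA_REAL), vmax(nn, -1e9), repol(nn, NA_REAL);
  std::vector<char> activated(nn, 0), repol_lock(nn, 0);
  std::vector<int> upcount(nn, 0);
  int nbin = upcross_bin > 0 ? (int)std::ceil(duration / upcross_bin) : 0;
  std::vector<double> bins(std::max(nbin, 1), 0.0);

  // traces
  int tthin = trace_dt > 0 ? std::max(1, (int)std::llround(trace_dt / dt)) : 0;
  std::vector<double> trace_times;
  std::vector<std::vector<double> > traces;  // one vector per sample
  std::vector<double> lap(nn);

  bool meas_init = false;
  double quiet_accum = 0.0, t_end = duration;

  for (long s = 0; s < nstep; ++s) {
    double t = s * dt;
    double step_maxdvdt = 0.0;

    // refresh stimulus field when any pulse switches on/off
    bool changed = false;
    for (size_t i = 0; i < st.size(); ++i) {
      char a = st[i].active(t) ? 1 : 0;
      if (a != stim_state[i]) { stim_state[i] = a; changed = true; }
    }
    if (changed) {
      std::fill(stim_now.begin(), stim_now.end(), 0.0);
      for (size_t i = 0; i < st.size(); ++i)
        if (stim_state[i])
          for (int c = st[i].c0; c <= st[i].c1; ++c)
            for (int r = st[i].r0; r <= st[i].r1; ++r)
              stim_now[c * ny + r] -= st[i].amp;
    }

    bool meas = t >= meas_start;
    if (meas && !meas_init) {
      for (int k = 0; k < nn; ++k) vrest[k] = V[k];
      meas_init = true;
    }
    if (tthin > 0 && meas && (s % tthin) == 0) {
      trace_times.push_back(t);
      traces.push_back(V);
    }

    // diffusion term
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int c = 0; c + 1 < nx; ++c) {
      const double *g = &gx[(size_t)c * ny];
      double *l0 = &lap[(size_t)c * ny], *l1 = &lap[(size_t)(c + 1) * ny];
      const double *v0 = &V[(size_t)c * ny], *v1 = &V[(size_t)(c + 1) * ny];
      for (int r = 0; r < ny; ++r) {
        double f = g[r] * (v1[r] - v0[r]);
        l0[r] += f;
        l1[r] -= f;
      }
    }
    if (ny > 1)
      for (int c = 0; c < nx; ++c) {
        const double *g = &gy[(size_t)c * (ny - 1)];
        double *l = &lap[(size_t)c * ny];
        const double *v = &V[(size_t)c * ny];
        for (int r = 0; r + 1 < ny; ++r) {
          double f = g[r] * (v[r + 1] - v[r]);
          l[r] += f;
          l[r + 1] -= f;
        }
      }

    // membrane update
    for (int k = 0; k < nn; ++k) {
      double *X = &S[(size_t)k * ORD_NSTATE];
      double Ist = stim_now[k];
      double Iion;
      X[0] = V[k];
      if (ct[k] == CT_FIB)
        Iion = fib_step(X, dt);
      else
        Iion = ord_step(X, (ct[k] == CT_MID) ? Tmid : Tepi, Ist);
      double vn = V[k] + dt * (lap[k] - Iion - Ist);
      if (!(vn > -200.0 && vn < 200.0))
        stop("numerical instability at node (%d, %d), t = %.3f ms",
             k % ny + 1, k / ny + 1, t);
      double dvdt = (vn - V[k]) / dt;
      double adv = dvdt < 0 ? -dvdt : dvdt;
      if (adv > step_maxdvdt) step_maxdvdt = adv;

      // upstroke crossings (whole run)
      if (V[k] <= upcross_level && vn > upcross_level) {
        ++upcount[k];
        if (nbin > 0) bins[(int)(t / upcross_bin)] += 1.0;
        if (meas) activated[k] = 1;
      }

      if (meas) {
        if (dvdt > dvdtmax[k]) {
          dvdtmax[k] = dvdt;
          act[k] = t + dt;
        }
        if (vn > vmax[k]) vmax[k] = vn;
        if (activated[k] && !repol_lock[k]) {
          double level = vmax[k] - 0.9 * (vmax[k] - vrest[k]);
          if (V[k] >= level && vn < level) {
            double frac = (V[k] - level) / (V[k] - vn);
            repol[k] = t + frac * dt;
            repol_lock[k] = 1;
          }
        } else if (repol_lock[k]) {
          // re-excitation invalidates the recorded repolarization
          double level = vmax[k] - 0.9 * (vmax[k] - vrest[k]);
          if (vn > level + 5.0) repol_lock[k] = 0;
        }
      }
      S[(size_t)k * ORD_NSTATE] = vn;  // keep state copy of v in sync
      V[k] = vn;
    }
    if ((s & 1023) == 0) Rcpp::checkUserInterrupt();

    // optional early exit once the whole tissue is electrically quiet
    if (quiet_stop > 0 && t >= quiet_after) {
      if (step_maxdvdt < 0.05)
        quiet_accum += dt;
      else
        quiet_accum = 0.0;
      if (quiet_accum >= quiet_stop) {
        t_end = t + dt;
        break;
      }
    }
  }

  auto mat = [&](std::vector<double> &x) {
    NumericMatrix m(ny, nx);
    std::copy(x.begin(), x.end(), m.begin());
    return m;
  };
  std::vector<double> vmax_out(vmax);
  for (int k = 0; k < nn; ++k)
    if (vmax_out[k] < -1e8) vmax_out[k] = NA_REAL;
  // censor activation/repolarization where no upstroke was detected
  std::vector<double> act_out(act), repol_out(repol);
  for (int k = 0; k < nn; ++k)
    if (!activated[k]) { act_out[k] = NA_REAL; repol_out[k] = NA_REAL; }
    else if (!repol_lock[k]) repol_out[k] = NA_REAL;

  NumericMatrix trace_mat(0, 0);
  if (!traces.empty()) {
    trace_mat = NumericMatrix(nn, (int)traces.size());
    for (size_t j = 0; j < traces.size(); ++j)
      std::copy(traces[j].begin(), traces[j].end(),
                trace_mat.begin() + (size_t)j * nn);
  }

  IntegerMatrix upc(ny, nx);
  std::copy(upcount.begin(), upcount.end(), upc.begin());

  List out = List::create(
      _["act"] = mat(act_out), _["repol"] = mat(repol_out),
      _["dvdtmax"] = mat(dvdtmax), _["vpeak"] = mat(vmax_out),
      _["vrest"] = mat(vrest), _["v_final"] = mat(V),
      _["upcross_count"] = upc,
      _["upcross_bins"] = NumericVector(bins.begin(), bins.end()),
      _["trace_times"] = NumericVector(trace_times.begin(), trace_times.end()),
      _["traces"] = trace_mat, _["t_end"] = t_end);
  if (return_state) {
    NumericMatrix F(nn, ORD_NSTATE);
    for (int k = 0; k < nn; ++k)
      for (int j = 0; j < ORD_NSTATE; ++j) F(k, j) = S[(size_t)k * ORD_NSTATE + j];
    out["state"] = F;
  }
  return out;
}
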