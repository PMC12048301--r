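#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-variable excitable-medium (Mitchell-Schaeffer) monodomain stepper.
//
//   dv/dt = h v^2 (1 - v) / tau_in - v / tau_out + D lap(v) + I_stim
//   dh/dt = (1 - h)/tau_open        if v <  v_gate
//         = -h / tau_close(x, y)    if v >= v_gate
//
// Forward Euler, 5-point Laplacian, no-flux (mirrored) boundaries.
// tau_close is a per-pixel field: scaling it controls local APD.
//
// Stimuli are point discs. A stimulus flagged "defer" is postponed in 1-ms
// steps while its site is refractory (v high or gate not recovered), up to
// defer_cap_ms, after which it is recorded as a capture failure.
//
// Ground truth per pixel: activation time = linear-interpolated upward
// crossing of v_up; repolarization at 80 % = downward crossing of v_down
// (= 20 % of the unit AP amplitude); APD80 = down-crossing - AT.

// [[Rcpp::export]]
List ms_simulate_cpp(int nr, int nc, double dx, double D, double dt,
                     NumericMatrix tau_close,
                     double tau_in, double tau_out, double tau_open,
                     double v_gate,
                     double duration_ms, double frame_ms,
                     NumericVector stim_t0, NumericVector stim_dur,
                     IntegerVector stim_row, IntegerVector stim_col,
                     NumericVector stim_radius_px, NumericVector stim_amp,
                     LogicalVector stim_defer, IntegerVector stim_chain,
                     double defer_cap_ms,
                     double v_up, double v_down, int max_beats,
                     NumericVector v0, NumericVector h0) {
  const int npx = nr * nc;
  const int nsteps = (int) std::round(duration_ms / dt);
  const int frame_every = (int) std::round(frame_ms / dt);
  const int nframes = nsteps / frame_every + 1;
  const int nstim = stim_t0.size();
  const double r2dx = D / (dx * dx);

  std::vector<double> v(npx), h(npx), vnew(npx);
  if (v0.size() == npx) {
    for (int i = 0; i < npx; ++i) { v[i] = v0[i]; h[i] = h0[i]; }
  } else {
    for (int i = 0; i < npx; ++i) { v[i] = 0.0; h[i] = 1.0; }
  }

  NumericVector frames((R_xlen_t) npx * nframes);
  NumericMatrix at(npx, max_beats), apd(npx, max_beats);
  std::fill(at.begin(), at.end(), NA_REAL);
  std::fill(apd.begin(), apd.end(), NA_REAL);
  IntegerVector nbeats(npx);
  std::vector<int> inap(npx, 0);

  // stimulus state: 0 = pending, 1 = active/started, 2 = done, 3 = failed
  std::vector<int> sstate(nstim, 0);
  NumericVector realized(nstim); std::fill(realized.begin(), realized.end(), NA_REAL);
  LogicalVector failed(nstim, false);
  // scheduled time actually used (shifts when deferred). A stimulus with
  // stim_chain >= 0 is scheduled relative to its predecessor's realized
  // delivery: stim_t0 then holds the offset, and the schedule resolves
  // once the predecessor has fired (or failed).
  std::vector<double> sched(nstim), sched0(nstim);
  std::vector<bool> resolved(nstim);
  for (int s = 0; s < nstim; ++s) {
    sched[s] = sched0[s] = stim_t0[s];
    resolved[s] = stim_chain[s] < 0;
  }

  // precompute per-stimulus pixel lists
  std::vector< std::vector<int> > spix(nstim);
  for (int s = 0; s < nstim; ++s) {
    double rad = stim_radius_px[s];
    int r0 = stim_row[s], c0 = stim_col[s];
    int ri = (int) std::ceil(rad);
    for (int ccol = std::max(0, c0 - ri); ccol <= std::min(nc - 1, c0 + ri); ++ccol)
      for (int rrow = std::max(0, r0 - ri); rrow <= std::min(nr - 1, r0 + ri); ++rrow) {
        double dr = rrow - r0, dcc = ccol - c0;
        if (dr * dr + dcc * dcc <= rad * rad) spix[s].push_back(rrow + nr * ccol);
      }
  }

  // frame 0
  for (int i = 0; i < npx; ++i) frames[i] = v[i];
  int fidx = 1;

  std::vector<double> stim_cur(npx, 0.0);

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;          // time at start of step
    // --- stimulus bookkeeping ---
    bool any_stim = false;
    std::fill(stim_cur.begin(), stim_cur.end(), 0.0);
    for (int s = 0; s < nstim; ++s) {
      if (!resolved[s]) {
        int p = stim_chain[s];
        if (sstate[p] >= 1) {
          double base = R_finite(realized[p]) ? realized[p] : sched[p];
          sched[s] = sched0[s] = base + stim_t0[s];
          resolved[s] = true;
        } else continue;
      }
      if (sstate[s] == 0 && t >= sched[s] - 1e-9) {
        if (stim_defer[s]) {
          int site = stim_row[s] + nr * stim_col[s];
          bool refract = (v[site] > 0.18) || (h[site] < 0.30);
          if (refract) {
            if (sched[s] - sched0[s] >= defer_cap_ms - 1e-9) {
              sstate[s] = 3; failed[s] = true;
            } else {
              sched[s] += 1.0;     // retry 1 ms later
            }
            continue;
          }
        }
        sstate[s] = 1; realized[s] = sched[s];
      }
      if (sstate[s] == 1) {
        if (t >= realized[s] + stim_dur[s]) { sstate[s] = 2; continue; }
        any_stim = true;
        for (size_t k = 0; k < spix[s].size(); ++k) stim_cur[spix[s][k]] += stim_amp[s];
      }
    }
    (void) any_stim;

    // --- PDE update ---
    for (int c = 0; c < nc; ++c) {
      int cl = (c == 0) ? 1 : c - 1;
      int cr = (c == nc - 1) ? nc - 2 : c + 1;
      const double *vc = &v[nr * c], *vl = &v[nr * cl], *vr = &v[nr * cr];
      double *vn = &vnew[nr * c];
      for (int r = 0; r < nr; ++r) {
        int ru = (r == 0) ? 1 : r - 1;
        int rd = (r == nr - 1) ? nr - 2 : r + 1;
        double vv = vc[r];
        double lap = (vl[r] + vr[r] + vc[ru] + vc[rd] - 4.0 * vv) * r2dx;
        int i = r + nr * c;
        double hh = h[i];
        double dvdt = hh * vv * vv * (1.0 - vv) / tau_in - vv / tau_out
                      + lap + stim_cur[i];
        vn[r] = vv + dt * dvdt;
        // gate
        if (vv < v_gate) h[i] = hh + dt * (1.0 - hh) / tau_open;
        else             h[i] = hh - dt * hh / tau_close(r, c);
        if (h[i] > 1.0) h[i] = 1.0;
        if (h[i] < 0.0) h[i] = 0.0;
      }
    }

    double tnew = t + dt;
    // --- truth crossings ---
    for (int i = 0; i < npx; ++i) {
      double vp = v[i], vq = vnew[i];
      if (!inap[i] && vp < v_up && vq >= v_up) {
        if (nbeats[i] < max_beats) {
          double frac = (v_up - vp) / (vq - vp);
          at(i, nbeats[i]) = t + frac * dt;
        }
        inap[i] = 1;
      } else if (inap[i] && vp >= v_down && vq < v_down) {
        if (nbeats[i] < max_beats) {
          double frac = (vp - v_down) / (vp - vq);
          double tdown = t + frac * dt;
          if (!NumericVector::is_na(at(i, nbeats[i])))
            apd(i, nbeats[i]) = tdown - at(i, nbeats[i]);
          nbeats[i] += 1;
        }
        inap[i] = 0;
      }
    }
    std::swap(v, vnew);

    // --- frame capture ---
    if ((step + 1) % frame_every == 0 && fidx < nframes) {
      double *dst = &frames[(R_xlen_t) npx * fidx];
      for (int i = 0; i < npx; ++i) dst[i] = v[i];
      ++fidx;
    }
    (void) tnew;
  }

  frames.attr("dim") = IntegerVector::create(nr, nc, nframes);
  NumericVector vout(npx), hout(npx);
  for (int i = 0; i < npx; ++i) { vout[i] = v[i]; hout[i] = h[i]; }

  return List::create(
    _["frames"] = frames,
    _["at"] = at, _["apd"] = apd, _["nbeats"] = nbeats,
    _["stim_realized_ms"] = realized, _["stim_failed"] = failed,
    _["v_final"] = vout, _["h_final"] = hout,
    _["n_frames"] = fidx);
}

// Pseudo-ECG forward model: phi(t) = sum_px grad(V) . grad(1/r) * dA.
// lead_gr, lead_gc are the precomputed components of grad(1/r) at each pixel
// (same layout as a frame). Gradient of V by central differences with
// one-sided differences at the edges.

// [[Rcpp::export]]
NumericVector pseudo_ecg_cpp(NumericVector frames, int nr, int nc,
                             NumericMatrix lead_gr, NumericMatrix lead_gc,
                             double dx) {
  IntegerVector dim = frames.attr("dim");
  int nframes = dim[2];
  NumericVector out(nframes);
  double area = dx * dx;
  for (int f = 0; f < nframes; ++f) {
    const double *fr = &frames[(R_xlen_t) nr * nc * f];
    double acc = 0.0;
    for (int c = 0; c < nc; ++c) {
      int cl = (c == 0) ? 0 : c - 1;
      int cr = (c == nc - 1) ? nc - 1 : c + 1;
      double wc = (cr - cl) * dx;
      for (int r = 0; r < nr; ++r) {
        int ru = (r == 0) ? 0 : r - 1;
        int rd = (r == nr - 1) ? nr - 1 : r + 1;
        double wr = (rd - ru) * dx;
        double gvr = (fr[rd + nr * c] - fr[ru + nr * c]) / wr;
        double gvc = (fr[r + nr * cr] - fr[r + nr * cl]) / wc;
        acc += (gvr * lead_gr(r, c) + gvc * lead_gc(r, c)) * area;
      }
    }
    out[f] = acc;
  }
  return out;
}
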