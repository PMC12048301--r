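#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Fast path of the per-pixel map-extraction chain (conditioning,
// activation detection by maximum derivative, APD at a repolarization
// level). Mirrors the reference R implementation in signal_maps.R
// exactly; an equivalence test in the suite holds the two paths together.

static double quantile7(std::vector<double> v, double q) {
  int n = v.size();
  if (n == 0) return NA_REAL;
  double h = (n - 1) * q;            // 0-based: h = (n-1)q, lo = floor
  int lo = (int) std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  std::nth_element(v.begin(), v.begin() + lo, v.end());
  double vlo = v[lo];
  double vhi = vlo;
  if (hi != lo) {
    vhi = *std::min_element(v.begin() + lo + 1, v.end());
  }
  return vlo + (h - lo) * (vhi - vlo);
}

static double median_of(std::vector<double> v) {
  return quantile7(std::move(v), 0.5);
}

// [[Rcpp::export]]
List map_chain_cpp(NumericMatrix M, double frame_ms, double t0_ms,
                   NumericMatrix windows,
                   double baseline_win_ms, double baseline_q,
                   double snr_min, double min_window_amp_frac,
                   double deriv_frac, double min_upstroke,
                   double apd_level, NumericVector sg_kernel) {
  const int npx = M.nrow();
  const int nt = M.ncol();
  const int nw = windows.nrow();
  NumericMatrix at_out(npx, nw), apd_out(npx, nw);
  std::fill(at_out.begin(), at_out.end(), NA_REAL);
  std::fill(apd_out.begin(), apd_out.end(), NA_REAL);

  // chunked-baseline geometry (shared across pixels)
  int w = std::max(3, (int) std::round(baseline_win_ms / frame_ms));
  std::vector<int> starts, mids;
  {
    int by = std::max(1, w / 2);
    int last = -1;
    for (int s = 1; s <= nt; s += by) {
      int st = std::min(s, nt - 1);
      if (st == last) continue;
      last = st;
      starts.push_back(st);
      mids.push_back(std::min(st + w / 2, nt));
    }
  }
  const int nch = starts.size();

  // window sample index ranges (1-based, as in R)
  std::vector<int> wi0(nw), wi1(nw), wnb(nw);
  for (int k = 0; k < nw; ++k) {
    wi0[k] = std::max(1, (int) std::ceil((windows(k, 0) - t0_ms) / frame_ms) + 1);
    wi1[k] = std::min(nt, (int) std::floor((windows(k, 1) - t0_ms) / frame_ms) + 1);
    int len = wi1[k] - wi0[k] + 1;
    wnb[k] = std::max(3, std::min((int) std::round(50.0 / frame_ms), len / 4));
  }

  const int klen = sg_kernel.size();
  const int khalf = klen / 2;
  const int look = std::max(2, (int) std::round(30.0 / frame_ms));

  std::vector<double> x(nt), base(nt), bl(nch);

  for (int p = 0; p < npx; ++p) {
    for (int i = 0; i < nt; ++i) x[i] = M(p, i);
    // polarity from derivative asymmetry
    if (nt > 3) {
      double dmax = -INFINITY, dmin = INFINITY;
      for (int i = 1; i < nt; ++i) {
        double d = x[i] - x[i - 1];
        if (d > dmax) dmax = d;
        if (d < dmin) dmin = d;
      }
      if (dmax + dmin < 0) for (int i = 0; i < nt; ++i) x[i] = -x[i];
    }
    // chunked running-percentile baseline, linearly interpolated
    for (int c = 0; c < nch; ++c) {
      int s = starts[c];
      int e = std::min(nt, s + w - 1);
      bl[c] = quantile7(std::vector<double>(x.begin() + s - 1, x.begin() + e),
                        baseline_q);
    }
    for (int i = 1; i <= nt; ++i) {
      double b;
      if (i <= mids[0]) b = bl[0];
      else if (i >= mids[nch - 1]) b = bl[nch - 1];
      else {
        int c = 0;
        while (c < nch - 1 && mids[c + 1] < i) ++c;
        double f = (double)(i - mids[c]) / (mids[c + 1] - mids[c]);
        b = bl[c] + f * (bl[c + 1] - bl[c]);
      }
      x[i - 1] -= b;
    }
    double lo = quantile7(x, 0.02), hi = quantile7(x, 0.98);
    std::vector<double> adx(nt - 1);
    for (int i = 1; i < nt; ++i) adx[i - 1] = std::fabs(x[i] - x[i - 1]);
    double noise_sd = 1.4826 * median_of(std::move(adx)) / std::sqrt(2.0);
    double amplitude = hi - lo;
    bool valid = R_finite(amplitude) && amplitude > 0 &&
      (noise_sd == 0 || amplitude / noise_sd >= snr_min);
    if (!valid) continue;

    for (int k = 0; k < nw; ++k) {
      if (wi1[k] - wi0[k] < 2) continue;
      int i0 = wi0[k] - 1, i1 = wi1[k] - 1;   // 0-based inclusive
      int len = i1 - i0 + 1;
      // per-window normalization
      double b = median_of(std::vector<double>(x.begin() + i0,
                                               x.begin() + i0 + wnb[k]));
      double mx = -INFINITY;
      for (int i = i0; i <= i1; ++i) if (x[i] > mx) mx = x[i];
      double a = mx - b;
      bool ok = R_finite(a) && a > 0 &&
        (noise_sd == 0 || a / noise_sd >= snr_min) &&
        a >= min_window_amp_frac * amplitude;
      if (!ok) continue;
      std::vector<double> xw(len);
      for (int i = 0; i < len; ++i) xw[i] = (x[i0 + i] - b) / a;

      // optional symmetric-FIR smoothing (edges keep raw samples)
      std::vector<double> xs(xw);
      if (klen > 0 && len > klen) {
        for (int i = khalf; i < len - khalf; ++i) {
          double acc = 0;
          for (int j = 0; j < klen; ++j) acc += sg_kernel[j] * xw[i + j - khalf];
          xs[i] = acc;
        }
      }
      // derivative, candidates, earliest qualifying upstroke
      int nd = len - 1;
      std::vector<double> d(nd);
      double dmax = -INFINITY;
      for (int i = 0; i < nd; ++i) {
        d[i] = (xs[i + 1] - xs[i]) / frame_ms;
        if (d[i] > dmax) dmax = d[i];
      }
      if (!(dmax > 0)) continue;
      double thr = deriv_frac * dmax;
      double at = NA_REAL;
      for (int c0 = 0; c0 < nd; ++c0) {
        if (d[c0] < thr) continue;
        double dprev = (c0 > 0) ? d[c0 - 1] : -INFINITY;
        double dnext = (c0 < nd - 1) ? d[c0 + 1] : -INFINITY;
        if (!(d[c0] >= dprev && d[c0] >= dnext)) continue;
        double reach = -INFINITY;
        for (int i = c0; i <= std::min(len - 1, c0 + look); ++i)
          if (xs[i] > reach) reach = xs[i];
        if (reach - xs[c0] < min_upstroke) continue;
        double off = 0;
        if (c0 > 0 && c0 < nd - 1) {
          double den = d[c0 - 1] - 2 * d[c0] + d[c0 + 1];
          if (std::fabs(den) > 2.220446e-16)
            off = 0.5 * (d[c0 - 1] - d[c0 + 1]) / den;
          off = std::max(-0.5, std::min(0.5, off));
        }
        // R indexing: candidate index c0R = c0+1; AT = tt0+(c0R-0.5+off)*f
        double tt0 = t0_ms + (wi0[k] - 1) * frame_ms;
        at = tt0 + (c0 + 0.5 + off) * frame_ms;
        break;
      }
      if (!R_finite(at)) continue;
      at_out(p, k) = at;

      // APD at the configured level (on the unsmoothed normalized window)
      double base2 = median_of(std::vector<double>(xw.begin(),
                                                   xw.begin() + wnb[k]));
      double tt0 = t0_ms + (wi0[k] - 1) * frame_ms;
      int first_after = -1;
      for (int i = 0; i < len; ++i) {
        double ti = tt0 + i * frame_ms;
        if (ti >= at) { first_after = i; break; }
      }
      if (first_after < 0 || len - first_after < 3) continue;
      int pk = first_after;
      for (int i = first_after; i < len; ++i)
        if (xw[i] > xw[pk]) pk = i;
      double amp2 = xw[pk] - base2;
      if (!(amp2 > 0)) continue;
      double target = base2 + (1 - apd_level) * amp2;
      double apd = NA_REAL;
      for (int i = pk; i < len - 1; ++i) {
        if (xw[i] >= target && xw[i + 1] < target) {
          double frac = (xw[i] - target) / (xw[i] - xw[i + 1]);
          apd = tt0 + (i + frac) * frame_ms - at;
          break;
        }
      }
      if (!R_finite(apd) && apd_level >= 1) {
        for (int i = pk; i < len - 1; ++i) {
          if (xw[i + 1] <= target + 1e-12) {
            apd = tt0 + (i + 1) * frame_ms - at;
            break;
          }
        }
      }
      if (R_finite(apd)) apd_out(p, k) = apd;
    }
  }
  return List::create(_["at"] = at_out, _["apd"] = apd_out);
}
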