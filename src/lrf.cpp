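#include <Rcpp.h>
using namespace Rcpp;

// First-order low-pass (per-step update x += (I - x)/tau) of piecewise-
// constant illumination. illum: units x frames, each frame held for
// steps_per_frame 1-ms steps. Returns units x (frames * steps_per_frame).
// [[Rcpp::export]]
NumericMatrix cpp_lrf_filter(NumericMatrix illum, double tau,
                             int steps_per_frame, NumericVector init) {
  const int n = illum.nrow(), nf = illum.ncol();
  NumericMatrix out(n, nf * steps_per_frame);
  for (int i = 0; i < n; ++i) {
    double a = init[i];
    int t = 0;
    for (int k = 0; k < nf; ++k) {
      const double I = illum(i, k);
      for (int u = 0; u < steps_per_frame; ++u) {
        a += (I - a) / tau;
        out(i, t++) = a;
      }
    }
  }
  return out;
}

// Windowed peak of the full center-surround response C - f*S for a set of
// surround factors. Center and surround activations follow the same
// per-step update with their own time constants, driven by piecewise-
// constant illumination. Windows are half-open [lo, hi) in 1-ms steps,
// 0-based, one per unit; a unit with lo >= hi yields NA. Segments entirely
// before the window are advanced with the closed-form geometric update.
// [[Rcpp::export]]
NumericMatrix cpp_lrf_peaks(NumericMatrix illum_c, NumericMatrix illum_s,
                            double tau_c, double tau_s, int steps_per_frame,
                            NumericVector factors,
                            NumericVector init_c, NumericVector init_s,
                            IntegerVector win_lo, IntegerVector win_hi) {
  const int n = illum_c.nrow(), nf = illum_c.ncol(), nfac = factors.size();
  const double seg_c = std::pow(1.0 - 1.0 / tau_c, steps_per_frame);
  const double seg_s = std::pow(1.0 - 1.0 / tau_s, steps_per_frame);
  NumericMatrix out(n, nfac);
  for (int i = 0; i < n; ++i) {
    const int lo = win_lo[i], hi = win_hi[i];
    if (lo >= hi) {
      for (int f = 0; f < nfac; ++f) out(i, f) = NA_REAL;
      continue;
    }
    double c = init_c[i], s = init_s[i];
    std::vector<double> best(nfac, R_NegInf);
    int t = 0;
    for (int k = 0; k < nf && t < hi; ++k) {
      const double Ic = illum_c(i, k), Is = illum_s(i, k);
      if (t + steps_per_frame <= lo) {
        c = Ic + (c - Ic) * seg_c;
        s = Is + (s - Is) * seg_s;
        t += steps_per_frame;
        continue;
      }
      for (int u = 0; u < steps_per_frame && t < hi; ++u) {
        c += (Ic - c) / tau_c;
        s += (Is - s) / tau_s;
        if (t >= lo) {
          for (int f = 0; f < nfac; ++f) {
            const double v = c - factors[f] * s;
            if (v > best[f]) best[f] = v;
          }
        }
        ++t;
      }
    }
    for (int f = 0; f < nfac; ++f) out(i, f) = best[f];
  }
  return out;
}
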