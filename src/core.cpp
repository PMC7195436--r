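// Hot loops: Euler-Maruyama integration of the driven bistable model with
// the ictal/refractory state machine, and the batch ACF half-width walk.
#include <Rcpp.h>
using namespace Rcpp;

// Integrate dz = (-z^3 + 1e-3 r z + 1e-3 k) dt + dW with seizure holds.
// noise is pre-scaled (sd * sqrt(dt)); dur_steps is a pool of pre-drawn
// ictal durations in integrator steps (consumed in order).
// Returns z trace plus onset indices (1-based) and the durations used.
// [[Rcpp::export(name = ".em_integrate")]]
List em_integrate(double z0, double dt, double r,
                  NumericVector k, NumericVector noise,
                  NumericVector zth, NumericVector zlo,
                  IntegerVector dur_steps, int refr_steps,
                  double sanity_bound) {
  int n = k.size();
  NumericVector z(n);
  std::vector<int> onsets;
  std::vector<int> durs;
  z[0] = z0;
  int ictal_until = -1, refr_until = -1, next_dur = 0;
  double r3 = 1e-3 * r;
  for (int i = 1; i < n; ++i) {
    double zi = z[i - 1];
    z[i] = zi + (-zi * zi * zi + r3 * zi + 1e-3 * k[i - 1]) * dt + noise[i];
    if (std::abs(z[i]) > sanity_bound)
      stop("step-size error: trajectory diverged (|z| > %g)", sanity_bound);
    if (i <= ictal_until) continue;
    if (ictal_until > 0 && i == ictal_until + 1) {
      z[i] = zlo[i];
      refr_until = i + refr_steps;
      ictal_until = -1;
      continue;
    }
    if (i <= refr_until) {
      if (z[i] > zth[i]) z[i] = zlo[i];  // post-ictal suppression
      continue;
    }
    if (z[i] > zth[i] && z[i - 1] <= zth[i - 1]) {
      int d = dur_steps[next_dur % dur_steps.size()];
      next_dur++;
      onsets.push_back(i + 1);  // 1-based for R
      durs.push_back(d);
      ictal_until = i + (d > 0 ? d : 1);
    }
  }
  return List::create(_["z"] = z, _["onset_idx"] = wrap(onsets),
                      _["dur_steps"] = wrap(durs));
}

// Template spike counts per column of Y: signed Pearson correlation of the
// template against every window, local maxima above threshold, greedy
// non-overlap suppression of one template length.
// [[Rcpp::export(name = ".spike_counts_cols")]]
IntegerVector spike_counts_cols(NumericMatrix Y, NumericVector tpl,
                                double threshold) {
  int T = Y.nrow(), n = Y.ncol(), L = tpl.size();
  int nw = T - L + 1;
  double tmu = 0;
  for (int l = 0; l < L; ++l) tmu += tpl[l];
  tmu /= L;
  std::vector<double> tc(L);
  double st2 = 0;
  for (int l = 0; l < L; ++l) { tc[l] = tpl[l] - tmu; st2 += tc[l] * tc[l]; }
  double st = std::sqrt(st2);
  IntegerVector counts(n);
  std::vector<double> r(nw);
  for (int j = 0; j < n; ++j) {
    // running window sums for mean/sd
    double ws = 0, ws2 = 0;
    for (int t = 0; t < L; ++t) { ws += Y(t, j); ws2 += Y(t, j) * Y(t, j); }
    bool any_hit = false;
    for (int s = 0; s < nw; ++s) {
      if (s > 0) {
        double out = Y(s - 1, j), in = Y(s + L - 1, j);
        ws += in - out;
        ws2 += in * in - out * out;
      }
      double num = 0;
      for (int l = 0; l < L; ++l) num += tc[l] * Y(s + l, j);
      double den = std::sqrt(std::max(ws2 - ws * ws / L, 0.0)) * st;
      r[s] = (den > 1e-12) ? num / den : 0.0;
      if (r[s] > threshold) any_hit = true;
    }
    if (!any_hit) { counts[j] = 0; continue; }
    // local maxima above threshold
    std::vector<std::pair<double, int> > cand;
    for (int s = 0; s < nw; ++s) {
      double prev = (s > 0) ? r[s - 1] : R_NegInf;
      double next = (s < nw - 1) ? r[s + 1] : R_NegInf;
      if (r[s] > threshold && r[s] >= prev && r[s] > next)
        cand.push_back(std::make_pair(-r[s], s));
    }
    std::sort(cand.begin(), cand.end());
    std::vector<int> keep;
    for (size_t c = 0; c < cand.size(); ++c) {
      int p = cand[c].second;
      bool ok = true;
      for (size_t k = 0; k < keep.size(); ++k)
        if (std::abs(p - keep[k]) < L) { ok = false; break; }
      if (ok) keep.push_back(p);
    }
    counts[j] = keep.size();
  }
  return counts;
}

// First downward 0.5-crossing (linear interpolation) of the biased ACF of
// each column of Y; width = max_lag with saturated flag if never reached.
// [[Rcpp::export(name = ".halfwidth_cols")]]
List halfwidth_cols(NumericMatrix Y, int max_lag) {
  int T = Y.nrow(), n = Y.ncol();
  NumericVector width(n), variance(n);
  LogicalVector saturated(n);
  for (int j = 0; j < n; ++j) {
    double mu = 0;
    for (int t = 0; t < T; ++t) mu += Y(t, j);
    mu /= T;
    double V = 0;
    for (int t = 0; t < T; ++t) {
      double d = Y(t, j) - mu;
      V += d * d;
    }
    V /= T;
    variance[j] = V;
    if (V <= 0) { width[j] = NA_REAL; saturated[j] = false; continue; }
    double c_prev = 1.0;
    double w = NA_REAL;
    bool sat = true;
    for (int lag = 1; lag <= max_lag; ++lag) {
      double s = 0;
      for (int t = 0; t + lag < T; ++t)
        s += (Y(t, j) - mu) * (Y(t + lag, j) - mu);
      double c = s / (T * V);
      if (c <= 0.5) {
        w = (lag - 1) + (c_prev - 0.5) / (c_prev - c);
        sat = false;
        break;
      }
      c_prev = c;
    }
    if (sat) w = max_lag;
    width[j] = w;
    saturated[j] = sat;
  }
  return List::create(_["width"] = width, _["saturated"] = saturated,
                      _["variance"] = variance);
}
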