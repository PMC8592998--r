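#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed IIR filter of one vector. b and a must be
// zero-padded to equal length (a[0] assumed 1).
static void iir_filter(const std::vector<double>& b,
                       const std::vector<double>& a,
                       const std::vector<double>& x,
                       std::vector<double>& y) {
  const int n = (int)x.size();
  const int nz = (int)b.size() - 1;
  std::vector<double> z(nz + 1, 0.0);   // one spare slot, always 0
  y.resize(n);
  const double* bp = b.data();
  const double* ap = a.data();
  double* zp = z.data();
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bp[0] * xi + zp[0];
    for (int j = 0; j < nz; ++j)
      zp[j] = bp[j + 1] * xi + zp[j + 1] - ap[j + 1] * yi;
    zp[nz] = 0.0;
    y[i] = yi;
  }
}

// Zero-phase (forward-backward) filtering of each column of X with odd
// reflect padding of length npad at both ends. Coefficients come from
// signal::butter; this only applies them.
// [[Rcpp::export]]
NumericMatrix cpp_filtfilt_mat(NumericVector b, NumericVector a,
                               NumericMatrix X, int npad) {
  const int n = X.nrow(), p = X.ncol();
  if (npad >= n) npad = n - 1;
  if (npad < 0) npad = 0;
  std::vector<double> bc(b.begin(), b.end()), ac(a.begin(), a.end());
  while (bc.size() < ac.size()) bc.push_back(0.0);
  while (ac.size() < bc.size()) ac.push_back(0.0);
  NumericMatrix out(n, p);
  const int ntot = n + 2 * npad;
  std::vector<double> xp(ntot), tmp(ntot), rev(ntot);
  for (int c = 0; c < p; ++c) {
    // odd reflection: 2*x[0] - x[npad..1], x, 2*x[n-1] - x[n-2..]
    for (int i = 0; i < npad; ++i) xp[i] = 2.0 * X(0, c) - X(npad - i, c);
    for (int i = 0; i < n; ++i) xp[npad + i] = X(i, c);
    for (int i = 0; i < npad; ++i)
      xp[npad + n + i] = 2.0 * X(n - 1, c) - X(n - 2 - i, c);
    iir_filter(bc, ac, xp, tmp);
    for (int i = 0; i < ntot; ++i) rev[i] = tmp[ntot - 1 - i];
    iir_filter(bc, ac, rev, tmp);
    for (int i = 0; i < n; ++i) out(i, c) = tmp[ntot - 1 - npad - i];
  }
  return out;
}

// GEVI response dynamics: two parallel first-order states relaxing
// toward the per-sample steady-state target; on-kinetics when the
// target deviation (from the resting steady state `base`) exceeds the
// current response deviation, off-kinetics otherwise. Returns the
// response baselined to zero at rest.
// [[Rcpp::export]]
NumericMatrix cpp_gevi_dynamics(NumericMatrix target, double base, double dt,
                                double tau_on_f, double tau_on_s,
                                double frac_on,
                                double tau_off_f, double tau_off_s,
                                double frac_off) {
  const int n = target.nrow(), p = target.ncol();
  const double a_on_f = 1.0 - std::exp(-dt / tau_on_f);
  const double a_on_s = 1.0 - std::exp(-dt / tau_on_s);
  const double a_off_f = 1.0 - std::exp(-dt / tau_off_f);
  const double a_off_s = 1.0 - std::exp(-dt / tau_off_s);
  NumericMatrix out(n, p);
  for (int c = 0; c < p; ++c) {
    double x1 = base, x2 = base, y = base;
    for (int i = 0; i < n; ++i) {
      const double tgt = target(i, c);
      const bool on = std::fabs(tgt - base) >= std::fabs(y - base);
      const double af = on ? a_on_f : a_off_f;
      const double as = on ? a_on_s : a_off_s;
      const double fr = on ? frac_on : frac_off;
      x1 += af * (tgt - x1);
      x2 += as * (tgt - x2);
      y = fr * x1 + (1.0 - fr) * x2;
      out(i, c) = y - base;
    }
  }
  return out;
}

// Greedy correlation-ordered averaging: columns of X are pixel
// waveforms already sorted by descending correlation with the
// reference. Adds one pixel at a time; SNR of the running average =
// max|smoothed avg| / sd(raw avg over the first nbase samples). The
// peak is taken on a short moving average (smooth_n samples) so that
// single-sample noise at the peak does not jitter the stopping rule,
// and only over [peak_from, peak_to) so filter edge transients cannot
// pose as the peak. Stops once SNR stays below stop_ratio *
// best-so-far for `patience` consecutive additions; returns the
// average at the best SNR.
// [[Rcpp::export]]
List cpp_greedy_snr(NumericMatrix X, int nbase, double stop_ratio,
                    int smooth_n = 11, int patience = 5,
                    Nullable<IntegerVector> cols = R_NilValue,
                    int peak_from = 0, int peak_to = -1) {
  const int n = X.nrow();
  IntegerVector ord;
  if (cols.isNotNull()) ord = cols.get();           // 1-based column order
  else ord = seq_len(X.ncol());
  const int p = ord.size();
  if (peak_from < 0) peak_from = 0;
  if (peak_to < 0 || peak_to > n) peak_to = n;
  if (nbase > n) nbase = n;
  if (smooth_n < 1) smooth_n = 1;
  if (smooth_n > n) smooth_n = n;
  std::vector<double> s(n, 0.0), best_avg(n);
  double best_snr = -1.0;
  int best_k = 1, low_run = 0;
  std::vector<double> snr_path;
  snr_path.reserve(p);
  for (int k = 1; k <= p; ++k) {
    const int col = ord[k - 1] - 1;
    for (int i = 0; i < n; ++i) s[i] += X(i, col);
    const double inv = 1.0 / k;
    // moving-average peak over the guarded interior
    double acc = 0.0, peak = 0.0;
    const int pf = peak_from;
    const int pt = std::min(n, std::max(peak_to, pf + smooth_n));
    for (int i = pf; i < pf + smooth_n && i < n; ++i) acc += s[i];
    peak = std::fabs(acc) / smooth_n;
    for (int i = pf + smooth_n; i < pt; ++i) {
      acc += s[i] - s[i - smooth_n];
      const double v = std::fabs(acc) / smooth_n;
      if (v > peak) peak = v;
    }
    peak *= inv;
    double m = 0.0, m2 = 0.0;
    for (int i = 0; i < nbase; ++i) m += s[i] * inv;
    m /= nbase;
    for (int i = 0; i < nbase; ++i) {
      const double d = s[i] * inv - m;
      m2 += d * d;
    }
    const double sdv = std::sqrt(m2 / (nbase - 1));
    const double snr = (sdv > 0) ? peak / sdv : R_PosInf;
    snr_path.push_back(snr);
    if (snr >= best_snr) {   // ties extend the member set (flat SNR path)
      best_snr = snr;
      best_k = k;
      for (int i = 0; i < n; ++i) best_avg[i] = s[i] * inv;
    }
    if (snr < stop_ratio * best_snr) {
      if (++low_run >= patience) break;
    } else low_run = 0;
  }
  return List::create(_["n_members"] = best_k,
                      _["average"] = NumericVector(best_avg.begin(), best_avg.end()),
                      _["snr"] = best_snr,
                      _["snr_path"] = NumericVector(snr_path.begin(), snr_path.end()),
                      _["n_tried"] = (int)snr_path.size());
}

// k = 1 nearest-neighbour window scores. Training windows: every
// stride-1 window of length `win` fully inside [0, n_train). Each
// scored window (0-based start indices `starts`) gets the Euclidean
// distance to its nearest training window (early-abandon search).
// [[Rcpp::export]]
NumericVector cpp_knn_scores(NumericVector x, int win, int n_train,
                             IntegerVector starts) {
  const int n = x.size();
  const int t_last = n_train - win;  // last training start
  if (t_last < 0) stop("baseline shorter than the window");
  NumericVector out(starts.size());
  for (int q = 0; q < starts.size(); ++q) {
    const int s = starts[q];
    if (s < 0 || s + win > n) stop("scoring window out of range");
    double best = R_PosInf;
    for (int t = 0; t <= t_last; ++t) {
      double acc = 0.0;
      for (int i = 0; i < win; ++i) {
        const double d = x[s + i] - x[t + i];
        acc += d * d;
        if (acc >= best) break;
      }
      if (acc < best) best = acc;
      if (best == 0.0) break;
    }
    out[q] = std::sqrt(best);
  }
  return out;
}

// In-place GEVI transfer over a T x P voltage matrix: Boltzmann
// steady-state target + two-state on/off relaxation, baselined at the
// resting potential. X: voltage in, percent dF/F out.
// [[Rcpp::export]]
void cpp_gevi_transfer_ip(NumericMatrix X, double vhalf, double slope,
                          double dfmax, double rest, double dt,
                          double tau_on_f, double tau_on_s, double frac_on,
                          double tau_off_f, double tau_off_s,
                          double frac_off) {
  const int n = X.nrow(), p = X.ncol();
  const double base = dfmax / (1.0 + std::exp(-(rest - vhalf) / slope));
  const double a_on_f = 1.0 - std::exp(-dt / tau_on_f);
  const double a_on_s = 1.0 - std::exp(-dt / tau_on_s);
  const double a_off_f = 1.0 - std::exp(-dt / tau_off_f);
  const double a_off_s = 1.0 - std::exp(-dt / tau_off_s);
  for (int c = 0; c < p; ++c) {
    double x1 = base, x2 = base, y = base;
    for (int i = 0; i < n; ++i) {
      const double v = X(i, c);
      const double tgt = (v == rest)
        ? base : dfmax / (1.0 + std::exp(-(v - vhalf) / slope));
      const bool on = std::fabs(tgt - base) >= std::fabs(y - base);
      x1 += (on ? a_on_f : a_off_f) * (tgt - x1);
      x2 += (on ? a_on_s : a_off_s) * (tgt - x2);
      y = (on ? frac_on : frac_off) * x1 +
          (1.0 - (on ? frac_on : frac_off)) * x2;
      X(i, c) = y - base;
    }
  }
}

// In-place camera model: X holds percent dF/F on entry and camera
// counts on exit. counts = baseline * bleach[t] * (1 + X/100), dark
// columns replaced by dark_scale * baseline * bleach[t]; then a shared
// multiplicative illumination factor (1 + common[t]) if supplied,
// optional Poisson shot noise, Gaussian read noise, and clipping at 0.
// Uses R's RNG (seed with set.seed outside).
// [[Rcpp::export]]
void cpp_camera_ip(NumericMatrix X, NumericVector bleach, double baseline,
                   LogicalVector dark, double dark_scale,
                   NumericVector common, double noise_sd, bool shot) {
  const int n = X.nrow(), p = X.ncol();
  const bool has_common = common.size() > 0;
  for (int c = 0; c < p; ++c) {
    const bool is_dark = dark[c];
    for (int i = 0; i < n; ++i) {
      double v = is_dark ? dark_scale * baseline * bleach[i]
                         : baseline * bleach[i] * (1.0 + X(i, c) / 100.0);
      if (has_common) v *= 1.0 + common[i];
      if (shot) v = ::Rf_rpois(v > 0 ? v : 0.0);
      if (noise_sd > 0) v += ::norm_rand() * noise_sd;
      X(i, c) = v > 0 ? v : 0.0;
    }
  }
}

// In-place exponential-baseline handling: per column j the baseline is
// f0(t) = a[j] exp(-t/tau[j]) + c[j] (tau may be Inf). subtract = true
// removes it; otherwise X is divided by it and scaled to percent.
// [[Rcpp::export]]
void cpp_apply_baseline_ip(NumericMatrix X, NumericVector a,
                           NumericVector tau, NumericVector c0, double dt,
                           bool subtract) {
  const int n = X.nrow(), p = X.ncol();
  for (int c = 0; c < p; ++c) {
    const double aj = a[c], tj = tau[c], cj = c0[c];
    const bool flat = !R_FINITE(tj) || aj == 0.0;
    const double decay = flat ? 1.0 : std::exp(-dt / tj);
    double e = 1.0;
    for (int i = 0; i < n; ++i) {
      const double f0 = flat ? (aj + cj) : (aj * e + cj);
      if (subtract) X(i, c) -= f0;
      else X(i, c) = X(i, c) / f0 * 100.0;
      if (!flat) e *= decay;
    }
  }
}

// In-place variant of cpp_filtfilt_mat.
// [[Rcpp::export]]
void cpp_filtfilt_ip(NumericVector b, NumericVector a, NumericMatrix X,
                     int npad) {
  const int n = X.nrow(), p = X.ncol();
  if (npad >= n) npad = n - 1;
  if (npad < 0) npad = 0;
  std::vector<double> bc(b.begin(), b.end()), ac(a.begin(), a.end());
  while (bc.size() < ac.size()) bc.push_back(0.0);
  while (ac.size() < bc.size()) ac.push_back(0.0);
  const int ntot = n + 2 * npad;
  std::vector<double> xp(ntot), tmp(ntot), rev(ntot);
  for (int c = 0; c < p; ++c) {
    for (int i = 0; i < npad; ++i) xp[i] = 2.0 * X(0, c) - X(npad - i, c);
    for (int i = 0; i < n; ++i) xp[npad + i] = X(i, c);
    for (int i = 0; i < npad; ++i)
      xp[npad + n + i] = 2.0 * X(n - 1, c) - X(n - 2 - i, c);
    iir_filter(bc, ac, xp, tmp);
    for (int i = 0; i < ntot; ++i) rev[i] = tmp[ntot - 1 - i];
    iir_filter(bc, ac, rev, tmp);
    for (int i = 0; i < n; ++i) X(i, c) = tmp[ntot - 1 - npad - i];
  }
}

// Per-column maximum of |X| over rows [from, to) (optionally
// restricted to 1-based column indices `cols`, avoiding an R-side
// subset copy).
// [[Rcpp::export]]
NumericVector cpp_col_absmax(NumericMatrix X,
                             Nullable<IntegerVector> cols = R_NilValue,
                             int from = 0, int to = -1) {
  const int n = X.nrow();
  if (from < 0) from = 0;
  if (to < 0 || to > n) to = n;
  IntegerVector sel;
  if (cols.isNotNull()) sel = cols.get();
  else sel = seq_len(X.ncol());
  NumericVector out(sel.size());
  for (int k = 0; k < sel.size(); ++k) {
    const int c = sel[k] - 1;
    double m = 0.0;
    for (int i = from; i < to; ++i) {
      const double v = std::fabs(X(i, c));
      if (v > m) m = v;
    }
    out[k] = m;
  }
  return out;
}

// Event-anchored initiation index per column (1-based; 0 when absent):
// among runs of >= m consecutive samples with |x| > thr[j], runs closer
// than `gap` samples are chained into events, and the start of the
// event containing the column's largest qualifying excursion is
// returned. Searching starts at 0-based sample `from`.
// [[Rcpp::export]]
IntegerVector cpp_event_init(NumericMatrix X, NumericVector thr, int m,
                             int gap, int from = 0, int to = -1) {
  const int n = X.nrow(), p = X.ncol();
  if (from < 0) from = 0;
  if (to < 0 || to > n) to = n;
  IntegerVector out(p);
  std::vector<int> rs, re;
  std::vector<double> rpk;
  for (int c = 0; c < p; ++c) {
    const double t = thr[c];
    rs.clear(); re.clear(); rpk.clear();
    int run = 0;
    double pk = 0.0;
    for (int i = from; i < to; ++i) {
      const double v = std::fabs(X(i, c));
      if (v > t) {
        if (run == 0) pk = 0.0;
        ++run;
        if (v > pk) pk = v;
      } else if (run > 0) {
        if (run >= m) { rs.push_back(i - run); re.push_back(i - 1);
                        rpk.push_back(pk); }
        run = 0;
      }
    }
    if (run >= m) { rs.push_back(to - run); re.push_back(to - 1);
                    rpk.push_back(pk); }
    if (rs.empty()) { out[c] = 0; continue; }
    // chain runs into events and track each event's start and max peak
    int best_start = rs[0];
    double best_pk = rpk[0];
    int ev_start = rs[0];
    double ev_pk = rpk[0];
    for (size_t k = 1; k < rs.size(); ++k) {
      if (rs[k] - re[k - 1] - 1 > gap) {       // new event
        if (ev_pk > best_pk) { best_pk = ev_pk; best_start = ev_start; }
        ev_start = rs[k];
        ev_pk = rpk[k];
      } else if (rpk[k] > ev_pk) ev_pk = rpk[k];
    }
    if (ev_pk > best_pk) { best_pk = ev_pk; best_start = ev_start; }
    out[c] = best_start + 1;
  }
  return out;
}

// First index (1-based; 0 when absent) at which |X[,j]| > thr[j] for at
// least m consecutive samples.
// [[Rcpp::export]]
IntegerVector cpp_first_sustained(NumericMatrix X, NumericVector thr, int m) {
  const int n = X.nrow(), p = X.ncol();
  IntegerVector out(p);
  for (int c = 0; c < p; ++c) {
    const double t = thr[c];
    int run = 0, hit = 0;
    for (int i = 0; i < n; ++i) {
      if (std::fabs(X(i, c)) > t) {
        if (++run >= m) { hit = i - run + 2; break; }
      } else run = 0;
    }
    out[c] = hit;
  }
  return out;
}
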