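#include <Rcpp.h>
using namespace Rcpp;

// Sequentially generate beat times on [0, duration_s).
// Instantaneous RR (ms) at elapsed time t:
//   60000 / (hr_mesor + hr_amplitude * cos(2*pi*(clock_h - hr_acrophase_h)/24))
//   + lf_mod_ms * sin(2*pi*0.1*t) + hf_mod_ms * sin(2*pi*0.25*t) + noise_ms[k]
// noise_ms is pre-drawn in R so the stream is a pure function of the R RNG state.
// [[Rcpp::export]]
NumericVector gen_beat_times_cpp(double duration_s, double hr_mesor,
                                 double hr_amplitude, double hr_acrophase_h,
                                 double lf_mod_ms, double hf_mod_ms,
                                 NumericVector noise_ms, double start_clock_h) {
  std::vector<double> beats;
  beats.reserve(noise_ms.size());
  double t = 0.0;
  R_xlen_t k = 0;
  const double two_pi = 2.0 * M_PI;
  while (t < duration_s) {
    if (k >= noise_ms.size())
      stop("noise buffer exhausted before reaching requested duration");
    beats.push_back(t);
    double clock_h = start_clock_h + t / 3600.0;
    double hr = hr_mesor + hr_amplitude * std::cos(two_pi * (clock_h - hr_acrophase_h) / 24.0);
    if (hr <= 0.0) stop("circadian heart rate reached %f bpm (<= 0)", hr);
    double rr = 60000.0 / hr + lf_mod_ms * std::sin(two_pi * 0.1 * t) +
                hf_mod_ms * std::sin(two_pi * 0.25 * t) + noise_ms[k];
    if (rr <= 200.0)
      stop("simulated RR interval fell to %.1f ms (<= 200 ms); reduce modulation or noise", rr);
    t += rr / 1000.0;
    ++k;
  }
  return wrap(beats);
}

// Sample entropy with embedding dimension m, Chebyshev tolerance r.
// Counts template matches over i < j pairs at lengths m (B) and m+1 (A);
// returns -log(A/B), NA when either count is zero.
// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  R_xlen_t n = x.size();
  if (n < m + 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  R_xlen_t nm = n - m;  // number of m+1-length templates; m-length templates: use first n-m
  for (R_xlen_t i = 0; i < nm - 1; ++i) {
    for (R_xlen_t j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm <= r && (d >= dm ? d : dm) <= r) A += 1.0;
      }
    }
  }
  if (A <= 0.0 || B <= 0.0) return NA_REAL;
  return -std::log(A / B);
}
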