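#include <Rcpp.h>
using namespace Rcpp;

// Polyphase rational resampling (upfirdn): upsample by L, FIR filter h,
// downsample by M. The filter's group delay (h is odd-length, symmetric)
// is compensated so output sample m sits at input time m*M/L.
// [[Rcpp::export]]
NumericVector upfirdn_resample(NumericVector x, NumericVector h,
                               int L, int M, int n_out) {
  const int n = x.size();
  const int nh = h.size();
  const int delay = (nh - 1) / 2;
  NumericVector y(n_out);
  for (int m = 0; m < n_out; ++m) {
    const long long t = (long long)m * M + delay;
    long long i_lo = (t - nh + 1 + L - 1) / L; // ceil((t - nh + 1) / L)
    if (i_lo < 0) i_lo = 0;
    long long i_hi = t / L;
    if (i_hi > n - 1) i_hi = n - 1;
    double acc = 0.0;
    for (long long i = i_lo; i <= i_hi; ++i) {
      acc += h[t - i * L] * x[i];
    }
    y[m] = acc;
  }
  return y;
}
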