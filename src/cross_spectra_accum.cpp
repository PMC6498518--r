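#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate per-bin sufficient statistics of the imaginary cross-spectrum
// for one epoch's batched FFT.
//
// xf: nb x (ntaper * nchan) complex matrix, column (k*nchan + c) = taper k
//     applied to channel c (0-based).
// pi_idx/pj_idx: 1-based channel indices of the upper-triangle pairs.
// sum_sign/sum_imag/sum_abs: nb x npairs accumulators, updated in place
// (they are owned exclusively by the calling frame).
// [[Rcpp::export]]
void accum_cross_spectra(ComplexMatrix xf,
                         IntegerVector pi_idx,
                         IntegerVector pj_idx,
                         int nchan,
                         NumericMatrix sum_sign,
                         NumericMatrix sum_imag,
                         NumericMatrix sum_abs) {
  const int nb = xf.nrow();
  const int ntap = xf.ncol() / nchan;
  const int np = pi_idx.size();
  const Rcomplex* base = xf.begin();
  for (int p = 0; p < np; ++p) {
    const int ci = pi_idx[p] - 1;
    const int cj = pj_idx[p] - 1;
    double* ss = &sum_sign(0, p);
    double* si = &sum_imag(0, p);
    double* sa = &sum_abs(0, p);
    for (int k = 0; k < ntap; ++k) {
      const Rcomplex* xi = base + (size_t)(k * nchan + ci) * nb;
      const Rcomplex* xj = base + (size_t)(k * nchan + cj) * nb;
      for (int f = 0; f < nb; ++f) {
        const double im = xi[f].i * xj[f].r - xi[f].r * xj[f].i;
        si[f] += im;
        sa[f] += std::fabs(im);
        ss[f] += (im > 0) - (im < 0);
      }
    }
  }
}
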