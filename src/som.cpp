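#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential SOM training core. All randomness (initial weights, the
// presentation order for every epoch) is drawn in R beforehand, so this
// routine is fully deterministic given its arguments.
//
// Matrices arrive transposed (dimension-major) so that each sample and
// each cell weight vector is a contiguous column:
//   Xt:     d x n data (sample i = column i)
//   Wt:     d x ncell initial weights (modified copy returned)
// gr, gc:   per-cell grid row/col (0-based), length ncell
// orders:   n x epochs matrix of 1-based presentation orders
// lr0/lr_floor, rad0/rad_floor: linear decay over the total step count
// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(NumericMatrix Xt, NumericMatrix Wt,
                            IntegerVector gr, IntegerVector gc,
                            IntegerMatrix orders,
                            double lr0, double lr_floor,
                            double rad0, double rad_floor) {
  const int d = Xt.nrow(), n = Xt.ncol(), ncell = Wt.ncol();
  const int epochs = orders.ncol();
  const double total = (double) n * epochs;
  NumericMatrix Wout(clone(Wt));
  double *W = REAL(Wout);
  const double *X = REAL(Xt);
  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s, ++step) {
      const double *x = X + (size_t) (orders(s, e) - 1) * d;
      const double frac = total > 1 ? (double) step / (total - 1) : 0.0;
      const double lr = lr0 + (lr_floor - lr0) * frac;
      const double rad = rad0 + (rad_floor - rad0) * frac;
      // best matching unit (first minimum = smallest row-major cell index)
      int bmu = 0;
      double best = R_PosInf;
      for (int k = 0; k < ncell; ++k) {
        const double *w = W + (size_t) k * d;
        double acc = 0.0;
        for (int j = 0; j < d; ++j) {
          const double diff = w[j] - x[j];
          acc += diff * diff;
          if (acc >= best) break;
        }
        if (acc < best) { best = acc; bmu = k; }
      }
      const double two_sig2 = 2.0 * rad * rad;
      for (int k = 0; k < ncell; ++k) {
        const double dr = gr[k] - gr[bmu], dc = gc[k] - gc[bmu];
        const double h = std::exp(-(dr * dr + dc * dc) / two_sig2);
        const double step_k = lr * h;
        if (step_k < 1e-12) continue;
        double *w = W + (size_t) k * d;
        for (int j = 0; j < d; ++j) {
          w[j] += step_k * (x[j] - w[j]);
        }
      }
    }
  }
  return Wout;
}
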