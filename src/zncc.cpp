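#include <Rcpp.h>
using namespace Rcpp;

// Zero-normalized cross-correlation (ZNCC) search surfaces for subset
// matching. For every grid node the subset (interrogation window) of the
// reference frame is compared against all integer offsets within the search
// radius in the deformed frame.
//
// ref, def : matrices [rows, cols], same shape, row index = y, col index = x
// nx, ny   : 0-based node coordinates (x = column, y = row)
// half     : (subset_size - 1) / 2
// search   : search radius in px
//
// Returns a [2*search+1, 2*search+1, n_nodes] array; element [i, j, k]
// (1-based in R) is the ZNCC at offset (v = i - search - 1, u = j - search - 1)
// for node k. A node whose reference subset has zero variance yields an
// all-NA slice; an individual offset whose deformed window is flat yields NA.
// [[Rcpp::export]]
NumericVector zncc_surfaces(NumericMatrix ref, NumericMatrix def,
                            IntegerVector nx, IntegerVector ny,
                            int half, int search) {
  const int nrow = ref.nrow(), ncol = ref.ncol();
  const int nnode = nx.size();
  const int side = 2 * search + 1;
  const int sub = 2 * half + 1;
  const int npix = sub * sub;
  NumericVector out(Dimension(side, side, nnode));

  std::vector<double> tmpl(npix);
  for (int k = 0; k < nnode; ++k) {
    const int x0 = nx[k], y0 = ny[k];
    if (x0 - half - search < 0 || y0 - half - search < 0 ||
        x0 + half + search >= ncol || y0 + half + search >= nrow) {
      stop("node (%d, %d) too close to the border for subset half-width %d and search radius %d",
           x0, y0, half, search);
    }
    // reference subset statistics
    double tsum = 0.0, tsq = 0.0;
    int p = 0;
    for (int dx = -half; dx <= half; ++dx) {
      for (int dy = -half; dy <= half; ++dy) {
        const double v = ref(y0 + dy, x0 + dx);
        tmpl[p++] = v;
        tsum += v;
        tsq += v * v;
      }
    }
    const double tmean = tsum / npix;
    const double tvar = tsq - npix * tmean * tmean;
    if (tvar <= 1e-12) {
      for (int j = 0; j < side * side; ++j)
        out[k * side * side + j] = NA_REAL;
      continue;
    }
    const double tnorm = std::sqrt(tvar);
    for (int du = -search; du <= search; ++du) {
      for (int dv = -search; dv <= search; ++dv) {
        double wsum = 0.0, wsq = 0.0, cross = 0.0;
        p = 0;
        for (int dx = -half; dx <= half; ++dx) {
          const int xc = x0 + dx + du;
          for (int dy = -half; dy <= half; ++dy) {
            const double w = def(y0 + dy + dv, xc);
            wsum += w;
            wsq += w * w;
            cross += w * tmpl[p++];
          }
        }
        const double wmean = wsum / npix;
        const double wvar = wsq - npix * wmean * wmean;
        const int idx = k * side * side + (du + search) * side + (dv + search);
        if (wvar <= 1e-12) {
          out[idx] = NA_REAL;
        } else {
          out[idx] = (cross - npix * tmean * wmean) / (tnorm * std::sqrt(wvar));
        }
      }
    }
  }
  return out;
}
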