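// Gather/scatter kernels for the im2col 3D convolution: the only two
// memory-bound inner loops of the network.  Everything else stays in R/BLAS.
#include <Rcpp.h>
using namespace Rcpp;

// M[i, j + K*(c-1)] = P[idx[i, j], c]   (idx is 1-based)
// [[Rcpp::export(name = ".im2colGather")]]
NumericMatrix im2col_gather(const NumericMatrix& P, const IntegerMatrix& idx) {
  const int nOut = idx.nrow(), K = idx.ncol(), cin = P.ncol();
  NumericMatrix M(nOut, K * cin);
  for (int c = 0; c < cin; ++c) {
    const double* pc = &P(0, c);
    for (int j = 0; j < K; ++j) {
      double* mcol = &M(0, j + K * c);
      const int* id = &idx(0, j);
      for (int i = 0; i < nOut; ++i) mcol[i] = pc[id[i] - 1];
    }
  }
  return M;
}

// dP[idx[i, j], c] += dM[i, j + K*(c-1)]
// [[Rcpp::export(name = ".col2imScatter")]]
NumericMatrix col2im_scatter(const NumericMatrix& dM, const IntegerMatrix& idx,
                             const int padLen, const int cin) {
  const int nOut = idx.nrow(), K = idx.ncol();
  NumericMatrix dP(padLen, cin);
  for (int c = 0; c < cin; ++c) {
    double* pc = &dP(0, c);
    for (int j = 0; j < K; ++j) {
      const double* mcol = &dM(0, j + K * c);
      const int* id = &idx(0, j);
      for (int i = 0; i < nOut; ++i) pc[id[i] - 1] += mcol[i];
    }
  }
  return dP;
}
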