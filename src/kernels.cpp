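#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Layout convention for all volume tensors passed from R:
// numeric array with dim (d1, d2, d3, C); first index fastest (R column-major).
// Kernel offsets are ordered row = ((c*k + t3)*k + t2)*k + t1.

static inline int out_size(int d, int k, int s, int p) {
  return (d + 2 * p - k) / s + 1;
}

// Unfold a padded volume into patch rows for kernel-size-k convolution.
// Returns (o1*o2*o3) x (C*k^3) — patches as rows, so the innermost spatial
// loop writes contiguous memory; zero padding of width p.
// [[Rcpp::export]]
arma::mat vol2col(const NumericVector& x, int k, int stride, int pad) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("vol2col: input must be a 4-d array (d1,d2,d3,C)");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2], C = dm[3];
  const int o1 = out_size(d1, k, stride, pad);
  const int o2 = out_size(d2, k, stride, pad);
  const int o3 = out_size(d3, k, stride, pad);
  if (o1 < 1 || o2 < 1 || o3 < 1) stop("vol2col: kernel larger than padded input");
  const size_t P = (size_t)o1 * o2 * o3;
  arma::mat col(P, C * k * k * k, arma::fill::zeros);
  double* cp = col.memptr();
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)c * d1 * d2 * d3;
    for (int t3 = 0; t3 < k; ++t3) {
      for (int t2 = 0; t2 < k; ++t2) {
        for (int t1 = 0; t1 < k; ++t1) {
          const int row = ((c * k + t3) * k + t2) * k + t1;
          double* cr = cp + (size_t)row * P;
          for (int j3 = 0; j3 < o3; ++j3) {
            const int i3 = j3 * stride + t3 - pad;
            if (i3 < 0 || i3 >= d3) continue;
            for (int j2 = 0; j2 < o2; ++j2) {
              const int i2 = j2 * stride + t2 - pad;
              if (i2 < 0 || i2 >= d2) continue;
              const size_t colbase = (size_t)o1 * (j2 + (size_t)o2 * j3);
              const size_t inbase  = (size_t)d1 * (i2 + (size_t)d2 * i3);
              if (stride == 1) {
                // contiguous fast path along the first axis
                int j1lo = std::max(0, pad - t1);
                int j1hi = std::min(o1 - 1, d1 - 1 - t1 + pad);
                for (int j1 = j1lo; j1 <= j1hi; ++j1)
                  cr[colbase + j1] = xc[inbase + j1 + t1 - pad];
              } else {
                for (int j1 = 0; j1 < o1; ++j1) {
                  const int i1 = j1 * stride + t1 - pad;
                  if (i1 < 0 || i1 >= d1) continue;
                  cr[colbase + j1] = xc[inbase + i1];
                }
              }
            }
          }
        }
      }
    }
  }
  return col;
}

// Adjoint of vol2col: scatter-add patch rows back into a (d1,d2,d3,C)
// volume.
// [[Rcpp::export]]
NumericVector col2vol(const arma::mat& col, IntegerVector dims, int k,
                      int stride, int pad) {
  if (dims.size() != 4) stop("col2vol: dims must have length 4");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  const int o1 = out_size(d1, k, stride, pad);
  const int o2 = out_size(d2, k, stride, pad);
  const int o3 = out_size(d3, k, stride, pad);
  const size_t P = (size_t)o1 * o2 * o3;
  if ((int)col.n_cols != C * k * k * k || col.n_rows != P)
    stop("col2vol: column matrix does not match dims/kernel");
  NumericVector out((size_t)d1 * d2 * d3 * C);
  out.attr("dim") = dims;
  double* op = out.begin();
  const double* cp = col.memptr();
  for (int c = 0; c < C; ++c) {
    double* oc = op + (size_t)c * d1 * d2 * d3;
    for (int t3 = 0; t3 < k; ++t3) {
      for (int t2 = 0; t2 < k; ++t2) {
        for (int t1 = 0; t1 < k; ++t1) {
          const int row = ((c * k + t3) * k + t2) * k + t1;
          const double* cr = cp + (size_t)row * P;
          for (int j3 = 0; j3 < o3; ++j3) {
            const int i3 = j3 * stride + t3 - pad;
            if (i3 < 0 || i3 >= d3) continue;
            for (int j2 = 0; j2 < o2; ++j2) {
              const int i2 = j2 * stride + t2 - pad;
              if (i2 < 0 || i2 >= d2) continue;
              const size_t colbase = (size_t)o1 * (j2 + (size_t)o2 * j3);
              const size_t inbase  = (size_t)d1 * (i2 + (size_t)d2 * i3);
              for (int j1 = 0; j1 < o1; ++j1) {
                const int i1 = j1 * stride + t1 - pad;
                if (i1 < 0 || i1 >= d1) continue;
                oc[inbase + i1] += cr[colbase + j1];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Sliding-window maximum over a cubic window (side w, odd); the window is
// clipped at volume edges.
// [[Rcpp::export]]
NumericVector max_filter3(const NumericVector& x, int w) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("max_filter3: input must be a 3-d array");
  if (w < 1 || w % 2 == 0) stop("max_filter3: window must be odd and >= 1");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int h = w / 2;
  NumericVector out((size_t)d1 * d2 * d3);
  out.attr("dim") = dm;
  const double* xp = x.begin();
  double* op = out.begin();
  for (int i3 = 0; i3 < d3; ++i3) {
    const int a3 = std::max(0, i3 - h), b3 = std::min(d3 - 1, i3 + h);
    for (int i2 = 0; i2 < d2; ++i2) {
      const int a2 = std::max(0, i2 - h), b2 = std::min(d2 - 1, i2 + h);
      for (int i1 = 0; i1 < d1; ++i1) {
        const int a1 = std::max(0, i1 - h), b1 = std::min(d1 - 1, i1 + h);
        double m = -std::numeric_limits<double>::infinity();
        for (int j3 = a3; j3 <= b3; ++j3)
          for (int j2 = a2; j2 <= b2; ++j2) {
            const size_t base = (size_t)d1 * (j2 + (size_t)d2 * j3);
            for (int j1 = a1; j1 <= b1; ++j1)
              m = std::max(m, xp[base + j1]);
          }
        op[i1 + (size_t)d1 * (i2 + (size_t)d2 * i3)] = m;
      }
    }
  }
  return out;
}

// Local standard deviation over a cubic window (side w, odd), computed from
// integral images of x and x^2; the window is clipped at volume edges.
// [[Rcpp::export]]
NumericVector local_sd3(const NumericVector& x, int w) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("local_sd3: input must be a 3-d array");
  if (w < 1 || w % 2 == 0) stop("local_sd3: window must be odd and >= 1");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int h = w / 2;
  // integral images with a leading zero plane in each dimension
  const int e1 = d1 + 1, e2 = d2 + 1, e3 = d3 + 1;
  std::vector<double> S((size_t)e1 * e2 * e3, 0.0), Q((size_t)e1 * e2 * e3, 0.0);
  const double* xp = x.begin();
  for (int i3 = 1; i3 < e3; ++i3)
    for (int i2 = 1; i2 < e2; ++i2)
      for (int i1 = 1; i1 < e1; ++i1) {
        const double v = xp[(i1 - 1) + (size_t)d1 * ((i2 - 1) + (size_t)d2 * (i3 - 1))];
        const size_t id = i1 + (size_t)e1 * (i2 + (size_t)e2 * i3);
        #define AT(A, a, b, c) A[(a) + (size_t)e1 * ((b) + (size_t)e2 * (c))]
        S[id] = v + AT(S, i1 - 1, i2, i3) + AT(S, i1, i2 - 1, i3) + AT(S, i1, i2, i3 - 1)
              - AT(S, i1 - 1, i2 - 1, i3) - AT(S, i1 - 1, i2, i3 - 1) - AT(S, i1, i2 - 1, i3 - 1)
              + AT(S, i1 - 1, i2 - 1, i3 - 1);
        Q[id] = v * v + AT(Q, i1 - 1, i2, i3) + AT(Q, i1, i2 - 1, i3) + AT(Q, i1, i2, i3 - 1)
              - AT(Q, i1 - 1, i2 - 1, i3) - AT(Q, i1 - 1, i2, i3 - 1) - AT(Q, i1, i2 - 1, i3 - 1)
              + AT(Q, i1 - 1, i2 - 1, i3 - 1);
      }
  NumericVector out((size_t)d1 * d2 * d3);
  out.attr("dim") = dm;
  double* op = out.begin();
  for (int i3 = 0; i3 < d3; ++i3) {
    const int a3 = std::max(0, i3 - h), b3 = std::min(d3 - 1, i3 + h);
    for (int i2 = 0; i2 < d2; ++i2) {
      const int a2 = std::max(0, i2 - h), b2 = std::min(d2 - 1, i2 + h);
      for (int i1 = 0; i1 < d1; ++i1) {
        const int a1 = std::max(0, i1 - h), b1 = std::min(d1 - 1, i1 + h);
        const double n = (double)(b1 - a1 + 1) * (b2 - a2 + 1) * (b3 - a3 + 1);
        #define BOX(A) (AT(A, b1 + 1, b2 + 1, b3 + 1) - AT(A, a1, b2 + 1, b3 + 1) \
                      - AT(A, b1 + 1, a2, b3 + 1) - AT(A, b1 + 1, b2 + 1, a3) \
                      + AT(A, a1, a2, b3 + 1) + AT(A, a1, b2 + 1, a3) \
                      + AT(A, b1 + 1, a2, a3) - AT(A, a1, a2, a3))
        const double s = BOX(S), q = BOX(Q);
        double var = q / n - (s / n) * (s / n);
        if (var < 0) var = 0;
        op[i1 + (size_t)d1 * (i2 + (size_t)d2 * i3)] = std::sqrt(var);
        #undef BOX
      }
    }
  }
  #undef AT
  return out;
}

// Rotate a cubic volume about its centre: out(y) = in(Rinv %*% y), trilinear
// interpolation, reflected (mirror) padding outside the volume.
// [[Rcpp::export]]
NumericVector rotate_trilinear(const NumericVector& x, const arma::mat& Rinv) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("rotate_trilinear: input must be a 3-d array");
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  if (Rinv.n_rows != 3 || Rinv.n_cols != 3) stop("rotate_trilinear: Rinv must be 3x3");
  const double c1 = (d1 - 1) / 2.0, c2 = (d2 - 1) / 2.0, c3 = (d3 - 1) / 2.0;
  NumericVector out((size_t)d1 * d2 * d3);
  out.attr("dim") = dm;
  const double* xp = x.begin();
  double* op = out.begin();
  auto mirror = [](int i, int d) {
    if (d == 1) return 0;
    const int period = 2 * (d - 1);
    i = ((i % period) + period) % period;
    return i < d ? i : period - i;
  };
  for (int i3 = 0; i3 < d3; ++i3) {
    const double y3 = i3 - c3;
    for (int i2 = 0; i2 < d2; ++i2) {
      const double y2 = i2 - c2;
      for (int i1 = 0; i1 < d1; ++i1) {
        const double y1 = i1 - c1;
        const double u1 = Rinv(0,0)*y1 + Rinv(0,1)*y2 + Rinv(0,2)*y3 + c1;
        const double u2 = Rinv(1,0)*y1 + Rinv(1,1)*y2 + Rinv(1,2)*y3 + c2;
        const double u3 = Rinv(2,0)*y1 + Rinv(2,1)*y2 + Rinv(2,2)*y3 + c3;
        const int f1 = (int)std::floor(u1), f2 = (int)std::floor(u2), f3 = (int)std::floor(u3);
        const double w1 = u1 - f1, w2 = u2 - f2, w3 = u3 - f3;
        double acc = 0.0;
        for (int t3 = 0; t3 <= 1; ++t3) {
          const int j3 = mirror(f3 + t3, d3);
          const double g3 = t3 ? w3 : 1 - w3;
          for (int t2 = 0; t2 <= 1; ++t2) {
            const int j2 = mirror(f2 + t2, d2);
            const double g23 = g3 * (t2 ? w2 : 1 - w2);
            const size_t base = (size_t)d1 * (j2 + (size_t)d2 * j3);
            for (int t1 = 0; t1 <= 1; ++t1) {
              const int j1 = mirror(f1 + t1, d1);
              acc += g23 * (t1 ? w1 : 1 - w1) * xp[base + j1];
            }
          }
        }
        op[i1 + (size_t)d1 * (i2 + (size_t)d2 * i3)] = acc;
      }
    }
  }
  return out;
}
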