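// Numerical kernels for the 3D CNN and the synthetic-DTI generator.
//
// Layout conventions (all column-major, matching R arrays):
//   activations: dim (D, W, H, C, N)  -- voxel index fastest, sample slowest
//   conv weights: matrix (27 * c_in, c_out); row index = offset o + 27 * ci
//     with o = di + 3*dj + 9*dk, di/dj/dk in {0,1,2} standing for {-1,0,+1}
// Convolutions are SAME, stride 1, kernel 3x3x3. GEMMs run in single
// precision (arma::fmat -> sgemm); interfaces stay double.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline NumericVector alloc5(int D, int W, int H, int C, int N) {
  NumericVector v((R_xlen_t)D * W * H * C * N);
  v.attr("dim") = IntegerVector::create(D, W, H, C, N);
  return v;
}
static inline NumericVector alloc4(int D, int W, int H, int C) {
  NumericVector v((R_xlen_t)D * W * H * C);
  v.attr("dim") = IntegerVector::create(D, W, H, C);
  return v;
}

static inline int ceil_div2(int n) { return (n + 1) / 2; }

// Fill the patch matrix Pt (V x 27*Cin) for one sample.
// x points at the sample's (D,W,H,Cin) block. Column o + 27*ci of Pt is the
// volume shifted by (di-1, dj-1, dk-1), zero outside (SAME padding).
static void vol2col(const double* x, int D, int W, int H, int Cin,
                    arma::fmat& Pt) {
  const int V = D * W * H;
  Pt.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const double* xc = x + (size_t)ci * V;
    for (int dk = 0; dk < 3; ++dk) {
      int ok = dk - 1;
      for (int dj = 0; dj < 3; ++dj) {
        int oj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          int oi = di - 1;
          float* col = Pt.colptr(di + 3 * dj + 9 * dk + 27 * ci);
          // dest voxel (i,j,k) takes x[i+oi, j+oj, k+ok]
          int k0 = std::max(0, -ok), k1 = std::min(H, H - ok);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              const double* src = xc + (size_t)(k + ok) * D * W + (size_t)(j + oj) * D + (i0 + oi);
              float* dst = col + (size_t)k * D * W + (size_t)j * D + i0;
              for (int i = i0; i < i1; ++i) *dst++ = (float)*src++;
            }
          }
        }
      }
    }
  }
}

// Scatter-add of dPt (V x 27*Cin) back into the input-gradient block.
static void col2vol(const arma::fmat& dPt, int D, int W, int H, int Cin,
                    double* dx) {
  const int V = D * W * H;
  for (int ci = 0; ci < Cin; ++ci) {
    double* xc = dx + (size_t)ci * V;
    for (int dk = 0; dk < 3; ++dk) {
      int ok = dk - 1;
      for (int dj = 0; dj < 3; ++dj) {
        int oj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          int oi = di - 1;
          const float* col = dPt.colptr(di + 3 * dj + 9 * dk + 27 * ci);
          int k0 = std::max(0, -ok), k1 = std::min(H, H - ok);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              double* dst = xc + (size_t)(k + ok) * D * W + (size_t)(j + oj) * D + (i0 + oi);
              const float* src = col + (size_t)k * D * W + (size_t)j * D + i0;
              for (int i = i0; i < i1; ++i) *dst++ += (double)*src++;
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward_cpp(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("conv3d: input must be a 5D array (D,W,H,C,N)");
  int D = dm[0], W = dm[1], H = dm[2], Cin = dm[3], N = dm[4];
  int Cout = w.ncol();
  if (w.nrow() != 27 * Cin) stop("conv3d: weight rows != 27*c_in");
  const int V = D * W * H;
  arma::fmat Wf(w.nrow(), Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < w.nrow(); ++i) Wf(i, j) = (float)w(i, j);
  arma::frowvec bf(Cout);
  for (int j = 0; j < Cout; ++j) bf(j) = (float)b[j];

  NumericVector y = alloc5(D, W, H, Cout, N);
  arma::fmat Pt(V, 27 * Cin);
  for (int n = 0; n < N; ++n) {
    vol2col(REAL(x) + (size_t)n * V * Cin, D, W, H, Cin, Pt);
    arma::fmat Y = Pt * Wf;          // V x Cout
    Y.each_row() += bf;
    double* yp = REAL(y) + (size_t)n * V * Cout;
    const float* src = Y.memptr();
    for (size_t t = 0; t < (size_t)V * Cout; ++t) yp[t] = (double)src[t];
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                         bool need_dx) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], W = dm[1], H = dm[2], Cin = dm[3], N = dm[4];
  int Cout = w.ncol();
  const int V = D * W * H;
  arma::fmat Wf(w.nrow(), Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < w.nrow(); ++i) Wf(i, j) = (float)w(i, j);

  arma::fmat dW(27 * Cin, Cout, arma::fill::zeros);
  arma::frowvec db(Cout, arma::fill::zeros);
  NumericVector dx;
  if (need_dx) {
    dx = alloc5(D, W, H, Cin, N);
  }
  arma::fmat Pt(V, 27 * Cin), dY(V, Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyp = REAL(dy) + (size_t)n * V * Cout;
    float* dYp = dY.memptr();
    for (size_t t = 0; t < (size_t)V * Cout; ++t) dYp[t] = (float)dyp[t];
    vol2col(REAL(x) + (size_t)n * V * Cin, D, W, H, Cin, Pt);
    dW += Pt.t() * dY;
    db += arma::sum(dY, 0);
    if (need_dx) {
      arma::fmat dPt = dY * Wf.t();  // V x 27*Cin
      col2vol(dPt, D, W, H, Cin, REAL(dx) + (size_t)n * V * Cin);
    }
  }
  NumericMatrix dWr(27 * Cin, Cout);
  for (int j = 0; j < Cout; ++j)
    for (int i = 0; i < 27 * Cin; ++i) dWr(i, j) = (double)dW(i, j);
  NumericVector dbr(Cout);
  for (int j = 0; j < Cout; ++j) dbr[j] = (double)db(j);
  return List::create(_["dw"] = dWr, _["db"] = dbr,
                      _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
}

// Max pooling, window 2x2x2, stride 2, ceil mode. Returns pooled values and
// 1-based linear indices into the input array (for the backward pass).
// [[Rcpp::export(name = ".maxpool3d_forward")]]
List maxpool3d_forward_cpp(NumericVector x) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], W = dm[1], H = dm[2], C = dm[3], N = dm[4];
  int Do = ceil_div2(D), Wo = ceil_div2(W), Ho = ceil_div2(H);
  NumericVector y = alloc5(Do, Wo, Ho, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  size_t Vin = (size_t)D * W * H, Vout = (size_t)Do * Wo * Ho;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xb = xp + ((size_t)n * C + c) * Vin;
      size_t base_in = ((size_t)n * C + c) * Vin;
      double* yb = yp + ((size_t)n * C + c) * Vout;
      int* ib = ip + ((size_t)n * C + c) * Vout;
      for (int ko = 0; ko < Ho; ++ko) {
        for (int jo = 0; jo < Wo; ++jo) {
          for (int io = 0; io < Do; ++io) {
            double best = -std::numeric_limits<double>::infinity();
            size_t besti = 0;
            for (int k = 2 * ko; k < std::min(2 * ko + 2, H); ++k)
              for (int j = 2 * jo; j < std::min(2 * jo + 2, W); ++j)
                for (int i = 2 * io; i < std::min(2 * io + 2, D); ++i) {
                  size_t t = (size_t)k * D * W + (size_t)j * D + i;
                  if (xb[t] > best) { best = xb[t]; besti = t; }
                }
            size_t to = (size_t)ko * Do * Wo + (size_t)jo * Do + io;
            yb[to] = best;
            // 1-based global index; fits in int for the sizes used here
            ib[to] = (int)(base_in + besti + 1);
          }
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool3d_backward")]]
NumericVector maxpool3d_backward_cpp(IntegerVector idx, NumericVector dy,
                                     IntegerVector in_dim) {
  NumericVector dx = alloc5(in_dim[0], in_dim[1], in_dim[2], in_dim[3], in_dim[4]);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  R_xlen_t n = dy.size();
  for (R_xlen_t t = 0; t < n; ++t) dxp[ip[t] - 1] += dyp[t];
  return dx;
}

// Batch normalization over (voxels, samples) per channel.
// Training mode: returns y, xhat and the batch moments (biased variance).
// [[Rcpp::export(name = ".bn_forward_train")]]
List bn_forward_train_cpp(NumericVector x, NumericVector gamma,
                          NumericVector beta, double eps) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], W = dm[1], H = dm[2], C = dm[3], N = dm[4];
  size_t V = (size_t)D * W * H;
  const double* xp = REAL(x);
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xb = xp + ((size_t)n * C + c) * V;
      for (size_t t = 0; t < V; ++t) { s += xb[t]; s2 += xb[t] * xb[t]; }
    }
    double m = (double)V * N;
    mean[c] = s / m;
    var[c] = s2 / m - mean[c] * mean[c];
    if (var[c] < 0) var[c] = 0;
  }
  NumericVector y = alloc5(D, W, H, C, N), xhat = alloc5(D, W, H, C, N);
  double* yp = REAL(y); double* hp = REAL(xhat);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * V;
      double inv = 1.0 / std::sqrt(var[c] + eps);
      double g = gamma[c], b = beta[c], mu = mean[c];
      for (size_t t = 0; t < V; ++t) {
        double h = (xp[off + t] - mu) * inv;
        hp[off + t] = h;
        yp[off + t] = g * h + b;
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mean"] = mean, _["var"] = var);
}

// Inference mode: uses the running moments.
// [[Rcpp::export(name = ".bn_forward_infer")]]
NumericVector bn_forward_infer_cpp(NumericVector x, NumericVector gamma,
                                   NumericVector beta, NumericVector rmean,
                                   NumericVector rvar, double eps) {
  IntegerVector dm = x.attr("dim");
  int D = dm[0], W = dm[1], H = dm[2], C = dm[3], N = dm[4];
  size_t V = (size_t)D * W * H;
  const double* xp = REAL(x);
  NumericVector y = alloc5(D, W, H, C, N);
  double* yp = REAL(y);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * V;
      double inv = 1.0 / std::sqrt(rvar[c] + eps);
      double g = gamma[c], b = beta[c], mu = rmean[c];
      for (size_t t = 0; t < V; ++t)
        yp[off + t] = g * (xp[off + t] - mu) * inv + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".bn_backward")]]
List bn_backward_cpp(NumericVector xhat, NumericVector dy, NumericVector gamma,
                     NumericVector var, double eps) {
  IntegerVector dm = xhat.attr("dim");
  int D = dm[0], W = dm[1], H = dm[2], C = dm[3], N = dm[4];
  size_t V = (size_t)D * W * H;
  const double* hp = REAL(xhat);
  const double* dyp = REAL(dy);
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      size_t off = ((size_t)n * C + c) * V;
      for (size_t t = 0; t < V; ++t) {
        s1 += dyp[off + t];
        s2 += dyp[off + t] * hp[off + t];
      }
    }
    dbeta[c] = s1; dgamma[c] = s2;
  }
  NumericVector dx = alloc5(D, W, H, C, N);
  double* dxp = REAL(dx);
  double m = (double)V * N;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * V;
      double k = gamma[c] / std::sqrt(var[c] + eps);
      double a1 = dbeta[c] / m, a2 = dgamma[c] / m;
      for (size_t t = 0; t < V; ++t)
        dxp[off + t] = k * (dyp[off + t] - a1 - hp[off + t] * a2);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_forward")]]
NumericVector relu_forward_cpp(NumericVector x) {
  NumericVector y = clone(x);
  double* yp = REAL(y);
  for (R_xlen_t t = 0; t < y.size(); ++t) if (yp[t] < 0) yp[t] = 0;
  return y;
}

// [[Rcpp::export(name = ".relu_backward")]]
NumericVector relu_backward_cpp(NumericVector y, NumericVector dy) {
  NumericVector dx = clone(dy);
  const double* yp = REAL(y);
  double* dp = REAL(dx);
  for (R_xlen_t t = 0; t < dx.size(); ++t) if (yp[t] <= 0) dp[t] = 0;
  return dx;
}

// Per-voxel eigenvalues of a field of symmetric 3x3 tensors.
// tf: (D,W,H,6) in upper-triangle order Dxx,Dxy,Dxz,Dyy,Dyz,Dzz.
// Returns (D,W,H,3), eigenvalues sorted descending.
// [[Rcpp::export(name = ".eig_sym_field")]]
NumericVector eig_sym_field_cpp(NumericVector tf) {
  IntegerVector dm = tf.attr("dim");
  if (dm.size() != 4 || dm[3] != 6) stop("tensor field must be (D,W,H,6)");
  int D = dm[0], W = dm[1], H = dm[2];
  size_t V = (size_t)D * W * H;
  const double* tp = REAL(tf);
  NumericVector out = alloc4(D, W, H, 3);
  double* op = REAL(out);
  arma::mat33 T;
  arma::vec3 ev;
  for (size_t v = 0; v < V; ++v) {
    double xx = tp[v], xy = tp[v + V], xz = tp[v + 2 * V];
    double yy = tp[v + 3 * V], yz = tp[v + 4 * V], zz = tp[v + 5 * V];
    T(0,0) = xx; T(0,1) = xy; T(0,2) = xz;
    T(1,0) = xy; T(1,1) = yy; T(1,2) = yz;
    T(2,0) = xz; T(2,1) = yz; T(2,2) = zz;
    arma::eig_sym(ev, T);           // ascending
    op[v] = ev(2); op[v + V] = ev(1); op[v + 2 * V] = ev(0);
  }
  return out;
}

// Separable Gaussian smoothing with mirrored boundaries.
// [[Rcpp::export(name = ".gaussian_smooth3d")]]
NumericVector gaussian_smooth3d_cpp(NumericVector x, double sigma) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("volume must be 3D");
  if (sigma <= 0) return clone(x);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (auto& v : k) v /= s;
  int D = dm[0], W = dm[1], H = dm[2];
  NumericVector cur = clone(x);
  int dims[3] = {D, W, H};
  size_t strides[3] = {1, (size_t)D, (size_t)D * W};
  for (int ax = 0; ax < 3; ++ax) {
    NumericVector nxt(Dimension(D, W, H));
    const double* cp = REAL(cur);
    double* np = REAL(nxt);
    int n = dims[ax];
    size_t st = strides[ax];
    size_t total = (size_t)D * W * H;
    // iterate over all lines along axis ax
    for (size_t base = 0; base < total; ++base) {
      // position along the axis
      size_t pos = (base / st) % n;
      if (pos != 0) continue;  // handle each line once, at its start
      for (int p = 0; p < n; ++p) {
        double acc = 0;
        for (int o = -r; o <= r; ++o) {
          int q = p + o;
          // mirror (reflect about edge samples): -1 -> 1, n -> n-2
          while (q < 0 || q >= n) {
            if (q < 0) q = -q;
            if (q >= n) q = 2 * n - 2 - q;
          }
          acc += k[o + r] * cp[base + (size_t)q * st];
        }
        np[base + (size_t)p * st] = acc;
      }
    }
    cur = nxt;
  }
  return cur;
}

static inline double cubic_kernel(double t) {
  // Catmull-Rom (cubic convolution, a = -0.5)
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return ((a + 2.0) * t - (a + 3.0)) * t * t + 1.0;
  if (t < 2.0) return (((t - 5.0) * t + 8.0) * t - 4.0) * a;
  return 0.0;
}

static inline int mirror_index(int q, int n) {
  if (n == 1) return 0;
  while (q < 0 || q >= n) {
    if (q < 0) q = -q;
    if (q >= n) q = 2 * n - 2 - q;
  }
  return q;
}

// Resample one axis to n_out samples, pixel-center coordinate mapping,
// cubic convolution (order = 3) or linear (order = 1).
static void resample_axis(const std::vector<double>& in, int D, int W, int H,
                          int ax, int n_out, int order,
                          std::vector<double>& out, int& Dn, int& Wn, int& Hn) {
  int dims[3] = {D, W, H};
  int n_in = dims[ax];
  int odims[3] = {D, W, H};
  odims[ax] = n_out;
  Dn = odims[0]; Wn = odims[1]; Hn = odims[2];
  out.assign((size_t)Dn * Wn * Hn, 0.0);
  double scale = (double)n_in / (double)n_out;
  // precompute weights per output position
  int support = (order == 3) ? 4 : 2;
  std::vector<int> idx((size_t)n_out * support);
  std::vector<double> wts((size_t)n_out * support);
  for (int p = 0; p < n_out; ++p) {
    double xin = (p + 0.5) * scale - 0.5;
    int b = (int)std::floor(xin);
    double f = xin - b;
    if (order == 3) {
      for (int o = 0; o < 4; ++o) {
        idx[(size_t)p * 4 + o] = mirror_index(b - 1 + o, n_in);
        wts[(size_t)p * 4 + o] = cubic_kernel(f - (o - 1));
      }
    } else {
      idx[(size_t)p * 2] = mirror_index(b, n_in);
      idx[(size_t)p * 2 + 1] = mirror_index(b + 1, n_in);
      wts[(size_t)p * 2] = 1.0 - f;
      wts[(size_t)p * 2 + 1] = f;
    }
  }
  size_t in_strides[3] = {1, (size_t)D, (size_t)D * W};
  size_t out_strides[3] = {1, (size_t)Dn, (size_t)Dn * Wn};
  // loop over the two non-resampled axes
  int a1 = (ax + 1) % 3, a2 = (ax + 2) % 3;
  for (int u = 0; u < odims[a1]; ++u) {
    for (int v = 0; v < odims[a2]; ++v) {
      size_t ibase = (size_t)u * in_strides[a1] + (size_t)v * in_strides[a2];
      size_t obase = (size_t)u * out_strides[a1] + (size_t)v * out_strides[a2];
      for (int p = 0; p < n_out; ++p) {
        double acc = 0;
        for (int o = 0; o < support; ++o)
          acc += wts[(size_t)p * support + o] *
                 in[ibase + (size_t)idx[(size_t)p * support + o] * in_strides[ax]];
        out[obase + (size_t)p * out_strides[ax]] = acc;
      }
    }
  }
}

// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d_cpp(NumericVector x, IntegerVector target, int order) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 3) stop("volume must be 3D");
  if (order != 1 && order != 3) stop("order must be 1 or 3");
  int D = dm[0], W = dm[1], H = dm[2];
  std::vector<double> cur(REAL(x), REAL(x) + (size_t)D * W * H), nxt;
  double lo = *std::min_element(cur.begin(), cur.end());
  double hi = *std::max_element(cur.begin(), cur.end());
  int Dn, Wn, Hn;
  for (int ax = 0; ax < 3; ++ax) {
    resample_axis(cur, D, W, H, ax, target[ax], order, nxt, Dn, Wn, Hn);
    cur.swap(nxt);
    D = Dn; W = Wn; H = Hn;
  }
  NumericVector out(Dimension(D, W, H));
  double* op = REAL(out);
  for (size_t t = 0; t < cur.size(); ++t)
    op[t] = std::min(hi, std::max(lo, cur[t]));  // clip interpolation overshoot
  return out;
}

// ---------------------------------------------------------------------------
// Fused single-precision training step and inference pass for the full
// 3-hidden-layer network. The composable double-precision ops above define
// the reference semantics (and are what the tests check this path against);
// the fused path exists because R-level composition materializes hundreds of
// megabytes of intermediates per mini-batch.

static void vol2col_f(const float* x, int D, int W, int H, int Cin,
                      arma::fmat& Pt) {
  const int V = D * W * H;
  Pt.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = x + (size_t)ci * V;
    for (int dk = 0; dk < 3; ++dk) {
      int ok = dk - 1;
      for (int dj = 0; dj < 3; ++dj) {
        int oj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          int oi = di - 1;
          float* col = Pt.colptr(di + 3 * dj + 9 * dk + 27 * ci);
          int k0 = std::max(0, -ok), k1 = std::min(H, H - ok);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              const float* src = xc + (size_t)(k + ok) * D * W + (size_t)(j + oj) * D + (i0 + oi);
              float* dst = col + (size_t)k * D * W + (size_t)j * D + i0;
              for (int i = i0; i < i1; ++i) *dst++ = *src++;
            }
          }
        }
      }
    }
  }
}

static void col2vol_f(const arma::fmat& dPt, int D, int W, int H, int Cin,
                      float* dx) {
  const int V = D * W * H;
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = dx + (size_t)ci * V;
    for (int dk = 0; dk < 3; ++dk) {
      int ok = dk - 1;
      for (int dj = 0; dj < 3; ++dj) {
        int oj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          int oi = di - 1;
          const float* col = dPt.colptr(di + 3 * dj + 9 * dk + 27 * ci);
          int k0 = std::max(0, -ok), k1 = std::min(H, H - ok);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              float* dst = xc + (size_t)(k + ok) * D * W + (size_t)(j + oj) * D + (i0 + oi);
              const float* src = col + (size_t)k * D * W + (size_t)j * D + i0;
              for (int i = i0; i < i1; ++i) *dst++ += *src++;
            }
          }
        }
      }
    }
  }
}


// vol2col into rows [row_off, row_off+V) of a tall (nb*V x 27*Cin) matrix.
static void vol2col_f_off(const float* x, int D, int W, int H, int Cin,
                          arma::fmat& Pt, size_t row_off) {
  const int V = D * W * H;
  const size_t ldim = Pt.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    const float* xc = x + (size_t)ci * V;
    for (int dk = 0; dk < 3; ++dk) {
      int ok = dk - 1;
      for (int dj = 0; dj < 3; ++dj) {
        int oj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          int oi = di - 1;
          float* col = Pt.memptr() +
            (size_t)(di + 3 * dj + 9 * dk + 27 * ci) * ldim + row_off;
          std::memset(col, 0, sizeof(float) * V);
          int k0 = std::max(0, -ok), k1 = std::min(H, H - ok);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              const float* src = xc + (size_t)(k + ok) * D * W + (size_t)(j + oj) * D + (i0 + oi);
              float* dst = col + (size_t)k * D * W + (size_t)j * D + i0;
              for (int i = i0; i < i1; ++i) *dst++ = *src++;
            }
          }
        }
      }
    }
  }
}

static void col2vol_f_off(const arma::fmat& dPt, size_t row_off, int D, int W,
                          int H, int Cin, float* dx) {
  const int V = D * W * H;
  const size_t ldim = dPt.n_rows;
  for (int ci = 0; ci < Cin; ++ci) {
    float* xc = dx + (size_t)ci * V;
    for (int dk = 0; dk < 3; ++dk) {
      int ok = dk - 1;
      for (int dj = 0; dj < 3; ++dj) {
        int oj = dj - 1;
        for (int di = 0; di < 3; ++di) {
          int oi = di - 1;
          const float* col = dPt.memptr() +
            (size_t)(di + 3 * dj + 9 * dk + 27 * ci) * ldim + row_off;
          int k0 = std::max(0, -ok), k1 = std::min(H, H - ok);
          int j0 = std::max(0, -oj), j1 = std::min(W, W - oj);
          int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
          for (int k = k0; k < k1; ++k) {
            for (int j = j0; j < j1; ++j) {
              float* dst = xc + (size_t)(k + ok) * D * W + (size_t)(j + oj) * D + (i0 + oi);
              const float* src = col + (size_t)k * D * W + (size_t)j * D + i0;
              for (int i = i0; i < i1; ++i) *dst++ += *src++;
            }
          }
        }
      }
    }
  }
}

struct LayerDims {
  int D, W, H, Cin, Cout;       // pre-pool spatial dims and channels
  int Do, Wo, Ho;               // post-pool spatial dims
  bool pool;
  int V() const { return D * W * H; }
  int Vo() const { return Do * Wo * Ho; }
};

static std::vector<LayerDims> plan_layers(int D, int W, int H,
                                          const LogicalVector& pool) {
  const int ch[3] = {32, 64, 128};
  std::vector<LayerDims> L(3);
  int cin = 1;
  for (int l = 0; l < 3; ++l) {
    L[l].D = D; L[l].W = W; L[l].H = H;
    L[l].Cin = cin; L[l].Cout = ch[l];
    L[l].pool = pool[l];
    if (L[l].pool) {
      L[l].Do = ceil_div2(D); L[l].Wo = ceil_div2(W); L[l].Ho = ceil_div2(H);
    } else {
      L[l].Do = D; L[l].Wo = W; L[l].Ho = H;
    }
    D = L[l].Do; W = L[l].Wo; H = L[l].Ho;
    cin = ch[l];
  }
  return L;
}

static arma::fmat get_fmat(const List& p, const char* name) {
  NumericMatrix m = p[name];
  arma::fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = (float)m(i, j);
  return out;
}
static arma::fvec get_fvec(const List& p, const char* name) {
  NumericVector v = p[name];
  arma::fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

// Convolution over a batch stored as columns of (V*Cin) x nb. One sample at
// a time: the per-sample patch matrix stays cache-resident, which beats one
// tall batched GEMM on this workload.
static void conv_fw_batch(const arma::fmat& X, const LayerDims& L,
                          const arma::fmat& Wf, const arma::fvec& bf,
                          arma::fmat& A, arma::fmat& Pt) {
  int nb = X.n_cols;
  for (int n = 0; n < nb; ++n) {
    vol2col_f_off(X.colptr(n), L.D, L.W, L.H, L.Cin, Pt, 0);
    arma::fmat Ys = Pt * Wf;                    // V x Cout
    Ys.each_row() += bf.t();
    std::memcpy(A.colptr(n), Ys.memptr(), sizeof(float) * (size_t)L.V() * L.Cout);
  }
}

static void conv_bw_batch(const arma::fmat& Xin, const LayerDims& L,
                          const arma::fmat& Wf, const arma::fmat& dA,
                          arma::fmat* dXin, arma::fmat& dW, arma::fvec& db,
                          arma::fmat& Pt) {
  int nb = Xin.n_cols;
  dW.zeros(); db.zeros();
  if (dXin) dXin->zeros();
  for (int n = 0; n < nb; ++n) {
    const arma::fmat dYs(const_cast<float*>(dA.colptr(n)), L.V(), L.Cout,
                         false, true);
    vol2col_f_off(Xin.colptr(n), L.D, L.W, L.H, L.Cin, Pt, 0);
    dW += Pt.t() * dYs;
    db += arma::sum(dYs, 0).t();
    if (dXin) {
      arma::fmat dPt = dYs * Wf.t();
      col2vol_f_off(dPt, 0, L.D, L.W, L.H, L.Cin, dXin->colptr(n));
    }
  }
}

// Batch-norm statistics over (V, nb) per channel.
static void bn_stats(const arma::fmat& A, const LayerDims& L,
                     arma::fvec& mean, arma::fvec& var) {
  int nb = A.n_cols, V = L.V();
  arma::vec s(L.Cout, arma::fill::zeros), s2(L.Cout, arma::fill::zeros);
  for (int n = 0; n < nb; ++n) {
    const float* cp = A.colptr(n);
    for (int c = 0; c < L.Cout; ++c) {
      double a = 0, b = 0;
      const float* p = cp + (size_t)c * V;
      for (int t = 0; t < V; ++t) { a += p[t]; b += (double)p[t] * p[t]; }
      s(c) += a; s2(c) += b;
    }
  }
  double m = (double)V * nb;
  for (int c = 0; c < L.Cout; ++c) {
    double mu = s(c) / m;
    double va = s2(c) / m - mu * mu;
    mean(c) = (float)mu;
    var(c) = (float)(va < 0 ? 0 : va);
  }
}

// Normalize + scale/shift + ReLU + (optional) pool, one sample-channel block
// at a time. P gets the pooled output; idx the argmax position within the
// (V*Cout) column (-1 padding never occurs since window cells exist).
static void bn_relu_pool_fw(const arma::fmat& A, const LayerDims& L,
                            const arma::fvec& mean, const arma::fvec& var,
                            const arma::fvec& g, const arma::fvec& be,
                            float eps, arma::fmat& P, arma::Mat<int>* idx) {
  int nb = A.n_cols, V = L.V(), Vo = L.Vo();
  std::vector<float> buf(V);
  for (int n = 0; n < nb; ++n) {
    const float* ap = A.colptr(n);
    float* pp = P.colptr(n);
    int* ip = idx ? idx->colptr(n) : nullptr;
    for (int c = 0; c < L.Cout; ++c) {
      float inv = 1.0f / std::sqrt(var(c) + eps);
      float gg = g(c), bb = be(c), mu = mean(c);
      const float* a = ap + (size_t)c * V;
      for (int t = 0; t < V; ++t) {
        float y = gg * (a[t] - mu) * inv + bb;
        buf[t] = y > 0 ? y : 0;
      }
      if (!L.pool) {
        std::memcpy(pp + (size_t)c * V, buf.data(), sizeof(float) * V);
        continue;
      }
      float* po = pp + (size_t)c * Vo;
      int* io = ip + (size_t)c * Vo;
      for (int ko = 0; ko < L.Ho; ++ko)
        for (int jo = 0; jo < L.Wo; ++jo)
          for (int io2 = 0; io2 < L.Do; ++io2) {
            float best = -std::numeric_limits<float>::infinity();
            int besti = 0;
            for (int k = 2 * ko; k < std::min(2 * ko + 2, L.H); ++k)
              for (int j = 2 * jo; j < std::min(2 * jo + 2, L.W); ++j)
                for (int i = 2 * io2; i < std::min(2 * io2 + 2, L.D); ++i) {
                  int t = k * L.D * L.W + j * L.D + i;
                  if (buf[t] > best) { best = buf[t]; besti = t; }
                }
            int to = ko * L.Do * L.Wo + jo * L.Do + io2;
            po[to] = best;
            io[to] = c * V + besti;
          }
    }
  }
}

// Backward through pool+ReLU+BN. dP is the gradient at the pooled output;
// returns dA (gradient at the conv output) in place of dY, plus dgamma/dbeta.
static void bn_relu_pool_bw(const arma::fmat& A, const LayerDims& L,
                            const arma::fvec& mean, const arma::fvec& var,
                            const arma::fvec& g, const arma::fvec& be,
                            float eps, const arma::fmat& dP,
                            const arma::Mat<int>* idx, arma::fmat& dA,
                            arma::vec& dgamma, arma::vec& dbeta) {
  int nb = A.n_cols, V = L.V(), Vo = L.Vo();
  dA.zeros();
  // unpool + ReLU mask, accumulating the per-channel BN sums
  arma::vec s1(L.Cout, arma::fill::zeros), s2(L.Cout, arma::fill::zeros);
  for (int n = 0; n < nb; ++n) {
    const float* ap = A.colptr(n);
    float* dp = dA.colptr(n);
    const float* dpp = dP.colptr(n);
    if (L.pool) {
      const int* ip = idx->colptr(n);
      for (size_t t = 0; t < (size_t)Vo * L.Cout; ++t) dp[ip[t]] += dpp[t];
    } else {
      std::memcpy(dp, dpp, sizeof(float) * (size_t)V * L.Cout);
    }
    for (int c = 0; c < L.Cout; ++c) {
      float inv = 1.0f / std::sqrt(var(c) + eps);
      float gg = g(c), bb = be(c), mu = mean(c);
      const float* a = ap + (size_t)c * V;
      float* d = dp + (size_t)c * V;
      double a1 = 0, a2 = 0;
      for (int t = 0; t < V; ++t) {
        float xh = (a[t] - mu) * inv;
        float y = gg * xh + bb;
        if (y <= 0) { d[t] = 0; continue; }
        a1 += d[t];
        a2 += (double)d[t] * xh;
      }
      s1(c) += a1; s2(c) += a2;
    }
  }
  dgamma = s2; dbeta = s1;
  double m = (double)V * nb;
  for (int n = 0; n < nb; ++n) {
    const float* ap = A.colptr(n);
    float* dp = dA.colptr(n);
    for (int c = 0; c < L.Cout; ++c) {
      float inv = 1.0f / std::sqrt(var(c) + eps);
      float k = g(c) * inv;
      float c1 = (float)(s1(c) / m), c2 = (float)(s2(c) / m), mu = mean(c);
      const float* a = ap + (size_t)c * V;
      float* d = dp + (size_t)c * V;
      for (int t = 0; t < V; ++t) {
        float xh = (a[t] - mu) * inv;
        d[t] = k * (d[t] - c1 - xh * c2);
      }
    }
  }
}

// One fused training step: forward, cost, full backward. Returns the
// gradients, batch probabilities and the per-layer batch moments.
// [[Rcpp::export(name = ".cnn_step")]]
List cnn_step(NumericVector x, NumericMatrix y, List params,
              LogicalVector pool, double eps) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("cnn_step: input must be (D,W,H,1,n)");
  int nb = dm[4];
  std::vector<LayerDims> L = plan_layers(dm[0], dm[1], dm[2], pool);

  arma::fmat W[3], Pl[3], A[3];
  arma::fvec b[3], g[3], be[3], mean[3], var[3];
  arma::Mat<int> idx[3];
  char nm[8];
  for (int l = 0; l < 3; ++l) {
    snprintf(nm, 8, "W%d", l + 1); W[l] = get_fmat(params, nm);
    snprintf(nm, 8, "b%d", l + 1); b[l] = get_fvec(params, nm);
    snprintf(nm, 8, "g%d", l + 1); g[l] = get_fvec(params, nm);
    snprintf(nm, 8, "be%d", l + 1); be[l] = get_fvec(params, nm);
    mean[l].set_size(L[l].Cout); var[l].set_size(L[l].Cout);
  }
  arma::fmat Wl = get_fmat(params, "Wl");
  arma::fvec bl = get_fvec(params, "bl");

  // input as float
  arma::fmat X0((size_t)L[0].V(), nb);
  { const double* xp = REAL(x);
    float* fp = X0.memptr();
    for (size_t t = 0; t < (size_t)L[0].V() * nb; ++t) fp[t] = (float)xp[t]; }

  // forward
  arma::fmat Pt;
  const arma::fmat* cur = &X0;
  for (int l = 0; l < 3; ++l) {
    A[l].set_size((size_t)L[l].V() * L[l].Cout, nb);
    Pt.set_size(L[l].V(), 27 * L[l].Cin);
    conv_fw_batch(*cur, L[l], W[l], b[l], A[l], Pt);
    bn_stats(A[l], L[l], mean[l], var[l]);
    Pl[l].set_size((size_t)L[l].Vo() * L[l].Cout, nb);
    if (L[l].pool) idx[l].set_size((size_t)L[l].Vo() * L[l].Cout, nb);
    bn_relu_pool_fw(A[l], L[l], mean[l], var[l], g[l], be[l], (float)eps,
                    Pl[l], L[l].pool ? &idx[l] : nullptr);
    cur = &Pl[l];
  }
  int F = Pl[2].n_rows;
  if (Wl.n_rows != (arma::uword)F) stop("linear weight shape mismatch");
  arma::fmat logits = Wl.t() * Pl[2];     // 2 x nb
  logits.each_col() += bl;

  NumericMatrix probs(nb, 2);
  arma::fmat dlog(2, nb);
  double cost = 0;
  for (int n = 0; n < nb; ++n) {
    double m = std::max(logits(0, n), logits(1, n));
    double e0 = std::exp((double)logits(0, n) - m);
    double e1 = std::exp((double)logits(1, n) - m);
    double z = e0 + e1;
    double p0 = e0 / z, p1 = e1 / z;
    probs(n, 0) = p0; probs(n, 1) = p1;
    double pt = y(n, 0) * p0 + y(n, 1) * p1;
    cost -= std::log(std::max(pt, 1e-12));
    dlog(0, n) = (float)(p0 - y(n, 0));
    dlog(1, n) = (float)(p1 - y(n, 1));
  }

  // backward
  List grads;
  arma::fmat gWl = Pl[2] * dlog.t();
  arma::fvec gbl = arma::sum(dlog, 1);
  arma::fmat dP = Wl * dlog;              // F x nb
  for (int l = 2; l >= 0; --l) {
    arma::fmat dA;
    dA.set_size((size_t)L[l].V() * L[l].Cout, nb);
    arma::vec dgamma, dbeta;
    bn_relu_pool_bw(A[l], L[l], mean[l], var[l], g[l], be[l], (float)eps,
                    dP, L[l].pool ? &idx[l] : nullptr, dA, dgamma, dbeta);
    arma::fmat dW(27 * L[l].Cin, L[l].Cout);
    arma::fvec db(L[l].Cout);
    arma::fmat dXin;
    const arma::fmat* Xin = (l == 0) ? &X0 : &Pl[l - 1];
    if (l > 0) dXin.set_size(Xin->n_rows, nb);
    Pt.set_size(L[l].V(), 27 * L[l].Cin);
    conv_bw_batch(*Xin, L[l], W[l], dA, l > 0 ? &dXin : nullptr, dW, db, Pt);
    snprintf(nm, 8, "W%d", l + 1);
    grads[nm] = NumericMatrix(dW.n_rows, dW.n_cols,
                              arma::conv_to<arma::mat>::from(dW).memptr());
    snprintf(nm, 8, "b%d", l + 1);
    grads[nm] = NumericVector(db.begin(), db.end());
    snprintf(nm, 8, "g%d", l + 1);
    grads[nm] = NumericVector(dgamma.begin(), dgamma.end());
    snprintf(nm, 8, "be%d", l + 1);
    grads[nm] = NumericVector(dbeta.begin(), dbeta.end());
    if (l > 0) dP = std::move(dXin);
  }
  grads["Wl"] = NumericMatrix(gWl.n_rows, gWl.n_cols,
                              arma::conv_to<arma::mat>::from(gWl).memptr());
  grads["bl"] = NumericVector(gbl.begin(), gbl.end());

  List means(3), vars(3);
  for (int l = 0; l < 3; ++l) {
    means[l] = NumericVector(mean[l].begin(), mean[l].end());
    vars[l] = NumericVector(var[l].begin(), var[l].end());
  }
  return List::create(_["cost"] = cost, _["probs"] = probs,
                      _["grads"] = grads, _["means"] = means, _["vars"] = vars);
}

// Fused inference pass. Returns class probabilities (upto = 3, probs = true)
// or the activations after hidden layer `upto` as a (D,W,H,C,n) array.
// [[Rcpp::export(name = ".cnn_infer")]]
SEXP cnn_infer(NumericVector x, List params, List running,
               LogicalVector pool, double eps, int upto, bool return_probs) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 5) stop("cnn_infer: input must be (D,W,H,1,n)");
  int nb = dm[4];
  std::vector<LayerDims> L = plan_layers(dm[0], dm[1], dm[2], pool);
  char nm[8];
  arma::fmat X0((size_t)L[0].V(), nb);
  { const double* xp = REAL(x);
    float* fp = X0.memptr();
    for (size_t t = 0; t < (size_t)L[0].V() * nb; ++t) fp[t] = (float)xp[t]; }
  arma::fmat cur = std::move(X0), Pt, A, P;
  for (int l = 0; l < upto; ++l) {
    snprintf(nm, 8, "W%d", l + 1); arma::fmat W = get_fmat(params, nm);
    snprintf(nm, 8, "b%d", l + 1); arma::fvec b = get_fvec(params, nm);
    snprintf(nm, 8, "g%d", l + 1); arma::fvec g = get_fvec(params, nm);
    snprintf(nm, 8, "be%d", l + 1); arma::fvec be = get_fvec(params, nm);
    snprintf(nm, 8, "rm%d", l + 1); arma::fvec rm = get_fvec(running, nm);
    snprintf(nm, 8, "rv%d", l + 1); arma::fvec rv = get_fvec(running, nm);
    A.set_size((size_t)L[l].V() * L[l].Cout, nb);
    Pt.set_size(L[l].V(), 27 * L[l].Cin);
    conv_fw_batch(cur, L[l], W, b, A, Pt);
    P.set_size((size_t)L[l].Vo() * L[l].Cout, nb);
    arma::Mat<int> idx;
    if (L[l].pool) idx.set_size((size_t)L[l].Vo() * L[l].Cout, nb);
    bn_relu_pool_fw(A, L[l], rm, rv, g, be, (float)eps, P,
                    L[l].pool ? &idx : nullptr);
    cur = std::move(P);
  }
  if (!return_probs) {
    const LayerDims& Ld = L[upto - 1];
    NumericVector out = alloc5(Ld.Do, Ld.Wo, Ld.Ho, Ld.Cout, nb);
    double* op = REAL(out);
    const float* fp = cur.memptr();
    for (size_t t = 0; t < cur.n_elem; ++t) op[t] = (double)fp[t];
    return out;
  }
  arma::fmat Wl = get_fmat(params, "Wl");
  arma::fvec bl = get_fvec(params, "bl");
  if (Wl.n_rows != cur.n_rows) stop("linear weight shape mismatch");
  arma::fmat logits = Wl.t() * cur;
  logits.each_col() += bl;
  NumericMatrix probs(nb, 2);
  for (int n = 0; n < nb; ++n) {
    double m = std::max(logits(0, n), logits(1, n));
    double e0 = std::exp((double)logits(0, n) - m);
    double e1 = std::exp((double)logits(1, n) - m);
    probs(n, 0) = e0 / (e0 + e1);
    probs(n, 1) = e1 / (e0 + e1);
  }
  return probs;
}

// Fused in-place Adam update. params, m and v must be private to the
// training loop (freshly allocated copies); they are modified through their
// memory directly, bypassing R's copy-on-write, which is safe only under
// that ownership contract (see train_cnn3d).
// [[Rcpp::export(name = ".adam_step_inplace")]]
void adam_step_inplace(List params, List grads, List m, List v, int t,
                       double lr, double b1, double b2, double eps) {
  double bc1 = 1.0 - std::pow(b1, t);
  double bc2 = 1.0 - std::pow(b2, t);
  CharacterVector nms = grads.names();
  for (int k = 0; k < grads.size(); ++k) {
    std::string nm = as<std::string>(nms[k]);
    NumericVector g = grads[nm];
    NumericVector p = params[nm];
    NumericVector mk = m[nm];
    NumericVector vk = v[nm];
    double* gp = REAL(g); double* pp = REAL(p);
    double* mp = REAL(mk); double* vp = REAL(vk);
    R_xlen_t n = g.size();
    for (R_xlen_t i = 0; i < n; ++i) {
      mp[i] = b1 * mp[i] + (1 - b1) * gp[i];
      vp[i] = b2 * vp[i] + (1 - b2) * gp[i] * gp[i];
      pp[i] -= lr * (mp[i] / bc1) / (std::sqrt(vp[i] / bc2) + eps);
    }
  }
}
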