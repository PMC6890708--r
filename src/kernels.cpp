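#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Dense 3D tensors are stored as R arrays in column-major order.
// Feature tensors carry dim (C, X, Y, Z) so the channel index is the
// fastest-moving one; plain volumes carry dim (X, Y, Z).

static inline int idx4(int c, int i, int j, int k, int C, int X, int Y) {
  return c + C * (i + X * (j + Y * k));
}

// repack w (Cin, k, k, k, Cout) into [spatial offset][ci][co] with co
// contiguous, so the inner accumulation loops vectorize
static std::vector<double> repack_w(const double *pw, int Cin, int K, int Cout) {
  const int K3 = K * K * K;
  std::vector<double> wt((size_t)K3 * Cin * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int off = 0; off < K3; ++off)
      for (int ci = 0; ci < Cin; ++ci)
        wt[((size_t)off * Cin + ci) * Cout + co] =
          pw[ci + (size_t)Cin * (off + (size_t)K3 * co)];
  return wt;
}

// 3D convolution, stride 1, zero ("same") padding, odd cubic kernel.
// w has dim (Cin, k, k, k, Cout); b has length Cout.
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Cin = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int K = wd[1], Cout = wd[4];
  const int r = (K - 1) / 2;
  NumericVector out(Cout * X * Y * Z);
  out.attr("dim") = IntegerVector::create(Cout, X, Y, Z);
  const double *px = x.begin(), *pb = b.begin();
  double *po = out.begin();
  std::vector<double> wt = repack_w(w.begin(), Cin, K, Cout);
  std::vector<double> acc(Cout);
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        for (int co = 0; co < Cout; ++co) acc[co] = pb[co];
        for (int dz = -r; dz <= r; ++dz) {
          int kk = k + dz; if (kk < 0 || kk >= Z) continue;
          for (int dy = -r; dy <= r; ++dy) {
            int jj = j + dy; if (jj < 0 || jj >= Y) continue;
            for (int dx = -r; dx <= r; ++dx) {
              int ii = i + dx; if (ii < 0 || ii >= X) continue;
              const double *xv = px + idx4(0, ii, jj, kk, Cin, X, Y);
              const int off = (dx + r) + K * ((dy + r) + K * (dz + r));
              const double *wp = &wt[(size_t)off * Cin * Cout];
              for (int ci = 0; ci < Cin; ++ci) {
                const double xc = xv[ci];
                if (xc == 0.0) continue;
                const double *wrow = wp + (size_t)ci * Cout;
                for (int co = 0; co < Cout; ++co)
                  acc[co] += xc * wrow[co];
              }
            }
          }
        }
        double *ov = po + idx4(0, i, j, k, Cout, X, Y);
        for (int co = 0; co < Cout; ++co) ov[co] = acc[co];
      }
  return out;
}

// Gradients of conv3d_fwd w.r.t. input, weights and biases.
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int Cin = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int K = wd[1], Cout = wd[4];
  const int r = (K - 1) / 2;
  NumericVector gx(x.size()), gw(w.size()), gb(Cout);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  const double *px = x.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  const int K3 = K * K * K;
  std::vector<double> wt = repack_w(w.begin(), Cin, K, Cout);
  std::vector<double> gwt((size_t)K3 * Cin * Cout, 0.0);
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        const double *gv = pg + idx4(0, i, j, k, Cout, X, Y);
        for (int co = 0; co < Cout; ++co) pgb[co] += gv[co];
        for (int dz = -r; dz <= r; ++dz) {
          int kk = k + dz; if (kk < 0 || kk >= Z) continue;
          for (int dy = -r; dy <= r; ++dy) {
            int jj = j + dy; if (jj < 0 || jj >= Y) continue;
            for (int dx = -r; dx <= r; ++dx) {
              int ii = i + dx; if (ii < 0 || ii >= X) continue;
              const int xoff = idx4(0, ii, jj, kk, Cin, X, Y);
              const int off = (dx + r) + K * ((dy + r) + K * (dz + r));
              for (int ci = 0; ci < Cin; ++ci) {
                const double xc = px[xoff + ci];
                double gacc = 0.0;
                const double *wrow = &wt[((size_t)off * Cin + ci) * Cout];
                double *gwrow = &gwt[((size_t)off * Cin + ci) * Cout];
                for (int co = 0; co < Cout; ++co) {
                  const double g = gv[co];
                  gacc += wrow[co] * g;
                  gwrow[co] += xc * g;
                }
                pgx[xoff + ci] += gacc;
              }
            }
          }
        }
      }
  // scatter gradients back to the R weight layout
  for (int co = 0; co < Cout; ++co)
    for (int off = 0; off < K3; ++off)
      for (int ci = 0; ci < Cin; ++ci)
        pgw[ci + (size_t)Cin * (off + (size_t)K3 * co)] =
          gwt[((size_t)off * Cin + ci) * Cout + co];
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2; dims must be even. Returns pooled tensor
// and the 0-based linear argmax index into the input (first max wins).
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out(C * Xo * Yo * Zo);
  IntegerVector idx(out.size());
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  const double *px = x.begin();
  double *po = out.begin();
  int *pi = idx.begin();
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i)
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL; int besti = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int li = idx4(c, 2 * i + dx, 2 * j + dy, 2 * k + dz, C, X, Y);
                if (px[li] > best) { best = px[li]; besti = li; }
              }
          int lo = idx4(c, i, j, k, C, Xo, Yo);
          po[lo] = best; pi[lo] = besti;
        }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t n = 0; n < gy.size(); ++n) gx[idx[n]] += gy[n];
  return gx;
}

// 3x3x3 max pooling, stride 1, same extent (window clipped at borders).
// [[Rcpp::export]]
List maxpool3s1_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  NumericVector out(x.size());
  IntegerVector idx(x.size());
  out.attr("dim") = xd;
  const double *px = x.begin();
  double *po = out.begin();
  int *pi = idx.begin();
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i)
        for (int c = 0; c < C; ++c) {
          double best = -HUGE_VAL; int besti = -1;
          for (int dz = -1; dz <= 1; ++dz) {
            int kk = k + dz; if (kk < 0 || kk >= Z) continue;
            for (int dy = -1; dy <= 1; ++dy) {
              int jj = j + dy; if (jj < 0 || jj >= Y) continue;
              for (int dx = -1; dx <= 1; ++dx) {
                int ii = i + dx; if (ii < 0 || ii >= X) continue;
                int li = idx4(c, ii, jj, kk, C, X, Y);
                if (px[li] > best) { best = px[li]; besti = li; }
              }
            }
          }
          int lo = idx4(c, i, j, k, C, X, Y);
          po[lo] = best; pi[lo] = besti;
        }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3s1_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t n = 0; n < gy.size(); ++n) gx[idx[n]] += gy[n];
  return gx;
}

// Nearest-neighbour 2x upsampling (each voxel replicated into a 2x2x2 block).
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int Xo = 2 * X, Yo = 2 * Y, Zo = 2 * Z;
  NumericVector out((size_t)C * Xo * Yo * Zo);
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  const double *px = x.begin();
  double *po = out.begin();
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i) {
        const double *xv = px + idx4(0, i / 2, j / 2, k / 2, C, X, Y);
        double *ov = po + idx4(0, i, j, k, C, Xo, Yo);
        for (int c = 0; c < C; ++c) ov[c] = xv[c];
      }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int C = yd[0], Xo = yd[1], Yo = yd[2], Zo = yd[3];
  const int X = Xo / 2, Y = Yo / 2, Z = Zo / 2;
  NumericVector gx((size_t)C * X * Y * Z);
  gx.attr("dim") = IntegerVector::create(C, X, Y, Z);
  const double *pg = gy.begin();
  double *po = gx.begin();
  for (int k = 0; k < Zo; ++k)
    for (int j = 0; j < Yo; ++j)
      for (int i = 0; i < Xo; ++i) {
        const double *gv = pg + idx4(0, i, j, k, C, Xo, Yo);
        double *ov = po + idx4(0, i / 2, j / 2, k / 2, C, X, Y);
        for (int c = 0; c < C; ++c) ov[c] += gv[c];
      }
  return gx;
}

static inline double tri_sample(const double *v, int X, int Y, int Z,
                                double sx, double sy, double sz,
                                bool zero_outside) {
  if (zero_outside &&
      (sx < 0 || sy < 0 || sz < 0 || sx > X - 1 || sy > Y - 1 || sz > Z - 1))
    return 0.0;
  if (sx < 0) sx = 0; if (sx > X - 1) sx = X - 1;
  if (sy < 0) sy = 0; if (sy > Y - 1) sy = Y - 1;
  if (sz < 0) sz = 0; if (sz > Z - 1) sz = Z - 1;
  int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
  int x1 = std::min(x0 + 1, X - 1), y1 = std::min(y0 + 1, Y - 1), z1 = std::min(z0 + 1, Z - 1);
  double fx = sx - x0, fy = sy - y0, fz = sz - z0;
  double acc = 0.0;
  const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
  const int xs[2] = {x0, x1}, ys[2] = {y0, y1}, zs[2] = {z0, z1};
  for (int a = 0; a < 2; ++a)
    for (int bq = 0; bq < 2; ++bq)
      for (int cq = 0; cq < 2; ++cq)
        acc += wx[a] * wy[bq] * wz[cq] *
               v[xs[a] + X * (ys[bq] + (size_t)Y * zs[cq])];
  return acc;
}

// Trilinear resampling of a (X,Y,Z) volume onto a new grid; grid endpoints
// of the two lattices coincide (align-corners convention).
// [[Rcpp::export]]
NumericVector resample_trilinear(NumericVector v, IntegerVector out_dim) {
  IntegerVector vd = v.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int A = out_dim[0], B = out_dim[1], C = out_dim[2];
  NumericVector out((size_t)A * B * C);
  out.attr("dim") = out_dim;
  const double *pv = v.begin();
  double *po = out.begin();
  const double rx = A > 1 ? (double)(X - 1) / (A - 1) : 0.0;
  const double ry = B > 1 ? (double)(Y - 1) / (B - 1) : 0.0;
  const double rz = C > 1 ? (double)(Z - 1) / (C - 1) : 0.0;
  size_t n = 0;
  for (int k = 0; k < C; ++k)
    for (int j = 0; j < B; ++j)
      for (int i = 0; i < A; ++i)
        po[n++] = tri_sample(pv, X, Y, Z, i * rx, j * ry, k * rz, false);
  return out;
}

// Sample v at src = M %*% p + off for every output voxel p (0-based),
// trilinear interpolation, zero fill outside the field of view.
// [[Rcpp::export]]
NumericVector affine_sample(NumericVector v, NumericMatrix M, NumericVector off) {
  IntegerVector vd = v.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  NumericVector out(v.size());
  out.attr("dim") = vd;
  const double *pv = v.begin();
  double *po = out.begin();
  size_t n = 0;
  for (int k = 0; k < Z; ++k)
    for (int j = 0; j < Y; ++j)
      for (int i = 0; i < X; ++i) {
        double sx = M(0, 0) * i + M(0, 1) * j + M(0, 2) * k + off[0];
        double sy = M(1, 0) * i + M(1, 1) * j + M(1, 2) * k + off[1];
        double sz = M(2, 0) * i + M(2, 1) * j + M(2, 2) * k + off[2];
        po[n++] = tri_sample(pv, X, Y, Z, sx, sy, sz, true);
      }
  return out;
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double *px = x.begin();
  double *po = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) po[i] = px[i] > 0 ? px[i] : 0.0;
  return out;
}

// gradient through the rectifier: g * 1[x > 0]
// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector g, NumericVector x) {
  NumericVector out(g.size());
  out.attr("dim") = g.attr("dim");
  const double *pg = g.begin(), *px = x.begin();
  double *po = out.begin();
  for (R_xlen_t i = 0; i < g.size(); ++i) po[i] = px[i] > 0 ? pg[i] : 0.0;
  return out;
}

static inline int reflect_ix(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable filtering of a (X,Y,Z) volume with a 1D kernel applied along
// each axis in turn; boundaries handled by reflection.
// [[Rcpp::export]]
NumericVector sep_filter3(NumericVector v, NumericVector kern) {
  IntegerVector vd = v.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const int K = kern.size(), r = (K - 1) / 2;
  std::vector<double> cur(v.begin(), v.end()), nxt(v.size());
  const double *pk = kern.begin();
  const int dims[3] = {X, Y, Z};
  const size_t strides[3] = {1, (size_t)X, (size_t)X * Y};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = dims[ax];
    const size_t st = strides[ax];
    for (int k = 0; k < Z; ++k)
      for (int j = 0; j < Y; ++j)
        for (int i = 0; i < X; ++i) {
          const int pos[3] = {i, j, k};
          size_t base = i + (size_t)X * (j + (size_t)Y * k);
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int q = reflect_ix(pos[ax] + t, n);
            acc += pk[t + r] * cur[base + st * (q - pos[ax])];
          }
          nxt[base] = acc;
        }
    std::swap(cur, nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = vd;
  return out;
}

// SLIC-style supervoxel clustering on (intensity, position). Returns an
// integer label array (1..K) partitioning the grid into contiguous regions.
// [[Rcpp::export]]
IntegerVector slic3d(NumericVector v, int n_segments, double compactness,
                     int max_iter, double min_frac) {
  IntegerVector vd = v.attr("dim");
  const int X = vd[0], Y = vd[1], Z = vd[2];
  const size_t N = (size_t)X * Y * Z;
  IntegerVector lab(N);
  lab.attr("dim") = vd;
  if (n_segments <= 1) {
    std::fill(lab.begin(), lab.end(), 1);
    return lab;
  }
  const double *pv = v.begin();
  const double S = std::cbrt((double)N / n_segments);
  // per-axis grid counts, grown greedily until their product reaches n_segments
  int nx[3];
  const int dims[3] = {X, Y, Z};
  const double f = std::cbrt((double)n_segments / N);
  for (int a = 0; a < 3; ++a)
    nx[a] = std::max(1, (int)std::floor(dims[a] * f));
  while ((long)nx[0] * nx[1] * nx[2] < n_segments) {
    int best = 0; double bestr = -1;
    for (int a = 0; a < 3; ++a) {
      double ratio = (double)dims[a] / nx[a];
      if (ratio > bestr) { bestr = ratio; best = a; }
    }
    nx[best] += 1;
  }
  const int K = nx[0] * nx[1] * nx[2];
  std::vector<double> cx(K), cy(K), cz(K), ci(K);
  int t = 0;
  for (int c = 0; c < nx[2]; ++c)
    for (int b = 0; b < nx[1]; ++b)
      for (int a = 0; a < nx[0]; ++a, ++t) {
        cx[t] = (a + 0.5) * X / nx[0] - 0.5;
        cy[t] = (b + 0.5) * Y / nx[1] - 0.5;
        cz[t] = (c + 0.5) * Z / nx[2] - 0.5;
        int xi = std::min(X - 1, std::max(0, (int)std::lround(cx[t])));
        int yi = std::min(Y - 1, std::max(0, (int)std::lround(cy[t])));
        int zi = std::min(Z - 1, std::max(0, (int)std::lround(cz[t])));
        ci[t] = pv[xi + (size_t)X * (yi + (size_t)Y * zi)];
      }
  std::vector<int> assign(N, -1);
  std::vector<double> dist(N);
  const double invm2 = 1.0 / (compactness * compactness);
  const double invS2 = 1.0 / (S * S);
  const int w = (int)std::ceil(2.0 * S);
  for (int it = 0; it < max_iter; ++it) {
    std::fill(dist.begin(), dist.end(), HUGE_VAL);
    for (int s = 0; s < K; ++s) {
      int x0 = std::max(0, (int)cx[s] - w), x1 = std::min(X - 1, (int)cx[s] + w);
      int y0 = std::max(0, (int)cy[s] - w), y1 = std::min(Y - 1, (int)cy[s] + w);
      int z0 = std::max(0, (int)cz[s] - w), z1 = std::min(Z - 1, (int)cz[s] + w);
      for (int k = z0; k <= z1; ++k)
        for (int j = y0; j <= y1; ++j)
          for (int i = x0; i <= x1; ++i) {
            size_t li = i + (size_t)X * (j + (size_t)Y * k);
            double dI = pv[li] - ci[s];
            double dx = i - cx[s], dy = j - cy[s], dz = k - cz[s];
            double d = dI * dI * invm2 + (dx * dx + dy * dy + dz * dz) * invS2;
            if (d < dist[li]) { dist[li] = d; assign[li] = s; }
          }
    }
    // fallback for voxels outside every search window
    for (size_t li = 0; li < N; ++li)
      if (assign[li] < 0) {
        int i = li % X, j = (li / X) % Y, k = li / ((size_t)X * Y);
        double bd = HUGE_VAL; int bs = 0;
        for (int s = 0; s < K; ++s) {
          double dx = i - cx[s], dy = j - cy[s], dz = k - cz[s];
          double d = dx * dx + dy * dy + dz * dz;
          if (d < bd) { bd = d; bs = s; }
        }
        assign[li] = bs;
      }
    std::vector<double> sx(K), sy(K), sz(K), si(K);
    std::vector<long> cnt(K);
    for (size_t li = 0; li < N; ++li) {
      int s = assign[li];
      int i = li % X, j = (li / X) % Y, k = li / ((size_t)X * Y);
      sx[s] += i; sy[s] += j; sz[s] += k; si[s] += pv[li]; cnt[s] += 1;
    }
    for (int s = 0; s < K; ++s)
      if (cnt[s] > 0) {
        cx[s] = sx[s] / cnt[s]; cy[s] = sy[s] / cnt[s];
        cz[s] = sz[s] / cnt[s]; ci[s] = si[s] / cnt[s];
      }
  }
  // enforce connectivity: relabel connected components, absorbing small ones
  const long min_size = std::max(1L, (long)(min_frac * (double)N / K));
  std::vector<int> newlab(N, -1);
  int next = 0;
  const int dxs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dzs[6] = {0, 0, 0, 0, 1, -1};
  for (size_t start = 0; start < N; ++start) {
    if (newlab[start] >= 0) continue;
    std::vector<size_t> comp;
    int adj = -1;
    std::queue<size_t> q;
    q.push(start);
    newlab[start] = next;
    while (!q.empty()) {
      size_t li = q.front(); q.pop();
      comp.push_back(li);
      int i = li % X, j = (li / X) % Y, k = li / ((size_t)X * Y);
      for (int d = 0; d < 6; ++d) {
        int ii = i + dxs[d], jj = j + dys[d], kk = k + dzs[d];
        if (ii < 0 || ii >= X || jj < 0 || jj >= Y || kk < 0 || kk >= Z) continue;
        size_t lj = ii + (size_t)X * (jj + (size_t)Y * kk);
        if (newlab[lj] < 0 && assign[lj] == assign[start]) {
          newlab[lj] = next;
          q.push(lj);
        } else if (newlab[lj] >= 0 && newlab[lj] != next) {
          adj = newlab[lj];
        }
      }
    }
    if ((long)comp.size() < min_size && adj >= 0) {
      for (size_t li : comp) newlab[li] = adj;
    } else {
      ++next;
    }
  }
  // compact ids to 1..K' (absorption can leave gaps)
  std::vector<int> remap(next, -1);
  int kk = 0;
  for (size_t li = 0; li < N; ++li) {
    int s = newlab[li];
    if (remap[s] < 0) remap[s] = kk++;
    lab[li] = remap[s] + 1;
  }
  return lab;
}
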