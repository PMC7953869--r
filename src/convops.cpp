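#include <Rcpp.h>
using namespace Rcpp;

// Volumetric tensors use the layout (X, Y, Z, B, C), column-major.

// Direct fused convolution: accumulates the 3D convolution (same padding),
// adds the bias and applies leaky-ReLU in one pass.  Weight layout matches
// the im2col convention: W[kidx + K*cin, cout] with
// kidx = (dx+rx) + kx*((dy+ry) + ky*(dz+rz)).
// Returns the activated output and a 0/1 mask of negative pre-activations.
// [[Rcpp::export]]
List conv3d_fwd_direct(NumericVector x, IntegerVector dims,
                       NumericMatrix W, NumericVector bias,
                       int kx, int ky, int kz, double alpha) {
  const int X = dims[0], Y = dims[1], Z = dims[2], B = dims[3], C = dims[4];
  const int K = kx * ky * kz;
  const int Co = W.ncol();
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  const R_xlen_t volXYZ = planeXY * Z;
  const R_xlen_t volXYZB = volXYZ * B;
  NumericVector out(volXYZB * Co);
  RawVector neg(volXYZB * Co);
  const double *xa = x.begin();
  double *o = out.begin();
  Rbyte *ng = neg.begin();

  for (int co = 0; co < Co; ++co) {
    double *oc = o + (R_xlen_t)co * volXYZB;
    const double bco = bias[co];
    for (R_xlen_t i = 0; i < volXYZB; ++i) oc[i] = bco;
    for (int ci = 0; ci < C; ++ci) {
      const double *xc = xa + (R_xlen_t)ci * volXYZB;
      for (int dz = -rz; dz <= rz; ++dz)
        for (int dy = -ry; dy <= ry; ++dy) {
          // all three x-taps of the 3-wide kernel in one row pass
          const double wm = W(0 + kx * ((dy + ry) + ky * (dz + rz)) + K * ci, co);
          const double w0 = W(1 + kx * ((dy + ry) + ky * (dz + rz)) + K * ci, co);
          const double wp = W(2 + kx * ((dy + ry) + ky * (dz + rz)) + K * ci, co);
          const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
          const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
          for (int b = 0; b < B; ++b) {
            const double *xb = xc + (R_xlen_t)b * volXYZ;
            double *ob = oc + (R_xlen_t)b * volXYZ;
            for (int z = z0; z < z1; ++z) {
              const double *xpl = xb + (R_xlen_t)(z + dz) * planeXY;
              double *opl = ob + (R_xlen_t)z * planeXY;
              for (int y = y0; y < y1; ++y) {
                const double *__restrict xrow = xpl + (R_xlen_t)(y + dy) * X;
                double *__restrict orow = opl + (R_xlen_t)y * X;
                orow[0] += w0 * xrow[0] + wp * xrow[1];
                for (int xi = 1; xi < X - 1; ++xi)
                  orow[xi] += wm * xrow[xi - 1] + w0 * xrow[xi] + wp * xrow[xi + 1];
                orow[X - 1] += wm * xrow[X - 2] + w0 * xrow[X - 1];
              }
            }
          }
        }
    }
    for (R_xlen_t i = 0; i < volXYZB; ++i) {
      if (oc[i] < 0) { ng[(R_xlen_t)co * volXYZB + i] = 1; oc[i] *= alpha; }
    }
  }
  return List::create(_["out"] = out, _["neg"] = neg);
}

// Single-pass backward for the fused convolution: given the gradient on the
// activated output, the negative-preactivation mask, the layer input and the
// weights, returns grad input, grad weights and grad bias.
// [[Rcpp::export]]
List conv3d_bwd_direct(NumericVector d_out, RawVector neg, NumericVector x,
                       IntegerVector dims, NumericMatrix W,
                       int kx, int ky, int kz, double alpha) {
  const int X = dims[0], Y = dims[1], Z = dims[2], B = dims[3], C = dims[4];
  const int K = kx * ky * kz;
  const int Co = W.ncol();
  const int rx = kx / 2, ry = ky / 2, rz = kz / 2;
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  const R_xlen_t volXYZ = planeXY * Z;
  const R_xlen_t volXYZB = volXYZ * B;
  NumericVector dX(x.size());
  NumericMatrix dW(W.nrow(), Co);
  NumericVector db(Co);
  std::vector<double> dpre(volXYZB);
  const double *go = d_out.begin();
  const Rbyte *ng = neg.begin();
  const double *xa = x.begin();
  double *dxa = dX.begin();

  for (int co = 0; co < Co; ++co) {
    const double *gc = go + (R_xlen_t)co * volXYZB;
    const Rbyte *nc = ng + (R_xlen_t)co * volXYZB;
    double bsum = 0.0;
    for (R_xlen_t i = 0; i < volXYZB; ++i) {
      dpre[i] = nc[i] ? gc[i] * alpha : gc[i];
      bsum += dpre[i];
    }
    db[co] = bsum;
    for (int ci = 0; ci < C; ++ci) {
      const double *xc = xa + (R_xlen_t)ci * volXYZB;
      double *dxc = dxa + (R_xlen_t)ci * volXYZB;
      for (int dz = -rz; dz <= rz; ++dz)
        for (int dy = -ry; dy <= ry; ++dy) {
          const int kbase = kx * ((dy + ry) + ky * (dz + rz)) + K * ci;
          const double wm = W(kbase + 0, co);
          const double w0 = W(kbase + 1, co);
          const double wp = W(kbase + 2, co);
          double sm = 0.0, s0 = 0.0, sp = 0.0;
          const int z0 = std::max(0, -dz), z1 = std::min(Z, Z - dz);
          const int y0 = std::max(0, -dy), y1 = std::min(Y, Y - dy);
          for (int b = 0; b < B; ++b) {
            const double *xb = xc + (R_xlen_t)b * volXYZ;
            double *dxb = dxc + (R_xlen_t)b * volXYZ;
            const double *gb = dpre.data() + (R_xlen_t)b * volXYZ;
            for (int z = z0; z < z1; ++z) {
              const double *xpl = xb + (R_xlen_t)(z + dz) * planeXY;
              double *dxpl = dxb + (R_xlen_t)(z + dz) * planeXY;
              const double *gpl = gb + (R_xlen_t)z * planeXY;
              for (int y = y0; y < y1; ++y) {
                const double *__restrict xrow = xpl + (R_xlen_t)(y + dy) * X;
                double *__restrict dxrow = dxpl + (R_xlen_t)(y + dy) * X;
                const double *__restrict grow = gpl + (R_xlen_t)y * X;
                {
                  const double g = grow[0];
                  s0 += g * xrow[0]; sp += g * xrow[1];
                  dxrow[0] += w0 * g; dxrow[1] += wp * g;
                }
                for (int xi = 1; xi < X - 1; ++xi) {
                  const double g = grow[xi];
                  sm += g * xrow[xi - 1]; s0 += g * xrow[xi]; sp += g * xrow[xi + 1];
                  dxrow[xi - 1] += wm * g; dxrow[xi] += w0 * g; dxrow[xi + 1] += wp * g;
                }
                {
                  const double g = grow[X - 1];
                  sm += g * xrow[X - 2]; s0 += g * xrow[X - 1];
                  dxrow[X - 2] += wm * g; dxrow[X - 1] += w0 * g;
                }
              }
            }
          }
          dW(kbase + 0, co) = sm;
          dW(kbase + 1, co) = s0;
          dW(kbase + 2, co) = sp;
        }
    }
  }
  return List::create(_["dx"] = dX, _["gW"] = dW, _["gb"] = db);
}

// Max pooling with a 3x3x3 (or 3x3x1) window, clipped at borders.  Output
// positions are given explicitly per axis as 0-based window-centre indices,
// which lets the caller realise the architecture's per-axis stride rules.
// [[Rcpp::export]]
List maxpool3d_fwd(NumericVector arr, IntegerVector dims,
                   IntegerVector cx, IntegerVector cy, IntegerVector cz,
                   int half_z) {
  const int X = dims[0], Y = dims[1], Z = dims[2], B = dims[3], C = dims[4];
  const int OX = cx.size(), OY = cy.size(), OZ = cz.size();
  const R_xlen_t planeXY = (R_xlen_t)X * Y;
  const R_xlen_t volXYZ = planeXY * Z;
  const R_xlen_t volXYZB = volXYZ * B;
  const R_xlen_t no = (R_xlen_t)OX * OY * OZ * B * C;
  NumericVector out(no);
  IntegerVector arg(no);
  const double *a = arr.begin();
  double *o = out.begin();
  int *am = arg.begin();
  R_xlen_t oi = 0;
  for (int c = 0; c < C; ++c)
    for (int b = 0; b < B; ++b) {
      const double *abc = a + (R_xlen_t)c * volXYZB + (R_xlen_t)b * volXYZ;
      const R_xlen_t base = (R_xlen_t)c * volXYZB + (R_xlen_t)b * volXYZ;
      for (int oz = 0; oz < OZ; ++oz) {
        const int z0 = std::max(cz[oz] - half_z, 0);
        const int z1 = std::min(cz[oz] + half_z, Z - 1);
        for (int oy = 0; oy < OY; ++oy) {
          const int y0 = std::max(cy[oy] - 1, 0);
          const int y1 = std::min(cy[oy] + 1, Y - 1);
          for (int ox = 0; ox < OX; ++ox) {
            const int x0 = std::max(cx[ox] - 1, 0);
            const int x1 = std::min(cx[ox] + 1, X - 1);
            double best = R_NegInf;
            R_xlen_t besti = 0;
            for (int z = z0; z <= z1; ++z)
              for (int y = y0; y <= y1; ++y) {
                const double *row = abc + (R_xlen_t)z * planeXY + (R_xlen_t)y * X;
                for (int x = x0; x <= x1; ++x)
                  if (row[x] > best) {
                    best = row[x];
                    besti = base + (R_xlen_t)z * planeXY + (R_xlen_t)y * X + x;
                  }
              }
            o[oi] = best;
            am[oi] = (int)(besti + 1);  // 1-based linear index into arr
            ++oi;
          }
        }
      }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd(NumericVector grad, IntegerVector argmax,
                            R_xlen_t n_in) {
  NumericVector out(n_in);
  const double *g = grad.begin();
  const int *am = argmax.begin();
  double *o = out.begin();
  const R_xlen_t n = grad.size();
  for (R_xlen_t i = 0; i < n; ++i) o[am[i] - 1] += g[i];
  return out;
}
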