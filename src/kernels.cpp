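// Per-particle kernels of the particle-field engine: particle-mesh
// deposition and gathering with a selectable B-spline assignment window
// (order 2 = cloud-in-cell / trilinear, order 3 = triangular-shaped
// cloud / quadratic spline), plus harmonic bond and cosine-harmonic angle
// terms.  Each kernel has a *_jvp companion computing the exact
// directional derivative with respect to a tangent (dR, dlog L) of
// positions and box.  All mesh indexing is periodic; positions need not
// be pre-wrapped.
//
// The quadratic window matters for energy conservation: forces are
// defined as the exact position-gradient of the deposited weights, which
// is discontinuous at cell faces for the trilinear window but continuous
// for the quadratic one.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int pmod(int i, int n) {
  int r = i % n;
  return r < 0 ? r + n : r;
}

// per-axis stencil: base node index, number of points (2 or 3), weights
// and dweights/du (u = r n / L is the fractional coordinate)
struct AxisStencil {
  int i0;
  int np;
  double w[3];
  double dw[3];
};

static inline AxisStencil spline_axis(double u, int order) {
  AxisStencil st;
  if (order == 2) {
    double fl = std::floor(u);
    double f = u - fl;
    st.i0 = (int)fl;
    st.np = 2;
    st.w[0] = 1.0 - f; st.w[1] = f; st.w[2] = 0.0;
    st.dw[0] = -1.0;   st.dw[1] = 1.0; st.dw[2] = 0.0;
  } else {
    double fl = std::floor(u + 0.5);
    double d = u - fl; // in [-0.5, 0.5)
    st.i0 = (int)fl - 1;
    st.np = 3;
    st.w[0] = 0.5 * (0.5 - d) * (0.5 - d);
    st.w[1] = 0.75 - d * d;
    st.w[2] = 0.5 * (0.5 + d) * (0.5 + d);
    st.dw[0] = -(0.5 - d);
    st.dw[1] = -2.0 * d;
    st.dw[2] = 0.5 + d;
  }
  return st;
}

struct Stencil3 {
  AxisStencil ax[3];
};

static inline Stencil3 locate(const double *r, const double *box,
                              const int *dims, int order) {
  Stencil3 s;
  for (int a = 0; a < 3; ++a)
    s.ax[a] = spline_axis(r[a] * dims[a] / box[a], order);
  return s;
}

// counts(cell, species) += window weight; 'weight' is an optional
// per-particle factor (1 for number density, q_i for charge density).
// [[Rcpp::export]]
NumericMatrix cic_deposit_cpp(const NumericMatrix &R,
                              const IntegerVector &species,
                              const NumericVector &weight,
                              const NumericVector &box,
                              const IntegerVector &dims, int nspecies,
                              int order = 2) {
  const int N = R.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int dd[3] = {nx, ny, nz};
  double bb[3] = {box[0], box[1], box[2]};
  NumericMatrix counts(nx * ny * nz, nspecies);
  for (int i = 0; i < N; ++i) {
    double r[3] = {R(i, 0), R(i, 1), R(i, 2)};
    Stencil3 st = locate(r, bb, dd, order);
    int s = species[i] - 1;
    double wi = weight[i];
    for (int cx = 0; cx < st.ax[0].np; ++cx) {
      int ix = pmod(st.ax[0].i0 + cx, nx);
      double wx = st.ax[0].w[cx];
      for (int cy = 0; cy < st.ax[1].np; ++cy) {
        int iy = pmod(st.ax[1].i0 + cy, ny);
        double wxy = wx * st.ax[1].w[cy];
        for (int cz = 0; cz < st.ax[2].np; ++cz) {
          int iz = pmod(st.ax[2].i0 + cz, nz);
          counts(ix + nx * (iy + ny * iz), s) += wi * wxy * st.ax[2].w[cz];
        }
      }
    }
  }
  return counts;
}

// Tangent of the deposited counts under (dR, dlogL): the fractional
// coordinate is u_a = r_a n_a / L_a so du_a = (n_a/L_a) dr_a - u_a
// dlogL_a.  The 1/Vcell normalisation is applied by the caller.
// [[Rcpp::export]]
NumericMatrix cic_deposit_jvp_cpp(const NumericMatrix &R,
                                  const NumericMatrix &dR,
                                  const NumericVector &dlogL,
                                  const IntegerVector &species,
                                  const NumericVector &weight,
                                  const NumericVector &box,
                                  const IntegerVector &dims, int nspecies,
                                  int order = 2) {
  const int N = R.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int dd[3] = {nx, ny, nz};
  double bb[3] = {box[0], box[1], box[2]};
  NumericMatrix dcounts(nx * ny * nz, nspecies);
  const bool hasdR = dR.nrow() == N;
  for (int i = 0; i < N; ++i) {
    double r[3] = {R(i, 0), R(i, 1), R(i, 2)};
    Stencil3 st = locate(r, bb, dd, order);
    double du[3];
    for (int a = 0; a < 3; ++a) {
      double u = r[a] * dd[a] / bb[a];
      double dra = hasdR ? dR(i, a) : 0.0;
      du[a] = dra * dd[a] / bb[a] - u * dlogL[a];
    }
    int s = species[i] - 1;
    double wi = weight[i];
    for (int cx = 0; cx < st.ax[0].np; ++cx) {
      int ix = pmod(st.ax[0].i0 + cx, nx);
      double wx = st.ax[0].w[cx];
      double dwx = st.ax[0].dw[cx] * du[0];
      for (int cy = 0; cy < st.ax[1].np; ++cy) {
        int iy = pmod(st.ax[1].i0 + cy, ny);
        double wy = st.ax[1].w[cy];
        double dwy = st.ax[1].dw[cy] * du[1];
        for (int cz = 0; cz < st.ax[2].np; ++cz) {
          int iz = pmod(st.ax[2].i0 + cz, nz);
          double wz = st.ax[2].w[cz];
          double dwz = st.ax[2].dw[cz] * du[2];
          dcounts(ix + nx * (iy + ny * iz), s) +=
              wi * (dwx * wy * wz + wx * dwy * wz + wx * wy * dwz);
        }
      }
    }
  }
  return dcounts;
}

// Interpolate a per-species mesh field at the particle positions.
// [[Rcpp::export]]
NumericVector cic_gather_cpp(const NumericMatrix &field,
                             const NumericMatrix &R,
                             const IntegerVector &species,
                             const NumericVector &box,
                             const IntegerVector &dims, int order = 2) {
  const int N = R.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int dd[3] = {nx, ny, nz};
  double bb[3] = {box[0], box[1], box[2]};
  NumericVector out(N);
  for (int i = 0; i < N; ++i) {
    double r[3] = {R(i, 0), R(i, 1), R(i, 2)};
    Stencil3 st = locate(r, bb, dd, order);
    int s = species[i] - 1;
    double acc = 0.0;
    for (int cx = 0; cx < st.ax[0].np; ++cx) {
      int ix = pmod(st.ax[0].i0 + cx, nx);
      for (int cy = 0; cy < st.ax[1].np; ++cy) {
        int iy = pmod(st.ax[1].i0 + cy, ny);
        double wxy = st.ax[0].w[cx] * st.ax[1].w[cy];
        for (int cz = 0; cz < st.ax[2].np; ++cz) {
          int iz = pmod(st.ax[2].i0 + cz, nz);
          acc += wxy * st.ax[2].w[cz] * field(ix + nx * (iy + ny * iz), s);
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// G_i = sum_c V_{t(i)}(c) dw_i(c)/dr_i: the exact position-gradient of the
// deposited weights contracted with a per-species mesh field.  The field
// force is -G when V is the filtered-back external potential.
// [[Rcpp::export]]
NumericMatrix cic_gather_grad_cpp(const NumericMatrix &V,
                                  const NumericMatrix &R,
                                  const IntegerVector &species,
                                  const NumericVector &box,
                                  const IntegerVector &dims,
                                  int order = 2) {
  const int N = R.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int dd[3] = {nx, ny, nz};
  double bb[3] = {box[0], box[1], box[2]};
  NumericMatrix G(N, 3);
  double inv_h[3] = {dims[0] / box[0], dims[1] / box[1], dims[2] / box[2]};
  for (int i = 0; i < N; ++i) {
    double r[3] = {R(i, 0), R(i, 1), R(i, 2)};
    Stencil3 st = locate(r, bb, dd, order);
    int s = species[i] - 1;
    double gx = 0, gy = 0, gz = 0;
    for (int cx = 0; cx < st.ax[0].np; ++cx) {
      int ix = pmod(st.ax[0].i0 + cx, nx);
      double wx = st.ax[0].w[cx], dx = st.ax[0].dw[cx];
      for (int cy = 0; cy < st.ax[1].np; ++cy) {
        int iy = pmod(st.ax[1].i0 + cy, ny);
        double wy = st.ax[1].w[cy], dy = st.ax[1].dw[cy];
        for (int cz = 0; cz < st.ax[2].np; ++cz) {
          int iz = pmod(st.ax[2].i0 + cz, nz);
          double wz = st.ax[2].w[cz], dz = st.ax[2].dw[cz];
          double v = V(ix + nx * (iy + ny * iz), s);
          gx += v * dx * inv_h[0] * wy * wz;
          gy += v * wx * dy * inv_h[1] * wz;
          gz += v * wx * wy * dz * inv_h[2];
        }
      }
    }
    G(i, 0) = gx;
    G(i, 1) = gy;
    G(i, 2) = gz;
  }
  return G;
}

// Directional derivative of cic_gather_grad under (dV, dR, dlogL).
// [[Rcpp::export]]
NumericMatrix cic_gather_grad_jvp_cpp(const NumericMatrix &V,
                                      const NumericMatrix &dV,
                                      const NumericMatrix &R,
                                      const NumericMatrix &dR,
                                      const NumericVector &dlogL,
                                      const IntegerVector &species,
                                      const NumericVector &box,
                                      const IntegerVector &dims,
                                      int order = 2) {
  const int N = R.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  int dd[3] = {nx, ny, nz};
  double bb[3] = {box[0], box[1], box[2]};
  NumericMatrix dG(N, 3);
  double inv_h[3] = {dims[0] / box[0], dims[1] / box[1], dims[2] / box[2]};
  const bool hasdR = dR.nrow() == N;
  const bool hasdV = dV.nrow() == V.nrow();
  // second derivatives of the per-axis window weights w''(u)
  auto d2w = [&](const AxisStencil &ax, int c) -> double {
    if (ax.np == 2) return 0.0;
    return c == 1 ? -2.0 : 1.0;
  };
  for (int i = 0; i < N; ++i) {
    double r[3] = {R(i, 0), R(i, 1), R(i, 2)};
    Stencil3 st = locate(r, bb, dd, order);
    double du[3];
    for (int a = 0; a < 3; ++a) {
      double u = r[a] * dd[a] / bb[a];
      double dra = hasdR ? dR(i, a) : 0.0;
      du[a] = dra * dd[a] / bb[a] - u * dlogL[a];
    }
    int s = species[i] - 1;
    double acc[3] = {0, 0, 0};
    for (int cx = 0; cx < st.ax[0].np; ++cx) {
      int ix = pmod(st.ax[0].i0 + cx, nx);
      double wx = st.ax[0].w[cx], dx = st.ax[0].dw[cx];
      double dwx = dx * du[0];
      double ddx = d2w(st.ax[0], cx) * du[0]; // d(dw_x)/dtheta
      for (int cy = 0; cy < st.ax[1].np; ++cy) {
        int iy = pmod(st.ax[1].i0 + cy, ny);
        double wy = st.ax[1].w[cy], dy = st.ax[1].dw[cy];
        double dwy = dy * du[1];
        double ddy = d2w(st.ax[1], cy) * du[1];
        for (int cz = 0; cz < st.ax[2].np; ++cz) {
          int iz = pmod(st.ax[2].i0 + cz, nz);
          double wz = st.ax[2].w[cz], dz = st.ax[2].dw[cz];
          double dwz = dz * du[2];
          double ddz = d2w(st.ax[2], cz) * du[2];
          int c = ix + nx * (iy + ny * iz);
          double v = V(c, s);
          double dv = hasdV ? dV(c, s) : 0.0;
          // d/dtheta [ v * (n_a/L_a) * dw_a * (others' w) ]
          acc[0] += inv_h[0] *
            (dv * dx * wy * wz +
             v * (ddx * wy * wz + dx * dwy * wz + dx * wy * dwz) -
             v * dx * wy * wz * dlogL[0]);
          acc[1] += inv_h[1] *
            (dv * wx * dy * wz +
             v * (dwx * dy * wz + wx * ddy * wz + wx * dy * dwz) -
             v * wx * dy * wz * dlogL[1]);
          acc[2] += inv_h[2] *
            (dv * wx * wy * dz +
             v * (dwx * wy * dz + wx * dwy * dz + wx * wy * ddz) -
             v * wx * wy * dz * dlogL[2]);
        }
      }
    }
    dG(i, 0) = acc[0];
    dG(i, 1) = acc[1];
    dG(i, 2) = acc[2];
  }
  return dG;
}

static inline void min_image(double *d, const double *box, double *shift) {
  for (int a = 0; a < 3; ++a) {
    double m = std::nearbyint(d[a] / box[a]);
    d[a] -= m * box[a];
    shift[a] = m;
  }
}

// Harmonic bonds U = sum 1/2 k (r - r0)^2 with minimum-image distances.
// Returns energy, forces and the Clausius virial sum_b f_a d_b.
// [[Rcpp::export]]
List bond_ef_cpp(const NumericMatrix &R, const NumericVector &box,
                 const IntegerVector &bi, const IntegerVector &bj,
                 const NumericVector &r0, const NumericVector &kb) {
  const int N = R.nrow(), NB = bi.size();
  NumericMatrix F(N, 3);
  NumericMatrix vir(3, 3);
  double bb[3] = {box[0], box[1], box[2]};
  double U = 0.0;
  for (int b = 0; b < NB; ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    double d[3] = {R(i, 0) - R(j, 0), R(i, 1) - R(j, 1), R(i, 2) - R(j, 2)};
    double m[3];
    min_image(d, bb, m);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (r <= 0)
      stop("bond %d has zero length", b + 1);
    double dr = r - r0[b];
    U += 0.5 * kb[b] * dr * dr;
    double A = -kb[b] * dr / r; // F_i = A * d
    for (int a = 0; a < 3; ++a) {
      double fa = A * d[a];
      F(i, a) += fa;
      F(j, a) -= fa;
      for (int c = 0; c < 3; ++c)
        vir(a, c) += fa * d[c];
    }
  }
  return List::create(_["energy"] = U, _["forces"] = F, _["virial"] = vir);
}

// Tangent of bond energy/forces/virial.  The minimum-image integer shift m
// is held fixed, so d(d) = dRi - dRj - m*dbox.
// [[Rcpp::export]]
List bond_ef_jvp_cpp(const NumericMatrix &R, const NumericMatrix &dR,
                     const NumericVector &box, const NumericVector &dbox,
                     const IntegerVector &bi, const IntegerVector &bj,
                     const NumericVector &r0, const NumericVector &kb) {
  const int N = R.nrow(), NB = bi.size();
  NumericMatrix dF(N, 3);
  NumericMatrix dvir(3, 3);
  double bb[3] = {box[0], box[1], box[2]};
  const bool hasdR = dR.nrow() == N;
  double dU = 0.0;
  for (int b = 0; b < NB; ++b) {
    int i = bi[b] - 1, j = bj[b] - 1;
    double d[3] = {R(i, 0) - R(j, 0), R(i, 1) - R(j, 1), R(i, 2) - R(j, 2)};
    double m[3];
    min_image(d, bb, m);
    double dd[3];
    for (int a = 0; a < 3; ++a) {
      double t = hasdR ? dR(i, a) - dR(j, a) : 0.0;
      dd[a] = t - m[a] * dbox[a];
    }
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double drt = (d[0] * dd[0] + d[1] * dd[1] + d[2] * dd[2]) / r;
    double dr = r - r0[b];
    dU += kb[b] * dr * drt;
    double A = -kb[b] * dr / r;
    double dA = -kb[b] * r0[b] * drt / (r * r); // A = -k + k r0 / r
    for (int a = 0; a < 3; ++a) {
      double dfa = dA * d[a] + A * dd[a];
      double fa = A * d[a];
      dF(i, a) += dfa;
      dF(j, a) -= dfa;
      for (int c = 0; c < 3; ++c)
        dvir(a, c) += dfa * d[c] + fa * dd[c];
    }
  }
  return List::create(_["energy"] = dU, _["forces"] = dF, _["virial"] = dvir);
}

// Cosine-harmonic angles U = 1/2 k (cos t - cos t0)^2 (form = 1) or plain
// harmonic U = 1/2 k (t - t0)^2 (form = 2).  theta0 passed as cos(theta0)
// for form 1 and theta0 [rad] for form 2.
// [[Rcpp::export]]
List angle_ef_cpp(const NumericMatrix &R, const NumericVector &box,
                  const IntegerVector &ai, const IntegerVector &aj,
                  const IntegerVector &ak, const NumericVector &t0,
                  const NumericVector &ka, int form) {
  const int N = R.nrow(), NA_ = ai.size();
  NumericMatrix F(N, 3);
  NumericMatrix vir(3, 3);
  double bb[3] = {box[0], box[1], box[2]};
  double U = 0.0;
  for (int q = 0; q < NA_; ++q) {
    int i = ai[q] - 1, j = aj[q] - 1, k = ak[q] - 1;
    double u[3] = {R(i, 0) - R(j, 0), R(i, 1) - R(j, 1), R(i, 2) - R(j, 2)};
    double v[3] = {R(k, 0) - R(j, 0), R(k, 1) - R(j, 1), R(k, 2) - R(j, 2)};
    double mu[3], mv[3];
    min_image(u, bb, mu);
    min_image(v, bb, mv);
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (nu < 1e-12 || nv < 1e-12)
      stop("angle %d has a zero bond vector; angle undefined", q + 1);
    double c = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double pref; // dU/dc
    if (form == 1) {
      double g = c - t0[q];
      U += 0.5 * ka[q] * g * g;
      pref = ka[q] * g;
    } else {
      double th = std::acos(c);
      double g = th - t0[q];
      U += 0.5 * ka[q] * g * g;
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8)
        stop("angle %d is collinear; harmonic-theta force undefined", q + 1);
      pref = -ka[q] * g / s;
    }
    double fi[3], fk[3];
    for (int a = 0; a < 3; ++a) {
      double dcdu = v[a] / (nu * nv) - c * u[a] / (nu * nu);
      double dcdv = u[a] / (nu * nv) - c * v[a] / (nv * nv);
      fi[a] = -pref * dcdu;
      fk[a] = -pref * dcdv;
    }
    for (int a = 0; a < 3; ++a) {
      F(i, a) += fi[a];
      F(k, a) += fk[a];
      F(j, a) -= fi[a] + fk[a];
      for (int cc = 0; cc < 3; ++cc)
        vir(a, cc) += fi[a] * u[cc] + fk[a] * v[cc];
    }
  }
  return List::create(_["energy"] = U, _["forces"] = F, _["virial"] = vir);
}

// Tangent of the cosine-harmonic angle term (form 1 only; the traced
// sampling segment requires the cosine-harmonic form).
// [[Rcpp::export]]
List angle_ef_jvp_cpp(const NumericMatrix &R, const NumericMatrix &dR,
                      const NumericVector &box, const NumericVector &dbox,
                      const IntegerVector &ai, const IntegerVector &aj,
                      const IntegerVector &ak, const NumericVector &t0,
                      const NumericVector &ka) {
  const int N = R.nrow(), NA_ = ai.size();
  NumericMatrix dF(N, 3);
  NumericMatrix dvir(3, 3);
  double bb[3] = {box[0], box[1], box[2]};
  const bool hasdR = dR.nrow() == N;
  double dU = 0.0;
  for (int q = 0; q < NA_; ++q) {
    int i = ai[q] - 1, j = aj[q] - 1, k = ak[q] - 1;
    double u[3] = {R(i, 0) - R(j, 0), R(i, 1) - R(j, 1), R(i, 2) - R(j, 2)};
    double v[3] = {R(k, 0) - R(j, 0), R(k, 1) - R(j, 1), R(k, 2) - R(j, 2)};
    double mu[3], mv[3];
    min_image(u, bb, mu);
    min_image(v, bb, mv);
    double du[3], dv[3];
    for (int a = 0; a < 3; ++a) {
      double tu = hasdR ? dR(i, a) - dR(j, a) : 0.0;
      double tv = hasdR ? dR(k, a) - dR(j, a) : 0.0;
      du[a] = tu - mu[a] * dbox[a];
      dv[a] = tv - mv[a] * dbox[a];
    }
    double nu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double uv = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
    double c = uv / (nu * nv);
    double dnu = (u[0] * du[0] + u[1] * du[1] + u[2] * du[2]) / nu;
    double dnv = (v[0] * dv[0] + v[1] * dv[1] + v[2] * dv[2]) / nv;
    double duv = du[0] * v[0] + du[1] * v[1] + du[2] * v[2] +
                 u[0] * dv[0] + u[1] * dv[1] + u[2] * dv[2];
    double dc = duv / (nu * nv) - c * (dnu / nu + dnv / nv);
    double g = c - t0[q];
    dU += ka[q] * g * dc;
    double pref = ka[q] * g;
    double dpref = ka[q] * dc;
    for (int a = 0; a < 3; ++a) {
      double dcdu = v[a] / (nu * nv) - c * u[a] / (nu * nu);
      double dcdv = u[a] / (nu * nv) - c * v[a] / (nv * nv);
      double d_dcdu = dv[a] / (nu * nv) -
                      v[a] * (dnu * nv + nu * dnv) / (nu * nu * nv * nv) -
                      dc * u[a] / (nu * nu) - c * du[a] / (nu * nu) +
                      2.0 * c * u[a] * dnu / (nu * nu * nu);
      double d_dcdv = du[a] / (nu * nv) -
                      u[a] * (dnu * nv + nu * dnv) / (nu * nu * nv * nv) -
                      dc * v[a] / (nv * nv) - c * dv[a] / (nv * nv) +
                      2.0 * c * v[a] * dnv / (nv * nv * nv);
      double fi = -pref * dcdu;
      double fk = -pref * dcdv;
      double dfi = -dpref * dcdu - pref * d_dcdu;
      double dfk = -dpref * dcdv - pref * d_dcdv;
      dF(i, a) += dfi;
      dF(k, a) += dfk;
      dF(j, a) -= dfi + dfk;
      for (int cc = 0; cc < 3; ++cc)
        dvir(a, cc) += dfi * u[cc] + fi * du[cc] + dfk * v[cc] + fk * dv[cc];
    }
  }
  return List::create(_["energy"] = dU, _["forces"] = dF, _["virial"] = dvir);
}
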