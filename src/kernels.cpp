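// Hot loops: hexahedral element matrix assembly (vector stiffness from a
// per-quadrature-point tangent dP/dF, scalar mass/stiffness for the pore
// pressure solve) and regularized-delta spreading/interpolation between
// Lagrangian points and a uniform Cartesian grid.
//
// Conventions shared with the R code:
//  - per-quadrature-point fields have (n_elem * 8) rows, row (e-1)*8 + k
//  - dNdX is an (E, 8, 3, 8) array: (element, local node, X-dir, gauss pt)
//  - tensors are column-major 9-vectors (11,21,31,12,22,32,13,23,33)
//  - the 4-point kernel acts per axis; grid arrays are flattened i-fastest

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List hex_vector_stiffness_cpp(IntegerMatrix elems, NumericVector dNdX,
                              NumericMatrix wq, NumericMatrix A4) {
  const int E = elems.nrow();
  const double *dn = dNdX.begin();
  const R_xlen_t len = (R_xlen_t)E * 576;
  IntegerVector ti(len), tj(len);
  NumericVector tx(len);
  R_xlen_t pos = 0;
  double Ke[24][24];
  double g[8][3];
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 24; ++a)
      for (int b = 0; b < 24; ++b) Ke[a][b] = 0.0;
    for (int k = 0; k < 8; ++k) {
      const double w = wq(e, k);
      const int q = e * 8 + k;
      for (int a = 0; a < 8; ++a)
        for (int J = 0; J < 3; ++J)
          g[a][J] = dn[e + (R_xlen_t)E * (a + 8 * (J + 3 * k))];
      for (int a = 0; a < 8; ++a) {
        for (int i = 0; i < 3; ++i) {
          for (int b = 0; b < 8; ++b) {
            for (int m = 0; m < 3; ++m) {
              double acc = 0.0;
              for (int J = 0; J < 3; ++J) {
                const int iJ = i + 3 * J;
                for (int L = 0; L < 3; ++L) {
                  acc += g[a][J] * A4(q, iJ + 9 * (m + 3 * L)) * g[b][L];
                }
              }
              Ke[3 * a + i][3 * b + m] += w * acc;
            }
          }
        }
      }
    }
    for (int a = 0; a < 8; ++a) {
      for (int i = 0; i < 3; ++i) {
        const int dofa = 3 * (elems(e, a) - 1) + i + 1;
        for (int b = 0; b < 8; ++b) {
          for (int m = 0; m < 3; ++m) {
            ti[pos] = dofa;
            tj[pos] = 3 * (elems(e, b) - 1) + m + 1;
            tx[pos] = Ke[3 * a + i][3 * b + m];
            ++pos;
          }
        }
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// [[Rcpp::export]]
List hex_scalar_stiffness_cpp(IntegerMatrix elems, NumericVector dNdX,
                              NumericMatrix wq, NumericMatrix D) {
  const int E = elems.nrow();
  const double *dn = dNdX.begin();
  const R_xlen_t len = (R_xlen_t)E * 64;
  IntegerVector ti(len), tj(len);
  NumericVector tx(len);
  R_xlen_t pos = 0;
  double Ke[8][8];
  double g[8][3];
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b) Ke[a][b] = 0.0;
    for (int k = 0; k < 8; ++k) {
      const double w = wq(e, k);
      const int q = e * 8 + k;
      for (int a = 0; a < 8; ++a)
        for (int J = 0; J < 3; ++J)
          g[a][J] = dn[e + (R_xlen_t)E * (a + 8 * (J + 3 * k))];
      double Dq[3][3];
      for (int J = 0; J < 3; ++J)
        for (int L = 0; L < 3; ++L) Dq[J][L] = D(q, J + 3 * L);
      for (int a = 0; a < 8; ++a) {
        double Dg[3];
        for (int J = 0; J < 3; ++J) {
          Dg[J] = 0.0;
          for (int L = 0; L < 3; ++L) Dg[J] += Dq[J][L] * g[a][L];
        }
        for (int b = 0; b < 8; ++b) {
          double acc = 0.0;
          for (int J = 0; J < 3; ++J) acc += Dg[J] * g[b][J];
          Ke[a][b] += w * acc;
        }
      }
    }
    for (int a = 0; a < 8; ++a) {
      for (int b = 0; b < 8; ++b) {
        ti[pos] = elems(e, a);
        tj[pos] = elems(e, b);
        tx[pos] = Ke[a][b];
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// [[Rcpp::export]]
List hex_scalar_mass_cpp(IntegerMatrix elems, NumericMatrix N,
                         NumericMatrix wq, NumericVector coef) {
  const int E = elems.nrow();
  const R_xlen_t len = (R_xlen_t)E * 64;
  IntegerVector ti(len), tj(len);
  NumericVector tx(len);
  R_xlen_t pos = 0;
  double Me[8][8];
  for (int e = 0; e < E; ++e) {
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b) Me[a][b] = 0.0;
    for (int k = 0; k < 8; ++k) {
      const double cw = coef[e * 8 + k] * wq(e, k);
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b)
          Me[a][b] += cw * N(a, k) * N(b, k);
    }
    for (int a = 0; a < 8; ++a) {
      for (int b = 0; b < 8; ++b) {
        ti[pos] = elems(e, a);
        tj[pos] = elems(e, b);
        tx[pos] = Me[a][b];
        ++pos;
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}

// Peskin 4-point regularized delta (argument in units of the grid spacing)
static inline double peskin4(double r) {
  const double ar = std::fabs(r);
  if (ar >= 2.0) return 0.0;
  if (ar <= 1.0)
    return 0.125 * (3.0 - 2.0 * ar + std::sqrt(1.0 + 4.0 * ar - 4.0 * ar * ar));
  return 0.125 * (5.0 - 2.0 * ar - std::sqrt(-7.0 + 12.0 * ar - 4.0 * ar * ar));
}

// [[Rcpp::export]]
NumericVector ib_kernel_phi_cpp(NumericVector r) {
  NumericVector out(r.size());
  for (R_xlen_t i = 0; i < r.size(); ++i) out[i] = peskin4(r[i]);
  return out;
}

// Spread point values to a uniform grid component whose node (i,j,k) sits
// at origin + (i, j, k) * h (0-based).  out[idx] += val * wt * phi3 / h^3.
// [[Rcpp::export]]
NumericVector ib_spread_cpp(NumericMatrix pts, NumericVector val,
                            NumericVector wt, NumericVector origin,
                            double h, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double inv_h3 = 1.0 / (h * h * h);
  for (int p = 0; p < pts.nrow(); ++p) {
    const double gx = (pts(p, 0) - origin[0]) / h;
    const double gy = (pts(p, 1) - origin[1]) / h;
    const double gz = (pts(p, 2) - origin[2]) / h;
    const int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
              iz = (int)std::floor(gz);
    if (ix - 1 < 0 || ix + 2 >= nx || iy - 1 < 0 || iy + 2 >= ny ||
        iz - 1 < 0 || iz + 2 >= nz) {
      stop("structure point within kernel support of the domain boundary");
    }
    double wx[4], wy[4], wz[4];
    for (int o = 0; o < 4; ++o) {
      wx[o] = peskin4(gx - (ix - 1 + o));
      wy[o] = peskin4(gy - (iy - 1 + o));
      wz[o] = peskin4(gz - (iz - 1 + o));
    }
    const double vw = val[p] * wt[p] * inv_h3;
    for (int oz = 0; oz < 4; ++oz) {
      const R_xlen_t base_z = (R_xlen_t)(iz - 1 + oz) * nx * ny;
      for (int oy = 0; oy < 4; ++oy) {
        const R_xlen_t base = base_z + (R_xlen_t)(iy - 1 + oy) * nx + ix - 1;
        const double wzy = vw * wz[oz] * wy[oy];
        for (int ox = 0; ox < 4; ++ox) {
          out[base + ox] += wzy * wx[ox];
        }
      }
    }
  }
  return out;
}

// Interpolate a grid component at structure points (adjoint of spreading
// w.r.t. the grid/structure inner products).
// [[Rcpp::export]]
NumericVector ib_interp_cpp(NumericMatrix pts, NumericVector field,
                            NumericVector origin, double h,
                            IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); ++p) {
    const double gx = (pts(p, 0) - origin[0]) / h;
    const double gy = (pts(p, 1) - origin[1]) / h;
    const double gz = (pts(p, 2) - origin[2]) / h;
    const int ix = (int)std::floor(gx), iy = (int)std::floor(gy),
              iz = (int)std::floor(gz);
    if (ix - 1 < 0 || ix + 2 >= nx || iy - 1 < 0 || iy + 2 >= ny ||
        iz - 1 < 0 || iz + 2 >= nz) {
      stop("structure point within kernel support of the domain boundary");
    }
    double wx[4], wy[4], wz[4];
    for (int o = 0; o < 4; ++o) {
      wx[o] = peskin4(gx - (ix - 1 + o));
      wy[o] = peskin4(gy - (iy - 1 + o));
      wz[o] = peskin4(gz - (iz - 1 + o));
    }
    double acc = 0.0;
    for (int oz = 0; oz < 4; ++oz) {
      const R_xlen_t base_z = (R_xlen_t)(iz - 1 + oz) * nx * ny;
      for (int oy = 0; oy < 4; ++oy) {
        const R_xlen_t base = base_z + (R_xlen_t)(iy - 1 + oy) * nx + ix - 1;
        const double wzy = wz[oz] * wy[oy];
        for (int ox = 0; ox < 4; ++ox) {
          acc += field[base + ox] * wzy * wx[ox];
        }
      }
    }
    out[p] = acc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Quadrature-point kernels for the Lagrangian FE machinery (the R wrappers
// in fem.R keep the user-facing interface).

// deformation gradient stack: F[(e*8+k), i+3*j] = sum_a chi(elem(e,a), i) *
// dNdX(e, a, j, k)
// [[Rcpp::export]]
NumericMatrix qp_def_grad_cpp(IntegerMatrix elems, NumericVector dNdX,
                              NumericMatrix chi) {
  const int E = elems.nrow();
  NumericMatrix F((R_xlen_t)E * 8, 9);
  const double *dn = dNdX.begin();
  for (int e = 0; e < E; ++e) {
    double xn[8][3];
    for (int a = 0; a < 8; ++a) {
      const int nd = elems(e, a) - 1;
      for (int i = 0; i < 3; ++i) xn[a][i] = chi(nd, i);
    }
    for (int k = 0; k < 8; ++k) {
      const int row = e * 8 + k;
      for (int j = 0; j < 3; ++j) {
        double g[8];
        for (int a = 0; a < 8; ++a)
          g[a] = dn[e + (R_xlen_t)E * (a + 8 * (j + 3 * k))];
        for (int i = 0; i < 3; ++i) {
          double acc = 0.0;
          for (int a = 0; a < 8; ++a) acc += xn[a][i] * g[a];
          F(row, i + 3 * j) = acc;
        }
      }
    }
  }
  return F;
}

// reference gradient of a nodal scalar at quadrature points
// [[Rcpp::export]]
NumericMatrix qp_grad_cpp(IntegerMatrix elems, NumericVector dNdX,
                          NumericVector u) {
  const int E = elems.nrow();
  NumericMatrix out((R_xlen_t)E * 8, 3);
  const double *dn = dNdX.begin();
  for (int e = 0; e < E; ++e) {
    double un[8];
    for (int a = 0; a < 8; ++a) un[a] = u[elems(e, a) - 1];
    for (int k = 0; k < 8; ++k) {
      const int row = e * 8 + k;
      for (int j = 0; j < 3; ++j) {
        double acc = 0.0;
        for (int a = 0; a < 8; ++a)
          acc += un[a] * dn[e + (R_xlen_t)E * (a + 8 * (j + 3 * k))];
        out(row, j) = acc;
      }
    }
  }
  return out;
}

// nodal field interpolated to quadrature points
// [[Rcpp::export]]
NumericMatrix qp_interp_cpp(IntegerMatrix elems, NumericMatrix N,
                            NumericMatrix U) {
  const int E = elems.nrow();
  const int nc = U.ncol();
  NumericMatrix out((R_xlen_t)E * 8, nc);
  for (int e = 0; e < E; ++e) {
    for (int k = 0; k < 8; ++k) {
      const int row = e * 8 + k;
      for (int c = 0; c < nc; ++c) {
        double acc = 0.0;
        for (int a = 0; a < 8; ++a)
          acc += N(a, k) * U(elems(e, a) - 1, c);
        out(row, c) = acc;
      }
    }
  }
  return out;
}

// weak-form internal force (already accumulated over shared nodes):
// f(n, i) -= sum_{e,k,a: elem(e,a)=n} w(e,k) * P(q, iJ) * dNdX(e, a, J, k)
// [[Rcpp::export]]
NumericMatrix internal_force_cpp(IntegerMatrix elems, NumericVector dNdX,
                                 NumericMatrix wq, NumericMatrix P,
                                 int n_nodes) {
  const int E = elems.nrow();
  NumericMatrix f(n_nodes, 3);
  const double *dn = dNdX.begin();
  for (int e = 0; e < E; ++e) {
    for (int k = 0; k < 8; ++k) {
      const int q = e * 8 + k;
      const double w = wq(e, k);
      for (int a = 0; a < 8; ++a) {
        const int nd = elems(e, a) - 1;
        for (int i = 0; i < 3; ++i) {
          double acc = 0.0;
          for (int J = 0; J < 3; ++J)
            acc += P(q, i + 3 * J) *
              dn[e + (R_xlen_t)E * (a + 8 * (J + 3 * k))];
          f(nd, i) -= w * acc;
        }
      }
    }
  }
  return f;
}

// lumped projection numerator: sum_q N_a(q) w(q) V(q, c) scattered to nodes
// [[Rcpp::export]]
NumericMatrix qp_to_nodes_cpp(IntegerMatrix elems, NumericMatrix N,
                              NumericMatrix wq, NumericMatrix V,
                              int n_nodes) {
  const int E = elems.nrow();
  const int nc = V.ncol();
  NumericMatrix out(n_nodes, nc);
  for (int e = 0; e < E; ++e) {
    for (int k = 0; k < 8; ++k) {
      const int q = e * 8 + k;
      const double w = wq(e, k);
      for (int a = 0; a < 8; ++a) {
        const int nd = elems(e, a) - 1;
        const double nw = N(a, k) * w;
        for (int c = 0; c < nc; ++c) out(nd, c) += nw * V(q, c);
      }
    }
  }
  return out;
}

// nodal load vector of a per-quadrature-point scalar: int coef N_a dX
// [[Rcpp::export]]
NumericVector qp_load_cpp(IntegerMatrix elems, NumericMatrix N,
                          NumericMatrix wq, NumericVector coef,
                          int n_nodes) {
  const int E = elems.nrow();
  NumericVector out(n_nodes);
  for (int e = 0; e < E; ++e) {
    for (int k = 0; k < 8; ++k) {
      const double cw = coef[e * 8 + k] * wq(e, k);
      for (int a = 0; a < 8; ++a) out[elems(e, a) - 1] += N(a, k) * cw;
    }
  }
  return out;
}

// rank-one element stiffness of the mean-dilatation volumetric term:
// K_e = scale_e * g_e g_e^T with g_e[(a,i)] = sum_k w(e,k) *
//   JFt(q, i+3J) * dNdX(e, a, J, k)   (JFt = J F^-T per qp)
// [[Rcpp::export]]
List hex_bulk_rank1_cpp(IntegerMatrix elems, NumericVector dNdX,
                        NumericMatrix wq, NumericMatrix JFt,
                        NumericVector scale) {
  const int E = elems.nrow();
  const double *dn = dNdX.begin();
  const R_xlen_t len = (R_xlen_t)E * 576;
  IntegerVector ti(len), tj(len);
  NumericVector tx(len);
  R_xlen_t pos = 0;
  double g[24];
  for (int e = 0; e < E; ++e) {
    for (int d = 0; d < 24; ++d) g[d] = 0.0;
    for (int k = 0; k < 8; ++k) {
      const int q = e * 8 + k;
      const double w = wq(e, k);
      for (int a = 0; a < 8; ++a) {
        for (int i = 0; i < 3; ++i) {
          double acc = 0.0;
          for (int J = 0; J < 3; ++J)
            acc += JFt(q, i + 3 * J) *
              dn[e + (R_xlen_t)E * (a + 8 * (J + 3 * k))];
          g[3 * a + i] += w * acc;
        }
      }
    }
    for (int a = 0; a < 8; ++a) {
      for (int i = 0; i < 3; ++i) {
        const int dofa = 3 * (elems(e, a) - 1) + i + 1;
        for (int b = 0; b < 8; ++b) {
          for (int m = 0; m < 3; ++m) {
            ti[pos] = dofa;
            tj[pos] = 3 * (elems(e, b) - 1) + m + 1;
            tx[pos] = scale[e] * g[3 * a + i] * g[3 * b + m];
            ++pos;
          }
        }
      }
    }
  }
  return List::create(_["i"] = ti, _["j"] = tj, _["x"] = tx);
}
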