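# Immersed-boundary coupling: uniform staggered (MAC) Eulerian grid,
# Peskin 4-point regularized-delta spreading/interpolation between the
# Lagrangian structure and the grid, and a semi-implicit incompressible
# fluid step with a volumetric source: explicit upwind advection, implicit
# viscosity, and an exact discrete projection enforcing div v = s* cell by
# cell.
#
# Outer boundary condition: zero normal traction approximated as zero
# pressure with zero tangential slip on all boundaries; the normal velocity
# at the boundary is free (flow may enter or leave, as required by a net
# volumetric source).

#' Uniform staggered Eulerian grid
#'
#' Face-centred velocity components, cell-centred pressure multiplier and
#' source.  The spacing must be isotropic.
#'
#' @param box_min,box_max domain corners (m), length 3.
#' @param N cells per axis (scalar or length 3); `>= 8`.
#' @return an object of class `"eulerian_grid"`.
#' @export
eulerian_grid <- function(box_min, box_max, N) {
  N <- as.integer(rep_len(N, 3L))
  stopifnot(all(N >= 8L), all(box_max > box_min))
  h <- (box_max - box_min) / N
  if (diff(range(h)) > 1e-12 * max(h)) {
    stop("eulerian_grid(): spacing must be isotropic")
  }
  h <- h[1]
  dims <- list(u = c(N[1] + 1L, N[2], N[3]),
               v = c(N[1], N[2] + 1L, N[3]),
               w = c(N[1], N[2], N[3] + 1L),
               p = N)
  # coordinate of grid index (1,1,1) per component
  org <- function(face_axis) {
    o <- box_min + h / 2
    if (!is.na(face_axis)) o[face_axis] <- box_min[face_axis]
    o
  }
  origins <- list(u = org(1L), v = org(2L), w = org(3L), p = org(NA))
  structure(list(box_min = box_min, box_max = box_max, N = N, h = h,
                 dims = dims, origins = origins),
            class = "eulerian_grid")
}

#' Zero Eulerian state
#'
#' @param grid an [eulerian_grid()].
#' @return list of arrays `u`, `v`, `w` (face velocities, m/s) and `p_ib`
#'   (cell pressure multiplier, Pa), all zero.
#' @export
euler_state <- function(grid) {
  z <- function(d) array(0, d)
  list(u = z(grid$dims$u), v = z(grid$dims$v), w = z(grid$dims$w),
       p_ib = z(grid$dims$p))
}

# 1D building blocks -------------------------------------------------------

spmat <- function(i, j, x, d1, d2) {
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(d1, d2))
}

speye <- function(n) Matrix::Diagonal(n)

# divergence: n cells from n+1 faces, 1/h factors applied by caller
d1_div <- function(n) {
  spmat(c(1:n, 1:n), c(1:n, 2:(n + 1)), c(rep(-1, n), rep(1, n)), n, n + 1L)
}

# gradient: n+1 faces from n cells with p = 0 Dirichlet at the two
# boundary faces (ghost mirror): boundary rows carry factor 2
d1_grad <- function(n) {
  i <- c(1L, 2:n, 2:n, n + 1L)
  j <- c(1L, 1:(n - 1), 2:n, n)
  x <- c(2, rep(-1, n - 1), rep(1, n - 1), -2)
  spmat(i, j, x, n + 1L, n)
}

# 1D Laplacian on cell-centred points with Dirichlet-0 walls (ghost mirror)
d1_lap_cell <- function(n) {
  main <- c(-3, rep(-2, max(n - 2L, 0L)), -3)[1:n]
  spmat(c(1:n, 1:(n - 1), 2:n), c(1:n, 2:n, 1:(n - 1)),
        c(main, rep(1, n - 1), rep(1, n - 1)), n, n)
}

# 1D Laplacian on node points (faces) with zero-gradient ends
d1_lap_node <- function(n) {
  main <- c(-1, rep(-2, max(n - 2L, 0L)), -1)[1:n]
  spmat(c(1:n, 1:(n - 1), 2:n), c(1:n, 2:n, 1:(n - 1)),
        c(main, rep(1, n - 1), rep(1, n - 1)), n, n)
}

kron3 <- function(Az, Ay, Ax) {
  Matrix::kronecker(Az, Matrix::kronecker(Ay, Ax))
}

#' Precompute grid operators and factorizations
#'
#' Divergence and gradient operators, the projection Poisson factorization
#' (with zero-pressure boundary), and the implicit-viscosity Helmholtz
#' factorizations per velocity component (zero tangential slip at walls,
#' zero normal gradient for the normal component).
#'
#' @param grid an [eulerian_grid()].
#' @param mu dynamic viscosity (Pa s).
#' @param rho fluid density (kg m^-3).
#' @param dt time step (s) for which the Helmholtz operators are built.
#' @return an opaque list used by [fluid_step()].
#' @export
grid_ops <- function(grid, mu, rho, dt) {
  N <- grid$N; h <- grid$h
  Ix <- speye(N[1]); Iy <- speye(N[2]); Iz <- speye(N[3])
  Du <- kron3(Iz, Iy, d1_div(N[1])) / h
  Dv <- kron3(Iz, d1_div(N[2]), Ix) / h
  Dw <- kron3(d1_div(N[3]), Iy, Ix) / h
  Gu <- kron3(Iz, Iy, d1_grad(N[1])) / h
  Gv <- kron3(Iz, d1_grad(N[2]), Ix) / h
  Gw <- kron3(d1_grad(N[3]), Iy, Ix) / h
  L <- Du %*% Gu + Dv %*% Gv + Dw %*% Gw  # negative definite
  facP <- Matrix::Cholesky(Matrix::forceSymmetric(-L))
  nu <- mu / rho
  lap_u <- (kron3(Iz, Iy, d1_lap_node(N[1] + 1L)) +
            kron3(Iz, d1_lap_cell(N[2]), speye(N[1] + 1L)) +
            kron3(d1_lap_cell(N[3]), Iy, speye(N[1] + 1L))) / h^2
  lap_v <- (kron3(Iz, speye(N[2] + 1L), d1_lap_cell(N[1])) +
            kron3(Iz, d1_lap_node(N[2] + 1L), Ix) +
            kron3(d1_lap_cell(N[3]), speye(N[2] + 1L), Ix)) / h^2
  lap_w <- (kron3(speye(N[3] + 1L), Iy, d1_lap_cell(N[1])) +
            kron3(speye(N[3] + 1L), d1_lap_cell(N[2]), Ix) +
            kron3(d1_lap_node(N[3] + 1L), Iy, Ix)) / h^2
  nu_dt <- nu * dt
  facU <- Matrix::Cholesky(Matrix::forceSymmetric(
    speye(prod(grid$dims$u)) - nu_dt * lap_u))
  facV <- Matrix::Cholesky(Matrix::forceSymmetric(
    speye(prod(grid$dims$v)) - nu_dt * lap_v))
  facW <- Matrix::Cholesky(Matrix::forceSymmetric(
    speye(prod(grid$dims$w)) - nu_dt * lap_w))
  list(Du = Du, Dv = Dv, Dw = Dw, Gu = Gu, Gv = Gv, Gw = Gw,
       facP = facP, facU = facU, facV = facV, facW = facW,
       mu = mu, rho = rho, dt = dt)
}

# first-order upwind advection term for one component field `q` on its own
# grid, advected by (au, av, aw) given on the same grid
upwind_advect <- function(q, au, av, aw, h) {
  d <- dim(q)
  shift <- function(arr, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  term <- function(a, ax) {
    back <- (q - shift(q, ax, -1L)) / h
    fwd <- (shift(q, ax, 1L) - q) / h
    a * ifelse(a > 0, back, fwd)
  }
  term(au, 1L) + term(av, 2L) + term(aw, 3L)
}

# average a MAC component onto another component's grid (for advecting
# velocities); simple 4-point face average with edge clamping
avg_to <- function(src, from_axis, to_axis, dims_to) {
  # average over the `from_axis` face pairs and interpolate along `to_axis`
  d <- dim(src)
  pick <- function(arr, ax, ids) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[ax]] <- ids
    do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  # to cell centres along from_axis
  cc <- (pick(src, from_axis, 1:(d[from_axis] - 1L)) +
         pick(src, from_axis, 2:d[from_axis])) / 2
  # to faces along to_axis (clamped ends)
  n <- dim(cc)[to_axis]
  lo <- pick(cc, to_axis, c(1L, 1:n))
  hi <- pick(cc, to_axis, c(1:n, n))
  out <- (lo + hi) / 2
  stopifnot(all(dim(out) == dims_to))
  out
}

#' One semi-implicit fluid step with a volumetric source
#'
#' Advances the Eulerian momentum equation
#' `rho Dv/Dt = -grad p_ib + mu lap v + f_e` subject to `div v = s*`:
#' explicit first-order upwind advection and force, implicit (backward
#' Euler) viscosity, then a pressure projection solving
#' `lap phi = (rho/dt)(div v* - s*)` with zero boundary pressure, so the
#' end-of-step discrete divergence equals `s*` in every cell to solver
#' precision.
#'
#' @param state an [euler_state()].
#' @param f list of face arrays `fu`, `fv`, `fw` (force density, N m^-3),
#'   or `NULL`.
#' @param s_star cell array of the volumetric source (s^-1), or `NULL`.
#' @param grid an [eulerian_grid()].
#' @param ops a [grid_ops()] built with the same `dt`.
#' @param dt time step (s).
#' @return the updated state.
#' @export
fluid_step <- function(state, f, s_star, grid, ops, dt) {
  stopifnot(abs(dt - ops$dt) < 1e-14 * dt)
  h <- grid$h; rho <- ops$rho
  vmax <- max(abs(state$u), abs(state$v), abs(state$w))
  if (vmax * dt / h > 0.5) {
    stop(sprintf("CFL violation: |v| dt/h = %.3f > 0.5 (|v|max = %.3g m/s)",
                 vmax * dt / h, vmax))
  }
  adv_u <- upwind_advect(state$u, state$u,
                         avg_to(state$v, 2L, 1L, grid$dims$u),
                         avg_to(state$w, 3L, 1L, grid$dims$u), h)
  adv_v <- upwind_advect(state$v, avg_to(state$u, 1L, 2L, grid$dims$v),
                         state$v,
                         avg_to(state$w, 3L, 2L, grid$dims$v), h)
  adv_w <- upwind_advect(state$w, avg_to(state$u, 1L, 3L, grid$dims$w),
                         avg_to(state$v, 2L, 3L, grid$dims$w),
                         state$w, h)
  rhs_u <- state$u + dt * (-adv_u + (if (is.null(f)) 0 else f$fu) / rho)
  rhs_v <- state$v + dt * (-adv_v + (if (is.null(f)) 0 else f$fv) / rho)
  rhs_w <- state$w + dt * (-adv_w + (if (is.null(f)) 0 else f$fw) / rho)
  us <- as.vector(Matrix::solve(ops$facU, as.vector(rhs_u)))
  vs <- as.vector(Matrix::solve(ops$facV, as.vector(rhs_v)))
  ws <- as.vector(Matrix::solve(ops$facW, as.vector(rhs_w)))
  div_star <- as.vector(ops$Du %*% us + ops$Dv %*% vs + ops$Dw %*% ws)
  src <- if (is.null(s_star)) 0 else as.vector(s_star)
  phi <- as.vector(Matrix::solve(ops$facP, -(rho / dt) * (div_star - src)))
  un <- us - (dt / rho) * as.vector(ops$Gu %*% phi)
  vn <- vs - (dt / rho) * as.vector(ops$Gv %*% phi)
  wn <- ws - (dt / rho) * as.vector(ops$Gw %*% phi)
  list(u = array(un, grid$dims$u), v = array(vn, grid$dims$v),
       w = array(wn, grid$dims$w), p_ib = array(phi, grid$dims$p))
}

#' Cell-wise divergence of the staggered velocity
#'
#' @param state an [euler_state()].
#' @param ops a [grid_ops()].
#' @param grid an [eulerian_grid()].
#' @return cell array of `div v` (s^-1).
#' @export
grid_divergence <- function(state, ops, grid) {
  array(as.vector(ops$Du %*% as.vector(state$u) +
                  ops$Dv %*% as.vector(state$v) +
                  ops$Dw %*% as.vector(state$w)), grid$dims$p)
}

# Spreading / interpolation -------------------------------------------------

#' Peskin 4-point regularized delta (one axis)
#'
#' Satisfies the discrete partition of unity and zero first moment for any
#' sub-grid offset; support `|r| < 2` grid cells.
#'
#' @param r offset in units of the grid spacing.
#' @return kernel weights.
#' @export
ib_kernel <- function(r) ib_kernel_phi_cpp(as.numeric(r))

#' Spread Lagrangian point forces to the staggered grid
#'
#' `f(x) = sum_q F(X_q) phi_h(x - chi_q) w_q`, per velocity component on
#' its own face grid; `phi_h` is the tensor-product 4-point kernel scaled
#' by `1/h^3`, so the grid integral of `f` equals the total Lagrangian
#' force exactly.
#'
#' @param Fq `np x 3` force densities at structure points (N m^-3 of
#'   reference volume).
#' @param pts `np x 3` current positions (m); must keep two cells of
#'   clearance from the domain boundary.
#' @param wts reference quadrature weights (m^3).
#' @param grid an [eulerian_grid()].
#' @return list of face arrays `fu`, `fv`, `fw`.
#' @export
spread_force <- function(Fq, pts, wts, grid) {
  list(fu = array(ib_spread_cpp(pts, Fq[, 1], wts, grid$origins$u, grid$h,
                                grid$dims$u), grid$dims$u),
       fv = array(ib_spread_cpp(pts, Fq[, 2], wts, grid$origins$v, grid$h,
                                grid$dims$v), grid$dims$v),
       fw = array(ib_spread_cpp(pts, Fq[, 3], wts, grid$origins$w, grid$h,
                                grid$dims$w), grid$dims$w))
}

#' Spread the Lagrangian volumetric source to cell centres
#'
#' @param Sq source values at structure points (s^-1, per reference
#'   volume).
#' @inheritParams spread_force
#' @return cell array `s*`; its grid integral equals `sum(Sq * wts)`
#'   exactly (kernel partition of unity).
#' @export
spread_source <- function(Sq, pts, wts, grid) {
  array(ib_spread_cpp(pts, Sq, wts, grid$origins$p, grid$h, grid$dims$p),
        grid$dims$p)
}

#' Interpolate the grid velocity at structure points
#'
#' Adjoint of [spread_force()] with respect to the grid and structure
#' inner products; exact for linear velocity fields (kernel moment
#' conditions).
#'
#' @param state an [euler_state()].
#' @param pts `np x 3` positions (m).
#' @param grid an [eulerian_grid()].
#' @return `np x 3` matrix of velocities (m/s).
#' @export
interpolate_velocity <- function(state, pts, grid) {
  cbind(ib_interp_cpp(pts, as.vector(state$u), grid$origins$u, grid$h,
                      grid$dims$u),
        ib_interp_cpp(pts, as.vector(state$v), grid$origins$v, grid$h,
                      grid$dims$v),
        ib_interp_cpp(pts, as.vector(state$w), grid$origins$w, grid$h,
                      grid$dims$w))
}
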