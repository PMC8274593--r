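# Lagrangian finite-element Darcy solver for the pore fluid on the deforming
# skeleton mesh: the split-step temporal scheme advancing (p, W, m) through
# two half-steps, with the pore pressure updated implicitly (Q1 Galerkin,
# backward Euler) and the Darcy flux and added mass recovered explicitly.
#
# The pressure equation is used in the rederived, dimensionally consistent
# form obtained by substituting the mass balance dm/dt = rho S - div_X(rho W)
# into the chain rule dp/dt = A_aug dm/dt + (B + C) dJ/dt:
#
#   (1/(A_aug rho)) dp/dt - div_X( J F^-1 K F^-T grad_X p )
#        = S + (B + C) (dJ/dt) / (A_aug rho)
#
# with A_aug = Mb f(J)/rho + kappa0 rho/(m + rho phi0)^2 (the penalty-term
# rate folded into the compressibility coefficient).

#' Pore-fluid state on a skeleton mesh
#'
#' @param mesh a [lagrangian_mesh()].
#' @return an object of class `"porous_field"`: nodal pore pressure `p`
#'   (Pa), added mass `m` (kg m^-3) and Lagrangian Darcy flux `W` (m s^-1)
#'   at quadrature points, and the source `S` (s^-1) at quadrature points.
#'   All zero: the reference (trivial) state.
#' @export
pore_field <- function(mesh) {
  structure(list(p = numeric(mesh$n_nodes), m = numeric(mesh$nq),
                 W = matrix(0, mesh$nq, 3), S = numeric(mesh$nq)),
            class = "porous_field")
}

#' Pore-pressure boundary conditions
#'
#' Dirichlet pressure values on tagged facet sets; every untagged facet
#' carries the natural zero-flux condition of the weak form.
#'
#' @param dirichlet named list mapping facet tags to a pressure ramp: a
#'   constant (Pa) or a function of time `t` (s).
#' @return an object of class `"pore_bc"`.
#' @export
pore_bc <- function(dirichlet = list()) {
  structure(list(dirichlet = dirichlet), class = "pore_bc")
}

bc_nodes_values <- function(mesh, bc, t) {
  nodes <- integer(0); vals <- numeric(0)
  for (tag in names(bc$dirichlet)) {
    fn <- mesh$facets[[tag]]
    if (is.null(fn)) stop("pore BC references unknown facet tag '", tag, "'")
    v <- bc$dirichlet[[tag]]
    val <- if (is.function(v)) v(t) else v
    nd <- unique(as.vector(fn))
    nodes <- c(nodes, nd); vals <- c(vals, rep(val, length(nd)))
  }
  if (anyDuplicated(nodes)) {
    keep <- !duplicated(nodes)
    nodes <- nodes[keep]; vals <- vals[keep]
  }
  list(nodes = nodes, values = vals)
}

# permeability pushed to the reference frame: J F^-1 K F^-T per qp (nq x 9)
reference_permeability <- function(kin, K) {
  Fi <- t3_inv(kin$F)
  Kst <- as_t3(K, nrow(Fi))
  kin$J * t3_mul(Fi, t3_mul(Kst, t3_transpose(Fi)))
}

#' Implicit pressure half-step
#'
#' Backward-Euler solve of the rederived pressure equation over `dt/2` with
#' first-order (trilinear) Lagrangian basis functions:
#' `(2/dt) M_c (p* - p^n) + K p* = b`, where `M_c` is the mass matrix
#' weighted by `1/(A_aug rho)`, `K` the stiffness matrix with conductivity
#' `J F^-1 K F^-T`, and `b` carries the source `S` plus the dilatation-rate
#' forcing `(B + C) (dJ/dt)/(A_aug rho)`.  Dirichlet rows are eliminated
#' symmetrically; the SPD system is solved by sparse Cholesky.
#'
#' Both distributed source models are affine in the pore pressure,
#' `S(p) = s0 - s1 p` with `s1 >= 0`, so the source is taken implicitly at
#' the new pressure (the system stays linear and the update remains stable
#' for steps far larger than the source relaxation time
#' `1/(A_aug rho s1)`).  Any additional per-quadrature-point forcing in
#' `field$S` (e.g. manufactured solutions) enters explicitly.
#'
#' @param field a [pore_field()] (supplies `p^n`, `m^n`, and the explicit
#'   extra forcing `S`).
#' @param kin a [compute_kinematics()] result (supplies `F`, `J`, `dJ/dt`).
#' @param mesh a [lagrangian_mesh()].
#' @param bc a [pore_bc()].
#' @param params a [poro_params()].
#' @param dt full time step (s); the solve advances `dt/2`.
#' @param t_target time at which Dirichlet ramps are evaluated (s).
#' @param src a [source_params()] treated implicitly, or `NULL`.
#' @param Dperm optional precomputed reference permeability (`nq x 9`).
#' @return nodal pressure vector `p` at the half step (Pa).
#' @export
assemble_pressure_halfstep <- function(field, kin, mesh, bc, params, dt,
                                       t_target, src = NULL, Dperm = NULL) {
  co <- pressure_coefficients(field$m, kin$J, params)
  c0 <- 1 / (co$A_aug * params$rho)
  if (is.null(Dperm)) Dperm <- reference_permeability(kin, params$K)
  tm <- hex_scalar_mass_cpp(mesh$elems, mesh$N, mesh$wq, c0)
  tk <- hex_scalar_stiffness_cpp(mesh$elems, mesh$dNdX, mesh$wq, Dperm)
  n <- mesh$n_nodes
  ai <- c(tm$i, tk$i); aj <- c(tm$j, tk$j)
  ax <- c(tm$x * 2 / dt, tk$x)
  rhs_coef <- field$S + c0 * (co$B + co$C) * kin$dJdt
  if (!is.null(src)) {
    sc <- source_affine_coeffs(src)
    if (sc$s1 > 0) {
      ts <- hex_scalar_mass_cpp(mesh$elems, mesh$N, mesh$wq,
                                rep(sc$s1, mesh$nq))
      ai <- c(ai, ts$i); aj <- c(aj, ts$j); ax <- c(ax, ts$x)
    }
    rhs_coef <- rhs_coef + sc$s0
  }
  A <- Matrix::sparseMatrix(i = ai, j = aj, x = ax, dims = c(n, n))
  b <- qp_load_vector(mesh, rhs_coef)
  Mp <- Matrix::sparseMatrix(i = tm$i, j = tm$j, x = tm$x * 2 / dt,
                             dims = c(n, n))
  rhs <- b + as.vector(Mp %*% field$p)
  bcnv <- bc_nodes_values(mesh, bc, t_target)
  p <- numeric(n)
  if (length(bcnv$nodes) > 0) {
    fixed <- bcnv$nodes
    free <- setdiff(seq_len(n), fixed)
    p[fixed] <- bcnv$values
    rhs_free <- rhs[free] -
      as.vector(A[free, fixed, drop = FALSE] %*% bcnv$values)
    p[free] <- as.vector(Matrix::solve(A[free, free], rhs_free))
  } else {
    p <- as.vector(Matrix::solve(A, rhs))
  }
  p
}

#' Lagrangian Darcy flux from the pore-pressure field
#'
#' `W = -J F^-1 K F^-T grad_X p` at quadrature points: the reference-frame
#' (pulled-back) Darcy law.
#'
#' @param p nodal pore pressure (Pa).
#' @param kin a [compute_kinematics()] result.
#' @param mesh a [lagrangian_mesh()].
#' @param K permeability (scalar or 3x3, m^2 Pa^-1 s^-1).
#' @param Dperm optional precomputed reference permeability (`nq x 9`).
#' @return `nq x 3` matrix of fluxes (m s^-1).
#' @export
darcy_flux <- function(p, kin, mesh, K, Dperm = NULL) {
  gp <- qp_grad(mesh, p)
  if (is.null(Dperm)) {
    Dperm <- reference_permeability(kin,
                                    if (length(K) == 1L) diag(3) * K else K)
  }
  -t3_matvec(Dperm, gp)
}

#' Added mass recovered from the half-step pressure
#'
#' Inverts the pore-pressure law at each quadrature point,
#' `pore_pressure(m, J^n) = p*`, by safeguarded Newton iteration (the exact
#' nonlinear counterpart of the printed linearized recovery; identical when
#' the penalty term is negligible).
#'
#' @param p_half nodal half-step pressure (Pa).
#' @param kin a [compute_kinematics()] result.
#' @param mesh a [lagrangian_mesh()].
#' @param field the current [pore_field()] (its `m` seeds the iteration).
#' @param params a [poro_params()].
#' @return added mass per quadrature point (kg m^-3).
#' @export
recover_added_mass <- function(p_half, kin, mesh, field, params) {
  pq <- qp_interp(mesh, p_half)
  invert_pore_pressure(pq, kin$J, params, m_guess = field$m)
}

#' Explicit added-mass half-update from the mass balance
#'
#' `m^(n+1) = m* + (dt/2) (rho S - div_X(rho W))`, with the divergence of
#' the (quadrature-point) flux evaluated through a lumped nodal projection
#' followed by shape-function differentiation.
#'
#' @param m_half added mass after the recovery half-step (kg m^-3).
#' @param W Lagrangian flux used in the divergence (the start-of-step flux
#'   in the printed scheme), `nq x 3`.
#' @param S volumetric source per quadrature point (s^-1).
#' @param mesh a [lagrangian_mesh()].
#' @param dt full time step (s); the update advances `dt/2`.
#' @param params a [poro_params()].
#' @return updated added mass per quadrature point (kg m^-3).
#' @export
advance_added_mass <- function(m_half, W, S, mesh, dt, params) {
  Wn <- qp_to_nodes(mesh, W)
  divW <- qp_grad(mesh, Wn[, 1])[, 1] + qp_grad(mesh, Wn[, 2])[, 2] +
    qp_grad(mesh, Wn[, 3])[, 3]
  m <- m_half + (dt / 2) * (params$rho * S - params$rho * divW)
  # porosity floor: the kappa0 penalty keeps the implicit stages above
  # -rho*phi0, but this explicit update can overshoot through the wall
  # when the pore space is nearly exhausted (full drainage); clamp just
  # above the bound (well below where the penalty equilibrates)
  floor_m <- -params$rho * params$phi0
  pmax(m, floor_m + 1e-8 * abs(floor_m))
}

#' One full split-step Darcy update
#'
#' Advances `(p, W, m)` by `dt` in the printed order, twice `p -> W -> m`:
#' first half-step -- implicit pressure, flux from the new pressure, added
#' mass recovered from the pressure law; second half-step -- implicit
#' pressure with the half-step coefficients, flux, then the explicit mass
#' balance update using the start-of-step flux.  The distributed source is
#' evaluated at the lagged pressure so each pressure solve stays linear.
#'
#' @param field a [pore_field()] at time `t`.
#' @param kin a [compute_kinematics()] result for this time level.
#' @param mesh a [lagrangian_mesh()].
#' @param bc a [pore_bc()].
#' @param src a [source_params()] or `NULL` for no source.
#' @param params a [poro_params()].
#' @param dt time step (s).
#' @param t current time (s).
#' @return the updated [pore_field()] at `t + dt`.
#' @export
step_darcy <- function(field, kin, mesh, bc, src, params, dt, t) {
  fld <- field; fld$S <- field$S * 0  # field$S holds diagnostics; forcing
                                      # hooks call the half-step directly
  Dperm <- reference_permeability(kin, params$K)  # fixed kinematics per step
  # first half: p -> W -> m
  p_half <- assemble_pressure_halfstep(fld, kin, mesh, bc, params, dt,
                                       t_target = t + dt / 2, src = src,
                                       Dperm = Dperm)
  W_half <- darcy_flux(p_half, kin, mesh, params$K, Dperm = Dperm)
  m_half <- recover_added_mass(p_half, kin, mesh, field, params)
  # second half with half-step coefficients
  fld$p <- p_half; fld$m <- m_half
  p_full <- assemble_pressure_halfstep(fld, kin, mesh, bc, params, dt,
                                       t_target = t + dt, src = src,
                                       Dperm = Dperm)
  W_full <- darcy_flux(p_full, kin, mesh, params$K, Dperm = Dperm)
  pfq <- qp_interp(mesh, p_full)
  S_full <- if (is.null(src)) numeric(mesh$nq) else distributed_source(pfq, src)
  m_full <- advance_added_mass(m_half, field$W, S_full, mesh, dt, params)
  structure(list(p = p_full, m = m_full, W = W_full, S = S_full),
            class = "porous_field")
}

#' Run the Darcy solver on a frozen (rigid) skeleton to steady state
#'
#' Repeats [step_darcy()] with identity kinematics until the nodal pressure
#' stops changing (relative change below `tol`) or `max_steps` is reached.
#' The fixed point solves the discrete steady Darcy (Laplace) problem.
#'
#' @param mesh a [lagrangian_mesh()].
#' @param bc a [pore_bc()].
#' @param params a [poro_params()].
#' @param src a [source_params()] or `NULL`.
#' @param dt time step (s).
#' @param tol relative steady-state tolerance.
#' @param max_steps step cap.
#' @param t0 start time passed to the BC ramps.
#' @return list with the final `field`, the number of `steps`, and the
#'   final relative change `delta`.
#' @export
rigid_darcy_steady <- function(mesh, bc, params, src = NULL, dt = 0.01,
                               tol = 1e-10, max_steps = 500L, t0 = 0) {
  kin <- compute_kinematics(mesh, mesh$nodes)
  field <- pore_field(mesh)
  t <- t0
  delta <- Inf
  for (s in seq_len(max_steps)) {
    newf <- step_darcy(field, kin, mesh, bc, src, params, dt, t)
    scale <- max(abs(newf$p), 1e-300)
    delta <- max(abs(newf$p - field$p)) / scale
    field <- newf
    t <- t + dt
    if (delta < tol) break
  }
  list(field = field, steps = s, delta = delta)
}

#' Volume-averaged mass-conservation gap
#'
#' Reports the volume-averaged relative violation of the mixture identity
#' `J = 1 + m/rho`, which the continuous model satisfies exactly and the
#' split-step scheme only approximately.  Used as a regression diagnostic.
#'
#' @param kin a [compute_kinematics()] result.
#' @param field a [pore_field()].
#' @param mesh a [lagrangian_mesh()].
#' @param params a [poro_params()].
#' @return volume-averaged `|J - (1 + m/rho)|`.
#' @export
mass_conservation_gap <- function(kin, field, mesh, params) {
  w <- as.vector(t(mesh$wq))
  sum(abs(kin$J - 1 - field$m / params$rho) * w) / sum(w)
}
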