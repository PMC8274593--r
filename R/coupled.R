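# The full three-phase coupled step: immersed-boundary/finite-element
# update of the common velocity field and structure positions, followed by
# the split-step Darcy update on the new kinematics, with the Darcy flux
# and source fed back into the next step's Eulerian volumetric source.

# penalty tether forces realizing the structural constraints in IB mode
tether_forces <- function(mesh, chi, sbc, k_tether) {
  f <- matrix(0, mesh$n_nodes, 3)
  u <- chi - mesh$nodes
  for (cs in sbc$constraints) {
    if (cs$type == "plane_normal") {
      nd <- unique(as.vector(mesh$facets[[cs$tag]]))
      f[nd, cs$axis] <- f[nd, cs$axis] - k_tether * u[nd, cs$axis]
    } else if (cs$type == "fixed_point") {
      d2 <- rowSums((mesh$nodes -
                     matrix(cs$point, mesh$n_nodes, 3, byrow = TRUE))^2)
      nd <- which.min(d2)
      f[nd, ] <- f[nd, ] - k_tether * u[nd, ]
    } else if (cs$type == "basal_cylindrical") {
      nd <- unique(as.vector(mesh$facets[[cs$tag]]))
      x <- mesh$nodes[nd, 1]; y <- mesh$nodes[nd, 2]
      r <- pmax(sqrt(x^2 + y^2), 1e-12)
      eth <- cbind(-y / r, x / r, 0)
      uth <- rowSums(u[nd, , drop = FALSE] * eth)
      f[nd, ] <- f[nd, ] - k_tether * (uth * eth)
      f[nd, 3] <- f[nd, 3] - k_tether * u[nd, 3]
    }
  }
  f
}

# weak per-element divergence of a quadrature-point vector field
qp_divergence <- function(mesh, W) {
  Wn <- qp_to_nodes(mesh, W)
  qp_grad(mesh, Wn[, 1])[, 1] + qp_grad(mesh, Wn[, 2])[, 2] +
    qp_grad(mesh, Wn[, 3])[, 3]
}

#' Set up an immersed-boundary coupled simulation
#'
#' Bundles the Lagrangian structure, constitutive laws, Eulerian grid and
#' prefactored operators, and the numerical parameters of the IB coupling.
#'
#' @param mesh a [lagrangian_mesh()].
#' @param law skeleton law; `fibres` per element for the HO law.
#' @param fibres a [fibre_triad()] or `NULL`.
#' @param params a [poro_params()].
#' @param sbc a [structural_bc()] (constraints become stiff tethers; loads
#'   are applied as Lagrangian surface forces).
#' @param pbc a [pore_bc()].
#' @param src a [source_params()] or `NULL`.
#' @param grid an [eulerian_grid()].
#' @param mu bathing-fluid viscosity (Pa s).
#' @param dt time step (s).
#' @param k_tether tether spring constant (N/m per node); the default
#'   scales with the skeleton bulk modulus and mesh spacing so constraint
#'   violations stay well below the structure size.
#' @param eta_vol optional volumetric damping (Pa s): a dissipative
#'   stress `eta_vol * dJ/dt * J F^-T` modelling intra-element Darcy
#'   resistance that the trilinear pressure space cannot resolve (a
#'   sensible scale is a fraction of `h_s^2 / k`).  Being explicit it has
#'   its own stability limit; default 0.
#' @param active an [active_params()] or `NULL`.
#' @param poroelastic `FALSE` disables the Darcy phase entirely
#'   (`s* = 0`): the plain hyperelastic immersed scheme.
#' @return an object of class `"ib_setup"`.
#' @export
ib_setup <- function(mesh, law, fibres = NULL, params, sbc = structural_bc(),
                     pbc = pore_bc(), src = NULL, grid, mu, dt,
                     k_tether = NULL, eta_vol = NULL, active = NULL,
                     poroelastic = TRUE) {
  Kbulk <- if (!is.null(law$Ks)) law$Ks else law$Kbulk
  hs <- (8 * mean(mesh$wq))^(1 / 3)  # element size
  if (is.null(k_tether)) {
    # spring with stiffness ~ Kbulk * h gives O(sigma/Kbulk) relative
    # constraint violation under stresses of order the bulk modulus
    k_tether <- 5 * Kbulk * hs
  }
  if (is.null(eta_vol)) eta_vol <- 0
  ops <- grid_ops(grid, mu, params$rho, dt)
  fib_qp <- if (!is.null(fibres)) triad_at_qps(fibres, mesh) else NULL
  structure(list(mesh = mesh, law = law, fibres = fibres, fib_qp = fib_qp,
                 params = params, sbc = sbc, pbc = pbc, src = src,
                 grid = grid, ops = ops, mu = mu, dt = dt,
                 k_tether = k_tether, eta_vol = eta_vol, active = active,
                 poroelastic = poroelastic),
            class = "ib_setup")
}

#' Initial coupled state
#'
#' @param setup an [ib_setup()].
#' @return list with the Lagrangian state (`chi`, `chi_prev`, `field`) and
#'   the Eulerian state (`euler`), all at the reference/trivial values.
#' @export
ib_state <- function(setup) {
  list(chi = setup$mesh$nodes, chi_prev = setup$mesh$nodes,
       field = pore_field(setup$mesh), euler = euler_state(setup$grid),
       t = 0)
}

#' One coupled three-phase step
#'
#' Executes the printed update sequence: (i) IB/FE -- structural internal
#' forces (plus tethers and surface loads) are spread to the grid together
#' with the effective source `S* = S - div_X W` from the previous Darcy
#' state, the fluid step advances the common velocity field, the structure
#' moves with the interpolated velocity and the kinematics are recomputed;
#' (ii) the split-step Darcy update runs on the new kinematics; (iii) the
#' new flux and source feed the next step's `s*`.
#'
#' @param state an [ib_state()].
#' @param setup an [ib_setup()].
#' @return the updated state (time advanced by `setup$dt`).
#' @export
coupled_step <- function(state, setup) {
  mesh <- setup$mesh; dt <- setup$dt
  kin <- compute_kinematics(mesh, state$chi, state$chi_prev, dt)
  Ta <- if (is.null(setup$active)) 0 else setup$active$ramp(state$t)
  P <- pk1_total(kin$F, state$field$m, setup$law, fibres = setup$fib_qp,
                 params = setup$params, Ta = Ta,
                 poroelastic = setup$poroelastic,
                 Jbar = qp_element_mean(mesh, kin$J),
                 mbar = qp_element_mean(mesh, state$field$m))
  if (setup$eta_vol > 0) {
    # sub-grid Darcy resistance to element-scale volume exchange
    dJbar <- qp_element_mean(mesh, kin$dJdt)
    P <- P + (setup$eta_vol * dJbar * kin$J) *
      t3_transpose(t3_inv(kin$F))
  }
  b <- internal_force(P, mesh) +
    tether_forces(mesh, state$chi, setup$sbc, setup$k_tether)
  if (length(setup$sbc$loads) > 0) {
    b <- b + external_force(mesh, state$chi, setup$sbc, state$t)
  }
  dens <- b / mesh$lumped_volume
  pts <- qp_interp(mesh, state$chi)
  Fq <- qp_interp(mesh, dens)
  wq <- as.vector(t(mesh$wq))
  f_grid <- spread_force(Fq, pts, wq, setup$grid)
  s_cells <- NULL
  if (setup$poroelastic) {
    Sstar <- state$field$S - qp_divergence(mesh, state$field$W)
    s_cells <- spread_source(Sstar, pts, wq, setup$grid)
  }
  euler <- fluid_step(state$euler, f_grid, s_cells, setup$grid, setup$ops, dt)
  U <- interpolate_velocity(euler, state$chi, setup$grid)
  chi_new <- state$chi + dt * U
  kin_new <- compute_kinematics(mesh, chi_new, state$chi, dt)
  field <- state$field
  if (setup$poroelastic) {
    field <- step_darcy(field, kin_new, mesh, setup$pbc, setup$src,
                        setup$params, dt, state$t)
  }
  list(chi = chi_new, chi_prev = state$chi, field = field, euler = euler,
       t = state$t + dt)
}

#' Run an immersed-boundary coupled simulation
#'
#' @param setup an [ib_setup()].
#' @param n_steps number of coupled steps.
#' @param on_step optional callback `function(k, state)` after each step.
#' @param state optional starting state (defaults to [ib_state()]).
#' @return the final state.
#' @export
ib_run <- function(setup, n_steps, on_step = NULL, state = NULL) {
  if (is.null(state)) state <- ib_state(setup)
  for (k in seq_len(n_steps)) {
    state <- coupled_step(state, setup)
    if (!is.null(on_step)) on_step(k, state)
  }
  state
}
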