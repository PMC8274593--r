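# Split-step Darcy solver: trivial fixed point, steady linear profile,
# flux law, added-mass recovery/advance, manufactured-solution spatial
# order, and time-step self-convergence.

test_that("the trivial state is a machine-precision fixed point", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(3, edge = 0.01)
  kin <- compute_kinematics(mesh, mesh$nodes)
  field <- pore_field(mesh)
  for (k in 1:50) field <- step_darcy(field, kin, mesh, pore_bc(), NULL,
                                      pp, 1e-3, (k - 1) * 1e-3)
  # machine zero: the only perturbation is J = 1 +/- eps from the
  # floating-point quadrature geometry
  expect_identical(max(abs(field$p)), 0)
  expect_lt(max(abs(field$m)), 1e-10)
  expect_identical(max(abs(field$W)), 0)
})

test_that("rigid-skeleton swelling reaches the linear steady profile", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(8, edge = 0.01)
  bc <- pore_bc(list(x0 = 1000, x1 = 0))
  res <- rigid_darcy_steady(mesh, bc, pp, dt = 0.01)
  p_exact <- 1000 * (1 - mesh$nodes[, 1] / 0.01)
  expect_lt(max(abs(res$field$p - p_exact)), 1e-8 * 1000)
  # steady fixed point solves the direct Laplace-Darcy system: compare
  # with a one-shot huge-dt implicit solve (pure stiffness balance)
  kin <- compute_kinematics(mesh, mesh$nodes)
  f0 <- pore_field(mesh)
  p_direct <- assemble_pressure_halfstep(f0, kin, mesh, bc, pp, dt = 1e9,
                                         t_target = 0)
  expect_lt(max(abs(res$field$p - p_direct)), 1e-8 * 1000)
})

test_that("Darcy flux follows the pulled-back law", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(3, edge = 0.01)
  kin <- compute_kinematics(mesh, mesh$nodes)
  p <- 1000 * mesh$nodes[, 1]  # grad 1000 Pa/m
  W <- darcy_flux(p, kin, mesh, 1e-7)
  expect_equal(W[, 1], rep(-1e-4, mesh$nq), tolerance = 1e-12)
  expect_lt(max(abs(W[, 2:3])), 1e-18)
  expect_equal(max(abs(darcy_flux(rep(5, mesh$n_nodes), kin, mesh, 1e-7))),
               0, tolerance = 1e-18)
  # pure rotation with isotropic K: flux magnitude invariant
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  kinR <- compute_kinematics(mesh, mesh$nodes %*% t(R))
  WR <- darcy_flux(p, kinR, mesh, 1e-7)
  expect_equal(sqrt(rowSums(WR^2)), sqrt(rowSums(W^2)), tolerance = 1e-10)
})

test_that("added-mass recovery inverts the pressure law at quadrature points", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(2, edge = 0.01)
  kin <- compute_kinematics(mesh, mesh$nodes %*% diag(c(1.1, 1, 1)))
  field <- pore_field(mesh)
  m <- recover_added_mass(rep(0.05, mesh$n_nodes), kin, mesh, field, pp)
  expect_equal(m, rep(100, mesh$nq), tolerance = 1e-6)
  # round trip on a seeded heterogeneous state
  set.seed(31)
  p_nodal <- runif(mesh$n_nodes, -50, 200)
  m2 <- recover_added_mass(p_nodal, kin, mesh, field, pp)
  expect_equal(pore_pressure(m2, kin$J, pp), qp_interp_probe(mesh, p_nodal),
               tolerance = 1e-10)
})

test_that("explicit mass-balance update matches direct arithmetic", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(3, edge = 0.01)
  m0 <- rep(2, mesh$nq)
  # S = 0, W = 0: unchanged
  expect_equal(advance_added_mass(m0, matrix(0, mesh$nq, 3), rep(0, mesh$nq),
                                  mesh, 0.01, pp), m0)
  # uniform S = 0.01 /s over dt/2 = 0.005 s: dm = 1000 * 0.01 * 0.005
  m1 <- advance_added_mass(m0, matrix(0, mesh$nq, 3), rep(0.01, mesh$nq),
                           mesh, 0.01, pp)
  expect_equal(m1 - m0, rep(0.05, mesh$nq), tolerance = 1e-12)
  # uniform (divergence-free) flux leaves m unchanged
  Wu <- matrix(rep(c(1e-4, -2e-4, 5e-5), each = mesh$nq), mesh$nq, 3)
  m2 <- advance_added_mass(m0, Wu, rep(0, mesh$nq), mesh, 0.01, pp)
  expect_equal(m2, m0, tolerance = 1e-10)
})

test_that("pressure solve converges at second order in space (manufactured solution)", {
  pp <- swelling_pp()
  L <- 0.01
  k_iso <- pp$K[1, 1]
  co0 <- pressure_coefficients(0, 1, pp)
  c0 <- 1 / (co0$A_aug * pp$rho)
  p_ex <- function(x, t) cos(pi * x / L) * exp(-t)
  s_mms <- function(x, t) (k_iso * (pi / L)^2 - c0) * p_ex(x, t)
  Tend <- 0.02
  errs <- sapply(c(4, 8, 16), function(n) {
    mesh <- unit_cube_mesh(n, edge = L)
    kin <- compute_kinematics(mesh, mesh$nodes)
    bc <- pore_bc(list(x0 = function(t) exp(-t),
                       x1 = function(t) -exp(-t)))
    nst <- (n / 4)^2 * 4  # dt ~ h^2 so time error tracks the spatial order
    dt2 <- Tend / nst     # each call advances dt2 via a half-step of 2*dt2
    field <- pore_field(mesh)
    field$p <- p_ex(mesh$nodes[, 1], 0)
    t <- 0
    for (s in seq_len(nst)) {
      field$S <- s_mms(mesh$Xq[, 1], t + dt2)
      field$p <- assemble_pressure_halfstep(field, kin, mesh, bc, pp,
                                            dt = 2 * dt2,
                                            t_target = t + dt2)
      t <- t + dt2
    }
    pq <- qp_interp_probe(mesh, field$p)
    ex <- p_ex(mesh$Xq[, 1], Tend)
    sqrt(sum((pq - ex)^2 * as.vector(t(mesh$wq))) / L^3)
  })
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_gt(min(orders), 1.9)
})

test_that("split-step scheme self-converges at first order in time", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(4, edge = 0.01)
  kin <- compute_kinematics(mesh, mesh$nodes)
  bc <- pore_bc(list(x0 = swelling_inlet_ramp, x1 = 0))
  run <- function(dt) {
    field <- pore_field(mesh)
    t <- 0
    while (t < 0.2 - 1e-12) {
      field <- step_darcy(field, kin, mesh, bc, NULL, pp, dt, t)
      t <- t + dt
    }
    field$p
  }
  p1 <- run(0.02); p2 <- run(0.01); p4 <- run(0.005)
  e1 <- max(abs(p1 - p4)); e2 <- max(abs(p2 - p4))
  expect_gt(log2(e1 / e2), 0.9)
  # halving dt changes the solution by well under 1%
  expect_lt(e2 / max(abs(p4)), 0.01)
})

test_that("coupled staggered swelling keeps J close to 1 + m/rho", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(4, edge = 0.01)
  pbc <- pore_bc(list(x0 = swelling_inlet_ramp, x1 = 0))
  sol <- quasi_static_solve(mesh, iso_skeleton_law(), NULL, pp, cube_sbc(),
                            pbc, NULL, duration = 1.0, n_increments = 50)
  gap <- mass_conservation_gap(sol$kin, sol$field, mesh, pp)
  expect_lt(gap, 0.02)
  expect_gt(max(sol$field$m), 0)  # pore fluid entered the cube
})
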