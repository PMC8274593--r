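# Lagrangian solid machinery: kinematics, weak-form internal force,
# quasi-static equilibrium, and the cavity-volume integral.

test_that("kinematics are exact for affine maps and match analytic gradients", {
  mesh <- unit_cube_mesh(3, edge = 0.01)
  kin <- compute_kinematics(mesh, mesh$nodes)
  expect_equal(max(abs(kin$F - t3_eye(mesh$nq))), 0, tolerance = 1e-12)
  expect_equal(kin$J, rep(1, mesh$nq), tolerance = 1e-12)
  A <- diag(c(1.1, 1, 1))
  kin2 <- compute_kinematics(mesh, mesh$nodes %*% A)
  expect_equal(kin2$J, rep(1.1, mesh$nq), tolerance = 1e-12)
  # trilinear map: chi = X + alpha * (X1*X2, X2*X3, X1*X3) has gradient
  # I + alpha * [[X2, X1, 0], [0, X3, X2], [X3, 0, X1]], exact for Q1
  a <- 5
  X <- mesh$nodes
  chi <- X + a * cbind(X[, 1] * X[, 2], X[, 2] * X[, 3], X[, 1] * X[, 3])
  kin3 <- compute_kinematics(mesh, chi)
  Xq <- mesh$Xq
  Fex <- t3_eye(mesh$nq)
  Fex[, 1] <- 1 + a * Xq[, 2]; Fex[, 4] <- a * Xq[, 1]
  Fex[, 5] <- 1 + a * Xq[, 3]; Fex[, 8] <- a * Xq[, 2]
  Fex[, 3] <- a * Xq[, 3];     Fex[, 9] <- 1 + a * Xq[, 1]
  expect_equal(kin3$F, Fex, tolerance = 1e-10)
  # dJ/dt backward difference and nodal velocity
  kin4 <- compute_kinematics(mesh, mesh$nodes %*% A, mesh$nodes, dt = 0.1)
  expect_equal(kin4$dJdt, rep(0.1 / 0.1, mesh$nq), tolerance = 1e-9)
  expect_error(compute_kinematics(mesh, mesh$nodes[, c(2, 1, 3)]),
               "inversion")
})

test_that("internal force reproduces the single-element traction pattern", {
  nodes <- as.matrix(expand.grid(0:1, 0:1, 0:1))[, c(1, 2, 3)]
  # order nodes to the VTK hex convention
  ord <- c(1, 2, 4, 3, 5, 6, 8, 7)
  nodes <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))[ord, ]
  mesh <- lagrangian_mesh(nodes, matrix(1:8, 1, 8))
  s0 <- 1234
  P <- matrix(0, 8, 9); P[, 1] <- s0  # constant sigma0 e1 (x) e1
  f <- internal_force(P, mesh)
  on_x1 <- nodes[, 1] == 1
  expect_equal(f[on_x1, 1], rep(-s0 / 4, 4), tolerance = 1e-12)
  expect_equal(f[!on_x1, 1], rep(s0 / 4, 4), tolerance = 1e-12)
  expect_equal(max(abs(f[, 2:3])), 0, tolerance = 1e-12)
  expect_equal(max(abs(internal_force(matrix(0, 8, 9), mesh))), 0)
})

test_that("constant stress gives zero total force on any mesh (divergence theorem)", {
  for (mesh in list(unit_cube_mesh(3), ellipsoid_lv(lv_geometry_params(
         n_circ = 12, n_long = 4, n_trans = 1))$mesh)) {
    P <- matrix(rep(rnorm(9), each = mesh$nq), mesh$nq, 9)
    f <- internal_force(P, mesh)
    expect_lt(max(abs(colSums(f))), 1e-10 * max(abs(f)))
  }
})

test_that("internal force is the discrete energy gradient for the iso law", {
  pp <- swelling_pp()
  law <- iso_skeleton_law()
  mesh <- unit_cube_mesh(2, edge = 0.01)
  set.seed(5)
  chi <- mesh$nodes * 1.02 + matrix(rnorm(3 * mesh$n_nodes, sd = 1e-4),
                                    ncol = 3)
  m_qp <- rep(20, mesh$nq)
  energy <- function(chi) {
    kin <- compute_kinematics(mesh, chi)
    sum(strain_energy(kin$F, m_qp, law, params = pp) *
        as.vector(t(mesh$wq)))
  }
  kin <- compute_kinematics(mesh, chi)
  f <- internal_force(pk1_passive(kin$F, m_qp, law, params = pp), mesh)
  h <- 1e-8
  set.seed(6)
  probe <- sample(seq_len(3 * mesh$n_nodes), 12)
  for (d in probe) {
    nd <- (d - 1) %/% 3 + 1; cmp <- (d - 1) %% 3 + 1
    cp <- chi; cp[nd, cmp] <- cp[nd, cmp] + h
    cm <- chi; cm[nd, cmp] <- cm[nd, cmp] - h
    g <- (energy(cp) - energy(cm)) / (2 * h)
    expect_lt(abs(f[nd, cmp] + g), 1e-6 * max(abs(f)))
  }
})

test_that("hydrostatic compression of a cube is homogeneous", {
  pp <- swelling_pp()
  law <- iso_skeleton_law()
  mesh <- unit_cube_mesh(3, edge = 0.01)
  sbc <- structural_bc(
    constraints = cube_sbc()$constraints,
    loads = lapply(c("x0", "x1", "y0", "y1", "z0", "z1"), function(tg)
      list(tag = tg, ramp = 1e4, follower = FALSE)))
  sol <- newton_solve(mesh, mesh$nodes, numeric(mesh$nq), law, NULL, pp,
                      sbc, t = 1, poroelastic = FALSE)
  kin <- compute_kinematics(mesh, sol$chi)
  expect_lt(max(kin$J), 1)
  expect_lt(diff(range(kin$J)) / mean(kin$J), 1e-6)
})

test_that("quasi-static equilibria are load-path independent", {
  pp <- swelling_pp()
  law <- iso_skeleton_law()
  mesh <- unit_cube_mesh(2, edge = 0.01)
  sbc <- structural_bc(
    constraints = cube_sbc()$constraints,
    loads = list(list(tag = "x1", ramp = function(t) 8e3 * t,
                      follower = FALSE)))
  run <- function(nin) {
    quasi_static_solve(mesh, law, NULL, pp, sbc, duration = 1,
                       n_increments = nin, poroelastic = FALSE)$chi
  }
  expect_equal(run(4), run(9), tolerance = 1e-6)
})

test_that("zero loads keep the identity deformation", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(2, edge = 0.01)
  sol <- newton_solve(mesh, mesh$nodes, numeric(mesh$nq),
                      iso_skeleton_law(), NULL, pp, cube_sbc(), t = 1,
                      poroelastic = FALSE)
  expect_equal(sol$chi, mesh$nodes, tolerance = 1e-12)
  expect_equal(sol$iters, 0L)
})

test_that("fibres along the load stiffen the uniaxial response", {
  pp <- swelling_pp()
  law <- ho_skeleton_law()
  mesh <- unit_cube_mesh(2, edge = 0.01)
  sbc <- structural_bc(
    constraints = cube_sbc()$constraints,
    loads = list(list(tag = "x1", ramp = -2e3, follower = FALSE)))  # tension
  stretch <- function(orientation) {
    fib <- cube_fibres(mesh, orientation)
    sol <- quasi_static_solve(mesh, law, fib, pp, sbc, duration = 1,
                              n_increments = 4, poroelastic = FALSE)
    max(sol$chi[, 1]) / 0.01
  }
  expect_lt(stretch("x"), stretch("y"))
})

test_that("cavity volume matches closed forms and scaling laws", {
  hp <- lv_geometry_params(a_endo = 0.01, c_endo = 0.01, a_epi = 0.013,
                           c_epi = 0.013, base_height = 0, apex_angle = 0.12,
                           n_circ = 40, n_long = 16, n_trans = 1)
  hs <- ellipsoid_lv(hp)
  # hemispherical shell: (2/3) pi r^3 (apical opening is O(angle^4))
  expect_equal(cavity_volume(hs$mesh), 2 / 3 * pi * 0.01^3,
               tolerance = 0.01)
  lv <- ellipsoid_lv(lv_geometry_params(n_circ = 20, n_long = 8,
                                        n_trans = 1))
  v0 <- cavity_volume(lv$mesh)
  expect_equal(cavity_volume(lv$mesh, lv$mesh$nodes * 1.1), v0 * 1.1^3,
               tolerance = 1e-10)
})
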