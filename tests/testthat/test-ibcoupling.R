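# Immersed-boundary coupling: kernel moment conditions, spreading /
# interpolation duality and conservation, the projection fluid step, and
# reduction to the plain hyperelastic scheme at zero porosity.

test_grid <- function(N = 12) {
  eulerian_grid(rep(-0.0025, 3), rep(0.0125, 3), N)
}

test_that("4-point kernel satisfies partition of unity and zero first moment", {
  set.seed(17)
  r <- runif(100, -0.5, 0.5)
  for (x in r) {
    w <- ib_kernel(x - (-3:3))
    expect_lt(abs(sum(w) - 1), 1e-13)
    expect_lt(abs(sum((x - (-3:3)) * w)), 1e-13)
  }
  expect_equal(ib_kernel(c(-1.2, 1.2)), rev(ib_kernel(c(1.2, -1.2))))
  expect_identical(ib_kernel(2.5), 0)
})

test_that("spreading and interpolation are exact adjoints", {
  g <- test_grid()
  set.seed(23)
  np <- 60
  pts <- matrix(runif(np * 3, 0.003, 0.009), np, 3)
  Fq <- matrix(rnorm(np * 3), np, 3)
  wts <- runif(np, 0.5, 1.5) * 1e-9
  fg <- spread_force(Fq, pts, wts, g)
  st <- list(u = array(rnorm(prod(g$dims$u)), g$dims$u),
             v = array(rnorm(prod(g$dims$v)), g$dims$v),
             w = array(rnorm(prod(g$dims$w)), g$dims$w))
  ip_grid <- (sum(fg$fu * st$u) + sum(fg$fv * st$v) + sum(fg$fw * st$w)) *
    g$h^3
  Uq <- interpolate_velocity(st, pts, g)
  ip_str <- sum(rowSums(Fq * Uq) * wts)
  expect_lt(abs(ip_grid - ip_str), 1e-12 * abs(ip_str))
})

test_that("spread source conserves the total and spread force the net force", {
  g <- test_grid()
  set.seed(29)
  np <- 40
  pts <- matrix(runif(np * 3, 0.003, 0.009), np, 3)
  wts <- runif(np, 0.5, 1.5) * 1e-9
  Sq <- rnorm(np)
  s <- spread_source(Sq, pts, wts, g)
  expect_lt(abs(sum(s) * g$h^3 - sum(Sq * wts)), 1e-12 * sum(abs(Sq * wts)))
  Fq <- matrix(rnorm(np * 3), np, 3)
  fg <- spread_force(Fq, pts, wts, g)
  expect_lt(abs(sum(fg$fu) * g$h^3 - sum(Fq[, 1] * wts)),
            1e-12 * sum(abs(Fq[, 1] * wts)))
  # clearance error near the boundary
  expect_error(spread_source(1, matrix(c(-0.0024, 0.005, 0.005), 1, 3),
                             1e-9, g), "kernel support")
})

test_that("interpolation is exact on constant and linear velocity fields", {
  g <- test_grid()
  set.seed(37)
  pts <- matrix(runif(45, 0.003, 0.009), 15, 3)
  stc <- list(u = array(3.5, g$dims$u), v = array(-1.2, g$dims$v),
              w = array(0.7, g$dims$w))
  U <- interpolate_velocity(stc, pts, g)
  expect_equal(U, cbind(rep(3.5, 15), -1.2, 0.7), tolerance = 1e-14)
  A <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9) * 0.1, 3, 3)
  coords <- function(dims, org) {
    xs <- org[1] + (seq_len(dims[1]) - 1) * g$h
    ys <- org[2] + (seq_len(dims[2]) - 1) * g$h
    zs <- org[3] + (seq_len(dims[3]) - 1) * g$h
    list(x = array(rep(xs, prod(dims[2:3])), dims),
         y = array(rep(rep(ys, each = dims[1]), dims[3]), dims),
         z = array(rep(zs, each = prod(dims[1:2])), dims))
  }
  cu <- coords(g$dims$u, g$origins$u)
  cv <- coords(g$dims$v, g$origins$v)
  cw <- coords(g$dims$w, g$origins$w)
  stl <- list(u = A[1, 1] * cu$x + A[1, 2] * cu$y + A[1, 3] * cu$z,
              v = A[2, 1] * cv$x + A[2, 2] * cv$y + A[2, 3] * cv$z,
              w = A[3, 1] * cw$x + A[3, 2] * cw$y + A[3, 3] * cw$z)
  Ul <- interpolate_velocity(stl, pts, g)
  expect_lt(max(abs(Ul - pts %*% t(A))), 1e-12)
})

test_that("fluid step: rest state, projection identity, and CFL guard", {
  g <- test_grid()
  ops <- grid_ops(g, mu = 4e-3, rho = 1e3, dt = 1e-3)
  st0 <- euler_state(g)
  st1 <- fluid_step(st0, NULL, NULL, g, ops, 1e-3)
  expect_identical(max(abs(st1$u)), 0)
  expect_identical(max(abs(st1$p_ib)), 0)
  # point volumetric source: end-of-step divergence equals s* cell-wise
  s <- array(0, g$dims$p); s[6, 6, 6] <- 2.5; s[3, 9, 4] <- -0.8
  st2 <- fluid_step(st0, NULL, s, g, ops, 1e-3)
  expect_lt(max(abs(grid_divergence(st2, ops, g) - s)), 1e-10)
  stbad <- st0; stbad$u[] <- 10
  expect_error(fluid_step(stbad, NULL, NULL, g, ops, 1e-3), "CFL")
})

test_that("viscous decay between no-slip walls matches the closed form", {
  g <- test_grid()
  L <- 0.015
  mu <- 4e-3; rho <- 1e3; nu <- mu / rho
  dt <- 2e-3
  ops <- grid_ops(g, mu, rho, dt)
  st <- euler_state(g)
  yc <- g$origins$u[2] + (seq_len(g$dims$u[2]) - 1) * g$h - g$box_min[2]
  for (j in seq_len(g$dims$u[2])) st$u[, j, ] <- 1e-4 * sin(pi * yc[j] / L)
  a0 <- max(st$u)
  nst <- 50
  for (k in seq_len(nst)) st <- fluid_step(st, NULL, NULL, g, ops, dt)
  rate <- -log(max(st$u) / a0) / (nst * dt)
  expect_equal(rate, nu * pi^2 / L^2, tolerance = 0.02)
})

test_that("coupled trivial state is preserved to machine zero", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(2, edge = 0.01)
  grid <- eulerian_grid(rep(-0.005, 3), rep(0.015, 3), 8)
  su <- ib_setup(mesh, iso_skeleton_law(), NULL, pp, structural_bc(),
                 pore_bc(), NULL, grid, mu = 4e-3, dt = 1e-3)
  stt <- ib_run(su, 50)
  # machine zero relative to the kPa / cm / m-per-s problem scales
  expect_lt(max(abs(stt$field$p)), 1e-8)
  expect_lt(max(abs(stt$field$m)), 1e-8)
  expect_lt(max(abs(stt$chi - mesh$nodes)), 1e-13)
  expect_lt(max(abs(stt$euler$u)), 1e-11)
})

test_that("zero-porosity coupling reduces to the plain hyperelastic scheme", {
  pp <- swelling_pp()
  mesh <- unit_cube_mesh(3, edge = 0.01)
  grid <- eulerian_grid(rep(-0.0025, 3), rep(0.0125, 3), 12)
  pbc <- pore_bc(list(x0 = swelling_inlet_ramp, x1 = 0))
  su <- ib_setup(mesh, iso_skeleton_law(), NULL, pp, cube_sbc(), pbc, NULL,
                 grid, mu = 4e-3, dt = 1e-4, poroelastic = FALSE)
  stt <- ib_run(su, 200)
  # no source is spread, so the structure takes up no volume
  kin <- compute_kinematics(mesh, stt$chi)
  expect_lt(max(abs(kin$J - 1)), 1e-6)
  expect_identical(max(abs(stt$field$m)), 0)
})
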