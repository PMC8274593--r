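# Pointwise material laws: the volume-change weighting, the pore-pressure
# law and its inverse, pressure-equation coefficients, skeleton energies
# and stresses, active stress, and distributed sources.

test_that("volume-change weighting matches direct evaluation and is smooth at J = 1", {
  expect_equal(relative_volume_factor(2), 2 * (1 - log(2)), tolerance = 1e-12)
  expect_equal(relative_volume_factor(1.1),
               2 * (0.1 - log(1.1)) / 0.1^2, tolerance = 1e-12)
  expect_identical(relative_volume_factor(1), 1)
  # continuity across the series switch
  expect_lt(abs(relative_volume_factor(1 + 1e-6) - 1), 1e-5)
  expect_lt(abs(relative_volume_factor(1 - 1e-6) - 1), 1e-5)
  # derivative against central differences on both branches
  for (J in c(0.9, 1.0001, 1.5)) {
    h <- 1e-6
    fd <- (relative_volume_factor(J + h) - relative_volume_factor(J - h)) /
      (2 * h)
    expect_equal(relative_volume_factor(J, 1L), fd, tolerance = 1e-6)
  }
  expect_error(relative_volume_factor(-1), "positive")
})

test_that("pore pressure law reproduces the worked states and errors out of domain", {
  pp <- swelling_pp()
  expect_identical(pore_pressure(0, 1, pp), 0)  # trivial state, exact
  # first (Biot) term vanishes when b(1-J) + m/rho = 0
  expect_equal(pore_pressure(100, 1.1, pp), pp$p0 - 0.05, tolerance = 1e-8)
  expect_equal(pore_pressure(0, 1.1, pp),
               pp$p0 - 2.18e5 * 0.1 * relative_volume_factor(1.1) - 0.1,
               tolerance = 1e-12)
  expect_error(pore_pressure(-200, 1, pp), "porosity")
})

test_that("pore pressure is strictly increasing in m and exactly invertible", {
  pp <- swelling_pp()
  set.seed(7)
  for (rep in 1:20) {
    J <- runif(1, 0.85, 1.25)
    m <- sort(runif(5, -50, 400))
    p <- pore_pressure(m, J, pp)
    expect_true(all(diff(p) > 0))
    m_back <- invert_pore_pressure(p, J, pp)
    expect_equal(m_back, m, tolerance = 1e-10)
  }
  # worked inverse values
  expect_equal(invert_pore_pressure(0.05, 1.1, pp), 100, tolerance = 1e-8)
  expect_equal(invert_pore_pressure(0, 1, pp), 0, tolerance = 1e-12)
  expect_equal(invert_pore_pressure(pore_pressure(50, 1.05, pp), 1.05, pp),
               50, tolerance = 1e-9)
})

test_that("pressure-equation coefficients have the closed-form values", {
  pp <- swelling_pp()
  co <- pressure_coefficients(0, 1, pp)
  expect_equal(co$A, 2.18e5 / 1e3, tolerance = 1e-12)
  expect_equal(co$B, -2.18e5, tolerance = 1e-12)
  expect_equal(co$D_rate, 0.01 * 1e3 / (1e3 * 0.1)^2, tolerance = 1e-12)
  # C vanishes whenever the bracket b(1-J) + m/rho does
  for (J in c(0.9, 1.05, 1.2)) {
    m <- pp$rho * pp$b * (J - 1)
    expect_equal(pressure_coefficients(m, J, pp)$C, 0, tolerance = 1e-9)
  }
  # dp/dt chain rule: A_aug and B + C against finite differences of the law
  m0 <- 80; J0 <- 1.07; h <- 1e-4
  co <- pressure_coefficients(m0, J0, pp)
  dpdm <- (pore_pressure(m0 + h, J0, pp) - pore_pressure(m0 - h, J0, pp)) /
    (2 * h)
  dpdJ <- (pore_pressure(m0, J0 + h, pp) - pore_pressure(m0, J0 - h, pp)) /
    (2 * h)
  expect_equal(co$A_aug, dpdm, tolerance = 1e-6)
  expect_equal(co$B + co$C, dpdJ, tolerance = 1e-6)
})

test_that("strain energies at the reference and under fibre compression", {
  pp <- swelling_pp()
  ho <- ho_skeleton_law()
  iso <- iso_skeleton_law()
  I3 <- diag(3)
  expect_equal(strain_energy(I3, 0, ho, unit_triad(), pp), 2240 / (2 * 1.62),
               tolerance = 1e-12)
  expect_equal(strain_energy(I3, 0, iso, params = pp), 0, tolerance = 1e-12)
  # fibre compression: the clamped I4 term stores no energy
  lam <- 0.9
  Fc <- diag(c(lam, 1, 1))
  ho0 <- ho_skeleton_law(afs = 1e-10)  # isolate the I4f term
  W <- strain_energy(Fc, 0, ho0, unit_triad(), pp)
  Wiso_only <- ho0$a / (2 * ho0$b) * exp(ho0$b * (lam^2 + 2 - 3)) +
    ho0$Kbulk * log(lam)^2
  expect_equal(W, Wiso_only, tolerance = 1e-9)
  expect_error(strain_energy(I3, 2000, iso, params = pp), "domain")
})

test_that("passive stress is the energy gradient (thermodynamic consistency)", {
  pp <- swelling_pp()
  iso <- iso_skeleton_law()
  ho <- ho_skeleton_law()
  tri <- unit_triad()
  Fs <- random_defgrads(100, seed = 11)
  m <- rep(30, 100)
  # isotropic law: correction is integrable, so pk1 == dW/dF exactly
  P <- pk1_passive(Fs, m, iso, params = pp)
  for (i in seq(1, 100, by = 7)) {
    g <- fd_energy_gradient(Fs[i, ], function(F)
      strain_energy(F, m[i], iso, params = pp))
    expect_equal(P[i, ], g, tolerance = 1e-6 * max(abs(g), 1))
  }
  # HO law: compare with the (non-integrable) reference correction removed
  # from the stress, away from the I4 clamp
  Fs2 <- random_defgrads(40, seed = 12, spread = 0.08)
  C11 <- rowSums(matrix(Fs2[, c(1, 2, 3)]^2, ncol = 3))
  keep <- which(abs(C11 - 1) > 0.02)[1:8]
  P2 <- pk1_passive(Fs2, 0, ho, tri, pp)
  for (i in keep) {
    F1 <- matrix(Fs2[i, ], 1, 9)
    I1 <- sum(matrix(F1, 3, 3)^2)
    corr <- ho$a * exp(ho$b * (I1 - 3)) *
      as.vector(t(solve(matrix(F1, 3, 3))))
    g <- fd_energy_gradient(Fs2[i, ], function(F)
      strain_energy(F, 0, ho, tri, pp))
    expect_equal(P2[i, ] + corr, g, tolerance = 1e-5 * max(abs(g), 1))
  }
})

test_that("reference configuration is exactly stress free for both laws", {
  pp <- swelling_pp()
  I3 <- diag(3)
  expect_equal(max(abs(pk1_passive(I3, 0, iso_skeleton_law(), params = pp))),
               0, tolerance = 1e-12)
  expect_equal(max(abs(pk1_passive(I3, 0, ho_skeleton_law(), unit_triad(),
                                   pp))), 0, tolerance = 1e-12)
  # the printed half-scale correction leaves a nonzero reference stress
  half <- ho_skeleton_law(reference_correction_scale = 0.5)
  expect_gt(max(abs(pk1_passive(I3, 0, half, unit_triad(), pp))), 100)
})

test_that("fibre terms carry no stress in compression (I4 clamp)", {
  pp <- swelling_pp()
  ho <- ho_skeleton_law()
  tri <- unit_triad()
  set.seed(21)
  for (rep in 1:20) {
    lams <- runif(2, 0.8, 0.999)  # both fibre and sheet shortened
    F <- diag(c(lams[1], lams[2], 1 / (lams[1] * lams[2])))
    P_with <- pk1_passive(F, 0, ho, tri, pp)
    nof <- ho_skeleton_law(af = 1e-300, as_ = 1e-300)
    P_wo <- pk1_passive(F, 0, nof, tri, pp)
    expect_equal(P_with, P_wo, tolerance = 1e-10)
  }
})

test_that("active stress is the fibre outer-product tension", {
  P <- pk1_active(diag(3), 1000, c(1, 0, 0))
  expect_equal(as.vector(P), c(1000, rep(0, 8)), tolerance = 1e-12)
  expect_equal(max(abs(pk1_active(diag(3), 0, c(1, 0, 0)))), 0)
  P2 <- pk1_active(diag(3), 1, c(0, 1, 0))
  expect_equal(P2[1, 5], 1); expect_equal(sum(abs(P2)), 1)
  # P_a = J Ta F (f0 x f0) for a non-trivial F
  F <- matrix(c(1.1, 0.05, 0, 0, 0.95, 0.02, 0, 0, 1.02), 3, 3)
  Pa <- pk1_active(F, 500, c(1, 0, 0))
  expect_equal(matrix(Pa[1, ], 3, 3),
               det(F) * 500 * F %*% (c(1, 0, 0) %o% c(1, 0, 0)),
               tolerance = 1e-12)
})

test_that("distributed sources: equilibrium roots and sink values", {
  src <- source_params("compartment")
  p_eq <- (src$beta_a * src$pa + src$beta_v * src$pv) /
    (src$beta_a + src$beta_v)
  expect_equal(p_eq, 1301.4, tolerance = 1e-4)
  expect_equal(distributed_source(p_eq, src), 0, tolerance = 1e-12)
  sink <- source_params("sink", beta = 1e-4, p_sink = 0)
  expect_equal(distributed_source(1000, sink), -0.1, tolerance = 1e-12)
  expect_equal(distributed_source(0, sink), 0)
  # affine decomposition agrees with the direct evaluation
  for (s in list(src, sink)) {
    co <- source_affine_coeffs(s)
    p <- c(0, 500, 2000)
    expect_equal(distributed_source(p, s), co$s0 - co$s1 * p,
                 tolerance = 1e-12)
  }
})

test_that("parameter validation rejects inadmissible inputs", {
  expect_error(poro_params(Mb = -1, b = 1, kappa0 = 0.01, phi0 = 0.1,
                           rho = 1e3, K = 1e-7))
  expect_error(poro_params(Mb = 1, b = 1, kappa0 = 0.01, phi0 = 1.2,
                           rho = 1e3, K = 1e-7))
  expect_error(poro_params(Mb = 1, b = 1, kappa0 = 0.01, phi0 = 0.1,
                           rho = 1e3, K = matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1),
                                                 3, 3) * 1e-7),
               "symmetric")
  expect_error(fibre_triad(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1)), "orthogonal")
  expect_error(fibre_triad(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1)), "unit")
})
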