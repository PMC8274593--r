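# Shared fixtures: benchmark parameter sets, small meshes, and seeded
# random deformation gradients.

swelling_pp <- function() benchmark_params("swelling")
ventricle_pp <- function() benchmark_params("ventricle")

# seeded random deformation gradients with det F in (lo, hi)
random_defgrads <- function(n, seed = 42, lo = 0.8, hi = 1.2, spread = 0.1) {
  set.seed(seed)
  out <- matrix(0, n, 9)
  k <- 0L
  while (k < n) {
    F <- diag(3) + matrix(rnorm(9, sd = spread), 3, 3)
    d <- det(F)
    if (d > lo && d < hi) {
      k <- k + 1L
      out[k, ] <- as.vector(F)
    }
  }
  out
}

# central finite-difference gradient of a scalar energy w.r.t. F (one row)
fd_energy_gradient <- function(Frow, efun, h = 1e-6) {
  g <- numeric(9)
  for (c in 1:9) {
    Fp <- Frow; Fp[c] <- Fp[c] + h
    Fm <- Frow; Fm[c] <- Fm[c] - h
    g[c] <- (efun(matrix(Fp, 1, 9)) - efun(matrix(Fm, 1, 9))) / (2 * h)
  }
  g
}

unit_triad <- function() fibre_triad(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))

cube_sbc <- function() structural_bc(constraints = list(
  list(type = "plane_normal", tag = "x0", axis = 1),
  list(type = "plane_normal", tag = "y0", axis = 2),
  list(type = "plane_normal", tag = "z0", axis = 3)))

# aliases for internal helpers used by oracles
qp_interp_probe <- function(mesh, u) poroifem:::qp_interp(mesh, u)
t3_eye <- function(n) poroifem:::t3_eye(n)
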