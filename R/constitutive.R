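# Pointwise material laws for the poroelastic myocardium model:
# pore-fluid constitutive constants, skeleton strain energies and first
# Piola-Kirchhoff stresses, the Biot-type pore-pressure law and its inverse,
# the coefficients of the split-step pressure equation, active stress, and
# distributed perfusion sources.

# ---------------------------------------------------------------------------
# Parameter containers
# ---------------------------------------------------------------------------

#' Pore-fluid constitutive parameters
#'
#' Bundles the constants of the pore-fluid free energy: the Biot modulus
#' `Mb`, the skeleton coupling parameter `b`, the porosity-bound penalty
#' coefficient `kappa0`, the initial porosity `phi0`, the common density
#' `rho` of all constituents, the permeability tensor `K`, and the reference
#' pore pressure `p0`.
#'
#' The default `p0 = kappa0 / phi0` makes the unloaded reference state
#' `(m, p, J) = (0, 0, 1)` an exact zero of the pore-pressure law, so the
#' reference configuration is a trivial solution of the whole scheme.  `p0`
#' may be overridden.
#'
#' @param Mb Biot modulus (Pa), `> 0`.
#' @param b dimensionless skeleton coupling parameter.
#' @param kappa0 porosity-bound penalty coefficient (Pa), `> 0`.
#' @param phi0 initial porosity, in `(0, 1)`.
#' @param rho common density of skeleton, pore fluid and bathing fluid
#'   (kg m^-3).
#' @param K permeability (m^2 Pa^-1 s^-1): a scalar (isotropic `k * I`) or a
#'   symmetric positive-definite 3x3 matrix.
#' @param p0 reference pore pressure (Pa); defaults to `kappa0 / phi0`.
#' @return an object of class `"poro_params"`.
#' @export
#' @examples
#' pp <- poro_params(Mb = 2.18e5, b = 1, kappa0 = 0.01, phi0 = 0.1,
#'                   rho = 1e3, K = 1e-7)
#' pore_pressure(0, 1, pp) # exactly zero in the reference state
poro_params <- function(Mb, b, kappa0, phi0, rho, K, p0 = NULL) {
  stopifnot(Mb > 0, kappa0 > 0, phi0 > 0, phi0 < 1, rho > 0)
  # default written exactly as the penalty term evaluates at m = 0, so that
  # pore_pressure(0, 1) cancels to floating-point zero
  if (is.null(p0)) p0 <- kappa0 * rho / (rho * phi0)
  if (length(K) == 1L) K <- diag(3) * as.numeric(K)
  stopifnot(is.matrix(K), all(dim(K) == c(3L, 3L)))
  if (max(abs(K - t(K))) > 1e-12 * max(abs(K))) {
    stop("permeability tensor K must be symmetric")
  }
  if (any(eigen(K, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("permeability tensor K must be positive definite")
  }
  structure(list(Mb = Mb, b = b, kappa0 = kappa0, phi0 = phi0, rho = rho,
                 K = K, p0 = p0),
            class = "poro_params")
}

#' Isotropic (Mooney-Rivlin-type) skeleton law
#'
#' `Whyp = kappa1 (I1 - 3) + kappa2 (I2 - 3) - (2 kappa1 + 4 kappa2) ln J`,
#' plus the bulk term `Ks ln^2(J - m/rho)` that penalises deviations from
#' skeleton mass conservation `J = 1 + m/rho`.  The `ln J` correction makes
#' the reference configuration exactly stress free; it is the integrable
#' analogue of the reference correction used for the fibre-reinforced law.
#'
#' @param kappa1,kappa2 Mooney-Rivlin-type coefficients (Pa), `>= 0`.
#' @param Ks skeleton bulk modulus (Pa), `> 0`.
#' @return an object of class `c("iso_law", "skeleton_law")`.
#' @export
iso_skeleton_law <- function(kappa1 = 2000, kappa2 = 1000, Ks = 2.2e5) {
  stopifnot(kappa1 >= 0, kappa2 >= 0, Ks > 0)
  structure(list(kappa1 = kappa1, kappa2 = kappa2, Ks = Ks),
            class = c("iso_law", "skeleton_law"))
}

#' Holzapfel-Ogden orthotropic skeleton law
#'
#' Fibre-reinforced strain energy for passive myocardium with fibre (`f0`),
#' sheet (`s0`) and sheet-normal (`n0`) material axes:
#' an exponential isotropic term `a/(2b) exp(b(I1 - 3))`, exponential fibre
#' and sheet terms in the clamped invariants `I4* = max(I4, 1) - 1` (so that
#' fibres do not support compression), a fibre-sheet coupling term in
#' `I8fs`, and the bulk term `Kbulk ln^2(J - m/rho)`.
#'
#' The stress carries a reference correction
#' `- reference_correction_scale * a * exp(b(I1 - 3)) * F^-T` so that the
#' reference configuration is exactly stress free; the default scale 1
#' achieves `P(I) = 0` under the convention `dI1/dF = 2F`.
#'
#' @param a,af,as_,afs stress-scale coefficients (Pa), `> 0`.
#' @param b,bf,bs,bfs dimensionless exponents, `> 0`.
#' @param Kbulk bulk penalty modulus (Pa), `> 0`.
#' @param reference_correction_scale factor multiplying the stress-free
#'   reference correction; 1 (default) zeroes the reference stress.
#' @return an object of class `c("ho_law", "skeleton_law")`.
#' @export
ho_skeleton_law <- function(a = 2240, b = 1.62, af = 2420, bf = 1.83,
                            as_ = 550, bs = 0.77, afs = 400, bfs = 1.7,
                            Kbulk = 2.2e5, reference_correction_scale = 1) {
  stopifnot(a > 0, af > 0, as_ > 0, afs > 0,
            b > 0, bf > 0, bs > 0, bfs > 0, Kbulk > 0)
  structure(list(a = a, b = b, af = af, bf = bf, as_ = as_, bs = bs,
                 afs = afs, bfs = bfs, Kbulk = Kbulk,
                 reference_correction_scale = reference_correction_scale),
            class = c("ho_law", "skeleton_law"))
}

#' Fibre-sheet-normal material triad
#'
#' @param f0,s0,n0 unit vectors (length 3, or `n x 3` matrices for fields):
#'   myofibre, sheet and sheet-normal directions in the reference
#'   configuration.  Checked for unit norm and pairwise orthogonality to
#'   1e-10.
#' @return an object of class `"fibre_triad"` holding `n x 3` matrices.
#' @export
fibre_triad <- function(f0, s0, n0) {
  tovec <- function(v) if (is.matrix(v)) v else matrix(v, 1L, 3L)
  f0 <- tovec(f0); s0 <- tovec(s0); n0 <- tovec(n0)
  stopifnot(ncol(f0) == 3L, nrow(f0) == nrow(s0), nrow(f0) == nrow(n0))
  nrm <- function(v) sqrt(rowSums(v^2))
  dt <- function(u, v) abs(rowSums(u * v))
  if (max(abs(nrm(f0) - 1), abs(nrm(s0) - 1), abs(nrm(n0) - 1)) > 1e-10) {
    stop("fibre triad vectors must be unit norm")
  }
  if (max(dt(f0, s0), dt(f0, n0), dt(s0, n0)) > 1e-10) {
    stop("fibre triad vectors must be pairwise orthogonal")
  }
  structure(list(f0 = f0, s0 = s0, n0 = n0), class = "fibre_triad")
}

#' Prescribed active-tension transient
#'
#' A surrogate for a calcium-driven contraction model: a prescribed scalar
#' tension `Ta(t)` that is zero before `t_on`, rises smoothly (half-cosine)
#' to its plateau `Treq` over `t_rise`, and stays at the plateau.
#'
#' @param Treq peak active tension (Pa).
#' @param t_on activation onset time (s).
#' @param t_rise rise time from 0 to the plateau (s).
#' @return an object of class `"active_params"` with a `ramp(t)` function.
#' @export
active_params <- function(Treq = 124e3, t_on = 0.5, t_rise = 0.15) {
  stopifnot(Treq >= 0, t_rise > 0)
  ramp <- function(t) {
    s <- pmin(pmax((t - t_on) / t_rise, 0), 1)
    Treq * 0.5 * (1 - cos(pi * s))
  }
  structure(list(Treq = Treq, t_on = t_on, t_rise = t_rise, ramp = ramp),
            class = "active_params")
}

#' Distributed perfusion source parameters
#'
#' Either a single-compartment model connecting the pore space to coronary
#' arterial and venous reservoirs, `S = beta_a (pa - p) - beta_v (p - pv)`,
#' or a plain drainage sink `S = -beta (p - p_sink)`.
#'
#' @param mode `"compartment"` or `"sink"`.
#' @param beta_a,beta_v arterial and venous conductances (Pa^-1 s^-1).
#' @param pa,pv arterial and venous pressures (Pa).
#' @param beta sink conductance (Pa^-1 s^-1).
#' @param p_sink sink pressure (Pa).
#' @return an object of class `"source_params"`.
#' @export
source_params <- function(mode = c("compartment", "sink"),
                          beta_a = 3e-5, beta_v = 3e-2, pa = 2.7e3, pv = 1.3e3,
                          beta = 1e-4, p_sink = 0) {
  mode <- match.arg(mode)
  stopifnot(beta_a >= 0, beta_v >= 0, beta >= 0)
  structure(list(mode = mode, beta_a = beta_a, beta_v = beta_v, pa = pa,
                 pv = pv, beta = beta, p_sink = p_sink),
            class = "source_params")
}

# ---------------------------------------------------------------------------
# Volume-change weighting f(J)
# ---------------------------------------------------------------------------

#' Dimensionless volume-change weighting f(J)
#'
#' `f(J) = 2 (J - 1 - ln J) / (J - 1)^2`, the weighting of the dilatational
#' terms in the pore free energy and the pore-pressure law, together with
#' its derivative.  The removable singularity at `J = 1` (where `f = 1`,
#' `f' = -2/3`) is evaluated by series expansion to avoid cancellation.
#'
#' @param J Jacobian determinant(s), `> 0`.
#' @param deriv 0 for `f(J)`, 1 for `f'(J)`.
#' @return numeric vector the length of `J`.
#' @export
#' @examples
#' relative_volume_factor(2)        # 2 (1 - ln 2)
#' relative_volume_factor(1)        # 1, the removable-singularity limit
#' relative_volume_factor(1.1, 1)   # derivative
relative_volume_factor <- function(J, deriv = 0L) {
  if (any(!is.finite(J)) || any(J <= 0)) {
    stop("relative_volume_factor(): J must be positive")
  }
  h <- J - 1
  out <- numeric(length(J))
  near <- abs(h) < 1e-3
  if (deriv == 0L) {
    # f = 2 * sum_{k>=2} (-1)^k h^(k-2) / k
    hs <- h[near]
    out[near] <- 2 * (1 / 2 - hs / 3 + hs^2 / 4 - hs^3 / 5 + hs^4 / 6)
    hf <- h[!near]
    out[!near] <- 2 * (hf - log1p(hf)) / hf^2
  } else if (deriv == 1L) {
    hs <- h[near]
    out[near] <- 2 * (-1 / 3 + hs / 2 - 3 * hs^2 / 5 + 2 * hs^3 / 3)
    Jf <- J[!near]
    f <- relative_volume_factor(Jf)
    out[!near] <- (2 / (Jf - 1)) * (1 / Jf - f)
  } else {
    stop("deriv must be 0 or 1")
  }
  out
}

# ---------------------------------------------------------------------------
# Pore-pressure law and inverse
# ---------------------------------------------------------------------------

#' Interstitial pore pressure
#'
#' `p = p0 + Mb (b (1 - J) + m/rho) f(J) - kappa0 rho / (m + rho phi0)`.
#' The penalty term diverges as the added mass approaches `-rho phi0`
#' (porosity zero), keeping the porosity admissible.  Strictly increasing in
#' `m` at fixed `J`.
#'
#' @param m added fluid mass per unit reference volume (kg m^-3); must
#'   exceed `-rho * phi0`.
#' @param J Jacobian determinant(s), `> 0`.
#' @param params a [poro_params()] object.
#' @return pore pressure (Pa), vectorized over `m` and `J`.
#' @export
pore_pressure <- function(m, J, params) {
  stopifnot(inherits(params, "poro_params"))
  if (any(J <= 0)) stop("pore_pressure(): J must be positive")
  denom <- m + params$rho * params$phi0
  if (any(denom <= 0)) {
    stop("pore_pressure(): porosity bound violated (m <= -rho * phi0)")
  }
  fJ <- relative_volume_factor(J)
  params$p0 + params$Mb * (params$b * (1 - J) + m / params$rho) * fJ -
    params$kappa0 * params$rho / denom
}

#' Added mass from pore pressure (inverse of the pressure law)
#'
#' Solves `pore_pressure(m, J) = p` for `m` by a safeguarded Newton
#' iteration.  The pressure law is strictly increasing in `m` (both the
#' Biot term and the penalty term increase with `m`), so the root is unique
#' on the admissible interval `(-rho phi0, Inf)`.
#'
#' @param p target pore pressure(s) (Pa).
#' @param J Jacobian determinant(s), `> 0`.
#' @param params a [poro_params()] object.
#' @param m_guess starting value(s) for the iteration.
#' @param tol relative tolerance on the pressure residual.
#' @return added mass `m` (kg m^-3) with `pore_pressure(m, J) = p` to `tol`.
#' @export
invert_pore_pressure <- function(p, J, params, m_guess = 0, tol = 1e-12) {
  stopifnot(inherits(params, "poro_params"))
  n <- max(length(p), length(J))
  p <- rep_len(p, n); J <- rep_len(J, n)
  m <- rep_len(m_guess, n)
  rphi <- params$rho * params$phi0
  m <- pmax(m, -rphi * (1 - 1e-9))
  fJ <- relative_volume_factor(J)
  scale <- pmax(abs(p), params$Mb * 1e-12, 1e-300)
  lo <- rep(-rphi * (1 - 1e-12), n)  # running lower bracket
  for (it in 1:200) {
    denom <- m + rphi
    pv <- params$p0 + params$Mb * (params$b * (1 - J) + m / params$rho) * fJ -
      params$kappa0 * params$rho / denom
    res <- pv - p
    if (all(abs(res) <= tol * scale)) break
    dpdm <- params$Mb * fJ / params$rho +
      params$kappa0 * params$rho / denom^2
    step <- res / dpdm
    if (max(abs(step)) < 1e-16 * max(abs(m) + rphi)) break  # at roundoff
    m_new <- m - step
    # safeguard: p is increasing in m, so a point with res > 0 is above the
    # root; keep the iterate inside (lo, m_hi) by damped bisection
    lo[res < 0] <- pmax(lo[res < 0], m[res < 0])
    bad <- m_new <= lo
    m_new[bad] <- 0.5 * (m[bad] + lo[bad])
    m <- m_new
    if (it == 200L) stop("invert_pore_pressure(): no convergence")
  }
  m
}

#' Coefficients of the split-step pressure equation
#'
#' Chain-rule coefficients of `dp/dt` in terms of `dm/dt` and `dJ/dt`:
#' `A = Mb f(J) / rho`, `B = -Mb f(J) b`,
#' `C = Mb f'(J) (b (1 - J) + m/rho)` and the penalty-term rate coefficient
#' `D_rate = kappa0 rho / (m + rho phi0)^2`, so that
#' `dp/dt = (A + D_rate) dm/dt + (B + C) dJ/dt`.
#' `A_aug = A + D_rate` is the augmented compressibility coefficient used by
#' the implicit pressure half-step.
#'
#' @inheritParams pore_pressure
#' @return a list of numeric vectors `A`, `B`, `C`, `D_rate`, `A_aug`.
#' @export
pressure_coefficients <- function(m, J, params) {
  stopifnot(inherits(params, "poro_params"))
  if (any(J <= 0)) stop("pressure_coefficients(): J must be positive")
  denom <- m + params$rho * params$phi0
  if (any(denom <= 0)) {
    stop("pressure_coefficients(): porosity bound violated")
  }
  fJ <- relative_volume_factor(J)
  fpJ <- relative_volume_factor(J, 1L)
  A <- params$Mb * fJ / params$rho
  B <- -params$Mb * fJ * params$b
  C <- params$Mb * fpJ * (params$b * (1 - J) + m / params$rho)
  D_rate <- params$kappa0 * params$rho / denom^2
  list(A = A, B = B, C = C, D_rate = D_rate, A_aug = A + D_rate)
}

# ---------------------------------------------------------------------------
# Skeleton strain energy and stresses
# ---------------------------------------------------------------------------

expand_triad <- function(fibres, n) {
  f0 <- fibres$f0; s0 <- fibres$s0; n0 <- fibres$n0
  if (nrow(f0) == 1L && n > 1L) {
    f0 <- f0[rep(1L, n), , drop = FALSE]
    s0 <- s0[rep(1L, n), , drop = FALSE]
    n0 <- n0[rep(1L, n), , drop = FALSE]
  }
  stopifnot(nrow(f0) == n)
  list(f0 = f0, s0 = s0, n0 = n0)
}

bulk_energy <- function(J, m, K, rho) {
  arg <- J - m / rho
  if (any(arg <= 0)) stop("bulk term domain error: J - m/rho <= 0")
  K * log(arg)^2
}

# volumetric stress; with element-averaged Jbar/mbar this is the
# mean-dilatation (B-bar) form: coefficient from the averages, geometric
# factor J F^-T pointwise
bulk_pk1 <- function(F, J, m, K, rho, Jbar = J, mbar = m) {
  arg <- Jbar - mbar / rho
  if (any(arg <= 0)) stop("bulk term domain error: J - m/rho <= 0")
  coef <- 2 * K * log(arg) / arg * J
  coef * t3_transpose(t3_inv(F))
}

#' Skeleton strain energy density
#'
#' `W = Whyp(F) + Wbulk(J, m)` per unit reference volume, for either the
#' isotropic Mooney-Rivlin-type law or the Holzapfel-Ogden fibre-reinforced
#' law (which requires a [fibre_triad()]).  Fibre and sheet invariants are
#' clamped, `I4* = max(I4, 1) - 1`, so these terms store no energy in
#' compression.
#'
#' @param F deformation gradient(s): an `n x 9` matrix in column-major
#'   order, or a single 3x3 matrix.
#' @param m added mass (kg m^-3), recycled to `n`.
#' @param law an [iso_skeleton_law()] or [ho_skeleton_law()] object.
#' @param fibres a [fibre_triad()]; required for the HO law.
#' @param params a [poro_params()] object (supplies `rho`).
#' @return energy density (Pa), one value per row of `F`.
#' @export
strain_energy <- function(F, m, law, fibres = NULL, params) {
  UseMethod("strain_energy", law)
}

#' @export
strain_energy.iso_law <- function(F, m, law, fibres = NULL, params) {
  F <- as_t3(F)
  n <- nrow(F); m <- rep_len(m, n)
  J <- t3_det(F)
  if (any(J <= 0)) stop("strain_energy(): det F must be positive")
  C <- t3_mul(t3_transpose(F), F)
  I1 <- t3_trace(C)
  I2 <- 0.5 * (I1^2 - t3_ddot(C, C))
  whyp <- law$kappa1 * (I1 - 3) + law$kappa2 * (I2 - 3) -
    (2 * law$kappa1 + 4 * law$kappa2) * log(J)
  whyp + bulk_energy(J, m, law$Ks, params$rho)
}

#' @export
strain_energy.ho_law <- function(F, m, law, fibres = NULL, params) {
  if (is.null(fibres)) stop("the Holzapfel-Ogden law requires a fibre triad")
  F <- as_t3(F)
  n <- nrow(F); m <- rep_len(m, n)
  tr <- expand_triad(fibres, n)
  J <- t3_det(F)
  if (any(J <= 0)) stop("strain_energy(): det F must be positive")
  C <- t3_mul(t3_transpose(F), F)
  I1 <- t3_trace(C)
  Cf <- t3_matvec(C, tr$f0); Cs <- t3_matvec(C, tr$s0)
  I4f <- rowSums(tr$f0 * Cf)
  I4s <- rowSums(tr$s0 * Cs)
  I8 <- rowSums(tr$f0 * Cs)
  I4fs_ <- pmax(I4f, 1) - 1
  I4ss_ <- pmax(I4s, 1) - 1
  whyp <- law$a / (2 * law$b) * exp(law$b * (I1 - 3)) +
    law$af / (2 * law$bf) * (exp(law$bf * I4fs_^2) - 1) +
    law$as_ / (2 * law$bs) * (exp(law$bs * I4ss_^2) - 1) +
    law$afs / (2 * law$bfs) * (exp(law$bfs * I8^2) - 1)
  whyp + bulk_energy(J, m, law$Kbulk, params$rho)
}

#' Passive first Piola-Kirchhoff stress of the skeleton
#'
#' `P = dW/dF` for the selected skeleton law (including the bulk term),
#' minus the stress-free reference correction, so that `P(I, m = 0) = 0`
#' exactly.  For the isotropic law the correction is the gradient of the
#' `ln J` term already contained in the energy; for the HO law it is the
#' non-integrable term `scale * a * exp(b(I1-3)) F^-T` (see
#' [ho_skeleton_law()]).  The clamped fibre terms have one-sided zero
#' derivative at `I4 = 1`, so the stress is continuous across the clamp.
#'
#' @inheritParams strain_energy
#' @return an `n x 9` matrix of stresses (Pa).
#' @export
pk1_passive <- function(F, m, law, fibres = NULL, params, Jbar = NULL,
                        mbar = NULL) {
  UseMethod("pk1_passive", law)
}

#' @export
pk1_passive.iso_law <- function(F, m, law, fibres = NULL, params,
                                Jbar = NULL, mbar = NULL) {
  F <- as_t3(F)
  n <- nrow(F); m <- rep_len(m, n)
  J <- t3_det(F)
  if (any(J <= 0)) stop("pk1_passive(): det F must be positive")
  C <- t3_mul(t3_transpose(F), F)
  I1 <- t3_trace(C)
  FC <- t3_mul(F, C)
  Finvt <- t3_transpose(t3_inv(F))
  P <- 2 * law$kappa1 * F + 2 * law$kappa2 * (I1 * F - FC) -
    (2 * law$kappa1 + 4 * law$kappa2) * Finvt
  P + bulk_pk1(F, J, m, law$Ks, params$rho,
               Jbar = if (is.null(Jbar)) J else Jbar,
               mbar = if (is.null(mbar)) m else mbar)
}

#' @export
pk1_passive.ho_law <- function(F, m, law, fibres = NULL, params,
                               Jbar = NULL, mbar = NULL) {
  if (is.null(fibres)) stop("the Holzapfel-Ogden law requires a fibre triad")
  F <- as_t3(F)
  n <- nrow(F); m <- rep_len(m, n)
  tr <- expand_triad(fibres, n)
  J <- t3_det(F)
  if (any(J <= 0)) stop("pk1_passive(): det F must be positive")
  C <- t3_mul(t3_transpose(F), F)
  I1 <- t3_trace(C)
  Cf <- t3_matvec(C, tr$f0); Cs <- t3_matvec(C, tr$s0)
  I4f <- rowSums(tr$f0 * Cf)
  I4s <- rowSums(tr$s0 * Cs)
  I8 <- rowSums(tr$f0 * Cs)
  I4fs_ <- pmax(I4f, 1) - 1
  I4ss_ <- pmax(I4s, 1) - 1
  expI1 <- exp(law$b * (I1 - 3))
  P <- law$a * expI1 * F
  # fibre/sheet terms: d/dF [ a_i/(2 b_i) (exp(b_i I4*^2) - 1) ]
  #   = a_i I4* exp(b_i I4*^2) * 2 F (v0 x v0), zero where I4 <= 1
  cf <- 2 * law$af * I4fs_ * exp(law$bf * I4fs_^2)
  cs <- 2 * law$as_ * I4ss_ * exp(law$bs * I4ss_^2)
  if (any(cf != 0)) P <- P + cf * t3_mul(F, t3_outer(tr$f0, tr$f0))
  if (any(cs != 0)) P <- P + cs * t3_mul(F, t3_outer(tr$s0, tr$s0))
  c8 <- law$afs * I8 * exp(law$bfs * I8^2)
  P <- P + c8 * t3_mul(F, t3_outer(tr$f0, tr$s0) + t3_outer(tr$s0, tr$f0))
  Finvt <- t3_transpose(t3_inv(F))
  P <- P - law$reference_correction_scale * law$a * expI1 * Finvt
  P + bulk_pk1(F, J, m, law$Kbulk, params$rho,
               Jbar = if (is.null(Jbar)) J else Jbar,
               mbar = if (is.null(mbar)) m else mbar)
}

#' Active first Piola-Kirchhoff stress
#'
#' `P_a = J Ta F (f0 x f0)`: a uniaxial tension of magnitude `Ta` along the
#' deformed fibre direction.
#'
#' @param F deformation gradient(s), `n x 9` or 3x3.
#' @param Ta active tension (Pa), `>= 0`, recycled to `n`.
#' @param f0 reference fibre direction(s): length-3 vector or `n x 3`.
#' @return an `n x 9` matrix of stresses (Pa).
#' @export
pk1_active <- function(F, Ta, f0) {
  F <- as_t3(F)
  n <- nrow(F)
  if (!is.matrix(f0)) f0 <- matrix(f0, 1L, 3L)
  if (nrow(f0) == 1L && n > 1L) f0 <- f0[rep(1L, n), , drop = FALSE]
  Ta <- rep_len(Ta, n)
  if (any(Ta < 0)) stop("pk1_active(): Ta must be non-negative")
  J <- t3_det(F)
  if (any(J <= 0)) stop("pk1_active(): det F must be positive")
  (J * Ta) * t3_mul(F, t3_outer(f0, f0))
}

#' Total first Piola-Kirchhoff stress of the skeleton
#'
#' Passive skeleton stress plus (optionally) active stress: the elastic
#' stress of the mixture entering the structural weak form.  The pore
#' fluid acts on the mechanics through the added mass `m` in the bulk term
#' (driving `J` toward the mass-conservation state `1 + m/rho`), not
#' through a separate pore-pressure stress, matching the model's working
#' constitutive equations where the stress is `dW/dF` of the skeleton
#' energy alone.
#'
#' @inheritParams strain_energy
#' @param Ta active tension (Pa); 0 disables the active term.
#' @param poroelastic if `FALSE`, `m` is ignored and the bulk term acts on
#'   `ln(J)` alone: the pure hyperelastic comparator.
#' @return an `n x 9` matrix of stresses (Pa).
#' @export
pk1_total <- function(F, m, law, fibres = NULL, params, Ta = 0,
                      poroelastic = TRUE, Jbar = NULL, mbar = NULL) {
  if (!poroelastic) { m <- 0; mbar <- NULL }
  P <- pk1_passive(F, m, law, fibres = fibres, params = params,
                   Jbar = Jbar, mbar = mbar)
  if (any(Ta > 0)) {
    n <- nrow(as_t3(F))
    trd <- expand_triad(fibres, n)
    P <- P + pk1_active(F, Ta, trd$f0)
  }
  P
}

# ---------------------------------------------------------------------------
# Distributed sources
# ---------------------------------------------------------------------------

#' Distributed pore-fluid source
#'
#' Compartment mode: `S = beta_a (pa - p) - beta_v (p - pv)` (coronary
#' arterial inflow minus venous outflow).  Sink mode:
#' `S = -beta (p - p_sink)` (plain drainage).
#'
#' @param p pore pressure(s) (Pa).
#' @param src a [source_params()] object.
#' @return volumetric source rate (s^-1), vectorized over `p`.
#' @export
distributed_source <- function(p, src) {
  stopifnot(inherits(src, "source_params"))
  if (src$mode == "compartment") {
    src$beta_a * (src$pa - p) - src$beta_v * (p - src$pv)
  } else {
    -src$beta * (p - src$p_sink)
  }
}

#' Affine decomposition of a distributed source
#'
#' Writes the source as `S(p) = s0 - s1 p` (both models are affine in the
#' pore pressure), the form used for its implicit treatment in the
#' pressure solve.
#'
#' @param src a [source_params()] object.
#' @return list with `s0` (s^-1) and `s1` (Pa^-1 s^-1).
#' @export
source_affine_coeffs <- function(src) {
  stopifnot(inherits(src, "source_params"))
  if (src$mode == "compartment") {
    list(s0 = src$beta_a * src$pa + src$beta_v * src$pv,
         s1 = src$beta_a + src$beta_v)
  } else {
    list(s0 = src$beta * src$p_sink, s1 = src$beta)
  }
}
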