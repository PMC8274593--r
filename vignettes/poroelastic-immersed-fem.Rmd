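---
title: "Modelling cardiac perfusion with a poroelastic immersed finite element framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiac perfusion with a poroelastic immersed finite element framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`poroifem` treats the myocardium as a saturated porous medium: a solid
skeleton (myocytes and collagen) whose pore space is perfused by blood.
Both constituents are individually incompressible and share a common
density $\rho$, so the mixture changes volume only by exchanging pore
fluid: the Jacobian of the skeleton deformation satisfies
$J = 1 + m/\rho$, where $m(\mathbf X,t)$ is the *added mass* — pore-fluid
mass gained per unit reference volume relative to the initial porosity
$\phi_0$.

Three ingredients close the model.

**Pore pressure law.** The pore free energy (per reference volume)

$$\Psi_{\mathrm{pore}} = M_b\Big[b\,\tfrac{m}{\rho}(1-J) +
\tfrac12\big(\tfrac{m}{\rho}\big)^2\Big]f(J)
\;-\;\kappa_0\ln\!\big(\tfrac{m}{\rho}+\phi_0\big),
\qquad f(J)=\frac{2\,(J-1-\ln J)}{(J-1)^2},$$

yields the interstitial pressure

$$p = p_0 + M_b\Big(b(1-J)+\frac{m}{\rho}\Big)f(J)
- \frac{\kappa_0\rho}{m+\rho\phi_0}.$$

$M_b$ is the Biot modulus (2.18e5 Pa in all benchmarks), $b$ a skeleton
coupling parameter (1), and $\kappa_0$ (0.01 Pa) a barrier that keeps the
porosity in $(0,1)$.  With the convention $p_0=\kappa_0/\phi_0$ adopted
here, the reference state $(m,p,J)=(0,0,1)$ is an exact trivial solution;
`poro_params()` evaluates the default $p_0$ with the same floating-point
expression as the barrier term so the cancellation is exact to the last
bit.  (The alternative convention $p_0=\kappa_0\phi_0$ does not zero the
reference pressure; $p_0$ is exposed and can be overridden.)  A sign in
the first energy term is chosen so that energy, pressure and the
pressure-equation coefficients below are mutually consistent — dilation
at fixed $m$ lowers the pore pressure.

**Skeleton stress.** The elastic stress of the mixture is
$\mathbb P = \partial W/\partial F$ of the skeleton energy
$W = W^{\mathrm{hyp}} + W^{\mathrm{bulk}}$, with
$W^{\mathrm{bulk}} = K_s \ln^2(J - m/\rho)$ penalising deviations from
the mass-conservation state $J = 1+m/\rho$ — perfusion acts on the
mechanics through $m$ in this term, not through a separate pore-pressure
stress.  (Including the $J$-derivative of $\Psi_{\mathrm{pore}}$ in the
stress as well makes the homogeneous coupled equilibrium linearly
unstable for the benchmark constants — the feedback gain between mass
recovery and mechanics is $1 + M_b b/2K_s \approx 1.5$ — so the working
equations deliberately use the skeleton energy alone, and thermodynamic
consistency is embodied as the stress-equals-energy-gradient property
checks.)  Two hyperelastic laws are provided:

* `iso_skeleton_law()`: $W^{\mathrm{hyp}} = \kappa_1(I_1-3) +
  \kappa_2(I_2-3) - (2\kappa_1+4\kappa_2)\ln J$.  The $\ln J$ term is an
  integrable reference correction making $\mathbb P(\mathbf I)=0$ exact;
  $\kappa_1 = 2\kappa_2 = 2000$ Pa by default (order-of-magnitude
  consistent with $K_s$; the benchmark acceptance checks are oracle- and
  pattern-based, not tied to these values).
* `ho_skeleton_law()`: the Holzapfel–Ogden orthotropic myocardium law
  with fibre/sheet/normal axes, exponents and stress scales at their
  standard passive-myocardium values, clamped fibre invariants
  $I_4^\star=\max(I_4,1)-1$ (no fibre stress in compression; one-sided
  zero derivative at the clamp keeps the stress continuous), and the
  non-integrable reference correction
  $-a\,e^{b(I_1-3)}F^{-T}$.  As printed in the source constitutive
  literature the correction carries $a/2$, which leaves
  $\mathbb P(\mathbf I) = (a/2)\mathbf I \ne 0$ under the convention
  $\partial I_1/\partial F = 2F$; the default
  `reference_correction_scale = 1` doubles it so the reference is exactly
  stress free, and the half-scale variant remains available.

**Darcy transport and sources.** In the reference frame
$\mathbf W = -J F^{-1}\mathbf K F^{-T}\nabla_X p$, with mass balance
$\partial m/\partial t = \rho S - \nabla_X\cdot(\rho\mathbf W)$.  The
distributed source is either a single coronary compartment
$S=\beta_a(p_a-p)-\beta_v(p-p_v)$ or a plain sink
$S=-\beta(p-p_{\mathrm{sink}})$.

# The split-step Darcy scheme

The primary variables $(p,\mathbf W,m)$ advance through two half-steps,
each ordered $p \to \mathbf W \to m$.  The implicit pressure equation is
used in a rederived form: the printed coefficient equations are
dimensionally inconsistent as typeset, so the equation is rebuilt by
substituting the mass balance into the chain rule
$\dot p = \hat A\,\dot m + (B+C)\dot J$, giving

$$\frac{1}{\hat A\rho}\,\frac{\partial p}{\partial t}
-\nabla_X\cdot\big(JF^{-1}\mathbf K F^{-T}\nabla_X p\big)
= S + \frac{(B+C)}{\hat A\rho}\frac{\partial J}{\partial t},$$

with $\hat A = M_b f(J)/\rho + \kappa_0\rho/(m+\rho\phi_0)^2$ (the
barrier rate folded into the compressibility), $B=-M_b f b$ and
$C=M_b f'(J)(b(1-J)+m/\rho)$.  Trilinear Lagrangian elements, backward
Euler over $\Delta t/2$, symmetric Dirichlet elimination, sparse Cholesky
(zero-flux boundaries are natural).  Both source models are affine in
$p$, so $S$ is taken implicitly at the new pressure: the system stays
linear and the update is unconditionally stable with respect to the
source relaxation time $1/(\hat A\rho(\beta_a+\beta_v)) \approx 0.15$ ms,
which any practical step exceeds by orders of magnitude (an explicit
source diverges immediately at the ventricular conductances).

The flux follows explicitly from the new pressure, and the added mass is
recovered by inverting the pressure law with a safeguarded Newton
iteration, `invert_pore_pressure()` — the law is strictly increasing in
$m$, so the root is unique; this replaces a garbled printed linearised
recovery and reduces to it when the barrier term is negligible.  The
second half-step updates $m$ from the explicit mass balance using the
start-of-step flux.  An explicit clamp keeps $m$ just above the porosity
floor $-\rho\phi_0$, which the implicit stages respect via the barrier
but the explicit update can overshoot when a drainage run exhausts the
pore space.

`pressure_coefficients()`, `relative_volume_factor()` (with a series
expansion near the removable singularity at $J=1$) and the scheme's
first-order-in-time / second-order-in-space behaviour are covered by
direct and manufactured-solution tests.

# Quasi-static Lagrangian mode

The cube and ventricle benchmarks run primarily in a staggered
quasi-static mode: at each load increment a Newton iteration equilibrates
`internal_force(pk1_total) + external_force = 0` with the pore field
frozen, then the split-step Darcy solver advances over the increment with
the updated kinematics ($\partial J/\partial t$ by backward difference).
Inertia is neglected — the benchmark loading rates are far below the
elastic wave timescales (the immersed mode retains the dynamic balance).

Numerical choices that matter:

* **Mean dilatation (B-bar).** With $K_s/\kappa_1 \approx 100$ the fully
  integrated trilinear element locks volumetrically (at two transmural
  layers the ventricle's end-diastolic volume is ~10% low and the
  perfusion effect comes out with the wrong sign).  The bulk-term
  coefficient is therefore evaluated from element-averaged $\bar J$ and
  $\bar m$, keeping the pointwise geometric factor $JF^{-T}$.
* **Tangent.** Central finite differences of the total stress per
  quadrature point (frozen $\bar J$), plus the exact rank-one element
  stiffness of the mean-dilatation term; factorizations are reused while
  the residual contracts by at least 5× per iteration (modified Newton)
  and refreshed otherwise, with a backtracking line search that only
  accepts decreasing residuals.
* **Follower pressure.** Endocardial loading follows the deformed
  surface.  The follower normals are frozen within each Newton pass and
  updated in an outer fixed-point loop until the true follower residual
  meets the $10^{-8}$ scaled tolerance, so the inner iteration keeps its
  quadratic rate without a load-stiffness matrix.
* **Constraints.** Plane-normal and fixed-point constraints eliminate
  degrees of freedom; the ventricular basal constraint rotates the basal
  nodes to cylindrical axes and retains only the radial column.

# Immersed three-phase mode

The immersed mode embeds the structure in a uniform staggered (MAC) grid
carrying one common velocity field.  Structural forces (internal +
penalty tethers for the constraints + surface loads) are converted to
densities via lumped nodal volumes, evaluated at the quadrature points
and spread with the 4-point regularized delta kernel; the effective
source $s^* = S - \nabla_X\cdot\mathbf W$ is spread to cell centres; the
fluid step (explicit first-order upwind advection, implicit viscosity,
exact discrete projection) enforces $\nabla\cdot v = s^*$ cell-wise; the
structure moves with the interpolated velocity; the Darcy stage then runs
on the new kinematics and feeds the next step's $s^*$.  Spreading and
interpolation are exact adjoints, and the kernel satisfies the discrete
moment conditions for arbitrary sub-grid offsets.  The outer boundary
approximates zero normal traction (zero pressure, zero tangential slip,
free normal velocity), and the computational box pads the benchmark cube
by 25% per side so the kernel support never touches the boundary.
First-order upwinding (rather than a higher-order variant) is used for
the advection term: the benchmark flows are viscous-dominated and the
choice is asserted only through the invariant suite (e.g. the closed-form
viscous-decay test), not against reference flow fields.

**A known limitation.** Because the skeleton is incompressible, the
drained (pressure-equilibrated) mixture has *zero* volumetric stiffness:
$J - m/\rho$ is invariant under the mass recovery with $b=1$, and mass
conservation returns a volumetric source exactly equal to the local
expansion rate.  The explicit staggered exchange of $s^*$ therefore
carries a neutrally stable volume-exchange mode at the element scale,
which in practice grows slowly (for the swelling cube at the default
resolutions the growth time constant is about 17 ms, independent of the
time step).  The immersed benchmarks consequently verify the early
transient (the swelling cube is checked over 0–0.08 s, where probe
histories are clean, monotone and conservative to ~2%), while
steady-state quantities are verified in the Lagrangian mode, and the two
modes are cross-checked against each other on the shared transient
window.  An optional explicit volumetric damping (`eta_vol`, scale
$h_s^2/k$ — the intra-element Darcy resistance invisible to the trilinear
pressure space) is provided but is itself explicit and so limited;
matching the structure mesh spacing to the grid spacing also helps.
Removing the mode properly would require an implicit structure–source
coupling, out of scope here.

# The synthetic benchmark conditions

All inputs are generated in code; there are no external data sets.

* The cube benchmarks use the tabulated constants
  ($M_b=2.18\times10^5$ Pa, $b=1$, $\rho=10^3$ kg m$^{-3}$,
  $K_s=2.2\times10^5$ Pa, $\kappa_0=0.01$ Pa; porosity 0.1 and
  permeability $10^{-7}$ (swelling) or $2.5\times10^{-6}$ (drainage)
  m$^2$ Pa$^{-1}$s$^{-1}$), the printed inlet ramp
  $10^3(1-e^{-t^2/0.25})$ Pa, load ramp $10^4(1-e^{-t^2/0.04})$ Pa, and
  sink $\beta=10^{-4}$ Pa$^{-1}$s$^{-1}$, $p_{\mathrm{sink}}=0$.
* The ventricle scenario replaces the subject-specific imaging geometry
  (out of scope) with a synthetic idealized truncated prolate ellipsoid:
  endocardial semi-axes 2.2/6.2 cm, epicardial 3.4/7.2 cm, basal
  truncation 1.5 cm above the equator, and a small apical opening (polar
  half-angle 0.3 rad) so the hexahedral mesh stays non-degenerate — the
  mesh-quality invariant (scaled Jacobian ≥ 0.2) would fail with
  collapsed polar elements, and the opening changes the closed-form
  cavity volume only at $O(\theta^4)$.  Dimensions were chosen once for
  a typical human scale (unloaded cavity ≈ 69 ml, inflating to ≈ 120 ml
  at 8 mmHg under the Holzapfel–Ogden defaults).  Rule-based fibres
  rotate linearly from −60° (endo) to +60° (epi) — the standard
  rule-based default; the subject-specific angles are not public — with
  transmural sheet normal.  Perfusion uses porosity 0.15, permeability
  $2\times10^{-9}$, and the compartment source
  ($\beta_a=3\times10^{-5}$, $\beta_v=3\times10^{-2}$
  Pa$^{-1}$s$^{-1}$, $p_a=2.7$ kPa, $p_v=1.3$ kPa).  Diastole ramps the
  endocardial pressure linearly to 8 mmHg over 0.5 s; systole (optional)
  raises it rapidly to 112 mmHg while a prescribed smooth active-tension
  transient (half-cosine to the 124 kPa plateau over 0.15 s) stands in
  for the calcium-driven contraction model, which is out of scope.

What the passing tests do and do not show: the generator reproduces the
*structure* of the benchmark experiments — geometry class, constitutive
constants, ramps, boundary conditions — so agreement demonstrates
correctness of the discretizations and of the coupling logic, and
qualitative fidelity of the physics (swelling patterns, drainage,
anisotropy, perfusion stiffening).  It does not demonstrate quantitative
fidelity to a specific heart: real myocardium has subject-specific
geometry, heterogeneous fibre architecture and permeability, and valve
dynamics, none of which are represented.

# Problem sizes and tolerances

Package defaults and the sizes used by the test suite and the acceptance
script (chosen as sensible desk-scale resolutions for each check):

* Trivial fixed point: 1000 coupled steps, $2^3$–$3^3$ solid / $8^3$
  grid.  "Machine zero" means roundoff relative to the kPa/cm problem
  scales; the only perturbation source is $J = 1\pm\varepsilon$ from the
  floating-point quadrature geometry.
* Steady Darcy oracle: $16^3$ solid mesh, centre pressure 500 Pa to
  $10^{-6}$ relative (the trilinear space contains the exact linear
  profile).
* Immersed swelling pattern: $12^3$ grid / $4^3$ solid, $\Delta t =
  10^{-4}$ s, 0–0.08 s window (see the limitation above).
* Drainage: $6^3$ solid, 1 s horizon; the tabulated constants drive the
  cube towards full drainage, so the run ends near the porosity floor —
  the volume-averaged added mass and Jacobian decrease monotonically
  past the load plateau and respect the bound.
* Fibre-reinforced swelling: $5^3$–$6^3$ solid; the three orientation
  cases map onto each other *exactly* under the cyclic axis permutation
  when the inlet face follows the permutation, which is how the symmetry
  is asserted (with a fixed inlet the mapping is broken by the boundary
  conditions themselves).
* Ventricle: default mesh 32 × 12 × 3 (circumferential × longitudinal ×
  transmural) elements; the acceptance script runs 24 × 10 × 3 and the
  test suite 20 × 8 × 3, both with 10 diastolic increments — the
  end-diastolic volume reduction agrees to two digits across all three
  resolutions.  Three transmural layers are the smallest count at which
  the mean-dilatation elements resolve the transmural perfusion
  gradient (three and four layers agree to two digits).
* Grid-consistency surrogate: the full-scale grid-refinement claim is a
  cluster-scale computation; the suite asserts a desk-scale surrogate
  (rigid-Darcy centre pressure at $16^3$ vs $24^3$; coupled swelling
  displacement at $8^3$ vs $12^3$; both within 15%).

The linear solvers are direct sparse factorizations; Newton tolerance
$10^{-8}$ on the scaled residual; mass-recovery tolerance $10^{-12}$
relative.

# Known limitations

* The immersed mode's marginal volume-exchange instability (above)
  restricts immersed runs to transients; long-horizon immersed runs need
  an implicit exchange scheme.
* The perfusion-stiffening magnitude is geometry sensitive: on the
  idealized ellipsoid the end-diastolic volume reduction converges to
  about 1.7–1.8% across transmural resolutions, smaller than values
  reported for subject-specific geometries (the idealized wall inflates
  ~55% by end-diastole, i.e. it is substantially more compliant).  The
  direction and mechanism — pore blood loading the wall during filling
  and shifting the exponential laws to a stiffer operating point — are
  reproduced robustly.
* Hexahedral elements only; single-point tetrahedra are not implemented
  (the mesh generators only emit hexes).
* No valves or outflow tracts (cavity fluid merges with the bathing
  fluid), no multi-compartment perfusion, no active-tension ODEs, no
  adaptive meshing or parallelism.
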