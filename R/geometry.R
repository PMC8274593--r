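# Mesh and fixture generation: structured unit-cube hex meshes with tagged
# faces, constant fibre triads for the fibre-reinforced cube cases, and an
# idealized truncated prolate-ellipsoid left ventricle with rule-based
# fibres (a synthetic stand-in for subject-specific imaging geometry).

#' Structured hexahedral cube mesh
#'
#' `n^3` axis-aligned hex elements on `[0, edge]^3` with boundary facet tags
#' `x0`, `x1`, `y0`, `y1`, `z0`, `z1`.  Element volumes sum to `edge^3`
#' exactly.
#'
#' @param n elements per axis (`>= 2`).
#' @param edge edge length (m); default 0.01 (the 1 cm benchmark cube).
#' @return a [lagrangian_mesh()].
#' @export
unit_cube_mesh <- function(n, edge = 0.01) {
  stopifnot(n >= 2)
  m <- n + 1L
  g <- seq(0, edge, length.out = m)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  colnames(nodes) <- NULL
  idx <- function(i, j, k) i + m * ((j - 1L) + m * (k - 1L))
  cells <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  i <- cells$i; j <- cells$j; k <- cells$k
  elems <- cbind(idx(i, j, k), idx(i + 1L, j, k), idx(i + 1L, j + 1L, k),
                 idx(i, j + 1L, k), idx(i, j, k + 1L), idx(i + 1L, j, k + 1L),
                 idx(i + 1L, j + 1L, k + 1L), idx(i, j + 1L, k + 1L))
  face_of <- function(sel, face) {
    e <- elems[sel, , drop = FALSE]
    e[, hex_faces[[face]], drop = FALSE]
  }
  facets <- list(x0 = face_of(i == 1L, "xm"), x1 = face_of(i == n, "xp"),
                 y0 = face_of(j == 1L, "ym"), y1 = face_of(j == n, "yp"),
                 z0 = face_of(k == 1L, "zm"), z1 = face_of(k == n, "zp"))
  lagrangian_mesh(nodes, elems, facets)
}

#' Constant fibre triads for the cube benchmarks
#'
#' The three printed orientation cases: fibres along `x` with
#' `f0 = (1,0,0)`, `s0 = (0,1,0)`, `n0 = (0,0,1)`; along `y` with
#' `f0 = (0,1,0)`, `s0 = (0,0,1)`, `n0 = (1,0,0)`; along `z` with
#' `f0 = (0,0,1)`, `s0 = (1,0,0)`, `n0 = (0,1,0)`.
#'
#' @param mesh a [lagrangian_mesh()].
#' @param orientation `"x"`, `"y"` or `"z"`.
#' @return a [fibre_triad()] with one row per element.
#' @export
cube_fibres <- function(mesh, orientation = c("x", "y", "z")) {
  orientation <- match.arg(orientation)
  tri <- switch(orientation,
                x = list(f0 = c(1, 0, 0), s0 = c(0, 1, 0), n0 = c(0, 0, 1)),
                y = list(f0 = c(0, 1, 0), s0 = c(0, 0, 1), n0 = c(1, 0, 0)),
                z = list(f0 = c(0, 0, 1), s0 = c(1, 0, 0), n0 = c(0, 1, 0)))
  E <- mesh$n_elems
  rep3 <- function(v) matrix(v, E, 3, byrow = TRUE)
  fibre_triad(rep3(tri$f0), rep3(tri$s0), rep3(tri$n0))
}

# expand a per-element fibre triad to quadrature points (qp-major rows)
triad_at_qps <- function(fibres, mesh) {
  expand <- function(v) {
    if (nrow(v) == 1L) return(v)
    stopifnot(nrow(v) == mesh$n_elems)
    v[rep(seq_len(mesh$n_elems), each = 8L), , drop = FALSE]
  }
  structure(list(f0 = expand(fibres$f0), s0 = expand(fibres$s0),
                 n0 = expand(fibres$n0)), class = "fibre_triad")
}

#' Idealized left-ventricle geometry parameters
#'
#' Truncated thick-walled prolate ellipsoid: endocardial and epicardial
#' surfaces are coaxial ellipsoids of revolution about the long (z) axis,
#' truncated by the basal plane `z = base_height` above the equator, with
#' the apex at `z = -c`.  A small polar opening of half-angle `apex_angle`
#' is left at the apex so the hexahedral mesh stays non-degenerate.  Fibre
#' helix angles vary linearly through the wall from `helix_endo` to
#' `helix_epi`; the sheet normal is transmural.
#'
#' Default dimensions give a reference (unloaded) cavity volume of about
#' 69 ml, a typical human scale.
#'
#' @param a_endo,c_endo endocardial short and long semi-axes (m).
#' @param a_epi,c_epi epicardial short and long semi-axes (m).
#' @param base_height basal truncation plane height above the equator (m).
#' @param apex_angle polar half-angle of the apical opening (radians).
#' @param n_circ,n_long,n_trans elements circumferentially, longitudinally
#'   and through the wall.
#' @param helix_endo,helix_epi fibre helix angles (degrees) at the
#'   endocardium and epicardium, in `(-90, 90)`.
#' @return an object of class `"lv_geometry_params"`.
#' @export
lv_geometry_params <- function(a_endo = 0.022, c_endo = 0.062,
                               a_epi = 0.034, c_epi = 0.072,
                               base_height = 0.015, apex_angle = 0.30,
                               n_circ = 32L, n_long = 12L, n_trans = 3L,
                               helix_endo = -60, helix_epi = 60) {
  stopifnot(a_epi > a_endo, c_epi > c_endo,
            base_height < c_endo, apex_angle > 0, apex_angle < pi / 4,
            n_circ >= 8, n_long >= 3, n_trans >= 1,
            abs(helix_endo) < 90, abs(helix_epi) < 90)
  structure(list(a_endo = a_endo, c_endo = c_endo, a_epi = a_epi,
                 c_epi = c_epi, base_height = base_height,
                 apex_angle = apex_angle, n_circ = as.integer(n_circ),
                 n_long = as.integer(n_long), n_trans = as.integer(n_trans),
                 helix_endo = helix_endo, helix_epi = helix_epi),
            class = "lv_geometry_params")
}

#' Closed-form cavity volume of the truncated idealized LV
#'
#' Volume enclosed by the endocardial ellipsoid between the flat apical cap
#' (at the apical opening) and the flat basal cap:
#' `V = pi a^2 [z - z^3/(3 c^2)]` evaluated between
#' `z = -c cos(apex_angle)` and `z = base_height`.
#'
#' @param params an [lv_geometry_params()].
#' @return cavity volume (m^3).
#' @export
lv_cavity_volume_exact <- function(params) {
  a <- params$a_endo; cc <- params$c_endo
  f <- function(z) z - z^3 / (3 * cc^2)
  pi * a^2 * (f(params$base_height) - f(-cc * cos(params$apex_angle)))
}

#' Idealized prolate-ellipsoid left ventricle with rule-based fibres
#'
#' Generates the hexahedral LV wall mesh (facet tags `endo`, `epi`, `base`,
#' `apex`) and a per-element fibre triad: the fibre direction makes the
#' helix angle with the circumferential direction in the local wall-tangent
#' plane, rotating linearly from `helix_endo` to `helix_epi` through the
#' wall, and the sheet normal is the transmural direction.
#'
#' @param params an [lv_geometry_params()].
#' @return a list with elements `mesh` (a [lagrangian_mesh()]) and
#'   `fibres` (a [fibre_triad()] with one row per element).
#' @export
ellipsoid_lv <- function(params = lv_geometry_params()) {
  stopifnot(inherits(params, "lv_geometry_params"))
  nc <- params$n_circ; nl <- params$n_long; nt <- params$n_trans
  # surface point at polar angle phi (from +z), angle theta, surface (a, c)
  surf <- function(a, cc, phi, theta) {
    cbind(a * sin(phi) * cos(theta), a * sin(phi) * sin(theta), cc * cos(phi))
  }
  phi_base_en <- acos(params$base_height / params$c_endo)
  phi_base_ep <- acos(params$base_height / params$c_epi)
  phi_apex <- pi - params$apex_angle
  # node grid: s in [0,1] base -> apex, xi in [0,1] endo -> epi, theta periodic
  svec <- seq(0, 1, length.out = nl + 1L)
  xivec <- seq(0, 1, length.out = nt + 1L)
  thvec <- 2 * pi * seq(0, nc - 1L) / nc
  node_id <- function(il, ic, it) {
    # il in 1..nl+1 (long), ic in 1..nc (circ, periodic), it in 1..nt+1
    ic <- (ic - 1L) %% nc + 1L
    il + (nl + 1L) * ((ic - 1L) + nc * (it - 1L))
  }
  n_nodes <- (nl + 1L) * nc * (nt + 1L)
  nodes <- matrix(0, n_nodes, 3)
  for (it in seq_len(nt + 1L)) {
    xi <- xivec[it]
    for (ic in seq_len(nc)) {
      th <- thvec[ic]
      phi_en <- phi_base_en + svec * (phi_apex - phi_base_en)
      phi_ep <- phi_base_ep + svec * (phi_apex - phi_base_ep)
      pe <- surf(params$a_endo, params$c_endo, phi_en, th)
      pp <- surf(params$a_epi, params$c_epi, phi_ep, th)
      nodes[node_id(seq_len(nl + 1L), ic, it), ] <- (1 - xi) * pe + xi * pp
    }
  }
  # elements: local dims (long, circ, trans) -> positive Jacobians
  cells <- expand.grid(il = 1:nl, ic = 1:nc, it = 1:nt)
  il <- cells$il; ic <- cells$ic; it <- cells$it
  elems <- cbind(node_id(il, ic, it),      node_id(il + 1L, ic, it),
                 node_id(il + 1L, ic + 1L, it), node_id(il, ic + 1L, it),
                 node_id(il, ic, it + 1L), node_id(il + 1L, ic, it + 1L),
                 node_id(il + 1L, ic + 1L, it + 1L),
                 node_id(il, ic + 1L, it + 1L))
  face_of <- function(sel, face) {
    e <- elems[sel, , drop = FALSE]
    e[, hex_faces[[face]], drop = FALSE]
  }
  facets <- list(endo = face_of(it == 1L, "zm"),
                 epi = face_of(it == nt, "zp"),
                 base = face_of(il == 1L, "xm"),
                 apex = face_of(il == nl, "xp"))
  mesh <- lagrangian_mesh(nodes, elems, facets)
  # rule-based fibres at element parametric centres
  E <- nrow(elems)
  sC <- (svec[il] + svec[il + 1L]) / 2
  xiC <- (xivec[it] + xivec[it + 1L]) / 2
  thC <- thvec[ic] + pi / nc
  phi_en <- phi_base_en + sC * (phi_apex - phi_base_en)
  phi_ep <- phi_base_ep + sC * (phi_apex - phi_base_ep)
  # interpolated-surface tangents at (s, theta, xi)
  dpe_s <- cbind(params$a_endo * cos(phi_en) * cos(thC),
                 params$a_endo * cos(phi_en) * sin(thC),
                 -params$c_endo * sin(phi_en)) * (phi_apex - phi_base_en)
  dpp_s <- cbind(params$a_epi * cos(phi_ep) * cos(thC),
                 params$a_epi * cos(phi_ep) * sin(thC),
                 -params$c_epi * sin(phi_ep)) * (phi_apex - phi_base_ep)
  dpe_t <- cbind(-params$a_endo * sin(phi_en) * sin(thC),
                 params$a_endo * sin(phi_en) * cos(thC), 0)
  dpp_t <- cbind(-params$a_epi * sin(phi_ep) * sin(thC),
                 params$a_epi * sin(phi_ep) * cos(thC), 0)
  d_s <- (1 - xiC) * dpe_s + xiC * dpp_s   # meridian tangent (toward apex)
  d_t <- (1 - xiC) * dpe_t + xiC * dpp_t   # circumferential tangent
  normalize <- function(v) v / sqrt(rowSums(v^2))
  e_c <- normalize(d_t)
  # longitudinal: meridian tangent toward the base, orthogonalized
  e_l <- -d_s
  e_l <- normalize(e_l - rowSums(e_l * e_c) * e_c)
  e_t <- cbind(e_c[, 2] * e_l[, 3] - e_c[, 3] * e_l[, 2],
               e_c[, 3] * e_l[, 1] - e_c[, 1] * e_l[, 3],
               e_c[, 1] * e_l[, 2] - e_c[, 2] * e_l[, 1])  # transmural (out)
  alpha <- (params$helix_endo + (params$helix_epi - params$helix_endo) * xiC) *
    pi / 180
  f0 <- cos(alpha) * e_c + sin(alpha) * e_l
  n0 <- e_t
  s0 <- cbind(n0[, 2] * f0[, 3] - n0[, 3] * f0[, 2],
              n0[, 3] * f0[, 1] - n0[, 1] * f0[, 3],
              n0[, 1] * f0[, 2] - n0[, 2] * f0[, 1])
  list(mesh = mesh, fibres = fibre_triad(f0, s0, n0),
       params = params)
}
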