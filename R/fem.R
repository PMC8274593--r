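# Lagrangian finite-element machinery for the skeleton: trilinear hexahedral
# meshes with tagged boundary facets, precomputed Gauss quadrature in the
# reference configuration, deformation kinematics, and the weak-form internal
# force.  Quadrature is 2x2x2 Gauss per hex; all per-quadrature-point fields
# are stored as (n_elem * 8)-row matrices with rows grouped as
# (element-1)*8 + gauss point.

# local corner signs of the trilinear hex (VTK node ordering)
hex_signs <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                      -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                    8, 3, byrow = TRUE)

# faces of the hex: local node quadruples ordered so the right-hand rule
# gives the outward reference normal
hex_faces <- list(xm = c(1L, 5L, 8L, 4L), xp = c(2L, 3L, 7L, 6L),
                  ym = c(1L, 2L, 6L, 5L), yp = c(4L, 8L, 7L, 3L),
                  zm = c(1L, 4L, 3L, 2L), zp = c(5L, 6L, 7L, 8L))

hex_shape <- function(xi) {
  # xi: 3-vector; returns list(N = 8-vector, dN = 8 x 3)
  s <- hex_signs
  N <- (1 + xi[1] * s[, 1]) * (1 + xi[2] * s[, 2]) * (1 + xi[3] * s[, 3]) / 8
  dN <- cbind(s[, 1] * (1 + xi[2] * s[, 2]) * (1 + xi[3] * s[, 3]),
              s[, 2] * (1 + xi[1] * s[, 1]) * (1 + xi[3] * s[, 3]),
              s[, 3] * (1 + xi[1] * s[, 1]) * (1 + xi[2] * s[, 2])) / 8
  list(N = N, dN = dN)
}

gauss_pts_hex <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
}

quad_shape <- function(xi, eta) {
  s1 <- c(-1, 1, 1, -1); s2 <- c(-1, -1, 1, 1)
  N <- (1 + xi * s1) * (1 + eta * s2) / 4
  dN <- cbind(s1 * (1 + eta * s2), s2 * (1 + xi * s1)) / 4
  list(N = N, dN = dN)
}

#' Construct a Lagrangian hexahedral mesh
#'
#' Builds the reference-configuration quadrature data used by all solvers:
#' shape-function gradients `dN/dX` and integration weights at the 2x2x2
#' Gauss points of every trilinear hexahedron, a node scatter operator for
#' assembly, lumped nodal volumes, and per-tag boundary facet quadrature.
#'
#' @param nodes `n x 3` matrix of reference coordinates (m).
#' @param elems `E x 8` integer matrix of hex connectivity, VTK node order.
#' @param facets named list of boundary facet sets; each entry is an
#'   `Ef x 4` integer matrix of facet corner nodes ordered so the
#'   right-hand rule gives the outward reference normal.
#' @return an object of class `"lagrangian_mesh"`.
#' @export
lagrangian_mesh <- function(nodes, elems, facets = list()) {
  stopifnot(is.matrix(nodes), ncol(nodes) == 3L,
            is.matrix(elems), ncol(elems) == 8L)
  storage.mode(elems) <- "integer"
  n <- nrow(nodes); E <- nrow(elems); nq <- 8L * E
  gp <- gauss_pts_hex()
  Nmat <- matrix(0, 8, 8)        # (local node, gauss point)
  dNxi <- array(0, c(8, 3, 8))   # (local node, xi-dir, gauss point)
  for (k in 1:8) {
    sh <- hex_shape(gp[k, ])
    Nmat[, k] <- sh$N
    dNxi[, , k] <- sh$dN
  }
  dNdX <- array(0, c(E, 8, 3, 8))  # (elem, local node, X-dir, gauss point)
  wq <- matrix(0, E, 8)            # reference weights (m^3)
  qual <- rep(Inf, E)              # min scaled Jacobian
  Xq <- matrix(0, nq, 3)           # quadrature point reference coordinates
  Xn <- array(0, c(E, 8, 3))
  for (a in 1:8) Xn[, a, ] <- nodes[elems[, a], ]
  for (k in 1:8) {
    # Jref[i, j] = dX_i / dxi_j, per element
    Jref <- matrix(0, E, 9)
    for (i in 1:3) for (j in 1:3) {
      acc <- 0
      for (a in 1:8) acc <- acc + Xn[, a, i] * dNxi[a, j, k]
      Jref[, i + 3L * (j - 1L)] <- acc
    }
    dJ <- t3_det(Jref)
    if (any(dJ <= 0)) {
      stop(sprintf("non-positive reference Jacobian in %d element(s)",
                   sum(dJ <= 0)))
    }
    cn <- sqrt(Jref[, 1]^2 + Jref[, 2]^2 + Jref[, 3]^2) *
      sqrt(Jref[, 4]^2 + Jref[, 5]^2 + Jref[, 6]^2) *
      sqrt(Jref[, 7]^2 + Jref[, 8]^2 + Jref[, 9]^2)
    qual <- pmin(qual, dJ / cn)
    Jinv <- t3_inv(Jref)
    for (a in 1:8) {
      # dN_a/dX_j = sum_l dN_a/dxi_l * dxi_l/dX_j  (Jinv[l, j] row-major lj)
      for (j in 1:3) {
        dNdX[, a, j, k] <- dNxi[a, 1, k] * Jinv[, 1L + 3L * (j - 1L)] +
          dNxi[a, 2, k] * Jinv[, 2L + 3L * (j - 1L)] +
          dNxi[a, 3, k] * Jinv[, 3L + 3L * (j - 1L)]
      }
    }
    wq[, k] <- dJ
    rows <- seq.int(k, nq, by = 8L)
    acc <- matrix(0, E, 3)
    for (a in 1:8) acc <- acc + Nmat[a, k] * Xn[, a, ]
    Xq[rows, ] <- acc
  }
  # scatter operator: node x (a-major element slots), for assembly by
  # sparse multiply (handles shared nodes exactly); slot (a-1)*E + e
  scatter <- Matrix::sparseMatrix(i = as.vector(elems), j = seq_len(8L * E),
                                  x = 1, dims = c(n, 8L * E))
  # lumped nodal volumes: sum_k N_a(k) w_e(k), scattered to nodes
  lump_slots <- sapply(1:8, function(a) as.vector(wq %*% Nmat[a, ]))
  lumped <- as.vector(scatter %*% as.vector(lump_slots))
  facq <- lapply(facets, function(fn) facet_quadrature(nodes, fn))
  structure(list(nodes = nodes, elems = elems, facets = facets,
                 n_nodes = n, n_elems = E, nq = nq,
                 N = Nmat, dNdX = dNdX, wq = wq, Xq = Xq,
                 scatter = scatter, lumped_volume = lumped,
                 facet_quad = facq, quality = qual),
            class = "lagrangian_mesh")
}

# 2x2 Gauss data on tagged facets: reference outward area vectors and shape
# values, for dead surface loads and surface integrals
facet_quadrature <- function(nodes, fnodes) {
  g <- 1 / sqrt(3)
  gp2 <- as.matrix(expand.grid(c(-g, g), c(-g, g)))
  Ef <- nrow(fnodes)
  Nf <- matrix(0, 4, 4); dNf <- array(0, c(4, 2, 4))
  for (k in 1:4) {
    sh <- quad_shape(gp2[k, 1], gp2[k, 2])
    Nf[, k] <- sh$N
    dNf[, , k] <- sh$dN
  }
  X <- array(0, c(Ef, 4, 3))
  for (a in 1:4) X[, a, ] <- nodes[fnodes[, a], ]
  narea <- array(0, c(Ef, 3, 4))  # outward normal * area weight per gp
  for (k in 1:4) {
    g1 <- matrix(0, Ef, 3); g2 <- matrix(0, Ef, 3)
    for (a in 1:4) {
      g1 <- g1 + dNf[a, 1, k] * X[, a, ]
      g2 <- g2 + dNf[a, 2, k] * X[, a, ]
    }
    narea[, , k] <- cbind(g1[, 2] * g2[, 3] - g1[, 3] * g2[, 2],
                          g1[, 3] * g2[, 1] - g1[, 1] * g2[, 3],
                          g1[, 1] * g2[, 2] - g1[, 2] * g2[, 1])
  }
  list(nodes = fnodes, N = Nf, dN = dNf, narea = narea)
}

#' @export
#' @method print lagrangian_mesh
print.lagrangian_mesh <- function(x, ...) {
  cat(sprintf("Lagrangian hex mesh: %d nodes, %d elements, tags: %s\n",
              x$n_nodes, x$n_elems,
              paste(names(x$facets), collapse = ", ")))
  cat(sprintf("  min scaled Jacobian: %.3f\n", min(x$quality)))
  invisible(x)
}

#' Deformation kinematics at quadrature points
#'
#' Computes the deformation gradient `F = d(chi)/dX` and its determinant
#' `J` at every Gauss point from current nodal positions, exactly for
#' affine maps.  If previous positions are supplied, also the backward
#' differences `dJ/dt` (per quadrature point) and the nodal skeleton
#' velocity.
#'
#' @param mesh a [lagrangian_mesh()].
#' @param chi `n x 3` current nodal positions (m).
#' @param chi_prev previous nodal positions, or `NULL`.
#' @param dt time step (s), required with `chi_prev`.
#' @return an object of class `"kinematics"`: list with `F` (`nq x 9`),
#'   `J` (`nq`), `dJdt` (`nq`), `vs` (`n x 3`), `chi`.
#' @export
compute_kinematics <- function(mesh, chi, chi_prev = NULL, dt = NULL) {
  F <- qp_def_grad(mesh, chi)
  J <- t3_det(F)
  if (any(J <= 0)) {
    bad <- unique((which(J <= 0) - 1L) %/% 8L + 1L)
    stop(sprintf("element inversion (J <= 0) in element(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  dJdt <- rep(0, mesh$nq)
  vs <- matrix(0, mesh$n_nodes, 3)
  if (!is.null(chi_prev)) {
    stopifnot(!is.null(dt), dt > 0)
    Jp <- t3_det(qp_def_grad(mesh, chi_prev))
    dJdt <- (J - Jp) / dt
    vs <- (chi - chi_prev) / dt
  }
  structure(list(chi = chi, F = F, J = J, dJdt = dJdt, vs = vs),
            class = "kinematics")
}

# deformation gradient stack (nq x 9) for nodal positions chi
qp_def_grad <- function(mesh, chi) {
  qp_def_grad_cpp(mesh$elems, mesh$dNdX, chi)
}

# interpolate a nodal scalar/vector field to quadrature points
qp_interp <- function(mesh, u) {
  out <- qp_interp_cpp(mesh$elems, mesh$N, as.matrix(u))
  if (ncol(out) == 1L) out <- as.vector(out)
  out
}

# lumped L2 projection of a quadrature-point field to nodes
qp_to_nodes <- function(mesh, v) {
  num <- qp_to_nodes_cpp(mesh$elems, mesh$N, mesh$wq, as.matrix(v),
                         mesh$n_nodes)
  out <- num / mesh$lumped_volume
  if (ncol(out) == 1L) out <- as.vector(out)
  out
}

# reference gradient of a nodal scalar field at quadrature points (nq x 3)
qp_grad <- function(mesh, u) {
  qp_grad_cpp(mesh$elems, mesh$dNdX, as.numeric(u))
}

#' Weak-form internal (elastic) nodal force
#'
#' Assembles the load vector of the structural weak form: for every
#' first-order test function `V`, `<F_e, V> = -integral P : grad_X V dX`,
#' with the same 2x2x2 quadrature as the kinematics.  For a constant stress
#' over a closed mesh the result sums to zero (discrete divergence
#' theorem).
#'
#' @param P first Piola-Kirchhoff stress per quadrature point (`nq x 9`).
#' @param mesh a [lagrangian_mesh()].
#' @return `n x 3` matrix of nodal forces (N).
#' @export
internal_force <- function(P, mesh) {
  stopifnot(nrow(P) == mesh$nq)
  internal_force_cpp(mesh$elems, mesh$dNdX, mesh$wq, P, mesh$n_nodes)
}

# assemble nodal load vector of a per-qp scalar source: b_a = int coef N_a dX
qp_load_vector <- function(mesh, coef) {
  as.vector(qp_load_cpp(mesh$elems, mesh$N, mesh$wq, as.numeric(coef),
                        mesh$n_nodes))
}

# element-volume-weighted mean of a quadrature-point scalar, expanded back
# to quadrature points (for the mean-dilatation volumetric treatment)
qp_element_mean <- function(mesh, v) {
  vm <- matrix(v, mesh$n_elems, 8L, byrow = TRUE)
  mean_e <- rowSums(vm * mesh$wq) / rowSums(mesh$wq)
  rep(mean_e, each = 8L)
}
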