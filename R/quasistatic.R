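# Quasi-static nonlinear solid mechanics for the skeleton: structural
# boundary conditions, surface pressure loads (dead or follower), Newton
# iteration on the weak-form residual with a consistent tangent obtained by
# central finite differences of the total first Piola-Kirchhoff stress, and
# the staggered driver interleaving mechanics increments with split-step
# Darcy updates.  Inertia is neglected (the benchmark loading rates are far
# below the elastic wave time scales); the immersed-boundary mode retains
# the dynamic momentum balance.

#' Structural boundary conditions and loads
#'
#' @param constraints list of constraint specs:
#'   `list(type = "plane_normal", tag =, axis =)` fixes the `axis`
#'   displacement component of every node on the tagged facets;
#'   `list(type = "fixed_point", point =)` fixes all components of the node
#'   nearest `point`;
#'   `list(type = "basal_cylindrical", tag =)` fixes the circumferential
#'   and axial components at the tagged nodes, leaving radial motion free
#'   (the basal-plane constraint of the ventricle model).
#' @param loads list of pressure-load specs
#'   `list(tag =, ramp =, follower = FALSE)`: a normal pressure of
#'   magnitude `ramp(t)` (Pa) applied on the tagged facets against the
#'   outward normal -- on the reference normals for dead loads, on the
#'   deformed normals for follower loads.
#' @return an object of class `"structural_bc"`.
#' @export
structural_bc <- function(constraints = list(), loads = list()) {
  structure(list(constraints = constraints, loads = loads),
            class = "structural_bc")
}

# reduced-basis operator for the displacement constraints: columns of T
# span the admissible nodal motions (identity columns for free dofs, a
# radial column for basal-cylindrical nodes)
constraint_basis <- function(mesh, sbc) {
  n <- mesh$n_nodes
  fixed_comp <- matrix(FALSE, n, 3)
  radial <- integer(0)
  for (cs in sbc$constraints) {
    if (cs$type == "plane_normal") {
      fn <- mesh$facets[[cs$tag]]
      if (is.null(fn)) stop("unknown facet tag '", cs$tag, "'")
      fixed_comp[unique(as.vector(fn)), cs$axis] <- TRUE
    } else if (cs$type == "fixed_point") {
      d2 <- rowSums((mesh$nodes - matrix(cs$point, n, 3, byrow = TRUE))^2)
      fixed_comp[which.min(d2), ] <- TRUE
    } else if (cs$type == "basal_cylindrical") {
      fn <- mesh$facets[[cs$tag]]
      if (is.null(fn)) stop("unknown facet tag '", cs$tag, "'")
      radial <- union(radial, unique(as.vector(fn)))
    } else stop("unknown constraint type '", cs$type, "'")
  }
  if (length(radial) > 0 && any(fixed_comp[radial, ])) {
    warning("nodes shared between basal and component constraints; ",
            "component constraint takes precedence")
    radial <- radial[rowSums(fixed_comp[radial, , drop = FALSE]) == 0]
  }
  # plain free dofs: one identity column each
  free_dofs <- which(t(!fixed_comp))  # dof order 3*(node-1)+comp
  dof_node <- (free_dofs - 1L) %/% 3L + 1L
  keep <- !(dof_node %in% radial)
  free_dofs <- free_dofs[keep]
  ncols <- length(free_dofs) + length(radial)
  ti <- free_dofs
  tj <- seq_along(free_dofs)
  tx <- rep(1, length(free_dofs))
  col <- length(free_dofs)
  for (nd in radial) {
    x <- mesh$nodes[nd, 1]; y <- mesh$nodes[nd, 2]
    r <- sqrt(x^2 + y^2)
    er <- if (r > 1e-12) c(x, y, 0) / r else c(1, 0, 0)
    col <- col + 1L
    ti <- c(ti, 3L * (nd - 1L) + 1:3)
    tj <- c(tj, rep(col, 3))
    tx <- c(tx, er)
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(3L * n, ncols))
}

# nodal load vector of the pressure loads at time t (N); follower normals
# are evaluated at chi_load (which may lag chi during Newton passes)
external_force <- function(mesh, chi, sbc, t, chi_load = chi) {
  f <- matrix(0, mesh$n_nodes, 3)
  for (ld in sbc$loads) {
    val <- if (is.function(ld$ramp)) ld$ramp(t) else ld$ramp
    if (val == 0) next
    quads <- mesh$facets[[ld$tag]]
    if (is.null(quads)) stop("unknown facet tag '", ld$tag, "'")
    fq <- if (isTRUE(ld$follower)) facet_quadrature(chi_load, quads)
          else mesh$facet_quad[[ld$tag]]
    Ef <- nrow(quads)
    idx <- integer(0); con <- NULL
    for (k in 1:4) {
      na <- matrix(fq$narea[, , k], Ef, 3)
      for (a in 1:4) {
        idx <- c(idx, quads[, a])
        con <- rbind(con, -val * fq$N[a, k] * na)
      }
    }
    rs <- rowsum(con, idx)
    ids <- as.integer(rownames(rs))
    f[ids, ] <- f[ids, ] + rs
  }
  f
}

# consistent material tangent dP/dF per quadrature point by central finite
# differences of the total stress (includes bulk, pore and active terms)
tangent_fd <- function(F, pk1_fun, h = 1e-6) {
  nq <- nrow(F)
  A4 <- matrix(0, nq, 81)
  for (c in 1:9) {
    Fp <- F; Fp[, c] <- Fp[, c] + h
    Fm <- F; Fm[, c] <- Fm[, c] - h
    A4[, (c - 1L) * 9L + 1:9] <- (pk1_fun(Fp) - pk1_fun(Fm)) / (2 * h)
  }
  A4
}

#' Quasi-static Newton solve of one load increment
#'
#' Finds nodal positions `chi` with
#' `internal_force(P_total) + external_force = 0` in the constrained
#' subspace, by Newton iteration with a finite-difference consistent
#' tangent and backtracking line search.  Follower-pressure normals are
#' frozen during each Newton pass (so the inner iteration converges
#' quadratically) and updated in an outer fixed-point loop until the true
#' follower residual meets the tolerance.  The pore field (`m` at
#' quadrature points) is held frozen.
#'
#' @param mesh a [lagrangian_mesh()].
#' @param chi0 starting nodal positions.
#' @param m_qp added mass per quadrature point (kg m^-3).
#' @param law a skeleton law; `fibres` required for the HO law.
#' @param fibres a [fibre_triad()] (per element) or `NULL`.
#' @param params a [poro_params()].
#' @param sbc a [structural_bc()].
#' @param t time at which load ramps are evaluated (s).
#' @param Ta active tension (Pa).
#' @param poroelastic include `m` in the bulk term?
#' @param tol relative residual tolerance.
#' @param maxit Newton iteration cap per pass.
#' @return list with `chi`, iteration count `iters`, residual norms
#'   `res_history`, and `converged`.
#' @export
newton_solve <- function(mesh, chi0, m_qp, law, fibres, params, sbc, t,
                         Ta = 0, poroelastic = TRUE, tol = 1e-8,
                         maxit = 40L) {
  Tb <- constraint_basis(mesh, sbc)
  fib_qp <- if (!is.null(fibres)) triad_at_qps(fibres, mesh) else NULL
  mbar <- qp_element_mean(mesh, rep_len(m_qp, mesh$nq))
  if (!poroelastic) mbar <- 0 * mbar
  Kbulk <- if (!is.null(law$Ks)) law$Ks else law$Kbulk
  pfun <- function(F, Jbar = qp_element_mean(mesh, t3_det(F))) {
    pk1_total(F, m_qp, law, fibres = fib_qp, params = params, Ta = Ta,
              poroelastic = poroelastic, Jbar = Jbar, mbar = mbar)
  }
  has_follower <- any(vapply(sbc$loads,
                             function(l) isTRUE(l$follower), TRUE))
  chi <- chi0
  residual <- function(chi, chi_load) {
    F <- qp_def_grad(mesh, chi)
    J <- t3_det(F)
    if (any(J <= 0)) return(NULL)
    fext <- external_force(mesh, chi, sbc, t, chi_load = chi_load)
    list(F = F, r = internal_force(pfun(F), mesh) + fext, fext = fext)
  }
  project <- function(r) as.vector(Matrix::crossprod(Tb, as.vector(t(r))))
  st <- residual(chi, chi)
  if (is.null(st)) stop("element inversion in the initial state")
  rfree <- project(st$r)
  ref <- max(sqrt(sum(project(st$fext)^2)), sqrt(sum(rfree^2)), 1e-300)
  hist <- numeric(0)
  iters <- 0L
  converged <- FALSE
  for (pass in 1:15) {
    chi_load <- chi
    fac <- NULL
    fresh <- FALSE
    rn_prev <- Inf
    pass_done <- FALSE
    for (it in seq_len(maxit)) {
      rn <- sqrt(sum(rfree^2))
      hist <- c(hist, rn)
      if (rn <= tol * ref + 1e-14) { pass_done <- TRUE; break }
      # modified Newton: refresh the tangent factorization when absent or
      # when the residual is no longer contracting fast
      fresh <- FALSE
      if (is.null(fac) || rn > 0.2 * rn_prev) {
        fresh <- TRUE
        # frozen-coefficient tangent by finite differences plus the exact
        # rank-one element stiffness of the mean-dilatation bulk term
        J <- t3_det(st$F)
        Jbar <- qp_element_mean(mesh, J)
        A4 <- tangent_fd(st$F, function(F) pfun(F, Jbar = Jbar))
        tr <- hex_vector_stiffness_cpp(mesh$elems, mesh$dNdX, mesh$wq, A4)
        JFt <- J * t3_transpose(t3_inv(st$F))
        arg_e <- matrix(Jbar - mbar / params$rho, mesh$n_elems, 8,
                        byrow = TRUE)[, 1]
        Ve <- rowSums(mesh$wq)
        scale_e <- 2 * Kbulk * (1 - log(arg_e)) / arg_e^2 / Ve
        t1 <- hex_bulk_rank1_cpp(mesh$elems, mesh$dNdX, mesh$wq, JFt,
                                 scale_e)
        K <- Matrix::sparseMatrix(i = c(tr$i, t1$i), j = c(tr$j, t1$j),
                                  x = c(tr$x, t1$x),
                                  dims = c(3L * mesh$n_nodes,
                                           3L * mesh$n_nodes))
        Kr <- Matrix::crossprod(Tb, K %*% Tb)
        fac <- tryCatch(Matrix::lu(Kr), error = function(e) NULL)
        if (is.null(fac)) stop("singular tangent at increment time t = ", t)
      }
      rn_prev <- rn
      iters <- iters + 1L
      dq <- as.vector(Matrix::solve(fac, rfree))
      du <- as.vector(Tb %*% dq)
      # backtracking line search on the residual norm; a step is accepted
      # only if it reduces the residual
      alpha <- 1
      accepted <- FALSE
      for (ls in 1:10) {
        chi_try <- chi + matrix(du * alpha, ncol = 3, byrow = TRUE)
        st_try <- residual(chi_try, chi_load)
        if (!is.null(st_try)) {
          rfree_try <- project(st_try$r)
          if (sqrt(sum(rfree_try^2)) < rn) {
            chi <- chi_try; st <- st_try; rfree <- rfree_try
            accepted <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (!accepted) {
        if (!fresh) {
          # a stale tangent may point uphill: refresh and retry
          fac <- NULL
          next
        }
        stop("line search failed at t = ", t,
             " (residual ", format(rn), ")")
      }
    }
    if (!pass_done) break
    if (!has_follower) { converged <- TRUE; break }
    # true residual with follower normals at the converged configuration
    st <- residual(chi, chi)
    rfree <- project(st$r)
    if (sqrt(sum(rfree^2)) <= tol * ref + 1e-14) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf("Newton did not converge at t = %g: residuals %s", t,
                 paste(format(utils::tail(hist, 5), digits = 3),
                       collapse = " ")))
  }
  list(chi = chi, iters = iters, res_history = hist, converged = converged)
}

#' Staggered quasi-static poroelastic run
#'
#' Advances the coupled system over `n_increments` uniform increments of
#' the loading ramps: at each increment the mechanics is equilibrated by
#' [newton_solve()] with the pore field frozen, then the split-step Darcy
#' solver is advanced over the increment with the updated kinematics
#' (backward-difference `dJ/dt`).  With `poroelastic = FALSE` the Darcy
#' stage is skipped entirely (`m` stays 0): the pure hyperelastic
#' comparator.
#'
#' @param mesh a [lagrangian_mesh()].
#' @param law skeleton law; `fibres` per element for the HO law.
#' @param fibres a [fibre_triad()] or `NULL`.
#' @param params a [poro_params()].
#' @param sbc a [structural_bc()].
#' @param pbc a [pore_bc()].
#' @param src a [source_params()] or `NULL`.
#' @param duration total time (s).
#' @param n_increments number of uniform increments.
#' @param active an [active_params()] or `NULL`.
#' @param poroelastic logical; `FALSE` gives the hyperelastic comparator.
#' @param rigid logical; `TRUE` freezes the skeleton at the reference
#'   (Darcy-only verification mode).
#' @param darcy_substeps Darcy steps per mechanics increment.
#' @param on_step optional callback `function(k, t, chi, kin, field)` run
#'   after each increment (probes).
#' @return list with final `chi`, `kin`, `field`, and `steps` (times).
#' @export
quasi_static_solve <- function(mesh, law, fibres = NULL, params, sbc,
                               pbc = pore_bc(), src = NULL, duration,
                               n_increments, active = NULL,
                               poroelastic = TRUE, rigid = FALSE,
                               darcy_substeps = 1L, on_step = NULL) {
  chi <- mesh$nodes
  chi_prev <- chi
  field <- pore_field(mesh)
  dt <- duration / n_increments
  kin <- compute_kinematics(mesh, chi)
  for (k in seq_len(n_increments)) {
    t <- k * dt
    Ta <- if (is.null(active)) 0 else active$ramp(t)
    if (!rigid) {
      sol <- newton_solve(mesh, chi, field$m, law, fibres, params, sbc, t,
                          Ta = Ta, poroelastic = poroelastic)
      chi_prev <- chi
      chi <- sol$chi
      kin <- compute_kinematics(mesh, chi, chi_prev, dt)
    }
    if (poroelastic) {
      sdt <- dt / darcy_substeps
      for (s in seq_len(darcy_substeps)) {
        field <- step_darcy(field, kin, mesh, pbc, src, params, sdt,
                            t - dt + (s - 1) * sdt)
      }
    }
    if (!is.null(on_step)) {
      if (isTRUE(on_step(k, t, chi, kin, field))) break
    }
  }
  list(chi = chi, kin = kin, field = field, t_end = t,
       steps = seq_len(k) * dt)
}
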