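# End-to-end drivers reproducing the benchmark experiments: the swelling
# and drainage cubes, the fibre-reinforced swelling cube, and the perfused
# idealized left ventricle with its hyperelastic comparator.  Each driver
# returns a probe report (time series of pore pressure, added mass,
# Jacobian and derived quantities at the printed probe locations).

#' Benchmark parameter sets
#'
#' The pore-fluid constants of the three benchmark columns: common Biot
#' modulus 2.18e5 Pa, coupling parameter b = 1, density 1e3 kg m^-3,
#' penalty 0.01 Pa; porosity 0.1/0.1/0.15 and isotropic permeability
#' 1e-7 / 2.5e-6 / 2e-9 m^2 Pa^-1 s^-1 for the swelling test, drainage
#' test and ventricle model respectively.
#'
#' @param case `"swelling"`, `"drainage"` or `"ventricle"`.
#' @return a [poro_params()] object.
#' @export
benchmark_params <- function(case = c("swelling", "drainage", "ventricle")) {
  case <- match.arg(case)
  k <- switch(case, swelling = 1e-7, drainage = 2.5e-6, ventricle = 2e-9)
  phi0 <- switch(case, swelling = 0.1, drainage = 0.1, ventricle = 0.15)
  poro_params(Mb = 2.18e5, b = 1, kappa0 = 0.01, phi0 = phi0, rho = 1e3,
              K = k)
}

#' Skeleton bulk modulus of the benchmarks (Pa)
#' @export
benchmark_Ks <- function() 2.2e5

#' Printed boundary ramps
#'
#' The swelling-test inlet pressure `1e3 (1 - exp(-t^2/0.25))` Pa
#' (plateau 1 kPa) and the drainage-test external load
#' `1e4 (1 - exp(-t^2/0.04))` Pa (plateau 10 kPa).
#'
#' @param t time (s).
#' @return ramp value (Pa).
#' @export
swelling_inlet_ramp <- function(t) 1e3 * (1 - exp(-t^2 / 0.25))

#' @rdname swelling_inlet_ramp
#' @export
drainage_load_ramp <- function(t) 1e4 * (1 - exp(-t^2 / 0.04))

#' mmHg to Pa
#' @param x pressure in mmHg.
#' @export
mmHg <- function(x) 133.322 * x

new_probe_report <- function(df, meta = list()) {
  structure(list(series = df, meta = meta), class = "probe_report")
}

#' @export
#' @method print probe_report
print.probe_report <- function(x, ...) {
  cat("Probe report:", nrow(x$series), "samples of",
      paste(setdiff(names(x$series), "time"), collapse = ", "), "\n")
  invisible(x)
}

# volume-weighted average of a quadrature-point field
volume_average <- function(mesh, v) {
  w <- as.vector(t(mesh$wq))
  sum(v * w) / sum(w)
}

# mean of a nodal field over the unique nodes of a facet tag
surface_average <- function(mesh, tag, nodal) {
  nd <- unique(as.vector(mesh$facets[[tag]]))
  mean(nodal[nd])
}

# nearest-node probe index for a point given in unit-cube coordinates
cube_probe_nodes <- function(mesh, edge) {
  pts <- rbind(c(0, 0, 0), c(0.5, 0.5, 0.5), c(1, 1, 1)) * edge
  apply(pts, 1, function(p) {
    which.min(rowSums((mesh$nodes - matrix(p, mesh$n_nodes, 3,
                                           byrow = TRUE))^2))
  })
}

cube_constraints <- function() {
  list(list(type = "plane_normal", tag = "x0", axis = 1),
       list(type = "plane_normal", tag = "y0", axis = 2),
       list(type = "plane_normal", tag = "z0", axis = 3))
}

# shared scaffolding: run a cube scenario in lagrangian or ib mode and
# collect per-step probe rows via `sample_fun(t, chi, kin, field)`
run_cube_scenario <- function(mesh, law, fibres, params, sbc, pbc, src,
                              duration, mode, sample_fun, n_increments,
                              grid_N, dt_ib, mu, steady_tol, edge) {
  rows <- list()
  if (mode == "lagrangian" || mode == "rigid") {
    prev <- NULL
    on_step <- function(k, t, chi, kin, field) {
      row <- sample_fun(t, chi, kin, field)
      rows[[length(rows) + 1L]] <<- row
      cur <- unlist(row)
      done <- FALSE
      if (!is.null(prev)) {
        num <- max(abs(cur - prev))
        done <- num < steady_tol * max(abs(cur), 1e-12)
      }
      prev <<- cur
      done
    }
    quasi_static_solve(mesh, law, fibres, params, sbc, pbc, src,
                       duration = duration, n_increments = n_increments,
                       rigid = (mode == "rigid"), on_step = on_step)
  } else {
    pad <- 0.25 * edge
    grid <- eulerian_grid(rep(-pad, 3), rep(edge + pad, 3), grid_N)
    su <- ib_setup(mesh, law, fibres, params, sbc, pbc, src, grid,
                   mu = mu, dt = dt_ib)
    n_steps <- ceiling(duration / dt_ib)
    sample_every <- max(1L, floor(n_steps / 400))
    stt <- ib_state(su)
    for (k in seq_len(n_steps)) {
      stt <- coupled_step(stt, su)
      if (k %% sample_every == 0L || k == n_steps) {
        kin <- compute_kinematics(mesh, stt$chi, stt$chi_prev, dt_ib)
        rows[[length(rows) + 1L]] <- sample_fun(stt$t, stt$chi, kin,
                                                stt$field)
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Swelling-cube benchmark
#'
#' A 1 cm poroelastic cube with zero normal displacement on the planes
#' `x = 0`, `y = 0`, `z = 0`; the inlet pressure ramp
#' [swelling_inlet_ramp()] on the face `x = 0`, zero pore pressure on
#' `x = 1`, zero flux elsewhere; no source.  Probes at the cube corners
#' `(0,0,0)`, `(1,1,1)` and centre.
#'
#' @param n_solid solid-mesh elements per axis.
#' @param law skeleton law (defaults to the isotropic benchmark law with
#'   bulk modulus [benchmark_Ks()]).
#' @param params a [poro_params()]; Table-column defaults.
#' @param duration horizon (s); the run stops earlier at steady state
#'   (relative probe change below `steady_tol` per increment).
#' @param mode `"lagrangian"` (staggered quasi-static), `"ib"` (immersed
#'   coupled), or `"rigid"` (frozen skeleton; Darcy only).
#' @param n_increments increments in Lagrangian mode.
#' @param grid_N,dt_ib,mu Eulerian grid resolution, time step and
#'   bathing-fluid viscosity in IB mode.
#' @param steady_tol steady-state stopping tolerance (Lagrangian mode).
#' @param edge cube edge (m).
#' @return a `probe_report` with pore pressure, added mass and Jacobian at
#'   the three probes plus volume averages.
#' @export
run_swelling <- function(n_solid = 8, law = iso_skeleton_law(Ks = benchmark_Ks()),
                         params = benchmark_params("swelling"),
                         duration = 2.5, mode = c("lagrangian", "ib", "rigid"),
                         n_increments = 125, grid_N = 16, dt_ib = 1e-4,
                         mu = 4e-3, steady_tol = 1e-6, edge = 0.01) {
  mode <- match.arg(mode)
  mesh <- unit_cube_mesh(n_solid, edge)
  sbc <- structural_bc(constraints = cube_constraints())
  pbc <- pore_bc(list(x0 = swelling_inlet_ramp, x1 = 0))
  pn <- cube_probe_nodes(mesh, edge)
  sample_fun <- function(t, chi, kin, field) {
    mn <- qp_to_nodes(mesh, field$m)
    Jn <- qp_to_nodes(mesh, kin$J)
    list(time = t,
         p_corner0 = field$p[pn[1]], p_centre = field$p[pn[2]],
         p_corner1 = field$p[pn[3]],
         m_corner0 = mn[pn[1]], m_centre = mn[pn[2]], m_corner1 = mn[pn[3]],
         J_centre = Jn[pn[2]],
         p_mean = volume_average(mesh, qp_interp(mesh, field$p)),
         m_mean = volume_average(mesh, field$m),
         J_mean = volume_average(mesh, kin$J),
         max_disp = max(abs(chi - mesh$nodes)))
  }
  df <- run_cube_scenario(mesh, law, NULL, params, sbc, pbc, NULL, duration,
                          mode, sample_fun, n_increments, grid_N, dt_ib, mu,
                          steady_tol, edge)
  new_probe_report(df, list(scenario = "swelling", mode = mode,
                            n_solid = n_solid, edge = edge))
}

#' Drainage-cube benchmark
#'
#' The cube is compressed by the external load ramp [drainage_load_ramp()]
#' (plateau 10 kPa) on all six faces, with zero normal displacement on the
#' planes `x = 0`, `y = 0`, `z = 0` and the corner `(0,0,0)` fixed.  All
#' faces carry the no-flux pore condition; the pore fluid drains through a
#' distributed pressure sink `S = -beta (p - p_sink)` with
#' `beta = 1e-4 Pa^-1 s^-1`, `p_sink = 0`.
#'
#' @inheritParams run_swelling
#' @param src the sink [source_params()].
#' @return a `probe_report` with volume-averaged `m`, `p`, `J` histories.
#' @export
run_drainage <- function(n_solid = 6, law = iso_skeleton_law(Ks = benchmark_Ks()),
                         params = benchmark_params("drainage"),
                         src = source_params("sink", beta = 1e-4, p_sink = 0),
                         duration = 1.0, mode = c("lagrangian", "ib"),
                         n_increments = 50, grid_N = 16, dt_ib = 1e-4,
                         mu = 4e-3, steady_tol = 1e-6, edge = 0.01) {
  mode <- match.arg(mode)
  mesh <- unit_cube_mesh(n_solid, edge)
  sbc <- structural_bc(
    constraints = c(cube_constraints(),
                    list(list(type = "fixed_point", point = c(0, 0, 0)))),
    loads = lapply(c("x0", "x1", "y0", "y1", "z0", "z1"), function(tg)
      list(tag = tg, ramp = drainage_load_ramp, follower = FALSE)))
  pbc <- pore_bc()
  sample_fun <- function(t, chi, kin, field) {
    list(time = t,
         p_mean = volume_average(mesh, qp_interp(mesh, field$p)),
         m_mean = volume_average(mesh, field$m),
         J_mean = volume_average(mesh, kin$J),
         max_disp = max(abs(chi - mesh$nodes)))
  }
  df <- run_cube_scenario(mesh, law, NULL, params, sbc, pbc, src, duration,
                          mode, sample_fun, n_increments, grid_N, dt_ib, mu,
                          steady_tol, edge)
  new_probe_report(df, list(scenario = "drainage", mode = mode,
                            n_solid = n_solid, edge = edge))
}

#' Fibre-reinforced swelling cube
#'
#' The swelling benchmark with the Holzapfel-Ogden law and one of the
#' three printed constant fibre orientations.  Reports the maximum
#' displacement component along each axis (the cube swells preferentially
#' across the fibres).
#'
#' @inheritParams run_swelling
#' @param orientation fibre direction: `"x"`, `"y"` or `"z"`.
#' @param inlet_axis axis whose lower face carries the inlet pressure ramp
#'   (`"x"` default; the three orientation cases map exactly onto each
#'   other under the cyclic axis permutation when the inlet follows it).
#' @param law an [ho_skeleton_law()]; printed myocardial defaults.
#' @return a `probe_report` including `ux_max`, `uy_max`, `uz_max`.
#' @export
run_fibre_swelling <- function(orientation = c("x", "y", "z"), n_solid = 6,
                               law = ho_skeleton_law(Kbulk = benchmark_Ks()),
                               params = benchmark_params("swelling"),
                               duration = 2.5,
                               mode = c("lagrangian", "ib"),
                               n_increments = 125, grid_N = 16, dt_ib = 1e-4,
                               mu = 4e-3, steady_tol = 1e-6, edge = 0.01,
                               inlet_axis = "x") {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  mesh <- unit_cube_mesh(n_solid, edge)
  fibres <- cube_fibres(mesh, orientation)
  sbc <- structural_bc(constraints = cube_constraints())
  pbc_list <- stats::setNames(list(swelling_inlet_ramp, 0),
                              paste0(inlet_axis, c("0", "1")))
  pbc <- pore_bc(pbc_list)
  sample_fun <- function(t, chi, kin, field) {
    u <- chi - mesh$nodes
    list(time = t,
         ux_max = max(abs(u[, 1])), uy_max = max(abs(u[, 2])),
         uz_max = max(abs(u[, 3])),
         m_mean = volume_average(mesh, field$m),
         J_mean = volume_average(mesh, kin$J))
  }
  df <- run_cube_scenario(mesh, law, fibres, params, sbc, pbc, NULL,
                          duration, mode, sample_fun, n_increments, grid_N,
                          dt_ib, mu, steady_tol, edge)
  new_probe_report(df, list(scenario = "fibre_swelling", mode = mode,
                            orientation = orientation, n_solid = n_solid))
}

#' Perfused idealized left ventricle
#'
#' Diastolic filling (endocardial pressure ramped linearly to 8 mmHg over
#' `t_diastole`) followed optionally by systole (pressure rapidly raised
#' to 112 mmHg while the prescribed active tension ramps to its plateau
#' `Treq`).  The basal plane is constrained in the circumferential and
#' axial directions (radial expansion free); all pore boundaries are
#' no-flux and perfusion enters through the single-compartment source
#' with the ventricle Table values (`beta_a = 3e-5`, `beta_v = 3e-2`
#' Pa^-1 s^-1, `pa = 2.7` kPa, `pv = 1.3` kPa).  `poroelastic = FALSE`
#' gives the pure hyperelastic comparator (zero-porosity limit).
#'
#' @param geometry an [lv_geometry_params()].
#' @param law an [ho_skeleton_law()].
#' @param params a [poro_params()] (ventricle column defaults).
#' @param src compartment [source_params()].
#' @param poroelastic logical.
#' @param duration end time (s): 0.5 runs diastole only, 1.1 the full
#'   beat.
#' @param dt increment (s).
#' @param p_ed,p_es end-diastolic and end-systolic cavity pressures (Pa).
#' @param t_diastole diastolic filling duration (s).
#' @param t_sys_rise systolic pressure/tension rise time (s).
#' @param active an [active_params()].
#' @return a `probe_report` with cavity volume, volume-averaged and
#'   endo/epi surface-averaged added mass and pore pressure.
#' @export
run_lv <- function(geometry = lv_geometry_params(),
                   law = ho_skeleton_law(Kbulk = benchmark_Ks()),
                   params = benchmark_params("ventricle"),
                   src = source_params("compartment"),
                   poroelastic = TRUE, duration = 0.5, dt = 0.025,
                   p_ed = mmHg(8), p_es = mmHg(112), t_diastole = 0.5,
                   t_sys_rise = 0.15,
                   active = active_params(Treq = 124e3, t_on = 0.5,
                                          t_rise = 0.15)) {
  lv <- ellipsoid_lv(geometry)
  mesh <- lv$mesh
  pressure_ramp <- function(t) {
    ifelse(t <= t_diastole, p_ed * t / t_diastole,
           pmin(p_ed + (p_es - p_ed) * (t - t_diastole) / t_sys_rise, p_es))
  }
  sbc <- structural_bc(
    constraints = list(list(type = "basal_cylindrical", tag = "base")),
    loads = list(list(tag = "endo", ramp = pressure_ramp, follower = TRUE)))
  rows <- list()
  on_step <- function(k, t, chi, kin, field) {
    mn <- qp_to_nodes(mesh, field$m)
    pq <- qp_interp(mesh, field$p)
    rows[[length(rows) + 1L]] <<- list(
      time = t,
      cavity_volume = cavity_volume(mesh, chi),
      m_mean = volume_average(mesh, field$m),
      m_endo = surface_average(mesh, "endo", mn),
      m_epi = surface_average(mesh, "epi", mn),
      p_mean = volume_average(mesh, pq),
      p_endo = surface_average(mesh, "endo", field$p),
      p_epi = surface_average(mesh, "epi", field$p),
      J_mean = volume_average(mesh, kin$J))
    FALSE
  }
  sol <- quasi_static_solve(mesh, law, lv$fibres, params, sbc, pore_bc(),
                            src = if (poroelastic) src else NULL,
                            duration = duration,
                            n_increments = round(duration / dt),
                            active = if (duration > t_diastole) active
                                     else NULL,
                            poroelastic = poroelastic, on_step = on_step)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  new_probe_report(df, list(scenario = "lv", poroelastic = poroelastic,
                            geometry = geometry, chi = sol$chi,
                            mesh = mesh))
}
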