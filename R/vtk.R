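# Minimal legacy-ASCII VTK writers for inspecting simulation states:
# structured points for Eulerian cell fields, unstructured hexahedral grids
# for the Lagrangian skeleton.

#' Write Eulerian cell fields as legacy VTK structured points
#'
#' @param grid an [eulerian_grid()].
#' @param fields named list of cell arrays (dimensions `grid$dims$p`).
#' @param path output `.vtk` file.
#' @export
write_vtk_grid <- function(grid, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- grid$N
  writeLines(c("# vtk DataFile Version 3.0", "poroifem eulerian fields",
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", N[1], N[2], N[3]),
               sprintf("ORIGIN %g %g %g", grid$origins$p[1],
                       grid$origins$p[2], grid$origins$p[3]),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("CELL_DATA 0"),
               sprintf("POINT_DATA %d", prod(N))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.vector(fields[[nm]]), digits = 9), con)
  }
  invisible(path)
}

#' Write the skeleton mesh and nodal fields as legacy VTK unstructured grid
#'
#' @param mesh a [lagrangian_mesh()].
#' @param chi current nodal positions (defaults to reference).
#' @param fields named list of nodal scalar vectors.
#' @param path output `.vtk` file.
#' @export
write_vtk_mesh <- function(mesh, chi = mesh$nodes, fields = list(), path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- mesh$n_nodes; E <- mesh$n_elems
  writeLines(c("# vtk DataFile Version 3.0", "poroifem skeleton", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(chi, digits = 9), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", E, 9L * E), con)
  writeLines(apply(cbind(8L, mesh$elems - 1L), 1, paste, collapse = " "),
             con)
  writeLines(sprintf("CELL_TYPES %d", E), con)
  writeLines(rep("12", E), con)
  if (length(fields) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(fields[[nm]], digits = 9), con)
    }
  }
  invisible(path)
}
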