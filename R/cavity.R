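# Cavity volume by the divergence theorem: (1/3) closed-surface integral of
# x . n dA over the deformed endocardial surface, closed by flat caps over
# its boundary rings (basal opening and, if present, the small apical
# opening).

#' Ventricular cavity volume
#'
#' Integrates `(1/3) x . n dA` over the deformed endocardial facets
#' (oriented out of the cavity) plus centroid-fan caps over each boundary
#' ring of the endocardial surface.  Exact for affine deformations of the
#' mesh; the basal ring is assumed (and, under the basal constraint, kept)
#' planar so its cap is flat.
#'
#' @param mesh a [lagrangian_mesh()] with an endocardial facet tag.
#' @param chi `n x 3` current nodal positions; defaults to the reference.
#' @param endo_tag facet tag of the endocardial surface.
#' @return cavity volume (m^3), positive.
#' @export
cavity_volume <- function(mesh, chi = mesh$nodes, endo_tag = "endo") {
  quads <- mesh$facets[[endo_tag]]
  if (is.null(quads)) stop("no facet tag '", endo_tag, "' in mesh")
  fq <- facet_quadrature(chi, quads)
  vol <- 0
  for (k in 1:4) {
    xg <- matrix(0, nrow(quads), 3)
    for (a in 1:4) xg <- xg + fq$N[a, k] * chi[quads[, a], ]
    # facet normals are solid-outward (into the cavity): flip for
    # cavity-outward orientation
    vol <- vol - sum(xg * fq$narea[, , k]) / 3
  }
  # boundary rings of the flipped surface; cap each with a centroid fan
  edges <- rbind(quads[, c(2, 1)], quads[, c(3, 2)],
                 quads[, c(4, 3)], quads[, c(1, 4)])  # flipped orientation
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  bnd <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  if (nrow(bnd) > 0) {
    succ <- integer(max(bnd))
    succ[bnd[, 1]] <- bnd[, 2]
    seen <- rep(FALSE, max(bnd))
    for (r in seq_len(nrow(bnd))) {
      start <- bnd[r, 1]
      if (seen[start]) next
      ring <- start
      nxt <- succ[start]
      while (nxt != start) {
        ring <- c(ring, nxt)
        nxt <- succ[nxt]
      }
      seen[ring] <- TRUE
      ctr <- colMeans(chi[ring, , drop = FALSE])
      # cap triangles traverse each boundary edge opposite to the surface:
      # triangle (centroid, b, a) for surface edge a -> b, contributing the
      # signed origin-tet volume (1/6) ctr . (b x a)
      aa <- chi[ring, , drop = FALSE]
      bb <- chi[succ[ring], , drop = FALSE]
      cr <- cbind(bb[, 2] * aa[, 3] - bb[, 3] * aa[, 2],
                  bb[, 3] * aa[, 1] - bb[, 1] * aa[, 3],
                  bb[, 1] * aa[, 2] - bb[, 2] * aa[, 1])
      vol <- vol + sum(cr[, 1] * ctr[1] + cr[, 2] * ctr[2] +
                       cr[, 3] * ctr[3]) / 6
    }
  }
  abs(vol)
}
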