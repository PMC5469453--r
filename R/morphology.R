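# Morphological indicators of the aneurysm sac: volume, non-sphericity
# index and aspect ratio, computed from the labeled wall surface and the
# delineated neck.

# Faces forming the closed sac solid: dome (sac) plus the neck cap.
sac_closed_faces <- function(mesh) {
  sel <- mesh$face_region %in% c("sac", "neck")
  if (!any(mesh$face_region == "sac")) stop("region 'sac' is empty")
  sel
}

# Boundary edges (edges used by exactly one face) of a face subset.
subset_boundary_edges <- function(mesh, faces) {
  tr <- mesh$triangles[faces, , drop = FALSE]
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Aneurysm sac volume
#'
#' Volume of the solid bounded by the dome (sac faces) and the neck surface,
#' by the divergence theorem: the sum of signed tetrahedra spanned by each
#' face and the origin. The surface must be closed; orientation may be
#' inward or outward (the absolute value is returned), but must be
#' consistent.
#'
#' @param mesh a [labeled_surface_mesh()] whose sac and neck faces form a
#'   closed surface.
#' @return Volume in mm^3.
#' @export
sac_volume <- function(mesh) {
  stopifnot(inherits(mesh, "labeled_surface_mesh"))
  sel <- sac_closed_faces(mesh)
  be <- subset_boundary_edges(mesh, sel)
  if (nrow(be)) {
    stop(
      "sac+neck surface is not closed; ", nrow(be),
      " boundary edges, e.g. ",
      paste(apply(utils::head(be, 5L), 1L, paste, collapse = "-"),
        collapse = ", "
      )
    )
  }
  tr <- mesh$triangles[sel, , drop = FALSE]
  # consistent orientation: every shared edge traversed once in each direction
  de <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  fwd <- paste(de[, 1L], de[, 2L])
  if (anyDuplicated(fwd)) {
    stop("sac+neck surface is inconsistently oriented")
  }
  p1 <- mesh$vertices[tr[, 1L], , drop = FALSE]
  p2 <- mesh$vertices[tr[, 2L], , drop = FALSE]
  p3 <- mesh$vertices[tr[, 3L], , drop = FALSE]
  signed <- (p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
    p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
    p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])) / 6
  abs(sum(signed))
}

#' Non-sphericity index (NSI)
#'
#' `1 - (18 pi)^(1/3) * V^(2/3) / A`: zero for a hemispherical dome (whose
#' curved area satisfies A^3 = 18 pi V^2 exactly) and approaching 1 for
#' increasingly non-spherical shapes. The area is that of the dome faces
#' only, consistent with the neck being the surface separating dome from
#' parent vessels; the volume is that of the dome closed by the neck.
#'
#' @param volume sac volume Va, mm^3 (or a [labeled_surface_mesh()], from
#'   which both volume and dome area are computed).
#' @param area dome area Aa, mm^2; ignored when `volume` is a mesh.
#' @return NSI, dimensionless.
#' @export
nsi <- function(volume, area = NULL) {
  if (inherits(volume, "labeled_surface_mesh")) {
    mesh <- volume
    volume <- sac_volume(mesh)
    area <- region_area(mesh, "sac")
  }
  if (!is.numeric(volume) || !is.numeric(area) || volume <= 0 || area <= 0) {
    stop("volume and area must be positive")
  }
  1 - (18 * pi)^(1 / 3) * volume^(2 / 3) / area
}

# Least-squares plane through points: returns unit normal and centroid.
fit_plane <- function(pts) {
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  sv <- svd(x, nu = 0L, nv = 3L)
  if (sv$d[2L] <= 1e-12 * sv$d[1L]) {
    stop("neck boundary is degenerate (collinear points)")
  }
  list(normal = sv$v[, 3L], centroid = ctr)
}

#' Aneurysm aspect ratio (AR)
#'
#' Depth of the sac divided by the neck width. Depth is the maximum distance
#' from the sac vertices to the least-squares plane of the neck boundary
#' curve, taken on the dome side; neck width is, by default, the diameter of
#' the circle with the neck's area, `2 * sqrt(A_neck / pi)`
#' (`width = "equivalent"`), with the maximum chord of the neck boundary
#' curve as an alternative (`width = "max_chord"`).
#'
#' @param mesh a [labeled_surface_mesh()] with sac and neck regions.
#' @param width neck-width convention, `"equivalent"` or `"max_chord"`.
#' @return A list with `ar`, `depth` (mm) and `neck_width` (mm).
#' @export
aspect_ratio <- function(mesh, width = c("equivalent", "max_chord")) {
  width <- match.arg(width)
  stopifnot(inherits(mesh, "labeled_surface_mesh"))
  if (!any(mesh$face_region == "sac")) stop("region 'sac' is empty")
  vb <- neck_boundary_vertices(mesh)
  if (length(vb) < 3L) stop("neck boundary curve has fewer than 3 vertices")
  pts <- mesh$vertices[vb, , drop = FALSE]
  pl <- fit_plane(pts)

  sac_v <- unique(as.vector(mesh$triangles[mesh$face_region == "sac", ]))
  d <- as.numeric(sweep(
    mesh$vertices[sac_v, , drop = FALSE], 2L,
    pl$centroid
  ) %*% pl$normal)
  # orient toward the dome: the side holding most of the sac
  if (sum(d) < 0) d <- -d
  depth <- max(d)
  if (depth <= 0) stop("sac lies in the neck plane; degenerate geometry")

  neck_width <- if (width == "equivalent") {
    2 * sqrt(region_area(mesh, "neck") / pi)
  } else {
    max(stats::dist(pts))
  }
  list(ar = depth / neck_width, depth = depth, neck_width = neck_width)
}

#' All morphological indicators for one case
#'
#' @param mesh a [labeled_surface_mesh()] with sac and neck regions.
#' @return Named list: `volume_mm3`, `area_mm2` (dome), `nsi`, `ar`,
#'   `depth_mm`, `neck_width_mm`.
#' @export
morphology_indicators <- function(mesh) {
  va <- sac_volume(mesh)
  aa <- region_area(mesh, "sac")
  ar <- aspect_ratio(mesh)
  list(
    volume_mm3 = va, area_mm2 = aa, nsi = nsi(va, aa),
    ar = ar$ar, depth_mm = ar$depth, neck_width_mm = ar$neck_width
  )
}
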