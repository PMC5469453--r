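# Surface / volume mesh containers with region labels.
#
# Coordinates are in mm throughout; WSS in Pa; time in s. Unit conversion, if
# any, belongs at the I/O boundary.

REGION_LEVELS <- c("other", "sac", "neck", "parent", "near_vessel")
REGION_CODES <- stats::setNames(seq_along(REGION_LEVELS) - 1L, REGION_LEVELS)

#' Construct a labeled triangulated surface mesh
#'
#' The carrier for all surface-based indicator computations: a triangulated
#' vessel/aneurysm wall in which every face carries exactly one region label
#' (`sac` for the aneurysm dome, `neck` for the surface separating the dome
#' from the parent vessels, `parent`, `near_vessel` or `other`). Face areas
#' and unit outward normals are derived on construction.
#'
#' @param vertices numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param triangles integer matrix, `m x 3`, 1-based vertex indices per face.
#' @param face_region character vector of length `m` (or length 1, recycled)
#'   with values in `other`, `sac`, `neck`, `parent`, `near_vessel`.
#' @return An object of class `labeled_surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `face_region`, `face_area` (mm^2),
#'   `normals` (unit outward normals, one row per face).
#' @examples
#' v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' tr <- rbind(c(1, 2, 3), c(1, 3, 4))
#' m <- labeled_surface_mesh(v, tr, "sac")
#' sum(m$face_area) # 1 mm^2
#' @export
labeled_surface_mesh <- function(vertices, triangles, face_region = "other") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop("triangle vertex indices out of range")
  }
  m <- nrow(triangles)
  face_region <- rep_len(as.character(face_region), m)
  bad <- setdiff(unique(face_region), REGION_LEVELS)
  if (length(bad)) {
    stop("unknown region label(s): ", paste(bad, collapse = ", "))
  }

  geom <- triangle_geometry(vertices, triangles)
  degen <- which(geom$area <= 0 | !is.finite(geom$area))
  if (length(degen)) {
    stop(
      "degenerate (zero-area) faces at indices: ",
      paste(utils::head(degen, 20L), collapse = ", ")
    )
  }

  structure(
    list(
      vertices = vertices,
      triangles = triangles,
      face_region = face_region,
      face_area = geom$area,
      normals = geom$normal
    ),
    class = "labeled_surface_mesh"
  )
}

# Areas (via cross product) and unit normals for all faces at once.
triangle_geometry <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1L], , drop = FALSE]
  p2 <- vertices[triangles[, 2L], , drop = FALSE]
  p3 <- vertices[triangles[, 3L], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2, normal = cr / pmax(nrm, .Machine$double.xmin))
}

#' @export
print.labeled_surface_mesh <- function(x, ...) {
  cat(
    "labeled_surface_mesh:", nrow(x$vertices), "vertices,",
    nrow(x$triangles), "faces\n"
  )
  tab <- table(factor(x$face_region, levels = REGION_LEVELS))
  tab <- tab[tab > 0]
  for (r in names(tab)) {
    cat(
      sprintf(
        "  %-12s %5d faces, %.3f mm^2\n", r, tab[[r]],
        sum(x$face_area[x$face_region == r])
      )
    )
  }
  invisible(x)
}

#' Total area of a labeled region
#'
#' @param mesh a [labeled_surface_mesh()].
#' @param region region label, e.g. `"sac"`.
#' @return Area in mm^2.
#' @export
region_area <- function(mesh, region = "sac") {
  sel <- mesh$face_region %in% region
  if (!any(sel)) stop("region '", paste(region, collapse = "/"), "' is empty")
  sum(mesh$face_area[sel])
}

#' Construct a labeled tetrahedral volume mesh
#'
#' @param vertices numeric matrix, `n x 3`, mm.
#' @param tetrahedra integer matrix, `m x 4`, 1-based vertex indices.
#' @param cell_region character vector per cell with values in
#'   `other`, `aneurysm`, `near_vessel`.
#' @return An object of class `labeled_volume_mesh` with derived
#'   `cell_volume` (mm^3).
#' @export
labeled_volume_mesh <- function(vertices, tetrahedra, cell_region = "other") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  tetrahedra <- as.matrix(tetrahedra)
  storage.mode(tetrahedra) <- "integer"
  dimnames(vertices) <- dimnames(tetrahedra) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(tetrahedra) != 4L) stop("tetrahedra must be an m x 4 matrix")
  if (any(tetrahedra < 1L) || any(tetrahedra > nrow(vertices))) {
    stop("tetrahedron vertex indices out of range")
  }
  m <- nrow(tetrahedra)
  cell_region <- rep_len(as.character(cell_region), m)
  bad <- setdiff(unique(cell_region), c("other", "aneurysm", "near_vessel"))
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))

  vol <- tet_volumes(vertices, tetrahedra)
  degen <- which(vol <= 0 | !is.finite(vol))
  if (length(degen)) {
    stop(
      "degenerate (non-positive volume) cells at indices: ",
      paste(utils::head(degen, 20L), collapse = ", ")
    )
  }

  structure(
    list(
      vertices = vertices,
      tetrahedra = tetrahedra,
      cell_region = cell_region,
      cell_volume = vol
    ),
    class = "labeled_volume_mesh"
  )
}

# Unsigned tetrahedron volumes.
tet_volumes <- function(vertices, tetrahedra) {
  p1 <- vertices[tetrahedra[, 1L], , drop = FALSE]
  a <- vertices[tetrahedra[, 2L], , drop = FALSE] - p1
  b <- vertices[tetrahedra[, 3L], , drop = FALSE] - p1
  c_ <- vertices[tetrahedra[, 4L], , drop = FALSE] - p1
  det <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
    a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
    a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  abs(det) / 6
}

#' @export
print.labeled_volume_mesh <- function(x, ...) {
  cat(
    "labeled_volume_mesh:", nrow(x$vertices), "vertices,",
    nrow(x$tetrahedra), "cells,",
    sprintf("%.3f mm^3 total\n", sum(x$cell_volume))
  )
  invisible(x)
}

#' Total volume of a labeled cell region
#'
#' @param mesh a [labeled_volume_mesh()].
#' @param region `"aneurysm"`, `"near_vessel"` or `"other"`.
#' @return Volume in mm^3.
#' @export
region_volume <- function(mesh, region = "aneurysm") {
  sel <- mesh$cell_region %in% region
  if (!any(sel)) stop("region '", paste(region, collapse = "/"), "' is empty")
  sum(mesh$cell_volume[sel])
}

#' Time series of vector fields on a surface mesh
#'
#' Holds one cardiac cycle of a vector field (typically the wall shear stress
#' tau, in Pa) sampled on a uniform time grid spanning `[T0, T1]`. For a
#' periodic series the first and last samples represent the same cycle phase.
#'
#' @param times numeric vector, strictly increasing uniform grid, s.
#' @param values numeric array `n_loc x 3 x n_time` (vector per location per
#'   time).
#' @param location `"face"` or `"vertex"`.
#' @param periodic logical; whether the series spans exactly one period with
#'   `values[ , , 1] == values[ , , n_time]` in phase.
#' @return Object of class `surface_series`.
#' @export
surface_series <- function(times, values, location = c("face", "vertex"),
                           periodic = TRUE) {
  location <- match.arg(location)
  times <- as.numeric(times)
  if (length(times) < 3L) stop("need at least 3 time samples")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1L])) > 1e-12 * max(abs(times))) {
    stop("time grid must be uniform")
  }
  values <- as.array(values)
  if (length(dim(values)) != 3L || dim(values)[2L] != 3L ||
    dim(values)[3L] != length(times)) {
    stop("values must be an n_loc x 3 x n_time array")
  }
  structure(
    list(
      times = times, values = values, location = location,
      periodic = isTRUE(periodic)
    ),
    class = "surface_series"
  )
}

#' @export
print.surface_series <- function(x, ...) {
  cat(
    "surface_series:", dim(x$values)[1L], x$location, "locations,",
    length(x$times), "times in",
    sprintf("[%.4g, %.4g] s", x$times[1L], x$times[length(x$times)]),
    if (x$periodic) "(periodic)\n" else "\n"
  )
  invisible(x)
}

#' Time series of a velocity field on a volume mesh
#'
#' @param times uniform, strictly increasing time grid, s.
#' @param values numeric array `n_vertex x 3 x n_time`, velocity in m/s.
#' @param mesh the [labeled_volume_mesh()] the values live on.
#' @param periodic logical.
#' @return Object of class `volume_series`.
#' @export
volume_series <- function(times, values, mesh, periodic = TRUE) {
  stopifnot(inherits(mesh, "labeled_volume_mesh"))
  s <- surface_series(times, values, location = "vertex", periodic = periodic)
  if (dim(s$values)[1L] != nrow(mesh$vertices)) {
    stop("values must have one row per mesh vertex")
  }
  structure(
    list(
      times = s$times, values = s$values, mesh = mesh,
      periodic = s$periodic
    ),
    class = "volume_series"
  )
}

# Composite-trapezoid weights for averaging over [T0, T1]; weights sum to 1.
trapezoid_weights <- function(times) {
  n <- length(times)
  dt <- times[2L] - times[1L]
  w <- rep(dt, n)
  w[c(1L, n)] <- dt / 2
  w / (times[n] - times[1L])
}

#' Time-average a surface vector series
#'
#' Averages over the cycle `[T0, T1]` with the composite trapezoidal rule on
#' the uniform grid. Two modes reflect the two averages appearing in
#' oscillatory-shear-type indicators: `vector_then_norm` returns the magnitude
#' of the time-averaged vector (|mean tau|), `norm_then_average` the time
#' average of the magnitude (mean |tau|). By the triangle inequality the
#' former never exceeds the latter.
#'
#' @param series a [surface_series()].
#' @param mode `"vector_then_norm"` or `"norm_then_average"`.
#' @return Numeric vector, one scalar per location (same units as the field).
#' @export
time_average <- function(series,
                         mode = c("norm_then_average", "vector_then_norm")) {
  stopifnot(inherits(series, "surface_series") ||
    inherits(series, "volume_series"))
  mode <- match.arg(mode)
  w <- trapezoid_weights(series$times)
  v <- series$values
  comp <- function(k) matrix(v[, k, ], nrow = dim(v)[1L])
  if (mode == "vector_then_norm") {
    mx <- comp(1L) %*% w
    my <- comp(2L) %*% w
    mz <- comp(3L) %*% w
    as.numeric(sqrt(mx^2 + my^2 + mz^2))
  } else {
    mag <- sqrt(comp(1L)^2 + comp(2L)^2 + comp(3L)^2)
    as.numeric(mag %*% w)
  }
}

# Per-location, per-time magnitude matrix (n_loc x n_time).
series_magnitude <- function(series) {
  v <- series$values
  comp <- function(k) matrix(v[, k, ], nrow = dim(v)[1L])
  sqrt(comp(1L)^2 + comp(2L)^2 + comp(3L)^2)
}

# Average a vertex-centered scalar (length n_vertex) onto faces.
vertex_to_face <- function(field, mesh) {
  tr <- mesh$triangles
  (field[tr[, 1L]] + field[tr[, 2L]] + field[tr[, 3L]]) / 3
}

#' Integrate a per-face scalar field over a labeled region
#'
#' Midpoint (piecewise-constant per face) rule: the sum of `field * area` over
#' the faces of the region. Vertex-centered fields are first averaged onto
#' faces, which makes the rule exact for fields linear over each face.
#'
#' @param field numeric vector: one value per face, or one per vertex.
#' @param mesh a [labeled_surface_mesh()].
#' @param region region label (or vector of labels) to integrate over.
#' @return The integral, in field units times mm^2.
#' @export
surface_integral <- function(field, mesh, region = "sac") {
  stopifnot(inherits(mesh, "labeled_surface_mesh"))
  if (length(field) == nrow(mesh$vertices) &&
    nrow(mesh$vertices) != nrow(mesh$triangles)) {
    field <- vertex_to_face(field, mesh)
  }
  if (length(field) != nrow(mesh$triangles)) {
    stop("field length matches neither faces nor vertices")
  }
  sel <- mesh$face_region %in% region
  if (!any(sel)) stop("region '", paste(region, collapse = "/"), "' is empty")
  sum(field[sel] * mesh$face_area[sel])
}

# Undirected edge list of the surface mesh with Euclidean lengths.
mesh_edge_graph <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e <- unique(e)
  len <- sqrt(rowSums((mesh$vertices[e[, 1L], , drop = FALSE] -
    mesh$vertices[e[, 2L], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  igraph::E(g)$weight <- len
  g
}

# Vertices on the neck boundary curve: vertices incident to both a neck face
# and a non-neck face. Falls back to the sac/non-sac interface when the neck
# has no faces of its own.
neck_boundary_vertices <- function(mesh) {
  in_region <- function(region) {
    unique(as.vector(mesh$triangles[mesh$face_region == region, ]))
  }
  if (any(mesh$face_region == "neck")) {
    on_neck <- in_region("neck")
    off <- unique(as.vector(mesh$triangles[mesh$face_region != "neck", ]))
    vb <- intersect(on_neck, off)
    if (length(vb)) {
      return(vb)
    }
    return(on_neck)
  }
  if (!any(mesh$face_region == "sac")) stop("mesh has neither neck nor sac faces")
  intersect(
    in_region("sac"),
    unique(as.vector(mesh$triangles[mesh$face_region != "sac", ]))
  )
}

#' Label the near-vessel band by shortest-path distance from the neck
#'
#' Re-labels `parent`/`other` faces whose shortest-path (Dijkstra) distance
#' from the neck boundary is below `cutoff` as `near_vessel`. Distances are
#' measured on the surface edge graph with Euclidean edge lengths, from the
#' neck boundary vertices as sources; a face is inside the band when its
#' nearest vertex is. Wall components unreachable from the neck keep their
#' label and trigger a warning.
#'
#' @param mesh a [labeled_surface_mesh()] with a delineated neck (or at least
#'   a sac region whose boundary stands in for the neck curve).
#' @param cutoff geodesic distance in mm; the conventional near-vessel domain
#'   extends 10 mm (1 cm) from the neck.
#' @return The mesh with `face_region` updated.
#' @export
near_vessel_labels <- function(mesh, cutoff = 10) {
  stopifnot(inherits(mesh, "labeled_surface_mesh"), cutoff >= 0)
  relabel <- mesh$face_region %in% c("parent", "other")
  if (!any(relabel) || cutoff == 0) {
    return(mesh)
  }
  src <- neck_boundary_vertices(mesh)
  g <- mesh_edge_graph(mesh)
  d <- suppressWarnings(
    igraph::distances(g, v = src, mode = "all")
  )
  dmin <- apply(d, 2L, min)
  if (any(!is.finite(dmin))) {
    warning("wall component(s) unreachable from the neck; left as-is")
  }
  tr <- mesh$triangles
  fdist <- pmin(dmin[tr[, 1L]], pmin(dmin[tr[, 2L]], dmin[tr[, 3L]]))
  mesh$face_region[relabel & fdist < cutoff] <- "near_vessel"
  mesh
}
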