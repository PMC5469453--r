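# Idealized labeled geometries with closed-form areas and volumes: a
# spherical-cap sac seated on the end of a straight cylindrical vessel.
# These stand in for patient segmentations so that every downstream
# indicator has an analytic reference value.

#' Specification of an idealized aneurysm geometry
#'
#' A spherical-cap sac (radius `sac_radius`, neck opening of radius
#' `neck_radius`) seated on one end of a straight cylindrical parent vessel.
#' With `neck_radius == sac_radius` the sac is a hemisphere. The sac depth
#' above the neck plane is `sac_radius + sqrt(sac_radius^2 - neck_radius^2)`.
#'
#' @param vessel_radius parent vessel radius, mm.
#' @param vessel_length parent vessel length, mm.
#' @param sac_radius sac sphere radius, mm.
#' @param neck_radius neck opening radius, mm; at most `sac_radius` and at
#'   most `vessel_radius`.
#' @param edge_length target mesh edge length, mm.
#' @return Object of class `aneurysm_geometry_spec`.
#' @export
aneurysm_geometry_spec <- function(vessel_radius = 2, vessel_length = 20,
                                   sac_radius = 2, neck_radius = sac_radius,
                                   edge_length = 0.4) {
  stopifnot(
    vessel_radius > 0, vessel_length > 0, sac_radius > 0,
    edge_length > 0
  )
  if (neck_radius > sac_radius + 1e-12) {
    stop("neck radius cannot exceed sac radius")
  }
  if (neck_radius > vessel_radius + 1e-12) {
    stop("neck radius cannot exceed vessel radius (self-intersection)")
  }
  structure(
    list(
      vessel_radius = vessel_radius, vessel_length = vessel_length,
      sac_radius = sac_radius, neck_radius = neck_radius,
      edge_length = edge_length
    ),
    class = "aneurysm_geometry_spec"
  )
}

# Lat-long triangulation of the spherical cap z >= z_plane of a sphere of
# radius rs centered at (0, 0, zc), whose rim circle has radius rn. The
# center sits above the plane so the cap is the majority cap (an aneurysm
# dome deeper than its neck opening); rn = rs gives the hemisphere. Returns
# vertices and triangles; the rim ring comes first so callers can stitch.
spherical_cap_mesh <- function(rs, rn, z_plane, n_theta, n_phi) {
  zc <- z_plane + sqrt(max(rs^2 - rn^2, 0))
  phi_rim <- asin(pmax(pmin((z_plane - zc) / rs, 1), -1)) # rim latitude
  phi <- seq(phi_rim, pi / 2, length.out = n_phi + 1L)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  verts <- NULL
  ring_start <- integer(n_phi) # index of first vertex of each ring
  for (i in seq_len(n_phi)) { # rings up to (not incl.) the pole
    ring_start[i] <- if (i == 1L) 1L else ring_start[i - 1L] + n_theta
    r <- rs * cos(phi[i])
    verts <- rbind(verts, cbind(r * cos(theta), r * sin(theta), zc + rs * sin(phi[i])))
  }
  pole <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, zc + rs))
  tris <- NULL
  for (i in seq_len(n_phi - 1L)) {
    a <- ring_start[i] + (seq_len(n_theta) - 1L)
    a2 <- ring_start[i] + (seq_len(n_theta) %% n_theta)
    b <- ring_start[i + 1L] + (seq_len(n_theta) - 1L)
    b2 <- ring_start[i + 1L] + (seq_len(n_theta) %% n_theta)
    tris <- rbind(tris, cbind(a, a2, b2), cbind(a, b2, b))
  }
  top <- ring_start[n_phi] + (seq_len(n_theta) - 1L)
  top2 <- ring_start[n_phi] + (seq_len(n_theta) %% n_theta)
  tris <- rbind(tris, cbind(top, top2, pole))
  list(vertices = verts, triangles = tris, rim = seq_len(n_theta))
}

# Fan triangulation of a disc over an existing rim ring (vertex indices,
# counter-clockwise seen from +z). `up = TRUE` orients normals toward +z.
disc_fan <- function(rim_idx, center_idx, up = TRUE) {
  n <- length(rim_idx)
  nxt <- rim_idx[c(2:n, 1L)]
  if (up) cbind(rim_idx, nxt, center_idx) else cbind(nxt, rim_idx, center_idx)
}

#' Build an idealized labeled aneurysm geometry
#'
#' Constructs the surface and volume meshes of a spherical-cap sac seated on
#' the end of a straight cylindrical vessel. Surface faces are labeled
#' `sac` (the dome), `neck` (the disc closing the dome at the neck plane),
#' `parent` (the vessel wall and, when `neck_radius < vessel_radius`, the
#' annulus joining neck rim and vessel rim) and `other` (the far-end cap).
#' Volume cells are labeled `aneurysm` (inside the dome) and `near_vessel`
#' (vessel lumen). The construction is deterministic: the same spec always
#' yields identical meshes.
#'
#' @param spec an [aneurysm_geometry_spec()].
#' @return List with `surface` (a [labeled_surface_mesh()]) and `volume`
#'   (a [labeled_volume_mesh()]).
#' @export
build_idealized_aneurysm <- function(spec = aneurysm_geometry_spec()) {
  stopifnot(inherits(spec, "aneurysm_geometry_spec"))
  rv <- spec$vessel_radius
  rn <- spec$neck_radius
  rs <- spec$sac_radius
  len <- spec$vessel_length
  h <- spec$edge_length

  n_theta <- max(12L, ceiling(2 * pi * rv / h))
  n_z <- max(4L, ceiling(len / h))
  n_phi <- max(6L, ceiling((pi / 2) * rs / h))

  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  zs <- seq(0, len, length.out = n_z + 1L)

  ## vessel wall rings (radius rv), z = 0 .. len
  verts <- do.call(rbind, lapply(zs, function(z) {
    cbind(rv * cos(theta), rv * sin(theta), z)
  }))
  ring <- function(i) (i - 1L) * n_theta + seq_len(n_theta) # i = 1..n_z+1
  tris <- NULL
  regions <- character()
  for (i in seq_len(n_z)) {
    a <- ring(i)
    a2 <- ring(i)[c(2:n_theta, 1L)]
    b <- ring(i + 1L)
    b2 <- ring(i + 1L)[c(2:n_theta, 1L)]
    tris <- rbind(tris, cbind(a, a2, b2), cbind(a, b2, b))
    regions <- c(regions, rep("parent", 2L * n_theta))
  }

  ## bottom cap at z = 0
  bottom_center <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, 0))
  tris <- rbind(tris, disc_fan(ring(1L), bottom_center, up = FALSE))
  regions <- c(regions, rep("other", n_theta))

  ## neck rim ring at z = len (radius rn); annulus to the vessel rim if needed
  if (rn < rv - 1e-12) {
    neck_rim <- nrow(verts) + seq_len(n_theta)
    verts <- rbind(verts, cbind(rn * cos(theta), rn * sin(theta), len))
    a <- ring(n_z + 1L)
    a2 <- a[c(2:n_theta, 1L)]
    b <- neck_rim
    b2 <- neck_rim[c(2:n_theta, 1L)]
    tris <- rbind(tris, cbind(a, a2, b2), cbind(a, b2, b))
    regions <- c(regions, rep("parent", 2L * n_theta))
  } else {
    neck_rim <- ring(n_z + 1L)
  }

  ## neck disc (interior surface separating dome from vessel lumen);
  ## oriented -z = outward for the closed dome solid
  neck_center <- nrow(verts) + 1L
  verts <- rbind(verts, c(0, 0, len))
  tris <- rbind(tris, disc_fan(neck_rim, neck_center, up = FALSE))
  regions <- c(regions, rep("neck", n_theta))

  ## dome: spherical cap above the neck plane, stitched to the neck rim
  cap <- spherical_cap_mesh(rs, rn, len, n_theta, n_phi)
  # cap rim vertices coincide with the neck rim; remap them
  offset <- nrow(verts) - n_theta # cap vertex j -> global offset + j (j > rim)
  cap_map <- c(neck_rim, offset + (n_theta + 1L):nrow(cap$vertices))
  verts <- rbind(verts, cap$vertices[-(seq_len(n_theta)), , drop = FALSE])
  dome_tris <- matrix(cap_map[cap$triangles], ncol = 3L)
  tris <- rbind(tris, dome_tris)
  regions <- c(regions, rep("sac", nrow(dome_tris)))

  surface <- labeled_surface_mesh(verts, tris, regions)

  ## volume: dome fanned to the neck center; vessel lumen as layered prisms
  dome_tets <- cbind(dome_tris, neck_center)
  tet_regions <- rep("aneurysm", nrow(dome_tets))
  lumen <- tube_volume_mesh(rv, len, h, region = "near_vessel")
  nv_off <- nrow(verts)
  verts <- rbind(verts, lumen$vertices)
  tets <- rbind(dome_tets, lumen$tetrahedra + nv_off)
  tet_regions <- c(tet_regions, lumen$cell_region)
  volume <- labeled_volume_mesh(verts, tets, tet_regions)

  list(surface = surface, volume = volume, spec = spec)
}

#' Structured tetrahedral mesh of a circular tube
#'
#' A layered prism mesh of the cylinder `x^2 + y^2 <= r^2, 0 <= z <= length`,
#' each prism split into three tetrahedra. Useful for analytic volume-field
#' fixtures (Poiseuille dissipation, region-ratio tests).
#'
#' @param radius tube radius, mm.
#' @param length tube length, mm.
#' @param edge_length target edge length, mm.
#' @param region cell region label, or a function of the cell-centroid
#'   coordinates (n x 3 matrix) returning labels.
#' @return A [labeled_volume_mesh()].
#' @export
tube_volume_mesh <- function(radius, length, edge_length,
                             region = "near_vessel") {
  n_r <- max(2L, ceiling(radius / edge_length))
  n_theta <- max(8L, ceiling(2 * pi * radius / edge_length))
  n_z <- max(2L, ceiling(length / edge_length))

  ## disc: center + n_r rings of n_theta vertices
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  radii <- radius * seq_len(n_r) / n_r
  disc_pts <- rbind(
    c(0, 0),
    do.call(rbind, lapply(radii, function(r) cbind(r * cos(theta), r * sin(theta))))
  )
  ring <- function(i) 1L + (i - 1L) * n_theta + seq_len(n_theta)
  disc_tris <- disc_fan(ring(1L), 1L)[, c(3L, 1L, 2L)] # (center, a, a+1)
  for (i in seq_len(n_r - 1L)) {
    a <- ring(i)
    a2 <- a[c(2:n_theta, 1L)]
    b <- ring(i + 1L)
    b2 <- b[c(2:n_theta, 1L)]
    disc_tris <- rbind(disc_tris, cbind(a, a2, b2), cbind(a, b2, b))
  }

  np <- nrow(disc_pts)
  zs <- seq(0, length, length.out = n_z + 1L)
  verts <- do.call(rbind, lapply(zs, function(z) cbind(disc_pts, z)))

  tets <- NULL
  for (k in seq_len(n_z)) {
    lo <- (k - 1L) * np
    hi <- k * np
    a1 <- lo + disc_tris[, 1L]
    b1 <- lo + disc_tris[, 2L]
    c1 <- lo + disc_tris[, 3L]
    a2 <- hi + disc_tris[, 1L]
    b2 <- hi + disc_tris[, 2L]
    c2 <- hi + disc_tris[, 3L]
    tets <- rbind(
      tets,
      cbind(a1, b1, c1, a2), cbind(b1, c1, a2, b2), cbind(c1, a2, b2, c2)
    )
  }

  lab <- if (is.function(region)) {
    ctr <- (verts[tets[, 1L], , drop = FALSE] + verts[tets[, 2L], , drop = FALSE] +
      verts[tets[, 3L], , drop = FALSE] + verts[tets[, 4L], , drop = FALSE]) / 4
    region(ctr)
  } else {
    region
  }
  labeled_volume_mesh(verts, tets, lab)
}

#' Triangulated sphere by icosahedral subdivision
#'
#' Repeatedly subdivides an icosahedron and projects onto the sphere;
#' subdivision level `k` gives `20 * 4^k` faces. Used for convergence checks
#' of surface integrals against the closed-form sphere area.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions subdivision level (0 = icosahedron).
#' @param region face region label.
#' @return A [labeled_surface_mesh()].
#' @export
icosphere_mesh <- function(radius = 1, subdivisions = 3, region = "sac") {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  normalize <- function(m) m / sqrt(rowSums(m^2))
  v <- normalize(v)
  for (s in seq_len(subdivisions)) {
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    mids <- new.env()
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      if (!is.null(mids[[k]])) {
        return(mids[[k]])
      }
      nv <<- nv + 1L
      newv[[length(newv) + 1L]] <<- (v[i, ] + v[j, ]) / 2
      mids[[k]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]
      b <- f[i, 2L]
      c_ <- f[i, 3L]
      ab <- midpoint(a, b)
      bc <- midpoint(b, c_)
      ca <- midpoint(c_, a)
      newf[(4L * i - 3L):(4L * i), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca)
      )
    }
    v <- normalize(rbind(v, do.call(rbind, newv)))
    f <- newf
  }
  labeled_surface_mesh(v * radius, f, region)
}

#' Flat rectangular strip mesh
#'
#' A regular triangulation of the rectangle `[0, lx] x [0, ly]` in the z = 0
#' plane. Exact fixture for surface-gradient operators: linear fields have
#' constant gradients on it.
#'
#' @param lx,ly side lengths, mm.
#' @param nx,ny subdivisions per side.
#' @param region face region label.
#' @return A [labeled_surface_mesh()].
#' @export
strip_mesh <- function(lx = 10, ly = 2, nx = 20, ny = 4, region = "sac") {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  verts <- cbind(
    rep(xs, times = ny + 1L), rep(ys, each = nx + 1L), 0
  )
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- NULL
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      a <- idx(i, j)
      b <- idx(i + 1L, j)
      c_ <- idx(i + 1L, j + 1L)
      d <- idx(i, j + 1L)
      tris <- rbind(tris, c(a, b, c_), c(a, c_, d))
    }
  }
  labeled_surface_mesh(verts, tris, region)
}
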