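# Hemodynamic indicators computed from WSS and velocity time series on
# labeled meshes. Notation: tau = WSS vector (Pa) on the wall, Gamma_a = sac
# (dome) surface with area A_a, Omega_a / Omega_nv = aneurysm / near-vessel
# lumen volumes, overbar = time average over one cycle [T0, T1].

# Resolve a WSS series to face-centered per-time magnitudes and averages.
wss_checks <- function(wss, mesh) {
  stopifnot(
    inherits(wss, "surface_series"),
    inherits(mesh, "labeled_surface_mesh")
  )
  n_expected <- if (wss$location == "face") {
    nrow(mesh$triangles)
  } else {
    nrow(mesh$vertices)
  }
  if (dim(wss$values)[1L] != n_expected) {
    stop("WSS series size does not match the mesh (", wss$location, "-centered)")
  }
  if (!any(mesh$face_region == "sac")) stop("region 'sac' is empty")
  invisible(TRUE)
}

# Per-time |tau| on faces (n_face x n_time), resampling vertex input.
magnitude_on_faces <- function(wss, mesh) {
  mag <- series_magnitude(wss)
  if (wss$location == "vertex") {
    mag <- apply(mag, 2L, vertex_to_face, mesh = mesh)
    if (is.null(dim(mag))) mag <- matrix(mag, nrow = nrow(mesh$triangles))
  }
  mag
}

# Time-averaged |tau| per face (overbar of the magnitude).
tavg_magnitude_faces <- function(wss, mesh) {
  x <- time_average(wss, "norm_then_average")
  if (wss$location == "vertex") x <- vertex_to_face(x, mesh)
  x
}

# |time-averaged tau| per face (magnitude of the overbar vector).
tavg_vector_faces <- function(wss, mesh) {
  x <- time_average(wss, "vector_then_norm")
  if (wss$location == "vertex") {
    # average the mean *vector* onto faces before taking its norm
    w <- trapezoid_weights(wss$times)
    mv <- sapply(1:3, function(k) {
      as.numeric(matrix(wss$values[, k, ], nrow = dim(wss$values)[1L]) %*% w)
    })
    fv <- sapply(1:3, function(k) vertex_to_face(mv[, k], mesh))
    x <- sqrt(rowSums(fv^2))
  }
  x
}

#' Time- and space-averaged WSS (AWSS)
#'
#' The sac-area average of the time-averaged WSS magnitude:
#' `(1 / A_a) * integral over Gamma_a of mean|tau| dS`.
#'
#' @param wss a [surface_series()] of WSS vectors (Pa).
#' @param mesh a [labeled_surface_mesh()] with a non-empty sac region.
#' @return AWSS in Pa.
#' @export
awss <- function(wss, mesh) {
  wss_checks(wss, mesh)
  surface_integral(tavg_magnitude_faces(wss, mesh), mesh, "sac") /
    region_area(mesh, "sac")
}

#' Maximum WSS (MWSS)
#'
#' The spatial maximum over the sac of the time-averaged WSS magnitude
#' (time average inside the max). A space-time maximum variant — the maximum
#' over both sac location and cycle phase of the instantaneous magnitude —
#' is available via `variant = "space_time"`.
#'
#' @inheritParams awss
#' @param variant `"time_averaged"` (default) or `"space_time"`.
#' @return MWSS in Pa.
#' @export
mwss <- function(wss, mesh, variant = c("time_averaged", "space_time")) {
  variant <- match.arg(variant)
  wss_checks(wss, mesh)
  if (variant == "time_averaged") {
    f <- tavg_magnitude_faces(wss, mesh)
    max(f[mesh$face_region == "sac"])
  } else {
    mag <- magnitude_on_faces(wss, mesh)
    max(mag[mesh$face_region == "sac", ])
  }
}

#' Oscillatory shear index (OSI)
#'
#' The sac-area average of `0.5 * (1 - |mean tau| / mean|tau|)`, where the
#' numerator is the magnitude of the time-averaged WSS *vector* and the
#' denominator the time average of the magnitude. OSI is 0 for steady
#' unidirectional shear and 0.5 for fully reversing shear; it always lies in
#' [0, 0.5]. Faces with vanishing average magnitude (stagnant wall) carry no
#' directional oscillation and contribute 0.
#'
#' @inheritParams awss
#' @return OSI, dimensionless in [0, 0.5].
#' @export
osi <- function(wss, mesh) {
  wss_checks(wss, mesh)
  num <- tavg_vector_faces(wss, mesh)
  den <- tavg_magnitude_faces(wss, mesh)
  ratio <- ifelse(den > 0, pmin(num / den, 1), 1)
  f <- 0.5 * (1 - ratio)
  surface_integral(f, mesh, "sac") / region_area(mesh, "sac")
}

#' Low shear area (LSA)
#'
#' The fraction of sac area where the time-averaged WSS magnitude falls
#' (strictly) below `threshold_fraction` times a reference WSS. The reference
#' defaults to the AWSS of the same case (threshold `0.1 * AWSS`); the
#' original literature instead normalizes by a parent-artery WSS, which can be
#' supplied through `reference`.
#'
#' @inheritParams awss
#' @param threshold_fraction the low-shear cut as a fraction of the reference.
#' @param reference reference WSS in Pa; `NULL` means the case's own AWSS.
#' @return Area fraction in [0, 1].
#' @export
lsa <- function(wss, mesh, threshold_fraction = 0.1, reference = NULL) {
  wss_checks(wss, mesh)
  f <- tavg_magnitude_faces(wss, mesh)
  if (is.null(reference)) reference <- awss(wss, mesh)
  low <- f < threshold_fraction * reference
  sel <- mesh$face_region == "sac"
  sum(mesh$face_area[sel & low]) / region_area(mesh, "sac")
}

# Per-cell velocity gradient (3x3) from linear tet shape functions, returned
# as an n_cell x 9 matrix (column-major d u_i / d x_j). Velocities are vertex
# values at one instant (n_vertex x 3); coordinates in mm so gradients come
# out in field-units per mm.
tet_cell_gradients <- function(mesh, u) {
  tet <- mesh$tetrahedra
  p1 <- mesh$vertices[tet[, 1L], , drop = FALSE]
  a <- mesh$vertices[tet[, 2L], , drop = FALSE] - p1
  b <- mesh$vertices[tet[, 3L], , drop = FALSE] - p1
  c_ <- mesh$vertices[tet[, 4L], , drop = FALSE] - p1
  # explicit inverse of J = [a; b; c] (rows), det-scaled cofactors
  det <- a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
    a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
    a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])
  # rows of inv(J)^T are gradients of the barycentric coordinates 2..4
  g2 <- cbind(
    b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L],
    b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L],
    b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L]
  ) / det
  g3 <- cbind(
    c_[, 2L] * a[, 3L] - c_[, 3L] * a[, 2L],
    c_[, 3L] * a[, 1L] - c_[, 1L] * a[, 3L],
    c_[, 1L] * a[, 2L] - c_[, 2L] * a[, 1L]
  ) / det
  g4 <- cbind(
    a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
    a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
    a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  ) / det
  g1 <- -(g2 + g3 + g4)
  grad <- matrix(0, nrow(tet), 9L)
  for (i in 1:3) { # velocity component
    ui <- cbind(
      u[tet[, 1L], i], u[tet[, 2L], i],
      u[tet[, 3L], i], u[tet[, 4L], i]
    )
    for (j in 1:3) { # spatial direction
      grad[, (j - 1L) * 3L + i] <- ui[, 1L] * g1[, j] + ui[, 2L] * g2[, j] +
        ui[, 3L] * g3[, j] + ui[, 4L] * g4[, j]
    }
  }
  grad
}

# Squared Frobenius norm of the strain-rate tensor eps = (grad + grad^T)/2
# per cell, from the n_cell x 9 gradient matrix.
strain_rate_sq <- function(grad) {
  idx <- function(i, j) (j - 1L) * 3L + i
  s <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      e <- (grad[, idx(i, j)] + grad[, idx(j, i)]) / 2
      s <- s + e^2
    }
  }
  s
}

#' Viscous dissipation ratio (VDR)
#'
#' The time average over the cycle of the ratio of volume-averaged viscous
#' dissipation density `(2 mu / rho) * ||eps||_F^2` in the aneurysm region
#' to that in the near-vessel region, with `eps` the strain-rate tensor
#' computed cell-wise from the linear shape functions of each tetrahedron.
#' The physical prefactor cancels in the ratio but is applied so the
#' intermediate densities carry their stated units.
#'
#' @param vel a [volume_series()] of velocities (m/s) on a mesh with
#'   non-empty `aneurysm` and `near_vessel` regions.
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @return VDR, dimensionless and non-negative.
#' @export
vdr <- function(vel, mu = 3.45e-3, rho = 1056) {
  stopifnot(inherits(vel, "volume_series"))
  mesh <- vel$mesh
  va <- region_volume(mesh, "aneurysm")
  vnv <- region_volume(mesh, "near_vessel")
  in_a <- mesh$cell_region == "aneurysm"
  in_nv <- mesh$cell_region == "near_vessel"
  nt <- length(vel$times)
  ratio <- numeric(nt)
  for (k in seq_len(nt)) {
    grad <- tet_cell_gradients(mesh, vel$values[, , k])
    dens <- (2 * mu / rho) * strain_rate_sq(grad)
    num <- sum(dens[in_a] * mesh$cell_volume[in_a]) / va
    den <- sum(dens[in_nv] * mesh$cell_volume[in_nv]) / vnv
    if (den <= 0) {
      stop("near-vessel dissipation vanishes at t = ", vel$times[k],
        "; VDR is ill-posed",
        call. = FALSE
      )
    }
    ratio[k] <- num / den
  }
  sum(ratio * trapezoid_weights(vel$times))
}

#' Inflow concentration index (ICI)
#'
#' The time average of `(Q_in / Q_pa) / (A_in / A_neck)`: the fraction of
#' parent-artery flow entering the sac, relative to the fraction of neck area
#' it enters through. `Q_in` integrates the positive (into-sac) normal
#' velocity over the neck surface, `A_in` is the area where that component is
#' positive, `Q_pa` is the flux through a parent-artery cross-section.
#' Instants with no inflow (`A_in = 0`) contribute 0 to the time average.
#'
#' The neck-normal velocity is supplied directly (faces x times, m/s,
#' positive into the sac), which keeps the operation independent of how the
#' volume field was interpolated onto the neck.
#'
#' @param u_neck numeric matrix `n_neck_faces x n_times`: velocity component
#'   normal to the neck, oriented into the sac, m/s.
#' @param neck_area numeric vector of neck face areas, mm^2.
#' @param qpa numeric vector of parent-artery fluxes per time (same units as
#'   `u_neck * neck_area`); must be positive (antegrade) throughout.
#' @param times uniform time grid, s.
#' @return ICI, dimensionless and non-negative.
#' @export
ici <- function(u_neck, neck_area, qpa, times) {
  u_neck <- as.matrix(u_neck)
  stopifnot(
    nrow(u_neck) == length(neck_area),
    ncol(u_neck) == length(times), length(qpa) == length(times)
  )
  if (any(qpa <= 0)) {
    stop("parent-artery flux must be positive (antegrade) at every instant")
  }
  a_neck <- sum(neck_area)
  vals <- vapply(seq_along(times), function(k) {
    pos <- u_neck[, k] > 0
    if (!any(pos)) {
      return(0)
    }
    q_in <- sum(u_neck[pos, k] * neck_area[pos])
    a_in <- sum(neck_area[pos])
    (q_in / qpa[k]) / (a_in / a_neck)
  }, numeric(1L))
  sum(vals * trapezoid_weights(times))
}

#' Shear concentration index (SCI)
#'
#' The time average of `(F_h / F_a) / (A_h / A_a)`, where at each instant
#' `F_a` is the integral of |tau| over the sac, the high-shear region H holds
#' the faces with |tau| strictly above a threshold, `F_h` the shear force on
#' H and `A_h` its area. The threshold is the area-weighted mean plus
#' `n_sd` area-weighted standard deviations of |tau| over the reference
#' region (the sac by default; the near-vessel wall as an alternative
#' convention). Instants with an empty high-shear set contribute 0.
#'
#' @inheritParams awss
#' @param n_sd number of standard deviations above the mean for the
#'   high-shear threshold.
#' @param threshold_region region over which the threshold moments are taken:
#'   `"sac"` (default) or `"near_vessel"`.
#' @return SCI, dimensionless and non-negative.
#' @export
sci <- function(wss, mesh, n_sd = 1, threshold_region = c("sac", "near_vessel")) {
  threshold_region <- match.arg(threshold_region)
  wss_checks(wss, mesh)
  mag <- magnitude_on_faces(wss, mesh)
  sel <- mesh$face_region == "sac"
  ref <- mesh$face_region == threshold_region
  if (!any(ref)) stop("region '", threshold_region, "' is empty")
  area <- mesh$face_area
  a_a <- sum(area[sel])
  a_ref <- sum(area[ref])
  vals <- vapply(seq_along(wss$times), function(k) {
    m <- mag[, k]
    mu_ref <- sum(m[ref] * area[ref]) / a_ref
    sd_ref <- sqrt(sum((m[ref] - mu_ref)^2 * area[ref]) / a_ref)
    thr <- mu_ref + n_sd * sd_ref
    high <- sel & (m > thr)
    if (!any(high)) {
      return(0)
    }
    f_a <- sum(m[sel] * area[sel])
    f_h <- sum(m[high] * area[high])
    a_h <- sum(area[high])
    (f_h / f_a) / (a_h / a_a)
  }, numeric(1L))
  sum(vals * trapezoid_weights(wss$times))
}

# Per-face surface-tangential gradient of a vertex-centered scalar: the
# gradient of the linear interpolant over each triangle (lies in the face
# plane by construction). Returns an n_face x 3 matrix, units per mm.
face_tangential_gradient <- function(field, mesh) {
  tr <- mesh$triangles
  p1 <- mesh$vertices[tr[, 1L], , drop = FALSE]
  p2 <- mesh$vertices[tr[, 2L], , drop = FALSE]
  p3 <- mesh$vertices[tr[, 3L], , drop = FALSE]
  n <- mesh$normals
  two_a <- 2 * mesh$face_area
  cross3 <- function(u, v) {
    cbind(
      u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
      u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
      u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
    )
  }
  # gradient of the linear shape function of vertex i is n x (opposite edge)
  # rotated into the face plane: grad phi_1 = (n x (p3 - p2)) / 2A, etc.
  g1 <- cross3(n, p3 - p2) / two_a
  g2 <- cross3(n, p1 - p3) / two_a
  g3 <- cross3(n, p2 - p1) / two_a
  f1 <- field[tr[, 1L]]
  f2 <- field[tr[, 2L]]
  f3 <- field[tr[, 3L]]
  g1 * f1 + g2 * f2 + g3 * f3
}

#' WSS spatial gradient indicator (WSSG)
#'
#' The sac-area average of the time-averaged norm of the surface-tangential
#' gradient of the WSS field: each Cartesian component of tau is linearly
#' interpolated over a triangle from its vertex values and differentiated
#' in-plane; by default the Frobenius norm of the resulting 3x3 tangential
#' gradient is taken (`norm = "vector_frobenius"`), with the norm of the
#' gradient of |tau| as an alternative convention (`norm = "magnitude"`).
#' Requires a vertex-centered series — a face-centered field carries no
#' within-face variation to differentiate.
#'
#' @inheritParams awss
#' @param norm `"vector_frobenius"` or `"magnitude"`.
#' @return WSSG in Pa/mm.
#' @export
wssg <- function(wss, mesh, norm = c("vector_frobenius", "magnitude")) {
  norm <- match.arg(norm)
  wss_checks(wss, mesh)
  if (wss$location != "vertex") {
    stop("WSSG needs a vertex-centered WSS series; resample faces to vertices")
  }
  nt <- length(wss$times)
  gn <- matrix(0, nrow(mesh$triangles), nt)
  for (k in seq_len(nt)) {
    if (norm == "vector_frobenius") {
      s <- 0
      for (i in 1:3) {
        g <- face_tangential_gradient(wss$values[, i, k], mesh)
        s <- s + rowSums(g^2)
      }
      gn[, k] <- sqrt(s)
    } else {
      m <- sqrt(rowSums(sapply(1:3, function(i) wss$values[, i, k])^2))
      g <- face_tangential_gradient(m, mesh)
      gn[, k] <- sqrt(rowSums(g^2))
    }
  }
  f <- as.numeric(gn %*% trapezoid_weights(wss$times))
  surface_integral(f, mesh, "sac") / region_area(mesh, "sac")
}

#' Temporal WSS derivative indicator (TDWSS)
#'
#' The sac-area average of the time-averaged absolute rate of change of the
#' WSS magnitude, `mean |d|tau|/dt|`, with the derivative taken by central
#' differences and periodic wrap-around over the cycle.
#'
#' @inheritParams awss
#' @return TDWSS in Pa/s.
#' @export
tdwss <- function(wss, mesh) {
  wss_checks(wss, mesh)
  if (!wss$periodic) {
    stop("TDWSS assumes a periodic series spanning one full cycle")
  }
  mag <- magnitude_on_faces(wss, mesh)
  nt <- length(wss$times)
  dt <- wss$times[2L] - wss$times[1L]
  # samples 1..nt-1 cover one period; sample nt repeats sample 1 in phase
  m <- mag[, -nt, drop = FALSE]
  np <- nt - 1L
  fwd <- m[, c(2:np, 1L), drop = FALSE]
  bwd <- m[, c(np, 1:(np - 1L)), drop = FALSE]
  deriv <- abs(fwd - bwd) / (2 * dt)
  deriv <- cbind(deriv, deriv[, 1L]) # re-close the cycle for the trapezoid
  f <- as.numeric(deriv %*% trapezoid_weights(wss$times))
  surface_integral(f, mesh, "sac") / region_area(mesh, "sac")
}

#' Compute all WSS-based indicators for one case
#'
#' Convenience wrapper returning AWSS, MWSS, OSI, LSA, SCI, WSSG and TDWSS in
#' one named list. WSSG is reported as `NA` for face-centered input (it needs
#' vertex values); VDR and ICI require velocity data and are computed
#' separately.
#'
#' @inheritParams awss
#' @param ... passed on to the individual indicator functions.
#' @return Named list of indicator values.
#' @export
wss_indicators <- function(wss, mesh, ...) {
  list(
    awss = awss(wss, mesh),
    mwss = mwss(wss, mesh),
    osi = osi(wss, mesh),
    lsa = lsa(wss, mesh, ...),
    sci = sci(wss, mesh),
    wssg = if (wss$location == "vertex") wssg(wss, mesh) else NA_real_,
    tdwss = tdwss(wss, mesh)
  )
}
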