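# Shared fixtures, built in code at test time.

# Two-triangle unit square in the z = 0 plane.
unit_square_mesh <- function(region = "sac") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  tr <- rbind(c(1, 2, 3), c(1, 3, 4))
  labeled_surface_mesh(v, tr, region)
}

# Spatially uniform vector series tau(t) = mag(t) * direction on a mesh.
uniform_series <- function(mesh, mag_t, times, direction = c(1, 0, 0),
                           location = "face") {
  n <- if (location == "face") nrow(mesh$triangles) else nrow(mesh$vertices)
  vals <- array(0, c(n, 3, length(times)))
  for (k in 1:3) {
    vals[, k, ] <- matrix(mag_t * direction[k], n, length(times), byrow = TRUE)
  }
  surface_series(times, vals, location = location, periodic = TRUE)
}

# Random periodic WSS series (face-centered) for property tests.
random_series <- function(mesh, n_times = 9, period = 0.949) {
  nf <- nrow(mesh$triangles)
  times <- seq(0, period, length.out = n_times)
  vals <- array(stats::rnorm(nf * 3 * (n_times - 1)), c(nf, 3, n_times - 1))
  vals <- array(c(vals, vals[, , 1]), c(nf, 3, n_times)) # periodic closure
  surface_series(times, vals, location = "face", periodic = TRUE)
}

# Small default idealized geometry reused across tests.
small_aneurysm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_idealized_aneurysm(
        aneurysm_geometry_spec(edge_length = 0.35)
      )
    }
    cache
  }
})

rigid_transform <- function(mesh, angle = 0.7, axis = c(1, 2, 2),
                            shift = c(3, -1, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle)
  s <- sin(angle)
  k <- matrix(
    c(
      0, -axis[3], axis[2],
      axis[3], 0, -axis[1],
      -axis[2], axis[1], 0
    ),
    3, 3,
    byrow = TRUE
  )
  rot <- diag(3) + s * k + (1 - c_) * (k %*% k)
  m2 <- mesh
  m2$vertices <- sweep(mesh$vertices %*% t(rot), 2L, -shift)
  labeled_surface_mesh(m2$vertices, mesh$triangles, mesh$face_region)
}

# Rotate a face-centered vector series with the same rotation.
rotate_series <- function(series, angle = 0.7, axis = c(1, 2, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle)
  s <- sin(angle)
  k <- matrix(
    c(
      0, -axis[3], axis[2],
      axis[3], 0, -axis[1],
      -axis[2], axis[1], 0
    ),
    3, 3,
    byrow = TRUE
  )
  rot <- diag(3) + s * k + (1 - c_) * (k %*% k)
  v <- series$values
  out <- array(0, dim(v))
  for (t in seq_along(series$times)) {
    out[, , t] <- v[, , t] %*% t(rot)
  }
  surface_series(series$times, out,
    location = series$location,
    periodic = series$periodic
  )
}
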