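# WSS-based indicators against closed forms and hand evaluations.

period <- 0.949

test_that("AWSS matches uniform, Poiseuille and offset-sine references", {
  g <- small_aneurysm()
  m <- g$surface
  times <- seq(0, period, length.out = 65)

  expect_equal(awss(uniform_series(m, rep(2, 65), times), m), 2)

  # |tau|(t) = 2 + sin(w t): the periodic trapezoid annihilates the sine
  s_off <- uniform_series(m, 2 + sin(2 * pi * times / period), times)
  expect_equal(awss(s_off, m), 2, tolerance = 1e-12)

  # steady Poiseuille wall shear on a cylinder labeled entirely as sac:
  # tau_w = 4 mu ubar / R = 1.863 Pa for R = 2 mm, ubar = 0.27 m/s
  tube <- build_idealized_aneurysm(
    aneurysm_geometry_spec(vessel_length = 10, edge_length = 0.3)
  )$surface
  wall <- labeled_surface_mesh(
    tube$vertices, tube$triangles,
    ifelse(tube$face_region == "parent", "sac", "other")
  )
  tau_w <- 4 * 3.45e-3 * 0.27 / 2e-3
  s_pois <- uniform_series(wall, rep(tau_w, 5), seq(0, period, length.out = 5))
  expect_equal(awss(s_pois, wall), 1.863, tolerance = 0.01)

  expect_error(awss(s_pois, labeled_surface_mesh(
    wall$vertices, wall$triangles, "other"
  )), "sac")
})

test_that("MWSS takes the sac maximum of the time-averaged magnitude", {
  m <- icosphere_mesh(1, 2)
  times <- seq(0, period, length.out = 9)
  nf <- nrow(m$triangles)

  s_unif <- uniform_series(m, rep(2, 9), times)
  expect_equal(mwss(s_unif, m), 2)

  vals <- array(0, c(nf, 3, 9))
  vals[, 1, ] <- 1
  vals[17, 1, ] <- 5
  s_peak <- surface_series(times, vals)
  expect_equal(mwss(s_peak, m), 5)

  # random fields: equals a brute-force per-face trapezoid maximum
  set.seed(7)
  for (i in 1:5) {
    s <- random_series(m)
    w <- diff(s$times)[1] / (period) * c(0.5, rep(1, length(s$times) - 2), 0.5)
    brute <- max(vapply(seq_len(nf), function(f) {
      sum(sqrt(colSums(s$values[f, , ]^2)) * w)
    }, numeric(1)))
    expect_equal(mwss(s, m), brute, tolerance = 1e-12)
  }

  # space-time variant bounds the time-averaged one from above
  s <- random_series(m)
  expect_gte(mwss(s, m, variant = "space_time"), mwss(s, m))
})

test_that("OSI matches steady, reversing and oblique-oscillation references", {
  m <- icosphere_mesh(1, 2)
  times <- seq(0, period, length.out = 201)

  expect_equal(osi(uniform_series(m, rep(1, 201), times), m), 0)
  expect_equal(
    osi(uniform_series(m, sin(2 * pi * times / period), times), m), 0.5
  )

  # tau = (1, sin wt, 0): OSI = (1 - 1/avg|tau|)/2 with
  # avg|tau| = (1/T) int sqrt(1 + sin^2) dt = 1.2160
  nf <- nrow(m$triangles)
  vals <- array(0, c(nf, 3, 201))
  vals[, 1, ] <- 1
  vals[, 2, ] <- matrix(sin(2 * pi * times / period), nf, 201, byrow = TRUE)
  s <- surface_series(times, vals)
  expect_equal(osi(s, m), 0.5 * (1 - 1 / 1.2160), tolerance = 1e-3)

  # stagnant wall contributes zero, keeping OSI finite
  vals0 <- array(0, c(nf, 3, 201))
  s0 <- surface_series(times, vals0)
  expect_equal(osi(s0, m), 0)
})

test_that("LSA follows the 0.1 x AWSS threshold with strict inequality", {
  m <- icosphere_mesh(1, 3)
  times <- seq(0, period, length.out = 5)
  nf <- nrow(m$triangles)

  expect_equal(lsa(uniform_series(m, rep(2, 5), times), m), 0)

  # ~25% of area at 0.1 Pa, the rest at 2 Pa: AWSS = 1.525, threshold
  # 0.1525, so exactly the low faces qualify (faces have equal areas on the
  # icosphere up to projection distortion; use realized areas for truth)
  low_faces <- seq_len(nf) <= nf / 4
  vals <- array(0, c(nf, 3, 5))
  vals[, 1, ] <- ifelse(low_faces, 0.1, 2)
  s <- surface_series(times, vals)
  frac_low <- sum(m$face_area[low_faces]) / sum(m$face_area)
  awss_exp <- 0.1 * frac_low + 2 * (1 - frac_low)
  expect_equal(awss(s, m), awss_exp, tolerance = 1e-12)
  expect_equal(lsa(s, m), frac_low, tolerance = 1e-12)

  # ties fall outside the low-shear set (strict <)
  s_unif <- uniform_series(m, rep(1, 5), times)
  expect_equal(lsa(s_unif, m, threshold_fraction = 1), 0)

  # parent-artery reference option
  expect_equal(lsa(s_unif, m, reference = 100), 1)
})

test_that("SCI reproduces the two-level hand evaluation and conventions", {
  m <- icosphere_mesh(1, 3)
  times <- seq(0, period, length.out = 5)
  nf <- nrow(m$triangles)

  # concentrated spot: fraction f at 10 Pa, rest at 1 Pa;
  # SCI = (Fh/Fa)/f with the high set = the spot when 10 > mean + sd
  spot <- analytic_wss_series("spot", m,
    n_times = 5, high = 10, low = 1,
    spot_fraction = 0.1
  )
  expect_equal(sci(spot$series, m), spot$truth$sci, tolerance = 1e-10)
  f <- spot$truth$spot_fraction_realized
  expect_equal(spot$truth$sci, (f * 10 / (f * 10 + (1 - f) * 1)) / f)

  # uniform field: empty high-shear set, SCI = 0 by convention
  expect_equal(sci(uniform_series(m, rep(3, 5), times), m), 0)

  # scale invariance
  s <- spot$series
  s2 <- surface_series(s$times, s$values * 7.3, location = s$location)
  expect_equal(sci(s2, m), sci(s, m), tolerance = 1e-12)
})

test_that("WSSG is exact for linear fields on planar meshes and frame-invariant", {
  st <- strip_mesh(lx = 10, ly = 2, nx = 20, ny = 4)
  ramp <- analytic_wss_series("ramp", st,
    n_times = 4, gradient = 0.5,
    location = "vertex"
  )
  expect_equal(wssg(ramp$series, st), 0.5, tolerance = 1e-12)

  # uniform field has zero gradient
  times <- seq(0, period, length.out = 4)
  expect_equal(wssg(uniform_series(st, rep(2, 4), times,
    location = "vertex"
  ), st), 0, tolerance = 1e-12)

  # rigid rotation of mesh + field leaves the value unchanged
  st_rot <- rigid_transform(st)
  s_rot <- rotate_series(ramp$series)
  expect_equal(wssg(s_rot, st_rot), 0.5, tolerance = 1e-10)

  # face-centered input cannot be differentiated
  expect_error(wssg(uniform_series(st, rep(1, 4), times), st), "vertex")
})

test_that("TDWSS matches the smooth-oscillation quadrature value", {
  m <- icosphere_mesh(1, 2)
  omega <- 2 * pi / period
  times <- seq(0, period, length.out = 201)

  # steady field: zero temporal derivative
  expect_equal(tdwss(uniform_series(m, rep(2, 201), times), m), 0)

  # |tau| = 2 + sin(wt): mean |w cos wt| = 2 w / pi = 4.215 Pa/s
  s <- uniform_series(m, 2 + sin(omega * times), times)
  expect_equal(tdwss(s, m), 2 * omega / pi, tolerance = 0.01)
  expect_equal(2 * omega / pi, 4.215, tolerance = 1e-3)

  # linear in the oscillation amplitude
  s2 <- uniform_series(m, 2 + 2 * sin(omega * times), times)
  expect_equal(tdwss(s2, m), 2 * tdwss(s, m), tolerance = 1e-9)

  s_np <- uniform_series(m, 2 + sin(omega * times), times)
  s_np$periodic <- FALSE
  expect_error(tdwss(s_np, m), "periodic")
})

test_that("VDR matches Poiseuille dissipation and region-ratio limits", {
  mu <- 3.45e-3
  rho <- 1056
  ub <- 0.27
  R <- 2
  reg <- function(ctr) ifelse(ctr[, 3] < 4, "aneurysm", "near_vessel")
  tm <- tube_volume_mesh(R, 8, 0.3, region = reg)
  r2 <- tm$vertices[, 1]^2 + tm$vertices[, 2]^2
  uz <- 2 * ub * (1 - r2 / R^2)
  nt <- 3
  tt <- seq(0, period, length.out = nt)
  vals <- array(0, c(nrow(tm$vertices), 3, nt))
  for (k in seq_len(nt)) vals[, 3, k] <- uz
  vs <- volume_series(tt, vals, tm)

  # identical flow in both regions: ratio is exactly 1
  expect_equal(vdr(vs), 1, tolerance = 1e-12)

  # volume-averaged dissipation density matches the closed form
  # (2 mu / rho) * 4 ubar^2 / R^2 within 2% on this resolution
  dens <- (2 * mu / rho) *
    hemorobust:::strain_rate_sq(hemorobust:::tet_cell_gradients(tm, vals[, , 1]))
  va <- sum(dens * tm$cell_volume) / sum(tm$cell_volume)
  expect_equal(va, (2 * mu / rho) * 4 * ub^2 / R^2, tolerance = 0.02)

  # quiescent aneurysm region: VDR = 0
  vals0 <- vals
  in_a_vert <- tm$vertices[, 3] < 4 - 1e-9
  for (k in seq_len(nt)) vals0[in_a_vert, 3, k] <- 0
  # zero only strictly inside so the near-vessel side keeps dissipating
  vs0 <- volume_series(tt, vals0, tm)
  expect_lt(vdr(vs0), 0.55) # interface cells straddle; must drop far below 1

  # zero near-vessel dissipation is ill-posed
  vals_nv0 <- vals
  vals_nv0[tm$vertices[, 3] >= 4 - 1e-9, 3, ] <- 0
  vals_nv0[tm$vertices[, 3] < 4 - 1e-9, 3, ] <- 1 # rigid motion, no strain
  # constant field in aneurysm, zero in near-vessel: denominator vanishes
  vs_bad <- volume_series(tt, array(0, dim(vals)), tm)
  expect_error(vdr(vs_bad), "ill-posed")

  # scale invariance: u -> c u leaves the ratio unchanged
  vs2 <- volume_series(tt, vals * 3.7, tm)
  expect_equal(vdr(vs2), vdr(vs), tolerance = 1e-12)
})

test_that("ICI matches plug-flow and concentrated-jet references", {
  times <- seq(0, 1, length.out = 5)
  area <- rep(0.5, 20) # 20 equal neck faces

  # plug flow through the whole neck carrying all parent flow
  u_plug <- matrix(0.3, 20, 5)
  qpa <- colSums(u_plug * area)
  expect_equal(ici(u_plug, area, qpa, times), 1)

  # Qin = 0.5 Qpa through Ain = 0.1 Aneck -> ICI = 5
  u_jet <- matrix(0, 20, 5)
  u_jet[1:2, ] <- 1
  qin <- colSums(pmax(u_jet, 0) * area)
  expect_equal(ici(u_jet, area, qin / 0.5, times), 5)

  # scale invariance in the velocity
  expect_equal(
    ici(3 * u_jet, area, 3 * qin / 0.5, times),
    ici(u_jet, area, qin / 0.5, times)
  )

  # no-inflow instants contribute zero rather than being skipped
  u_half <- u_jet
  u_half[, 1:2] <- 0 # includes t = 0; periodic endpoint stays active
  expect_lt(
    ici(u_half, area, qin / 0.5, times),
    ici(u_jet, area, qin / 0.5, times)
  )

  expect_error(ici(u_jet, area, c(-1, 1, 1, 1, 1), times), "antegrade")
})

test_that("indicator bounds and scalings hold on random fields", {
  set.seed(23)
  m <- icosphere_mesh(1, 2)
  for (i in 1:25) {
    s <- random_series(m)
    o <- osi(s, m)
    expect_gte(o, 0)
    expect_lte(o, 0.5)
    l <- lsa(s, m)
    expect_gte(l, 0)
    expect_lte(l, 1)
    a <- awss(s, m)
    expect_lte(a, mwss(s, m) + 1e-12)
    # linear scaling of tau
    s3 <- surface_series(s$times, s$values * 3, location = "face")
    expect_equal(awss(s3, m), 3 * a, tolerance = 1e-12)
    expect_equal(osi(s3, m), o, tolerance = 1e-12)
    expect_equal(lsa(s3, m), l, tolerance = 1e-12)
  }
})

test_that("indicators are invariant under rigid motion of mesh and field", {
  set.seed(5)
  m <- icosphere_mesh(1, 2)
  s <- random_series(m)
  m2 <- rigid_transform(m)
  s2 <- rotate_series(s)
  expect_equal(awss(s2, m2), awss(s, m), tolerance = 1e-10)
  expect_equal(mwss(s2, m2), mwss(s, m), tolerance = 1e-10)
  expect_equal(osi(s2, m2), osi(s, m), tolerance = 1e-10)
  expect_equal(lsa(s2, m2), lsa(s, m), tolerance = 1e-10)
  expect_equal(sci(s2, m2), sci(s, m), tolerance = 1e-10)
  expect_equal(tdwss(s2, m2), tdwss(s, m), tolerance = 1e-10)
})
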