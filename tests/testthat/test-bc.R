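# Boundary-condition constructions and resolution arithmetic.

test_that("waveform dampening preserves the mean and contracts the pulse", {
  w <- carotid_waveform()
  expect_equal(60 / w$period, 63, tolerance = 0.005) # 0.949 s ~ 63 bpm

  d <- dampen_pulsatility(w, 0.15)
  expect_equal(d$mean, w$mean, tolerance = 1e-12)
  expect_equal(d$pulsatility, 0.85 * w$pulsatility, tolerance = 1e-12)

  # constant waveform is unchanged; fraction 0 is the identity
  wc <- flow_waveform(rep(245, 10))
  expect_equal(dampen_pulsatility(wc, 0.15)$q, wc$q)
  expect_equal(dampen_pulsatility(w, 0)$q, w$q)

  expect_error(dampen_pulsatility(w, 1), "fraction")
  expect_error(dampen_pulsatility(w, -0.1), "fraction")
  expect_error(flow_waveform(c(1, 2, 3, 4)), "periodic")
})

test_that("Womersley number and profile match the classical references", {
  # alpha = R sqrt(omega / nu) for R = 2 mm, nu = 3.45e-3/1056, T = 0.949 s
  expect_equal(womersley_alpha(2), 2.85, tolerance = 0.005)

  # steady waveform: the Poiseuille parabola with centerline 2 ubar
  sp0 <- womersley_spec(2, flow_waveform(rep(245, 16)))
  expect_equal(womersley_velocity(sp0, 0, 0.3), 2 * 0.27, tolerance = 1e-12)
  r <- c(0, 0.5, 1, 1.5, 2)
  expect_equal(
    womersley_velocity(sp0, r, 0),
    2 * 0.27 * (1 - (r / 2)^2),
    tolerance = 1e-12
  )
  expect_error(womersley_velocity(sp0, 2.5, 0), "outside")

  # flux reproduces the (band-limited) waveform at its own sample instants
  w <- carotid_waveform(n_samples = 64)
  sp <- womersley_spec(2, w, n_harmonics = 8)
  q_model <- womersley_flux(sp, w$times)
  q_expect <- 0.27 * (w$q / w$mean) * pi * 0.002^2
  expect_equal(q_model, q_expect, tolerance = 1e-6)

  # cycle-mean cross-section-average velocity equals the target
  tavg <- mean(q_model[-length(q_model)]) / (pi * 0.002^2)
  expect_equal(tavg, 0.27, tolerance = 1e-9)
})

test_that("Womersley profile limits: Poiseuille at low alpha, flat at high", {
  w <- carotid_waveform(n_samples = 64)
  # low alpha (small vessel): profile tracks the quasi-steady parabola
  sp_small <- womersley_spec(0.15, w, n_harmonics = 5)
  ts <- c(0.1, 0.4, 0.7)
  q_t <- 0.27 * stats::approx(w$times, w$q / w$mean, xout = ts)$y
  u_center <- womersley_velocity(sp_small, 0, ts)
  expect_equal(u_center, 2 * q_t, tolerance = 0.02)

  # high alpha (large vessel): the oscillatory centerline excess over the
  # section-average velocity shrinks toward 0 (flat profile); at low alpha
  # it stays near the parabolic value (centerline = 2 x average)
  excess <- function(radius) {
    sp <- womersley_spec(radius, w, n_harmonics = 5)
    u_center <- womersley_velocity(sp, 0, w$times)
    u_mean <- womersley_flux(sp, w$times) / (pi * (radius / 1000)^2)
    sd(u_center - u_mean) / sd(u_mean)
  }
  expect_lt(excess(8), 0.3)
  expect_gt(excess(0.15), 0.9)
  expect_lt(excess(8), excess(2))
  expect_lt(excess(2), excess(0.15))
})

test_that("Murray outlet pressures and flow splits follow radius cubed", {
  expect_equal(murray_outlet_pressure(2, c(2, 2), 0), 0)
  q <- 2.5e-6
  expect_equal(murray_outlet_pressure(2, c(2, 2), q), 2 * 1e9 * q)
  expect_equal(
    murray_outlet_pressure(2, c(2, 2), q, K = 2e9),
    2 * murray_outlet_pressure(2, c(2, 2), q)
  )
  expect_error(murray_outlet_pressure(0, c(1, 1), q), "positive")

  # lumped-network split: flows proportional to r^3 to near machine precision
  s <- murray_flow_split(c(2, 1), 10)
  expect_equal(s$flows[1] / s$flows[2], 8, tolerance = 1e-12)
  expect_equal(sum(s$flows), 10, tolerance = 1e-12)

  s3 <- murray_flow_split(c(1.7, 1.2, 0.8), 7.3)
  expect_equal(s3$flows / s3$flows[3], (c(1.7, 1.2, 0.8) / 0.8)^3,
    tolerance = 1e-12
  )
  expect_equal(sum(s3$flows), 7.3, tolerance = 1e-12)

  # equal radii split equally
  se <- murray_flow_split(c(1.3, 1.3, 1.3), 9)
  expect_equal(se$flows, rep(3, 3), tolerance = 1e-12)
})

test_that("boundary-layer schedule is geometric with the printed totals", {
  bl <- boundary_layer_schedule()
  expect_length(bl, 4)
  expect_equal(sum(bl), 0.3, tolerance = 1e-15)
  expect_equal(bl[2] / bl[1], 0.6, tolerance = 1e-12)
  # thinnest sublayer ~ 0.03 h: total * r^3 / (1 + r + r^2 + r^3)
  expect_equal(min(bl), 0.3 * 0.6^3 / sum(0.6^(0:3)), tolerance = 1e-15)
  expect_equal(round(min(bl), 2), 0.03)

  expect_equal(
    boundary_layer_schedule(0.3, 4, 1),
    rep(0.075, 4)
  )
})

test_that("Courant and resolution arithmetic reproduce the study bounds", {
  # coarse mesh: 8000 steps/cycle at h = 0.18 mm stays below CFL 1 up to
  # 1.5 m/s
  cfl <- courant_number(1.5, 0.949 / 8000, 0.18)
  expect_lte(cfl, 1)
  expect_gt(cfl, 0.9) # the bound is tight, not slack
  expect_equal(courant_number(1.5, 0.949 / 16000, 0.18), cfl / 2)
  expect_equal(courant_number(0, 1e-4, 0.18), 0)
  expect_equal(timestep_count(0.949, 0.949 / 8000), 8000L)

  expect_equal(effective_resolution(0.13, 2), 0.065)
  expect_equal(effective_resolution(0.18, 2), 0.09)
  expect_equal(effective_resolution(0.25, 1), 0.25)

  # 4.0 M quadratic tets correspond to 32 M linear elements
  expect_equal(linear_element_equivalent(4e6), 3.2e7)

  rep_ <- mesh_sizing_report(0.18)
  expect_equal(rep_$parent_h_mm, 0.225)
  expect_equal(rep_$far_h_mm, 0.36)
  expect_lte(rep_$cfl, 1)
})
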