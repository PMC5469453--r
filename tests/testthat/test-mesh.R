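test_that("surface mesh construction derives areas and unit normals", {
  m <- unit_square_mesh()
  expect_equal(sum(m$face_area), 1)
  expect_equal(region_area(m, "sac"), 1)
  expect_equal(rowSums(m$normals^2), rep(1, 2), tolerance = 1e-12)

  # icosphere area converges to the closed form 4 pi r^2
  s <- icosphere_mesh(2, subdivisions = 4)
  expect_equal(sum(s$face_area), 4 * pi * 4, tolerance = 0.01)
  # refinement improves the estimate (order >= 1)
  s_coarse <- icosphere_mesh(2, subdivisions = 2)
  err_c <- abs(sum(s_coarse$face_area) - 16 * pi)
  err_f <- abs(sum(s$face_area) - 16 * pi)
  expect_lt(err_f, err_c / 4)
})

test_that("degenerate and malformed meshes are rejected with indices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  tr <- rbind(c(1, 2, 4), c(1, 2, 3)) # second face is collinear
  expect_error(labeled_surface_mesh(v, tr, "sac"), "degenerate.*2")
  expect_error(
    labeled_surface_mesh(v[1:2, ], rbind(c(1, 2, 3)), "sac"),
    "out of range"
  )
  expect_error(
    labeled_surface_mesh(v, rbind(c(1, 2, 4)), "lumen"),
    "unknown region"
  )
})

test_that("time_average distinguishes vector-then-norm from norm-then-average", {
  m <- unit_square_mesh()
  times <- seq(0, 1, length.out = 101)

  # constant vector: both modes agree
  s_const <- uniform_series(m, rep(2, 101), times)
  expect_equal(time_average(s_const, "vector_then_norm"), c(2, 2))
  expect_equal(time_average(s_const, "norm_then_average"), c(2, 2))

  # pure sine over a full period: vector average vanishes on the periodic
  # trapezoid grid; magnitude average tends to 2/pi
  s_sin <- uniform_series(m, sin(2 * pi * times), times)
  expect_equal(time_average(s_sin, "vector_then_norm"),
    c(0, 0),
    tolerance = 1e-12
  )
  expect_equal(time_average(s_sin, "norm_then_average"),
    rep(2 / pi, 2),
    tolerance = 1e-3
  )

  # offset sine: the sine integrates away exactly
  s_off <- uniform_series(m, 2 + sin(2 * pi * times), times)
  expect_equal(time_average(s_off, "vector_then_norm"),
    c(2, 2),
    tolerance = 1e-12
  )

  expect_error(
    surface_series(c(0, 0.1, 0.35), array(0, c(2, 3, 3))),
    "uniform"
  )
  expect_error(surface_series(c(0, 0.1), array(0, c(2, 3, 2))), "3 time")
})

test_that("triangle inequality holds between the two averaging modes", {
  set.seed(11)
  m <- icosphere_mesh(1, 1)
  for (i in 1:20) {
    s <- random_series(m)
    expect_true(all(
      time_average(s, "vector_then_norm") <=
        time_average(s, "norm_then_average") + 1e-12
    ))
  }
})

test_that("surface_integral is exact for per-face fields and additive", {
  m <- unit_square_mesh()
  expect_equal(surface_integral(rep(1, 2), m, "sac"), 1)

  # vertex-centered linear field integrates exactly via the midpoint rule
  f_lin <- m$vertices[, 1L] # f(x, y) = x on the unit square
  expect_equal(surface_integral(f_lin, m, "sac"), 0.5)

  expect_error(surface_integral(rep(1, 2), m, "parent"), "empty")

  # additivity over disjoint regions and linearity in the field
  g <- small_aneurysm()$surface
  f <- seq_len(nrow(g$triangles)) * 0.1
  tot <- surface_integral(f, g, c("sac", "neck", "parent", "other"))
  parts <- sum(
    surface_integral(f, g, "sac"), surface_integral(f, g, "neck"),
    surface_integral(f, g, "parent"), surface_integral(f, g, "other")
  )
  expect_equal(tot, parts, tolerance = 1e-12)
  expect_equal(
    surface_integral(3 * f, g, "sac"),
    3 * surface_integral(f, g, "sac"),
    tolerance = 1e-12
  )
})

test_that("near-vessel labeling follows geodesic distance from the neck", {
  g <- build_idealized_aneurysm(aneurysm_geometry_spec(
    vessel_length = 25, edge_length = 0.5
  ))
  m <- near_vessel_labels(g$surface, cutoff = 10)
  # the band should cover wall within 10 mm (by arclength) of the neck plane
  ctr_z <- (m$vertices[m$triangles[, 1L], 3L] +
    m$vertices[m$triangles[, 2L], 3L] + m$vertices[m$triangles[, 3L], 3L]) / 3
  nv <- m$face_region == "near_vessel"
  wall <- m$face_region %in% c("near_vessel", "parent")
  # geodesic distance along the straight tube = 25 - z; one-edge tolerance
  expect_true(all(25 - ctr_z[nv] < 10 + 0.5 + 1e-9))
  expect_true(all(25 - ctr_z[wall & !nv] > 10 - 0.5 - 1e-9))

  # cutoff 0 changes nothing; huge cutoff converts every reachable wall face
  m0 <- near_vessel_labels(g$surface, cutoff = 0)
  expect_identical(m0$face_region, g$surface$face_region)
  mall <- near_vessel_labels(g$surface, cutoff = 1e6)
  expect_false(any(mall$face_region == "parent"))

  # sac and neck labels are never overwritten
  expect_identical(
    m$face_region[g$surface$face_region == "sac"],
    rep("sac", sum(g$surface$face_region == "sac"))
  )
})

test_that("unreachable wall components keep their label with a warning", {
  g <- small_aneurysm()$surface
  # add a detached floating triangle labeled parent
  v2 <- rbind(g$vertices, c(100, 100, 100), c(101, 100, 100), c(100, 101, 100))
  n <- nrow(g$vertices)
  t2 <- rbind(g$triangles, c(n + 1L, n + 2L, n + 3L))
  m <- labeled_surface_mesh(v2, t2, c(g$face_region, "parent"))
  expect_warning(out <- near_vessel_labels(m, cutoff = 1e6), "unreachable")
  expect_identical(out$face_region[nrow(t2)], "parent")
})

test_that("mesh round-trips through STL, VTP and VTU", {
  g <- build_idealized_aneurysm(aneurysm_geometry_spec(edge_length = 0.8))
  m <- g$surface

  p_vtp <- withr::local_tempfile(fileext = ".vtp")
  write_mesh(m, p_vtp)
  m2 <- read_mesh(p_vtp)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-10)
  expect_identical(m2$triangles, m$triangles)
  expect_identical(m2$face_region, m$face_region)

  # STL drops labels and welds vertices; area must survive both dialects
  for (bin in c(FALSE, TRUE)) {
    p_stl <- withr::local_tempfile(fileext = ".stl")
    write_mesh(m, p_stl, format = "stl", binary = bin)
    m3 <- read_mesh(p_stl, region = "sac")
    expect_equal(sum(m3$face_area), sum(m$face_area), tolerance = 1e-5)
    expect_equal(nrow(m3$triangles), nrow(m$triangles))
  }

  p_vtu <- withr::local_tempfile(fileext = ".vtu")
  write_mesh(g$volume, p_vtu)
  vm <- read_mesh(p_vtu)
  expect_equal(sum(vm$cell_volume), sum(g$volume$cell_volume),
    tolerance = 1e-10
  )
  expect_identical(vm$cell_region, g$volume$cell_region)
})

test_that("volume mesh rejects degenerate cells", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(2, 0, 0))
  expect_error(
    labeled_volume_mesh(v, rbind(c(1, 2, 3, 4), c(1, 2, 5, 5)), "other"),
    "degenerate"
  )
  ok <- labeled_volume_mesh(v, rbind(c(1, 2, 3, 4)), "aneurysm")
  expect_equal(ok$cell_volume, 1 / 6)
  expect_equal(region_volume(ok, "aneurysm"), 1 / 6)
})
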