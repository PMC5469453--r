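# Analytic WSS time series with attached ground truth. Every generated
# field carries a record of the indicator values it should produce, computed
# from closed forms or dense quadrature, so that tests never have to derive
# expected values through the code under test.

# Time average of |f(t)| on a dense grid (independent quadrature oracle).
dense_time_average <- function(f, period, n = 20000L) {
  t <- seq(0, period, length.out = n + 1L)
  w <- trapezoid_weights(t)
  sum(abs(f(t)) * w)
}

#' Analytic WSS time series with known indicator values
#'
#' Builds a WSS vector series on the sac of a labeled mesh following one of
#' several analytic patterns, each with closed-form (or dense-quadrature)
#' values for the WSS-based indicators, returned alongside the series:
#'
#' * `uniform`: constant vector of magnitude `amplitude` everywhere.
#' * `reversing`: `amplitude * sin(omega t)` along a fixed direction — fully
#'   oscillatory shear (OSI = 1/2).
#' * `offset_sine`: `(offset + amplitude * sin(omega t))` along a fixed
#'   direction, `offset > amplitude` so the sign never reverses.
#' * `spot`: steady field, `high` on the sac faces nearest the chosen pole
#'   until a fraction `spot_fraction` of sac area is covered, `low`
#'   elsewhere — a concentrated shear spot with hand-computable SCI and LSA.
#' * `ramp`: steady vertex-centered field with components growing linearly
#'   along x at `gradient` Pa/mm — exact fixture for the WSS-gradient
#'   indicator on planar meshes.
#' * `womersley`: spatially uniform wall shear of pulsatile pipe flow for a
#'   [womersley_spec()], via the analytic Bessel-function wall gradient.
#'
#' @param pattern one of `"uniform"`, `"reversing"`, `"offset_sine"`,
#'   `"spot"`, `"ramp"`, `"womersley"`.
#' @param mesh a [labeled_surface_mesh()] with a non-empty sac.
#' @param n_times number of time samples over the cycle (endpoints
#'   included).
#' @param period cycle duration, s.
#' @param amplitude,offset magnitudes in Pa (pattern-specific).
#' @param high,low,spot_fraction spot-pattern parameters (Pa, Pa, area
#'   fraction).
#' @param gradient ramp slope, Pa/mm.
#' @param direction unit 3-vector for the shear direction.
#' @param womersley a [womersley_spec()] for `pattern = "womersley"`.
#' @param location `"face"` or `"vertex"` centering of the generated series.
#' @return List with `series` (a [surface_series()]) and `truth`, a named
#'   list of expected indicator values (`NA` where no closed form applies).
#' @export
analytic_wss_series <- function(pattern = c(
                                  "uniform", "reversing", "offset_sine",
                                  "spot", "ramp", "womersley"
                                ),
                                mesh, n_times = 64, period = 0.949,
                                amplitude = 2, offset = 4,
                                high = 10, low = 1, spot_fraction = 0.1,
                                gradient = 0.5,
                                direction = c(1, 0, 0),
                                womersley = NULL,
                                location = c("face", "vertex")) {
  pattern <- match.arg(pattern)
  location <- match.arg(location)
  stopifnot(inherits(mesh, "labeled_surface_mesh"))
  direction <- direction / sqrt(sum(direction^2))
  times <- seq(0, period, length.out = n_times)
  omega <- 2 * pi / period
  n_loc <- if (location == "face") nrow(mesh$triangles) else nrow(mesh$vertices)

  make_series <- function(mag_loc_time) {
    vals <- array(0, c(n_loc, 3L, n_times))
    for (k in 1:3) vals[, k, ] <- mag_loc_time * direction[k]
    surface_series(times, vals, location = location, periodic = TRUE)
  }
  sel <- mesh$face_region == "sac"
  a_a <- sum(mesh$face_area[sel])

  if (pattern == "uniform") {
    series <- make_series(matrix(amplitude, n_loc, n_times))
    truth <- list(
      awss = amplitude, mwss = amplitude, osi = 0, lsa = 0, sci = 0,
      wssg = 0, tdwss = 0
    )
  } else if (pattern == "reversing") {
    mag_t <- amplitude * sin(omega * times)
    series <- make_series(matrix(mag_t, n_loc, n_times, byrow = TRUE))
    truth <- list(
      awss = 2 * amplitude / pi, mwss = 2 * amplitude / pi, osi = 0.5,
      lsa = 0, sci = 0, wssg = 0,
      tdwss = dense_time_average(
        function(t) amplitude * omega * cos(omega * t), period
      )
    )
  } else if (pattern == "offset_sine") {
    if (offset <= amplitude) stop("offset_sine requires offset > amplitude")
    mag_t <- offset + amplitude * sin(omega * times)
    series <- make_series(matrix(mag_t, n_loc, n_times, byrow = TRUE))
    truth <- list(
      awss = offset, mwss = offset, osi = 0, lsa = 0, sci = 0, wssg = 0,
      tdwss = dense_time_average(
        function(t) amplitude * omega * cos(omega * t), period
      )
    )
  } else if (pattern == "spot") {
    if (location != "face") stop("spot pattern is face-centered")
    # grow the spot from the sac face nearest the +z pole of the sac
    ctr <- (mesh$vertices[mesh$triangles[, 1L], , drop = FALSE] +
      mesh$vertices[mesh$triangles[, 2L], , drop = FALSE] +
      mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]) / 3
    sac_idx <- which(sel)
    ord <- sac_idx[order(-ctr[sac_idx, 3L])]
    cum <- cumsum(mesh$face_area[ord])
    n_spot <- max(1L, sum(cum <= spot_fraction * a_a))
    spot_faces <- ord[seq_len(n_spot)]
    mag <- rep(low, n_loc)
    mag[spot_faces] <- high
    series <- make_series(matrix(mag, n_loc, n_times))
    # hand evaluation of the definitions with the realized areas
    a_h <- sum(mesh$face_area[spot_faces])
    f <- a_h / a_a
    awss_t <- f * high + (1 - f) * low
    mu <- awss_t
    sdv <- sqrt(f * (high - mu)^2 + (1 - f) * (low - mu)^2)
    thr <- mu + sdv
    hi_set <- if (high > thr) f else 0
    sci_t <- if (hi_set > 0) (f * high / awss_t) / f else 0
    lsa_t <- if (low < 0.1 * awss_t) 1 - f else 0
    truth <- list(
      awss = awss_t, mwss = high, osi = 0, lsa = lsa_t, sci = sci_t,
      wssg = NA_real_, tdwss = 0, spot_fraction_realized = f
    )
  } else if (pattern == "ramp") {
    if (location != "vertex") stop("ramp pattern is vertex-centered")
    x <- mesh$vertices[, 1L]
    mag <- gradient * x
    series <- make_series(matrix(mag, n_loc, n_times))
    ctr_x <- (x[mesh$triangles[, 1L]] + x[mesh$triangles[, 2L]] +
      x[mesh$triangles[, 3L]]) / 3
    awss_t <- sum(abs(gradient * ctr_x[sel]) * mesh$face_area[sel]) / a_a
    truth <- list(
      awss = awss_t, mwss = NA_real_, osi = 0, lsa = NA_real_,
      sci = NA_real_, wssg = abs(gradient), tdwss = 0
    )
  } else { # womersley
    if (is.null(womersley)) womersley <- womersley_spec(radius_mm = 2)
    tau_fun <- function(t) womersley_wall_shear(womersley, t)
    mag_t <- tau_fun(times)
    series <- make_series(matrix(mag_t, n_loc, n_times, byrow = TRUE))
    aw <- dense_time_average(tau_fun, womersley$period)
    t_dense <- seq(0, womersley$period, length.out = 20001L)
    signed_avg <- sum(tau_fun(t_dense) * trapezoid_weights(t_dense))
    truth <- list(
      awss = aw, mwss = aw,
      osi = 0.5 * (1 - abs(signed_avg) / aw), lsa = 0, sci = 0,
      wssg = 0,
      tdwss = dense_time_average(
        function(t) wall_shear_time_derivative(womersley, t),
        womersley$period
      )
    )
  }
  list(series = series, truth = truth, pattern = pattern)
}

#' Analytic wall shear of the Womersley profile
#'
#' The signed wall shear stress `tau(t) = -mu du/dr` at `r = R` of pulsatile
#' pipe flow: the steady part is the Poiseuille value `4 mu ubar / R`, each
#' harmonic contributes its Bessel-function wall gradient.
#'
#' @param spec a [womersley_spec()].
#' @param t time(s), s.
#' @return Wall shear in Pa (radius converted to m internally).
#' @export
womersley_wall_shear <- function(spec, t) {
  R_m <- spec$radius_mm / 1000
  ubar <- spec$target_mean_velocity
  tau <- rep(4 * spec$mu * ubar / R_m, length(t))
  omega <- 2 * pi / spec$period
  i32 <- complex(modulus = 1, argument = 3 * pi / 4)
  for (n in seq_along(spec$rel_harmonics)) {
    alpha_n <- womersley_alpha(
      spec$radius_mm, spec$period, spec$mu, spec$rho,
      harmonic = n
    )
    lam <- i32 * alpha_n
    j0l <- besselJ_complex(lam, 0L)
    j1l <- besselJ_complex(lam, 1L)
    denom <- 1 - 2 * j1l / (lam * j0l)
    cn <- 2 * ubar * spec$rel_harmonics[n]
    dshape_dr_wall <- (lam / R_m) * j1l / (j0l * denom)
    tau <- tau + Re(-spec$mu * cn * dshape_dr_wall * exp(1i * n * omega * t))
  }
  tau # tau = -mu du/dr, positive for forward flow
}

# d tau / dt of the Womersley wall shear (for the temporal indicator oracle).
wall_shear_time_derivative <- function(spec, t) {
  omega <- 2 * pi / spec$period
  R_m <- spec$radius_mm / 1000
  ubar <- spec$target_mean_velocity
  i32 <- complex(modulus = 1, argument = 3 * pi / 4)
  d <- rep(0, length(t))
  for (n in seq_along(spec$rel_harmonics)) {
    alpha_n <- womersley_alpha(
      spec$radius_mm, spec$period, spec$mu, spec$rho,
      harmonic = n
    )
    lam <- i32 * alpha_n
    j0l <- besselJ_complex(lam, 0L)
    j1l <- besselJ_complex(lam, 1L)
    denom <- 1 - 2 * j1l / (lam * j0l)
    cn <- 2 * ubar * spec$rel_harmonics[n]
    term <- spec$mu * cn * (lam / R_m) * j1l / (j0l * denom)
    d <- d + Re(term * 1i * n * omega * exp(1i * n * omega * t))
  }
  d
}
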