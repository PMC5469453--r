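# Boundary-condition constructions (pulsatile waveform, Womersley inflow
# profile, Murray's-law resistance outlets) and the mesh-resolution /
# timestep arithmetic of a grid-refinement study.
#
# Physical defaults: blood viscosity mu = 3.45 mPa s, density rho = 1056
# kg/m^3, cardiac period T = 0.949 s (63 bpm), mean inflow velocity 0.27 m/s.

#' Periodic flow-rate waveform
#'
#' One cardiac cycle of a volumetric flow rate on a uniform time grid, with
#' the first and last samples at the same phase (Q(0) = Q(T)).
#'
#' @param samples flow-rate samples, ml/min, including both endpoints.
#' @param period cycle duration T, s.
#' @return Object of class `flow_waveform` with elements `times`, `q`,
#'   `period`, `mean` (cycle average, ml/min) and `pulsatility`
#'   (peak-to-peak amplitude, ml/min).
#' @export
flow_waveform <- function(samples, period = 0.949) {
  samples <- as.numeric(samples)
  if (length(samples) < 4L) stop("waveform needs at least 4 samples")
  if (abs(samples[1L] - samples[length(samples)]) >
    1e-9 * max(abs(samples), 1e-300)) {
    stop("waveform must be periodic: first and last samples must agree")
  }
  times <- seq(0, period, length.out = length(samples))
  w <- trapezoid_weights(times)
  m <- sum(samples * w)
  if (m <= 0) stop("waveform mean must be positive")
  structure(
    list(
      times = times, q = samples, period = period, mean = m,
      pulsatility = max(samples) - min(samples)
    ),
    class = "flow_waveform"
  )
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf(
    "flow_waveform: T = %.4g s (%.1f bpm), mean %.4g ml/min, peak-to-peak %.4g\n",
    x$period, 60 / x$period, x$mean, x$pulsatility
  ))
  invisible(x)
}

# Relative harmonic content of an internal-carotid-like flow pulse: sharp
# systolic upstroke, dicrotic notch, diastolic decay. Columns: amplitude of
# cos(n w t - phase) relative to the mean.
ICA_HARMONICS <- cbind(
  amplitude = c(0.330, 0.240, 0.120, 0.050, 0.020),
  phase = c(1.2, 2.0, 2.7, 3.2, 3.8)
)

#' Generate a carotid-like pulsatile waveform
#'
#' A band-limited stand-in for a measured internal-carotid flow pulse: the
#' mean plus a small number of harmonics with fixed relative amplitudes and
#' phases, sampled on a uniform grid. Being exactly band-limited, its
#' discrete Fourier coefficients are recovered exactly, which makes
#' Womersley-profile flux reproduction testable to round-off.
#'
#' @param mean_flow cycle-mean flow rate, ml/min.
#' @param period cycle duration, s.
#' @param n_samples samples per cycle (including the repeated endpoint).
#' @param harmonics two-column matrix (`amplitude`, `phase`) of relative
#'   harmonic content; defaults to the built-in carotid-like shape.
#' @return A [flow_waveform()].
#' @export
carotid_waveform <- function(mean_flow = 245, period = 0.949,
                             n_samples = 200, harmonics = ICA_HARMONICS) {
  t <- seq(0, period, length.out = n_samples)
  rel <- rep(1, n_samples)
  for (n in seq_len(nrow(harmonics))) {
    rel <- rel + harmonics[n, 1L] *
      cos(2 * pi * n * t / period - harmonics[n, 2L])
  }
  if (min(rel) <= 0) stop("harmonic content produces reverse flow")
  flow_waveform(mean_flow * rel, period)
}

#' Reduce the pulsatility of a waveform
#'
#' Contracts the waveform about its mean: `Q'(t) = mean + (1 - fraction) *
#' (Q(t) - mean)`. The cycle mean is preserved exactly; the peak-to-peak
#' amplitude shrinks by the given fraction. A 15% reduction is the
#' conventional allowance for dampening of the pulse along the carotid
#' siphon between the measurement site and the middle cerebral artery.
#'
#' @param w a [flow_waveform()].
#' @param fraction fraction of the pulsatility to remove, in `[0, 1)`.
#' @return A [flow_waveform()] with the same mean.
#' @export
dampen_pulsatility <- function(w, fraction = 0.15) {
  stopifnot(inherits(w, "flow_waveform"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  flow_waveform(w$mean + (1 - fraction) * (w$q - w$mean), w$period)
}

## ---- Womersley profile ----

# Bessel J0 / J1 for complex argument by power series; adequate for the
# |z| <~ 30 range arising from physiological Womersley numbers.
besselJ_complex <- function(z, nu) {
  stopifnot(nu %in% c(0L, 1L))
  term <- (0i + z / 2)^nu # k = 0 term; 0!, nu! are both 1 here
  total <- term
  zz <- -(z / 2)^2
  for (k in seq_len(300L)) {
    term <- term * zz / (k * (k + nu))
    total <- total + term
    if (all(Mod(term) <= 1e-17 * pmax(Mod(total), 1e-300))) break
  }
  total
}

#' Womersley number
#'
#' `alpha = R * sqrt(omega / nu)` with `omega = 2 pi / T` and kinematic
#' viscosity `nu = mu / rho`; the dimensionless ratio of pulsatile to viscous
#' effects that sets the shape of pulsatile pipe-flow profiles.
#'
#' @param radius_mm vessel radius, mm.
#' @param period cardiac period, s.
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @param harmonic harmonic index (alpha scales with sqrt(n)).
#' @return alpha, dimensionless.
#' @export
womersley_alpha <- function(radius_mm, period = 0.949, mu = 3.45e-3,
                            rho = 1056, harmonic = 1) {
  omega <- 2 * pi * harmonic / period
  (radius_mm / 1000) * sqrt(omega / (mu / rho))
}

#' Womersley inflow specification
#'
#' Packages the geometry, fluid constants and waveform harmonics needed to
#' evaluate the pulsatile (Womersley) velocity profile in a circular pipe.
#' The profile is scaled with the cross-sectional area so that the cycle-mean
#' cross-section-average velocity equals `target_mean_velocity`; the
#' waveform contributes only its relative shape.
#'
#' @param radius_mm pipe radius R, mm.
#' @param waveform a [flow_waveform()]; its shape (normalized by its mean)
#'   sets the harmonic content.
#' @param target_mean_velocity cycle-mean cross-section-average velocity,
#'   m/s.
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @param n_harmonics harmonics retained from the waveform's discrete
#'   Fourier transform.
#' @return Object of class `womersley_spec`.
#' @export
womersley_spec <- function(radius_mm, waveform = carotid_waveform(),
                           target_mean_velocity = 0.27, mu = 3.45e-3,
                           rho = 1056, n_harmonics = 8) {
  stopifnot(radius_mm > 0, target_mean_velocity > 0, mu > 0, rho > 0)
  stopifnot(inherits(waveform, "flow_waveform"))
  # DFT on the open grid (duplicate endpoint dropped)
  q <- waveform$q[-length(waveform$q)]
  np <- length(q)
  n_harmonics <- min(n_harmonics, floor((np - 1) / 2))
  coef <- stats::fft(q) / np
  rel <- coef[1 + seq_len(n_harmonics)] / Re(coef[1L]) # harmonics / mean
  structure(
    list(
      radius_mm = radius_mm, period = waveform$period,
      target_mean_velocity = target_mean_velocity,
      mu = mu, rho = rho, rel_harmonics = rel
    ),
    class = "womersley_spec"
  )
}

#' Evaluate the Womersley axial velocity
#'
#' Axial velocity of pulsatile laminar pipe flow at radial position `r` and
#' time `t`: the zeroth harmonic is the Poiseuille parabola
#' `2 ubar (1 - r^2/R^2)`; each higher harmonic is the classical
#' Bessel-function solution
#' `u_n(r) = c_n [1 - J0(L r/R)/J0(L)] / [1 - 2 J1(L)/(L J0(L))]`,
#' `L = i^(3/2) alpha_n`, with complex amplitude `c_n` set by the waveform's
#' Fourier coefficients so that the cross-sectional flux reproduces the
#' (band-limited) waveform exactly.
#'
#' @param spec a [womersley_spec()].
#' @param r_mm radial position(s), mm, in `[0, R]`.
#' @param t time(s), s.
#' @return Matrix of axial velocities (m/s), `length(r_mm) x length(t)`,
#'   dropped to a vector when either argument has length 1.
#' @export
womersley_velocity <- function(spec, r_mm, t) {
  stopifnot(inherits(spec, "womersley_spec"))
  if (any(r_mm < 0 | r_mm > spec$radius_mm)) {
    stop("radial position outside [0, R]")
  }
  R <- spec$radius_mm
  ubar <- spec$target_mean_velocity
  omega <- 2 * pi / spec$period
  xi <- r_mm / R
  u <- outer(2 * ubar * (1 - xi^2), rep(1, length(t))) # Poiseuille base
  i32 <- complex(modulus = 1, argument = 3 * pi / 4) # i^(3/2)
  for (n in seq_along(spec$rel_harmonics)) {
    alpha_n <- womersley_alpha(R, spec$period, spec$mu, spec$rho, harmonic = n)
    lam <- i32 * alpha_n
    j0l <- besselJ_complex(lam, 0L)
    j1l <- besselJ_complex(lam, 1L)
    shape <- (1 - besselJ_complex(lam * xi, 0L) / j0l) /
      (1 - 2 * j1l / (lam * j0l))
    # factor 2: one-sided harmonic amplitude relative to the complex DFT
    cn <- 2 * ubar * spec$rel_harmonics[n]
    u <- u + Re(outer(cn * shape, exp(1i * n * omega * t)))
  }
  drop(u)
}

#' Cross-sectional flux of the Womersley profile
#'
#' Integrates `u(r, t) * 2 pi r dr` over the pipe section by high-resolution
#' midpoint quadrature in `r^2` (exact for the parabolic base profile).
#'
#' @param spec a [womersley_spec()].
#' @param t time(s), s.
#' @param n_r number of radial quadrature shells.
#' @return Flux in m^3/s at each `t` (radius converted from mm).
#' @export
womersley_flux <- function(spec, t, n_r = 400) {
  R_m <- spec$radius_mm / 1000
  # uniform shells in r^2: exact midpoint quadrature for smooth profiles
  s_mid <- (seq_len(n_r) - 0.5) / n_r # r^2 / R^2 at shell midpoints
  r_mm <- sqrt(s_mid) * spec$radius_mm
  u <- womersley_velocity(spec, r_mm, t)
  u <- matrix(u, nrow = length(r_mm))
  as.numeric(pi * R_m^2 / n_r * colSums(u))
}

## ---- Murray's-law outlets ----

#' Resistance outlet pressure from Murray's law
#'
#' The outlet pressure `p_i = K * (sum_j r_j^3 / r_i^3) * flux_i`, a pure
#' resistance proportional to the inverse cube of the outlet radius relative
#' to its siblings, which distributes flow according to the principle of
#' minimum work (flow proportional to radius cubed).
#'
#' @param radius_mm radius of outlet i, mm.
#' @param sibling_radii_mm radii of all outlets at the junction (including
#'   outlet i), mm.
#' @param flux flux through outlet i, m^3/s.
#' @param K resistance constant, kg m^-4 s^-1.
#' @return Pressure in Pa.
#' @export
murray_outlet_pressure <- function(radius_mm, sibling_radii_mm, flux,
                                   K = 1e9) {
  if (any(c(radius_mm, sibling_radii_mm) <= 0)) stop("radii must be positive")
  K * (sum(sibling_radii_mm^3) / radius_mm^3) * flux
}

#' Lumped-network flow split across resistance outlets
#'
#' Solves the lumped linear system of a single junction feeding `n` outlets
#' with resistances `R_i = K * sum_j r_j^3 / r_i^3` and a common junction
#' pressure: unknown flows and pressure satisfy `R_i Q_i = p` and
#' `sum Q_i = total`. The solution distributes flow in proportion to radius
#' cubed (Murray's law).
#'
#' @param radii_mm outlet radii, mm (at least 2).
#' @param total_flow total flow to distribute (any unit; split is linear).
#' @param K resistance constant, kg m^-4 s^-1.
#' @return Named list: `flows` (per outlet, same order), `pressure` (junction
#'   pressure, consistent units), `resistances`.
#' @export
murray_flow_split <- function(radii_mm, total_flow, K = 1e9) {
  n <- length(radii_mm)
  if (n < 2L) stop("need at least 2 outlets")
  if (any(radii_mm <= 0)) stop("radii must be positive")
  res <- K * sum(radii_mm^3) / radii_mm^3
  # unknowns x = (Q_1..Q_n, p/K): (R_i/K) Q_i - p/K = 0; sum Q_i = total.
  # Solving in units of K keeps the system well-conditioned for K ~ 1e9.
  a <- cbind(diag(res / K, n), -1)
  a <- rbind(a, c(rep(1, n), 0))
  b <- c(rep(0, n), total_flow)
  x <- solve(a, b)
  list(flows = x[seq_len(n)], pressure = K * x[n + 1L], resistances = res)
}

## ---- Mesh-resolution and timestep arithmetic ----

#' Boundary-layer sublayer schedule
#'
#' Thicknesses of `n` prismatic sublayers forming a geometric sequence with
#' the given ratio and summing to `total_fraction` of the target nodal
#' distance, returned thickest first. With the defaults (total 0.3 h, 4
#' sublayers, ratio 0.6) the innermost sublayer comes out at about 0.03 h.
#'
#' @param total_fraction total boundary-layer thickness as a fraction of the
#'   target nodal distance h.
#' @param n_sublayers number of sublayers.
#' @param ratio thickness ratio between consecutive sublayers, in (0, 1].
#' @return Numeric vector of length `n_sublayers`, thickest to thinnest,
#'   summing to `total_fraction`.
#' @export
boundary_layer_schedule <- function(total_fraction = 0.3, n_sublayers = 4,
                                    ratio = 0.6) {
  stopifnot(total_fraction > 0, n_sublayers >= 1, ratio > 0, ratio <= 1)
  geom <- ratio^(seq_len(n_sublayers) - 1L)
  total_fraction * geom / sum(geom)
}

#' Courant (CFL) number
#'
#' `CFL = u * dt / h`, with velocity in m/s, timestep in s and nodal
#' distance in mm (converted internally).
#'
#' @param u velocity, m/s.
#' @param dt timestep, s.
#' @param h_mm nodal distance, mm.
#' @return CFL, dimensionless.
#' @export
courant_number <- function(u, dt, h_mm) {
  stopifnot(u >= 0, dt > 0, h_mm > 0)
  u * dt / (h_mm / 1000)
}

#' Timesteps per cycle
#'
#' @param period cycle duration, s.
#' @param dt timestep, s.
#' @return Integer number of steps covering one cycle.
#' @export
timestep_count <- function(period, dt) {
  stopifnot(period > 0, dt > 0)
  as.integer(round(period / dt))
}

#' Effective resolution of a higher-order discretization
#'
#' With polynomial order `p`, each cell carries `p` intervals of degrees of
#' freedom per edge, so the effective nodal spacing is `h / p` (0.13 mm
#' piecewise-quadratic cells resolve like 0.065 mm linear ones).
#'
#' @param h_mm nodal distance, mm.
#' @param order polynomial order of the velocity space (>= 1).
#' @return Effective resolution in mm.
#' @export
effective_resolution <- function(h_mm, order = 2) {
  stopifnot(h_mm > 0, order >= 1)
  h_mm / order
}

#' Linear-element equivalent of a quadratic tetrahedral mesh
#'
#' A quadratic tetrahedron carries the degrees of freedom of 8 linear ones
#' (one uniform refinement), so `n` quadratic cells correspond to `8 n`
#' linear elements.
#'
#' @param n_cells number of quadratic tetrahedra.
#' @return Equivalent linear element count.
#' @export
linear_element_equivalent <- function(n_cells) {
  stopifnot(n_cells > 0)
  8 * n_cells
}

#' Mesh sizing report
#'
#' Collects the resolution arithmetic for one refinement level: sublayer
#' schedule, effective resolution and the CFL number for a reference
#' velocity.
#'
#' @param h_mm target nodal distance, mm.
#' @param period cycle duration, s.
#' @param n_steps timesteps per cycle.
#' @param u_ref reference velocity for the CFL bound, m/s.
#' @param order velocity polynomial order.
#' @param parent_factor nodal-distance factor for the parent artery.
#' @param far_factor nodal-distance factor furthest from the aneurysm.
#' @return Named list with the derived quantities.
#' @export
mesh_sizing_report <- function(h_mm, period = 0.949, n_steps = 8000,
                               u_ref = 1.5, order = 2, parent_factor = 1.25,
                               far_factor = 2) {
  dt <- period / n_steps
  list(
    h_mm = h_mm,
    parent_h_mm = parent_factor * h_mm,
    far_h_mm = far_factor * h_mm,
    sublayers = boundary_layer_schedule(),
    effective_h_mm = effective_resolution(h_mm, order),
    dt_s = dt,
    cfl = courant_number(u_ref, dt, h_mm)
  )
}
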