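# End-to-end orchestration: per-case indicator rows and the full
# two-resolution cohort study (agreement + group tests + correlations).

#' Run configuration
#'
#' Collects the physical constants and threshold conventions of a run so
#' that every configurable choice is explicit, serializable and
#' overridable. Round-trips losslessly through JSON.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @param period cardiac period, s.
#' @param lsa_threshold_fraction low-shear threshold as a fraction of the
#'   reference WSS.
#' @param sci_n_sd standard deviations above the mean for the high-shear
#'   threshold.
#' @param mwss_variant `"time_averaged"` or `"space_time"`.
#' @param near_vessel_cutoff_mm geodesic extent of the near-vessel domain,
#'   mm.
#' @param seed integer seed for any stochastic stage.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(mu = 3.45e-3, rho = 1056, period = 0.949,
                       lsa_threshold_fraction = 0.1, sci_n_sd = 1,
                       mwss_variant = "time_averaged",
                       near_vessel_cutoff_mm = 10, seed = 1) {
  stopifnot(mu > 0, rho > 0, period > 0)
  structure(
    list(
      mu = mu, rho = rho, period = period,
      lsa_threshold_fraction = lsa_threshold_fraction,
      sci_n_sd = sci_n_sd, mwss_variant = mwss_variant,
      near_vessel_cutoff_mm = near_vessel_cutoff_mm, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Write / read a run configuration as JSON
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' Compute all indicators for one case
#'
#' Runs the full indicator battery on one case: the seven WSS-based
#' indicators from the WSS series, VDR from the velocity series (when
#' given), ICI from the neck-flow data (when given), and the three
#' morphological indicators from the labeled surface. Missing inputs yield
#' `NA` for the indicators that need them; everything else is still
#' computed.
#'
#' @param case_id case identifier.
#' @param mesh a [labeled_surface_mesh()] with sac and neck regions.
#' @param wss a [surface_series()] of WSS vectors.
#' @param vel optional [volume_series()] for VDR.
#' @param neck_flow optional list with `u_neck` (matrix, neck faces x
#'   times, m/s into the sac), `neck_area` (mm^2 per face), `qpa` (parent
#'   flux per time) and `times` for ICI.
#' @param config a [run_config()].
#' @return One-row data frame: `case_id`, the 9 hemodynamic and 3
#'   morphological indicators.
#' @export
run_case <- function(case_id, mesh, wss, vel = NULL, neck_flow = NULL,
                     config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hi <- list(
    awss = awss(wss, mesh),
    mwss = mwss(wss, mesh, variant = config$mwss_variant),
    osi = osi(wss, mesh),
    lsa = lsa(wss, mesh, threshold_fraction = config$lsa_threshold_fraction),
    vdr = if (is.null(vel)) NA_real_ else vdr(vel, mu = config$mu, rho = config$rho),
    ici = if (is.null(neck_flow)) {
      NA_real_
    } else {
      ici(neck_flow$u_neck, neck_flow$neck_area, neck_flow$qpa, neck_flow$times)
    },
    sci = sci(wss, mesh, n_sd = config$sci_n_sd),
    wssg = if (wss$location == "vertex") wssg(wss, mesh) else NA_real_,
    tdwss = tdwss(wss, mesh)
  )
  mo <- morphology_indicators(mesh)
  data.frame(
    case_id = case_id, hi,
    ar = mo$ar, nsi = mo$nsi, volume = mo$volume_mm3
  )
}

#' Run the full two-resolution cohort study
#'
#' Generates (or accepts) a paired coarse/fine indicator cohort and
#' produces the complete robustness analysis: per-indicator coarse-vs-fine
#' agreement (correlation, mean relative difference, logarithmic
#' Bland-Altman with zero-pair exclusion), normality-gated rupture-group
#' comparisons at both resolutions, and the indicator cross-correlation
#' matrix at the fine resolution.
#'
#' @param spec a [cohort_spec()] used to synthesize the cohort, ignored
#'   when `fine`/`coarse` tables are supplied.
#' @param fine,coarse optional pre-computed indicator tables (data frames
#'   with `case_id`, `ruptured` and indicator columns).
#' @param seed seed for the synthetic cohort.
#' @return List with `agreement` (an [agreement_report()]),
#'   `group_tests_fine`, `group_tests_coarse` (data frames),
#'   `correlations` (from [indicator_correlation_matrix()]), `cohort`
#'   (the tables used) and `truth` (generator ground truth, when
#'   synthesized).
#' @export
run_cohort_study <- function(spec = cohort_spec(), fine = NULL, coarse = NULL,
                             seed = 1) {
  truth <- NULL
  if (is.null(fine) || is.null(coarse)) {
    cohort <- synthetic_cohort(spec, seed = seed)
    fine <- cohort$fine
    coarse <- cohort$coarse
    truth <- cohort$truth
  }
  ind_cols <- setdiff(
    names(fine)[vapply(fine, is.numeric, logical(1L))],
    c("case_id")
  )
  list(
    agreement = agreement_report(coarse, fine, indicators = ind_cols),
    group_tests_fine = group_test_table(fine, indicators = ind_cols),
    group_tests_coarse = group_test_table(coarse, indicators = ind_cols),
    correlations = indicator_correlation_matrix(fine, indicators = ind_cols),
    cohort = list(fine = fine, coarse = coarse),
    truth = truth
  )
}
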