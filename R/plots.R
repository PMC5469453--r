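# Diagnostic plots for agreement analyses (ggplot2, Suggests-only).

needs_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package")
  }
}

#' Logarithmic Bland-Altman panel for an agreement report
#'
#' One panel per indicator: log2 coarse/fine ratio against the normalized
#' log2 geometric-mean magnitude, with the mean ratio and 95% limits of
#' agreement as horizontal lines.
#'
#' @param report an [agreement_report()].
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report) {
  needs_ggplot()
  stopifnot(inherits(report, "agreement_report"))
  pts <- do.call(rbind, lapply(names(report$detail), function(nm) {
    ba <- report$detail[[nm]]$bland_altman
    if (is.null(ba)) {
      return(NULL)
    }
    cbind(indicator = nm, ba$points)
  }))
  lims <- do.call(rbind, lapply(names(report$detail), function(nm) {
    ba <- report$detail[[nm]]$bland_altman
    if (is.null(ba)) {
      return(NULL)
    }
    data.frame(
      indicator = nm, mean = ba$mean_log2_ratio,
      lower = ba$limits[["lower"]], upper = ba$limits[["upper"]]
    )
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(
      data = lims, ggplot2::aes(yintercept = mean),
      linetype = "solid"
    ) +
    ggplot2::geom_hline(
      data = lims, ggplot2::aes(yintercept = lower),
      linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      data = lims, ggplot2::aes(yintercept = upper),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~indicator, scales = "free") +
    ggplot2::labs(
      x = "log2 geometric mean (normalized)",
      y = "log2 coarse / fine"
    )
}

#' Coarse-vs-fine correlation panel
#'
#' Scatter of coarse against fine values per indicator (both normalized by
#' the maximum fine value) with the identity line.
#'
#' @param coarse,fine paired indicator tables.
#' @param indicators indicator columns to plot.
#' @return A ggplot object.
#' @export
plot_resolution_correlation <- function(coarse, fine, indicators) {
  needs_ggplot()
  pts <- do.call(rbind, lapply(indicators, function(nm) {
    nmax <- max(fine[[nm]])
    data.frame(
      indicator = nm, fine = fine[[nm]] / nmax,
      coarse = coarse[[nm]] / nmax
    )
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = fine, y = coarse)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~indicator, scales = "free") +
    ggplot2::labs(x = "fine (normalized)", y = "coarse (normalized)")
}
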