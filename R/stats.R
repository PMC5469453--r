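# Coarse-vs-fine agreement statistics (correlation, mean relative
# difference, logarithmic Bland-Altman with the zero-pair exclusion rule),
# normality-gated rupture-group comparison, and the indicator
# cross-correlation matrix.

#' Mean relative difference between paired resolutions
#'
#' `d = mean((coarse_i - fine_i) / fine_i)` over the included pairs: the
#' average signed deviation of the coarse value from the fine value as a
#' fraction of the fine value.
#'
#' @param coarse,fine paired numeric vectors of equal length.
#' @return d, a fraction (0.10 means the coarse values run 10% high).
#' @export
mean_relative_difference <- function(coarse, fine) {
  stopifnot(length(coarse) == length(fine))
  if (length(fine) == 0L) stop("no pairs to compare (all excluded?)")
  if (any(fine == 0)) {
    stop("fine values contain zeros; apply exclude_zero_pairs() first")
  }
  mean((coarse - fine) / fine)
}

#' Exclude pairs where either resolution is zero
#'
#' Ratio-based agreement measures (the mean relative difference and the
#' logarithmic Bland-Altman plot) are undefined when either member of a
#' pair is zero; such pairs are dropped and logged. Correlation is not
#' affected by this rule and should be computed on all pairs.
#'
#' @param coarse,fine paired numeric vectors.
#' @param ids optional case identifiers (defaults to indices).
#' @return List with `coarse`, `fine` (retained pairs), `included_ids`,
#'   `excluded_ids` and `n_excluded`.
#' @export
exclude_zero_pairs <- function(coarse, fine, ids = seq_along(fine)) {
  stopifnot(length(coarse) == length(fine), length(ids) == length(fine))
  drop <- coarse == 0 | fine == 0
  if (all(drop)) warning("all pairs have a zero member; nothing retained")
  list(
    coarse = coarse[!drop], fine = fine[!drop],
    included_ids = ids[!drop], excluded_ids = ids[drop],
    n_excluded = sum(drop)
  )
}

#' Logarithmic Bland-Altman analysis of a coarse/fine pair
#'
#' For each retained (positive) pair the plot coordinates are
#' `y = log2(coarse / fine)` (the resolution disagreement in doublings) and
#' `x = log2(sqrt(coarse * fine) / normalizer)` (the pair's geometric-mean
#' magnitude, normalized by the maximum fine value so that x = 0 marks the
#' largest case). Limits of agreement are `mean(y) +/- 1.96 sd(y)`.
#'
#' @param coarse,fine paired positive vectors (zeros must have been
#'   excluded beforehand).
#' @param normalizer magnitude normalizer; defaults to `max(fine)`.
#' @return List with `points` (data frame `x`, `y`), `mean_log2_ratio`,
#'   `limits` (length-2 vector) and `normalizer`.
#' @export
bland_altman_log <- function(coarse, fine, normalizer = max(fine)) {
  stopifnot(length(coarse) == length(fine))
  if (any(coarse <= 0 | fine <= 0)) {
    stop("non-positive values retained; apply exclude_zero_pairs() first")
  }
  y <- log2(coarse / fine)
  x <- log2(sqrt(coarse * fine) / normalizer)
  mu <- mean(y)
  s <- stats::sd(y)
  list(
    points = data.frame(x = x, y = y),
    mean_log2_ratio = mu,
    limits = c(lower = mu - 1.96 * s, upper = mu + 1.96 * s),
    normalizer = normalizer
  )
}

#' Coarse-vs-fine agreement report over an indicator table
#'
#' For each indicator column present in both tables: the Pearson
#' correlation over all pairs, the mean relative difference and logarithmic
#' Bland-Altman statistics over the zero-excluded pairs, and the exclusion
#' log.
#'
#' @param coarse,fine data frames with matching `case_id` and indicator
#'   columns.
#' @param indicators indicator column names; defaults to the intersection
#'   of numeric columns.
#' @return Object of class `agreement_report`: list with `summary` (data
#'   frame: indicator, r, d, n, n_excluded, loa_lower, loa_upper) and
#'   `detail` (per-indicator Bland-Altman points and exclusion ids).
#' @export
agreement_report <- function(coarse, fine, indicators = NULL) {
  stopifnot(is.data.frame(coarse), is.data.frame(fine))
  if (!identical(coarse$case_id, fine$case_id)) {
    bad <- union(
      setdiff(coarse$case_id, fine$case_id),
      setdiff(fine$case_id, coarse$case_id)
    )
    stop(
      "coarse and fine tables are not paired; mismatched case ids: ",
      paste(utils::head(bad, 10L), collapse = ", ")
    )
  }
  if (is.null(indicators)) {
    shared <- intersect(names(coarse), names(fine))
    indicators <- shared[vapply(
      shared,
      function(nm) is.numeric(coarse[[nm]]) && is.numeric(fine[[nm]]),
      logical(1L)
    )]
  }
  rows <- list()
  detail <- list()
  for (nm in indicators) {
    cv <- coarse[[nm]]
    fv <- fine[[nm]]
    r <- suppressWarnings(stats::cor(cv, fv))
    kept <- exclude_zero_pairs(cv, fv, ids = coarse$case_id)
    d <- if (length(kept$fine)) {
      mean_relative_difference(kept$coarse, kept$fine)
    } else {
      NA_real_
    }
    ba <- if (length(kept$fine) >= 2L && all(kept$coarse > 0)) {
      bland_altman_log(kept$coarse, kept$fine)
    } else {
      NULL
    }
    rows[[nm]] <- data.frame(
      indicator = nm, r = r, d = d, n = length(cv),
      n_excluded = kept$n_excluded,
      loa_lower = if (is.null(ba)) NA_real_ else ba$limits[["lower"]],
      loa_upper = if (is.null(ba)) NA_real_ else ba$limits[["upper"]]
    )
    detail[[nm]] <- list(bland_altman = ba, excluded_ids = kept$excluded_ids)
  }
  structure(
    list(summary = do.call(rbind, c(rows, make.row.names = FALSE)), detail = detail),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("agreement_report (coarse vs fine):\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Normality-gated two-group comparison
#'
#' Tests each group for normality with the Shapiro-Wilk test at level
#' `alpha`; when neither group rejects, the groups are compared with a
#' two-tailed two-sample t-test (classical equal-variance Student test by
#' default), otherwise with a two-sided Mann-Whitney U (Wilcoxon rank-sum)
#' test.
#'
#' @param values numeric vector of indicator values.
#' @param groups logical or two-level factor splitting the cases (e.g.
#'   ruptured vs unruptured).
#' @param alpha level for the normality gate.
#' @param var_equal passed to [stats::t.test()]; `TRUE` gives the classical
#'   Student test, `FALSE` the Welch variant.
#' @return List with `test` (`"t"` or `"mann_whitney"`), `p_value`, group
#'   `means`, `sds`, `n`, and `shapiro_p` (per group).
#' @export
gated_group_test <- function(values, groups, alpha = 0.05, var_equal = TRUE) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("groups must have exactly two levels")
  split_v <- split(values, g)
  if (any(vapply(split_v, length, integer(1L)) < 3L)) {
    stop("each group needs at least 3 observations for the normality gate")
  }
  sh <- vapply(split_v, function(v) stats::shapiro.test(v)$p.value, numeric(1L))
  normal <- all(sh >= alpha)
  res <- if (normal) {
    stats::t.test(values ~ g, var.equal = var_equal)
  } else {
    stats::wilcox.test(values ~ g, exact = FALSE, correct = TRUE)
  }
  list(
    test = if (normal) "t" else "mann_whitney",
    p_value = res$p.value,
    means = vapply(split_v, mean, numeric(1L)),
    sds = vapply(split_v, stats::sd, numeric(1L)),
    n = vapply(split_v, length, integer(1L)),
    shapiro_p = sh
  )
}

#' Group-comparison table over all indicators
#'
#' Applies [gated_group_test()] to every indicator column and shapes the
#' result like the rupture-comparison tables of grid-refinement studies:
#' one row per indicator with group means, SDs, the chosen test and its
#' p-value.
#'
#' @param table data frame with a logical `ruptured` column and indicator
#'   columns.
#' @param indicators indicator column names; defaults to all numeric
#'   columns except bookkeeping ones.
#' @param alpha normality-gate level.
#' @return Data frame: indicator, test, p_value, mean/sd/n per group.
#' @export
group_test_table <- function(table, indicators = NULL, alpha = 0.05) {
  stopifnot("ruptured" %in% names(table))
  if (is.null(indicators)) {
    indicators <- setdiff(
      names(table)[vapply(table, is.numeric, logical(1L))],
      c("case_id")
    )
  }
  g <- factor(ifelse(table$ruptured, "ruptured", "unruptured"),
    levels = c("ruptured", "unruptured")
  )
  rows <- lapply(indicators, function(nm) {
    gt <- gated_group_test(table[[nm]], g, alpha = alpha)
    data.frame(
      indicator = nm, test = gt$test, p_value = gt$p_value,
      mean_ruptured = gt$means[["ruptured"]],
      sd_ruptured = gt$sds[["ruptured"]],
      mean_unruptured = gt$means[["unruptured"]],
      sd_unruptured = gt$sds[["unruptured"]]
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Indicator cross-correlation matrix with significance flags
#'
#' Pairwise Pearson correlations across cases for all indicator columns,
#' with two-sided p-values flagged at the 0.05 and 0.001 levels. Constant
#' columns have no defined correlation and are reported as `NA`.
#'
#' @param table data frame of per-case indicator values.
#' @param indicators indicator column names; defaults to all numeric
#'   columns.
#' @return List with `r` (correlation matrix), `p` (p-value matrix) and
#'   `flags` (character matrix: `""`, `"*"` for p < 0.05, `"**"` for
#'   p < 0.001).
#' @export
indicator_correlation_matrix <- function(table, indicators = NULL) {
  if (is.null(indicators)) {
    indicators <- names(table)[vapply(table, is.numeric, logical(1L))]
  }
  x <- as.matrix(table[indicators])
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 cases for a correlation matrix")
  k <- length(indicators)
  r <- matrix(NA_real_, k, k, dimnames = list(indicators, indicators))
  p <- r
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (stats::sd(x[, i]) == 0 || stats::sd(x[, j]) == 0) next
      if (i == j) {
        r[i, j] <- 1
        p[i, j] <- 0
        next
      }
      ct <- stats::cor.test(x[, i], x[, j])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  flags <- matrix("", k, k, dimnames = dimnames(r))
  flags[!is.na(p) & p < 0.05] <- "*"
  flags[!is.na(p) & p < 0.001] <- "**"
  diag(flags) <- ""
  list(r = r, p = p, flags = flags)
}

#' Coefficient of variation
#'
#' The sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector with non-zero mean.
#' @return sd/mean, dimensionless.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  stats::sd(values) / m
}
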