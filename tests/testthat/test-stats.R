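# Agreement statistics, gated group tests and correlation matrices.

test_that("mean relative difference matches hand arithmetic", {
  expect_equal(mean_relative_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_relative_difference(1.1 * c(5, 9, 2), c(5, 9, 2)), 0.1)
  expect_equal(
    mean_relative_difference(c(2, 1, 3), c(1, 2, 3)),
    (1 - 0.5 + 0) / 3
  )
  expect_error(mean_relative_difference(c(1, 2), c(1, 0)), "zero")
  expect_error(mean_relative_difference(numeric(0), numeric(0)), "no pairs")
})

test_that("zero-pair exclusion drops the right cases and logs them", {
  coarse <- c(1, 0, 3, 4, 0)
  fine <- c(1, 2, 0, 4, 5)
  out <- exclude_zero_pairs(coarse, fine, ids = letters[1:5])
  expect_equal(out$included_ids, c("a", "d"))
  expect_equal(out$excluded_ids, c("b", "c", "e"))
  expect_equal(out$n_excluded, 3)
  expect_equal(out$coarse, c(1, 4))

  # no zeros: identity
  out2 <- exclude_zero_pairs(c(1, 2), c(3, 4))
  expect_equal(out2$n_excluded, 0)
  expect_equal(out2$coarse, c(1, 2))

  expect_warning(exclude_zero_pairs(c(0, 0), c(1, 0)), "nothing retained")
})

test_that("logarithmic Bland-Altman coordinates and limits are correct", {
  f <- c(1, 2, 4, 8)
  # identical pairs: all y = 0, zero-width limits
  ba0 <- bland_altman_log(f, f)
  expect_equal(ba0$points$y, rep(0, 4))
  expect_equal(unname(ba0$limits), c(0, 0))

  # coarse = 16 x fine: y = 4 doublings everywhere
  ba16 <- bland_altman_log(16 * f, f)
  expect_equal(ba16$points$y, rep(4, 4))

  # normalizer shifts x only, never y
  ba_a <- bland_altman_log(2 * f, f, normalizer = 1)
  ba_b <- bland_altman_log(2 * f, f, normalizer = 4)
  expect_equal(ba_a$points$y, ba_b$points$y)
  expect_equal(ba_a$points$x - ba_b$points$x, rep(log2(4), 4))

  # limits of agreement are mean +/- 1.96 sd of the log ratios
  set.seed(3)
  c2 <- f * exp(rnorm(4, 0, 0.2))
  ba <- bland_altman_log(c2, f)
  y <- log2(c2 / f)
  expect_equal(unname(ba$limits), mean(y) + c(-1.96, 1.96) * sd(y))

  expect_error(bland_altman_log(c(1, -1), c(1, 1)), "non-positive")
})

test_that("agreement_report combines correlation, d and exclusions", {
  co <- synthetic_cohort(seed = 11)
  rep_ <- agreement_report(co$coarse, co$fine)
  s <- rep_$summary

  # r uses all pairs, also when LSA zeros were excluded from d
  lsa_row <- s[s$indicator == "lsa", ]
  expect_equal(lsa_row$r, cor(co$coarse$lsa, co$fine$lsa))
  expect_equal(lsa_row$n, 38)
  keep <- co$coarse$lsa != 0 & co$fine$lsa != 0
  expect_equal(lsa_row$n_excluded, sum(!keep))
  expect_equal(
    lsa_row$d,
    mean((co$coarse$lsa[keep] - co$fine$lsa[keep]) / co$fine$lsa[keep])
  )

  # unpaired tables are rejected with the offending ids
  co2 <- co$coarse
  co2$case_id[1] <- "case_99"
  expect_error(agreement_report(co2, co$fine), "case_99")
})

test_that("normality gate picks the t-test or Mann-Whitney correctly", {
  # deterministic gating on fixed data
  set.seed(42)
  g <- rep(c(TRUE, FALSE), each = 19)
  v_norm <- rnorm(38)
  out_n <- gated_group_test(v_norm, g)
  expect_equal(out_n$test, "t")
  expect_equal(
    out_n$p_value,
    t.test(v_norm ~ g, var.equal = TRUE)$p.value
  )

  v_heavy <- exp(rnorm(38, 0, 2))
  out_h <- gated_group_test(v_heavy, g)
  expect_equal(out_h$test, "mann_whitney")
  expect_equal(
    out_h$p_value,
    wilcox.test(v_heavy ~ g, exact = FALSE)$p.value
  )

  # heavy-tailed groups route to Mann-Whitney in the vast majority of draws
  picks <- vapply(1:100, function(i) {
    set.seed(500 + i)
    gated_group_test(exp(rnorm(38, 0, 2)), g)$test
  }, character(1))
  expect_gte(mean(picks == "mann_whitney"), 0.9)

  # strongly separated groups are detected regardless of branch
  v_sep <- c(rnorm(19, 0, 0.1), rnorm(19, 10, 0.1))
  expect_lt(gated_group_test(v_sep, g)$p_value, 1e-3)

  expect_error(gated_group_test(rnorm(4), c(TRUE, TRUE, FALSE, FALSE)), "at least 3")
})

test_that("group_test_table mirrors the per-indicator gated tests", {
  co <- synthetic_cohort(seed = 2)
  tab <- group_test_table(co$fine)
  expect_true(all(c("ici", "nsi", "ar") %in% tab$indicator))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  row <- tab[tab$indicator == "ici", ]
  ref <- gated_group_test(co$fine$ici, co$fine$ruptured)
  expect_equal(row$p_value, ref$p_value)
})

test_that("correlation matrix flags significance and handles degeneracy", {
  set.seed(9)
  tab <- data.frame(a = rnorm(38), b = rnorm(38))
  tab$c <- tab$a + rnorm(38, 0, 0.1) # strongly correlated with a
  tab$d <- -tab$a # perfectly anti-correlated
  tab$e <- 1 # constant: undefined correlation

  out <- indicator_correlation_matrix(tab)
  expect_equal(diag(out$r)[1:4], rep(1, 4), ignore_attr = TRUE)
  expect_true(is.na(out$r["e", "e"])) # constant column: undefined
  expect_equal(out$r["a", "d"], -1)
  expect_equal(out$flags["a", "c"], "**")
  expect_true(is.na(out$r["a", "e"]))
  expect_equal(out$r["a", "b"], cor(tab$a, tab$b))

  # independent columns: false-positive rate of the p<0.05 flag ~ 5%
  set.seed(31)
  hits <- replicate(300, {
    x <- rnorm(38)
    y <- rnorm(38)
    cor.test(x, y)$p.value < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.03)

  expect_error(indicator_correlation_matrix(tab[1:2, ]), "at least 3")
})

test_that("coefficient of variation matches hand arithmetic and scaling", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  x <- c(2, 5, 9, 4)
  expect_equal(
    coefficient_of_variation(7 * x),
    coefficient_of_variation(x)
  )
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})
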