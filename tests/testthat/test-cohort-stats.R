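test_that("paired test: null identity, degeneracy flag, textbook oracle", {
  x <- c(5.1, 4.8, 6.0, 5.5)
  same <- paired_change_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  # constant shift: zero-variance differences are flagged, not p = 0
  shifted <- paired_change_test(c(1, 2, 3), c(2, 3, 4))
  expect_true(shifted$degenerate)
  expect_true(is.na(shifted$p_value))
  # textbook formula on random pairs
  set.seed(41)
  for (k in 1:10) {
    pre <- rnorm(8, 5, 1); post <- pre + rnorm(8, 0.5, 0.8)
    got <- paired_change_test(pre, post)
    d <- post - pre
    tstat <- mean(d) / (sd(d) / sqrt(8))
    expect_equal(got$statistic, tstat, tolerance = 1e-9)
    expect_equal(got$p_value, 2 * pt(-abs(tstat), 7), tolerance = 1e-9)
    expect_gte(got$p_value, 0); expect_lte(got$p_value, 1)
    # invariant to adding a constant to both periods
    expect_equal(paired_change_test(pre + 3, post + 3)$p_value, got$p_value)
  }
  expect_error(paired_change_test(1:3, 1:4), "paired")
})

test_that("between-group tests: null identity, U oracle, label symmetry", {
  a <- c(1, 2, 3)
  eq <- group_difference_test(a, a, "t")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # U by exhaustive enumeration: no a-value exceeds any b-value
  u <- group_difference_test(c(1, 2, 3), c(4, 5, 6), "u")
  expect_equal(u$statistic, 0)
  oracle_u <- sum(outer(c(1, 2, 3), c(4, 5, 6), ">")) +
    0.5 * sum(outer(c(1, 2, 3), c(4, 5, 6), "==") )
  expect_equal(u$statistic, oracle_u)
  set.seed(43)
  for (k in 1:10) {
    x <- rnorm(6); y <- rnorm(9, 0.4)
    for (m in c("t", "u")) {
      p1 <- group_difference_test(x, y, m)$p_value
      p2 <- group_difference_test(y, x, m)$p_value
      expect_equal(p1, p2, tolerance = 1e-12)
      expect_gte(p1, 0); expect_lte(p1, 1)
    }
    # Welch form against the direct formula
    tt <- group_difference_test(x, y, "t")
    se <- sqrt(var(x) / 6 + var(y) / 9)
    expect_equal(tt$statistic, (mean(x) - mean(y)) / se, tolerance = 1e-9)
  }
  expect_error(group_difference_test(1:3, 2:4, "anova"), "arg")
  expect_error(group_difference_test(1, 1:3, "t"), "at least 2")
})

test_that("chi-squared plumbing works on categorical labels", {
  a <- rep(c("m", "f"), c(6, 4))
  b <- rep(c("m", "f"), c(2, 5))
  res <- group_difference_test(a, b, "chisq")
  expect_equal(res$method, "chi-squared")
  expect_gte(res$p_value, 0); expect_lte(res$p_value, 1)
})

test_that("degree-of-change test composes delta computation with Welch's t", {
  set.seed(47)
  for (k in 1:10) {
    pre_a <- rnorm(10, 5); post_a <- pre_a + rnorm(10, 1)
    pre_b <- rnorm(7, 5); post_b <- pre_b + rnorm(7, 0.3)
    got <- change_difference_test(pre_a, post_a, pre_b, post_b)
    via <- group_difference_test(post_a - pre_a, post_b - pre_b, "t")
    expect_equal(got$statistic, via$statistic, tolerance = 1e-12)
    expect_equal(got$p_value, via$p_value, tolerance = 1e-12)
    # two-step oracle: deltas then the Welch formula
    da <- post_a - pre_a; db <- post_b - pre_b
    se <- sqrt(var(da) / 10 + var(db) / 7)
    tstat <- (mean(da) - mean(db)) / se
    df <- se^4 / ((var(da) / 10)^2 / 9 + (var(db) / 7)^2 / 6)
    expect_equal(got$statistic, tstat, tolerance = 1e-9)
    expect_equal(got$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-9)
  }
  d <- c(0.5, 0.7, 0.2)
  expect_equal(change_difference_test(c(1, 2, 3), c(1, 2, 3) + d,
                                      c(4, 5, 6), c(4, 5, 6) + d)$p_value, 1)
  expect_error(change_difference_test(1, 2, 1:3, 2:4), "at least 2")
})

test_that("group table assembles means, sds and the three p-value columns", {
  set.seed(53)
  mk <- function(g, n, pre_mu, post_mu)
    do.call(rbind, lapply(seq_len(n), function(i) data.frame(
      patient_id = sprintf("%s%02d", g, i), group = g,
      period = c("pre", "post"), metric = "pct_below_4",
      value = c(rnorm(1, pre_mu, 2), rnorm(1, post_mu, 2)))))
  vals <- rbind(mk("RYGB", 10, 9, 28), mk("OAGB", 7, 2, 38))
  tab <- build_group_table(vals)
  expect_equal(nrow(tab), 2)  # one metric x two groups
  # hypoglycaemia increases post-operatively in both groups
  expect_true(all(tab$mean_post > tab$mean_pre))
  expect_true(all(tab$p_within <= 1, na.rm = TRUE))
  first <- tab[tab$group == "RYGB", ]
  expect_true(is.finite(first$p_pre) && is.finite(first$p_post) &&
                is.finite(first$p_change))
  # direct recomputation of one cell
  ry <- vals[vals$group == "RYGB", ]
  expect_equal(first$mean_pre, mean(ry$value[ry$period == "pre"]))

  # single-group input: between-group columns stay empty
  tab1 <- build_group_table(mk("RYGB", 5, 9, 28))
  expect_equal(nrow(tab1), 1)
  expect_true(is.na(tab1$p_pre) && is.na(tab1$p_change))
  expect_false(is.na(tab1$p_within))

  # missing period is named
  broken <- rbind(mk("RYGB", 3, 9, 28))
  broken <- broken[-2, ]
  expect_error(build_group_table(broken), "RYGB01")
})
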