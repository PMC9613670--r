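test_that("group comparison picks the test the normality gate dictates", {
  set.seed(30)
  d <- make_labeled(rnorm(30, 0, 1), rnorm(30, 3, 1))
  d$percentile <- (d$percentile - min(d$percentile)) /
    diff(range(d$percentile)) * 100  # keep within [0, 100]
  r <- compare_groups(d, "passive")
  expect_equal(r$test, "t-test")
  expect_lt(r$p_value, 0.001)

  same <- make_labeled(seq(10, 90, length.out = 20),
                       seq(10, 90, length.out = 20))
  r2 <- compare_groups(same, "passive")
  expect_gt(r2$p_value, 0.95)

  # heavy skew: Lilliefors rejects normality, rank-sum is chosen
  set.seed(31)
  sk <- make_labeled(rexp(50) * 10, rexp(50) * 10 + 2)
  r3 <- compare_groups(sk, "passive")
  expect_equal(r3$test, "wilcoxon")
  expect_lt(r3$lilliefors_p[1], 0.05)

  tiny <- make_labeled(c(1, 2), c(3, 4))
  expect_error(compare_groups(tiny, "passive"),
               class = "nmmap_validation_error")
})

test_that("Harrell-Davis estimator tracks true quantiles", {
  set.seed(32)
  x <- rnorm(4000, 50, 10)
  expect_equal(harrell_davis(x, 0.5), 50, tolerance = 1)
  expect_equal(harrell_davis(x, 0.9), qnorm(0.9, 50, 10), tolerance = 1)
  expect_lt(harrell_davis(x, 0.1), harrell_davis(x, 0.2))
})

test_that("shift function flags pure shifts and localized differences", {
  set.seed(33)
  a <- rnorm(100, 50, 5)
  s0 <- shift_function(a, a, n_boot = 400, seed = 1)
  expect_true(all(s0$difference == 0))
  expect_false(any(s0$significant))

  s1 <- shift_function(a, a + 10, n_boot = 400, seed = 2)
  expect_equal(s1$difference, rep(10, 9), tolerance = 1e-9)
  expect_true(all(s1$significant))

  # difference confined to the lower tail: only low deciles flagged
  set.seed(34)
  a2 <- rnorm(200, 50, 5)
  b2 <- rnorm(200, 50, 5)
  low <- b2 < qnorm(0.3, 50, 5)
  b2[low] <- b2[low] - 15  # shift only the bottom 30% of the distribution
  s2 <- shift_function(a2, b2, n_boot = 600, seed = 3)
  expect_true(all(s2$significant[1:2]))   # well inside the shifted tail
  expect_false(any(s2$significant[5:9]))  # above the mixture boundary

  expect_error(shift_function(1:5, 1:20), class = "nmmap_validation_error")
})

test_that("in-package Fisher exact agrees with stats::fisher.test", {
  set.seed(35)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 5, 12), 1)), 2, 2)
    p1 <- fisher_exact_2x2(tab)$p_value
    p2 <- fisher.test(tab)$p.value
    expect_equal(p1, p2, tolerance = 1e-9)
  }
})

test_that("Fisher exact equals lgamma-based hypergeometric enumeration", {
  set.seed(36)
  for (i in 1:300) {
    cells <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    tab <- matrix(cells, 2, 2)
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher_oracle_p(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("odds ratios from printed rule-in proportions round as published", {
  or_passive <- odds_ratio_from_rates(0.82, 0.25)
  expect_equal(round(or_passive), 14)
  expect_equal(or_passive, (0.82 / 0.18) / (0.25 / 0.75), tolerance = 1e-12)

  or_active <- odds_ratio_from_rates(0.70, 0.34)
  expect_equal(round(or_active), 5)

  expect_equal(odds_ratio_from_rates(0.5, 0.5), 1)
  # inverting the groups inverts the odds ratio
  expect_equal(odds_ratio_from_rates(0.82, 0.25) *
                 odds_ratio_from_rates(0.25, 0.82), 1, tolerance = 1e-12)
  expect_error(odds_ratio_from_rates(0, 0.5),
               class = "nmmap_degenerate_error")
})

test_that("threshold separation finds perfect and chance structure", {
  perfect <- make_labeled(rep(1, 20), rep(99, 20))
  ta <- threshold_separation(perfect, "passive", n_shuffle = 100, seed = 1)
  expect_equal(ta$max_difference, 1)
  expect_lt(ta$best_threshold, 99)
  expect_equal(ta$rate_plus, 1)
  expect_equal(ta$rate_minus, 0)
  expect_lt(ta$fisher_p, 1e-8)

  set.seed(37)
  pooled <- runif(60, 0, 100)
  rand <- make_labeled(pooled[1:30], pooled[31:60])
  tr <- threshold_separation(rand, "passive", n_shuffle = 200, seed = 2)
  expect_lt(tr$max_difference, 0.45)
  # shuffled curve sits between the group curves (up to MC error)
  expect_true(all(tr$curve_shuffled <=
                    pmax(tr$curve_plus, tr$curve_minus) + 0.08))
  expect_true(all(tr$curve_shuffled >=
                    pmin(tr$curve_plus, tr$curve_minus) - 0.08))
})

test_that("shuffled baseline converges to the pooled empirical CDF", {
  set.seed(38)
  d <- make_labeled(rbeta(40, 2, 5) * 100, rbeta(25, 4, 2) * 100)
  ta <- threshold_separation(d, "passive", n_shuffle = 5000, seed = 3)
  pooled_cdf <- vapply(ta$thresholds,
                       function(t) mean(d$percentile <= t), 0)
  expect_lt(max(abs(ta$curve_shuffled - pooled_cdf)), 0.02)
})

test_that("threshold separation is invariant to monotone transforms", {
  set.seed(39)
  d <- make_labeled(rbeta(30, 2, 6) * 100, rbeta(30, 5, 3) * 100)
  t1 <- threshold_separation(d, "passive", n_shuffle = 50, seed = 4)
  d2 <- d
  d2$percentile <- (d$percentile / 100)^1.7 * 100  # strictly monotone
  t2 <- threshold_separation(d2, "passive", n_shuffle = 50, seed = 4)
  expect_equal(t2$max_difference, t1$max_difference)
  expect_equal(t2$table_at_best, t1$table_at_best)
  expect_equal(t2$odds_ratio, t1$odds_ratio)
  expect_equal(t2$fisher_p, t1$fisher_p)
})

test_that("curves are monotone CDF-like and evaluation assembles a report", {
  set.seed(40)
  d <- rbind(make_labeled(rbeta(30, 2, 6) * 100, rbeta(28, 4, 2) * 100,
                          "passive"),
             make_labeled(rbeta(25, 2, 5) * 100, rbeta(26, 3, 3) * 100,
                          "active"))
  ta <- threshold_separation(d, "active", n_shuffle = 50, seed = 5)
  expect_true(all(diff(ta$curve_plus) >= 0))
  expect_true(all(diff(ta$curve_minus) >= 0))
  expect_true(all(ta$curve_plus >= 0 & ta$curve_plus <= 1))

  ev <- nm_evaluate(d, n_shuffle = 50, n_boot = 100, seed = 6)
  expect_s3_class(ev, "nm_evaluation")
  expect_setequal(names(ev), c("active", "passive"))
  expect_false(is.null(ev$passive$comparison))
  expect_false(is.null(ev$passive$shift))
  expect_output(print(ev), "passive movements")
})
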