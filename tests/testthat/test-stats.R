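test_that("exact Mann-Whitney p-values match hand-enumerated cases", {
  # complete separation, 6 vs 6: the smaller tail holds a single labeling
  t66 <- mann_whitney_exact(1:6, 7:12)
  expect_equal(t66$method, "exact")
  expect_equal(t66$U, 0)
  expect_equal(t66$p_two_tailed, 2 / 924)
  expect_equal(round(t66$p_two_tailed, 4), 0.0022)

  t22 <- mann_whitney_exact(c(1, 2), c(3, 4))
  expect_equal(t22$p_two_tailed, 2 / 6)

  tied <- mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$p_two_tailed, 1)
  expect_equal(tied$method, "normal_approx")   # ties force the approximation

  expect_error(mann_whitney_exact(numeric(0), 1:3), "nonempty")
})

test_that("exact enumeration agrees with the independent oracle for n <= 6", {
  # property: p matches wilcox.test's exact p over random tie-free inputs
  set.seed(5)
  for (rep in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq(0, 1, by = 1e-4), n1)
    y <- sample(seq(2, 3, by = 1e-4), n2)[seq_len(n2)]
    y <- y - runif(1, 0, 2.5)            # varying overlap
    ours <- mann_whitney_exact(x, y)
    oracle <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(ours$p_two_tailed, oracle$p.value, tolerance = 1e-12)
    expect_equal(ours$U, unname(oracle$statistic))
  }
})

test_that("the test is symmetric in its arguments", {
  set.seed(6)
  for (rep in 1:10) {
    x <- rnorm(5); y <- rnorm(6, 1)
    a <- mann_whitney_exact(x, y)
    b <- mann_whitney_exact(y, x)
    expect_equal(a$p_two_tailed, b$p_two_tailed)
    expect_equal(a$U, a$n1 * a$n2 - b$U)
  }
})

test_that("through-origin fit matches closed forms", {
  f <- linear_fit_origin(1:5, 2 * (1:5))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)

  f2 <- linear_fit_origin(c(1, 2), c(1, 4))
  expect_equal(f2$slope, 9 / 5)
  expect_equal(f2$r_squared, 1 - 0.8 / 4.5)

  # slope equals sum(xy)/sum(x^2) on random inputs
  set.seed(7)
  for (rep in 1:20) {
    x <- runif(8, 0, 10); y <- 1.3 * x + rnorm(8)
    f3 <- linear_fit_origin(x, y)
    expect_equal(f3$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
    expect_true(f3$ci95[1] <= f3$slope && f3$slope <= f3$ci95[2])
  }
  expect_error(linear_fit_origin(c(0, 0), c(1, 2)), "all x are zero")
  expect_warning(linear_fit_origin(1:4, 2 * (1:4), centered_r2 = FALSE),
                 "uncentered")
})

test_that("group comparisons flag the study's contrasts", {
  tab <- data.frame(group = rep(c("pigmented", "albino"), each = 6),
                    value = c(7:12, 1:6))
  cmp <- compare_groups(tab, list(c("pigmented", "albino")))
  expect_equal(cmp$p_two_tailed, 2 / 924)
  expect_true(cmp$significant_01)

  same <- data.frame(group = rep(c("a", "b"), each = 5),
                     value = c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10))
  cmp2 <- compare_groups(same, list(c("a", "b")))
  expect_false(cmp2$significant_05)
  expect_error(compare_groups(tab, list(c("pigmented", "missing"))),
               "unknown group")
})

test_that("nanorod vs control cohorts separate in most replicates", {
  hits <- 0
  for (s in 1:100) {
    tab <- simulate_lesion_cohort(n_per_group = 7, seed = s)
    p <- mann_whitney_exact(tab$value[tab$group == "gnr"],
                            tab$value[tab$group == "control"])$p_two_tailed
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits, 90)
})

test_that("power-series analysis fits, flags detection and handles nulls", {
  # noiseless generator round trip: slope is exactly kappa * C
  tab <- simulate_power_cohort(n_eyes = 6, powers = c(0.4, 1, 2, 4, 8, 10),
                               slope = 1.56, cv = 0, seed = 1)
  psa <- power_series_analysis(tab)
  expect_equal(psa$fit$slope, 1.56, tolerance = 1e-12)

  # all-zero signals: slope 0 and flagged undefined R^2
  tab0 <- data.frame(power = rep(c(1, 2, 4), each = 3), value = 0)
  psa0 <- power_series_analysis(tab0)
  expect_equal(psa0$fit$slope, 0)
  expect_equal(psa0$fit$r_squared, 0)
  expect_true(psa0$fit$r_squared_flagged)
  expect_error(power_series_analysis(data.frame(power = 1, value = 1)),
               "2 power levels")

  # detection-limit flags: sub-floor powers do not differ from 0 mW
  tabf <- simulate_power_cohort(n_eyes = 6,
                                powers = c(0, 0.2, 0.4, 1, 2, 4, 8),
                                slope = 1.56, cv = 0.2, floor_nm = 0.8,
                                seed = 3)
  psaf <- power_series_analysis(tabf)
  det <- psaf$per_power
  expect_false(det$detected[det$power == 0])
  expect_false(any(det$detected[det$power < 0.5]))
  expect_true(all(det$detected[det$power >= 1]))
})

test_that("the 95% CI covers the generating slope at nominal rate", {
  cover <- 0
  for (s in 1:500) {
    tab <- simulate_power_cohort(n_eyes = 6, powers = c(0.4, 1, 2, 4, 8, 10),
                                 slope = 1.56, cv = 0.2, seed = s)
    psa <- power_series_analysis(tab)
    ci <- psa$fit$ci95
    cover <- cover + (ci[1] <= 1.56 && 1.56 <= ci[2])
  }
  expect_gte(cover / 500, 0.90)
  expect_lte(cover / 500, 0.99)
})
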