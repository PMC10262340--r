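test_that("design effect is the standard inflation factor", {
  expect_equal(design_effect(1, 0.3), 1)
  expect_equal(design_effect(12, 0), 1)
  expect_equal(design_effect(12, 0.0296), 1.3256)
  expect_error(design_effect(0.5, 0.1), "m")
  expect_error(design_effect(5, -0.1), "rho")
})

test_that("cluster power reproduces the planned-trial calculation", {
  p <- power_cluster(2.52, 8.32, 0.0296, k_per_arm = 20, m = 12)
  expect_equal(round(p, 3), 0.822)
  expect_equal(round(100 * p), 82)

  # null effect: two-sided power equals the significance level
  expect_equal(power_cluster(0, 8.32, 0.0296, 20, 12, alpha = 0.05), 0.05,
               tolerance = 1e-12)

  # no clustering: closed-form normal power at n_eff = k * m per arm
  ne <- 172
  ncp <- 2.52 / (8.32 * sqrt(2 / ne))
  expected <- pnorm(ncp - qnorm(0.975)) + pnorm(-ncp - qnorm(0.975))
  expect_equal(power_cluster(2.52, 8.32, 0, k_per_arm = 4, m = 43), expected)
  expect_equal(round(expected, 3), 0.802)
})

test_that("power is monotone in the design inputs", {
  base <- power_cluster(2.5, 8, 0.05, 20, 10)
  expect_gt(power_cluster(2.5, 8, 0.05, 25, 10), base)
  expect_gt(power_cluster(2.5, 8, 0.05, 20, 14), base)
  expect_gt(power_cluster(3.0, 8, 0.05, 20, 10), base)
  expect_lt(power_cluster(2.5, 8, 0.10, 20, 10), base)
  expect_lt(power_cluster(2.5, 10, 0.05, 20, 10), base)
})

test_that("power with no clustering and single-subject clusters matches the two-sample formula", {
  # m = 1, rho = 0: k subjects per arm, classical two-sample z test
  for (k in c(50, 120, 300)) {
    ncp <- 1.5 / (6 * sqrt(2 / k))
    expected <- pnorm(ncp - qnorm(0.975)) + pnorm(-ncp - qnorm(0.975))
    expect_equal(power_cluster(1.5, 6, 0, k, 1), expected)
  }
  # t variant with subject df matches power.t.test closely at moderate n
  p_t <- power_cluster(1.5, 6, 0, 100, 1, method = "t_subject_df")
  ref <- power.t.test(n = 100, delta = 1.5, sd = 6)$power
  expect_equal(p_t, ref, tolerance = 0.005)
})

test_that("minimum cluster size reproduces the planned-trial sample sizes", {
  r20 <- min_cluster_size(2.52, 8.32, 0.0296, k_per_arm = 20)
  expect_true(r20$feasible)
  expect_equal(r20$m, 12L)
  expect_equal(r20$n_total, 480)
  r25 <- min_cluster_size(2.52, 8.32, 0.0296, k_per_arm = 25)
  expect_equal(r25$m, 9L)
  expect_equal(r25$n_total, 450)

  # too few clusters for this ICC: k / rho caps the effective size
  r10 <- min_cluster_size(2.52, 8.32, 0.0682, k_per_arm = 10)
  expect_false(r10$feasible)
  expect_true(is.na(r10$m))

  # no clustering: ceiling of the classical per-arm size over k
  r0 <- min_cluster_size(2.52, 8.32, 0, k_per_arm = 20)
  expect_equal(r0$m, 9L)
  expect_equal(r0$n_total, 360)
})

test_that("the returned cluster size is minimal over a grid of designs", {
  set.seed(5)
  for (i in 1:60) {
    delta <- runif(1, 0.8, 3)
    sdv <- runif(1, 4, 12)
    icc <- runif(1, 0, 0.12)
    k <- sample(5:40, 1)
    res <- min_cluster_size(delta, sdv, icc, k)
    if (!res$feasible) next
    expect_gte(power_cluster(delta, sdv, icc, k, res$m), res$target_power)
    if (res$m > 1)
      expect_lt(power_cluster(delta, sdv, icc, k, res$m - 1),
                res$target_power)
  }
})

test_that("sample sizes over posterior quantiles form the design grid", {
  qs <- c(0.012, 0.0296, 0.0682)
  grid <- sample_size_over_quantiles(qs, k_per_arm = c(20, 25),
                                     probs = NULL, delta = 2.52, sd = 8.32)
  expect_equal(nrow(grid), 6L)
  # N nondecreasing in the ICC quantile at fixed k
  for (k in c(20, 25)) {
    nn <- grid$n_total[grid$k_per_arm == k]
    expect_true(all(diff(nn) >= 0))
  }
  # the median column reproduces the headline sizes
  expect_equal(grid$n_total[grid$k_per_arm == 20 & grid$icc == 0.0296], 480)
  expect_equal(grid$n_total[grid$k_per_arm == 25 & grid$icc == 0.0296], 450)

  # infeasible cells are kept, marked, and NA-sized
  g2 <- sample_size_over_quantiles(qs, k_per_arm = 10, probs = NULL,
                                   delta = 2.52, sd = 8.32)
  expect_false(g2$feasible[3])
  expect_true(is.na(g2$n_total[3]))

  # draws input: quantiles taken internally
  set.seed(8)
  draws <- rbeta(5000, 2, 40)
  g3 <- sample_size_over_quantiles(draws, k_per_arm = 20, delta = 2.52,
                                   sd = 8.32)
  expect_equal(g3$icc, unname(quantile(draws, c(0.25, 0.5, 0.75))))
  expect_error(sample_size_over_quantiles(qs, numeric(0), probs = NULL,
                                          delta = 2.52, sd = 8.32),
               "at least one")
})

test_that("sample size stabilises as the number of clusters grows", {
  ks <- c(10, 15, 20, 25, 30, 40, 60)
  grid <- sample_size_over_quantiles(0.0296, k_per_arm = ks, probs = NULL,
                                     delta = 2.52, sd = 8.32)
  n <- grid$n_total
  # the total size is far more sensitive to k when clusters are scarce:
  # the first step dwarfs every later one, and from k = 20 on the size
  # moves by small integer-cluster adjustments only
  expect_gt(abs(n[2] - n[1]), max(abs(diff(n[-1]))))
  expect_true(all(abs(diff(n[3:7])) <= 80))
})
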