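test_that("joint log posterior matches a term-by-term hand computation", {
  tab <- study_table("s", 1, icc = 0.1, n = 100, k = 10)
  ctl <- icc_control()
  mu <- qlogis(0.12)
  state <- list(mu = mu, sigma_b = 0.8, sigma_w = 0.4, mu_m = mu, rho = 0.12)
  v <- swiger_ref(0.12, 100, 10)
  expected <- dnorm(0.1, 0.12, sqrt(v), log = TRUE) +
    dnorm(qlogis(0.12), mu, 0.4, log = TRUE) +
    dnorm(mu, mu, 0.8, log = TRUE) +
    dnorm(mu, 0, 100, log = TRUE) +
    2 * dunif(0.5, 0, 5, log = TRUE)
  expect_equal(icc_log_posterior(state, tab, ctl), expected)

  # observed-variance mode evaluates V at the estimate instead
  ctl_obs <- icc_control(variance_at = "observed")
  v_obs <- swiger_ref(0.1, 100, 10)
  expect_equal(icc_log_posterior(state, tab, ctl_obs),
               expected - dnorm(0.1, 0.12, sqrt(v), log = TRUE) +
                 dnorm(0.1, 0.12, sqrt(v_obs), log = TRUE))
})

test_that("states outside the support give -Inf, not errors", {
  tab <- study_table("s", 1, icc = 0.1, n = 100, k = 10)
  ctl <- icc_control()
  ok <- list(mu = 0, sigma_b = 1, sigma_w = 1, mu_m = 0, rho = 0.5)
  expect_true(is.finite(icc_log_posterior(ok, tab, ctl)))
  expect_identical(icc_log_posterior(modifyList(ok, list(sigma_b = 5.5)),
                                     tab, ctl), -Inf)
  expect_identical(icc_log_posterior(modifyList(ok, list(sigma_w = 0)),
                                     tab, ctl), -Inf)
  expect_identical(icc_log_posterior(modifyList(ok, list(rho = 1)),
                                     tab, ctl), -Inf)
})

test_that("doubling an outcome weight tightens the within-study term by the closed form", {
  ctl <- icc_control()
  mk <- function(w) study_table("s", 1, icc = 0.1, n = 100, k = 10,
                                outcome_weight = w)
  st <- list(mu = -2, sigma_b = 1, sigma_w = 0.5, mu_m = -1.8, rho = 0.09)
  lp1 <- icc_log_posterior(st, mk(1), ctl)
  lp05 <- icc_log_posterior(st, mk(0.5), ctl)
  d2 <- (qlogis(0.09) - (-1.8))^2
  expect_equal(lp1 - lp05,
               0.5 * log(2) - d2 * (1 - 0.5) / (2 * 0.5^2))
})

test_that("fits are bit-reproducible given a seed and draws stay in support", {
  tab <- two_record_table()
  f1 <- icc_fit(tab, quick_control(), seed = 42)
  f2 <- icc_fit(tab, quick_control(), seed = 42)
  expect_identical(f1$draws, f2$draws)

  dm <- do.call(rbind, f1$draws)
  expect_true(all(dm[, "rho_star"] > 0 & dm[, "rho_star"] < 1))
  rho_cols <- grep("^rho\\[", colnames(dm))
  expect_true(all(dm[, rho_cols] > 0 & dm[, rho_cols] < 1))
  expect_true(all(dm[, "sigma_b"] > 0 & dm[, "sigma_b"] <= 5))
  expect_true(all(dm[, "sigma_w"] > 0 & dm[, "sigma_w"] <= 5))
})

test_that("with unit weights the posterior is invariant to record order", {
  tab <- two_record_table()
  swapped <- validate_study_table(as.data.frame(tab)[2:1, ])
  ctl <- icc_control(n_chains = 2, n_iter = 6000, n_burnin = 1000)
  fa <- icc_fit(tab, ctl, seed = 7)
  fb <- icc_fit(swapped, ctl, seed = 7)
  sa <- summary(fa, pars = "main")
  sb <- summary(fb, pars = "main")
  tol <- 3 * (sa[, "mc_error"] + sb[, "mc_error"])
  expect_true(all(abs(sa[, "mean"] - sb[, "mean"]) < pmax(tol, 0.02)))
  expect_lt(abs(sa["rho_star", "q50"] - sb["rho_star", "q50"]), 0.01)
})

test_that("raising an outcome's relevance weight pulls the predictive ICC toward it", {
  ctl <- icc_control(n_chains = 2, n_iter = 6000, n_burnin = 1500)
  lo <- icc_fit(two_record_table(w2 = 0.1, sw2 = 0.1), ctl, seed = 5)
  hi <- icc_fit(two_record_table(w2 = 1, sw2 = 1), ctl, seed = 5)
  med_lo <- median(predict(lo))
  med_hi <- median(predict(hi))
  # record 2 has the larger estimate (0.30); upweighting it moves the
  # predictive median towards 0.30
  expect_gt(med_hi, med_lo)
})

test_that("the model recovers known generating parameters", {
  set.seed(100)
  tab <- simulate_study_table(30, 3, mu = -3, sigma_b = 0.5, sigma_w = 0.3)
  fit <- icc_fit(tab, icc_control(n_chains = 2, n_iter = 3000,
                                  n_burnin = 1000), seed = 101)
  s <- summary(fit, pars = c("mu", "sigma_b", "sigma_w"))
  truth <- c(-3, 0.5, 0.3)
  expect_true(all(abs(s[, "q50"] - truth) < 3 * s[, "sd"]))
  d <- convergence_diagnostics(fit, pars = c("mu", "sigma_b", "sigma_w"))
  expect_true(all(d$rhat < 1.2))
})

test_that("non-positive weights are rejected before sampling", {
  tab <- as.data.frame(two_record_table())
  tab$outcome_weight[1] <- 0
  expect_error(icc_fit(tab, quick_control(), seed = 1), "outcome_weight")
})

test_that("posterior summaries follow their definitions", {
  x <- rep(0.3, 500)
  s <- posterior_summary(x)
  expect_equal(unname(s), c(0.3, 0, 0, 0.3, 0.3, 0.3, 0.3, 0.3))

  y <- seq_len(10000) / 10001
  sy <- posterior_summary(y)
  expect_lt(abs(sy[["q2.5"]] - 0.025), 2e-4)
  expect_lt(abs(sy[["q50"]] - 0.5), 2e-4)
  expect_equal(sy[["mean"]], mean(y))
  expect_equal(sy[["sd"]], sd(y))
  # percentiles nondecreasing, mc_error below sd for correlated-free draws
  expect_true(all(diff(sy[c("q2.5", "q25", "q50", "q75", "q97.5")]) >= 0))
  expect_lt(sy[["mc_error"]], sy[["sd"]])

  expect_error(posterior_summary(1:50), "at least 100")
})

test_that("convergence diagnostics separate mixed from stuck chains", {
  const <- matrix(rep(c(1, 2, 3), each = 100), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  fake <- list(draws = list(const, const))
  d <- convergence_diagnostics(fake)
  expect_equal(d$rhat, rep(1, 3))          # identical chains
  expect_true(attr(d, "converged"))

  set.seed(6)
  far <- list(draws = list(
    matrix(rnorm(200, 0, 0.1), ncol = 1, dimnames = list(NULL, "x")),
    matrix(rnorm(200, 10, 0.1), ncol = 1, dimnames = list(NULL, "x"))))
  d2 <- convergence_diagnostics(far)
  expect_gt(d2$rhat, 5)
  expect_false(attr(d2, "converged"))

  short <- list(draws = list(matrix(rnorm(50), ncol = 1,
                                    dimnames = list(NULL, "x"))))
  expect_error(convergence_diagnostics(short), "at least 2 chains")
})

test_that("DIC behaves like an effective-parameter count", {
  tab <- study_table("s", 1, icc = 0.5, n = 20000, k = 200)
  ctl <- icc_control(n_chains = 2, n_iter = 4000, n_burnin = 1000,
                     variance_at = "observed")
  fit <- icc_fit(tab, ctl, seed = 9)

  # degenerate draws: pD = 0 and DIC equals the plug-in deviance
  degen <- fit
  cm <- colMeans(do.call(rbind, fit$draws))
  degen$draws <- lapply(degen$draws, function(d) {
    d[] <- rep(cm, each = nrow(d)); d
  })
  d0 <- dic(degen)
  expect_equal(d0$p_d, 0, tolerance = 1e-8)
  expect_equal(d0$dic, d0$mean_deviance)

  # one precisely measured record under an effectively flat prior:
  # pD is close to one free parameter
  d1 <- dic(fit)
  expect_equal(d1$p_d, 1, tolerance = 0.15)

  # subsetting to the seemingly most relevant records is measurable:
  # full-table and subset DICs are both finite and comparable
  tab2 <- fixture_table()
  ctl2 <- icc_control(n_chains = 1, n_iter = 2000, n_burnin = 500)
  full <- dic(icc_fit(tab2, ctl2, seed = 11))
  sub <- dic(icc_fit(validate_study_table(as.data.frame(tab2)[1:9, ]),
                     ctl2, seed = 11))
  expect_true(is.finite(full$dic) && is.finite(sub$dic))
  expect_gt(full$p_d, sub$p_d)  # more records, more effective parameters
})

test_that("a long fixture run is well mixed with ordered percentiles", {
  fit <- icc_fit(fixture_table(),
                 icc_control(n_chains = 2, n_iter = 4000, n_burnin = 1500),
                 seed = 3)
  s <- summary(fit, pars = "main")
  q <- s["rho_star", c("q2.5", "q25", "q50", "q75", "q97.5")]
  expect_true(all(diff(q) > 0))
  expect_true(all(s[, "mc_error"] <= s[, "sd"]))
  d <- convergence_diagnostics(fit, pars = c("mu", "sigma_b", "sigma_w",
                                             "rho_star"))
  expect_true(all(d$rhat <= 1.05))
  # acceptance rates were adapted into the target band
  expect_true(all(fit$acceptance > 0.1 & fit$acceptance < 0.6))
})

test_that("model methods expose coherent views of the fit", {
  tab <- fixture_table()
  fit <- icc_fit(tab, quick_control(), seed = 2)
  cf <- coef(fit)
  expect_named(cf, c("mu", "sigma_b", "sigma_w", "rho_star"))
  expect_equal(unname(cf["rho_star"]),
               unname(summary(fit)["rho_star", "q50"]))

  draws <- predict(fit)
  expect_length(draws, 2 * 1500)
  qs <- predict(fit, type = "quantiles", probs = c(0.25, 0.75))
  expect_equal(unname(qs), unname(quantile(draws, c(0.25, 0.75))))

  res <- residuals(fit)
  expect_length(res, nrow(tab))
  expect_true(all(is.finite(res)))

  sim <- simulate(fit, nsim = 5, seed = 4)
  expect_equal(dim(sim), c(5L, nrow(tab)))
  expect_true(all(sim >= 0 & sim < 1))
})
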