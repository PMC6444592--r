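exact_curve <- function(taus, fracs, fi = 0.5, t_max = 60, n_dwells = 1e5) {
  tt <- fi * seq_len(ceiling(t_max / fi))
  surv <- as.vector(exp(-outer(tt, taus, "/")) %*% fracs)
  structure(list(t = tt, surv = surv, n_dwells = n_dwells, n_censored = 0L,
                 frame_interval = fi), class = "survival_curve")
}

test_that("survival curve matches a hand count and flags censoring", {
  d <- dwell_dataset(c(1, 2, 3), frame_interval = 1)
  cv <- suppressWarnings(survival_curve(d))
  expect_equal(cv$t, c(1, 2, 3))
  expect_equal(cv$surv, c(1, 2 / 3, 1 / 3))
  # single dwell value: step function
  cv1 <- suppressWarnings(survival_curve(dwell_dataset(rep(2, 20),
                                                       frame_interval = 1)))
  expect_equal(cv1$surv, c(1, 1))
  # censored dwells are excluded and counted
  dc <- dwell_dataset(c(1, 2, 3, 9), frame_interval = 1,
                      censored = c(FALSE, FALSE, FALSE, TRUE))
  cvc <- suppressWarnings(survival_curve(dc))
  expect_equal(cvc$n_censored, 1L)
  expect_equal(max(cvc$t), 3)
  expect_error(survival_curve(dwell_dataset(c(1, 2), censored = c(TRUE, TRUE))),
               "censored")
})

test_that("the BIC implements the stated formula and is monotone in RSS", {
  # direct arithmetic oracle
  n <- 100; p <- 3; rss <- 1.0
  expect_equal(bic(n, p, rss),
               log(100) * 4 + 100 * (log(2 * pi * 1 / 100) + 1),
               tolerance = 1e-12)
  expect_equal(bic(57, 5, 0.37),
               log(57) * 6 + 57 * (log(2 * pi * 0.37 / 57) + 1),
               tolerance = 1e-12)
  expect_equal(bic(100, 3, 1, variant = "textbook"),
               100 * log(1 / 100) + 3 * log(100), tolerance = 1e-12)
  # lower RSS, same n and p: lower BIC
  expect_lt(bic(100, 3, 0.5), bic(100, 3, 1.0))
  expect_error(bic(100, 3, 0), "degenerate")
  expect_error(bic(0, 3, 1), "n must")
})

test_that("an exact single-exponential curve is recovered to 1e-6", {
  cv <- exact_curve(5, 1)
  fit <- fit_exponential_mixture(cv, 1)
  expect_lt(abs(fit$components$tau - 5) / 5, 1e-6)
  fit2 <- fit_exponential_mixture(cv, 1, target = "survival")
  expect_lt(abs(fit2$components$tau - 5) / 5, 1e-6)
})

test_that("two-component dwell mixtures are recovered from 5000 samples", {
  taus <- matrix(NA, 3, 2); f1 <- numeric(3)
  for (s in 1:3) {
    d <- simulate_dwell_times(two_exp_components(), 5000, seed = s)
    fit <- fit_exponential_mixture(survival_curve(d), 2)
    taus[s, ] <- fit$components$tau
    f1[s] <- fit$components$fraction[1]
  }
  med <- apply(taus, 2, median)
  expect_lt(abs(med[1] - 2.4) / 2.4, 0.10)     # unspecific tau
  expect_lt(abs(med[2] - 28.8) / 28.8, 0.15)   # specific tau
  expect_lt(abs(median(f1) - 0.88), 0.03)      # specific fraction within 3 pts
  expect_true(all(abs(taus[, 2] - 28.8) / 28.8 < 0.15))
})

test_that("BIC model selection is parsimonious and finds both binding
           modes", {
  for (s in 1:3) {
    d1 <- simulate_dwell_times(data.frame(fraction = 1, tau = 5), 5000,
                               seed = s)
    expect_equal(select_dwell_model(survival_curve(d1))$n_components, 1L)
    d2 <- simulate_dwell_times(two_exp_components(), 5000, seed = s)
    expect_equal(select_dwell_model(survival_curve(d2))$n_components, 2L)
  }
  # a third component with vanishing weight is not selected (majority)
  k3 <- vapply(1:5, function(s) {
    d <- simulate_dwell_times(
      data.frame(fraction = c(0.875, 0.12, 0.005), tau = c(2.4, 28.8, 120)),
      5000, seed = s)
    select_dwell_model(survival_curve(d))$n_components
  }, integer(1))
  expect_gte(sum(k3 == 2L), 4)
})

test_that("parametric bootstrap is reproducible and tracks the analytic
           uncertainty", {
  d <- simulate_dwell_times(data.frame(fraction = 1, tau = 10), 500,
                            seed = 1)
  fit <- fit_exponential_mixture(survival_curve(d), 1)
  b1 <- parametric_bootstrap(fit, n_boot = 200, seed = 7)
  b2 <- parametric_bootstrap(fit, n_boot = 200, seed = 7)
  expect_identical(b1$bootstrap_mean, b2$bootstrap_mean)
  expect_identical(b1$bootstrap_sd, b2$bootstrap_sd)
  # bootstrap mean consistent with the base estimate
  expect_lt(abs(b1$bootstrap_mean[["tau1"]] - fit$components$tau),
            b1$bootstrap_sd[["tau1"]])
  # analytic MLE standard error of an exponential mean is tau/sqrt(n)
  se_theory <- fit$components$tau / sqrt(500)
  expect_lt(abs(b1$bootstrap_sd[["tau1"]] - se_theory) / se_theory, 0.30)
  expect_equal(b1$n_boot, 200L)
})

test_that("dwell_fit behaves like a fitted-model object", {
  d <- simulate_dwell_times(two_exp_components(), 2000, seed = 2)
  fit <- fit_exponential_mixture(survival_curve(d), 2)
  expect_named(coef(fit), c("tau1", "tau2", "f1", "f2"))
  expect_equal(sum(fit$components$fraction), 1, tolerance = 1e-6)
  expect_equal(predict(fit, 0), 1, tolerance = 1e-12)
  expect_equal(length(residuals(fit)), length(fit$curve$t))
  sim <- simulate(fit, nsim = 50, seed = 3)
  expect_s3_class(sim, "dwell_dataset")
  expect_length(sim$dwells, 50)
  expect_output(print(summary(fit)), "Residence-time")
})

test_that("the fitted mixture beats any single exponential on two-mode
           data", {
  d <- simulate_dwell_times(two_exp_components(), 5000, seed = 9)
  cv <- survival_curve(d)
  f2 <- fit_exponential_mixture(cv, 2, target = "survival")
  f1 <- fit_exponential_mixture(cv, 1, target = "survival")
  expect_lt(f2$rss, f1$rss)
})

test_that("the Z-test compares replicate-level residence times", {
  same <- compare_conditions(c(10, 12, 11), c(10, 12, 11))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # condition summaries as reported for WT vs R38/9A specific times
  wt <- list(mean = 49.2, sd = 12.3, n = 3)
  mut <- list(mean = 29.5, sd = 4.1, n = 3)
  res <- compare_conditions(wt, mut)
  z_oracle <- (49.2 - 29.5) / sqrt(12.3^2 / 3 + 4.1^2 / 3)
  expect_equal(res$z, z_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * (1 - pnorm(z_oracle)), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_error(compare_conditions(c(5, 5), c(4, 4)), "zero variance")
})
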