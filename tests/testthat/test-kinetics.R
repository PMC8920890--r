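test_that("telegraph fits recover parameters and handle degeneracy", {
  kin <- two_state_kinetics(0.5, 5, 50)
  x <- sample_beta_poisson(kin, 2000, seed = 101)
  fit <- fit_two_state(x)
  est <- coef(fit)
  expect_equal(fit$convergence, 0)
  expect_lt(abs(log2(est["k_on"] / kin$k_on)), 0.5)
  expect_lt(abs(log2(est["burst_size"] / burst_size(kin))), 0.5)
  # always-ON limit: near-Poisson data, fitted mean tracks the sample mean
  y <- sample_beta_poisson(two_state_kinetics(100, 0.01, 8), 1000,
                           seed = 102)
  fy <- fit_two_state(y)
  expect_lt(abs(coef(fy)["mean"] / mean(y) - 1), 0.05)
  # all-zero input is degenerate, no estimate
  fz <- fit_two_state(rep(0L, 100))
  expect_true(fz$degenerate)
  expect_true(all(is.na(coef(fz))))
  # fewer than five expressing cells is below the inference minimum
  expect_true(fit_two_state(c(3L, 2L, rep(0L, 50)))$degenerate)
  # missing-masked cells are excluded from the inference
  fm <- fit_two_state(c(x[1:500], rep(99L, 5)),
                      missing = c(rep(FALSE, 500), rep(TRUE, 5)))
  expect_equal(fm$n_cells, 500)
  expect_equal(fm$n_missing, 5)
})

test_that("bootstrap CIs are reproducible and cover a true parameter", {
  kin <- two_state_kinetics(1, 8, 60)
  x <- sample_beta_poisson(kin, 800, seed = 7)
  fit <- fit_two_state(x)
  b1 <- bootstrap_ci(fit, n_boot = 60, seed = 99)
  b2 <- bootstrap_ci(fit, n_boot = 60, seed = 99)
  expect_identical(b1$boot$ci, b2$boot$ci)
  expect_lte(b1$boot$ci["k_on", 1], coef(fit)["k_on"] + 1e-8)
  expect_gte(b1$boot$ci["k_on", 2], coef(fit)["k_on"] - 1e-8)
  expect_false(b1$boot$unstable)
  expect_error(bootstrap_ci(fit_two_state(rep(0L, 20))), "degenerate")
})

test_that("the post-inference filter enforces every published bound", {
  kin <- two_state_kinetics(1, 8, 60)
  x <- sample_beta_poisson(kin, 500, seed = 8)
  fit <- bootstrap_ci(fit_two_state(x), n_boot = 80, seed = 1)
  res <- kinetics_filter(fit)
  expect_true(res$pass)
  # burst size 0.1 is outside (0.2, 50)
  tiny <- fit
  tiny$estimate <- two_state_kinetics(1, 600, 60)   # size 0.1
  expect_true("size" %in% kinetics_filter(tiny)$reasons)
  # CI width ratio of 40 exceeds 10^1.5 ~ 31.6
  wide <- fit
  wide$boot$ci["burst_size", ] <- c(1, 40)
  expect_true("ci_width_burst_size" %in% kinetics_filter(wide)$reasons)
  # frequency and mean bounds
  slow <- fit
  slow$estimate <- two_state_kinetics(0.005, 8, 60)
  expect_true("frequency" %in% kinetics_filter(slow)$reasons)
  fit_noci <- fit
  fit_noci$boot <- NULL
  expect_true("no_ci" %in% kinetics_filter(fit_noci)$reasons)
})

test_that("LRT is null at identity and detects a doubled frequency", {
  x <- sample_beta_poisson(two_state_kinetics(1, 5, 50), 600, seed = 11)
  same <- lrt_kinetics(x, x, "frequency")
  expect_lt(same$lambda_LR, 0.02)
  expect_false(same$significant_one_sided)
  expect_equal(same$theta_hat, 0, tolerance = 1e-6)
  same_s <- lrt_kinetics(x, x, "size")
  expect_lt(same_s$lambda_LR, 0.02)
  # the one-sided threshold is the chi-squared(1) 95% quantile
  expect_equal(qchisq(0.95, df = 1), 3.84, tolerance = 0.005)
  expect_equal(unname(same$critical["one_sided"]), 3.84)
  expect_equal(unname(same$critical["two_sided"]), 7.68)
  y <- sample_beta_poisson(two_state_kinetics(2, 5, 50), 600, seed = 12)
  diff <- lrt_kinetics(x, y, "frequency")
  expect_true(diff$significant_one_sided)
  expect_gt(diff$theta_hat, 0.5)
  expect_false(diff$optimizer_failure)
  # free optimum is never beaten by the constrained one
  expect_gte(diff$fit_a$logLik + diff$fit_b$logLik,
             diff$logLik_null - 1e-4)
})

test_that("inference-spread simulation tracks the imposed perturbation", {
  kin <- two_state_kinetics(1, 6, 40)
  x <- sample_beta_poisson(kin, 600, seed = 21)
  fit <- fit_two_state(x)
  ref <- coef(fit)
  sp <- simulate_inference_spread(fit, r = 1, mode = "frequency",
                                  n_sim = 20, seed = 22)
  expect_lt(abs(log2(median(sp$k_on, na.rm = TRUE) / ref["k_on"])), 0.35)
  sp2 <- simulate_inference_spread(fit, r = 2, mode = "frequency",
                                   n_sim = 20, seed = 23)
  expect_lt(abs(log2(median(sp2$k_on, na.rm = TRUE) / (2 * ref["k_on"]))),
            0.4)
  expect_error(simulate_inference_spread(fit, r = -1), "r > 0")
})

test_that("burst durations convert frequencies through the half-life", {
  expect_equal(burst_duration_hours(1, log(2)), 1)
  # lambda = ln2 / 4 = 0.17329 /h; 1 / (0.25 * lambda) = 23.08 h
  expect_equal(burst_duration_hours(0.25, 4), 23.08, tolerance = 1e-3)
  expect_equal(burst_duration_hours(0.7, 6), 2 * burst_duration_hours(0.7, 3))
  expect_error(burst_duration_hours(-1, 2), "k_on > 0")
})
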