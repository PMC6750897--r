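noiseless_obs <- function(params, times = c(0.1, 0.3, 0.7, 1.5, 2.5, 4)) {
  simulate_observations(params, times, noise_sd = 0, n_per_time = 1, seed = 1)
}

test_that("noiseless observations are recovered exactly", {
  truth <- model_params("M2", R0 = 1.5, Y0 = 40)
  fit <- fit_divergence_model(noiseless_obs(truth), "M2")
  expect_s3_class(fit, "div_fit")
  expect_true(fit$converged)
  expect_equal(fit$coef[["R0"]], 1.5, tolerance = 1e-5)
  expect_equal(fit$coef[["Y0"]], 40, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)

  truth3 <- model_params("M3", R0 = 2, alpha = 0.5)
  fit3 <- fit_divergence_model(noiseless_obs(truth3), "M3")
  expect_equal(fit3$coef[["alpha"]], 0.5, tolerance = 1e-3)
  expect_equal(fit3$coef[["R0"]], 2, tolerance = 1e-3)
})

test_that("noisy M2 data is recovered near the truth with finite standard errors", {
  obs <- simulate_observations(model_params("M2", R0 = 1.5, Y0 = 40),
                               times = rep(c(0.25, 0.5, 1, 2, 3, 4), each = 8),
                               noise_sd = 5, seed = 7)
  fit <- fit_divergence_model(obs, "M2")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(is.finite(td$std.error)) && all(td$std.error > 0))
  expect_lt(abs(fit$coef[["Y0"]] - 40), 3 * td$std.error[td$term == "Y0"] + 1e-9)
  gl <- glance(fit)
  expect_equal(gl$model, "M2")
  expect_equal(gl$n, nrow(obs))
  expect_equal(gl$df.residual, nrow(obs) - 2)
})

test_that("fitting is invariant to row order and weights duplicates by multiplicity", {
  obs <- simulate_observations(model_params("M1", R0 = 1),
                               times = c(0.2, 0.5, 1, 2, 3, 4),
                               noise_sd = 4, n_per_time = 3, seed = 3)
  f1 <- fit_divergence_model(obs, "M1")
  f2 <- fit_divergence_model(obs[sample(nrow(obs)), ], "M1")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  # a duplicated point pulls the fit: same as stacking the rows explicitly
  dup <- rbind(obs, obs[c(1, 1, 1), ])
  f3 <- fit_divergence_model(dup, "M1")
  expect_equal(f3$n, nrow(obs) + 3)
  expect_false(isTRUE(all.equal(f1$coef[["R0"]], f3$coef[["R0"]], tolerance = 1e-10)))
})

test_that("column aliases are accepted and preconditions enforced", {
  obs <- noiseless_obs(model_params("M1", R0 = 1))
  alias <- dplyr::rename(obs, identity_pct = identity, time_gy = time)
  expect_equal(fit_divergence_model(alias, "M1")$coef,
               fit_divergence_model(obs, "M1")$coef)
  expect_error(fit_divergence_model(obs[1:4, ], "M1"),
               class = "divlimit_too_few_times")
  expect_silent(fit_divergence_model(obs[1:4, ], "M1", min_times = 4))
  expect_error(fit_divergence_model(tibble::tibble(identity = 50, foo = 1), "M1"),
               class = "divlimit_invalid_input")
  bad <- obs; bad$identity[1] <- 105
  expect_error(fit_divergence_model(bad, "M1"), class = "divlimit_invalid_input")
})

test_that("F-test detects a genuine floor and is clamped when M2 adds nothing", {
  obs <- noiseless_obs(model_params("M2", R0 = 1.5, Y0 = 40))
  f1 <- fit_divergence_model(obs, "M1")
  f2 <- fit_divergence_model(obs, "M2")
  res <- f_test_nested(f1, f2)
  expect_named(res, c("statistic", "df1", "df2", "p.value", "rss1", "rss2"))
  expect_equal(res$df1, 1)
  expect_equal(res$df2, nrow(obs) - 2)
  expect_lt(res$p.value, 1e-10)
  # identical rss => F = 0, p = 1 (clamped)
  f2b <- f2; f2b$rss <- f1$rss + 1e-9  # rss2 marginally above rss1
  res0 <- f_test_nested(f1, f2b)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_error(f_test_nested(f2, f2), class = "divlimit_invalid_input")
})

test_that("Wald floor test is one-sided against the baseline", {
  obs <- simulate_observations(model_params("M2", R0 = 1.5, Y0 = 40),
                               times = rep(c(0.25, 0.5, 1, 2, 3, 4), each = 10),
                               noise_sd = 4, seed = 5)
  fit <- fit_divergence_model(obs, "M2")
  w <- wald_test_floor(fit)
  expect_equal(w$baseline, 13.5)
  expect_equal(w$statistic, (w$estimate - 13.5) / w$std.error)
  expect_equal(w$p.value, pnorm(w$statistic, lower.tail = FALSE))
  expect_lt(w$p.value, 0.01)
  # a floor below the baseline gives p > 0.5 (hand-built degenerate example)
  fit_low <- fit
  fit_low$coef[["Y0"]] <- 10
  expect_gt(wald_test_floor(fit_low)$p.value, 0.5)
  expect_error(wald_test_floor(fit_divergence_model(obs, "M1")),
               class = "divlimit_invalid_input")
})

test_that("project_identity evaluates the fitted curve at the horizon", {
  fit <- fit_divergence_model(noiseless_obs(model_params("M2", R0 = 1.5, Y0 = 40)), "M2")
  expect_equal(project_identity(fit, 7.8),
               40 + 60 * exp(-fit$coef[["R0"]] * 7.8), tolerance = 1e-6)
  expect_equal(project_identity(model_params("M1", R0 = log(2)), 1), 50)
})

test_that("divergence-time resampling reduces to a point mass when min == max", {
  obs <- noiseless_obs(model_params("M2", R0 = 1.5, Y0 = 40))
  obs$time_min <- obs$time
  obs$time_max <- obs$time
  res <- resample_divergence_times(obs, n_runs = 5, seed = 2)
  expect_equal(nrow(res$runs), 5)
  expect_true(all(res$runs$frac_Y0_gt == res$runs$frac_Y0_gt[1]))
  expect_equal(res$summary$fraction_Y0_gt_25, 1)  # true floor 40 > 25
  # zero runs: NA summary, empty runs table
  res0 <- resample_divergence_times(obs, n_runs = 0)
  expect_equal(nrow(res0$runs), 0)
  expect_true(is.na(res0$summary$fraction_Y0_gt_25))
  obs$time_min <- NULL
  expect_error(resample_divergence_times(obs, n_runs = 1),
               class = "divlimit_configuration_error")
})

test_that("resampling actually flips times between the reported bounds", {
  obs <- noiseless_obs(model_params("M2", R0 = 1.5, Y0 = 40))
  obs$time_min <- obs$time * 0.8
  obs$time_max <- obs$time * 1.2
  res <- resample_divergence_times(obs, n_runs = 20, seed = 4, min_times = 4)
  expect_equal(nrow(res$runs), 20)
  expect_true(all(res$runs$frac_Y0_gt %in% c(0, 1)))
  # a true floor of 40 should survive modest time jitter in most runs
  expect_gt(res$summary$fraction_Y0_gt_25, 0.8)
})
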