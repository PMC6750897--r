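#' Fit a divergence model to identity-vs-time observations
#'
#' Ordinary (unweighted) least squares over all pairwise observations, as in
#' the original analysis workflow: every ortholog pair contributes one point,
#' phylogenetic non-independence is deliberately ignored, and duplicated
#' observations count with their multiplicity. Optimization is multi-start
#' bounded quasi-Newton (L-BFGS-B): `R0` starts on a log grid in
#' `[0.05, 20]`, `alpha` on a log grid in `[0.1, 50]`, `Y0` starts at
#' `{0, 20, 40}`; bounds are `R0` in (0, 50], `Y0` in [0, 100], `alpha` in
#' (0, 100]. The asymptotic covariance of the free parameters is computed
#' from the Jacobian of the model at the optimum,
#' `sigma^2 * (J'J)^{-1}` with `sigma^2 = rss / (n - p)`.
#'
#' @param obs Data frame of divergence observations with columns
#'   `identity` (percent, `identity_pct` accepted) and `time` (Gy,
#'   `time_gy` accepted); extra columns (`pair_id`, `family_id`,
#'   `time_min`, `time_max`) are carried along untouched.
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param min_times Minimum number of distinct divergence times required
#'   (default 5; the validated-annotation reanalysis uses 4).
#' @param n_starts Number of multi-start grid points per nonlinear
#'   parameter.
#' @return An object of class `"div_fit"`: a list with `params`
#'   ([model_params()]), `coef` (named free-parameter vector), `vcov`,
#'   `rss`, `n`, `df.residual`, `converged`, and the fitting data.
#'   Non-convergence is flagged, not raised. Use [tidy()] / [glance()] for
#'   tabular summaries.
#' @examples
#' obs <- simulate_observations(model_params("M2", R0 = 1.5, Y0 = 40),
#'                              times = c(0.5, 1, 2, 3, 4),
#'                              noise_sd = 0, n_per_time = 1, seed = 1)
#' fit <- fit_divergence_model(obs, "M2")
#' tidy(fit)
#' @export
fit_divergence_model <- function(obs, model = c("M1", "M2", "M3"),
                                 min_times = 5L, n_starts = 10L) {
  model <- match.arg(model)
  obs <- normalize_obs(obs)
  n <- nrow(obs)
  n_times <- length(unique(obs$time))
  if (n_times < min_times) {
    abort(sprintf("Need observations at >= %d distinct divergence times (have %d).",
                  min_times, n_times),
          class = "divlimit_too_few_times")
  }

  y <- obs$identity
  t <- obs$time

  predict_free <- function(theta) {
    switch(model,
      M1 = 100 * exp(-theta[["R0"]] * t),
      M2 = theta[["Y0"]] + (100 - theta[["Y0"]]) * exp(-theta[["R0"]] * t),
      M3 = 100 * (theta[["R0"]] * t / theta[["alpha"]] + 1)^(-theta[["alpha"]])
    )
  }
  rss_fn <- function(theta) {
    r <- y - predict_free(theta)
    sum(r * r)
  }

  eps <- 1e-8
  lower <- switch(model,
    M1 = c(R0 = eps),
    M2 = c(R0 = eps, Y0 = 0),
    M3 = c(R0 = eps, alpha = eps)
  )
  upper <- switch(model,
    M1 = c(R0 = 50),
    M2 = c(R0 = 50, Y0 = 100),
    M3 = c(R0 = 50, alpha = 100)
  )

  r0_grid <- exp(seq(log(0.05), log(20), length.out = n_starts))
  starts <- switch(model,
    M1 = lapply(r0_grid, function(r) c(R0 = r)),
    M2 = {
      g <- expand.grid(R0 = r0_grid, Y0 = c(0, 20, 40))
      lapply(seq_len(nrow(g)), function(i) c(R0 = g$R0[i], Y0 = g$Y0[i]))
    },
    M3 = {
      a_grid <- exp(seq(log(0.1), log(50), length.out = n_starts))
      lapply(seq_len(n_starts), function(i) c(R0 = r0_grid[i], alpha = a_grid[i]))
    }
  )

  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, rss_fn, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort("All optimization starts failed.", class = "divlimit_fit_error")
  }

  # L-BFGS-B can land a hair outside its box through floating-point fuzz
  theta <- pmin(pmax(best$par, lower), upper)
  p <- length(theta)
  rss <- best$value
  sigma2 <- rss / max(n - p, 1)
  J <- numeric_jacobian(predict_free, theta)
  vcov <- tryCatch({
    V <- sigma2 * solve(crossprod(J))
    dimnames(V) <- list(names(theta), names(theta))
    V
  }, error = function(e) {
    V <- matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
    V
  })

  params <- switch(model,
    M1 = model_params("M1", R0 = theta[["R0"]]),
    M2 = model_params("M2", R0 = theta[["R0"]], Y0 = theta[["Y0"]]),
    M3 = model_params("M3", R0 = theta[["R0"]], alpha = theta[["alpha"]])
  )

  structure(list(
    params = params,
    coef = theta,
    vcov = vcov,
    rss = rss,
    n = n,
    df.residual = n - p,
    converged = any_converged,
    data = obs
  ), class = "div_fit")
}

normalize_obs <- function(obs) {
  obs <- tibble::as_tibble(obs)
  if (!"identity" %in% names(obs) && "identity_pct" %in% names(obs)) {
    obs <- dplyr::rename(obs, identity = "identity_pct")
  }
  if (!"time" %in% names(obs) && "time_gy" %in% names(obs)) {
    obs <- dplyr::rename(obs, time = "time_gy")
  }
  if ("time_min_gy" %in% names(obs)) obs <- dplyr::rename(obs, time_min = "time_min_gy")
  if ("time_max_gy" %in% names(obs)) obs <- dplyr::rename(obs, time_max = "time_max_gy")
  if (!all(c("identity", "time") %in% names(obs))) {
    abort("Observations need `identity` and `time` columns.",
          class = "divlimit_invalid_input")
  }
  if (any(obs$identity < 0 | obs$identity > 100) || any(obs$time < 0)) {
    abort("Identity must be in [0, 100] percent and time >= 0 Gy.",
          class = "divlimit_invalid_input")
  }
  obs
}

# forward-difference Jacobian of a vector-valued function of named theta
numeric_jacobian <- function(f, theta, rel_h = 1e-6) {
  f0 <- f(theta)
  J <- matrix(0, length(f0), length(theta))
  for (k in seq_along(theta)) {
    h <- max(abs(theta[k]), 1e-4) * rel_h
    th <- theta
    th[k] <- th[k] + h
    J[, k] <- (f(th) - f0) / h
  }
  J
}

#' @export
print.div_fit <- function(x, ...) {
  cat(sprintf("<div_fit %s: n = %d, rss = %.4g, converged = %s>\n",
              x$params$model, x$n, x$rss, x$converged))
  print(x$params)
  invisible(x)
}

#' @method coef div_fit
#' @export
coef.div_fit <- function(object, ...) object$coef

#' @method vcov div_fit
#' @export
vcov.div_fit <- function(object, ...) object$vcov

#' Tidy a fitted divergence model
#'
#' @param x A `"div_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.div_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(term = names(x$coef),
                 estimate = unname(x$coef),
                 std.error = unname(se))
}

#' Glance at a fitted divergence model
#'
#' @param x A `"div_fit"` object.
#' @param ... Unused.
#' @return One-row tibble: `model`, `rss`, `sigma`, `n`, `df.residual`,
#'   `converged`.
#' @export
glance.div_fit <- function(x, ...) {
  tibble::tibble(model = x$params$model, rss = x$rss,
                 sigma = sqrt(x$rss / max(x$df.residual, 1)),
                 n = x$n, df.residual = x$df.residual,
                 converged = x$converged)
}

#' F-test comparing the nested divergence models
#'
#' Compares the single-exponential model (M1) against the divergence-floor
#' model (M2) fitted to the same observations:
#' `F = (rss1 - rss2) / (rss2 / (n - 2))` on `(1, n - 2)` degrees of
#' freedom. A negative numerator (an optimizer artifact on the nested pair)
#' is clamped to `F = 0`.
#'
#' @param fit1 A `"div_fit"` for M1.
#' @param fit2 A `"div_fit"` for M2, same observations.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p.value`, `rss1`,
#'   `rss2`.
#' @export
f_test_nested <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "div_fit"), inherits(fit2, "div_fit"))
  if (fit1$params$model != "M1" || fit2$params$model != "M2") {
    abort("`f_test_nested()` compares an M1 fit against an M2 fit.",
          class = "divlimit_invalid_input")
  }
  if (fit1$n != fit2$n) {
    abort("Both fits must use the same observations.", class = "divlimit_invalid_input")
  }
  n <- fit1$n
  if (n <= 2) abort("Need n > 2 observations.", class = "divlimit_insufficient_data")
  Fstat <- max((fit1$rss - fit2$rss) / 1, 0) / (fit2$rss / (n - 2))
  tibble::tibble(statistic = Fstat, df1 = 1, df2 = n - 2,
                 p.value = pf(Fstat, 1, n - 2, lower.tail = FALSE),
                 rss1 = fit1$rss, rss2 = fit2$rss)
}

#' Wald test of the divergence floor against a baseline identity
#'
#' One-sided test of whether the fitted long-term identity floor `Y0`
#' exceeds a baseline (by default the random-alignment identity of
#' unrelated proteins, 13.5%): `z = (Y0 - baseline) / SE(Y0)`, upper normal
#' tail.
#'
#' @param fit2 A converged `"div_fit"` for M2.
#' @param baseline Baseline identity in percent (default 13.5; see
#'   [random_identity_baseline()] for estimating it afresh).
#' @return One-row tibble: `estimate` (Y0), `std.error`, `baseline`,
#'   `statistic` (z), `p.value`.
#' @export
wald_test_floor <- function(fit2, baseline = 13.5) {
  stopifnot(inherits(fit2, "div_fit"))
  if (fit2$params$model != "M2") {
    abort("`wald_test_floor()` needs an M2 fit.", class = "divlimit_invalid_input")
  }
  se <- sqrt(fit2$vcov["Y0", "Y0"])
  if (!is.finite(se) || se <= 0) {
    abort("Standard error of Y0 is zero or undefined (degenerate fit).",
          class = "divlimit_degenerate_fit")
  }
  z <- (fit2$coef[["Y0"]] - baseline) / se
  tibble::tibble(estimate = fit2$coef[["Y0"]], std.error = se,
                 baseline = baseline, statistic = z,
                 p.value = pnorm(z, lower.tail = FALSE))
}

#' Project identity to a future horizon
#'
#' Evaluates a fitted model at a divergence-time horizon (default 7.8 Gy,
#' roughly the remaining habitable lifetime of Earth added to the deepest
#' divergences in the data).
#'
#' @param fit A `"div_fit"` or [model_params()] object.
#' @param horizon Horizon in Gy, `>= 0`.
#' @return Identity in percent.
#' @export
project_identity <- function(fit, horizon = 7.8) {
  evaluate_model(as_model_params(fit), check_time(horizon))
}

#' Propagate divergence-time uncertainty by min/max resampling
#'
#' Each distinct species pair's divergence time is independently set to its
#' reported minimum or maximum (fair coin) in every run; the floor model
#' (M2) and gamma-rates model (M3) are refitted per family and the fraction
#' of families whose long-term identity exceeds `threshold` is recorded:
#' for M2 via the fitted floor `Y0`, for M3 via the identity projected at
#' `horizon`.
#'
#' @param obs Observations (see [fit_divergence_model()]) with `family_id`,
#'   `time_min` and `time_max` columns; a `species_pair` column identifies
#'   which rows share one divergence-time estimate (defaults to the
#'   distinct `(time, time_min, time_max)` triple).
#' @param n_runs Number of independent assignment runs.
#' @param seed RNG seed.
#' @param threshold Long-term identity threshold in percent (default 25).
#' @param horizon Projection horizon for M3 in Gy (default 7.8).
#' @param min_times Passed to [fit_divergence_model()].
#' @return A list with `runs` (tibble: `run`, `frac_Y0_gt`,
#'   `frac_projected_gt`) and `summary` (one-row tibble with the mean
#'   fractions `fraction_Y0_gt_25` and `fraction_projected_gt_25` across
#'   runs; `NA` when `n_runs = 0`).
#' @export
resample_divergence_times <- function(obs, n_runs = 1000L, seed = 0L,
                                      threshold = 25, horizon = 7.8,
                                      min_times = 5L) {
  obs <- normalize_obs(obs)
  if (!all(c("time_min", "time_max") %in% names(obs)) ||
      any(!is.finite(obs$time_min)) || any(!is.finite(obs$time_max))) {
    abort("Resampling needs `time_min` and `time_max` for every observation.",
          class = "divlimit_configuration_error")
  }
  if (any(obs$time_min > obs$time_max)) {
    abort("`time_min` must not exceed `time_max`.", class = "divlimit_configuration_error")
  }
  if (!"family_id" %in% names(obs)) obs$family_id <- "family1"
  if (!"species_pair" %in% names(obs)) {
    obs$species_pair <- paste(obs$time, obs$time_min, obs$time_max, sep = "|")
  }
  pairs <- unique(obs$species_pair)

  runs <- with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_runs), function(run) {
      take_max <- setNames(runif(length(pairs)) < 0.5, pairs)
      obs2 <- obs
      obs2$time <- ifelse(take_max[obs2$species_pair], obs2$time_max, obs2$time_min)
      fam <- dplyr::group_split(dplyr::group_by(obs2, .data$family_id))
      res <- purrr::map_lgl(fam, function(d) {
        f2 <- tryCatch(fit_divergence_model(d, "M2", min_times = min_times),
                       error = function(e) NULL)
        !is.null(f2) && f2$coef[["Y0"]] > threshold
      })
      res3 <- purrr::map_lgl(fam, function(d) {
        f3 <- tryCatch(fit_divergence_model(d, "M3", min_times = min_times),
                       error = function(e) NULL)
        !is.null(f3) && project_identity(f3, horizon) > threshold
      })
      tibble::tibble(run = run, frac_Y0_gt = mean(res), frac_projected_gt = mean(res3))
    })
  })
  if (n_runs == 0) {
    runs <- tibble::tibble(run = integer(), frac_Y0_gt = numeric(),
                           frac_projected_gt = numeric())
  }
  list(
    runs = runs,
    summary = tibble::tibble(
      fraction_Y0_gt_25 = if (n_runs > 0) mean(runs$frac_Y0_gt) else NA_real_,
      fraction_projected_gt_25 = if (n_runs > 0) mean(runs$frac_projected_gt) else NA_real_
    )
  )
}
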