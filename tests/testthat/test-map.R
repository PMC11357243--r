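test_that("MAP optimizer reproduces the conjugate posterior on a linear-Gaussian surrogate", {
  # identity model y = eta + eps with a normal prior: the MAP estimate is
  # the precision-weighted posterior mean
  theta <- 2.0; omega2 <- 0.5^2; sigma <- 0.3; y <- 2.9
  fit <- map_optimize(function(z) z, y, prior_z = theta, omega2 = omega2,
                      sigma = sigma, lower = -10, upper = 10)
  expect_equal(fit$z, (omega2 * y + sigma^2 * theta) / (omega2 + sigma^2),
               tolerance = 1e-5)
  # several observations
  ys <- c(2.9, 3.1, 2.5)
  fit2 <- map_optimize(function(z) rep(z, 3), ys, theta, omega2, sigma,
                       -10, 10)
  post <- (omega2 * mean(ys) * 3 / sigma^2 + theta / 1) /
    (3 * omega2 / sigma^2 + 1)
  expect_equal(fit2$z, post, tolerance = 1e-5)
  # prior dominance: omega -> 0 returns the prior mode
  fit3 <- map_optimize(function(z) z, 10, theta, 1e-10, sigma, -10, 10)
  expect_equal(fit3$z, theta, tolerance = 1e-4)
})

test_that("day-zero equilibration retains the prior for a self-consistent observation", {
  pr <- prior_spec(params = nominal)
  d0 <- fit_day0_equilibrium(nominal$norm_plasma_K, prior = pr,
                             params = nominal)
  for (pn in estimable_parameters())
    expect_equal(unname(d0$eta[[pn]]), unname(pr$theta[[pn]]),
                 tolerance = 0.02)
  kss <- d0$state[["K_ecf"]] / d0$params$V_ecf * 1000
  expect_equal(kss, nominal$norm_plasma_K, tolerance = 0.01)
  # a GFR covariate scales the nephron number proportionally before fitting
  d1 <- fit_day0_equilibrium(4.2, covariates = list(GFR = 50), prior = pr,
                             params = nominal)
  expect_equal(d1$params$N_nephrons / nominal$N_nephrons, 0.5)
  # a high observed potassium pulls the estimates away from the prior
  d2 <- fit_day0_equilibrium(5.4, prior = pr, params = nominal)
  pp <- do.call(set_parameter, c(list(nominal), as.list(d2$eta)))
  k2 <- spirok:::steady_state_analytic(pp)[["K_ecf"]] / pp$V_ecf * 1000
  expect_gt(k2, 4.8)
})

test_that("sequential updates respect prior and likelihood limits", {
  pr <- prior_spec(params = nominal)
  d0 <- fit_day0_equilibrium(4.2, prior = pr, params = nominal)
  reg <- dose_regimen(1800, "spironolactone", 50)
  # an observation exactly on the prediction leaves the estimates unchanged
  pred <- spirok:::simulate_course(d0$eta, d0$params, d0$state, 0, reg,
                                   upto = 2000, times = 1990)$K
  up <- map_update(d0$eta, pr$omega2, pr$residual_sd,
                   data.frame(time = 1990, value = pred),
                   d0$params, d0$state, 0, reg)
  for (pn in names(up$eta))
    expect_equal(unname(up$eta[[pn]]), unname(d0$eta[[pn]]),
                 tolerance = 0.01)
  # omega -> 0 pins the update to the carried-forward prior even for a
  # discrepant observation
  up0 <- map_update(d0$eta, pr$omega2 * 1e-8, pr$residual_sd,
                    data.frame(time = 1990, value = pred + 0.8),
                    d0$params, d0$state, 0, reg)
  for (pn in setdiff(names(up0$eta), "V_ecf"))
    expect_equal(unname(up0$eta[[pn]]), unname(d0$eta[[pn]]),
                 tolerance = 1e-3)
  expect_error(map_update(d0$eta, pr$omega2, 0.2,
                          data.frame(time = numeric(0), value = numeric(0)),
                          d0$params, d0$state, 0, reg))
})

test_that("forecasts are flat at equilibrium and rise under planned spironolactone", {
  d0 <- fit_day0_equilibrium(4.2, prior = prior_spec(params = nominal),
                             params = nominal)
  flat <- forecast_day(d0$eta, d0$params, d0$state, 0, dose_regimen())
  expect_lt(diff(range(flat$K_pred)), 0.02)
  dosed <- forecast_day(d0$eta, d0$params, d0$state, 0,
                        dose_regimen(120, "spironolactone", 100))
  expect_gt(max(dosed$K_pred - flat$K_pred), 0.05)
  expect_true(all(dosed$K_pred >= flat$K_pred - 1e-6))
})

test_that("state carry-over is continuous across simulation-only days", {
  d0 <- fit_day0_equilibrium(4.2, prior = prior_spec(params = nominal),
                             params = nominal)
  reg <- dose_regimen(c(480, 1920), rep("spironolactone", 2), c(50, 50))
  a <- spirok:::simulate_course(d0$eta, d0$params, d0$state, 0, reg, 1440)
  b <- spirok:::simulate_course(d0$eta, d0$params, a$terminal, 1440, reg, 2880)
  direct <- spirok:::simulate_course(d0$eta, d0$params, d0$state, 0, reg, 2880)
  expect_equal(b$terminal, direct$terminal, tolerance = 1e-5)
})

test_that("the sequential scheme uses only information available at each split", {
  pt <- make_patient(days = 4, residual_sd = 0.1, seed = 21)
  lg <- run_sequential_forecast(pt, prior_spec(params = nominal), nominal,
                                settings = forecast_settings(n_starts = 2))
  for (sp in lg$splits) {
    if (length(sp$obs_used_times))
      expect_lte(max(sp$obs_used_times), sp$time)
    expect_true(all(sp$pairs$time > sp$time))
    expect_true(all(sp$pairs$time <= sp$time + 1440))
  }
  # split schedule alternates midnight and 11 am
  types <- vapply(lg$splits, `[[`, character(1), "type")
  expect_true(all(types %in% c("midnight", "11am")))
  expect_true(any(types == "midnight") && any(types == "11am"))
})

test_that("a patient with a single day-zero observation is simulated, never updated", {
  pt <- make_patient(days = 3, obs_times = 400, seed = 5)
  lg <- run_sequential_forecast(pt, prior_spec(params = nominal), nominal,
                                settings = forecast_settings(n_starts = 2))
  expect_true(all(!vapply(lg$splits, `[[`, logical(1), "updated")))
  expect_equal(nrow(lg$pairs), 0)
})

test_that("a morning observation is seen by the 11 am split but not by midnight", {
  pt <- make_patient(days = 5, obs_times = c(400, 3 * 1440 + 540), seed = 6)
  lg <- run_sequential_forecast(pt, prior_spec(params = nominal), nominal,
                                settings = forecast_settings(n_starts = 2))
  mid3 <- Filter(function(s) s$time == 3 * 1440 && s$type == "midnight",
                 lg$splits)[[1]]
  am3 <- Filter(function(s) s$time == 3 * 1440 + 660 && s$type == "11am",
                lg$splits)[[1]]
  expect_false(mid3$updated)
  expect_equal(mid3$n_obs_used, 0)
  expect_true(am3$updated)
  expect_equal(am3$obs_used_times, 3 * 1440 + 540)
})

test_that("noise-free observations from a known individual recover its parameters", {
  eta_true <- c(Kin = nominal$Kin * 1.25, V_ecf = 15000)
  pt <- make_patient(days = 10, eta = eta_true, residual_sd = 0,
                     spiro_mg = 100, seed = 31)
  lg <- run_sequential_forecast(pt, prior_spec(params = nominal), nominal,
                                settings = forecast_settings(n_starts = 2))
  final_eta <- lg$splits[[length(lg$splits)]]$eta
  expect_lt(abs(final_eta[["Kin"]] - eta_true[["Kin"]]) / eta_true[["Kin"]],
            0.10)
  # and the late predictions track the truth closely
  late <- lg$pairs[lg$pairs$split_time >= 5 * 1440, ]
  expect_lt(aafe(late$predicted, late$observed), 1.05)
  # V_ecf was estimated at day zero only and stays frozen across splits
  v <- vapply(lg$splits, function(s) s$eta[["V_ecf"]], numeric(1))
  expect_true(all(v == lg$day0$eta[["V_ecf"]]))
})

test_that("administration-time jitter degrades forecast accuracy on average", {
  aafe_at <- function(jitter_sd, seed) {
    cfg <- cohort_config(n_patients = 1, los_median_days = 4, los_sdlog = 0,
                         los_jitter_sd = 0, supplementation_fraction = 0,
                         iiv = data.frame(parameter = estimable_parameters(),
                                          cv_percent = c(10, 0, 10, 20, 0)),
                         residual_sd = 0.03, spiro_doses_mg = 100,
                         admin_jitter_sd = jitter_sd, seed = seed)
    coh <- generate_cohort(cfg, nominal)
    lg <- run_sequential_forecast(coh[[1]], prior_spec(params = nominal),
                                  nominal,
                                  settings = forecast_settings(n_starts = 2))
    if (nrow(lg$pairs) == 0) return(NA_real_)
    aafe(lg$pairs$predicted, lg$pairs$observed)
  }
  # paired replicates: the same seed generates the same patient, only the
  # magnitude of the planned-vs-actual administration shift differs
  reps <- 1:20
  a0 <- vapply(reps, function(s) aafe_at(0, s), numeric(1))
  a1 <- vapply(reps, function(s) aafe_at(60, s), numeric(1))
  a2 <- vapply(reps, function(s) aafe_at(120, s), numeric(1))
  m <- c(mean(a0, na.rm = TRUE), mean(a1, na.rm = TRUE),
         mean(a2, na.rm = TRUE))
  expect_gt(m[2], m[1] - 0.002)
  expect_gt(m[3], m[2] - 0.002)
  expect_gt(m[3], m[1])
})
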