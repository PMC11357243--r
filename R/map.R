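#' Prior specification for individual Bayesian estimation
#'
#' @param theta Named prior means of the estimable parameters; defaults to
#'   the nominal physiological values.
#' @param omega2 Named random-effect variances on the transform scale;
#'   defaults to [default_iiv()].
#' @param residual_sd Additive residual SD on potassium, mEq/L.
#' @param params Nominal `qsp_parameters` used for defaulting `theta`.
#' @return `prior_spec` object.
#' @export
prior_spec <- function(theta = NULL, omega2 = NULL, residual_sd = 0.2,
                       params = build_nominal_parameters()) {
  sel <- estimable_parameters()
  if (is.null(theta))
    theta <- setNames(as.numeric(unlist(params[sel])), sel)
  if (is.null(omega2)) {
    d <- default_iiv()
    omega2 <- setNames(d$omega2, d$parameter)[sel]
  }
  stopifnot(all(sel %in% names(theta)), all(sel %in% names(omega2)),
            all(omega2 >= 0), residual_sd > 0)
  ef <- param_ranges("efast")
  for (pn in sel)
    if (theta[[pn]] < ef[[pn]][1] - 1e-9 || theta[[pn]] > ef[[pn]][2] + 1e-9)
      warning("prior mean of ", pn, " outside the physiological range")
  structure(list(theta = theta[sel], omega2 = omega2[sel],
                 residual_sd = residual_sd), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec>\n")
  for (pn in names(x$theta))
    cat(sprintf("  %-18s theta = %-10.4g CV = %.1f%%\n", pn, x$theta[[pn]],
                100 * omega2_to_cv(x$omega2[[pn]], pn)))
  cat(sprintf("  residual SD = %.2f mEq/L\n", x$residual_sd))
  invisible(x)
}

#' Bounded multi-start MAP optimization
#'
#' Minimizes the MAP objective
#' `sum((pred - obs)^2) / (2 sigma^2) + sum((z - prior_z)^2 / (2 omega2))`
#' over the transform-scale parameters `z`, with L-BFGS-B under box bounds
#' and deterministic multi-starts spread at `0, +-0.5, +-1` prior SDs around
#' the prior mode. Exposed separately so the estimator can be validated on
#' surrogate models with closed-form posteriors.
#'
#' @param predict_fn Function of `z` returning predictions aligned to `obs`.
#' @param obs Observation vector.
#' @param prior_z Prior mode on the transform scale.
#' @param omega2 Prior variances (transform scale).
#' @param sigma Residual SD.
#' @param lower,upper Bounds on `z`.
#' @param n_starts Number of multi-starts (1..5).
#' @return List with `z`, `value`, `convergence`, `at_bound`.
#' @export
map_optimize <- function(predict_fn, obs, prior_z, omega2, sigma,
                         lower, upper, n_starts = 5) {
  d <- length(prior_z)
  omega2 <- pmax(omega2, 1e-10)
  obj <- function(z) {
    pred <- try(predict_fn(z), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred))) return(1e8)
    sum((pred - obs)^2) / (2 * sigma^2) +
      sum((z - prior_z)^2 / (2 * omega2))
  }
  spread <- c(0, 0.5, -0.5, 1, -1)[seq_len(max(1, min(n_starts, 5)))]
  best <- NULL
  for (sp in spread) {
    z0 <- pmin(pmax(prior_z + sp * sqrt(omega2), lower), upper)
    fit <- try(stats::optim(z0, obj, method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(maxit = 100, factr = 1e9)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("MAP optimization failed from every start")
  at_bound <- (best$par - lower < 1e-6) | (upper - best$par < 1e-6)
  list(z = best$par, value = best$value, convergence = best$convergence,
       at_bound = at_bound)
}

estimation_bounds <- function(sel) {
  b <- param_ranges("clinical")[sel]
  list(
    lower = vapply(sel, function(pn)
      if (iiv_transform(pn) == "log") log(b[[pn]][1]) else b[[pn]][1],
      numeric(1)),
    upper = vapply(sel, function(pn)
      if (iiv_transform(pn) == "log") log(b[[pn]][2]) else b[[pn]][2],
      numeric(1))
  )
}

#' Day-zero equilibration fit
#'
#' Fits the five estimable parameters to the first potassium observation by
#' MAP, with the model evaluated at its drug-free equilibrium (the long
#' equilibration offset of t = 3000 min). Covariates are applied first: an
#' observed GFR scales the nephron number proportionally, an observed sodium
#' sets the sodium normal value. Returns the individual estimates and the
#' equilibrium state, which provides the initial values of the state
#' variables for the sequential forecast.
#'
#' @param first_K_obs First observed plasma potassium, mEq/L.
#' @param covariates List with optional `GFR` and `sodium`.
#' @param prior [prior_spec()].
#' @param params Nominal `qsp_parameters`.
#' @param n_starts Multi-starts for the MAP fit.
#' @param t_equil Equilibration offset, minutes.
#' @return List with `eta` (named, natural scale), `state` (equilibrium
#'   `qsp_state`), `params` (covariate-adjusted base set), `at_bound`.
#' @export
fit_day0_equilibrium <- function(first_K_obs, covariates = list(),
                                 prior = prior_spec(),
                                 params = build_nominal_parameters(),
                                 n_starts = 5, t_equil = 3000) {
  stopifnot(is.finite(first_K_obs), first_K_obs > 0)
  sel <- estimable_parameters()
  base <- apply_covariates(params, GFR = covariates$GFR,
                           sodium = covariates$sodium)
  bz <- estimation_bounds(sel)
  prior_z <- eta_to_z(as.list(prior$theta))
  predict_fn <- function(z) {
    eta <- z_to_eta(setNames(as.list(z), sel))
    pp <- do.call(set_parameter, c(list(base), as.list(eta)))
    st <- steady_state_analytic(pp)  # the model state after the offset
    unname(st["K_ecf"] / pp$V_ecf * 1000)
  }
  fit <- map_optimize(predict_fn, first_K_obs, prior_z, prior$omega2,
                      prior$residual_sd, bz$lower, bz$upper, n_starts)
  eta <- z_to_eta(setNames(as.list(fit$z), sel))
  pp <- do.call(set_parameter, c(list(base), as.list(eta)))
  state <- find_steady_state(pp, t_equil = t_equil)
  list(eta = eta, state = state, params = base, at_bound = fit$at_bound,
       convergence = fit$convergence)
}

# Simulate the patient's course from the day-0 equilibrium under individual
# parameters eta, applying the planned regimen, and return K at `times` plus
# the terminal state at `upto`.
simulate_course <- function(eta, base_params, state0, t0, regimen, upto,
                            times = NULL, dt = 120, rtol = 1e-6, atol = 1e-8) {
  pp <- do.call(set_parameter, c(list(base_params), as.list(eta)))
  tr <- simulate_qsp(pp, initial_state = state0, regimen = regimen,
                     horizon = max(upto - t0, 1), dt = dt, t0 = t0,
                     times = times, rtol = rtol, atol = atol)
  list(
    K = if (!is.null(times)) tr$K_plasma[match(times, tr$time)],
    terminal = setNames(as.numeric(tr[nrow(tr), qsp_state_names()]),
                        qsp_state_names())
  )
}

#' Sequential MAP update of individual parameters
#'
#' Re-estimates the free individual parameters (all estimable parameters
#' except the extracellular fluid volume, which is estimated only once at
#' day zero) from the observations of the current window, with the previous
#' estimates as prior modes (theta' = eta) and the maintained IIV Omega.
#'
#' @param eta_prior Current individual estimates (named, natural scale).
#' @param omega2 IIV variances (named, transform scale).
#' @param residual_sd Residual SD, mEq/L.
#' @param window_obs Data frame (time, value) of potassium observations.
#' @param base_params Covariate-adjusted `qsp_parameters`.
#' @param state0,t0 Model state and time at the start of the estimation
#'   window (the last successful update; the day-zero equilibrium for the
#'   first one).
#' @param regimen Planned [dose_regimen()] covering the window.
#' @param n_starts Multi-starts.
#' @return List with updated `eta`, `at_bound`, `convergence`, `value`.
#' @export
map_update <- function(eta_prior, omega2, residual_sd, window_obs,
                       base_params, state0, t0, regimen, n_starts = 5) {
  stopifnot(nrow(window_obs) >= 1)
  sel <- estimable_parameters()
  free <- setdiff(sel, "V_ecf")
  bz <- estimation_bounds(free)
  prior_z <- eta_to_z(as.list(eta_prior[free]))
  predict_fn <- function(z) {
    eta <- eta_prior
    eta[free] <- z_to_eta(setNames(as.list(z), free))
    simulate_course(eta, base_params, state0, t0, regimen,
                    upto = max(window_obs$time) + 1,
                    times = window_obs$time)$K
  }
  fit <- map_optimize(predict_fn, window_obs$value, prior_z,
                      omega2[free], residual_sd, bz$lower, bz$upper, n_starts)
  eta <- eta_prior
  eta[free] <- z_to_eta(setNames(as.list(fit$z), free))
  list(eta = eta, at_bound = fit$at_bound, convergence = fit$convergence,
       value = fit$value)
}

#' Forecast the following 24 hours
#'
#' Simulates one day ahead from the current model state under the current
#' individual estimates, including the planned administrations of the
#' upcoming day.
#'
#' @param eta Individual estimates (named, natural scale).
#' @param base_params Covariate-adjusted `qsp_parameters`.
#' @param state Current model state (named vector).
#' @param from Split time, minutes.
#' @param regimen Planned [dose_regimen()] (absolute times).
#' @param grid_dt Prediction grid step, minutes (<= 5 for observation
#'   matching).
#' @return Data frame (time, K_pred).
#' @export
forecast_day <- function(eta, base_params, state, from, regimen,
                         grid_dt = 5) {
  pp <- do.call(set_parameter, c(list(base_params), as.list(eta)))
  tr <- simulate_qsp(pp, initial_state = state, regimen = regimen,
                     horizon = 1440, dt = grid_dt, t0 = from)
  data.frame(time = tr$time, K_pred = tr$K_plasma)
}

#' Forecast settings
#'
#' @param n_starts MAP multi-starts per estimation.
#' @param grid_dt Prediction grid, minutes.
#' @param plausibility_band Clinical plausibility band for predicted
#'   potassium, mEq/L; predictions outside trigger iterative IIV shrinkage.
#' @param guard_max_iter Maximum shrinkage iterations per split.
#' @param window `"incremental"` (observations since the last successful
#'   update; default, matching the carry-forward prior design) or
#'   `"full_history"`.
#' @export
forecast_settings <- function(n_starts = 5, grid_dt = 5,
                              plausibility_band = c(2, 8),
                              guard_max_iter = 3,
                              window = c("incremental", "full_history")) {
  list(n_starts = n_starts, grid_dt = grid_dt,
       plausibility_band = plausibility_band,
       guard_max_iter = guard_max_iter, window = match.arg(window))
}

#' Run the sequential Bayesian forecast for one patient
#'
#' Implements the sequential scheme: day zero is the first day with a
#' potassium measurement, whose value anchors the day-zero equilibration fit
#' of all five parameters (the extracellular fluid volume is frozen
#' afterwards). From the next midnight on, estimation splits alternate at
#' 00:00 and 11:00; a split re-estimates the free parameters only if a new
#' observation arrived since the last successful update, using the previous
#' estimates as prior modes (theta' = eta) with the IIV Omega maintained,
#' and in every case simulates the following 24 h under the planned regimen.
#' Days without measurements are pure simulation, and the terminal state of
#' each day carries over to the next. Predictions outside the clinical
#' plausibility band trigger iterative shrinkage of Omega for that split.
#'
#' @param patient A patient record (see [generate_cohort()] /
#'   [read_event_table()]).
#' @param prior [prior_spec()].
#' @param params Nominal `qsp_parameters`.
#' @param settings [forecast_settings()].
#' @return `forecast_log`: list with `patient_id`, `day0` (eta, state, time),
#'   `splits` (per-split records incl. eta used, observations used, matched
#'   prediction/observation pairs, guard iterations), and `pairs` (pooled
#'   data frame: split_time, split_type, time, predicted, observed).
#' @export
run_sequential_forecast <- function(patient, prior = prior_spec(),
                                    params = build_nominal_parameters(),
                                    settings = forecast_settings()) {
  kobs <- patient$labs[patient$labs$analyte == "potassium", , drop = FALSE]
  kobs <- kobs[order(kobs$time), , drop = FALSE]
  if (nrow(kobs) < 1) stop("patient has no potassium observation")
  labs_f <- locf_impute(patient$labs)
  t0 <- kobs$time[1]
  cov_at <- function(an) {
    d <- labs_f[labs_f$analyte == an & labs_f$time <= t0, , drop = FALSE]
    if (nrow(d)) d$value[nrow(d)] else NULL
  }
  day0 <- fit_day0_equilibrium(kobs$value[1],
                               covariates = list(GFR = cov_at("GFR"),
                                                 sodium = cov_at("sodium")),
                               prior = prior, params = params,
                               n_starts = settings$n_starts)
  base <- day0$params
  regimen <- subject_regimen(patient, use_planned = TRUE)
  eta <- day0$eta
  last_update <- t0
  day0_day <- floor(t0 / 1440)
  end <- patient$discharge
  first_mid <- (day0_day + 1) * 1440
  mids <- if (first_mid < end) seq(first_mid, end - 1, by = 1440) else numeric(0)
  split_times <- sort(c(mids, mids + 660))
  split_times <- split_times[split_times < end]
  splits <- list(); pooled <- list()
  # model state carried forward from split to split ("final values on the
  # following day"); on re-estimation only the window since the last
  # successful update is re-simulated under the candidate parameters
  cur_state <- day0$state
  cur_time <- t0
  for (s in split_times) {
    type <- if (s %% 1440 == 0) "midnight" else "11am"
    full_hist <- settings$window == "full_history"
    from_state <- if (full_hist) day0$state else cur_state
    from_time <- if (full_hist) t0 else cur_time
    window_obs <- kobs[kobs$time > from_time & kobs$time <= s, , drop = FALSE]
    omega2_s <- prior$omega2
    guard_iter <- 0L
    repeat {
      updated <- FALSE; conv <- NA_integer_; at_bound <- NULL
      eta_s <- eta
      if (nrow(window_obs) > 0) {
        up <- try(map_update(eta, omega2_s, prior$residual_sd, window_obs,
                             base, from_state, from_time, regimen,
                             n_starts = settings$n_starts), silent = TRUE)
        if (!inherits(up, "try-error")) {
          eta_s <- up$eta; updated <- TRUE
          conv <- up$convergence; at_bound <- up$at_bound
        }
      }
      state_s <- simulate_course(eta_s, base, from_state, from_time, regimen,
                                 upto = s)$terminal
      state_s["K_excreted"] <- 0
      pred <- forecast_day(eta_s, base, state_s, s, regimen,
                           grid_dt = settings$grid_dt)
      inside <- all(pred$K_pred >= settings$plausibility_band[1] &
                    pred$K_pred <= settings$plausibility_band[2])
      if (inside || guard_iter >= settings$guard_max_iter || !updated) break
      omega2_s <- omega2_s * 0.25   # halve the IIV SDs and re-estimate
      guard_iter <- guard_iter + 1L
    }
    if (updated) { eta <- eta_s; last_update <- s }
    if (updated || nrow(window_obs) == 0) {
      # commit the carried state; after a failed update the state stays at
      # the last successful update so the window is retried next split
      cur_state <- state_s
      cur_time <- s
    }
    fut <- kobs[kobs$time > s & kobs$time <= s + 1440, , drop = FALSE]
    pairs <- if (nrow(fut)) {
      idx <- vapply(fut$time, function(tt) which.min(abs(pred$time - tt)),
                    integer(1))
      data.frame(time = fut$time, predicted = pred$K_pred[idx],
                 observed = fut$value)
    } else data.frame(time = numeric(0), predicted = numeric(0),
                      observed = numeric(0))
    splits[[length(splits) + 1]] <- list(
      time = s, type = type, updated = updated, eta = eta_s,
      obs_used_times = window_obs$time, n_obs_used = nrow(window_obs),
      guard_iterations = guard_iter, convergence = conv,
      at_bound = at_bound, pairs = pairs
    )
    if (nrow(pairs))
      pooled[[length(pooled) + 1]] <-
        cbind(split_time = s, split_type = type, pairs)
  }
  pooled_df <- if (length(pooled)) do.call(rbind, pooled)
    else data.frame(split_time = numeric(0), split_type = character(0),
                    time = numeric(0), predicted = numeric(0),
                    observed = numeric(0))
  structure(list(patient_id = patient$id,
                 day0 = list(time = t0, eta = day0$eta, state = day0$state,
                             at_bound = day0$at_bound),
                 splits = splits, pairs = pooled_df,
                 meta = patient$meta),
            class = "forecast_log")
}

#' @export
print.forecast_log <- function(x, ...) {
  cat(sprintf("<forecast_log> %s: %d splits (%d with update), %d prediction/observation pairs\n",
              x$patient_id, length(x$splits),
              sum(vapply(x$splits, `[[`, logical(1), "updated")),
              nrow(x$pairs)))
  invisible(x)
}

#' Run the sequential forecast over a cohort
#'
#' @param cohort `qsp_cohort`.
#' @inheritParams run_sequential_forecast
#' @return List of `forecast_log` (class `forecast_set`).
#' @export
forecast_cohort <- function(cohort, prior = prior_spec(),
                            params = build_nominal_parameters(),
                            settings = forecast_settings()) {
  logs <- lapply(cohort, run_sequential_forecast, prior = prior,
                 params = params, settings = settings)
  structure(logs, class = "forecast_set")
}
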