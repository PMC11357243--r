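#' Conversions between CV% and random-effect variance
#'
#' Parameters with strictly positive support carry log-normal random effects,
#' for which `omega^2 = log(1 + CV^2)` and `CV = sqrt(exp(omega^2) - 1)`.
#' The hyperaldosteronism effect spans negative values and carries an
#' additive normal random effect, for which the reported "CV" is the standard
#' deviation of the effect itself (the effect multiplies aldosterone
#' production as `1 + hyperaldo_effect`, so an SD of 0.36 corresponds to a
#' 36% spread of that multiplier around neutral).
#'
#' @param cv Coefficient of variation as a fraction (0.18 = 18%).
#' @param omega2 Random-effect variance on the transform scale.
#' @param parameter Parameter name (decides the transform).
#' @export
cv_to_omega2 <- function(cv, parameter) {
  stopifnot(cv >= 0)
  if (iiv_transform(parameter) == "log") log(1 + cv^2) else cv^2
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2, parameter) {
  stopifnot(omega2 >= 0)
  if (iiv_transform(parameter) == "log") sqrt(exp(omega2) - 1) else sqrt(omega2)
}

iiv_transform <- function(parameter) {
  if (parameter == "hyperaldo_effect") "identity" else "log"
}

eta_to_z <- function(eta) {
  vapply(names(eta), function(n)
    if (iiv_transform(n) == "log") log(eta[[n]]) else eta[[n]], numeric(1))
}

z_to_eta <- function(z) {
  vapply(names(z), function(n)
    if (iiv_transform(n) == "log") exp(z[[n]]) else z[[n]], numeric(1))
}

#' Default inter-individual variability magnitudes
#'
#' The CV% set used as forecasting priors when estimation is skipped:
#' sodium intake 5.2%, extracellular fluid volume 18%, hyperaldosteronism
#' effect 36%, and mineralocorticoid receptor abundance and potassium intake
#' both capped at 80% (raw historical estimates of 131% exceed the cap).
#'
#' @return Data frame (parameter, cv_percent, capped, omega2).
#' @export
default_iiv <- function() {
  d <- data.frame(
    parameter = c("Kin", "Nain", "V_ecf", "MR", "hyperaldo_effect"),
    cv_percent = c(80, 5.2, 18, 80, 36),
    capped = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
  d$omega2 <- mapply(function(cv, pn) cv_to_omega2(cv / 100, pn),
                     d$cv_percent, d$parameter)
  d
}

#' Cap IIV estimates
#'
#' CVs above the cap are replaced by the cap (flagged `capped`) and the
#' random-effect variances recomputed from the capped CVs. A CV exactly at
#' the cap is left uncapped.
#'
#' @param estimates Data frame with columns `parameter`, `cv_percent` (and
#'   optionally `omega2`, `capped`).
#' @param cap Cap in percent.
#' @export
cap_iiv <- function(estimates, cap = 80) {
  stopifnot(is.data.frame(estimates), "cv_percent" %in% names(estimates))
  over <- estimates$cv_percent > cap
  estimates$capped <- over
  estimates$cv_percent[over] <- cap
  estimates$omega2 <- mapply(function(cv, pn) cv_to_omega2(cv / 100, pn),
                             estimates$cv_percent, estimates$parameter)
  estimates
}

# Predicted plasma K for one subject at the observation times, given
# individual parameter values (named), the subject's covariate-adjusted
# parameter set, and the dose regimen on the planned-time clock.
subject_predict <- function(eta, base_params, doses, obs_times,
                            rtol = 1e-6, atol = 1e-8) {
  pp <- do.call(set_parameter, c(list(base_params), as.list(eta)))
  init <- steady_state_analytic(pp)
  horizon <- max(obs_times, doses$time[nrow(doses)], 1440) + 1
  tr <- simulate_qsp(pp, initial_state = init, regimen = doses,
                     horizon = horizon, dt = horizon / 8, times = obs_times,
                     rtol = rtol, atol = atol)
  tr$K_plasma[match(obs_times, tr$time)]
}

subject_regimen <- function(patient, use_planned = TRUE) {
  d <- patient$doses
  if (is.null(d) || nrow(d) == 0) return(dose_regimen())
  tm <- if (use_planned && !is.null(d$planned_time)) d$planned_time else d$time
  dose_regimen(tm, d$drug, d$amount)
}

subject_base_params <- function(patient, params) {
  labs <- patient$labs
  g <- labs$value[labs$analyte == "GFR"]
  na <- labs$value[labs$analyte == "sodium"]
  apply_covariates(params,
                   GFR = if (length(g)) g[1] else NULL,
                   sodium = if (length(na)) na[1] else NULL)
}

#' Estimate inter-individual variability from a multi-subject cohort
#'
#' Hierarchical estimation of the random-effect variances (reported as CV%)
#' of selected model parameters from sparse potassium time series. The
#' estimator is an iterative MAP-EM scheme: each iteration computes
#' per-subject MAP estimates under the current variances (Laplace
#' approximation around the mode), then updates each variance with the
#' shrinkage-corrected moment `mean((z_i - mu)^2 + V_i)` where `V_i` is the
#' subject's posterior variance -- so variances are not deflated by the
#' shrinkage of the individual estimates. Population means stay fixed at the
#' nominal values (they are priors, not estimands) unless `update_means`.
#' Bounds are the clinically orientated parameter ranges, enforced as hard
#' constraints.
#'
#' @param cohort List of patient records (see [generate_cohort()]).
#' @param selected_params Parameters whose IIV is estimated.
#' @param params Nominal `qsp_parameters`.
#' @param residual_sd_init Initial additive residual SD on potassium, mEq/L.
#' @param estimate_residual Re-estimate the residual SD each iteration.
#' @param init_cv Initial CV (fraction) for every estimated parameter.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative change in the random-effect SDs below which iteration
#'   stops.
#' @param update_means Also update the population means (off by default).
#' @return List with `estimates` (parameter, cv_percent, capped, omega2,
#'   n_subjects), `residual_sd`, `eta` (per-subject modes, natural scale),
#'   `iterations`.
#' @export
estimate_iiv <- function(cohort, selected_params = estimable_parameters(),
                         params = build_nominal_parameters(),
                         residual_sd_init = 0.2, estimate_residual = TRUE,
                         init_cv = 0.20, max_iter = 8, tol = 0.02,
                         update_means = FALSE) {
  n_sub <- length(cohort)
  if (n_sub < 2) stop("need at least 2 subjects")
  subs <- lapply(cohort, function(pt) {
    k <- pt$labs[pt$labs$analyte == "potassium", , drop = FALSE]
    if (nrow(k) < 2) stop("every subject needs >= 2 potassium observations")
    list(bp = subject_base_params(pt, params),
         doses = subject_regimen(pt),
         times = k$time, obs = k$value)
  })
  d <- length(selected_params)
  bounds <- param_ranges("clinical")[selected_params]
  lower <- vapply(selected_params, function(pn)
    if (iiv_transform(pn) == "log") log(bounds[[pn]][1]) else bounds[[pn]][1],
    numeric(1))
  upper <- vapply(selected_params, function(pn)
    if (iiv_transform(pn) == "log") log(bounds[[pn]][2]) else bounds[[pn]][2],
    numeric(1))
  mu <- eta_to_z(setNames(as.list(unlist(params[selected_params])),
                          selected_params))
  omega2 <- vapply(selected_params, function(pn) cv_to_omega2(init_cv, pn),
                   numeric(1))
  sigma <- residual_sd_init
  # residual sum-of-squares part of the objective; the prior part is added
  # per EM iteration (omega2 changes between iterations)
  rss_fn <- function(su) function(z) {
    eta <- z_to_eta(setNames(as.list(z), selected_params))
    pred <- try(subject_predict(eta, su$bp, su$doses, su$times),
                silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred))) return(NA_real_)
    sum((pred - su$obs)^2)
  }
  z_modes <- matrix(rep(mu, each = n_sub), n_sub, d,
                    dimnames = list(NULL, selected_params))
  H_lik <- vector("list", n_sub)   # cached likelihood curvature per subject
  iter_done <- 0
  for (it in seq_len(max_iter)) {
    refresh_H <- it == 1 || it == 4
    fits <- lapply(seq_len(n_sub), function(i) {
      su <- subs[[i]]
      rss <- rss_fn(su)
      obj <- function(z) {
        r <- rss(z)
        if (!is.finite(r)) return(1e8)
        r / (2 * sigma^2) + sum((z - mu)^2 / (2 * omega2))
      }
      fit <- stats::optim(z_modes[i, ], obj, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = if (it == 1) 60 else 30,
                                         factr = 1e10))
      if (refresh_H || is.null(H_lik[[i]])) {
        H <- numeric_hessian(obj, fit$par, lower, upper)
        Hl <- H - diag(1 / omega2, d)
        # likelihood curvature scaled free of sigma so it can be reused
        H_lik[[i]] <<- pmax_psd(Hl) * sigma^2
      }
      Hcur <- H_lik[[i]] / sigma^2 + diag(1 / omega2, d)
      V <- tryCatch(diag(solve(Hcur)), error = function(e) omega2)
      V <- pmin(pmax(V, 0), omega2)  # posterior variance <= prior variance
      list(z = fit$par, V = V, rss = rss(fit$par), n = length(su$obs))
    })
    Z <- do.call(rbind, lapply(fits, `[[`, "z"))
    Vm <- do.call(rbind, lapply(fits, `[[`, "V"))
    z_modes <- Z
    if (update_means) mu <- colMeans(Z)
    omega2_new <- pmax(colMeans(sweep(Z, 2, mu)^2 + Vm), 1e-6)
    if (estimate_residual)
      sigma <- max(sqrt(sum(vapply(fits, `[[`, numeric(1), "rss")) /
                        sum(vapply(fits, `[[`, numeric(1), "n"))), 0.005)
    rel <- max(abs(sqrt(omega2_new) - sqrt(omega2)) /
                 pmax(sqrt(omega2), 1e-3))
    omega2 <- omega2_new
    iter_done <- it
    if (rel < tol && it > 2) break
  }
  cvs <- 100 * vapply(seq_along(selected_params), function(j)
    omega2_to_cv(omega2[j], selected_params[j]), numeric(1))
  est <- data.frame(parameter = selected_params, cv_percent = cvs,
                    capped = FALSE, omega2 = unname(omega2),
                    n_subjects = n_sub)
  rownames(est) <- NULL
  eta_nat <- sapply(seq_len(d), function(j)
    if (iiv_transform(selected_params[j]) == "log") exp(Z[, j]) else Z[, j])
  eta_nat <- matrix(eta_nat, nrow = n_sub,
                    dimnames = list(NULL, selected_params))
  list(estimates = est, residual_sd = sigma, eta = eta_nat,
       iterations = iter_done)
}

# clip a symmetric matrix to positive semidefinite via eigen decomposition
pmax_psd <- function(M, floor = 0) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, floor), nrow(M)) %*% t(e$vectors)
}

# Central-difference Hessian with bound-aware steps.
numeric_hessian <- function(f, x, lower = -Inf, upper = Inf, h_rel = 1e-3) {
  d <- length(x)
  h <- pmax(abs(x) * h_rel, 1e-4)
  h <- pmin(h, (upper - lower) / 4)
  f0 <- f(x)
  H <- matrix(0, d, d)
  fp <- numeric(d); fm <- numeric(d)
  step <- function(x, j, s) { x[j] <- min(max(x[j] + s, lower[j]), upper[j]); x }
  for (j in seq_len(d)) {
    fp[j] <- f(step(x, j, h[j])); fm[j] <- f(step(x, j, -h[j]))
    H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
  }
  if (d > 1) {
    for (j in seq_len(d - 1)) for (l in (j + 1):d) {
      fpp <- f(step(step(x, j, h[j]), l, h[l]))
      fmm <- f(step(step(x, j, -h[j]), l, -h[l]))
      H[j, l] <- H[l, j] <-
        (fpp - fp[j] - fp[l] + 2 * f0 - fm[j] - fm[l] + fmm) / (2 * h[j] * h[l])
    }
  }
  # guard against non-PD curvature from finite differences
  H[!is.finite(H)] <- 0
  diag(H) <- pmax(diag(H), 1e-8)
  H
}
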