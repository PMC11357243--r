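#' Dose regimen constructor
#'
#' @param time Dose times, minutes (non-negative).
#' @param drug Character, `"spironolactone"` (mg) or `"potassium_oral"` (mEq).
#' @param amount Dose amounts (positive).
#' @return A `dose_regimen` data frame sorted by time.
#' @export
dose_regimen <- function(time = numeric(), drug = character(),
                         amount = numeric()) {
  stopifnot(length(time) == length(drug), length(time) == length(amount))
  if (length(time)) {
    if (any(!is.finite(time)) || any(time < 0)) stop("dose times must be >= 0")
    if (any(!is.finite(amount)) || any(amount <= 0)) stop("doses must be positive")
    if (!all(drug %in% c("spironolactone", "potassium_oral")))
      stop("drug must be 'spironolactone' or 'potassium_oral'")
  }
  ord <- order(time)
  structure(data.frame(time = time[ord], drug = drug[ord],
                       amount = amount[ord], stringsAsFactors = FALSE),
            class = c("dose_regimen", "data.frame"))
}

regimen_events <- function(regimen, t0 = 0, t1 = Inf) {
  if (is.null(regimen) || nrow(regimen) == 0) return(NULL)
  keep <- regimen$time >= t0 & regimen$time <= t1
  if (!any(keep)) return(NULL)
  r <- regimen[keep, , drop = FALSE]
  data.frame(
    var = ifelse(r$drug == "spironolactone", "cren_gut", "K_gut"),
    time = r$time,
    value = r$amount,
    method = "add",
    stringsAsFactors = FALSE
  )
}

#' Evaluate the model derivatives at a state
#'
#' Thin wrapper around the compiled right-hand side; returns the state
#' derivative vector together with the derived outputs (plasma potassium,
#' segment fluxes, canrenone concentration, MR blockade).
#'
#' @param state Named state vector (see [find_steady_state()]).
#' @param t Time, minutes.
#' @param params `qsp_parameters`.
#' @return List with `derivatives` (named vector) and `outputs`.
#' @export
qsp_derivatives <- function(state, t = 0, params) {
  stopifnot(inherits(params, "qsp_parameters"))
  y <- unlist(state)[qsp_state_names()]
  res <- deSolve::DLLfunc(
    y = y, times = t, func = "spirok_derivs", parms = unlist(params),
    dllname = "spirok", initfunc = "spirok_initmod",
    nout = length(qsp_output_names()), outnames = qsp_output_names()
  )
  d <- setNames(as.numeric(res$dy), qsp_state_names())
  if (any(!is.finite(d)))
    stop("non-finite derivative at t = ", t, " (states: ",
         paste(qsp_state_names()[!is.finite(d)], collapse = ", "), ")")
  list(derivatives = d, outputs = unlist(res$var))
}

#' Simulate the potassium model
#'
#' Integrates the model with `deSolve::lsoda`, applying dose events
#' (spironolactone in mg to the canrenone absorption depot, oral potassium in
#' mEq to the gut depot) as discrete additions at their event times.
#'
#' @param params `qsp_parameters`.
#' @param initial_state Named state vector; defaults to the calibrated
#'   drug-free steady state stored in `params`.
#' @param regimen Optional [dose_regimen()]. Times are on the simulation
#'   clock; events outside `[t0, t0 + horizon]` are ignored.
#' @param horizon Simulation horizon in minutes.
#' @param dt Output grid step, minutes.
#' @param t0 Start time of the simulation clock, minutes.
#' @param times Optional explicit output times (minutes, within the
#'   horizon); merged into the regular grid so requested times are solver
#'   outputs rather than interpolations.
#' @param rtol,atol Solver tolerances.
#' @return A `qsp_trajectory`: data frame of time, states and derived outputs.
#' @export
simulate_qsp <- function(params, initial_state = NULL, regimen = NULL,
                         horizon = 1440, dt = 5, t0 = 0, times = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "qsp_parameters"), horizon > 0)
  if (is.null(initial_state)) initial_state <- attr(params, "steady_state")
  y <- unlist(initial_state)[qsp_state_names()]
  if (any(is.na(y))) stop("initial state is incomplete")
  if (any(y < -1e-8)) stop("initial state has negative components")
  times <- sort(unique(c(seq(t0, t0 + horizon, by = dt), t0 + horizon,
                         times[times >= t0 & times <= t0 + horizon])))
  ev <- regimen_events(regimen, t0, t0 + horizon)
  if (!is.null(ev)) {
    # deSolve requires strictly interior, ordered event times on the grid
    ev$time <- pmax(ev$time, t0 + 1e-9)
    ev <- ev[order(ev$time), , drop = FALSE]
    times <- sort(unique(c(times, ev$time)))
  }
  out <- deSolve::ode(
    y = y, times = times, func = "spirok_derivs", parms = unlist(params),
    dllname = "spirok", initfunc = "spirok_initmod",
    nout = length(qsp_output_names()), outnames = qsp_output_names(),
    events = if (!is.null(ev)) list(data = ev),
    method = "lsoda", rtol = rtol, atol = atol
  )
  istate <- attr(out, "istate")[1]
  if (istate < 0)
    stop("solver failure (istate = ", istate, ") near t = ",
         max(out[, "time"]), " min")
  traj <- as.data.frame(out)
  state_cols <- qsp_state_names()
  neg <- vapply(traj[state_cols], min, numeric(1))
  if (any(neg < -1e-6 * max(abs(y), 1)))
    stop("negative state excursion beyond tolerance in: ",
         paste(state_cols[neg < -1e-6 * max(abs(y), 1)], collapse = ", "))
  structure(traj, class = c("qsp_trajectory", "data.frame"),
            params = params, regimen = regimen)
}

#' @export
print.qsp_trajectory <- function(x, ...) {
  cat(sprintf("<qsp_trajectory> %d points, t = %.0f..%.0f min, plasma K %.2f..%.2f mEq/L\n",
              nrow(x), min(x$time), max(x$time),
              min(x$K_plasma), max(x$K_plasma)))
  invisible(x)
}

#' Potassium mass balance of a trajectory
#'
#' Checks that the change in total body potassium (all model pools including
#' the gut depot) plus cumulative urinary excretion equals the dietary intake
#' plus oral doses administered during the simulated window.
#'
#' @param traj `qsp_trajectory`.
#' @return List with absolute and relative imbalance.
#' @export
mass_balance <- function(traj) {
  params <- attr(traj, "params")
  regimen <- attr(traj, "regimen")
  pools <- c("K_ecf", "K_icf", "K_cell", "lumen_PT", "lumen_DCT",
             "lumen_CNT", "lumen_MCD", "K_gut")
  first <- traj[1, ]
  last <- traj[nrow(traj), ]
  delta <- sum(last[, pools]) - sum(first[, pools])
  excreted <- last$K_excreted - first$K_excreted
  span <- last$time - first$time
  input <- params$Kin * span
  if (!is.null(regimen) && nrow(regimen)) {
    oral <- regimen$drug == "potassium_oral" &
      regimen$time > first$time & regimen$time <= last$time
    input <- input + sum(regimen$amount[oral])
  }
  abs_err <- abs(delta + excreted - input)
  list(input = input, absorbed_change = delta, excreted = excreted,
       abs_error = abs_err, rel_error = abs_err / max(input, .Machine$double.eps))
}

# Drug-free steady state solved in closed form: given plasma K the aldosterone
# level, distal transport and luminal amounts cascade algebraically; a 1-D
# root finds the plasma K at which urinary excretion equals intake.
steady_state_analytic <- function(params) {
  p <- params
  sN <- p$N_nephrons / p$n_nephrons_ref
  flux_at <- function(K) {
    dK <- K - p$norm_plasma_K
    aldo <- p$aldo_norm * (1 + p$hyperaldo_effect) *
      exp(p$m_K_ALDO * (dK + p$K_aldo_offset)) / p$aldo_prod_scale *
      (p$Nain / p$nain_ref)^(-p$s_nain_aldo) *
      (p$norm_Na / p$na_ref)^(-p$s_na_aldo)
    sig <- p$MR * (aldo / p$aldo_norm)^p$Aldo_KSec_scale
    g <- (1 - p$phi_mr) + p$phi_mr * sig
    U <- sN * p$u0_cal * (K / p$norm_plasma_K) * g
    filt <- p$GFR * K / 1000
    delivered <- (1 - p$f_PT) * (1 - p$f_DCT) * filt
    toMCD <- delivered + U
    h <- max(1 + p$m_plasmaK_MCD * dK, 0.05)
    rr <- sN * p$n_nephrons_ref * p$K_reabsorption_MCD_rate0 * h / p$mcd_ref
    mcd <- toMCD / (rr + p$k_MCD)
    list(K = K, aldo = aldo, U = U, filt = filt, delivered = delivered,
         mcd = mcd, urine = p$k_MCD * mcd)
  }
  root <- uniroot(function(K) flux_at(K)$urine - p$Kin,
                  lower = 0.5, upper = 15, tol = 1e-12)
  f <- flux_at(root$root)
  state <- c(
    K_ecf = f$K * p$V_ecf / 1000,
    K_icf = p$k_ecf_icf * (f$K * p$V_ecf / 1000) / p$k_icf_ecf_cal,
    K_cell = f$U / p$k_secr_cal,
    lumen_PT = f$filt / p$k_PT,
    lumen_DCT = (1 - p$f_PT) * f$filt / p$k_DCT,
    lumen_CNT = (f$delivered + f$U) / p$k_CNT,
    lumen_MCD = f$mcd,
    K_excreted = 0,
    aldo = f$aldo,
    K_gut = 0, cren_gut = 0, cren_central = 0, cren_peripheral = 0
  )
  state
}

#' Drug-free steady state
#'
#' Solves the drug-free steady state in closed form (1-D root on plasma
#' potassium), then integrates the system for an equilibration offset of
#' `t_equil` minutes (3000 min by default, the offset used for patient
#' day-zero equilibration) and returns the terminal state with the cumulative
#' excretion counter reset to zero. The residual of the potassium-balance
#' derivatives at the returned state is checked against `tol_rel` times the
#' characteristic flux scale (the potassium intake).
#'
#' @param params `qsp_parameters`.
#' @param t_equil Equilibration offset, minutes.
#' @param tol_rel Relative residual tolerance.
#' @return Named steady-state vector (class `qsp_state`).
#' @export
find_steady_state <- function(params, t_equil = 3000, tol_rel = 1e-6) {
  stopifnot(inherits(params, "qsp_parameters"))
  guess <- steady_state_analytic(params)
  traj <- simulate_qsp(params, initial_state = guess, horizon = t_equil,
                       dt = t_equil / 20)
  st <- unlist(traj[nrow(traj), qsp_state_names()])
  names(st) <- qsp_state_names()
  st["K_excreted"] <- 0
  d <- qsp_derivatives(st, t = 0, params)$derivatives
  d <- d[setdiff(qsp_state_names(), "K_excreted")]
  if (max(abs(d)) > tol_rel * params$Kin)
    stop("steady state not reached (residual ", signif(max(abs(d)), 3),
         "); try a longer equilibration offset")
  class(st) <- c("qsp_state", class(st))
  st
}

#' Canrenone central-compartment concentration (closed form)
#'
#' Analytic superposition of first-order-absorption two-compartment kinetics
#' over the spironolactone doses of a regimen. This closed form is independent
#' of the ODE integrator and is also used to cross-check the compiled model.
#'
#' @param regimen [dose_regimen()]; only spironolactone rows contribute.
#' @param params `qsp_parameters` (or any list with `pk_ka`, `pk_CL`,
#'   `pk_Vc`, `pk_Q`, `pk_Vp`).
#' @param t Times (minutes) at which to evaluate, `t >= 0`.
#' @return Concentration (mg/L), same length as `t`.
#' @export
canrenone_concentration <- function(regimen, params, t) {
  stopifnot(all(t >= 0))
  ka <- params$pk_ka
  k10 <- params$pk_CL / params$pk_Vc
  k12 <- params$pk_Q / params$pk_Vc
  k21 <- params$pk_Q / params$pk_Vp
  b <- k10 + k12 + k21
  disc <- sqrt(b^2 - 4 * k10 * k21)
  l1 <- (b + disc) / 2
  l2 <- (b - disc) / 2
  unit <- function(tt) {
    # concentration after a unit oral dose at time 0
    out <- numeric(length(tt))
    pos <- tt >= 0
    tp <- tt[pos]
    A <- (k21 - l1) / ((ka - l1) * (l2 - l1))
    B <- (k21 - l2) / ((ka - l2) * (l1 - l2))
    C <- (k21 - ka) / ((l1 - ka) * (l2 - ka))
    out[pos] <- ka / params$pk_Vc *
      (A * exp(-l1 * tp) + B * exp(-l2 * tp) + C * exp(-ka * tp))
    out
  }
  conc <- numeric(length(t))
  if (is.null(regimen) || nrow(regimen) == 0) return(conc)
  sp <- regimen[regimen$drug == "spironolactone", , drop = FALSE]
  for (i in seq_len(nrow(sp)))
    conc <- conc + sp$amount[i] * unit(t - sp$time[i])
  conc
}

#' Fractional mineralocorticoid-receptor blockade by canrenone
#'
#' `Emax * C / (EC50 + C)`; the available receptor signal is
#' `MR * (1 - blockade)`.
#'
#' @param conc Canrenone concentration (>= 0).
#' @param Emax Maximal fractional blockade in `[0, 1]`.
#' @param EC50 Concentration at half-maximal blockade (> 0).
#' @export
mr_blockade <- function(conc, Emax, EC50) {
  stopifnot(all(conc >= 0), Emax >= 0, Emax <= 1, EC50 > 0)
  Emax * conc / (EC50 + conc)
}

#' Perturbation exploration over 24 h
#'
#' Perturbs one or two parameters multiplicatively, simulates 24 h from the
#' nominal steady state, and reports every compartment and transfer flux as a
#' percent change from the unperturbed run in 2-h intervals (the headless
#' computation behind an interactive model explorer).
#'
#' @param params Nominal `qsp_parameters`.
#' @param names One or two parameter names.
#' @param factors Multiplicative factors, same length as `names`.
#' @param horizon Horizon, minutes.
#' @return List with `deviations` (tidy data frame: time_h, variable,
#'   percent_change) and `plasma_K` (data frame: time_h, baseline, perturbed).
#' @export
explore_perturbation <- function(params, names, factors, horizon = 1440) {
  stopifnot(length(names) %in% 1:2, length(factors) == length(names))
  unknown <- setdiff(names, qsp_parm_names())
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  pert <- params
  for (i in seq_along(names))
    pert <- do.call(set_parameter,
                    c(list(pert), setNames(list(pert[[names[i]]] * factors[i]),
                                           names[i])))
  grid_h <- seq(0, horizon / 60, by = 2)
  base <- simulate_qsp(params, horizon = horizon, dt = 120)
  per <- simulate_qsp(pert, initial_state = attr(params, "steady_state"),
                      horizon = horizon, dt = 120)
  vars <- c(qsp_state_names(),
            c("urine_flux", "secretion", "uptake", "filtration",
              "reab_PT", "reab_DCT", "reab_MCD"))
  dev <- do.call(rbind, lapply(vars, function(v) {
    b <- base[[v]]
    pc <- ifelse(abs(b) > 1e-12, 100 * (per[[v]] - b) / b, 0)
    data.frame(time_h = base$time / 60, variable = v, percent_change = pc)
  }))
  list(
    deviations = dev,
    plasma_K = data.frame(time_h = base$time / 60,
                          baseline = base$K_plasma,
                          perturbed = per$K_plasma)
  )
}
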