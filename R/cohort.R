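#' Cohort generator configuration
#'
#' Defaults emulate the pilot inpatient sample: nine patients newly
#' initiating spironolactone, four of them with oral potassium
#' supplementation, a median length of stay of 10.2 days, roughly daily
#' potassium labs with additive assay error, sodium/GFR covariates with
#' occasional missingness, and administration-time jitter between planned and
#' actual dose times.
#'
#' @param n_patients Number of patients.
#' @param los_median_days Target median length of stay, days.
#' @param los_sdlog Log-scale spread of the stay distribution.
#' @param los_jitter_sd Multiplicative log-jitter applied to the stratified
#'   stay draws (kept small so the cohort median stays on target).
#' @param supplementation_fraction Fraction receiving oral potassium.
#' @param iiv Data frame (parameter, cv_percent) of inter-individual
#'   variability magnitudes used to draw individual parameters; defaults to
#'   [default_iiv()].
#' @param residual_sd Additive lab error SD, mEq/L.
#' @param lab_schedule Clock times (minutes after midnight) of the daily
#'   potassium draws; the single 07:00 draw of ward routine by default,
#'   several times per day for rich-sampling experiments.
#' @param lab_time_jitter Uniform jitter half-width on lab times, minutes.
#' @param covariate_missingness Probability that a sodium or GFR value is
#'   missing at a lab time.
#' @param covariate_lab_sd Measurement SDs of the sodium and GFR labs
#'   (named vector; mEq/L and mL/min).
#' @param admin_jitter_sd SD of the normal jitter between planned and actual
#'   administration times, minutes (truncated at +-3 h).
#' @param spiro_doses_mg Dose menu for once-daily spironolactone.
#' @param ksup_mEq Oral potassium per administration, mEq.
#' @param ksup_schedule Clock times (minutes after midnight) of the daily
#'   supplement administrations.
#' @param ace_i_fraction,diuretic_fraction Fractions with ACE-inhibitor and
#'   high-ceiling diuretic comedication (descriptive metadata).
#' @param seed Mandatory seed.
#' @return `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 9, los_median_days = 10.2,
                          los_sdlog = 0.35, los_jitter_sd = 0.03,
                          supplementation_fraction = 4 / 9,
                          iiv = default_iiv(), residual_sd = 0.15,
                          lab_schedule = 7 * 60, lab_time_jitter = 60,
                          covariate_missingness = 0.2,
                          covariate_lab_sd = c(sodium = 1, GFR = 3),
                          admin_jitter_sd = 45,
                          spiro_doses_mg = c(25, 50, 100), ksup_mEq = 20,
                          ksup_schedule = c(8 * 60, 18 * 60),
                          ace_i_fraction = 4 / 9, diuretic_fraction = 5 / 9,
                          seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_patients >= 1, los_median_days > 0,
            supplementation_fraction >= 0, supplementation_fraction <= 1,
            residual_sd >= 0, admin_jitter_sd >= 0,
            all(iiv$cv_percent >= 0))
  structure(as.list(environment()), class = "cohort_config")
}

#' Historical-cohort emulation config
#'
#' The cohort structure used for IIV estimation: 20 patient cases initiating
#' spironolactone, half of whom additionally receive oral potassium
#' supplementation.
#'
#' @param seed Mandatory seed.
#' @param ... Further overrides passed to [cohort_config()].
#' @export
historical_cohort_config <- function(seed, ...) {
  cohort_config(n_patients = 20, supplementation_fraction = 0.5,
                seed = seed, ...)
}

draw_individual_parameters <- function(config, params) {
  bounds <- param_ranges("clinical")
  eta <- setNames(numeric(0), character(0))
  for (j in seq_len(nrow(config$iiv))) {
    pn <- config$iiv$parameter[j]
    cv <- config$iiv$cv_percent[j] / 100
    mu <- params[[pn]]
    for (tries in 1:200) {
      v <- if (iiv_transform(pn) == "log")
        mu * exp(stats::rnorm(1, 0, sqrt(cv_to_omega2(cv, pn))))
      else mu + stats::rnorm(1, 0, cv)
      if (v >= bounds[[pn]][1] && v <= bounds[[pn]][2]) break
    }
    eta[pn] <- min(max(v, bounds[[pn]][1]), bounds[[pn]][2])
  }
  eta
}

#' Generate a synthetic inpatient cohort
#'
#' Each patient draws individual parameters from the population values with
#' the configured IIV (log-normal for positive parameters, additive normal
#' for the hyperaldosteronism effect, truncated to the clinical ranges), gets
#' a spironolactone regimen starting on day 1--3 (dose drawn from the menu,
#' once daily at 08:00 planned, actual times jittered), optionally twice-daily
#' oral potassium, and a stay whose length is drawn from a stratified
#' log-normal targeting the configured median. The true potassium course is
#' simulated from the patient's own drug-free steady state under the *actual*
#' dose times; daily potassium labs add the residual error, and sodium/GFR
#' labs are thinned by the missingness probability. The generative truth
#' (individual parameters, true course, actual times) is stored in a hidden
#' `truth` block that the export and the forecasting pipeline never read.
#'
#' @param config A [cohort_config()].
#' @param params Nominal `qsp_parameters`.
#' @return List of patient records (class `qsp_cohort`).
#' @export
generate_cohort <- function(config, params = build_nominal_parameters()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  # stratified stays: quantiles of the target distribution, small jitter,
  # random assignment to patients -- the cohort median sits on the target
  los_base <- stats::qlnorm((seq_len(n) - 0.5) / n,
                            log(config$los_median_days), config$los_sdlog)
  los <- sample(los_base * exp(stats::rnorm(n, 0, config$los_jitter_sd)))
  n_sup <- round(config$supplementation_fraction * n)
  sup_ids <- sample(n, n_sup)
  ace_ids <- sample(n, round(config$ace_i_fraction * n))
  diu_ids <- sample(n, round(config$diuretic_fraction * n))
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    discharge <- round(los[i] * 1440)
    eta <- draw_individual_parameters(config, params)
    gfr <- min(max(stats::rnorm(1, 90, 15), 40), 130)
    sodium <- stats::rnorm(1, 140, 3)
    pp <- do.call(set_parameter, c(list(params), as.list(eta)))
    pp <- apply_covariates(pp, GFR = gfr, sodium = sodium)
    # regimen: once-daily spironolactone from start day, planned 08:00
    start_day <- sample(1:3, 1)
    menu <- config$spiro_doses_mg
    dose_mg <- if (length(menu) == 1) menu else sample(menu, 1)
    sp_days <- start_day:max(start_day, floor(discharge / 1440))
    sp_planned <- sp_days * 1440 + 8 * 60
    sp_planned <- sp_planned[sp_planned < discharge]
    if (length(sp_planned) == 0)  # very short stay: dose once, right away
      sp_planned <- min(start_day * 1440 + 8 * 60, discharge - 60)
    jit <- function(m) {
      j <- stats::rnorm(length(m), 0, config$admin_jitter_sd)
      m + pmin(pmax(j, -180), 180)
    }
    doses <- data.frame(planned_time = sp_planned, time = jit(sp_planned),
                        drug = "spironolactone", amount = dose_mg)
    ks_planned <- if (i %in% sup_ids && length(sp_days))
      sort(as.vector(outer(config$ksup_schedule, sp_days * 1440, "+")))
    else numeric(0)
    ks_planned <- ks_planned[ks_planned < discharge]
    if (length(ks_planned)) {
      doses <- rbind(doses,
                     data.frame(planned_time = ks_planned,
                                time = jit(ks_planned),
                                drug = "potassium_oral",
                                amount = config$ksup_mEq))
    }
    doses$time <- pmax(doses$time, 1)
    doses <- doses[order(doses$time), , drop = FALSE]
    rownames(doses) <- NULL
    # true course under actual administration times
    actual_reg <- dose_regimen(doses$time, doses$drug, doses$amount)
    init <- steady_state_analytic(pp)
    truth_traj <- simulate_qsp(pp, initial_state = init, regimen = actual_reg,
                               horizon = discharge, dt = 10)
    lab_days <- 0:floor((discharge - 1) / 1440)
    k_times <- sort(as.vector(outer(config$lab_schedule, lab_days * 1440, "+")))
    k_times <- k_times +
      round(stats::runif(length(k_times), -config$lab_time_jitter,
                         config$lab_time_jitter))
    k_times <- pmin(pmax(k_times, 1), discharge - 1)
    k_true <- stats::approx(truth_traj$time, truth_traj$K_plasma,
                            xout = k_times, rule = 2)$y
    resid <- stats::rnorm(length(k_times), 0, config$residual_sd)
    labs <- data.frame(time = k_times, analyte = "potassium",
                       value = pmax(k_true + resid, 1.5))
    keep_na <- stats::runif(length(k_times)) > config$covariate_missingness
    keep_gfr <- stats::runif(length(k_times)) > config$covariate_missingness
    if (any(keep_na))
      labs <- rbind(labs, data.frame(
        time = k_times[keep_na], analyte = "sodium",
        value = sodium + stats::rnorm(sum(keep_na), 0,
                                      config$covariate_lab_sd[["sodium"]])))
    if (any(keep_gfr))
      labs <- rbind(labs, data.frame(
        time = k_times[keep_gfr], analyte = "GFR",
        value = pmax(gfr + stats::rnorm(sum(keep_gfr), 0,
                                        config$covariate_lab_sd[["GFR"]]), 10)))
    labs <- labs[order(labs$time, labs$analyte), , drop = FALSE]
    rownames(labs) <- NULL
    cohort[[i]] <- structure(list(
      id = sprintf("P%02d", i),
      admission = 0, discharge = discharge,
      doses = doses, labs = labs,
      meta = list(ace_i = i %in% ace_ids,
                  high_ceiling_diuretic = i %in% diu_ids,
                  potassium_supplementation = i %in% sup_ids,
                  potassium_binder = FALSE, potassium_infusion = FALSE,
                  new_initiation = TRUE),
      truth = list(eta = eta, gfr = gfr, sodium = sodium,
                   residuals = resid, k_true = k_true,
                   los_days = los[i])
    ), class = "patient_record")
  }
  structure(cohort, config = config, class = "qsp_cohort")
}

#' @export
print.qsp_cohort <- function(x, ...) {
  los <- vapply(x, function(p) (p$discharge - p$admission) / 1440, numeric(1))
  cat(sprintf("<qsp_cohort> %d patients, median stay %.1f days, %d with K supplementation\n",
              length(x), stats::median(los),
              sum(vapply(x, function(p) isTRUE(p$meta$potassium_supplementation),
                         logical(1)))))
  invisible(x)
}

#' Median length of stay of a cohort, days
#' @param cohort `qsp_cohort`.
#' @export
median_length_of_stay <- function(cohort) {
  stats::median(vapply(cohort, function(p)
    (p$discharge - p$admission) / 1440, numeric(1)))
}

#' Apply the inclusion filters
#'
#' Removes patients with potassium binders, with potassium infusions, without
#' new spironolactone initiation, or with incomplete spironolactone dosing
#' schedules (missing times or amounts, or no spironolactone doses at all).
#' Each exclusion is attributed to the first matching rule.
#'
#' @param cohort `qsp_cohort` (or plain list of patient records).
#' @return List with `cohort` (filtered) and `audit` (named exclusion counts).
#' @export
apply_inclusion_filters <- function(cohort) {
  rules <- c("potassium_binder", "potassium_infusion", "no_new_initiation",
             "incomplete_dosing")
  audit <- setNames(integer(length(rules)), rules)
  keep <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    sp <- p$doses[p$doses$drug == "spironolactone", , drop = FALSE]
    rule <- if (isTRUE(p$meta$potassium_binder)) "potassium_binder"
      else if (isTRUE(p$meta$potassium_infusion)) "potassium_infusion"
      else if (!isTRUE(p$meta$new_initiation)) "no_new_initiation"
      else if (nrow(sp) == 0 || anyNA(sp$time) || anyNA(sp$amount))
        "incomplete_dosing"
      else NA_character_
    if (is.na(rule)) keep[i] <- TRUE else audit[rule] <- audit[rule] + 1L
  }
  out <- cohort[keep]
  attr(out, "config") <- attr(cohort, "config")
  class(out) <- class(cohort)
  list(cohort = out, audit = audit)
}

#' Last-observation-carried-forward imputation of covariate labs
#'
#' At every potassium timestamp, missing sodium or GFR values are filled with
#' the last earlier value of the same analyte, or with the standard value if
#' no earlier value exists. Potassium itself is never imputed.
#'
#' @param labs Data frame (time, analyte, value), sorted by time per analyte.
#' @param standard_values Named vector of standards used for leading gaps.
#' @return Completed lab table; imputed rows carry `imputed = TRUE`.
#' @export
locf_impute <- function(labs, standard_values = c(sodium = 140, GFR = 100)) {
  stopifnot(all(c("time", "analyte", "value") %in% names(labs)))
  labs$imputed <- if (nrow(labs)) FALSE else logical(0)
  k_times <- sort(labs$time[labs$analyte == "potassium"])
  add <- list()
  for (an in names(standard_values)) {
    have <- labs[labs$analyte == an, , drop = FALSE]
    for (tt in k_times) {
      if (!any(have$time == tt)) {
        prior <- have$value[have$time < tt]
        val <- if (length(prior)) prior[length(prior)] else standard_values[[an]]
        add[[length(add) + 1]] <- data.frame(time = tt, analyte = an,
                                             value = val, imputed = TRUE)
        have <- rbind(have, data.frame(time = tt, analyte = an, value = val,
                                       imputed = TRUE))
        have <- have[order(have$time), , drop = FALSE]
      }
    }
  }
  out <- rbind(labs, do.call(rbind, add))
  out <- out[order(out$time, out$analyte), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Event-table I/O
#'
#' Writes the observed portion of a cohort as a tidy CSV event table with
#' columns `patient_id, time_min, record_type, name, value,
#' planned_time_min` (`record_type` one of dose/lab/meta), and reads it back
#' losslessly. The generative truth block is written to a separate
#' `*_truth.csv` (suffix added automatically) that the analysis pipeline
#' never reads.
#'
#' @param cohort `qsp_cohort`.
#' @param path CSV path for the observed event table.
#' @param truth Also write the truth sidecar.
#' @return `write_event_table`: the path, invisibly. `read_event_table`: a
#'   `qsp_cohort` (without truth blocks).
#' @export
write_event_table <- function(cohort, path, truth = TRUE) {
  rows <- list()
  for (p in cohort) {
    meta_flags <- p$meta
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = p$id,
      time_min = c(p$admission, p$discharge, rep(0, length(meta_flags))),
      record_type = "meta",
      name = c("admission", "discharge", names(meta_flags)),
      value = c(p$admission, p$discharge,
                as.numeric(unlist(meta_flags))),
      planned_time_min = NA_real_
    )
    if (nrow(p$doses))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p$id, time_min = p$doses$time, record_type = "dose",
        name = p$doses$drug, value = p$doses$amount,
        planned_time_min = p$doses$planned_time
      )
    if (nrow(p$labs))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p$id, time_min = p$labs$time, record_type = "lab",
        name = p$labs$analyte, value = p$labs$value,
        planned_time_min = NA_real_
      )
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (truth) {
    tr <- do.call(rbind, lapply(cohort, function(p) {
      if (is.null(p$truth)) return(NULL)
      data.frame(patient_id = p$id,
                 parameter = c(names(p$truth$eta), "gfr", "sodium", "los_days"),
                 value = c(unname(p$truth$eta), p$truth$gfr, p$truth$sodium,
                           p$truth$los_days))
    }))
    if (!is.null(tr))
      utils::write.csv(tr, sub("\\.csv$", "_truth.csv", path),
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_min", "record_type", "name", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad_t <- which(!is.finite(tab$time_min) | tab$time_min < 0)
  if (length(bad_t))
    stop("negative or missing time_min in row(s): ",
         paste(utils::head(bad_t, 10), collapse = ", "))
  bad_rt <- which(!tab$record_type %in% c("dose", "lab", "meta"))
  if (length(bad_rt))
    stop("unknown record_type in row(s): ",
         paste(utils::head(bad_rt, 10), collapse = ", "))
  if (!"planned_time_min" %in% names(tab)) tab$planned_time_min <- NA_real_
  cohort <- lapply(split(tab, tab$patient_id), function(d) {
    meta_rows <- d[d$record_type == "meta", , drop = FALSE]
    flag <- function(nm, default = NA) {
      v <- meta_rows$value[meta_rows$name == nm]
      if (length(v)) v[1] else default
    }
    doses <- d[d$record_type == "dose", , drop = FALSE]
    labs <- d[d$record_type == "lab", , drop = FALSE]
    flags <- setdiff(meta_rows$name, c("admission", "discharge"))
    meta <- lapply(setNames(flags, flags), function(nm) as.logical(flag(nm)))
    structure(list(
      id = d$patient_id[1],
      admission = flag("admission", 0),
      discharge = flag("discharge", max(d$time_min)),
      doses = {
        dd <- data.frame(planned_time = doses$planned_time_min,
                         time = doses$time_min, drug = doses$name,
                         amount = doses$value)
        dd <- dd[order(dd$time), , drop = FALSE]; rownames(dd) <- NULL; dd
      },
      labs = {
        ll <- data.frame(time = labs$time_min, analyte = labs$name,
                         value = labs$value)
        ll <- ll[order(ll$time, ll$analyte), , drop = FALSE]
        rownames(ll) <- NULL; ll
      },
      meta = meta,
      truth = NULL
    ), class = "patient_record")
  })
  cohort <- cohort[order(names(cohort))]
  names(cohort) <- NULL
  structure(cohort, class = "qsp_cohort")
}
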