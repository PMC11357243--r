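#' @useDynLib spirok
#' @importFrom stats setNames uniroot
NULL

# Order must match the #define block in src/qsp_derivs.c
qsp_parm_names <- function() {
  c("Kin", "Nain", "norm_plasma_K", "V_ecf", "MR", "hyperaldo_effect",
    "m_K_ALDO", "Aldo_KSec_scale", "m_plasmaK_MCD", "K_reabsorption_MCD_rate0",
    "GFR", "N_nephrons", "norm_Na", "k_ecf_icf", "aldo_norm",
    "pk_ka", "pk_CL", "pk_Vc", "pk_Q", "pk_Vp", "Emax", "EC50",
    "phi_mr", "f_PT", "f_DCT", "k_PT", "k_DCT", "k_CNT", "k_MCD",
    "k_aldo", "s_nain_aldo", "s_na_aldo", "K_aldo_offset", "ka_gut_K",
    "icf_ref", "cell_ref",
    "u0_cal", "k_secr_cal", "k_icf_ecf_cal", "mcd_ref",
    "n_nephrons_ref", "gfr_ref", "nain_ref", "na_ref", "aldo_prod_scale")
}

qsp_state_names <- function() {
  c("K_ecf", "K_icf", "K_cell", "lumen_PT", "lumen_DCT", "lumen_CNT",
    "lumen_MCD", "K_excreted", "aldo", "K_gut",
    "cren_gut", "cren_central", "cren_peripheral")
}

qsp_output_names <- function() {
  c("K_plasma", "urine_flux", "secretion", "uptake", "filtration",
    "reab_PT", "reab_DCT", "reab_MCD", "cren_conc", "mr_blockade",
    "transport_gain", "aldosterone")
}

#' The five parameters forwarded to individual (Bayesian) estimation
#' @export
estimable_parameters <- function() {
  c("Kin", "Nain", "V_ecf", "MR", "hyperaldo_effect")
}

#' Physiological parameter ranges
#'
#' Two range sets are used throughout the package. `"efast"` holds the narrow
#' physiologically plausible intervals used for global sensitivity and
#' uncertainty analysis (potassium intake 0.073--0.084 mEq/min, sodium intake
#' 0.01--0.17 mEq/min, extracellular fluid volume 10,000--25,000 mL,
#' mineralocorticoid receptor abundance factor 0.8--1.2, hyperaldosteronism
#' effect -0.5--0.5). `"clinical"` holds wider, clinically orientated bounds
#' used as hard constraints for individual parameter estimation and for
#' truncating cohort-simulation draws; they must admit, e.g., high potassium
#' intake under supplementation and large inter-individual spread in receptor
#' abundance.
#'
#' @param which `"efast"` or `"clinical"`.
#' @return Named list of `c(lower, upper)` vectors for
#'   [estimable_parameters()].
#' @export
param_ranges <- function(which = c("efast", "clinical")) {
  which <- match.arg(which)
  if (which == "efast") {
    list(
      Kin = c(0.073, 0.084),
      Nain = c(0.01, 0.17),
      V_ecf = c(10000, 25000),
      MR = c(0.8, 1.2),
      hyperaldo_effect = c(-0.5, 0.5)
    )
  } else {
    list(
      Kin = c(0.03, 0.30),
      Nain = c(0.01, 0.17),
      V_ecf = c(8000, 30000),
      MR = c(0.3, 3.0),
      hyperaldo_effect = c(-0.7, 1.0)
    )
  }
}

qsp_defaults <- function() {
  ef <- param_ranges("efast")
  list(
    # intakes and physiological normals
    Kin = mean(ef$Kin),                 # mEq/min
    Nain = mean(ef$Nain),               # mEq/min
    norm_plasma_K = 4.2,                # mEq/L
    V_ecf = mean(ef$V_ecf),             # mL
    MR = 1.0,
    hyperaldo_effect = 0.0,
    m_K_ALDO = 0.5,                     # per mEq/L
    Aldo_KSec_scale = 2.0,              # aldosterone-signal exponent
    m_plasmaK_MCD = -0.25,              # per mEq/L
    K_reabsorption_MCD_rate0 = 7.5e-10, # mEq/min/nephron
    GFR = 100,                          # mL/min
    N_nephrons = 2e6,
    norm_Na = 140,                      # mEq/L
    k_ecf_icf = 0.005,                  # 1/min
    aldo_norm = 1.0,                    # arbitrary units
    # canrenone PK (one-abs two-compartment) and MR blockade
    pk_ka = 0.012,                      # 1/min
    pk_CL = 0.08,                       # L/min
    pk_Vc = 35,                         # L
    pk_Q = 0.03,                        # L/min
    pk_Vp = 40,                         # L
    Emax = 0.8,
    EC50 = 0.25,                        # mg/L
    # structural constants of the reconstructed rate laws
    phi_mr = 0.5,
    f_PT = 0.95,
    f_DCT = 0.60,
    k_PT = 0.2,                         # 1/min
    k_DCT = 0.3,
    k_CNT = 0.3,
    k_MCD = 0.2,
    k_aldo = 0.01,                      # 1/min
    s_nain_aldo = 0.30,
    s_na_aldo = 0.5,
    K_aldo_offset = 0.04,               # mEq/L
    ka_gut_K = 0.03,                    # 1/min
    icf_ref = 3400,                     # mEq
    cell_ref = 30                       # mEq
  )
}

#' Build the nominal, calibrated model parameter set
#'
#' Returns the full parameter vector of the potassium model, calibrated so
#' that the drug-free steady state has plasma potassium equal to
#' `norm_plasma_K` and urinary excretion equal to the potassium intake `Kin`.
#' Calibration solves the steady-state flux balance in closed form and stores
#' the derived transport constants (distal uptake scale, secretion rate
#' constant, intracellular return rate, luminal reference amounts) alongside
#' the primary parameters. Overrides are applied *before* calibration, so an
#' overridden set is again self-consistently at steady state; to perturb a
#' parameter *without* re-calibrating (as in sensitivity analysis) use
#' [set_parameter()].
#'
#' @param ... Named overrides of any primary parameter, e.g. `Kin = 0.08`.
#' @return An object of class `qsp_parameters`: a named list with a
#'   `steady_state` attribute holding the calibrated initial state.
#' @export
build_nominal_parameters <- function(...) {
  par <- qsp_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("overrides must be named")
    unknown <- setdiff(names(over), names(par))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    par[names(over)] <- over
  }
  calibrate_parameters(par)
}

# Closed-form steady-state calibration; see the methods vignette.
calibrate_parameters <- function(par) {
  with(par, {
    stopifnot(Kin > 0, V_ecf > 0, GFR > 0, N_nephrons > 0, MR > 0,
              Emax >= 0, Emax <= 1, EC50 > 0, hyperaldo_effect > -1)
    Kstar <- norm_plasma_K
    filt <- GFR * Kstar / 1000
    delivered <- (1 - f_PT) * (1 - f_DCT) * filt
    reabMCD <- N_nephrons * K_reabsorption_MCD_rate0
    S0 <- Kin + reabMCD - delivered
    if (S0 <= 0)
      stop("infeasible calibration: distal secretion would be non-positive")
    par$u0_cal <- S0
    par$k_secr_cal <- S0 / cell_ref
    par$k_icf_ecf_cal <- k_ecf_icf * (Kstar * V_ecf / 1000) / icf_ref
    par$mcd_ref <- Kin / k_MCD
    par$n_nephrons_ref <- N_nephrons
    par$gfr_ref <- GFR
    par$nain_ref <- Nain
    par$na_ref <- norm_Na
    par$aldo_prod_scale <- exp(m_K_ALDO * K_aldo_offset)
    state <- c(
      K_ecf = Kstar * V_ecf / 1000,
      K_icf = icf_ref,
      K_cell = cell_ref,
      lumen_PT = filt / k_PT,
      lumen_DCT = (1 - f_PT) * filt / k_DCT,
      lumen_CNT = (delivered + S0) / k_CNT,
      lumen_MCD = Kin / k_MCD,
      K_excreted = 0,
      aldo = aldo_norm,
      K_gut = 0,
      cren_gut = 0, cren_central = 0, cren_peripheral = 0
    )
    structure(par[qsp_parm_names()], steady_state = state,
              class = "qsp_parameters")
  })
}

#' Modify parameters without re-calibrating
#'
#' Used for perturbation and sensitivity work: the calibration constants
#' frozen at the nominal point are kept, so the modified set is generally
#' *not* at steady state any more.
#'
#' @param params A `qsp_parameters` object.
#' @param ... Named new values, e.g. `Kin = 0.09`.
#' @export
set_parameter <- function(params, ...) {
  stopifnot(inherits(params, "qsp_parameters"))
  over <- list(...)
  unknown <- setdiff(names(over), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(over)] <- over
  validate_parameters(params)
  params
}

validate_parameters <- function(params) {
  pos <- c("Kin", "norm_plasma_K", "V_ecf", "MR", "GFR", "N_nephrons",
           "norm_Na", "k_ecf_icf", "aldo_norm", "pk_ka", "pk_CL", "pk_Vc",
           "pk_Q", "pk_Vp", "EC50")
  bad <- pos[vapply(pos, function(n) params[[n]] <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (params$Emax < 0 || params$Emax > 1) stop("Emax must lie in [0, 1]")
  if (params$hyperaldo_effect <= -1)
    stop("hyperaldo_effect must be > -1")
  invisible(params)
}

#' Apply patient covariates to a parameter set
#'
#' An observed (estimated) GFR scales the nephron number proportionally, so
#' the single-nephron GFR -- the mechanistically active filtration parameter
#' -- is preserved while whole-kidney transport capacity scales with the
#' covariate. An observed sodium concentration replaces the sodium normal
#' value used by the aldosterone production law.
#'
#' @param params `qsp_parameters`.
#' @param GFR Observed GFR, mL/min (optional).
#' @param sodium Observed plasma sodium, mEq/L (optional).
#' @export
apply_covariates <- function(params, GFR = NULL, sodium = NULL) {
  stopifnot(inherits(params, "qsp_parameters"))
  if (!is.null(GFR) && is.finite(GFR) && GFR > 0) {
    scale <- GFR / params$gfr_ref
    params$GFR <- GFR
    params$N_nephrons <- params$n_nephrons_ref * scale
  }
  if (!is.null(sodium) && is.finite(sodium) && sodium > 0)
    params$norm_Na <- sodium
  params
}

#' @export
print.qsp_parameters <- function(x, ...) {
  cat("<qsp_parameters> potassium homeostasis model\n")
  cat(sprintf("  Kin %.4f mEq/min | Nain %.3f mEq/min | V_ecf %.0f mL\n",
              x$Kin, x$Nain, x$V_ecf))
  cat(sprintf("  MR %.2f | hyperaldo %.2f | GFR %.0f mL/min | norm K %.1f mEq/L\n",
              x$MR, x$hyperaldo_effect, x$GFR, x$norm_plasma_K))
  invisible(x)
}

#' Read/write parameter configuration as YAML
#'
#' Only primary (non-derived) parameters are written; reading re-calibrates.
#' @param params `qsp_parameters`.
#' @param path File path.
#' @export
write_parameter_config <- function(params, path) {
  primary <- names(qsp_defaults())
  yaml::write_yaml(params[primary], path)
  invisible(path)
}

#' @rdname write_parameter_config
#' @export
read_parameter_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(build_nominal_parameters, cfg)
}
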