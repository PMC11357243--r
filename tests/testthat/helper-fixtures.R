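# Shared fixtures: one calibrated nominal parameter set, small cohorts built
# in code, and a hand-rolled patient constructor for targeted experiments.

nominal <- build_nominal_parameters()
nominal_ss <- attr(nominal, "steady_state")

# tiny deterministic patient: doses + potassium observations generated from
# the model itself (optionally with known individual parameters and noise)
make_patient <- function(id = "T01", eta = NULL, days = 5,
                         spiro_mg = 50, spiro_start_day = 1,
                         obs_times = NULL, residual_sd = 0,
                         supplement = FALSE, seed = 1,
                         params = nominal, meta = list()) {
  set.seed(seed)
  discharge <- days * 1440
  sp_days <- spiro_start_day:(days - 1)
  planned <- sp_days * 1440 + 480
  doses <- data.frame(planned_time = planned, time = planned,
                      drug = "spironolactone", amount = spiro_mg)
  if (supplement) {
    ks <- sort(as.vector(outer(c(480, 1080), sp_days * 1440, "+")))
    doses <- rbind(doses, data.frame(planned_time = ks, time = ks,
                                     drug = "potassium_oral", amount = 20))
    doses <- doses[order(doses$time), ]
  }
  if (is.null(obs_times)) obs_times <- (0:(days - 1)) * 1440 + 420
  pp <- if (is.null(eta)) params
        else do.call(set_parameter, c(list(params), as.list(eta)))
  init <- spirok:::steady_state_analytic(pp)
  reg <- dose_regimen(doses$time, doses$drug, doses$amount)
  tr <- simulate_qsp(pp, initial_state = init, regimen = reg,
                     horizon = discharge, dt = 10)
  k_true <- approx(tr$time, tr$K_plasma, xout = obs_times, rule = 2)$y
  labs <- data.frame(time = obs_times, analyte = "potassium",
                     value = k_true + rnorm(length(obs_times), 0, residual_sd))
  base_meta <- list(ace_i = FALSE, high_ceiling_diuretic = FALSE,
                    potassium_supplementation = supplement,
                    potassium_binder = FALSE, potassium_infusion = FALSE,
                    new_initiation = TRUE)
  base_meta[names(meta)] <- meta
  structure(list(id = id, admission = 0, discharge = discharge,
                 doses = doses, labs = labs, meta = base_meta,
                 truth = list(eta = eta, k_true = k_true)),
            class = "patient_record")
}
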