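test_that("drug-free simulation from steady state is stationary", {
  tr <- simulate_qsp(nominal, horizon = 1440, dt = 60)
  expect_lt(max(abs(tr$K_plasma - nominal$norm_plasma_K)) /
              nominal$norm_plasma_K, 0.001)
})

test_that("raised potassium intake drives plasma K to a higher plateau", {
  p2 <- set_parameter(nominal, Kin = nominal$Kin * 1.1)
  tr <- simulate_qsp(p2, initial_state = nominal_ss,
                     horizon = 7 * 1440, dt = 360)
  k <- tr$K_plasma
  expect_gt(tail(k, 1), nominal$norm_plasma_K + 0.05)
  # a plateau is reached: last-day drift is small compared to the total rise
  drift <- abs(tail(k, 1) - k[tr$time == 6 * 1440])
  expect_lt(drift, 0.1 * (tail(k, 1) - nominal$norm_plasma_K))
  # an immediate sign check: dK_ecf/dt > 0 right after the perturbation
  d <- qsp_derivatives(nominal_ss, 0, p2)$derivatives
  expect_gt(d[["K_ecf"]], 0)
})

test_that("mass is conserved under dosing regimens", {
  reg <- dose_regimen(c(480, 480, 1560, 1920),
                      c("spironolactone", "potassium_oral",
                        "spironolactone", "potassium_oral"),
                      c(50, 20, 50, 20))
  tr <- simulate_qsp(nominal, regimen = reg, horizon = 2880, dt = 30)
  mb <- mass_balance(tr)
  expect_lt(mb$rel_error, 1e-4)
  # cumulative excretion at steady state equals Kin * t, and matches the
  # trapezoidal integral of the urinary flux
  tr0 <- simulate_qsp(nominal, horizon = 2880, dt = 30)
  expect_equal(tail(tr0$K_excreted, 1), nominal$Kin * 2880,
               tolerance = 0.005)
  trap <- sum(diff(tr0$time) * (head(tr0$urine_flux, -1) +
                                tail(tr0$urine_flux, -1)) / 2)
  expect_equal(tail(tr0$K_excreted, 1), trap, tolerance = 0.005)
})

test_that("states stay non-negative across random parameter draws", {
  set.seed(42)
  ranges <- param_ranges("efast")
  for (i in 1:25) {
    draw <- lapply(ranges, function(r) runif(1, r[1], r[2]))
    pp <- do.call(set_parameter, c(list(nominal), draw))
    tr <- simulate_qsp(pp, initial_state = nominal_ss, horizon = 1440,
                       dt = 120)
    expect_true(all(as.matrix(tr[spirok:::qsp_state_names()]) > -1e-8))
  }
})

test_that("steady-state finder converges, is idempotent and monotone in Kin", {
  ss <- find_steady_state(nominal)
  expect_equal(unname(ss["K_ecf"] / nominal$V_ecf * 1000),
               nominal$norm_plasma_K, tolerance = 0.005)
  ss2 <- find_steady_state(nominal)
  expect_equal(ss, ss2, tolerance = 1e-8)
  kin_grid <- seq(0.073, 0.084, length.out = 4)
  k_ss <- vapply(kin_grid, function(kin) {
    s <- find_steady_state(set_parameter(nominal, Kin = kin))
    unname(s["K_ecf"] / nominal$V_ecf * 1000)
  }, numeric(1))
  expect_true(all(diff(k_ss) > 0))
})

test_that("GFR alone barely moves the steady state; proportional nephron scaling does", {
  alone <- find_steady_state(set_parameter(nominal, GFR = 50))
  joint <- find_steady_state(set_parameter(nominal, GFR = 50,
                                           N_nephrons = nominal$N_nephrons / 2))
  k0 <- nominal$norm_plasma_K
  d_alone <- abs(alone["K_ecf"] / nominal$V_ecf * 1000 - k0)
  d_joint <- abs(joint["K_ecf"] / nominal$V_ecf * 1000 - k0)
  expect_lt(d_alone, 0.25 * d_joint)
})

test_that("canrenone kinetics: superposition, terminal slope, ODE agreement", {
  expect_identical(canrenone_concentration(dose_regimen(), nominal, c(0, 100)),
                   c(0, 0))
  r1 <- dose_regimen(0, "spironolactone", 50)
  r2 <- dose_regimen(720, "spironolactone", 50)
  r12 <- dose_regimen(c(0, 720), rep("spironolactone", 2), c(50, 50))
  t <- 1440
  expect_equal(canrenone_concentration(r12, nominal, t),
               canrenone_concentration(r1, nominal, t) +
                 canrenone_concentration(r2, nominal, t),
               tolerance = 1e-12)
  # terminal log-linear slope equals the slow eigenvalue of the
  # disposition matrix
  A <- matrix(c(-(nominal$pk_CL + nominal$pk_Q) / nominal$pk_Vc,
                nominal$pk_Q / nominal$pk_Vp,
                nominal$pk_Q / nominal$pk_Vc,
                -nominal$pk_Q / nominal$pk_Vp), 2, 2, byrow = TRUE)
  lz <- min(abs(eigen(A)$values))
  tt <- seq(5000, 8000, by = 500)
  conc <- canrenone_concentration(r1, nominal, tt)
  slope <- -coef(lm(log(conc) ~ tt))[2]
  expect_equal(unname(slope), lz, tolerance = 0.02)
  # rises then falls
  prof <- canrenone_concentration(r1, nominal, seq(0, 4000, by = 30))
  pk <- which.max(prof)
  expect_gt(pk, 2); expect_lt(pk, length(prof))
  # closed form agrees with the compiled ODE route
  tr <- simulate_qsp(nominal, regimen = r1, horizon = 2880, dt = 60)
  expect_equal(tr$cren_conc,
               canrenone_concentration(r1, nominal, tr$time),
               tolerance = 1e-6)
})

test_that("MR blockade follows the Emax law and spironolactone raises plasma K", {
  expect_identical(mr_blockade(0, 0.8, 0.25), 0)
  expect_equal(mr_blockade(0.25, 0.8, 0.25), 0.4)
  cgrid <- seq(0, 50, length.out = 200)
  b <- mr_blockade(cgrid, 0.8, 0.25)
  expect_true(all(diff(b) >= 0))
  expect_true(all(b < 0.8))
  reg <- dose_regimen(60, "spironolactone", 50)
  tr <- simulate_qsp(nominal, regimen = reg, horizon = 2880, dt = 60)
  tr0 <- simulate_qsp(nominal, horizon = 2880, dt = 60)
  expect_gt(max(tr$K_plasma - tr0$K_plasma), 0.05)
  # no canrenone on board leaves distal secretion at its drug-free value
  st <- nominal_ss
  d0 <- qsp_derivatives(st, 0, nominal)$outputs
  st2 <- st; st2["cren_gut"] <- 40  # drug still unabsorbed
  d1 <- qsp_derivatives(st2, 0, nominal)$outputs
  expect_equal(d1[["secretion"]], d0[["secretion"]])
  expect_equal(d1[["mr_blockade"]], 0)
})

test_that("perturbation exploration reports percent deviations on the 2-h grid", {
  null <- explore_perturbation(nominal, "Kin", 1.0)
  expect_equal(nrow(null$plasma_K), 13)
  expect_lt(max(abs(null$deviations$percent_change)), 1e-6)
  up <- explore_perturbation(nominal, "Kin", 1.2)
  kdev <- up$plasma_K$perturbed - up$plasma_K$baseline
  expect_true(all(diff(kdev) > 0))
  urine <- subset(up$deviations, variable == "urine_flux" & time_h > 0)
  expect_true(all(urine$percent_change > 0))
  # near the identity, a two-parameter perturbation composes the single ones
  two <- explore_perturbation(nominal, c("Kin", "Nain"), c(1.02, 1.02))
  one_a <- explore_perturbation(nominal, "Kin", 1.02)
  one_b <- explore_perturbation(nominal, "Nain", 1.02)
  dev2 <- two$plasma_K$perturbed - two$plasma_K$baseline
  dev_sum <- (one_a$plasma_K$perturbed - one_a$plasma_K$baseline) +
    (one_b$plasma_K$perturbed - one_b$plasma_K$baseline)
  expect_equal(dev2, dev_sum, tolerance = 0.02)
  expect_error(explore_perturbation(nominal, "nope", 1.1), "unknown")
})

test_that("regimen validation rejects malformed inputs", {
  expect_error(dose_regimen(-5, "spironolactone", 50), ">= 0")
  expect_error(dose_regimen(5, "spironolactone", 0), "positive")
  expect_error(dose_regimen(5, "asprin", 50), "drug")
})
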