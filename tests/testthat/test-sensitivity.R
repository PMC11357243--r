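test_that("parameters outside the drug-free potassium pathway have zero sensitivity", {
  s <- local_sensitivity(nominal, "pk_Vp", scenarios = "standard")
  expect_lt(max(abs(s$S)), 1e-10)
  expect_equal(targeted_aldosterone_sensitivity(nominal, "pk_Vp"), 0,
               tolerance = 1e-10)
  expect_error(local_sensitivity(nominal, "hyperaldo_effect"), "zero")
})

test_that("extracellular volume sensitivity peaks right after the perturbation", {
  s <- local_sensitivity(nominal, "V_ecf", scenarios = "standard")
  a <- abs(s$S[s$time_min > 0])
  expect_equal(which.max(a), 1L)
  expect_true(all(diff(a) < 0))
})

test_that("forward differences agree with a central-difference oracle at 1% steps", {
  for (pn in c("Kin", "V_ecf")) {
    fwd <- attr(local_sensitivity(nominal, pn, step = 0.01,
                                  scenarios = "standard"), "summary")[["standard"]]
    # central difference, same 1% step
    init <- nominal_ss
    base <- simulate_qsp(nominal, horizon = 1440, dt = 60)
    up <- spirok:::perturbed_run(nominal, init, pn, nominal[[pn]] * 1.01,
                                 1440, 60)
    dn <- spirok:::perturbed_run(nominal, init, pn, nominal[[pn]] * 0.99,
                                 1440, 60)
    ctr <- mean(abs(((up$K_plasma - dn$K_plasma) / base$K_plasma) / 0.02))
    expect_equal(fwd, ctr, tolerance = 0.05)
  }
})

test_that("finite-difference sensitivity converges as the step shrinks", {
  s_at <- function(h) attr(local_sensitivity(nominal, "Kin", step = h,
                                             scenarios = "standard"),
                           "summary")[["standard"]]
  s10 <- s_at(0.10); s05 <- s_at(0.05); s01 <- s_at(0.01); s005 <- s_at(0.005)
  expect_lt(abs(s01 - s005), abs(s10 - s05))
})

test_that("targeted aldosterone sensitivities carry the expected signs", {
  s_kin <- targeted_aldosterone_sensitivity(nominal, "Kin")
  s_nain <- targeted_aldosterone_sensitivity(nominal, "Nain")
  expect_gt(s_kin, 0)
  expect_lt(s_nain, 0)
  s_m <- targeted_aldosterone_sensitivity(nominal, "m_K_ALDO")
  expect_gt(s_m, 0)
  # central-difference oracle at 1%
  init <- nominal_ss
  base <- simulate_qsp(nominal, horizon = 1440, dt = 60)
  up <- spirok:::perturbed_run(nominal, init, "m_K_ALDO",
                               nominal$m_K_ALDO * 1.01, 1440, 60)
  dn <- spirok:::perturbed_run(nominal, init, "m_K_ALDO",
                               nominal$m_K_ALDO * 0.99, 1440, 60)
  keep <- base$time > 0
  ctr <- ((max(up$aldosterone[keep]) - max(dn$aldosterone[keep])) /
            max(base$aldosterone[keep])) / 0.02
  fwd <- targeted_aldosterone_sensitivity(nominal, "m_K_ALDO", step = 0.01)
  expect_equal(fwd, ctr, tolerance = 0.05)
})

test_that("ranking orders magnitudes and applies the liberal margin", {
  r1 <- rank_parameters(c(a = 0.02))
  expect_true(r1$sensitive)
  r2 <- rank_parameters(c(big = 0.5, small = 0.005))
  expect_identical(r2$parameter, c("big", "small"))
  expect_identical(r2$sensitive, c(TRUE, FALSE))
  # ties break alphabetically
  r3 <- rank_parameters(c(zeta = 0.3, alpha = 0.3))
  expect_identical(r3$parameter, c("alpha", "zeta"))
})

test_that("the full local screen ranks volume and sodium intake among the top", {
  screened <- setdiff(investigated_parameters(), "hyperaldo_effect")
  sens <- lapply(screened, function(pn)
    local_sensitivity(nominal, pn, scenarios = "standard"))
  rk <- rank_parameters(sens)
  expect_identical(rk$parameter[1], "V_ecf")
  expect_true("Nain" %in% rk$parameter[rk$sensitive])
  expect_true(all(c("Kin", "MR", "norm_plasma_K") %in%
                    rk$parameter[rk$sensitive]))
  expect_false(any(c("m_K_ALDO", "Aldo_KSec_scale", "m_plasmaK_MCD",
                     "K_reabsorption_MCD_rate0") %in%
                     rk$parameter[rk$sensitive]))
})

test_that("receptor abundance matters more under mild hyperaldosteronism", {
  s <- local_sensitivity(nominal, "MR")
  m <- attr(s, "summary")
  expect_gt(m[["mild_hyperaldosteronism"]] / m[["standard"]], 1.05)
})

test_that("collinearity index: orthogonal columns give 1, duplicates explode", {
  S_orth <- cbind(a = c(1, 0, 0, 0), b = c(0, 2, 0, 0))
  expect_equal(spirok:::gamma_from_columns(S_orth), 1, tolerance = 1e-12)
  S_dup <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_gt(spirok:::gamma_from_columns(S_dup), 15)
  # invariance to column rescaling
  S <- cbind(a = c(1, 2, 0.5), b = c(0.3, -1, 2))
  expect_equal(spirok:::gamma_from_columns(S),
               spirok:::gamma_from_columns(sweep(S, 2, c(10, 0.01), "*")),
               tolerance = 1e-10)
  expect_error(spirok:::gamma_from_columns(cbind(a = c(0, 0), b = c(1, 1))),
               "inert")
})

test_that("sodium intake and hyperaldosteronism are mutually poorly identifiable", {
  ci <- collinearity_index(nominal, c("Nain", "hyperaldo_effect"),
                           n_sim = 5, seed = 11)
  expect_gt(ci$gamma, 15)
  expect_false(ci$identifiable)
  ci2 <- collinearity_index(nominal, c("Kin", "V_ecf"), n_sim = 5, seed = 11)
  expect_lt(ci2$gamma, 15)
  expect_true(ci2$identifiable)
  expect_true(all(c(ci$replicates, ci2$replicates) >= 1))
})

test_that("identifiability scan enumerates subsets and respects interlacing", {
  sc2 <- identifiability_scan(nominal, c("Kin", "V_ecf"), n_sim = 2, seed = 3)
  expect_equal(nrow(sc2), 1)
  cand <- c("Kin", "Nain", "V_ecf", "MR")
  sc <- identifiability_scan(nominal, cand, k = 4, n_sim = 2, seed = 3)
  expect_equal(nrow(sc), choose(4, 2) + choose(4, 3) + 1)
  # superset gamma >= contained subset gamma
  g_full <- sc$gamma[sc$size == 4]
  expect_true(all(g_full >= sc$gamma - 1e-8))
  expect_error(identifiability_scan(nominal, letters[1:11]), "guard")
})
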