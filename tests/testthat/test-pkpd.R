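test_that("metformin PK: empty system, linearity, analytic AUC", {
  dp <- metformin_parameters()
  d0 <- metformin_pk_rhs(0, pk_state(dp), dp)
  expect_identical(unname(d0), rep(0, length(d0)))

  out1 <- simulate_pk(dp, data.frame(time = 0, dose_mg = 500),
                      times = seq(0, 96, 0.25))
  out2 <- simulate_pk(dp, data.frame(time = 0, dose_mg = 1000),
                      times = seq(0, 96, 0.25))
  m1 <- pk_metrics(out1$time, out1$conc)
  m2 <- pk_metrics(out2$time, out2$conc)
  expect_equal(m2$Cmax / m1$Cmax, 2, tolerance = 1e-6)
  expect_equal(m2$AUC_0_t / m1$AUC_0_t, 2, tolerance = 1e-6)

  # linear-PK oracle: AUC_inf = F * dose / CL (ng/mL scale)
  auc_inf <- 500 * dp$F / dp$CL * 1000
  expect_equal(m1$AUC_0_t, auc_inf, tolerance = 0.01)
})

test_that("PK mass balance closes at every output time", {
  dp <- metformin_parameters()
  doses <- data.frame(time = c(0, 12, 24, 36), dose_mg = 500)
  # sample between dose instants: the state at an event time is pre-bolus
  out <- simulate_pk(dp, doses, times = seq(0.1, 48.1, 0.5))
  given <- vapply(out$time, function(t) sum(doses$dose_mg[doses$time < t]), 0)
  total <- out$depot + out$central + out$peripheral + out$cum_elim +
    out$cum_nonabs
  expect_lt(max(abs(total - given) / pmax(given, 1)), 1e-6)

  tp <- tak875_parameters()
  outT <- simulate_pk(tp, data.frame(time = 0, dose_mg = 100),
                      times = seq(0, 72, 0.5), trigger_times = c(8, 13, 19))
  totT <- outT$depot + outT$recirc + outT$central + outT$peripheral +
    outT$bile + outT$gallbladder + outT$cum_elim + outT$cum_nonabs
  expect_lt(max(abs(totT[-1] - 100) / 100), 1e-6)
})

test_that("steady-state bid profile obeys superposition of single doses", {
  dp <- metformin_parameters()
  times <- seq(0, 240, 0.5)
  doses <- data.frame(time = seq(0, 228, by = 12), dose_mg = 500)
  multi <- simulate_pk(dp, doses, times)$conc
  single <- simulate_pk(dp, data.frame(time = 0, dose_mg = 500), times)$conc
  lagged <- rep(0, length(times))
  for (t0 in doses$time) {
    idx <- times >= t0
    lagged[idx] <- lagged[idx] +
      stats::approx(times, single, xout = times[idx] - t0, rule = 2)$y
  }
  expect_equal(multi, lagged, tolerance = 1e-4)
})

test_that("EHRC: off reduces to the oral model, on gives secondary peaks", {
  tp <- tak875_parameters()
  tp0 <- tp
  tp0$biliary_frac <- 0
  plain <- drug_parameters("plain", "oral_3c", ka = tp$ka, F = tp$F,
                           V_central = tp$V_central,
                           V_peripheral = tp$V_peripheral,
                           CL = tp$CL, Q = tp$Q)
  times <- seq(0, 48, 0.1)
  cehrc0 <- simulate_pk(tp0, data.frame(time = 0, dose_mg = 50), times,
                        trigger_times = c(5, 11))$conc
  cplain <- simulate_pk(plain, data.frame(time = 0, dose_mg = 50), times)$conc
  expect_equal(cehrc0, cplain, tolerance = 1e-8)

  cehrc <- simulate_pk(tp, data.frame(time = 0, dose_mg = 50), times,
                       trigger_times = c(5, 11))$conc
  # a secondary rise after a gallbladder trigger: local minimum then rebound
  after <- times > 5 & times < 16
  expect_true(any(diff(cehrc[after]) > 0))
  expect_false(any(diff(cehrc0[after]) > 0))

  # terminal recovered mass is invariant to the biliary fraction
  cleared <- vapply(c(0, 0.4, 0.8), function(bf) {
    tpx <- tp
    tpx$biliary_frac <- bf
    o <- simulate_pk(tpx, data.frame(time = 0, dose_mg = 50),
                     times = seq(0, 1500, 5),
                     trigger_times = seq(8, 1495, by = 12))
    tail(o$cum_elim, 1)
  }, 0)
  expect_equal(cleared, rep(50 * tp$F, 3), tolerance = 1e-3)
})

test_that("apply_dose is an additive depot bolus", {
  dp <- metformin_parameters()
  pk <- pk_state(dp)
  expect_identical(apply_dose(pk, 0), pk)
  pk[["depot"]] <- 10
  expect_equal(apply_dose(pk, 500)[["depot"]], 510)
  expect_equal(apply_dose(apply_dose(pk, 250), 250), apply_dose(pk, 500))
  expect_error(apply_dose(pk, -1), "dose")
})

test_that("pd_effects: identity at zero, analytic half-max, combination", {
  drugs <- builtin_drugs()
  eff0 <- pd_effects(c(metformin = 0, tak875 = 0), drugs)
  expect_identical(as.numeric(eff0), rep(1, length(eff0)))

  custom <- list(metformin = drug_parameters(
    "metformin", "oral_3c", ka = 1, F = 0.5, V_central = 10,
    V_peripheral = 10, CL = 5, Q = 1,
    effects = list(visp:::.effect("hepatic_glucose_production", "inhibition",
                                  emax = 0.5, ec50 = 1000, n = 1))))
  eff <- pd_effects(c(metformin = 1000), custom)
  expect_equal(eff[["hepatic_glucose_production"]], 0.75)

  # two drugs on a shared tag combine multiplicatively
  two <- list(
    a = drug_parameters("a", "oral_3c", 1, 0.5, 10, 10, 5, 1,
                        effects = list(visp:::.effect(
                          "insulin_secretion_ca_gain", "activation", 1, 100, 1))),
    b = drug_parameters("b", "oral_3c", 1, 0.5, 10, 10, 5, 1,
                        effects = list(visp:::.effect(
                          "insulin_secretion_ca_gain", "activation", 1, 100, 1))))
  eff2 <- pd_effects(c(a = 100, b = 100), two)
  expect_equal(eff2[["insulin_secretion_ca_gain"]], 1.5^2)

  expect_error(pd_effects(c(nodrug = 1), drugs), "nodrug")
})

test_that("hypothesis switches gate their effects", {
  drugs <- builtin_drugs()
  off <- pd_effects(c(tak875 = 5000), drugs)
  expect_identical(off[["incretin_secretion_gain"]], 1)
  expect_gt(off[["insulin_secretion_ca_gain"]], 1)
  on <- pd_effects(c(tak875 = 5000), drugs,
                   hypotheses = c(gpr40_incretin_secretion = TRUE,
                                  metformin_beta_cell = FALSE))
  expect_gt(on[["incretin_secretion_gain"]], 1)

  met_off <- pd_effects(c(metformin = 1000), drugs)
  expect_identical(met_off[["beta_cell_function"]], 1)
})

test_that("pd_effects is pure", {
  drugs <- builtin_drugs()
  e1 <- pd_effects(c(metformin = 700, tak875 = 2000), drugs)
  e2 <- pd_effects(c(metformin = 700, tak875 = 2000), drugs)
  expect_identical(e1, e2)
})

test_that("pk_metrics: constant, triangle, validation", {
  m <- pk_metrics(c(0, 1, 2, 3), rep(4, 4))
  expect_equal(m$Cmax, 4)
  expect_equal(m$Tmax, 0)
  expect_equal(m$AUC_0_t, 12)

  tri <- pk_metrics(c(0, 2, 4), c(0, 10, 0))
  expect_equal(tri$Cmax, 10)
  expect_equal(tri$Tmax, 2)
  expect_equal(tri$AUC_0_t, 20)

  expect_error(pk_metrics(c(0, 1), c(1, 2, 3)), "length")
  expect_error(pk_metrics(c(0, 0, 1), c(1, 2, 3)), "increasing")
})
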