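test_that("steady-state flux conserves mass and respects blocks", {
  reg <- ssc_reg()
  sc <- simulation_scenario("all-on")
  fx <- steady_state_flux(reg, sc)
  expect_equal(sum(fx$sink), sc$input_flux, tolerance = 1e-9)
  expect_true(all(fx$sink >= 0))

  blocked <- simulation_scenario("no21", activities = c(CYP21A2 = 0))
  fxb <- steady_state_flux(reg, blocked)
  expect_equal(fxb$inflow[["11-deoxycortisol"]], 0)
  expect_equal(fxb$inflow[["DOC"]], 0)
  expect_gt(fxb$sink[["17OHP"]], fx$sink[["17OHP"]])

  expect_error(steady_state_flux(reg, simulation_scenario(
    activities = c(NOT_AN_ENZYME = 0.5))), "unknown enzyme")
})

test_that("exact linear solve matches the iterative fixed-point oracle", {
  reg <- ssc_reg()
  enz <- unique(reg$reactions$enzyme)
  set.seed(7)
  for (i in 1:10) {
    acts <- stats::setNames(runif(length(enz)), enz)
    sc <- simulation_scenario("rand", activities = acts,
                              por_activity = runif(1),
                              enable_backdoor = i %% 2 == 0)
    fx <- steady_state_flux(reg, sc)
    oracle <- flux_oracle(reg, sc)
    expect_equal(fx$inflow, oracle$inflow, tolerance = 1e-9)
    expect_equal(fx$sink, oracle$sink, tolerance = 1e-9)
  }
})

test_that("excretion mapping conserves mass and honours partition limits", {
  reg <- ssc_reg()
  sc <- simulation_scenario("default")
  prof <- excrete(steady_state_flux(reg, sc), sc, reg)
  expect_equal(sum(prof$amounts), sc$input_flux, tolerance = 1e-9)
  expect_identical(sort(names(prof$amounts)), sort(reg$metabolites$abbr))

  # beta_11oxo = 1: all cortisol-pathway metabolite mass on the 11-oxo side
  sc1 <- simulation_scenario("oxo", beta_11oxo = 1)
  p1 <- excrete(steady_state_flux(reg, sc1), sc1, reg)
  expect_equal(unname(p1$amounts[c("THF", "5aTHF", "a-cortol", "b-cortol",
                                   "6b-OH-cortisol", "F")]),
               rep(0, 6))
  expect_gt(p1$amounts[["THE"]], 0)
  expect_gt(p1$amounts[["a-cortolone"]], 0)
  expect_equal(sum(p1$amounts), sc1$input_flux, tolerance = 1e-9)

  # rho_5alpha = 0: no 5a-reduced metabolites at all (back-door disabled)
  sc0 <- simulation_scenario("no5a", rho_5alpha = 0)
  p0 <- excrete(steady_state_flux(reg, sc0), sc0, reg)
  expect_equal(unname(p0$amounts[c("An", "5aTHF", "5aTHB", "5aTHA",
                                   "5aTHDOC")]),
               rep(0, 5))
  expect_gt(p0$amounts[["Et"]], 0)
})

test_that("mass closure holds across random scenarios", {
  reg <- ssc_reg()
  enz <- unique(reg$reactions$enzyme)
  set.seed(70)
  for (i in 1:10) {
    sc <- simulation_scenario(
      "rand", activities = stats::setNames(runif(length(enz)), enz),
      por_activity = runif(1), rho_5alpha = runif(1),
      beta_11oxo = runif(1), free_escape = runif(1),
      input_flux = runif(1, 1e3, 1e5),
      enable_backdoor = i %% 2 == 0)
    prof <- excrete(steady_state_flux(reg, sc), sc, reg)
    expect_equal(sum(prof$amounts) / sc$input_flux, 1, tolerance = 1e-9)
  }
})

test_that("simulated cohorts are reproducible with deterministic noise", {
  reg <- ssc_reg()
  sc <- scenario_preset("normal")

  quiet <- scenario_preset("normal", noise_sigma = 0)
  ps <- simulate_cohort(quiet, 3, reg, seed = 1)
  expect_identical(ps[[1]]$amounts, ps[[2]]$amounts)
  expect_identical(ps[[2]]$amounts, ps[[3]]$amounts)

  a <- simulate_cohort(sc, 10, reg, seed = 123)
  b <- simulate_cohort(sc, 10, reg, seed = 123)
  expect_identical(lapply(a, `[[`, "amounts"), lapply(b, `[[`, "amounts"))
  c2 <- simulate_cohort(sc, 10, reg, seed = 124)
  expect_false(identical(a[[1]]$amounts, c2[[1]]$amounts))
})

test_that("log-normal noise preserves the noise-free median", {
  reg <- ssc_reg()
  sc <- scenario_preset("normal")
  nf <- noisefree("normal")$amounts
  cohort <- simulate_cohort(sc, 1000, reg, seed = 1)
  mat <- vapply(cohort, `[[`, nf, "amounts")
  med <- apply(mat, 1, stats::median)
  # median of exp(N(0, sigma)) is 1; SE of the log sample median is
  # ~ 1.2533 sigma / sqrt(n)
  se3 <- 3 * 1.2533 * sc$noise_sigma / sqrt(1000)
  expect_true(all(abs(log(med) - log(nf)) < se3))
})

test_that("presets encode the documented parameter deltas", {
  expect_error(scenario_preset("NOPE"), "normal")

  norm <- scenario_preset("normal")
  expect_length(norm$activities, 0L)
  expect_equal(norm$por_activity, 1)
  expect_equal(norm$rho_5alpha, 0.4)
  expect_equal(norm$beta_11oxo, 0.55)
  expect_equal(norm$gc_compensation, 1)

  acrd <- scenario_preset("ACRD")
  expect_equal(acrd$beta_11oxo, 0.95)
  expect_length(acrd$activities, 0L)

  ord <- scenario_preset("ORD")
  expect_equal(ord$por_activity, 0.05)
  expect_false(any(c("CYP11B1", "CYP11B2") %in% names(ord$activities)))

  preg <- scenario_preset("ORD_pregnancy")
  expect_true(preg$enable_backdoor)

  ame <- scenario_preset("AME")
  expect_equal(ame$beta_11oxo, 0.15)

  srd <- scenario_preset("SRD5A2")
  expect_equal(srd$rho_5alpha, 0.05)
})

test_that("the back-door route raises androsterone in ORD pregnancy", {
  an_ord <- noisefree("ORD")$amounts[["An"]]
  an_preg <- noisefree("ORD_pregnancy")$amounts[["An"]]
  expect_gt(an_preg / an_ord, 1.5)
  # and the 5a-reduced 17OHP intermediate spills into its urinary metabolite
  expect_gt(noisefree("ORD_pregnancy")$amounts[["3a5a17HP"]],
            noisefree("ORD")$amounts[["3a5a17HP"]])
})

test_that("scenario validation rejects out-of-range parameters", {
  expect_error(simulation_scenario(beta_11oxo = 1.2), "\\[0, 1\\]")
  expect_error(simulation_scenario(activities = c(CYP21A2 = -0.1)),
               "\\[0, 1\\]")
  expect_error(simulation_scenario(input_flux = 0), "input_flux")
  expect_error(simulation_scenario(noise_sigma = -1), "noise_sigma")
})
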