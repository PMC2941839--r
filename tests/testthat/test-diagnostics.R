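ratio_def <- function(id) {
  reg <- ssc_reg()
  reg$ratios[reg$ratios$id == id, ]
}

test_that("compute_ratio sums present analytes and propagates undefined", {
  p <- make_profile(c(THE = 100, THF = 60, "5aTHF" = 40))
  r <- compute_ratio(p, ratio_def("ACRD_1"), ssc_reg())
  expect_equal(r$value, 1.0)
  expect_equal(r$numerator_sum, 100)
  expect_equal(r$denominator_sum, 100)
  expect_length(r$missing, 0L)

  # denominator entirely unmeasured -> undefined, with the gaps recorded
  p2 <- make_profile(c(THE = 100))
  r2 <- compute_ratio(p2, ratio_def("ACRD_1"), ssc_reg())
  expect_true(is.na(r2$value))
  expect_setequal(r2$missing, c("THF", "5aTHF"))

  # measured-but-zero denominator does not support a ratio either
  p3 <- make_profile(c(THE = 100, THF = 0, "5aTHF" = 0))
  expect_true(is.na(compute_ratio(p3, ratio_def("ACRD_1"), ssc_reg())$value))
})

test_that("compute_ratio matches brute-force re-summation on random draws", {
  set.seed(31)
  def <- ratio_def("ORD_1")   # (17HP + PT) / (An + Et)
  for (i in 1:10) {
    x <- rlnorm(1, 5); a <- rlnorm(1, 4); b <- rlnorm(1, 4)
    p <- make_profile(c(An = x, Et = x, "17HP" = a, PT = b))
    expect_equal(compute_ratio(p, def, ssc_reg())$value, (a + b) / (2 * x),
                 tolerance = 1e-12)
  }
})

test_that("ratios are scale-invariant and monotone in their analytes", {
  set.seed(8)
  reg <- ssc_reg()
  base <- rlnorm(33, 4)
  names(base) <- reg$metabolites$abbr
  p <- make_profile(base)
  for (i in c(1, 9, 14, 23)) {
    def <- reg$ratios[i, ]
    v0 <- compute_ratio(p, def, reg)$value
    p_scaled <- make_profile(base * 3.7)
    expect_equal(compute_ratio(p_scaled, def, reg)$value, v0,
                 tolerance = 1e-12)
    up <- base; nm <- def$numerator[[1]][1]
    up[nm] <- up[nm] * 2
    expect_gt(compute_ratio(make_profile(up), def, reg)$value, v0)
    dn <- base; dm <- def$denominator[[1]][1]
    dn[dm] <- dn[dm] * 2
    expect_lt(compute_ratio(make_profile(dn), def, reg)$value, v0)
  }
})

test_that("group totals partition the profile mass", {
  reg <- ssc_reg()
  gt <- group_totals(make_profile(c(THE = 100, THF = 50, An = 25)), reg)
  expect_equal(gt[["glucocorticoids"]], 150)
  expect_equal(gt[["androgens"]], 25)
  expect_equal(sum(gt), 175)

  expect_equal(sum(group_totals(make_profile(numeric()), reg)), 0)

  set.seed(12)
  amounts <- stats::setNames(rlnorm(33, 5), reg$metabolites$abbr)
  gt <- group_totals(make_profile(amounts), reg)
  expect_equal(sum(gt), sum(amounts), tolerance = 1e-9)

  spot <- make_profile(c(THE = 1), collection = "spot")
  expect_error(group_totals(spot, reg), "24-h")
})

test_that("evaluate_panel returns the full panel and enforces versions", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- simulate_cohort(scenario_preset("normal"), 1, reg, seed = 3)[[1]]
  panel <- evaluate_panel(p, reg, ref)
  expect_identical(nrow(panel$ratios), 23L)
  expect_identical(nrow(panel$calls), 9L)
  expect_identical(sum(panel$calls$n_ratios), 23L)

  ref_bad <- ref
  attr(ref_bad, "registry_version") <- "v0"
  expect_error(evaluate_panel(p, reg, ref_bad), "version")
})

test_that("missing cortisol metabolites make those disorders uncallable", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- make_profile(c("17HP" = 500, PT = 400, An = 100, Et = 100,
                      DHEA = 50))
  panel <- evaluate_panel(p, reg, ref)
  den_cort <- vapply(seq_len(nrow(reg$ratios)), function(i)
    all(c("THE", "THF", "5aTHF") %in% reg$ratios$denominator[[i]]), TRUE)
  expect_true(all(is.na(panel$ratios$value[den_cort])))
  uncallable <- unique(reg$ratios$disorder[den_cort])
  expect_true(all(!panel$calls$positive[panel$calls$disorder %in%
                                          uncallable]))
  expect_true(all(panel$calls$n_undefined[panel$calls$disorder %in%
                                            uncallable] > 0))
})

test_that("normal profiles rarely trigger any positive call", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  normals <- simulate_cohort(scenario_preset("normal"), 50, reg, seed = 29)
  clean <- vapply(normals, function(p)
    is.na(top_call(evaluate_panel(p, reg, ref))), TRUE)
  # two single-ratio disorders x 5% one-sided false-high rate: expect ~90%
  expect_gte(mean(clean), 0.8)
})

test_that("a severe ORD case elevates all five ORD ratios", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- simulate_cohort(scenario_preset("ORD"), 1, reg, seed = 17)[[1]]
  panel <- evaluate_panel(p, reg, ref)
  ord <- panel$ratios[panel$ratios$disorder == "ORD", ]
  expect_identical(ord$flag, rep("high", 5L))
  call <- panel$calls[panel$calls$disorder == "ORD", ]
  expect_true(call$positive)
  expect_identical(top_call(panel), "ORD")
})
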