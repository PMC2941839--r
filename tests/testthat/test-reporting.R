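test_that("the ORD quantitative report shows the classic group pattern", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- simulate_cohort(scenario_preset("ORD"), 1, reg, seed = 21)[[1]]
  qr <- render_quant_report(p, ref, reg)
  flags <- stats::setNames(qr$group_rows$flag, qr$group_rows$group_label)
  expect_identical(flags[["glucocorticoid_precursors"]], "high")
  expect_identical(flags[["mineralocorticoids_and_precursors"]], "high")
  expect_identical(flags[["androgens"]], "low")
  expect_identical(flags[["glucocorticoids"]], "normal")
  # rows come out in fixed group order
  expect_identical(unique(qr$rows$group), reg$group_order)
})

test_that("an empty profile reports every flag as undefined", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  qr <- render_quant_report(make_profile(numeric()), ref, reg)
  expect_true(all(qr$rows$flag == "undefined"))
  expect_true(all(qr$group_rows$flag == "undefined"))
  expect_identical(nrow(qr$rows), 33L)
})

test_that("normal cases flag ~90% of analytes normal against 90% intervals", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  cases <- simulate_cohort(scenario_preset("normal"), 20, reg, seed = 37)
  frac <- vapply(cases, function(p) {
    qr <- render_quant_report(p, ref, reg)
    mean(qr$rows$flag == "normal")
  }, 0)
  expect_gte(mean(frac), 0.85)
})

test_that("the ACRD ratio panel flags both cortisone/cortisol ratios high", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- simulate_cohort(scenario_preset("ACRD"), 1, reg, seed = 23)[[1]]
  rp <- render_ratio_panel(p, ref, reg)
  expect_length(rp$sections, 9L)
  acrd <- rp$sections$ACRD
  expect_identical(acrd$ratios$flag, rep("high", 2L))
  expect_true(acrd$call$positive)
})

test_that("a noise-free normal profile yields no positive section", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  rp <- render_ratio_panel(noisefree("normal"), ref, reg)
  pos <- vapply(rp$sections, function(s) s$call$positive, TRUE)
  expect_false(any(pos))
})

test_that("all-undefined denominators yield zero positives", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- make_profile(c("17HP" = 10, PD = 5))   # no denominator analytes
  rp <- render_ratio_panel(p, ref, reg)
  expect_true(all(is.na(rp$panel$ratios$value)))
  expect_false(any(rp$panel$calls$positive))
})

test_that("plots are written with a deterministic structured sidecar", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- simulate_cohort(scenario_preset("ORD"), 1, reg, seed = 21)[[1]]
  rp <- render_ratio_panel(p, ref, reg)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  plot_reports(rp, f1, format = "svg")
  plot_reports(rp, f2, format = "svg")
  expect_gt(file.size(f1), 0)
  expect_identical(readLines(paste0(f1, ".json")),
                   readLines(paste0(f2, ".json")))
  side <- jsonlite::read_json(paste0(f1, ".json"))
  expect_identical(side$n_markers, 23L)

  qr <- render_quant_report(p, ref, reg)
  f3 <- withr::local_tempfile(fileext = ".svg")
  plot_reports(qr, f3)
  expect_gt(file.size(f3), 0)
  expect_error(plot_reports(qr, f3, format = "pdf"), "should be one of")
})

test_that("report JSON serializations are stable and typed", {
  reg <- ssc_reg()
  ref <- ssc_ref200()
  p <- simulate_cohort(scenario_preset("normal"), 1, reg, seed = 2)[[1]]
  qr <- render_quant_report(p, ref, reg)
  rp <- render_ratio_panel(p, ref, reg)
  expect_identical(report_json(qr), report_json(qr))
  expect_match(report_json(qr), '"type":"quant"')
  expect_match(report_json(rp), '"type":"ratio_panel"')
})

test_that("the CLI pipeline is byte-deterministic end to end", {
  dir <- withr::local_tempdir()
  path <- function(...) file.path(dir, ...)
  expect_identical(run_cli(c("simulate", "--preset", "normal", "-n", "30",
                             "--seed", "11", "-o", path("normals.tsv"))), 0L)
  expect_identical(run_cli(c("reference", "build", "-i",
                             path("normals.tsv"), "--min-n", "20",
                             "-o", path("ref.json"))), 0L)
  expect_identical(run_cli(c("simulate", "--preset", "ORD", "-n", "1",
                             "--seed", "13", "-o", path("case.tsv"))), 0L)
  expect_identical(run_cli(c("diagnose", "-i", path("case.tsv"), "--ref",
                             path("ref.json"), "-o", path("panel.json"))), 0L)
  expect_identical(run_cli(c("report", "panel", "-i", path("case.tsv"),
                             "--ref", path("ref.json"),
                             "-o", path("panel.svg"))), 0L)
  expect_true(file.size(path("panel.svg")) > 0)

  # identical re-run -> byte-identical artifacts
  expect_identical(run_cli(c("simulate", "--preset", "ORD", "-n", "1",
                             "--seed", "13", "-o", path("case2.tsv"))), 0L)
  expect_identical(run_cli(c("diagnose", "-i", path("case2.tsv"), "--ref",
                             path("ref.json"), "-o", path("panel2.json"))),
                   0L)
  expect_identical(readLines(path("panel.json")),
                   readLines(path("panel2.json")))
  expect_identical(readLines(path("case.tsv")), readLines(path("case2.tsv")))

  # validation failures exit with status 2
  expect_identical(suppressMessages(
    run_cli(c("simulate", "--preset", "BOGUS", "-o", path("x.tsv")))), 2L)
  expect_identical(suppressMessages(run_cli(c("nonsense"))), 2L)
  expect_identical(suppressMessages(run_cli(character())), 2L)
})
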