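test_that("the full analysis report has the expected structure", {
  co <- make_cohort(n = 900, seed = 37)
  rep <- analyze_cohort(co, m = 5, seed = 2, n_iterations = 3)
  expect_s3_class(rep, "followup_report")
  expect_equal(length(unique(rep$estimates$method)), 6)
  expect_setequal(unique(rep$estimates$group), c("PT", "UK", "Total"))
  expect_s3_class(rep$association_followup, "association_scan")
  expect_s3_class(rep$association_outcome, "association_scan")
  expect_true(all(c("Crude", "MI (non-responders)") %in% rep$estimates$method))
  chg <- rep$estimates[rep$estimates$method == "MI (total population)" & rep$estimates$group == "Total", "pct_change"]
  expect_false(is.na(chg))
})

test_that("with no missing data all six estimators coincide", {
  cfg <- default_epice_like_config(n_children = 1200, seed = 38)
  cfg$covariate_missing_rates[] <- 0
  cfg$responder_outcome_missing_rate <- 0
  # everyone responds: impairment can never bias follow-up
  cfg$followup_coefs <- list(intercept = 30)
  co <- derive_outcomes(generate_cohort(do.call(simulation_config, unclass(cfg))))
  expect_true(all(co$followed_up == 1))
  rep <- suppressWarnings(analyze_cohort(co, m = 4, seed = 3, n_iterations = 2))
  tot <- rep$estimates[rep$estimates$group == "Total", "estimate_pct"]
  expect_lt(max(tot[1:4]) - min(tot[1:4]), 0.3) # crude, both IPW, MI total
})

test_that("cmd_simulate is reproducible, creates directories, and rejects bad configs", {
  base <- withr::local_tempdir()
  cfg_path <- file.path(base, "cfg.json")
  jsonlite::write_json(list(n_children = 120, seed = 4), cfg_path, auto_unbox = TRUE)
  out1 <- file.path(base, "a", "deep")
  out2 <- file.path(base, "b")
  cmd_simulate(out1, config = cfg_path)
  cmd_simulate(out2, config = cfg_path)
  expect_identical(
    readLines(file.path(out1, "cohort.csv")),
    readLines(file.path(out2, "cohort.csv"))
  )
  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_true("cohort.csv" %in% unlist(manifest$files))

  bad <- file.path(base, "bad.json")
  jsonlite::write_json(list(n_children = 0), bad, auto_unbox = TRUE)
  expect_error(cmd_simulate(file.path(base, "c"), config = bad), "n_children")
})

test_that("cmd_analyze and cmd_sensitivity write deterministic reports", {
  base <- withr::local_tempdir()
  sim <- file.path(base, "sim")
  cmd_simulate(sim, config = NULL, seed = 6)
  # shrink for speed: regenerate a small cohort
  co <- make_cohort(n = 700, seed = 6)
  write_cohort(co, file.path(sim, "cohort.csv"))

  outA <- file.path(base, "runA")
  outB <- file.path(base, "runB")
  cmd_analyze(file.path(sim, "cohort.csv"), outA, m = 4, seed = 9, n_iterations = 2)
  cmd_analyze(file.path(sim, "cohort.csv"), outB, m = 4, seed = 9, n_iterations = 2)
  for (f in c("attrition.csv", "estimates.csv", "associations_followup.csv")) {
    expect_identical(
      readLines(file.path(outA, f)), readLines(file.path(outB, f)),
      label = f
    )
  }

  sens <- file.path(base, "sens")
  grid <- cmd_sensitivity(file.path(sim, "cohort.csv"), sens,
    deltas = c(-0.1, 0.1), m = 3, seed = 9, n_iterations = 2
  )
  expect_equal(grid$scenario, c("crude", "MAR", "MNAR", "MNAR"))
  expect_true(file.exists(file.path(sens, "delta_grid.md")))
})

test_that("the manifest config hash is stable under field reordering", {
  h1 <- followupbias:::config_hash(list(a = 1, b = list(x = "u", y = 2)))
  h2 <- followupbias:::config_hash(list(b = list(y = 2, x = "u"), a = 1))
  h3 <- followupbias:::config_hash(list(a = 2, b = list(x = "u", y = 2)))
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))
})
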