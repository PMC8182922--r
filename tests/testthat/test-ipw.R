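test_that("alpha = 1 retains every candidate and region comes first", {
  co <- make_cohort(n = 600, seed = 27)
  retained <- screen_predictors(co, alpha = 1)
  expect_equal(retained[1], "region")
  expect_setequal(setdiff(retained, "region"), setdiff(attr(co, "covariates"), "region"))
})

test_that("null candidates are retained at about the screening rate", {
  set.seed(600)
  hits <- replicate(200, {
    n <- 1500
    region <- factor(sample(c("PT", "UK"), n, TRUE))
    y <- rbinom(n, 1, plogis(0.2 + 0.3 * (region == "UK")))
    df <- data.frame(region = region, followed_up = y)
    df$noise <- rbinom(n, 1, 0.5)
    co <- followupbias:::as_cohort(df, covariates = "noise")
    suppressWarnings("noise" %in% screen_predictors(co, candidates = "noise", alpha = 0.2))
  })
  expect_equal(mean(hits), 0.2, tolerance = 0.06 / 0.2)
})

test_that("social predictors survive screening on default cohorts", {
  kept <- sapply(1:20, function(s) {
    co <- make_cohort(n = 2000, seed = 700 + s)
    retained <- screen_predictors(co, alpha = 0.2)
    c(
      deprivation = "deprivation" %in% retained,
      maternal_age = "maternal_age" %in% retained
    )
  })
  expect_gte(mean(kept["deprivation", ]), 0.9)
  expect_gte(mean(kept["maternal_age", ]), 0.9)
})

test_that("an intercept-only response model gives every responder the reciprocal rate", {
  co <- make_accounting_cohort()
  # region-only cohort where region is uninformative: force a single level
  flat <- co
  flat$region <- factor("PT", levels = "PT")
  suppressWarnings(ws <- fit_weights(flat, retained = character(0)))
  expect_equal(unname(ws$weights), rep(1737 / 941, 941), tolerance = 1e-8)
  # reciprocal of the 54.2% response rate
  expect_equal(unname(ws$weights[1]), 1 / 0.542, tolerance = 0.002)
})

test_that("weights are 1 when everyone responds", {
  co <- make_cohort(n = 300, seed = 28)
  co$followed_up <- 1L
  suppressWarnings(ws <- fit_weights(co, retained = "region"))
  expect_true(all(abs(ws$weights - 1) < 1e-6))
})

test_that("two-stratum weights satisfy the Horvitz-Thompson identity exactly", {
  # stratum A: 500 children, 400 respond, 30% impaired among responders;
  # stratum B: 500 children, 200 respond, 10% impaired among responders
  make_stratum <- function(id, n, n_resp, prev, region) {
    followed <- c(rep(1L, n_resp), rep(0L, n - n_resp))
    imp <- c(rep(1L, round(prev * n_resp)), rep(0L, n_resp - round(prev * n_resp)))
    data.frame(
      child_id = sprintf("%s%04d", id, 1:n),
      region = region,
      followed_up = followed,
      impaired_observed = c(imp, rep(NA_integer_, n - n_resp)),
      stringsAsFactors = FALSE
    )
  }
  df <- rbind(
    make_stratum("A", 500, 400, 0.3, "R1"),
    make_stratum("B", 500, 200, 0.1, "R2")
  )
  df$region <- factor(df$region)
  co <- followupbias:::as_cohort(df, covariates = character(0))
  ws <- fit_weights(co, retained = "region")
  wA <- ws$weights[grepl("^A", names(ws$weights))]
  wB <- ws$weights[grepl("^B", names(ws$weights))]
  expect_equal(unname(wA), rep(1.25, 400), tolerance = 1e-8)
  expect_equal(unname(wB), rep(2.5, 200), tolerance = 1e-8)
  expect_equal(ws$diagnostics$sum_weights, 1000, tolerance = 1e-6)

  est <- weighted_prevalence(co, ws)
  expect_equal(est$estimate, 0.2, tolerance = 1e-12)
})

test_that("equal weights reduce to the crude prevalence and scaling is irrelevant", {
  co <- make_cohort(n = 800, seed = 29)
  ws <- fit_weights(co, retained = "region")
  flat <- ws
  flat$weights[] <- 1.7
  est_flat <- weighted_prevalence(co, flat)
  expect_equal(est_flat$estimate, crude_prevalence(co)$estimate, tolerance = 1e-12)
  scaled <- ws
  scaled$weights <- ws$weights * 3.14
  expect_equal(
    weighted_prevalence(co, scaled)$estimate,
    weighted_prevalence(co, ws)$estimate,
    tolerance = 1e-12
  )
})

test_that("Horvitz-Thompson weight sum approximates the modeled cohort size", {
  co <- make_cohort(n = 3000, seed = 30)
  ws <- fit_weights(co, config = ipw_config())
  expect_equal(ws$diagnostics$sum_weights, ws$n_model, tolerance = 0.02)
})

test_that("IPW on imputed predictors equals complete-case IPW when nothing is missing", {
  co <- make_cohort(n = 800, seed = 32)
  covs <- attr(co, "covariates")
  complete <- co[stats::complete.cases(as.data.frame(co)[covs]), ]
  cc <- weighted_prevalence(complete, fit_weights(complete, config = ipw_config()))
  im <- ipw_on_imputed(complete, mice_config(m = 3, n_iterations = 2, seed = 3))
  expect_equal(im$estimate, cc$estimate, tolerance = 1e-10)
  expect_equal(im$B, 0)
})

test_that("IPW with imputed predictors is deterministic and usually no less precise", {
  narrower <- sapply(1:15, function(s) {
    cfg <- default_epice_like_config(n_children = 1500, seed = 800 + s)
    # raise covariate missingness so complete-case IPW loses ~15% of rows
    cfg$covariate_missing_rates[] <- 0.015
    co <- derive_outcomes(generate_cohort(do.call(
      simulation_config, unclass(cfg)
    )))
    cc <- weighted_prevalence(co, fit_weights(co, config = ipw_config()))
    im <- ipw_on_imputed(co, mice_config(m = 8, n_iterations = 3, seed = 900 + s))
    diff(im$ci) <= diff(cc$ci)
  })
  expect_gte(mean(narrower), 0.6)

  co <- make_cohort(n = 700, seed = 33)
  a <- ipw_on_imputed(co, mice_config(m = 4, n_iterations = 2, seed = 5))
  b <- ipw_on_imputed(co, mice_config(m = 4, n_iterations = 2, seed = 5))
  expect_identical(a$estimate, b$estimate)
})
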