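test_that("configuration validation names the offending field", {
  spec <- list(x = list(prob = 0.5))
  expect_error(
    simulation_config(
      n_children = 10, region_probs = c(A = 1), covariate_spec = spec,
      outcome_coefs = list(intercept = 0, ghost = 1),
      followup_coefs = list(intercept = 0)
    ),
    "ghost"
  )
  expect_error(
    simulation_config(
      n_children = 0, region_probs = c(A = 1), covariate_spec = spec,
      outcome_coefs = list(intercept = 0), followup_coefs = list(intercept = 0)
    ),
    "n_children"
  )
  expect_error(
    simulation_config(
      n_children = 10, region_probs = c(A = 0.5, B = 0.6), covariate_spec = spec,
      outcome_coefs = list(intercept = 0), followup_coefs = list(intercept = 0)
    ),
    "sum to 1"
  )
})

test_that("generated response and latent prevalence match the Bernoulli rates", {
  cfg <- simulation_config(
    n_children = 100000,
    region_probs = c(PT = 0.35, UK = 0.65),
    covariate_spec = list(x = list(prob = 0.5)),
    outcome_coefs = list(intercept = qlogis(0.184)),
    followup_coefs = list(intercept = qlogis(0.542)),
    delta_true = 0, seed = 20
  )
  co <- generate_cohort(cfg)
  expect_equal(mean(co$followed_up), 0.542, tolerance = 0.005 / 0.542)
  expect_lt(abs(mean(co$followed_up) - 0.542), 0.005)
  expect_lt(abs(mean(co$latent_impaired) - 0.184), 0.004)
})

test_that("a single-child cohort satisfies every invariant", {
  cfg <- default_epice_like_config(n_children = 1, seed = 5)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 1L)
  expect_true(validate_cohort(co))
})

test_that("same seed gives a bit-identical table; different seeds differ", {
  a <- generate_cohort(default_epice_like_config(n_children = 300, seed = 9))
  b <- generate_cohort(default_epice_like_config(n_children = 300, seed = 9))
  c <- generate_cohort(default_epice_like_config(n_children = 300, seed = 10))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("default config hits the cohort margins across seeds", {
  stats <- t(sapply(1:10, function(s) {
    co <- derive_outcomes(generate_cohort(
      default_epice_like_config(n_children = 2000, seed = s)
    ))
    resp <- co$followed_up == 1
    c(
      response = mean(resp),
      crude = mean(co$impaired_observed[resp], na.rm = TRUE),
      out_miss = mean(is.na(co$impaired_observed[resp])),
      cov_miss = mean(rowSums(is.na(co[attr(co, "covariates")])) > 0)
    )
  }))
  expect_gte(mean(stats[, "response"]), 0.50)
  expect_lte(mean(stats[, "response"]), 0.58)
  expect_gte(mean(stats[, "crude"]), 0.15)
  expect_lte(mean(stats[, "crude"]), 0.22)
  expect_equal(mean(stats[, "out_miss"]), 0.111, tolerance = 0.2)
  expect_equal(mean(stats[, "cov_miss"]), 0.145, tolerance = 0.25)
})

test_that("follow-up is conditionally independent of latent status iff delta_true = 0", {
  # logistic fit of followed_up on covariates + latent_impaired: the latent
  # coefficient recovers -delta_true
  fit_latent_coef <- function(delta_true) {
    co <- generate_cohort(default_epice_like_config(
      n_children = 200000, delta_true = delta_true, seed = 77
    ))
    covs <- attr(co, "covariates")
    df <- co[stats::complete.cases(co[covs]), c("region", covs, "latent_impaired", "followed_up")]
    fit <- suppressWarnings(stats::glm(
      followed_up ~ ., data = df, family = stats::binomial()
    ))
    unname(stats::coef(fit)["latent_impaired"])
  }
  expect_lt(abs(fit_latent_coef(0)), 0.05)
  expect_lt(abs(fit_latent_coef(0.5) - (-0.5)), 0.1)
})

test_that("social covariates predict response more strongly than neonatal morbidity", {
  co <- generate_cohort(default_epice_like_config(n_children = 50000, seed = 31))
  scan <- association_scan(co, "followup",
    factors = c("deprivation", "maternal_age", "severe_morbidity")
  )
  stat_per_df <- scan$statistic / scan$df
  names(stat_per_df) <- scan$factor
  expect_gt(stat_per_df[["deprivation"]], stat_per_df[["severe_morbidity"]])
  expect_gt(stat_per_df[["maternal_age"]], stat_per_df[["severe_morbidity"]])
})
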