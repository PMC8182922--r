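test_that("identical estimates pool to themselves with zero between-variance", {
  out <- rubin_pool(rep(0.2, 5), rep(1e-4, 5), scale = "raw")
  expect_equal(out$estimate, 0.2)
  expect_equal(out$B, 0)
  expect_equal(out$T, out$W)
  expect_true(out$ci[1] <= 0.2 && 0.2 <= out$ci[2])
})

test_that("pooling agrees with a straight-line implementation of the Rubin formulas", {
  est <- c(0.18, 0.20, 0.22)
  v <- rep(1e-4, 3)
  got <- rubin_pool(est, v, df_com = 999)

  # independent re-implementation, logit scale
  m <- 3
  q <- log(est / (1 - est))
  u <- v / (est * (1 - est))^2
  qbar <- sum(q) / m
  W <- sum(u) / m
  B <- sum((q - qbar)^2) / (m - 1)
  Tv <- W + (1 + 1 / m) * B
  r <- (1 + 1 / m) * B / W
  df_old <- (m - 1) * (1 + 1 / r)^2
  lambda <- (1 + 1 / m) * B / Tv
  df_obs <- (999 + 1) / (999 + 3) * 999 * (1 - lambda)
  df <- df_old * df_obs / (df_old + df_obs)
  est_pool <- exp(qbar) / (1 + exp(qbar))
  half <- qt(0.975, df) * sqrt(Tv)
  ci <- exp(qbar + c(-half, half)) / (1 + exp(qbar + c(-half, half)))

  expect_equal(got$estimate, est_pool, tolerance = 1e-12)
  expect_equal(got$W, W, tolerance = 1e-12)
  expect_equal(got$B, B, tolerance = 1e-12)
  expect_equal(got$T, Tv, tolerance = 1e-12)
  expect_equal(got$df, df, tolerance = 1e-12)
  expect_equal(got$ci, ci, tolerance = 1e-12)
})

test_that("pooled intervals achieve ~95% coverage on a proper-imputation simulation", {
  set.seed(500)
  q_true <- 0.2
  n <- 400
  m <- 10
  covered <- replicate(1000, {
    y <- rbinom(n, 1, q_true)
    miss <- rbinom(n, 1, 0.4) == 1
    y_obs <- y[!miss]
    X <- matrix(1, length(y_obs), 1)
    Xn <- matrix(1, sum(miss), 1)
    est <- numeric(m)
    v <- numeric(m)
    for (j in seq_len(m)) {
      yj <- y
      yj[miss] <- impute_binary_logit(y_obs, X, Xn)
      p <- mean(yj)
      est[j] <- p
      v[j] <- p * (1 - p) / n
    }
    ci <- rubin_pool(est, v, df_com = n - 1)$ci
    ci[1] <= q_true && q_true <= ci[2]
  })
  expect_equal(mean(covered), 0.95, tolerance = 0.02 / 0.95)
})

test_that("boundary estimates receive a continuity adjustment", {
  expect_warning(out <- rubin_pool(c(0, 0.01, 0.02), rep(1e-5, 3), n = 99), "continuity")
  expect_true(out$estimate > 0)
})

test_that("crude prevalence and its CI match the reference counts", {
  co <- make_accounting_cohort()
  crude <- crude_prevalence(co)
  expect_equal(round_half_up(100 * crude$estimate, 1), 18.4)
  expect_equal(crude$n, 837L)
  expect_equal(round_half_up(100 * crude$ci, 1), c(15.9, 21.2))
  by_region <- crude_prevalence(co, by = "region")
  expect_equal(round_half_up(100 * by_region$PT$estimate, 1), 16.5)
  expect_equal(round_half_up(100 * by_region$UK$estimate, 1), 20.0)

  tiny <- co[co$followed_up == 1 & !is.na(co$impaired_observed), ][1:100, ]
  tiny$impaired_observed <- c(rep(1L, 50), rep(0L, 50))
  expect_equal(crude_prevalence(tiny)$estimate, 0.5)
  none <- tiny
  none$impaired_observed <- 0L
  z <- crude_prevalence(none)
  expect_equal(z$estimate, 0)
  expect_equal(z$ci[1], 0)
})

test_that("percent change matches the reference arithmetic", {
  expect_equal(percent_change(20.4, 18.4), 10.9)
  expect_equal(percent_change(19.4, 18.4), 5.4)
  expect_equal(percent_change(20.0, 18.4), 8.7)
  expect_equal(percent_change(21.9, 20.0), 9.5)
  expect_equal(percent_change(17.3, 17.3), 0)
  expect_error(percent_change(10, 0), "undefined")
})

test_that("pooled point estimate stays inside the per-imputation range", {
  set.seed(501)
  for (i in 1:20) {
    est <- runif(8, 0.1, 0.4)
    v <- runif(8, 1e-5, 1e-3)
    out <- rubin_pool(est, v)
    expect_gte(out$estimate, min(est))
    expect_lte(out$estimate, max(est))
  }
})

test_that("subgroup estimates behave at the edges and mix to the total", {
  co <- make_cohort(n = 1500, seed = 26)
  imp <- run_mice(co, mice_config(m = 10, n_iterations = 4, seed = 13))
  sub <- subgroup_estimates(imp)
  tot <- mi_prevalence(imp)
  n_resp <- sum(co$followed_up == 1)
  n_non <- sum(co$followed_up == 0)
  mix <- (n_resp * sub$responders$estimate + n_non * sub$non_responders$estimate) /
    (n_resp + n_non)
  expect_lt(abs(mix - tot$estimate), 0.002)

  all_resp <- co
  all_resp$followed_up <- 1L
  imp2 <- run_mice(all_resp, mice_config(m = 3, n_iterations = 2, seed = 14))
  sub2 <- subgroup_estimates(imp2)
  expect_true(is.na(sub2$non_responders$estimate))
})
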