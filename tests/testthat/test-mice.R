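test_that("intercept-only binary imputation reproduces the observed prevalence", {
  set.seed(300)
  p_target <- 0.3
  y <- rbinom(50000, 1, p_target)
  p_obs <- mean(y)
  X <- matrix(1, length(y), 1)
  Xn <- matrix(1, 200000, 1)
  set.seed(301)
  imp <- impute_binary_logit(y, X, Xn, delta = 0)
  # Monte-Carlo SE: Bernoulli draws plus the single posterior intercept
  # draw shared by every imputed row (which dominates)
  se <- sqrt(p_obs * (1 - p_obs) * (1 / nrow(Xn) + 1 / length(y)))
  expect_lt(abs(mean(imp) - p_obs), 4 * se)
})

test_that("a saturating delta imputes the constant class", {
  set.seed(302)
  y <- rbinom(5000, 1, 0.2)
  X <- matrix(1, length(y), 1)
  Xn <- matrix(1, 1000, 1)
  expect_true(all(impute_binary_logit(y, X, Xn, delta = 50) == 1L))
  expect_true(all(impute_binary_logit(y, X, Xn, delta = -50) == 0L))
})

test_that("delta = log(1.5) shifts the imputed odds by exactly 1.5 (closed-form oracle)", {
  set.seed(303)
  y <- rbinom(50000, 1, 0.184)
  p_obs <- mean(y)
  odds <- p_obs / (1 - p_obs)
  expected <- 1.5 * odds / (1 + 1.5 * odds) # ~0.2527 at p_obs = 0.184
  X <- matrix(1, length(y), 1)
  Xn <- matrix(1, 200000, 1)
  set.seed(304)
  imp <- impute_binary_logit(y, X, Xn, delta = log(1.5))
  se <- sqrt(expected * (1 - expected) * (1 / nrow(Xn) + 1 / length(y)))
  expect_lt(abs(mean(imp) - expected), 4 * se)
})

test_that("single observed class imputes the constant with a warning", {
  y <- rep(1L, 100)
  X <- matrix(1, 100, 1)
  expect_warning(out <- impute_binary_logit(y, X, matrix(1, 50, 1)), "one observed class")
  expect_true(all(out == 1L))
})

test_that("intercept-only multinomial imputation reproduces observed level frequencies", {
  set.seed(305)
  f <- c(a = 0.5, b = 0.3, c = 0.2)
  y <- factor(sample(names(f), 30000, TRUE, f), levels = names(f))
  X <- matrix(1, length(y), 1)
  Xn <- matrix(1, 100000, 1)
  set.seed(306)
  imp <- impute_multinomial(y, X, Xn)
  got <- prop.table(table(imp))
  obs <- prop.table(table(y))
  expect_lt(max(abs(got - obs)), 0.01)

  # balanced three-level case
  set.seed(307)
  yb <- factor(sample(c("a", "b", "c"), 30000, TRUE), levels = c("a", "b", "c"))
  set.seed(308)
  impb <- impute_multinomial(yb, X[seq_along(yb), , drop = FALSE], Xn)
  expect_lt(max(abs(prop.table(table(impb)) - 1 / 3)), 0.01)
})

test_that("single observed multinomial level imputes the constant", {
  y <- factor(rep("a", 40), levels = c("a", "b"))
  X <- matrix(1, 40, 1)
  expect_warning(out <- impute_multinomial(y, X, matrix(1, 10, 1)), "dropped")
  expect_true(all(out == "a"))
})

test_that("engine imputations match an independent direct-draw oracle", {
  # one incomplete binary variable, one binary predictor: aggregate draws
  # over repeated posterior draws and compare the (predictor x value) cells
  set.seed(310)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-1 + 0.9 * x))
  X <- cbind(1, x)
  xnew <- rep(c(0, 1), each = 500)
  Xn <- cbind(1, xnew)
  reps <- 100

  set.seed(311)
  engine <- unlist(lapply(seq_len(reps), function(i) impute_binary_logit(y, X, Xn)))

  # straight-line oracle: glm fit, normal posterior draw, Bernoulli draws
  set.seed(312)
  ref_fit <- stats::glm(y ~ x, family = binomial())
  mu <- coef(ref_fit)
  V <- vcov(ref_fit)
  oracle <- unlist(lapply(seq_len(reps), function(i) {
    b <- MASS::mvrnorm(1, mu, V)
    rbinom(nrow(Xn), 1, plogis(cbind(1, xnew) %*% b))
  }))

  xs <- rep(xnew, times = reps)
  tab <- rbind(
    engine = c(sum(engine[xs == 0]), sum(1 - engine[xs == 0]), sum(engine[xs == 1]), sum(1 - engine[xs == 1])),
    oracle = c(sum(oracle[xs == 0]), sum(1 - oracle[xs == 0]), sum(oracle[xs == 1]), sum(1 - oracle[xs == 1]))
  )
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.001)
})

test_that("a complete table yields m identical copies and reruns are bit-identical", {
  co <- make_cohort(n = 300, seed = 19)
  complete <- co[stats::complete.cases(as.data.frame(co)[c(attr(co, "covariates"), "impaired_observed")]), ]
  cfg <- mice_config(m = 3, n_iterations = 2, seed = 7)
  imp <- run_mice(complete, cfg)
  expect_identical(imp$datasets[[1]], imp$datasets[[2]])
  expect_identical(as.data.frame(imp$datasets[[1]]), as.data.frame(complete))

  cfg2 <- mice_config(m = 4, n_iterations = 3, seed = 77)
  a <- run_mice(co, cfg2)
  b <- run_mice(co, cfg2)
  expect_identical(a$datasets, b$datasets)
  expect_false(identical(
    a$datasets,
    run_mice(co, mice_config(m = 4, n_iterations = 3, seed = 78))$datasets
  ))
})

test_that("observed cells are never changed by imputation", {
  co <- make_cohort(n = 500, seed = 22)
  imp <- run_mice(co, mice_config(m = 3, n_iterations = 3, seed = 5))
  df <- as.data.frame(co)
  for (j in seq_along(imp$datasets)) {
    dj <- imp$datasets[[j]]
    for (v in imp$include) {
      obs <- !is.na(df[[v]])
      expect_identical(dj[[v]][obs], df[[v]][obs])
      expect_false(anyNA(dj[[v]]))
    }
  }
})

test_that("a delta-method run with delta = 0 is bit-identical to the MAR run", {
  co <- make_cohort(n = 600, seed = 23)
  a <- run_mice(co, mice_config(m = 3, n_iterations = 3, seed = 9, delta = 0))
  b <- run_mice(co, mice_config(m = 3, n_iterations = 3, seed = 9))
  expect_identical(a$datasets, b$datasets)
})

test_that("chain means show no monotone trend after burn-in", {
  co <- make_cohort(n = 1200, seed = 24)
  imp <- run_mice(co, mice_config(m = 4, n_iterations = 10, seed = 11))
  tail_iters <- 5:10
  for (v in c("impaired_observed", "deprivation")) {
    avg <- rowMeans(imp$chain_means[v, tail_iters, ])
    slope <- unname(coef(stats::lm(avg ~ seq_along(avg)))[2])
    expect_lt(abs(slope), 0.02)
  }
})

test_that("a variable with 100% missingness is a configuration error", {
  co <- make_cohort(n = 200, seed = 25)
  co$breastfeeding <- NA_integer_
  expect_error(run_mice(co, mice_config(m = 2, n_iterations = 1)), "100%")
})
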