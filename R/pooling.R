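new_pooled_estimate <- function(estimate, ci, W, B, T, df, m, method,
                                subgroup = "total", delta = NA_real_, n = NA_integer_) {
  structure(
    list(
      estimate = estimate, ci = ci, W = W, B = B, T = T, df = df, m = m,
      method = method, subgroup = subgroup, delta = delta, n = n
    ),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "%s%s: %.1f%% [%.1f; %.1f]  (m = %d%s)\n",
    x$method,
    if (!identical(x$subgroup, "total")) paste0(" / ", x$subgroup) else "",
    100 * x$estimate, 100 * x$ci[1], 100 * x$ci[2], x$m,
    if (!is.na(x$delta) && x$delta != 0) sprintf(", delta = %.2f", x$delta) else ""
  ))
  invisible(x)
}

#' Pool per-imputation proportions by Rubin's rules
#'
#' Pooling is done on the logit scale: each per-imputation proportion and
#' its variance are transformed (delta method), the pooled mean, within-
#' imputation variance W, between-imputation variance B and total variance
#' T = W + (1 + 1/m) B are formed there, the confidence interval uses a t
#' quantile with Barnard-Rubin degrees of freedom (reducing to the classical
#' Rubin df when `df_com = Inf`), and the result is back-transformed. This
#' keeps intervals inside \[0, 1\].
#'
#' Estimates exactly 0 or 1 cannot be logit-transformed; they receive a
#' continuity adjustment of 0.5/(n + 1) (with a warning), using `n` when
#' supplied and 10^4 otherwise.
#'
#' @param estimates numeric vector of m proportions.
#' @param variances numeric vector of m variances (proportion scale).
#' @param df_com complete-data degrees of freedom for the Barnard-Rubin
#'   small-sample correction (`Inf` disables it).
#' @param scale `"logit"` (default) or `"raw"` to pool on the proportion
#'   scale for comparison.
#' @param method,subgroup,delta,n provenance labels carried into the result.
#' @return a `pooled_estimate` with the point estimate, W, B, T, df, and the
#'   95% confidence interval.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf, scale = c("logit", "raw"),
                       method = "MI", subgroup = "total", delta = NA_real_,
                       n = NA_integer_) {
  scale <- match.arg(scale)
  m <- length(estimates)
  if (m < 2) stop_cfg("Rubin pooling needs m >= 2 estimates")
  if (length(variances) != m) stop_cfg("'variances' must match 'estimates' in length")
  if (any(variances < 0)) stop_cfg("variances must be non-negative")
  if (any(estimates <= 0 | estimates >= 1)) {
    adj <- 0.5 / ((if (is.na(n)) 1e4 else n) + 1)
    warning("estimate at the boundary; applying continuity adjustment ", signif(adj, 3))
    estimates <- pmin(pmax(estimates, adj), 1 - adj)
    variances <- pmax(variances, adj * (1 - adj) / (if (is.na(n)) 1e4 else n))
  }
  if (scale == "logit") {
    q <- logit(estimates)
    u <- variances / (estimates * (1 - estimates))^2
  } else {
    q <- estimates
    u <- variances
  }
  qbar <- mean(q)
  W <- mean(u)
  B <- stats::var(q)
  T <- W + (1 + 1 / m) * B
  if (B > 0 && W > 0) {
    r <- (1 + 1 / m) * B / W
    df_old <- (m - 1) * (1 + 1 / r)^2
    lambda <- (1 + 1 / m) * B / T
    if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  } else {
    df <- Inf
  }
  tcrit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  half <- tcrit * sqrt(T)
  if (scale == "logit") {
    est <- inv_logit(qbar)
    ci <- inv_logit(c(qbar - half, qbar + half))
  } else {
    est <- qbar
    ci <- pmin(pmax(c(qbar - half, qbar + half), 0), 1)
  }
  new_pooled_estimate(est, ci, W, B, T, df, m, method,
    subgroup = subgroup, delta = delta, n = n
  )
}

# logit-scale Wald interval for a single proportion x/n
prevalence_ci <- function(x, n, level = 0.95) {
  if (n == 0) stop_cfg("zero denominator in prevalence")
  p <- x / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  alpha <- 1 - level
  if (x == 0) {
    return(c(0, 1 - (alpha / 2)^(1 / n))) # Clopper-Pearson bound at the boundary
  }
  if (x == n) {
    return(c((alpha / 2)^(1 / n), 1))
  }
  se <- sqrt(1 / x + 1 / (n - x))
  inv_logit(logit(p) + c(-z, z) * se)
}

#' Crude prevalence among responders with an observed outcome
#'
#' The uncorrected estimate: the proportion impaired among children who
#' were followed up and have a derived outcome, with a logit-scale Wald 95%
#' confidence interval (the same interval family the pooled estimates use).
#'
#' @param table a `cohort` data frame with `impaired_observed` derived.
#' @param by optional column name (e.g. `"region"`) for stratified crude
#'   estimates; returns a named list in that case.
#' @return a `pooled_estimate` with `m = 1` (between-imputation variance
#'   undefined).
#' @export
crude_prevalence <- function(table, by = NULL) {
  if (!"impaired_observed" %in% names(table)) {
    stop_cfg("derive the outcome first (see derive_outcomes())")
  }
  if (!is.null(by)) {
    groups <- levels(factor(table[[by]]))
    out <- lapply(groups, function(g) {
      crude_prevalence(table[table[[by]] == g, , drop = FALSE])
    })
    names(out) <- groups
    return(out)
  }
  obs <- table$followed_up == 1 & !is.na(table$impaired_observed)
  n <- sum(obs)
  if (n == 0) stop_cfg("no responder has an observed outcome")
  x <- sum(table$impaired_observed[obs] == 1)
  p <- x / n
  v <- p * (1 - p) / n
  new_pooled_estimate(
    p, prevalence_ci(x, n),
    W = v, B = NA_real_, T = v, df = Inf, m = 1L,
    method = "Crude", n = n
  )
}

#' Relative change of a corrected prevalence against the crude one
#'
#' `(corrected - crude) / crude * 100`, the "% change in prevalence" figure
#' of the report tables, rendered to 1 decimal (half-up).
#'
#' @param corrected,crude prevalences in percent (or both as proportions).
#' @return percent change, 1-decimal.
#' @export
percent_change <- function(corrected, crude) {
  if (any(crude == 0)) stop_cfg("percent change undefined for a crude prevalence of 0")
  round_half_up(100 * (corrected - crude) / crude, 1)
}

# prevalence + binomial variance within a completed dataset subset
completed_prevalence <- function(df, rows) {
  n <- sum(rows)
  p <- mean(df$impaired_observed[rows] == 1)
  c(p = p, v = p * (1 - p) / n, n = n)
}

#' Pooled prevalence from an imputed cohort
#'
#' Per completed dataset, the prevalence over all children (each child now
#' has an observed or imputed outcome) with its binomial variance; pooled
#' by [rubin_pool()] with Barnard-Rubin degrees of freedom.
#'
#' @param imputed an `imputed_cohort` from [run_mice()].
#' @param by optional stratification column (e.g. `"region"`); returns a
#'   named list of `pooled_estimate`s.
#' @param method label carried into the result.
#' @return a `pooled_estimate`, or a named list of them when `by` is given.
#' @export
mi_prevalence <- function(imputed, by = NULL, method = "MI") {
  stopifnot(inherits(imputed, "imputed_cohort"))
  d1 <- imputed$datasets[[1]]
  if (!is.null(by)) {
    groups <- levels(factor(d1[[by]]))
    out <- lapply(groups, function(g) {
      pool_over_datasets(imputed, d1[[by]] == g,
        method = method, subgroup = g
      )
    })
    names(out) <- groups
    return(out)
  }
  pool_over_datasets(imputed, rep(TRUE, nrow(d1)), method = method)
}

pool_over_datasets <- function(imputed, rows, method, subgroup = "total") {
  if (!sum(rows)) {
    return(new_pooled_estimate(
      NA_real_, c(NA_real_, NA_real_), NA_real_, NA_real_, NA_real_,
      NA_real_, imputed$config$m, method,
      subgroup = subgroup, n = 0L
    ))
  }
  pv <- vapply(
    imputed$datasets, completed_prevalence,
    numeric(3),
    rows = rows
  )
  rubin_pool(pv["p", ], pv["v", ],
    df_com = pv["n", 1] - 1,
    method = method, subgroup = subgroup,
    delta = imputed$config$delta, n = as.integer(pv["n", 1])
  )
}

#' Pooled prevalence within responder and non-responder strata
#'
#' The non-responder estimate rests entirely on imputed outcomes; under a
#' correctly specified MAR imputation model it estimates what follow-up
#' would have shown for the children who were lost.
#'
#' @param imputed an `imputed_cohort` whose outcome was imputed.
#' @return list with `responders` and `non_responders` `pooled_estimate`s
#'   (an empty stratum yields an all-`NA` flagged row).
#' @export
subgroup_estimates <- function(imputed) {
  d1 <- imputed$datasets[[1]]
  list(
    responders = pool_over_datasets(
      imputed, d1$followed_up == 1,
      method = "MI", subgroup = "responders"
    ),
    non_responders = pool_over_datasets(
      imputed, d1$followed_up == 0,
      method = "MI", subgroup = "non-responders"
    )
  )
}
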