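#' Configuration for inverse-probability-of-follow-up weighting
#'
#' @param screening_alpha p-value threshold for retaining a candidate
#'   predictor of follow-up (default 0.2; deliberately liberal so variables
#'   associated with follow-up only conditionally on others can enter).
#' @param weight_truncation optional percentile in (50, 100\]: weights above
#'   that percentile are capped (default none).
#' @param variance_method `"sandwich"` (robust, weights treated as known;
#'   default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (bootstrap variance only).
#' @param seed seed for the bootstrap.
#' @return an object of class `ipw_config`.
#' @export
ipw_config <- function(screening_alpha = 0.2, weight_truncation = NULL,
                       variance_method = c("sandwich", "bootstrap"),
                       n_boot = 200, seed = 1L) {
  if (screening_alpha <= 0 || screening_alpha > 1) {
    stop_cfg("'screening_alpha' must lie in (0, 1]")
  }
  if (!is.null(weight_truncation) &&
    (weight_truncation <= 50 || weight_truncation > 100)) {
    stop_cfg("'weight_truncation' must be a percentile in (50, 100]")
  }
  structure(
    list(
      screening_alpha = screening_alpha,
      weight_truncation = weight_truncation,
      variance_method = match.arg(variance_method),
      n_boot = n_boot, seed = as.integer(seed)
    ),
    class = "ipw_config"
  )
}

#' Screen candidate predictors of follow-up
#'
#' Retains every candidate whose region-adjusted bivariate association with
#' the follow-up indicator (the [association_scan()] machinery) has
#' p <= `alpha`. Region is always retained. An empty retained set falls back
#' to a region-only response model with a warning. Factors whose test
#' separated (p unavailable) are retained, since separation indicates an
#' extreme association with follow-up.
#'
#' @param table a `cohort` data frame.
#' @param candidates character vector of candidate columns (defaults to all
#'   baseline covariates).
#' @param alpha retention threshold (default 0.2).
#' @return character vector of retained predictors, `"region"` first, with
#'   the scan attached as attribute `"scan"`.
#' @export
screen_predictors <- function(table, candidates = NULL, alpha = 0.2) {
  candidates <- candidates %||% setdiff(cohort_covariates(table), "region")
  scan <- association_scan(table, target = "followup", factors = candidates)
  keep <- scan$factor[(!is.na(scan$p_value) & scan$p_value <= alpha) | scan$separation]
  if (!length(keep)) {
    warning("no candidate met the screening threshold; using a region-only response model")
  }
  out <- c("region", keep)
  attr(out, "scan") <- scan
  out
}

#' Fit inverse-probability-of-follow-up weights
#'
#' Maximum-likelihood logistic regression of the follow-up indicator on the
#' retained predictors over rows complete on those predictors (the
#' complete-case variant); each responder's weight is the reciprocal of its
#' fitted response probability, so the weighted responders stand for the
#' full eligible cohort.
#'
#' @param table a `cohort` data frame.
#' @param retained character vector of predictors (from
#'   [screen_predictors()]); defaults to screening with `config`'s alpha.
#' @param config an [ipw_config()].
#' @return an object of class `weight_set`: responder weights (named by
#'   `child_id`), the fitted model, and diagnostics (min/max weight,
#'   effective sample size `(sum w)^2 / sum w^2`, model rows).
#' @export
fit_weights <- function(table, retained = NULL, config = ipw_config()) {
  retained <- retained %||% screen_predictors(table, alpha = config$screening_alpha)
  retained <- unique(c("region", retained))
  complete <- !Reduce(`|`, lapply(table[retained], is.na))
  sub <- table[complete, , drop = FALSE]
  if (all(sub$followed_up == 1)) {
    # no non-response: the response probability MLE is 1 everywhere
    return(structure(
      list(
        weights = stats::setNames(rep(1, nrow(sub)), sub$child_id),
        fit = NULL, retained = retained,
        n_model = nrow(sub), n_eligible = nrow(table),
        diagnostics = list(
          min_weight = 1, max_weight = 1, sum_weights = nrow(sub),
          effective_sample_size = nrow(sub),
          n_responders = nrow(sub), n_model = nrow(sub)
        )
      ),
      class = "weight_set"
    ))
  }
  blocks <- lapply(retained, function(v) {
    x <- sub[[v]]
    if (is.factor(x)) x <- droplevels(x)
    encode_var(x)
  })
  X <- cbind(1, do.call(cbind, blocks))
  fit <- fit_logit(X, sub$followed_up)
  if (fit$separated) {
    warning("response model separated; ridge-stabilized fit used")
  }
  phat <- inv_logit(logit_lp(fit, X))
  if (any(phat[sub$followed_up == 1] < 1e-6)) {
    warning("fitted follow-up probability below 1e-6; very large weights")
  }
  resp <- sub$followed_up == 1
  w <- 1 / phat[resp]
  if (!is.null(config$weight_truncation)) {
    cap <- stats::quantile(w, config$weight_truncation / 100)
    w <- pmin(w, cap)
  }
  structure(
    list(
      weights = stats::setNames(w, sub$child_id[resp]),
      fit = fit, retained = retained,
      n_model = nrow(sub), n_eligible = nrow(table),
      diagnostics = list(
        min_weight = min(w), max_weight = max(w),
        sum_weights = sum(w),
        effective_sample_size = sum(w)^2 / sum(w^2),
        n_responders = sum(resp), n_model = nrow(sub)
      )
    ),
    class = "weight_set"
  )
}

#' @export
print.weight_set <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "IPW response model: %d predictors, %d rows\nweights: n = %d, range [%.2f, %.2f], sum = %.1f, ESS = %.1f\n",
    length(x$retained), d$n_model, d$n_responders, d$min_weight, d$max_weight,
    d$sum_weights, d$effective_sample_size
  ))
  invisible(x)
}

#' Inverse-probability-weighted prevalence
#'
#' The Horvitz-Thompson-style weighted mean of the outcome over responders
#' with an observed outcome: `sum(w y) / sum(w)`. Responders whose outcome
#' is missing are excluded (their weight addresses loss to follow-up, not
#' item missingness). The robust (sandwich) standard error treats the
#' weights as fixed; the 95% interval is formed on the logit scale.
#'
#' @param table a `cohort` data frame with the outcome derived.
#' @param weights a `weight_set` from [fit_weights()].
#' @param config an [ipw_config()] (variance method).
#' @param by optional stratification column (e.g. `"region"`).
#' @param method label for the result.
#' @return a `pooled_estimate` with `m = 1`.
#' @export
weighted_prevalence <- function(table, weights, config = ipw_config(),
                                by = NULL, method = "IPW complete cases") {
  if (!is.null(by)) {
    groups <- levels(factor(table[[by]]))
    out <- lapply(groups, function(g) {
      weighted_prevalence(table[table[[by]] == g, , drop = FALSE],
        weights, config,
        method = method
      )
    })
    names(out) <- groups
    return(out)
  }
  w_all <- weights$weights[match(table$child_id, names(weights$weights))]
  use <- !is.na(w_all) & table$followed_up == 1 & !is.na(table$impaired_observed)
  w <- w_all[use]
  y <- table$impaired_observed[use]
  if (!length(w) || sum(w)^2 / sum(w^2) < 1) stop_cfg("zero effective sample for weighted prevalence")
  est <- sum(w * y) / sum(w)
  v <- sum(w^2 * (y - est)^2) / sum(w)^2
  if (identical(config$variance_method, "bootstrap")) {
    set.seed(substream_seed(config$seed, "ipw-boot"))
    bstar <- replicate(config$n_boot, {
      i <- sample.int(length(w), replace = TRUE)
      sum(w[i] * y[i]) / sum(w[i])
    })
    v <- stats::var(bstar)
  }
  vl <- v / (est * (1 - est))^2
  ci <- inv_logit(logit(est) + c(-1, 1) * stats::qnorm(0.975) * sqrt(vl))
  new_pooled_estimate(
    est, ci,
    W = v, B = NA_real_, T = v, df = Inf, m = 1L,
    method = method, n = length(w)
  )
}

#' IPW with imputed predictors
#'
#' The second IPW variant: missing values on the *predictors* are multiply
#' imputed (the outcome is excluded from the imputation and stays
#' observed/missing as-is), the screen-fit-weight pipeline runs on each
#' completed dataset, and the m weighted prevalences are combined by
#' Rubin's rules. Recovers the rows a complete-case response model drops.
#'
#' @param table a `cohort` data frame with the outcome derived.
#' @param mice_cfg a [mice_config()] for the covariate imputation.
#' @param config an [ipw_config()].
#' @param by optional stratification column.
#' @param imputed optionally, a precomputed covariates-only
#'   `imputed_cohort` (skips the internal [run_mice()] call).
#' @return a `pooled_estimate` (or named list when `by` is given).
#' @export
ipw_on_imputed <- function(table, mice_cfg = mice_config(m = 20),
                           config = ipw_config(), by = NULL, imputed = NULL) {
  if (is.null(imputed)) {
    covs <- cohort_covariates(table)
    incomplete <- covs[vapply(as.data.frame(table)[covs], anyNA, logical(1))]
    imputed <- run_mice(table, mice_cfg, include = incomplete)
  }
  ests <- lapply(imputed$datasets, function(dfj) {
    dj <- as_cohort(dfj,
      covariates = cohort_covariates(table),
      cov_levels = attr(table, "cov_levels")
    )
    retained <- screen_predictors(dj, alpha = config$screening_alpha)
    ws <- fit_weights(dj, retained, config)
    weighted_prevalence(dj, ws, config, by = by, method = "IPW imputed")
  })
  pool_ipw <- function(lst, subgroup = "total") {
    rubin_pool(
      vapply(lst, function(e) e$estimate, numeric(1)),
      vapply(lst, function(e) e$W, numeric(1)),
      df_com = lst[[1]]$n - 1,
      method = "IPW imputed", subgroup = subgroup, n = lst[[1]]$n
    )
  }
  if (!is.null(by)) {
    groups <- names(ests[[1]])
    out <- lapply(groups, function(g) {
      pool_ipw(lapply(ests, `[[`, g), subgroup = g)
    })
    names(out) <- groups
    return(out)
  }
  pool_ipw(ests)
}
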