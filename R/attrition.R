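#' Loss-to-follow-up and missing-data accounting table
#'
#' Describes attrition overall and per region: numbers and percentages of
#' responders and non-responders, rows with at least one missing baseline
#' covariate (overall and within each response group), outcome missingness
#' among responders, the analyzed fraction (responders with an observed
#' outcome over all survivors) and the complete-case fraction (rows with no
#' missing covariate). Raw counts and unrounded percentages are returned
#' alongside 1-decimal display percentages, which always recompute exactly
#' from the counts.
#'
#' @param table a `cohort` data frame (outcome columns derived if available).
#' @return a data frame of class `attrition_report`, one row per scope
#'   (`Total` plus each region).
#' @export
attrition_table <- function(table) {
  if (anyNA(table$followed_up)) stop_cfg("'followed_up' must be observed for all rows")
  covs <- intersect(cohort_covariates(table), names(table))
  scopes <- c("Total", levels(factor(table$region)))
  rows <- lapply(scopes, function(sc) {
    idx <- if (sc == "Total") rep(TRUE, nrow(table)) else table$region == sc
    sub <- table[idx, , drop = FALSE]
    n <- nrow(sub)
    resp <- sub$followed_up == 1
    miss_cov <- if (length(covs)) rowSums(is.na(sub[covs])) > 0 else rep(FALSE, n)
    miss_out <- resp & is.na(sub$impaired_observed %||% rep(NA, n))
    analyzed <- resp & !is.na(sub$impaired_observed %||% rep(NA, n))
    data.frame(
      scope = sc,
      n = n,
      n_responders = sum(resp),
      pct_responders = fmt_pct(sum(resp), n),
      n_nonresponders = sum(!resp),
      pct_nonresponders = fmt_pct(sum(!resp), n),
      n_missing_covariate = sum(miss_cov),
      pct_missing_covariate = fmt_pct(sum(miss_cov), n),
      n_missing_covariate_responders = sum(miss_cov & resp),
      pct_missing_covariate_responders = fmt_pct(sum(miss_cov & resp), sum(resp)),
      n_missing_covariate_nonresponders = sum(miss_cov & !resp),
      pct_missing_covariate_nonresponders = fmt_pct(sum(miss_cov & !resp), sum(!resp)),
      n_missing_outcome_responders = sum(miss_out),
      pct_missing_outcome_responders = fmt_pct(sum(miss_out), sum(resp)),
      n_analyzed = sum(analyzed),
      pct_analyzed = fmt_pct(sum(analyzed), n),
      n_complete_case = sum(!miss_cov),
      pct_complete_case = fmt_pct(sum(!miss_cov), n),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("attrition_report", "data.frame")
  out
}

#' Region-adjusted association of each factor with follow-up or the outcome
#'
#' For each baseline factor, fits a maximum-likelihood logistic regression
#' of the target indicator (follow-up, or the derived impairment among
#' children with an observed outcome) on the factor's dummies plus region
#' dummies, and reports a Wald block test of the factor's coefficients.
#' Rows missing the factor are dropped per factor (the missing category is
#' never part of the test). With a single region the adjustment is skipped
#' with a warning. Complete separation is reported as a flagged row with a
#' missing p-value, not an error. A likelihood-ratio block test is
#' available via `test = "lr"`.
#'
#' @param table a `cohort` data frame.
#' @param target `"followup"` or `"outcome"`.
#' @param factors character vector of factor columns (defaults to all
#'   baseline covariates).
#' @param test `"wald"` (default) or `"lr"`.
#' @return data frame of class `association_scan`, one row per factor
#'   (factor, df, statistic, p_value, n, separation), with per-level
#'   count/percent tables by target group in the `"level_tables"` attribute.
#' @export
association_scan <- function(table, target = c("followup", "outcome"),
                             factors = NULL, test = c("wald", "lr")) {
  target <- match.arg(target)
  test <- match.arg(test)
  factors <- factors %||% setdiff(cohort_covariates(table), "region")
  y_all <- if (target == "followup") {
    table$followed_up
  } else {
    ifelse(table$followed_up == 1, table$impaired_observed, NA)
  }
  region <- factor(table$region)
  adjust_region <- nlevels(droplevels(region[!is.na(y_all)])) >= 2
  if (!adjust_region) {
    warning("fewer than 2 regions observed; association scan is unadjusted")
  }
  rows <- list()
  level_tables <- list()
  for (f in factors) {
    x <- table[[f]]
    use <- !is.na(x) & !is.na(y_all)
    y <- y_all[use]
    xf <- droplevels(factor(x[use]))
    rg <- droplevels(region[use])
    lt <- make_level_table(xf, y)
    level_tables[[f]] <- lt
    if (nlevels(xf) < 2 || length(unique(y)) < 2) {
      rows[[f]] <- data.frame(
        factor = f, df = NA_integer_, statistic = NA_real_,
        p_value = NA_real_, n = sum(use), separation = FALSE
      )
      next
    }
    Xf <- encode_var(xf)
    Xr <- if (adjust_region && nlevels(rg) >= 2) encode_var(rg) else NULL
    X <- cbind(1, Xf, Xr)
    block <- 1 + seq_len(ncol(Xf))
    fit <- fit_logit(X, y)
    sep <- fit$separated
    kept_block <- match(intersect(block, fit$keep), fit$keep)
    dfree <- length(kept_block)
    if (sep || dfree == 0) {
      rows[[f]] <- data.frame(
        factor = f, df = dfree, statistic = NA_real_,
        p_value = NA_real_, n = sum(use), separation = TRUE
      )
      next
    }
    if (test == "wald") {
      b <- fit$coef[kept_block]
      V <- fit$vcov[kept_block, kept_block, drop = FALSE]
      stat <- drop(t(b) %*% solve(V, b))
    } else {
      stat <- lr_block_stat(X, y, block)
    }
    rows[[f]] <- data.frame(
      factor = f, df = dfree, statistic = stat,
      p_value = stats::pchisq(stat, dfree, lower.tail = FALSE),
      n = sum(use), separation = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "level_tables") <- level_tables
  class(out) <- c("association_scan", "data.frame")
  out
}

make_level_table <- function(xf, y) {
  tab <- table(level = xf, group = factor(y, levels = c(0, 1)))
  pct <- prop.table(tab, margin = 2) * 100
  data.frame(
    level = rownames(tab),
    n_group0 = as.integer(tab[, 1]), pct_group0 = round_half_up(pct[, 1], 1),
    n_group1 = as.integer(tab[, 2]), pct_group1 = round_half_up(pct[, 2], 1),
    row.names = NULL
  )
}

lr_block_stat <- function(X, y, block) {
  fit_full <- suppressWarnings(stats::glm.fit(
    X[, full_rank_cols(X), drop = FALSE], y,
    family = stats::binomial()
  ))
  X0 <- X[, -block, drop = FALSE]
  fit_null <- suppressWarnings(stats::glm.fit(
    X0[, full_rank_cols(X0), drop = FALSE], y,
    family = stats::binomial()
  ))
  fit_null$deviance - fit_full$deviance
}
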