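#' Configuration for multiple imputation by chained equations
#'
#' @param m number of imputations (study default 100; tests and quick runs
#'   use 10-20).
#' @param n_iterations chained-equation cycles per imputation (default 15).
#' @param seed integer seed; the m imputation chains draw from independent
#'   substreams derived from it.
#' @param delta log-odds offset added to the *outcome's* imputation linear
#'   predictor before drawing imputed values. 0 imputes under missing at
#'   random; `delta = log(k)` multiplies the imputation-model odds of the
#'   outcome for children with missing outcomes by `k` (the delta /
#'   pattern-mixture MNAR sensitivity device). All other variables are always
#'   imputed with offset 0.
#' @param method_map optional named character vector mapping variables to an
#'   imputation method among `"logreg"` (binary posterior-draw logistic),
#'   `"polyreg"` (multinomial), `"pmm"` (predictive mean matching, 5
#'   donors). Unlisted variables get a method from their type.
#' @param predictor_matrix optional named list mapping each imputed variable
#'   to the character vector of its predictors (never including itself).
#' @return an object of class `mice_config`.
#' @export
mice_config <- function(m = 100, n_iterations = 15, seed = 1L, delta = 0,
                        method_map = NULL, predictor_matrix = NULL) {
  if (m < 2) stop_cfg("'m' must be at least 2")
  if (n_iterations < 1) stop_cfg("'n_iterations' must be at least 1")
  if (!is.finite(delta)) stop_cfg("'delta' must be finite")
  if (!is.null(predictor_matrix)) {
    self <- names(predictor_matrix)[mapply(
      function(v, p) v %in% p, names(predictor_matrix), predictor_matrix
    )]
    if (length(self)) stop_cfg("variable(s) predicting themselves: ", paste(self, collapse = ", "))
  }
  structure(
    list(
      m = as.integer(m), n_iterations = as.integer(n_iterations),
      seed = as.integer(seed), delta = delta,
      method_map = method_map, predictor_matrix = predictor_matrix
    ),
    class = "mice_config"
  )
}

#' Posterior-draw logistic imputation of a binary variable
#'
#' One conditional-model step of the chained-equations engine, exposed
#' directly: (1) maximum-likelihood logistic regression of the variable on
#' the predictors over the observed rows; (2) a coefficient vector drawn
#' from the asymptotic normal approximation of its posterior (mean = MLE,
#' covariance = inverse observed information); (3) the linear predictor for
#' the missing rows, plus `delta`; (4) each imputed value drawn
#' Bernoulli(plogis(lp + delta)).
#'
#' With `delta = log(k)` the imputation-model odds of a 1 for the imputed
#' rows are multiplied by `k` relative to imputation under MAR.
#'
#' Degenerate cases: if only one outcome class is observed the constant
#' class is imputed with a warning; if the fit separates, a
#' ridge-stabilized fit (penalty 1e-4) is used and flagged via the
#' `"separated"` attribute.
#'
#' @param y binary 0/1 vector of observed values.
#' @param X numeric design matrix for the observed rows (include an
#'   intercept column).
#' @param X_new design matrix for the rows to impute (same columns).
#' @param delta log-odds offset (default 0 = MAR).
#' @param start optional warm-start coefficients.
#' @param keep optional cached full-rank column subset (advanced; skips the
#'   rank-revealing QR).
#' @return integer vector of imputed 0/1 values with attributes `"prob"`
#'   (the drawn Bernoulli probabilities), `"coef"` (the posterior draw) and
#'   `"separated"`.
#' @export
impute_binary_logit <- function(y, X, X_new, delta = 0, start = NULL, keep = NULL) {
  y <- as.integer(y)
  n_new <- nrow(X_new)
  cls <- unique(y)
  if (length(cls) < 2) {
    warning("only one observed class; imputing the constant class")
    out <- rep(cls, n_new)
    attr(out, "prob") <- rep(as.numeric(cls), n_new)
    attr(out, "separated") <- FALSE
    return(out)
  }
  fit <- fit_logit(X, y, start = start, keep = keep)
  b <- draw_mvn(fit$coef, fit$vcov)
  p <- inv_logit(logit_lp(fit, X_new, coef = b) + delta)
  out <- as.integer(stats::runif(n_new) < p)
  attr(out, "prob") <- p
  attr(out, "coef") <- b
  attr(out, "mle") <- fit
  attr(out, "separated") <- fit$separated
  out
}

#' Posterior-draw multinomial imputation of a categorical variable
#'
#' The >= 3-level analogue of [impute_binary_logit()]: a multinomial-logit
#' MLE over the observed rows, a draw of the stacked coefficient vector from
#' its asymptotic normal posterior, and category draws from the resulting
#' class probabilities. No delta offset applies. Levels never observed are
#' dropped from the model and are never imputed (with a warning).
#'
#' @param y factor of observed values.
#' @param X,X_new design matrices as in [impute_binary_logit()].
#' @param start optional warm-start coefficient matrix.
#' @param keep optional cached full-rank column subset (advanced).
#' @return factor of imputed values (levels of `y`), with attributes
#'   `"prob"` (matrix of drawn class probabilities) and `"mle"`.
#' @export
impute_multinomial <- function(y, X, X_new, start = NULL, keep = NULL) {
  y <- droplevels_keep(y)
  n_new <- nrow(X_new)
  fit <- fit_multinom(X, y, init = start, keep = keep)
  if (fit$degenerate) {
    out <- factor(rep(fit$levels, n_new), levels = levels(y))
    return(out)
  }
  Bv <- draw_mvn(as.vector(fit$coef), fit$vcov)
  B <- matrix(Bv, nrow(fit$coef), ncol(fit$coef))
  P <- multinom_probs(fit, X_new, B = B)
  C <- P
  for (k in seq_len(ncol(P))[-1]) C[, k] <- C[, k - 1] + P[, k]
  u <- stats::runif(n_new)
  idx <- rowSums(u > C[, -ncol(C), drop = FALSE]) + 1L
  out <- factor(fit$levels[idx], levels = levels(y))
  attr(out, "prob") <- P
  attr(out, "mle") <- fit
  out
}

droplevels_keep <- function(y) factor(y, levels = levels(y))

#' Predictive mean matching imputation (5 donors)
#'
#' Compatibility method for continuous variables: Bayesian linear regression
#' draw (sigma^2 from the scaled inverse chi-square, coefficients from the
#' normal posterior), type-1 matching of each missing row's predicted value
#' to the `donors` nearest observed predictions, and a uniform draw among
#' the donors' observed values.
#'
#' @param y numeric observed values.
#' @param X,X_new design matrices as in [impute_binary_logit()].
#' @param donors number of candidate donors (default 5).
#' @return numeric vector of imputed values.
#' @export
impute_pmm <- function(y, X, X_new, donors = 5) {
  keep <- full_rank_cols(X)
  Xk <- X[, keep, drop = FALSE]
  XtX <- crossprod(Xk)
  XtXi <- solve(XtX + diag(1e-10, ncol(Xk)))
  beta <- drop(XtXi %*% crossprod(Xk, y))
  res <- y - drop(Xk %*% beta)
  df <- max(length(y) - ncol(Xk), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- draw_mvn(beta, sigma2 * XtXi)
  yhat_obs <- drop(Xk %*% beta) # MLE predictions for donors
  yhat_mis <- drop(X_new[, keep, drop = FALSE] %*% beta_star)
  vapply(yhat_mis, function(v) {
    d <- abs(yhat_obs - v)
    cand <- order(d)[seq_len(min(donors, length(d)))]
    y[cand[sample.int(length(cand), 1)]]
  }, numeric(1))
}

default_method <- function(x) {
  if (is.factor(x)) {
    if (nlevels(x) > 2) "polyreg" else "logreg"
  } else if (is_binary01(x)) {
    "logreg"
  } else {
    "pmm"
  }
}

#' Multiple imputation by chained equations
#'
#' Imputes the incomplete modeled variables of a cohort table m times.
#' Missing values are initialized by random draws from the observed margins;
#' each of `n_iterations` cycles then visits the variables in order of
#' increasing missingness, re-fitting each variable's conditional model on
#' its originally observed rows given the current completed values of its
#' predictors and drawing fresh imputations
#' ([impute_binary_logit()] / [impute_multinomial()] / [impute_pmm()]).
#' The outcome variable's model receives `config$delta` as a log-odds
#' offset; every other variable is imputed with offset 0.
#'
#' By default the modeled variables are every incomplete baseline covariate
#' plus the derived outcome `impaired_observed` (the outcome is imputed
#' directly as a binary variable, for non-responders and for responders with
#' missing questionnaires alike), and each variable's predictors are region,
#' the follow-up indicator, all covariates and the outcome, minus itself.
#'
#' Each (imputation, cycle, variable) step draws from its own seed
#' substream, so the m chains are independent, reruns are bit-identical,
#' and two runs differing only in `delta` share every draw that their
#' inputs share.
#'
#' @param table a `cohort` data frame (with derived outcome columns if the
#'   outcome is to be imputed; see [derive_outcomes()]).
#' @param config a [mice_config()].
#' @param include optional character vector of variables to impute
#'   (overrides the default). An empty vector, or a table with nothing
#'   missing, returns m identical copies of the input.
#' @param predictors optional predictor list (as `config$predictor_matrix`).
#' @param outcome_var name of the outcome column receiving the delta offset.
#' @return an object of class `imputed_cohort`: the m completed datasets,
#'   chain means per (variable, cycle, imputation), and the config used.
#' @seealso [complete_data()], [mi_prevalence()], [run_delta_grid()]
#' @export
run_mice <- function(table, config = mice_config(), include = NULL,
                     predictors = NULL, outcome_var = "impaired_observed") {
  stopifnot(inherits(config, "mice_config"))
  df <- as.data.frame(table)
  covs <- cohort_covariates(table)
  candidates <- intersect(c(covs, outcome_var), names(df))
  if (is.null(include)) {
    include <- candidates[vapply(df[candidates], anyNA, logical(1))]
  }
  all_missing <- include[vapply(df[include], function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop_cfg(
      "variable(s) with 100% missingness cannot be imputed: ",
      paste(all_missing, collapse = ", ")
    )
  }
  m <- config$m
  if (!length(include)) {
    return(structure(
      list(
        datasets = replicate(m, df, simplify = FALSE), chain_means = NULL,
        config = config, include = character(0), original = table
      ),
      class = "imputed_cohort"
    ))
  }

  method <- vapply(include, function(v) {
    config$method_map[[v]] %||% default_method(df[[v]])
  }, character(1))

  if (is.null(predictors)) predictors <- config$predictor_matrix
  if (is.null(predictors)) {
    base_pred <- intersect(
      unique(c("region", "followed_up", covs, outcome_var)),
      names(df)
    )
    # a variable that is incomplete but not being imputed cannot serve as a
    # predictor (it would leave NAs in the design)
    unusable <- setdiff(base_pred[vapply(df[base_pred], anyNA, logical(1))], include)
    base_pred <- setdiff(base_pred, unusable)
    predictors <- lapply(include, function(v) setdiff(base_pred, v))
    names(predictors) <- include
  }

  mis_idx <- lapply(df[include], function(x) which(is.na(x)))
  frac_mis <- vapply(mis_idx, length, integer(1)) / nrow(df)
  visit <- include[order(frac_mis)]
  design_vars <- unique(unlist(predictors))

  n_iter <- config$n_iterations
  chain <- array(
    NA_real_, c(length(include), n_iter, m),
    dimnames = list(include, NULL, NULL)
  )
  datasets <- vector("list", m)
  warm <- new.env(parent = emptyenv())

  for (j in seq_len(m)) {
    dfj <- df
    set.seed(substream_seed(config$seed, "init", j))
    for (v in visit) {
      obs_vals <- df[[v]][!is.na(df[[v]])]
      dfj[[v]][mis_idx[[v]]] <- sample(obs_vals, length(mis_idx[[v]]), TRUE)
    }
    des <- make_design(dfj, design_vars)
    D <- des$D
    colmap <- des$colmap
    for (t in seq_len(n_iter)) {
      for (v in visit) {
        idx <- mis_idx[[v]]
        obs <- which(!is.na(df[[v]]))
        xcols <- c(1L, unlist(colmap[predictors[[v]]], use.names = FALSE))
        X <- D[obs, xcols, drop = FALSE]
        Xn <- D[idx, xcols, drop = FALSE]
        set.seed(substream_seed(config$seed, "imp", j, "it", t, v))
        del <- if (identical(v, outcome_var)) config$delta else 0
        prev <- warm[[v]]
        keep_v <- warm[[paste0(".keep.", v)]]
        newv <- switch(method[[v]],
          logreg = impute_binary_logit(df[[v]][obs], X, Xn,
            delta = del, start = prev, keep = keep_v
          ),
          polyreg = impute_multinomial(
            factor(df[[v]][obs], levels = levels(df[[v]])), X, Xn,
            start = prev, keep = keep_v
          ),
          pmm = impute_pmm(df[[v]][obs], X, Xn),
          stop_cfg("unknown imputation method '", method[[v]], "' for ", v)
        )
        f <- attr(newv, "mle")
        if (!is.null(f) && length(f$keep) == ncol(X)) {
          warm[[paste0(".keep.", v)]] <- f$keep
        }
        if (method[[v]] == "logreg" && !is.null(f)) {
          b <- rep(0, f$p)
          b[f$keep] <- f$coef
          warm[[v]] <- b
        } else if (method[[v]] == "polyreg" && !is.null(f) &&
          !f$degenerate && length(f$keep) == ncol(X)) {
          warm[[v]] <- f$coef
        }
        vals <- as.vector(newv)
        if (is.factor(df[[v]])) {
          dfj[[v]][idx] <- factor(as.character(vals), levels = levels(df[[v]]))
        } else {
          dfj[[v]][idx] <- vals
        }
        if (length(colmap[[v]])) {
          D[idx, colmap[[v]]] <- encode_var(dfj[[v]])[idx, , drop = FALSE]
        }
        chain[v, t, j] <- mean(as.numeric(dfj[[v]][idx]))
      }
    }
    datasets[[j]] <- dfj
  }
  structure(
    list(
      datasets = datasets, chain_means = chain, config = config,
      include = include, method = method, predictors = predictors,
      visit_order = visit, original = table
    ),
    class = "imputed_cohort"
  )
}

#' Extract the i-th completed dataset
#' @param x an `imputed_cohort` from [run_mice()].
#' @param i imputation index in `1..m`.
#' @return a completed data frame.
#' @export
complete_data <- function(x, i = 1) {
  stopifnot(inherits(x, "imputed_cohort"))
  x$datasets[[i]]
}

#' @export
print.imputed_cohort <- function(x, ...) {
  cat(
    "Chained-equations imputation: m =", x$config$m,
    ", cycles =", x$config$n_iterations,
    ", delta =", x$config$delta, "\n",
    "imputed variables:", if (length(x$include)) paste(x$include, collapse = ", ") else "(none)", "\n"
  )
  invisible(x)
}

#' Serialize imputed datasets to a directory of CSVs plus a manifest
#' @param x an `imputed_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_imputed <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(x$config$m)
  for (j in seq_len(x$config$m)) {
    files[j] <- file.path(dir, sprintf("imputation_%03d.csv", j))
    utils::write.csv(x$datasets[[j]], files[j], row.names = FALSE, na = "")
  }
  manifest <- list(
    m = x$config$m, n_iterations = x$config$n_iterations,
    delta = x$config$delta, seed = x$config$seed,
    imputed_variables = x$include,
    config_hash = config_hash(x$config),
    files = basename(files)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
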