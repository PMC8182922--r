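#' Item column names of the questionnaire block
#'
#' Three gross-motor flags (unable to walk without assistance, unable to sit
#' without support, unable to hold head up) and the 34 binary non-verbal
#' cognitive (NVC) scale items of the PARCA-R parent questionnaire.
#' @name item_columns
#' @keywords internal
NULL

motor_item_names <- function() c("motor_walk", "motor_sit", "motor_head")
parca_item_names <- function() sprintf("parca_%02d", 1:34)
item_names <- function() c(motor_item_names(), parca_item_names())

reserved_columns <- function() {
  c(
    "child_id", "region", "latent_impaired", "followed_up",
    item_names(), "nvc_score", "impaired_observed"
  )
}

#' Configuration for the synthetic very-preterm cohort generator
#'
#' Defines the full data-generating process: categorical/binary baseline
#' covariates (optionally region-dependent margins), a logistic model for the
#' latent impairment status, a logistic response (follow-up) model with an
#' optional MNAR shift, questionnaire-item generation, and the missingness
#' mechanisms for covariates and for responders' outcome items.
#'
#' @param n_children number of surviving children (rows) to generate.
#' @param region_probs named probability vector over regions (>= 1 region,
#'   e.g. `c(PT = 0.35, UK = 0.65)`); must sum to 1.
#' @param covariate_spec named list, one entry per baseline covariate. Each
#'   entry is a list with either `levels` (character) and `probs` (numeric
#'   vector summing to 1, or a matrix with one named column per region) for a
#'   categorical covariate, or `prob` (scalar in \[0,1\], or a named
#'   per-region vector) for a binary 0/1 covariate.
#' @param outcome_coefs,followup_coefs lists with an `intercept` scalar plus
#'   per-covariate log-odds. For categorical covariates (and `"region"`) give
#'   a named vector over non-reference levels; for binary covariates a single
#'   scalar applied when the value is 1. Every name must be `"region"` or a
#'   covariate in `covariate_spec`.
#' @param delta_true log-odds MNAR shift: `delta_true > 0` means impaired
#'   children are *less* likely to respond (the response-model linear
#'   predictor receives `-delta_true * latent_impaired`). 0 gives attrition
#'   that is missing at random given the covariates.
#' @param item_error_rate probability that any individual generated item
#'   contradicts the latent status (independent flips).
#' @param covariate_missing_rates per-covariate MCAR missingness probability;
#'   a scalar (recycled) or a named vector over covariates.
#' @param responder_outcome_missing_rate probability that a responder's
#'   questionnaire items are jointly missing.
#' @param seed integer RNG seed; all generation is reproducible given it.
#' @return an object of class `simulation_config`.
#' @seealso [default_epice_like_config()], [generate_cohort()]
#' @export
simulation_config <- function(n_children,
                              region_probs,
                              covariate_spec,
                              outcome_coefs,
                              followup_coefs,
                              delta_true = 0,
                              item_error_rate = 0.001,
                              covariate_missing_rates = 0.02,
                              responder_outcome_missing_rate = 0.11,
                              seed = 1L) {
  if (!is.numeric(n_children) || length(n_children) != 1 || n_children < 1 ||
    n_children != floor(n_children)) {
    stop_cfg("'n_children' must be a positive integer (got ", n_children, ")")
  }
  if (is.null(names(region_probs)) || any(!nzchar(names(region_probs)))) {
    stop_cfg("'region_probs' must be a named probability vector")
  }
  if (abs(sum(region_probs) - 1) > 1e-9 || any(region_probs < 0)) {
    stop_cfg("'region_probs' must be non-negative and sum to 1")
  }
  if (is.null(names(covariate_spec))) stop_cfg("'covariate_spec' must be a named list")
  for (nm in names(covariate_spec)) {
    covariate_spec[[nm]] <- validate_covariate_entry(nm, covariate_spec[[nm]], names(region_probs))
  }
  for (what in c("outcome_coefs", "followup_coefs")) {
    coefs <- get(what)
    extra <- setdiff(names(coefs), c("intercept", "region", names(covariate_spec)))
    if (length(extra)) {
      stop_cfg(
        "unknown covariate in '", what, "': ",
        paste(extra, collapse = ", ")
      )
    }
  }
  rates <- covariate_missing_rates
  if (is.null(names(rates))) {
    if (length(rates) != 1) stop_cfg("'covariate_missing_rates' must be scalar or named")
    rates <- stats::setNames(rep(rates, length(covariate_spec)), names(covariate_spec))
  } else {
    full <- stats::setNames(rep(0, length(covariate_spec)), names(covariate_spec))
    bad <- setdiff(names(rates), names(covariate_spec))
    if (length(bad)) stop_cfg("missingness rate for unknown covariate: ", paste(bad, collapse = ", "))
    full[names(rates)] <- rates
    rates <- full
  }
  for (p in list(rates, item_error_rate, responder_outcome_missing_rate)) {
    if (any(p < 0 | p > 1)) stop_cfg("all probability parameters must lie in [0, 1]")
  }
  if (!is.finite(delta_true)) stop_cfg("'delta_true' must be finite")
  structure(
    list(
      n_children = as.integer(n_children),
      region_probs = region_probs,
      covariate_spec = covariate_spec,
      outcome_coefs = outcome_coefs,
      followup_coefs = followup_coefs,
      delta_true = delta_true,
      item_error_rate = item_error_rate,
      covariate_missing_rates = rates,
      responder_outcome_missing_rate = responder_outcome_missing_rate,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

validate_covariate_entry <- function(nm, entry, regions) {
  if (!is.null(entry[["prob"]])) {
    p <- entry[["prob"]]
    if (length(p) > 1) {
      if (is.null(names(p)) || !setequal(names(p), regions)) {
        stop_cfg("covariate '", nm, "': per-region 'prob' must be named by region")
      }
    }
    if (any(p < 0 | p > 1)) stop_cfg("covariate '", nm, "': 'prob' outside [0, 1]")
    entry$type <- "binary"
  } else if (!is.null(entry$levels)) {
    pr <- entry$probs
    if (is.matrix(pr)) {
      if (!setequal(colnames(pr), regions) || nrow(pr) != length(entry$levels)) {
        stop_cfg("covariate '", nm, "': 'probs' matrix must be levels x regions")
      }
      sums <- colSums(pr)
    } else {
      if (length(pr) != length(entry$levels)) {
        stop_cfg("covariate '", nm, "': 'probs' length must match 'levels'")
      }
      sums <- sum(pr)
    }
    if (any(abs(sums - 1) > 1e-9) || any(pr < 0)) {
      stop_cfg("covariate '", nm, "': 'probs' must be non-negative and sum to 1")
    }
    entry$type <- "factor"
  } else {
    stop_cfg("covariate '", nm, "': give either 'prob' (binary) or 'levels' + 'probs'")
  }
  entry
}

# linear predictor of a coefficient list over a covariate data frame;
# unnamed levels contribute 0 (reference)
linpred <- function(coefs, dat) {
  lp <- rep(coefs$intercept %||% 0, nrow(dat))
  for (nm in setdiff(names(coefs), "intercept")) {
    v <- coefs[[nm]]
    x <- dat[[nm]]
    if (is.factor(x) || is.character(x)) {
      contrib <- v[match(as.character(x), names(v))]
      contrib[is.na(contrib)] <- 0
      lp <- lp + contrib
    } else {
      lp <- lp + v * as.numeric(x)
    }
  }
  lp
}

draw_covariate <- function(entry, region) {
  n <- length(region)
  if (entry$type == "binary") {
    p <- if (length(entry[["prob"]]) > 1) entry[["prob"]][as.character(region)] else entry[["prob"]]
    stats::rbinom(n, 1L, p)
  } else {
    if (is.matrix(entry$probs)) {
      out <- character(n)
      for (r in colnames(entry$probs)) {
        idx <- which(region == r)
        if (length(idx)) {
          out[idx] <- sample(entry$levels, length(idx), TRUE, entry$probs[, r])
        }
      }
      factor(out, levels = entry$levels)
    } else {
      factor(sample(entry$levels, n, TRUE, entry$probs), levels = entry$levels)
    }
  }
}

#' Generate a synthetic cohort
#'
#' Draws baseline covariates, a latent binary impairment status from the
#' outcome logistic model, the follow-up indicator from the response logistic
#' model (shifted by `-delta_true` for impaired children), questionnaire
#' items consistent with the latent status up to `item_error_rate` flips, and
#' then applies covariate and responder-outcome missingness. Items are
#' present only for responders; a responder's items are jointly missing with
#' probability `responder_outcome_missing_rate`. The column
#' `latent_impaired` is a simulation-only ground-truth column: no estimator
#' in the package reads it.
#'
#' Derived outcome columns (`nvc_score`, `impaired_observed`) are *not*
#' filled here; see [derive_outcomes()].
#'
#' @param config a [simulation_config()].
#' @return a `cohort` data frame, one row per child.
#' @examples
#' cohort <- generate_cohort(default_epice_like_config(n_children = 500))
#' mean(cohort$followed_up)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_children
  set.seed(substream_seed(config$seed, "covariates"))
  region <- factor(
    sample(names(config$region_probs), n, TRUE, config$region_probs),
    levels = names(config$region_probs)
  )
  dat <- data.frame(
    child_id = sprintf("C%06d", seq_len(n)),
    region = region,
    stringsAsFactors = FALSE
  )
  for (nm in names(config$covariate_spec)) {
    dat[[nm]] <- draw_covariate(config$covariate_spec[[nm]], region)
  }

  set.seed(substream_seed(config$seed, "latent"))
  latent <- stats::rbinom(n, 1L, inv_logit(linpred(config$outcome_coefs, dat)))
  set.seed(substream_seed(config$seed, "followup"))
  lp_fu <- linpred(config$followup_coefs, dat) - config$delta_true * latent
  followed <- stats::rbinom(n, 1L, inv_logit(lp_fu))
  dat$latent_impaired <- latent
  dat$followed_up <- followed

  items <- draw_items(latent, config)
  set.seed(substream_seed(config$seed, "item-missing"))
  drop_items <- followed == 0L | stats::runif(n) < config$responder_outcome_missing_rate
  items[drop_items, ] <- NA_integer_
  dat <- cbind(dat, as.data.frame(items))

  set.seed(substream_seed(config$seed, "covariate-missing"))
  for (nm in names(config$covariate_spec)) {
    r <- config$covariate_missing_rates[[nm]]
    if (r > 0) dat[[nm]][stats::runif(n) < r] <- NA
  }
  as_cohort(dat, config)
}

# Items from latent status. Impaired children follow the NVC route (score
# uniform on 10..21, motor flags clear) with weight 0.8, or the motor route
# (one motor flag set, NVC score in the unimpaired range) with weight 0.2.
# Unimpaired children score uniform on 24..34 with motor flags clear. Each
# individual item then flips with probability item_error_rate.
draw_items <- function(latent, config) {
  n <- length(latent)
  set.seed(substream_seed(config$seed, "items"))
  motor <- matrix(0L, n, 3, dimnames = list(NULL, motor_item_names()))
  score <- integer(n)
  imp <- latent == 1L
  route_motor <- imp & stats::runif(n) < 0.2
  route_nvc <- imp & !route_motor
  score[route_nvc] <- sample(10:21, sum(route_nvc), TRUE)
  high <- !route_nvc
  score[high] <- sample(24:34, sum(high), TRUE)
  if (any(route_motor)) {
    which_flag <- sample.int(3, sum(route_motor), TRUE, prob = c(0.5, 0.3, 0.2))
    motor[cbind(which(route_motor), which_flag)] <- 1L
  }
  parca <- matrix(0L, n, 34, dimnames = list(NULL, parca_item_names()))
  for (i in seq_len(n)) {
    parca[i, sample.int(34, score[i])] <- 1L
  }
  if (config$item_error_rate > 0) {
    flip_m <- matrix(stats::runif(n * 3) < config$item_error_rate, n, 3)
    flip_p <- matrix(stats::runif(n * 34) < config$item_error_rate, n, 34)
    motor <- abs(motor - flip_m)
    parca <- abs(parca - flip_p)
    storage.mode(motor) <- "integer"
    storage.mode(parca) <- "integer"
  }
  cbind(motor, parca)
}

as_cohort <- function(dat, config = NULL, covariates = NULL, cov_levels = NULL) {
  if (!is.null(config)) {
    covariates <- names(config$covariate_spec)
    cov_levels <- lapply(config$covariate_spec, function(e) {
      if (e$type == "factor") e$levels else NULL
    })
  }
  attr(dat, "covariates") <- covariates
  attr(dat, "cov_levels") <- cov_levels
  class(dat) <- c("cohort", "data.frame")
  dat
}

cohort_covariates <- function(table) {
  attr(table, "covariates") %||%
    setdiff(names(table), c(reserved_columns()))
}

#' Default configuration emulating a European very-preterm cohort
#'
#' Returns a [simulation_config()] whose generated cohorts reproduce the
#' broad structure of a two-region very preterm follow-up study: a ~54%
#' response rate with a strong social gradient (young maternal age, high
#' parity, foreign birth, no breastfeeding at discharge and residence in
#' deprived areas all reduce response), an ~18% latent prevalence of
#' moderate-to-severe neurodevelopmental impairment driven mainly by
#' perinatal factors (low gestational age, male sex, severe neonatal
#' morbidity, low Apgar), area deprivation strongly associated with
#' follow-up but not with the outcome, ~11% outcome missingness among
#' responders, and per-covariate MCAR missingness calibrated so roughly 14.5%
#' of rows have at least one missing covariate.
#'
#' Covariate margins and the covariate log-odds for response and outcome are
#' taken from the observed two-way tables of such a cohort; the two model
#' intercepts are calibrated by exact enumeration of the covariate joint
#' distribution so that the marginal response rate is 0.542 and the latent
#' prevalence is 0.184.
#'
#' @param n_children cohort size (default 1737).
#' @param delta_true MNAR shift passed through to the config (default 0, i.e.
#'   attrition is MAR given covariates).
#' @param seed RNG seed.
#' @return a `simulation_config`.
#' @export
default_epice_like_config <- function(n_children = 1737, delta_true = 0, seed = 1L) {
  region_probs <- c(PT = 0.347, UK = 0.653)
  covariate_spec <- list(
    maternal_age = list(
      levels = c("<=24", "25-34", ">=35"),
      probs = c(0.228, 0.544, 0.228)
    ),
    parity = list(
      levels = c("first", "second", "third+"),
      probs = c(0.546, 0.252, 0.202)
    ),
    foreign_born = list(prob = 0.178),
    prev_cesarean = list(prob = 0.113),
    pprom = list(prob = 0.244),
    breastfeeding = list(prob = 0.622),
    sex_male = list(prob = 0.550),
    ga_group = list(
      levels = c("23-25", "26-27", "28-29", "30-31"),
      probs = c(0.077, 0.158, 0.275, 0.490)
    ),
    apgar_low = list(prob = 0.133),
    severe_morbidity = list(prob = 0.116),
    deprivation = list(
      levels = c("q1", "q2", "q3", "q4", "q5"),
      probs = c(0.206, 0.185, 0.203, 0.194, 0.212)
    )
  )
  followup_coefs <- list(
    intercept = NA_real_,
    region = c(UK = -0.85),
    maternal_age = c("<=24" = -0.93, ">=35" = 0.26),
    parity = c(second = -0.39, "third+" = -0.94),
    foreign_born = -0.70,
    prev_cesarean = -0.31,
    pprom = -0.28,
    breastfeeding = 0.65,
    sex_male = 0.11,
    apgar_low = -0.26,
    severe_morbidity = 0.05,
    deprivation = c(q2 = -0.27, q3 = -0.49, q4 = -0.94, q5 = -1.21)
  )
  outcome_coefs <- list(
    intercept = NA_real_,
    region = c(UK = 0.23),
    maternal_age = c("<=24" = 0.35),
    parity = c(second = 0.18, "third+" = 0.68),
    foreign_born = 0.18,
    prev_cesarean = -0.15,
    pprom = 0.14,
    breastfeeding = -0.37,
    sex_male = 0.69,
    ga_group = c("23-25" = 1.49, "26-27" = 0.42, "28-29" = 0.65),
    apgar_low = 0.77,
    severe_morbidity = 1.21
  )
  followup_coefs$intercept <- calibrate_intercept(
    covariate_spec, region_probs, followup_coefs, target = 0.542
  )
  outcome_coefs$intercept <- calibrate_intercept(
    covariate_spec, region_probs, outcome_coefs, target = 0.184
  )
  simulation_config(
    n_children = n_children,
    region_probs = region_probs,
    covariate_spec = covariate_spec,
    outcome_coefs = outcome_coefs,
    followup_coefs = followup_coefs,
    delta_true = delta_true,
    item_error_rate = 0.001,
    covariate_missing_rates = c(
      maternal_age = 0.004, parity = 0.002, foreign_born = 0.009,
      prev_cesarean = 0.036, pprom = 0.036, breastfeeding = 0.003,
      sex_male = 0, ga_group = 0, apgar_low = 0.022,
      severe_morbidity = 0.006, deprivation = 0.042
    ),
    responder_outcome_missing_rate = 0.111,
    seed = seed
  )
}

# Solve the model intercept so that the population-average event probability
# equals `target`, by exact enumeration of the joint distribution of the
# covariates that appear in `coefs` (covariates are independent given
# region, so the joint factorizes over the enumeration grid).
calibrate_intercept <- function(covariate_spec, region_probs, coefs, target) {
  vars <- intersect(names(coefs), names(covariate_spec))
  covariate_spec <- lapply(covariate_spec, function(e) {
    e$type <- if (is.null(e[["prob"]])) "factor" else "binary"
    e
  })
  lev_list <- list(region = names(region_probs))
  for (v in vars) {
    e <- covariate_spec[[v]]
    lev_list[[v]] <- if (e$type == "factor") e$levels else c(0, 1)
  }
  grid <- expand.grid(lev_list, stringsAsFactors = FALSE)
  pr <- region_probs[grid$region]
  for (v in vars) {
    e <- covariate_spec[[v]]
    if (e$type == "factor") {
      if (is.matrix(e$probs)) {
        pv <- e$probs[cbind(match(grid[[v]], e$levels), match(grid$region, colnames(e$probs)))]
      } else {
        pv <- e$probs[match(grid[[v]], e$levels)]
      }
    } else {
      p1 <- if (length(e[["prob"]]) > 1) e[["prob"]][grid$region] else e[["prob"]]
      pv <- ifelse(grid[[v]] == 1, p1, 1 - p1)
    }
    pr <- pr * pv
  }
  coefs0 <- coefs
  coefs0$intercept <- 0
  lp0 <- linpred(coefs0, grid)
  stats::uniroot(
    function(b0) sum(pr * inv_logit(b0 + lp0)) - target,
    interval = c(-15, 15), tol = 1e-10
  )$root
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(
    "Synthetic cohort configuration\n",
    "  children:        ", x$n_children, "\n",
    "  regions:         ", paste(sprintf("%s (%.1f%%)", names(x$region_probs), 100 * x$region_probs), collapse = ", "), "\n",
    "  covariates:      ", paste(names(x$covariate_spec), collapse = ", "), "\n",
    "  delta_true:      ", x$delta_true, if (x$delta_true == 0) "  (MAR given covariates)" else "  (MNAR)", "\n",
    "  item error rate: ", x$item_error_rate, "\n",
    "  responder outcome missingness: ", x$responder_outcome_missing_rate, "\n",
    "  seed:            ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}
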