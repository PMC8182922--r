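#' Full attrition-correction analysis of a cohort
#'
#' Runs the complete estimation sequence on a cohort table: attrition
#' accounting, region-adjusted association scans of every factor with
#' follow-up and with the outcome, and the prevalence of the outcome under
#' each correction method — crude, IPW on complete cases, IPW with imputed
#' predictors, and multiple imputation (total population plus responder and
#' non-responder strata) — with percent-change rows against the crude
#' estimate, per region and total.
#'
#' @param table a `cohort` data frame (outcome columns are derived if
#'   absent).
#' @param m number of imputations (default 100; use 10-20 for quick runs).
#' @param seed master seed; each stage draws from its own named substream,
#'   so adding a stage never perturbs another stage's draws.
#' @param alpha IPW screening threshold.
#' @param n_iterations chained-equation cycles.
#' @return an object of class `followup_report`: `attrition`,
#'   `association_followup`, `association_outcome`, `estimates` (long data
#'   frame: method, group, estimate/CI in percent, percent change), and
#'   diagnostics.
#' @export
analyze_cohort <- function(table, m = 100, seed = 1L, alpha = 0.2,
                           n_iterations = 15) {
  t0 <- proc.time()[["elapsed"]]
  if (!"impaired_observed" %in% names(table)) table <- derive_outcomes(table)
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  att <- attrition_table(table)
  asc_fu <- association_scan(table, "followup")
  asc_out <- association_scan(table, "outcome")
  tick("describe")

  regions <- levels(factor(table$region))
  groups <- c(regions, "Total")
  collect <- function(by_list, total) {
    c(by_list, list(Total = total))
  }

  crude <- collect(crude_prevalence(table, by = "region"), crude_prevalence(table))
  tick("crude")

  icfg <- ipw_config(screening_alpha = alpha, seed = substream_seed(seed, "ipw"))
  retained <- screen_predictors(table, alpha = alpha)
  ws <- fit_weights(table, retained, icfg)
  ipw_cc <- collect(
    weighted_prevalence(table, ws, icfg, by = "region"),
    weighted_prevalence(table, ws, icfg)
  )
  tick("ipw_complete")

  mcfg_cov <- mice_config(
    m = m, n_iterations = n_iterations,
    seed = substream_seed(seed, "mice-covariates")
  )
  covs <- cohort_covariates(table)
  incomplete_covs <- covs[vapply(as.data.frame(table)[covs], anyNA, logical(1))]
  imp_cov <- run_mice(table, mcfg_cov, include = incomplete_covs)
  ipw_imp <- collect(
    ipw_on_imputed(table, config = icfg, by = "region", imputed = imp_cov),
    ipw_on_imputed(table, config = icfg, imputed = imp_cov)
  )
  tick("ipw_imputed")

  mcfg <- mice_config(
    m = m, n_iterations = n_iterations,
    seed = substream_seed(seed, "mice-outcome")
  )
  imp <- run_mice(table, mcfg)
  mi_total <- collect(mi_prevalence(imp, by = "region"), mi_prevalence(imp))
  sub <- subgroup_estimates(imp)
  d1 <- imp$datasets[[1]]
  mi_resp <- collect(
    {
      out <- lapply(regions, function(g) {
        pool_over_datasets(imp, d1$region == g & d1$followed_up == 1,
          method = "MI", subgroup = paste0(g, "/responders")
        )
      })
      names(out) <- regions
      out
    },
    sub$responders
  )
  mi_nonresp <- collect(
    {
      out <- lapply(regions, function(g) {
        pool_over_datasets(imp, d1$region == g & d1$followed_up == 0,
          method = "MI", subgroup = paste0(g, "/non-responders")
        )
      })
      names(out) <- regions
      out
    },
    sub$non_responders
  )
  tick("mi")

  methods <- list(
    "Crude" = crude,
    "IPW complete cases" = ipw_cc,
    "IPW imputed" = ipw_imp,
    "MI (total population)" = mi_total,
    "MI (responders)" = mi_resp,
    "MI (non-responders)" = mi_nonresp
  )
  changed <- c(
    "IPW complete cases", "IPW imputed",
    "MI (total population)", "MI (responders)"
  )
  rows <- list()
  for (meth in names(methods)) {
    for (g in groups) {
      e <- methods[[meth]][[g]]
      est <- 100 * e$estimate
      rows[[length(rows) + 1]] <- data.frame(
        method = meth, group = g,
        estimate_pct = est,
        ci_lo_pct = 100 * e$ci[1], ci_hi_pct = 100 * e$ci[2],
        pct_change = if (meth %in% changed && !is.na(est)) {
          percent_change(est, 100 * crude[[g]]$estimate)
        } else {
          NA_real_
        },
        n = e$n,
        stringsAsFactors = FALSE
      )
    }
  }
  estimates <- do.call(rbind, rows)

  structure(
    list(
      attrition = att,
      association_followup = asc_fu,
      association_outcome = asc_out,
      estimates = estimates,
      weights = ws,
      mice_chain_means = imp$chain_means,
      retained_predictors = retained,
      m = m, seed = seed, timings = timings
    ),
    class = "followup_report"
  )
}

#' @export
print.followup_report <- function(x, ...) {
  att <- x$attrition[x$attrition$scope == "Total", ]
  cat(sprintf(
    "Cohort: %d children, %d responders (%.1f%%), outcome missing for %.1f%% of responders\n\n",
    att$n, att$n_responders, att$pct_responders, att$pct_missing_outcome_responders
  ))
  cat(paste(render_estimates(x$estimates), collapse = "\n"), "\n")
  invisible(x)
}

#' Render the estimates table as markdown (per-region and total columns)
#' @param estimates the `estimates` data frame of a `followup_report`.
#' @return character vector of markdown lines.
#' @export
render_estimates <- function(estimates) {
  groups <- unique(estimates$group)
  lines <- c(
    paste0("| Method | ", paste(groups, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(groups) + 1), collapse = "|"), "|")
  )
  for (meth in unique(estimates$method)) {
    sub <- estimates[estimates$method == meth, ]
    cells <- vapply(groups, function(g) {
      r <- sub[sub$group == g, ]
      if (!nrow(r) || is.na(r$estimate_pct)) {
        return("-")
      }
      sprintf(
        "%.1f [%.1f;%.1f]", round_half_up(r$estimate_pct, 1),
        round_half_up(r$ci_lo_pct, 1), round_half_up(r$ci_hi_pct, 1)
      )
    }, character(1))
    lines <- c(lines, paste0("| ", meth, " | ", paste(cells, collapse = " | "), " |"))
    if (any(!is.na(sub$pct_change))) {
      chg <- vapply(groups, function(g) {
        r <- sub[sub$group == g, ]
        if (!nrow(r) || is.na(r$pct_change)) "-" else sprintf("%.1f%%", r$pct_change)
      }, character(1))
      lines <- c(lines, paste0("| % change | ", paste(chg, collapse = " | "), " |"))
    }
  }
  lines
}

write_manifest <- function(out_dir, config, seed, files, timings = NULL) {
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    package = "followupbias",
    version = as.character(utils::packageVersion("followupbias")),
    seed = seed,
    config_hash = config_hash(config),
    timings_sec = as.list(timings),
    files = as.list(files)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

read_any_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
}

config_from_list <- function(lst) {
  if (inherits(lst, "simulation_config")) {
    return(lst)
  }
  base <- default_epice_like_config()
  for (nm in intersect(names(lst), c(
    "n_children", "delta_true", "seed", "item_error_rate",
    "responder_outcome_missing_rate"
  ))) {
    base[[nm]] <- lst[[nm]]
  }
  do.call(simulation_config, unclass(base))
}

#' Generate a cohort and write it to disk
#'
#' Orchestration command: builds the generator configuration (defaults, an
#' in-memory [simulation_config()], or a YAML/JSON file overriding the
#' default's scalar fields), generates the cohort, writes the CSV + schema
#' sidecar and a run manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param config `NULL` (defaults), a `simulation_config`, or a path to a
#'   YAML/JSON file.
#' @param seed optional seed override.
#' @return invisibly, the cohort CSV path.
#' @export
cmd_simulate <- function(out_dir, config = NULL, seed = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(config)) {
    config <- default_epice_like_config()
  } else if (is.character(config)) {
    config <- config_from_list(read_any_config(config))
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config <- do.call(simulation_config, unclass(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  path <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, path)
  write_manifest(out_dir, config, config$seed,
    c("cohort.csv", "cohort.csv.schema.json"),
    timings = c(simulate = round(proc.time()[["elapsed"]] - t0, 3))
  )
  invisible(path)
}

#' Analyze a cohort CSV and write all report tables
#'
#' @param cohort_path path to a cohort CSV (see [read_cohort()]).
#' @param out_dir output directory.
#' @param m,seed,alpha,n_iterations passed to [analyze_cohort()].
#' @return invisibly, the `followup_report`.
#' @export
cmd_analyze <- function(cohort_path, out_dir, m = 100, seed = 1L,
                        alpha = 0.2, n_iterations = 15) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_cohort(cohort_path)
  rep <- analyze_cohort(table, m = m, seed = seed, alpha = alpha, n_iterations = n_iterations)
  utils::write.csv(rep$attrition, file.path(out_dir, "attrition.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(rep$association_followup),
    file.path(out_dir, "associations_followup.csv"),
    row.names = FALSE
  )
  utils::write.csv(as.data.frame(rep$association_outcome),
    file.path(out_dir, "associations_outcome.csv"),
    row.names = FALSE
  )
  utils::write.csv(rep$estimates, file.path(out_dir, "estimates.csv"), row.names = FALSE)
  writeLines(render_estimates(rep$estimates), file.path(out_dir, "estimates.md"))
  write_manifest(
    out_dir, list(m = m, alpha = alpha, n_iterations = n_iterations), seed,
    c(
      "attrition.csv", "associations_followup.csv", "associations_outcome.csv",
      "estimates.csv", "estimates.md"
    ),
    timings = rep$timings
  )
  invisible(rep)
}

#' Run the MNAR delta-sensitivity grid on a cohort CSV
#'
#' @param cohort_path path to a cohort CSV.
#' @param out_dir output directory.
#' @param deltas grid of log-odds offsets (default [default_delta_grid()]).
#' @param m,seed,n_iterations imputation settings.
#' @return invisibly, the `delta_grid`.
#' @export
cmd_sensitivity <- function(cohort_path, out_dir, deltas = default_delta_grid(),
                            m = 100, seed = 1L, n_iterations = 15) {
  t0 <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  table <- read_cohort(cohort_path)
  if (!"impaired_observed" %in% names(table)) table <- derive_outcomes(table)
  cfg <- mice_config(
    m = m, n_iterations = n_iterations,
    seed = substream_seed(seed, "mice-outcome")
  )
  grid <- run_delta_grid(table, cfg, deltas = deltas)
  utils::write.csv(as.data.frame(grid), file.path(out_dir, "delta_grid.csv"), row.names = FALSE)
  writeLines(render_delta_grid(grid), file.path(out_dir, "delta_grid.md"))
  write_manifest(
    out_dir, list(m = m, deltas = deltas, n_iterations = n_iterations), seed,
    c("delta_grid.csv", "delta_grid.md"),
    timings = c(sensitivity = round(proc.time()[["elapsed"]] - t0, 3))
  )
  invisible(grid)
}
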