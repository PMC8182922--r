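#' Write a cohort table to CSV (with a sidecar schema)
#'
#' Writes the cohort as plain CSV (missing marker = empty field) plus a
#' sidecar JSON schema (`<path>.schema.json`) recording column order,
#' categorical levels and which columns are covariates, so that
#' [read_cohort()] round-trips the table exactly.
#'
#' @param table a `cohort` data frame.
#' @param path output CSV path; the parent directory is created if needed.
#' @return invisibly, the path.
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  schema <- list(
    format = "cohort-csv",
    version = 1L,
    columns = names(table),
    covariates = cohort_covariates(table),
    levels = Filter(Negate(is.null), c(
      list(region = levels(table$region)),
      lapply(table[cohort_covariates(table)], function(x) if (is.factor(x)) levels(x))
    ))
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Reads a CSV written by [write_cohort()], restoring factor levels from the
#' sidecar schema when present (otherwise levels are inferred from the data,
#' with a warning), and validates the cohort invariants: questionnaire items
#' only present for responders, PARCA-R items all-present-or-all-missing per
#' child, and categorical codes within their declared levels.
#'
#' @param path CSV path.
#' @param schema optional schema list or path to a schema JSON; defaults to
#'   the `<path>.schema.json` sidecar if it exists.
#' @return a validated `cohort` data frame.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_cfg("cohort file not found: ", path)
  if (is.null(schema)) {
    side <- paste0(path, ".schema.json")
    if (file.exists(side)) schema <- side
  }
  if (is.character(schema)) schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_cfg("malformed CSV '", path, "': ", conditionMessage(e))
  )
  if (nrow(raw) == 0) stop_cfg("no records in cohort file: ", path)

  lev <- schema$levels %||% list()
  covariates <- schema$covariates
  if (is.null(covariates)) {
    covariates <- setdiff(names(raw), reserved_columns())
    warning("no schema found; inferring covariates and factor levels from data")
  }
  numeric_cols <- c(
    "latent_impaired", "followed_up", item_names(),
    "nvc_score", "impaired_observed"
  )
  out <- raw
  out[out == ""] <- NA
  for (nm in names(out)) {
    if (nm == "child_id") next
    if (nm %in% numeric_cols) {
      suppressWarnings(v <- as.integer(out[[nm]]))
      bad <- which(!is.na(out[[nm]]) & is.na(v))
      if (length(bad)) stop_cfg("non-numeric value in column '", nm, "' at row ", bad[1])
      out[[nm]] <- v
    } else if (!is.null(lev[[nm]])) {
      v <- out[[nm]]
      bad <- which(!is.na(v) & !(v %in% lev[[nm]]))
      if (length(bad)) {
        stop_cfg(
          "undeclared level '", v[bad[1]], "' for '", nm,
          "' at row ", bad[1]
        )
      }
      out[[nm]] <- factor(v, levels = lev[[nm]])
    } else {
      # numeric-looking columns stay numeric, others become factors
      suppressWarnings(v <- as.numeric(out[[nm]]))
      if (all(is.na(v) == is.na(out[[nm]]))) {
        out[[nm]] <- if (all(is.na(v) | v == floor(v))) as.integer(v) else v
      } else {
        out[[nm]] <- factor(out[[nm]])
      }
    }
  }
  cov_levels <- lapply(out[intersect(covariates, names(out))], function(x) {
    if (is.factor(x)) levels(x)
  })
  table <- as_cohort(out, covariates = covariates, cov_levels = cov_levels)
  validate_cohort(table)
  table
}

#' Validate cohort invariants
#'
#' Checks that item columns are present only for responders, that PARCA-R
#' items are jointly present or jointly missing within each child, and that
#' binary columns are 0/1. Errors name the first offending row.
#'
#' @param table a `cohort` data frame.
#' @return invisibly `TRUE`.
#' @export
validate_cohort <- function(table) {
  if (!nrow(table)) stop_cfg("no records in cohort table")
  if (!"followed_up" %in% names(table)) stop_cfg("cohort lacks a 'followed_up' column")
  items <- intersect(item_names(), names(table))
  if (length(items)) {
    item_present <- rowSums(!is.na(table[items])) > 0
    bad <- which(item_present & table$followed_up == 0)
    if (length(bad)) {
      stop_cfg("questionnaire items present for non-responder at row ", bad[1])
    }
  }
  parca <- intersect(parca_item_names(), names(table))
  if (length(parca) > 1) {
    n_miss <- rowSums(is.na(table[parca]))
    bad <- which(n_miss > 0 & n_miss < length(parca))
    if (length(bad)) {
      stop_cfg("PARCA-R items partially missing at row ", bad[1], " (must be all-or-none)")
    }
  }
  for (nm in intersect(c("followed_up", "latent_impaired", "impaired_observed", items), names(table))) {
    if (!is_binary01(table[[nm]]) && !all(is.na(table[[nm]]))) {
      stop_cfg("column '", nm, "' must be binary 0/1")
    }
  }
  invisible(TRUE)
}
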