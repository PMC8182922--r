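#' Sum the 34 PARCA-R items into the non-verbal cognitive score
#'
#' No partial scoring: if any of the 34 items is missing the score is
#' missing. Outcome missingness among responders is handled downstream by
#' multiple imputation, not by pro-rating the scale.
#'
#' @param items an n x 34 matrix or data frame of binary (0/1) items.
#' @return integer vector of scores in \[0, 34\], `NA` where any item is
#'   missing.
#' @export
score_parca <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) != 34) stop_cfg("expected 34 PARCA-R items, got ", ncol(items))
  v <- items[!is.na(items)]
  if (length(v) && !all(v %in% c(0, 1))) stop_cfg("PARCA-R items must be binary 0/1")
  as.integer(rowSums(items))
}

#' Classify non-verbal cognitive impairment from the NVC score
#'
#' Scores strictly below the threshold (default 22, the < 2.5th percentile
#' cut-off of a term-born reference population) are classified as moderate
#' to severe NVC impairment. Missing scores propagate.
#'
#' @param score integer NVC score in \[0, 34\] (or `NA`).
#' @param nvc_threshold integer cut-off; impairment is `score < nvc_threshold`.
#' @return integer 0/1 flag, `NA` where `score` is missing.
#' @export
classify_nvc <- function(score, nvc_threshold = 22) {
  if (nvc_threshold <= 0 || nvc_threshold > 34) {
    stop_cfg("'nvc_threshold' must lie in (0, 34]")
  }
  as.integer(score < nvc_threshold)
}

#' Composite impairment: gross-motor and/or NVC impairment
#'
#' Three-valued (Kleene) inclusive OR of the three gross-motor flags and the
#' NVC impairment flag: 1 whenever any observed component is 1 (even if
#' others are missing); 0 only when every component is observed and 0;
#' `NA` when the composite is undeterminable (all observed components are 0
#' but at least one component is missing).
#'
#' @param motor_items n x 3 matrix/data frame of binary gross-motor flags.
#' @param nvc_flag binary NVC impairment flag (vector).
#' @return integer 0/1/`NA` composite.
#' @export
derive_impairment <- function(motor_items, nvc_flag) {
  motor_items <- as.matrix(motor_items)
  if (ncol(motor_items) != 3) stop_cfg("expected 3 gross-motor items")
  comp <- cbind(motor_items, nvc_flag)
  any_one <- rowSums(comp == 1, na.rm = TRUE) > 0
  any_na <- rowSums(is.na(comp)) > 0
  out <- integer(nrow(comp))
  out[any_one] <- 1L
  out[!any_one & any_na] <- NA_integer_
  out
}

#' Derive the outcome columns on a cohort table
#'
#' Adds/overwrites `nvc_score` (PARCA-R item sum) and `impaired_observed`
#' (the composite of [derive_impairment()]), operating on the item columns
#' in place. Children without items (non-responders, or responders whose
#' questionnaire block is missing) get missing outcomes.
#'
#' @param table a `cohort` data frame carrying the item columns.
#' @param nvc_threshold NVC cut-off passed to [classify_nvc()].
#' @return the table with `nvc_score` and `impaired_observed` columns.
#' @export
derive_outcomes <- function(table, nvc_threshold = 22) {
  miss <- setdiff(item_names(), names(table))
  if (length(miss)) stop_cfg("cohort lacks item columns: ", paste(miss[1:2], collapse = ", "), ", ...")
  table$nvc_score <- score_parca(table[parca_item_names()])
  nvc_flag <- classify_nvc(table$nvc_score, nvc_threshold)
  table$impaired_observed <- derive_impairment(table[motor_item_names()], nvc_flag)
  table
}

#' Apply eligibility exclusions
#'
#' Removes children who died before the 2-year follow-up, had a severe
#' congenital anomaly, or were deaf or blind (the composite outcome cannot
#' be assessed by parent report in those children). Exclusions are applied
#' sequentially, so the per-reason counts attached to the result partition
#' the removed rows in that order.
#'
#' @param table a `cohort` data frame.
#' @param flags data frame with binary columns `died_before_2y`,
#'   `severe_congenital_anomaly`, `deaf_or_blind`, aligned with the rows of
#'   `table`.
#' @return the filtered table, with an `"exclusions"` attribute giving the
#'   number removed per reason.
#' @export
apply_eligibility <- function(table, flags) {
  reasons <- c("died_before_2y", "severe_congenital_anomaly", "deaf_or_blind")
  miss <- setdiff(reasons, names(flags))
  if (length(miss)) stop_cfg("eligibility flags lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(flags) != nrow(table)) {
    stop_cfg(
      "eligibility flags have ", nrow(flags), " rows but cohort has ",
      nrow(table)
    )
  }
  removed <- stats::setNames(integer(3), reasons)
  keep <- rep(TRUE, nrow(table))
  for (r in reasons) {
    hit <- keep & !is.na(flags[[r]]) & flags[[r]] == 1
    removed[[r]] <- sum(hit)
    keep <- keep & !hit
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "covariates") <- attr(table, "covariates")
  attr(out, "cov_levels") <- attr(table, "cov_levels")
  class(out) <- class(table)
  attr(out, "exclusions") <- removed
  if (!nrow(out)) warning("all children excluded; cohort is empty")
  out
}
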