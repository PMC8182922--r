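#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Display rounding used throughout the report tables: 0.5 always rounds up
#' in magnitude (54.25 -> 54.3), unlike [base::round()]'s round-half-even.
#' Applied only at render time; internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# percentage of count/total at 1 decimal, half-up (the table convention)
fmt_pct <- function(count, total, digits = 1) {
  round_half_up(100 * count / total, digits)
}

# Deterministic substream seed derived from a base seed and a label path.
# Polynomial rolling hash mod a prime < 2^31 so every intermediate stays
# exactly representable in a double. Used so each stage / imputation /
# cycle / variable draws from its own reproducible stream: adding a stage
# never perturbs another stage's draws, and runs that share inputs share
# draws (the coupling the delta-grid monotonicity rests on).
substream_seed <- function(seed, ...) {
  label <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  p <- 2147483629
  h <- 17
  for (v in utf8ToInt(label)) {
    h <- (h * 31 + v) %% p
  }
  as.integer(h)
}

logit <- stats::qlogis
inv_logit <- stats::plogis

stop_cfg <- function(...) stop(..., call. = FALSE)

is_binary01 <- function(x) {
  v <- x[!is.na(x)]
  length(v) > 0 && all(v %in% c(0L, 1L))
}

# canonical JSON (recursively name-sorted) then a polynomial hash, so the
# manifest's config hash is stable under field reordering
canonicalize <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
    lapply(x, canonicalize)
  } else {
    x
  }
}

config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(canonicalize(unclass(x)),
    auto_unbox = TRUE, digits = 12, null = "null", force = TRUE
  ))
  p <- 2147483629
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% p
  sprintf("%08x", h)
}
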