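# Shared fixtures, all built in code.

# Small default-config cohort, derived outcomes included.
make_cohort <- function(n = 1500, seed = 1, delta_true = 0) {
  derive_outcomes(generate_cohort(
    default_epice_like_config(n_children = n, delta_true = delta_true, seed = seed)
  ))
}

# A cohort whose accounting matches a two-region very-preterm follow-up
# study exactly: 1737 survivors (603 PT / 1134 UK), 941 responders
# (407 PT / 534 UK), outcome missing for 104 responders (19 PT / 85 UK),
# 154 impaired among the 837 with an observed outcome (64 PT / 90 UK), and
# 251 rows with >= 1 missing covariate (PT: 37 non-resp / 35 resp,
# UK: 104 non-resp / 75 resp).
make_accounting_cohort <- function() {
  spec <- list(
    PT = list(n = 603, resp = 407, out_miss = 19, impaired = 64, cov_miss_nr = 37, cov_miss_r = 35),
    UK = list(n = 1134, resp = 534, out_miss = 85, impaired = 90, cov_miss_nr = 104, cov_miss_r = 75)
  )
  rows <- lapply(names(spec), function(rg) {
    s <- spec[[rg]]
    followed <- c(rep(1L, s$resp), rep(0L, s$n - s$resp))
    # responders: first `out_miss` have missing items, next `impaired`
    # impaired, the rest unimpaired
    status <- rep(NA_character_, s$n)
    status[seq_len(s$resp)] <- c(
      rep("missing", s$out_miss), rep("impaired", s$impaired),
      rep("ok", s$resp - s$out_miss - s$impaired)
    )
    parca <- matrix(NA_integer_, s$n, 34, dimnames = list(NULL, sprintf("parca_%02d", 1:34)))
    motor <- matrix(NA_integer_, s$n, 3, dimnames = list(NULL, c("motor_walk", "motor_sit", "motor_head")))
    imp <- which(status == "impaired")
    ok <- which(status == "ok")
    parca[imp, ] <- rep(c(rep(1L, 10), rep(0L, 24)), each = length(imp)) # score 10 < 22
    parca[ok, ] <- rep(c(rep(1L, 30), rep(0L, 4)), each = length(ok)) # score 30
    motor[c(imp, ok), ] <- 0L
    # one binary covariate; missing for the stated counts (resp first)
    cov_missing <- c(
      seq_len(s$cov_miss_r), # responders
      s$resp + seq_len(s$cov_miss_nr) # non-responders
    )
    covar <- rep(0L, s$n)
    covar[cov_missing] <- NA_integer_
    df <- data.frame(
      child_id = sprintf("%s%05d", rg, seq_len(s$n)),
      region = rg, baseline_flag = covar,
      followed_up = followed, stringsAsFactors = FALSE
    )
    cbind(df, as.data.frame(motor), as.data.frame(parca))
  })
  dat <- do.call(rbind, rows)
  dat$region <- factor(dat$region, levels = c("PT", "UK"))
  out <- followupbias:::as_cohort(dat, covariates = "baseline_flag")
  derive_outcomes(out)
}

# Independent possible-worlds oracle for the three-valued composite:
# enumerate every completion of the missing components; if all completions
# agree, that value, else NA.
kleene_or_oracle <- function(vals) {
  nas <- which(is.na(vals))
  if (!length(nas)) {
    return(as.integer(any(vals == 1)))
  }
  worlds <- expand.grid(rep(list(0:1), length(nas)))
  res <- apply(worlds, 1, function(w) {
    v <- vals
    v[nas] <- w
    as.integer(any(v == 1))
  })
  if (length(unique(res)) == 1) res[1] else NA_integer_
}
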