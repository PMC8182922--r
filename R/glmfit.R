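# Internal model-fitting layer used by the imputation engine and the IPW
# response model. Binary logistic models use a direct Fisher-scoring MLE on
# a numeric design matrix (with a ridge-stabilized fallback when the fit
# separates); the multinomial logit is a Newton-Raphson MLE. Both are
# warm-startable because the chained-equations loop refits them thousands of
# times, and both are asserted against stats::glm / nnet::multinom in the
# test suite. They return the pieces the posterior-draw imputation step
# needs: MLE coefficients and the inverse observed information.

# rank-revealing column selection so aliased dummies never reach the solver
full_rank_cols <- function(X) {
  q <- qr(X)
  sort(q$pivot[seq_len(q$rank)])
}

fit_logit <- function(X, y, start = NULL, ridge = 0, keep = NULL) {
  keep <- keep %||% full_rank_cols(X)
  Xk <- X[, keep, drop = FALSE]
  if (!is.null(start) && length(start) == ncol(X)) start <- start[keep]
  if (!is.null(start) && length(start) != ncol(Xk)) start <- NULL
  fit <- newton_logit(Xk, y, start = start)
  beta <- fit$coef
  separated <- !fit$converged || anyNA(beta) || any(abs(beta) > 15)
  if (separated || ridge > 0) {
    rf <- ridge_logit(Xk, y, lambda = max(ridge, 1e-4), start = NULL)
    beta <- rf$coef
    info <- rf$info
  } else {
    info <- fit$info
  }
  vcov <- tryCatch(
    chol2inv(chol(info)),
    error = function(e) solve(info + diag(1e-6, ncol(info)))
  )
  list(
    coef = as.numeric(beta), vcov = vcov, keep = keep, p = ncol(X),
    separated = separated
  )
}

# plain Fisher-scoring logistic MLE on a full-rank design; agrees with
# stats::glm to the convergence tolerance (asserted in the test suite) but
# without the per-call family overhead, which matters inside the
# chained-equations loop where it runs thousands of times warm-started
newton_logit <- function(X, y, start = NULL, maxit = 30, tol = 1e-8) {
  p <- ncol(X)
  beta <- start %||% rep(0, p)
  converged <- FALSE
  info <- NULL
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Xw <- X * w
    info <- crossprod(Xw, X)
    beta_new <- tryCatch(
      drop(solve(info, crossprod(Xw, z))),
      error = function(e) NULL
    )
    if (is.null(beta_new) || anyNA(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (is.null(info)) info <- diag(1, p)
  list(coef = beta, info = info, converged = converged)
}

# IRLS with an L2 penalty on all coefficients; lambda is small so this only
# regularizes degenerate (separated) fits
ridge_logit <- function(X, y, lambda = 1e-4, start = NULL, maxit = 100) {
  p <- ncol(X)
  beta <- start %||% rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- inv_logit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    info <- crossprod(X * w, X) + diag(lambda, p)
    beta_new <- solve(info, crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < 1e-9) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- inv_logit(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  list(coef = as.numeric(beta), info = crossprod(X * w, X) + diag(lambda, p))
}

logit_lp <- function(fit, X, coef = NULL) {
  drop(X[, fit$keep, drop = FALSE] %*% (coef %||% fit$coef))
}

# MVN posterior draw via the Cholesky root (cheap, called once per
# conditional-model fit); falls back to MASS::mvrnorm with a jitter when the
# covariance is numerically rank-deficient
draw_mvn <- function(mean, vcov) {
  vcov <- (vcov + t(vcov)) / 2
  R <- tryCatch(chol(vcov), error = function(e) NULL)
  if (is.null(R)) {
    return(drop(MASS::mvrnorm(1, mean, vcov + diag(1e-10, nrow(vcov)))))
  }
  drop(mean + t(R) %*% stats::rnorm(length(mean)))
}

# Multinomial logistic MLE (reference = first level) by Newton-Raphson with
# step halving. `ridge` keeps the Hessian invertible under near-separation.
# Returns coefficients as a p x (K-1) matrix, the vcov of vec(B), and the
# levels actually modeled (levels empty in `y` are dropped, never imputed).
fit_multinom <- function(X, y, ridge = 1e-6, init = NULL, maxit = 50, keep = NULL) {
  keep <- keep %||% full_rank_cols(X)
  Xk <- X[, keep, drop = FALSE]
  lev <- levels(y)
  counts <- table(factor(y, levels = lev))
  modeled <- lev[counts > 0]
  if (length(modeled) < length(lev)) {
    warning(
      "multinomial level(s) never observed, dropped from model: ",
      paste(setdiff(lev, modeled), collapse = ", ")
    )
  }
  K <- length(modeled)
  p <- ncol(Xk)
  if (K == 1) {
    return(list(
      coef = matrix(0, p, 0), vcov = matrix(0, 0, 0), keep = keep,
      levels = modeled, degenerate = TRUE
    ))
  }
  Y <- outer(as.character(y), modeled[-1], "==") * 1
  B <- if (!is.null(init) && all(dim(init) == c(p, K - 1))) init else matrix(0, p, K - 1)
  nll <- function(B) {
    Eta <- pmin(pmax(Xk %*% B, -30), 30)
    denom <- 1 + rowSums(exp(Eta))
    -(sum(Eta * Y) - sum(log(denom)))
  }
  obj <- nll(B)
  H <- NULL
  for (it in seq_len(maxit)) {
    Eta <- pmin(pmax(Xk %*% B, -30), 30)
    expEta <- exp(Eta)
    denom <- 1 + rowSums(expEta)
    P <- expEta / denom # n x (K-1), probabilities of non-reference levels
    G <- crossprod(Xk, Y - P) # p x (K-1)
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in seq_len(K - 1)) {
      for (l in k:(K - 1)) {
        W <- P[, k] * ((k == l) - P[, l])
        blk <- crossprod(Xk * W, Xk)
        ri <- (k - 1) * p + seq_len(p)
        ci <- (l - 1) * p + seq_len(p)
        H[ri, ci] <- blk
        if (l > k) H[ci, ri] <- t(blk)
      }
    }
    H <- H + diag(ridge, nrow(H))
    step <- solve(H, as.vector(G))
    sz <- 1
    repeat {
      B_new <- B + matrix(sz * step, p, K - 1)
      obj_new <- nll(B_new)
      if (obj_new <= obj + 1e-12 || sz < 1e-4) break
      sz <- sz / 2
    }
    moved <- max(abs(B_new - B))
    B <- B_new
    obj <- obj_new
    if (moved < 1e-5) break
  }
  vcov <- tryCatch(
    chol2inv(chol(H)),
    error = function(e) solve(H + diag(1e-6, nrow(H)))
  )
  list(
    coef = B, vcov = vcov, keep = keep, levels = modeled, degenerate = FALSE,
    p = ncol(X)
  )
}

# class probabilities (n x K, columns = modeled levels) for a coefficient
# matrix draw
multinom_probs <- function(fit, X, B = NULL) {
  Xk <- X[, fit$keep, drop = FALSE]
  B <- B %||% fit$coef
  Eta <- pmin(pmax(Xk %*% B, -30), 30)
  expEta <- cbind(1, exp(Eta))
  expEta / rowSums(expEta)
}

# --- dummy-coded design matrix maintenance --------------------------------
# The chained-equations loop keeps one numeric design matrix for all
# candidate predictor columns and rewrites only the columns of a variable
# just re-imputed, so each conditional model fit is pure linear algebra.

design_cols_for <- function(x, nm) {
  if (is.factor(x)) {
    lev <- levels(x)
    if (length(lev) < 2) {
      return(character(0))
    }
    paste0(nm, "=", lev[-1])
  } else {
    nm
  }
}

encode_var <- function(x) {
  if (is.factor(x)) {
    lev <- levels(x)
    out <- matrix(0, length(x), length(lev) - 1)
    for (j in seq_along(lev)[-1]) out[, j - 1] <- as.numeric(x == lev[j])
    out
  } else {
    matrix(as.numeric(x), ncol = 1)
  }
}

make_design <- function(df, vars) {
  colmap <- list()
  blocks <- list("(Intercept)" = matrix(1, nrow(df), 1))
  idx <- 1L
  for (nm in vars) {
    cols <- design_cols_for(df[[nm]], nm)
    if (!length(cols)) {
      colmap[[nm]] <- integer(0)
      next
    }
    blocks[[nm]] <- encode_var(df[[nm]])
    colmap[[nm]] <- idx + seq_along(cols)
    idx <- idx + length(cols)
  }
  D <- do.call(cbind, blocks)
  colnames(D) <- c("(Intercept)", unlist(lapply(vars, function(nm) {
    design_cols_for(df[[nm]], nm)
  })))
  list(D = D, colmap = colmap)
}
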