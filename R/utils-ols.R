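# Internal OLS helpers shared by the regression, mediation and SSM modules.
# qr-based so rank deficiency is detected and the offending columns can be
# named; lm.fit is used on the bootstrap hot path (coefficients come back in
# column order with NA for aliased terms).

#' @noRd
ols <- function(X, y, check_perfect = FALSE) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  resid <- y - fitted
  df <- length(y) - ncol(X)
  rss <- sum(resid^2)
  if (check_perfect && rss < 1e-10 * max(sum((y - mean(y))^2), 1e-300)) {
    stop("(near-)perfect fit: zero residual variance; is the outcome ",
         "included among the predictors?", call. = FALSE)
  }
  sigma2 <- if (df > 0) rss / df else NaN
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coef = coef, se = se, t = tval, p = pval, df = df,
       rss = rss, sigma = sqrt(sigma2), resid = resid, fitted = fitted)
}

# fast refit used inside bootstrap loops; returns NULL on rank deficiency
#' @noRd
ols_coef_fast <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NULL)
  fit$coefficients
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic substream seed: one global seed drives a per-equation (or
# per-replicate) sequence so adding a stream does not perturb existing ones
#' @noRd
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(index) * 7919) %% 2147483629)
}

#' @noRd
stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(name, " must be a single integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}
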