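#' Natural log transform with positivity check
#'
#' @param v Numeric vector, all entries strictly positive.
#' @return `log(v)`.
#' @export
log_transform <- function(v) {
  bad <- which(!is.finite(v) | v <= 0)
  if (length(bad))
    stop("non-positive values at position(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  log(v)
}

#' Standardized regression coefficient
#'
#' `beta = B * sd(x) / sd(y)`, the coefficient that would be obtained after
#' z-scoring predictor and outcome on the analysis sample. Binary predictors
#' are standardized by the same SD ratio.
#'
#' @param B Unstandardized coefficient.
#' @param sd_x,sd_y Sample SDs of predictor and outcome (> 0).
#' @return Standardized coefficient.
#' @export
standardized_beta <- function(B, sd_x, sd_y) {
  if (!is.finite(sd_x) || sd_x <= 0 || !is.finite(sd_y) || sd_y <= 0)
    stop("sd_x and sd_y must be positive", call. = FALSE)
  B * sd_x / sd_y
}

#' Exact t-based inference for a coefficient
#'
#' @param B Coefficient estimate.
#' @param SE Standard error (> 0).
#' @param df Residual degrees of freedom (>= 1).
#' @param level Confidence level (default 0.95).
#' @return List with `t`, `p` (two-sided Student-t) and `ci`
#'   (`B +/- t_crit * SE`).
#' @export
inference <- function(B, SE, df, level = 0.95) {
  if (!is.finite(SE) || SE <= 0) stop("SE must be positive", call. = FALSE)
  if (!is.finite(df) || df < 1) stop("df must be >= 1", call. = FALSE)
  tval <- B / SE
  p <- 2 * stats::pt(-abs(tval), df)
  tc <- stats::qt(1 - (1 - level) / 2, df)
  list(t = tval, p = p, ci = c(lower = B - tc * SE, upper = B + tc * SE))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts the raw p-values ascending, computes `p_(j) * m / j`, takes the
#' running minimum from the largest rank downwards, caps at 1, and restores
#' the input order (ties keep their original relative order).
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1]; names, if
#'   present, are preserved.
#' @return List of class `fdr_result` with `raw_p`, `adj_p`, `m`.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)                      # stable: ties keep original order
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  adj <- numeric(m)
  adj[o] <- pmin(adj_sorted, 1)
  names(adj) <- names(pvalues)
  structure(list(raw_p = pvalues, adj_p = adj, m = m), class = "fdr_result")
}

#' Residualize one score on another
#'
#' Ordinary least squares residuals of `y` on `x` (with intercept),
#' z-scored; the executive-function transform that removes processing-speed
#' variance from a timed score. An exactly linear relation yields an
#' all-zero residual vector, returned as zeros with a warning rather than
#' dividing by a zero SD.
#'
#' @param y,x Numeric vectors of equal length; `x` non-constant.
#' @return Standardized residual vector.
#' @export
residualize <- function(y, x) {
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant; cannot residualize", call. = FALSE)
  r <- stats::lm.fit(cbind(1, x), y)$residuals
  s <- stats::sd(r)
  if (s < 1e-12 * max(stats::sd(y), 1e-300)) {
    warning("residuals are numerically zero; returning zeros", call. = FALSE)
    return(rep(0, length(y)))
  }
  (r - mean(r)) / s
}

#' Block-wise regression of an outcome on a focal predictor
#'
#' Fits cumulative ordinary least squares models: the focal predictor plus
#' block 1, then plus block 2, and so on (block k always contains all
#' earlier blocks). Rows with missing values in any involved variable are
#' dropped once, so every block is fitted on the identical complete-case
#' sample. Returns the focal predictor's coefficient per block with
#' standardized beta, exact t inference and confidence interval; the final
#' block row is the headline result.
#'
#' @param data Data frame with all variables.
#' @param outcome Outcome column name.
#' @param blocks List of character vectors of covariate names, in entry
#'   order.
#' @param focal Focal predictor column name.
#' @param level Confidence level.
#' @return Data frame, one row per block, columns `outcome`, `predictor`,
#'   `block`, `beta`, `B`, `SE`, `t`, `df`, `p`, `ci_lower`, `ci_upper`,
#'   `n`.
#' @export
fit_blockwise <- function(data, outcome, blocks, focal, level = 0.95) {
  stopifnot(is.list(blocks), length(blocks) >= 1L)
  vars <- unique(c(outcome, focal, unlist(blocks)))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (focal == outcome)
    stop("focal predictor equals the outcome", call. = FALSE)
  df0 <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(df0)
  if (n <= length(vars))
    stop("too few complete cases (", n, ") for ", length(vars), " variables",
         call. = FALSE)
  y <- df0[[outcome]]
  sd_y <- stats::sd(y); sd_x <- stats::sd(df0[[focal]])
  if (sd_x == 0) stop("focal predictor is constant", call. = FALSE)
  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    preds <- unique(c(focal, unlist(blocks[seq_len(k)])))
    X <- cbind(`(Intercept)` = 1,
               as.matrix(df0[, preds, drop = FALSE]))
    colnames(X) <- c("(Intercept)", preds)
    fit <- ols(X, y, check_perfect = TRUE)
    B <- fit$coef[[focal]]; SE <- fit$se[[focal]]
    inf <- inference(B, SE, fit$df, level)
    out[[k]] <- data.frame(
      outcome = outcome, predictor = focal, block = k,
      beta = standardized_beta(B, sd_x, sd_y),
      B = B, SE = SE, t = inf$t, df = fit$df, p = inf$p,
      ci_lower = inf$ci[["lower"]], ci_upper = inf$ci[["upper"]],
      n = n, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Regression table for a family of outcomes with FDR correction
#'
#' Runs [fit_blockwise()] for each outcome, keeps the final-block row of the
#' focal predictor, and adjusts the family of final-block p-values by
#' Benjamini-Hochberg. This is the lobar gray-matter-volume table of the
#' motivating analysis (outcome per lobe, focal = pattern expression,
#' block 1 = TIV, block 2 = age, sex, education).
#'
#' @param data Data frame.
#' @param outcomes Character vector of outcome columns (the FDR family).
#' @param focal Focal predictor.
#' @param blocks Covariate blocks, see [fit_blockwise()].
#' @param level Confidence level.
#' @return Data frame with one row per outcome: `beta`, `B`, `SE`,
#'   `ci_lower`, `ci_upper`, `p`, `p_fdr`.
#' @export
regression_table <- function(data, outcomes, focal, blocks, level = 0.95) {
  rows <- lapply(outcomes, function(oc) {
    res <- fit_blockwise(data, oc, blocks, focal, level)
    res[nrow(res), , drop = FALSE]
  })
  tab <- do.call(rbind, rows)
  fdr <- bh_fdr(stats::setNames(tab$p, tab$outcome))
  tab$p_fdr <- unname(fdr$adj_p)
  rownames(tab) <- NULL
  tab
}
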