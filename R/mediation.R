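#' Specify a serial mediation model
#'
#' Defines the causal chain `x -> M1 -> ... -> Mk -> y` (k = 1..3 ordered
#' mediators) with a common covariate set entered into every submodel, the
#' bootstrap settings and the seed.
#'
#' @param x Predictor column name.
#' @param y Outcome column name.
#' @param mediators Character vector of 1-3 mediator names, in hypothesized
#'   causal order.
#' @param covariates Character vector of covariate names (may be empty).
#' @param n_boot Bootstrap iterations (>= 100; 10,000 for release runs).
#' @param ci_level Confidence level in (0, 1).
#' @param seed Integer seed driving per-replicate substreams.
#' @return An object of class `mediation_spec`.
#' @export
mediation_spec <- function(x, y, mediators, covariates = character(),
                           n_boot = 10000L, ci_level = 0.95, seed = 1L) {
  k <- length(mediators)
  if (k < 1L || k > 3L) stop("1 to 3 mediators supported", call. = FALSE)
  all_vars <- c(x, y, mediators)
  if (anyDuplicated(all_vars))
    stop("x, y and mediators must be disjoint", call. = FALSE)
  if (any(covariates %in% all_vars))
    stop("covariates overlap x/y/mediators", call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1)
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  n_boot <- stopifnot_scalar_count(n_boot, "n_boot", min = 100L)
  structure(list(x = x, y = y, mediators = mediators,
                 covariates = covariates, n_boot = n_boot,
                 ci_level = ci_level, seed = as.integer(seed)),
            class = "mediation_spec")
}

#' Enumerate serial indirect paths
#'
#' All nonempty ordered subsets of k serial mediators that respect the
#' causal order: 1 path for k = 1, 3 for k = 2, 7 for k = 3.
#'
#' @param k Number of mediators (1-3).
#' @return List of increasing integer vectors (mediator indices).
#' @export
enumerate_indirect_paths <- function(k) {
  k <- stopifnot_scalar_count(k, "k")
  if (k > 3L) stop("k must be 1, 2 or 3", call. = FALSE)
  lapply(seq_len(2^k - 1L), function(s)
    which(bitwAnd(s, 2L^(seq_len(k) - 1L)) > 0L))
}

# core coefficient extraction on a plain numeric matrix
# D columns: x, M1..Mk, y, covariates (in that order); returns NULL when any
# submodel is rank deficient
#' @noRd
path_core <- function(D, k) {
  n <- nrow(D)
  cov_idx <- if (ncol(D) > k + 2L) (k + 3L):ncol(D) else integer(0)
  X1 <- cbind(1, D)  # col 1 intercept, col 1+j = D[, j]
  a <- numeric(k)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) {
    pred <- c(1L, 1L + 1L, 1L + seq_len(i - 1L) + 1L, 1L + cov_idx)
    cf <- ols_coef_fast(X1[, pred, drop = FALSE], D[, 1L + i])
    if (is.null(cf)) return(NULL)
    a[i] <- cf[2L]
    if (i > 1L) d[i, seq_len(i - 1L)] <- cf[2L + seq_len(i - 1L)]
  }
  pred <- c(1L, 2L, 1L + seq_len(k) + 1L, 1L + cov_idx)
  cf <- ols_coef_fast(X1[, pred, drop = FALSE], D[, k + 2L])
  if (is.null(cf)) return(NULL)
  c_prime <- cf[[2L]]
  b <- unname(cf[2L + seq_len(k)])
  cf <- ols_coef_fast(X1[, c(1L, 2L, 1L + cov_idx), drop = FALSE], D[, k + 2L])
  if (is.null(cf)) return(NULL)
  list(a = a, d = d, b = b, c_prime = c_prime, c = cf[[2L]])
}

# raw indirect effect of one enumerated path
#' @noRd
path_product <- function(core, path) {
  eff <- core$a[path[1L]]
  if (length(path) > 1L)
    for (j in seq_len(length(path) - 1L))
      eff <- eff * core$d[path[j + 1L], path[j]]
  eff * core$b[path[length(path)]]
}

#' Estimate all paths of a serial mediation model
#'
#' Fits the k + 2 ordinary least squares submodels of a serial mediation
#' system on the shared complete-case sample: each mediator on the
#' predictor, all earlier mediators and the covariates; the outcome on the
#' predictor, all mediators and the covariates; and the total-effect model
#' (outcome on predictor and covariates). Standardized twins of every
#' coefficient are computed from the SD ratios of the shared sample.
#'
#' @param data Data frame.
#' @param spec A [mediation_spec()].
#' @return Object of class `path_estimates`: unstandardized `a` (x to each
#'   mediator), `d` (mediator i to later mediator j), `b` (mediator to
#'   outcome), `c_prime` (direct), `c` (total); matching `std` list;
#'   per-coefficient `se` and `p`; residual SDs; `sds`; `n_used`; and the
#'   complete-case analysis matrix used by the bootstrap.
#' @export
fit_paths <- function(data, spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  k <- length(spec$mediators)
  vars <- c(spec$x, spec$mediators, spec$y, spec$covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df0 <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  D <- as.matrix(df0)
  n <- nrow(D)
  max_par <- k + 2L + length(spec$covariates)
  if (n <= max_par + 1L)
    stop("insufficient complete cases (", n, ") for the largest submodel (",
         max_par + 1L, " parameters)", call. = FALSE)
  sds <- apply(D, 2L, stats::sd)
  if (any(sds[c(spec$x, spec$mediators, spec$y)] == 0))
    stop("constant x/mediator/outcome on the analysis sample", call. = FALSE)
  core <- path_core(D, k)
  if (is.null(core)) {
    # rerun with the strict fitter to name the collinear columns
    cov_idx <- if (ncol(D) > k + 2L) (k + 3L):ncol(D) else integer(0)
    X <- cbind(`(Intercept)` = 1, D[, c(1L, seq_len(k) + 1L, cov_idx),
                                    drop = FALSE])
    ols(X, D[, k + 2L])
    stop("rank-deficient mediation design", call. = FALSE)
  }

  # exact t inference per submodel via the strict fitter
  cov_nm <- spec$covariates
  se_fit <- function(resp, preds) {
    X <- cbind(`(Intercept)` = 1, D[, preds, drop = FALSE])
    ols(X, D[, resp])
  }
  med_nm <- spec$mediators
  a_se <- a_p <- numeric(k)
  d_se <- d_p <- matrix(NA_real_, k, k)
  resid_sd <- stats::setNames(numeric(k + 2L),
                              c(med_nm, spec$y, paste0(spec$y, "_total")))
  for (i in seq_len(k)) {
    fit <- se_fit(med_nm[i], c(spec$x, med_nm[seq_len(i - 1L)], cov_nm))
    a_se[i] <- fit$se[[spec$x]]; a_p[i] <- fit$p[[spec$x]]
    if (i > 1L) for (j in seq_len(i - 1L)) {
      d_se[i, j] <- fit$se[[med_nm[j]]]; d_p[i, j] <- fit$p[[med_nm[j]]]
    }
    resid_sd[i] <- fit$sigma
  }
  fit_y <- se_fit(spec$y, c(spec$x, med_nm, cov_nm))
  fit_tot <- se_fit(spec$y, c(spec$x, cov_nm))
  resid_sd[k + 1L] <- fit_y$sigma
  resid_sd[k + 2L] <- fit_tot$sigma

  std <- list(
    a = stats::setNames(core$a * sds[[spec$x]] / sds[med_nm], med_nm),
    d = core$d * outer(1 / sds[med_nm], sds[med_nm]),
    b = core$b * sds[med_nm] / sds[[spec$y]],
    c_prime = core$c_prime * sds[[spec$x]] / sds[[spec$y]],
    c = core$c * sds[[spec$x]] / sds[[spec$y]]
  )
  std$d[upper.tri(std$d, diag = TRUE)] <- 0

  structure(list(
    spec = spec, a = core$a, d = core$d, b = core$b,
    c_prime = core$c_prime, c = core$c, std = std,
    se = list(a = a_se, d = d_se, b = fit_y$se[med_nm],
              c_prime = fit_y$se[[spec$x]], c = fit_tot$se[[spec$x]]),
    p = list(a = a_p, d = d_p, b = fit_y$p[med_nm],
             c_prime = fit_y$p[[spec$x]], c = fit_tot$p[[spec$x]]),
    df = list(y = fit_y$df, total = fit_tot$df),
    resid_sd = resid_sd, sds = sds, n_used = n, D = D
  ), class = "path_estimates")
}

#' Point indirect effects of all serial paths
#'
#' Raw effect = product of unstandardized coefficients along each enumerated
#' path; completely standardized effect = raw * sd(x) / sd(y), which equals
#' the product of the standardized path coefficients (telescoping identity).
#'
#' @param paths A `path_estimates` from [fit_paths()].
#' @return Data frame with `path` label, mediator `indices`, `raw`, `std`.
#' @export
indirect_effects <- function(paths) {
  stopifnot(inherits(paths, "path_estimates"))
  spec <- paths$spec
  k <- length(spec$mediators)
  enum <- enumerate_indirect_paths(k)
  ratio <- paths$sds[[spec$x]] / paths$sds[[spec$y]]
  rows <- lapply(enum, function(s) {
    raw <- path_product(paths, s)
    data.frame(
      path = paste(c(spec$x, spec$mediators[s], spec$y), collapse = " -> "),
      indices = I(list(s)), raw = raw, std = raw * ratio,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Percentile-bootstrap serial mediation
#'
#' Resamples complete-case rows with replacement, refits every submodel per
#' replicate, and collects each enumerated indirect effect, both raw and
#' completely standardized (replicate-wise SDs inside the bootstrap; the
#' point estimate uses full-sample SDs). Confidence bounds are percentile
#' order statistics of the replicate vectors; an effect is flagged
#' significant when its interval excludes zero. Rank-deficient replicates
#' are skipped and counted; more than 5 percent failures is an error.
#' Replicates draw from per-iteration seed substreams, so results are
#' reproducible and extending `n_boot` does not change earlier replicates.
#'
#' @param data Data frame.
#' @param spec A [mediation_spec()].
#' @param keep_replicates Keep the replicate-by-path matrices (for
#'   diagnostics/oracle checks).
#' @return Object of class `mediation_result`: `spec`, `paths`
#'   (point estimates), `indirects` table (point, bootstrap SE, percentile
#'   CI and significance flag for raw and standardized effects), `total`
#'   and `direct` effects with exact t inference, `n_used`,
#'   `boot_failures`.
#' @export
bootstrap_mediation <- function(data, spec, keep_replicates = FALSE) {
  point <- fit_paths(data, spec)
  k <- length(spec$mediators)
  enum <- enumerate_indirect_paths(k)
  npth <- length(enum)
  D <- point$D
  n <- nrow(D)
  xi <- 1L; yi <- k + 2L
  raw_rep <- std_rep <- matrix(NA_real_, spec$n_boot, npth)
  failures <- 0L
  for (bb in seq_len(spec$n_boot)) {
    set.seed(substream_seed(spec$seed, bb))
    idx <- sample.int(n, n, replace = TRUE)
    Db <- D[idx, , drop = FALSE]
    sx <- stats::sd(Db[, xi]); sy <- stats::sd(Db[, yi])
    core <- if (sx > 0 && sy > 0) path_core(Db, k) else NULL
    if (is.null(core)) { failures <- failures + 1L; next }
    raw <- vapply(enum, function(s) path_product(core, s), numeric(1))
    raw_rep[bb, ] <- raw
    std_rep[bb, ] <- raw * sx / sy
  }
  if (failures > 0.05 * spec$n_boot)
    stop("bootstrap failure rate ", failures, "/", spec$n_boot,
         " exceeds 5%", call. = FALSE)
  ok <- stats::complete.cases(raw_rep)
  raw_rep <- raw_rep[ok, , drop = FALSE]
  std_rep <- std_rep[ok, , drop = FALSE]

  ind <- indirect_effects(point)
  ci_raw <- apply(raw_rep, 2L, percentile_ci, level = spec$ci_level)
  ci_std <- apply(std_rep, 2L, percentile_ci, level = spec$ci_level)
  ind$boot_se_raw <- apply(raw_rep, 2L, stats::sd)
  ind$ci_raw_lower <- ci_raw["lower", ]
  ind$ci_raw_upper <- ci_raw["upper", ]
  ind$boot_se_std <- apply(std_rep, 2L, stats::sd)
  ind$ci_std_lower <- ci_std["lower", ]
  ind$ci_std_upper <- ci_std["upper", ]
  ind$significant <- ind$ci_raw_lower > 0 | ind$ci_raw_upper < 0

  ratio <- point$sds[[spec$x]] / point$sds[[spec$y]]
  total <- c(effect = point$c, std = point$std$c, se = point$se$c,
             p = point$p$c)
  direct <- c(effect = point$c_prime, std = point$std$c_prime,
              se = point$se$c_prime, p = point$p$c_prime)
  structure(list(
    spec = spec, paths = point, indirects = ind,
    total = total, direct = direct,
    n_used = point$n_used, boot_failures = failures,
    replicates = if (keep_replicates)
      list(raw = raw_rep, std = std_rep) else NULL
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  s <- x$spec
  cat("Serial mediation:", s$x, "->", paste(s$mediators, collapse = " -> "),
      "->", s$y, "\n")
  cat("n =", x$n_used, "; boot =", s$n_boot, "(", x$boot_failures,
      "failures )\n")
  cat(sprintf("total = %.4f (std %.4f, p = %.4g); direct = %.4f (std %.4f, p = %.4g)\n",
              x$total[["effect"]], x$total[["std"]], x$total[["p"]],
              x$direct[["effect"]], x$direct[["std"]], x$direct[["p"]]))
  print(x$indirects[c("path", "raw", "std", "ci_std_lower", "ci_std_upper",
                      "significant")], digits = 3)
  invisible(x)
}

#' Total-effect decomposition report
#'
#' Verifies the ordinary-least-squares identity
#' `total = direct + sum(raw indirect effects)` (it holds exactly when every
#' submodel shares the same sample and covariates) and returns a tidy
#' decomposition table. A violation beyond tolerance signals a sample
#' mismatch across submodels and raises an error.
#'
#' @param result A `mediation_result` (or `path_estimates`).
#' @param tol Relative tolerance for the identity check.
#' @return Data frame of total, direct and per-path effects (raw and
#'   completely standardized).
#' @export
decompose_total <- function(result, tol = 1e-8) {
  paths <- if (inherits(result, "mediation_result")) result$paths else result
  stopifnot(inherits(paths, "path_estimates"))
  ind <- indirect_effects(paths)
  gap <- paths$c - (paths$c_prime + sum(ind$raw))
  ref <- max(abs(paths$c), abs(paths$c_prime), sum(abs(ind$raw)), 1e-12)
  if (abs(gap) > tol * ref)
    stop("total-effect identity violated (gap = ", signif(gap, 4),
         "); submodel samples are inconsistent", call. = FALSE)
  data.frame(
    effect = c("total", "direct", ind$path),
    raw = c(paths$c, paths$c_prime, ind$raw),
    std = c(paths$std$c, paths$std$c_prime, ind$std),
    stringsAsFactors = FALSE
  )
}

#' Reverse the mediator order of a specification
#'
#' Sensitivity-analysis helper: returns the same specification with the
#' hypothesized mediator sequence reversed (requires at least 2 mediators).
#'
#' @param spec A [mediation_spec()].
#' @return A `mediation_spec` with reversed mediator order.
#' @export
reverse_mediators <- function(spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  if (length(spec$mediators) < 2L)
    stop("need at least 2 mediators to reverse", call. = FALSE)
  spec$mediators <- rev(spec$mediators)
  spec
}
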