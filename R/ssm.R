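#' Preprocess a volume matrix for covariance-pattern analysis
#'
#' Natural-log transforms all volumes; in `log_tiv_residual` mode each
#' log-region column is additionally replaced by its residual from a simple
#' regression on log TIV, with the column mean added back so location is
#' preserved. The per-region slopes and the log-TIV centering constant are
#' recorded so new subjects can be preprocessed identically when scoring an
#' existing pattern. A constant TIV vector degenerates gracefully to
#' `log_only` (zero slopes).
#'
#' @param matrix A [volume_matrix()] (all entries > 0).
#' @param tiv Per-subject total intracranial volume (mL), all > 0.
#' @param mode `"log_tiv_residual"` (default) or `"log_only"`.
#' @return A plain numeric matrix of preprocessed log volumes with a
#'   `"preprocessing"` attribute (the reusable spec).
#' @export
preprocess_volumes <- function(matrix, tiv,
                               mode = c("log_tiv_residual", "log_only")) {
  mode <- match.arg(mode)
  vm <- as_volume_matrix(matrix)
  if (mode == "log_tiv_residual") {
    if (length(tiv) != nrow(vm))
      stop("tiv length (", length(tiv), ") != subject count (", nrow(vm), ")",
           call. = FALSE)
    if (any(!is.finite(tiv) | tiv <= 0))
      stop("all tiv values must be positive and finite", call. = FALSE)
  }
  logv <- log(unclass(vm))
  spec <- list(mode = mode, region_names = colnames(vm),
               slopes = stats::setNames(rep(0, ncol(vm)), colnames(vm)),
               log_tiv_center = NA_real_)
  if (mode == "log_tiv_residual") {
    lt <- log(tiv)
    ltc <- mean(lt)
    sxx <- sum((lt - ltc)^2)
    if (sxx > 0) {
      slopes <- colSums((lt - ltc) * sweep(logv, 2L, colMeans(logv))) / sxx
      logv <- logv - outer(lt - ltc, slopes)
      spec$slopes[] <- slopes
    }
    spec$log_tiv_center <- ltc
  }
  attr(logv, "preprocessing") <- spec
  logv
}

# apply a stored preprocessing spec to (possibly new) subjects
#' @noRd
apply_preprocessing <- function(spec, matrix, tiv) {
  vm <- as_volume_matrix(matrix)
  logv <- log(unclass(vm))
  if (spec$mode == "log_tiv_residual" && is.finite(spec$log_tiv_center)) {
    if (length(tiv) != nrow(vm))
      stop("tiv length != subject count", call. = FALSE)
    logv <- logv - outer(log(tiv) - spec$log_tiv_center, spec$slopes)
  }
  logv
}

#' Double-center a log-volume matrix
#'
#' Removes each subject's mean profile and each region's group mean, the
#' subject-residual-profile (SRP) construction of the Scaled Subprofile
#' Model: `srp[i,j] = x[i,j] - rowmean_i - colmean_j + grandmean`.
#'
#' @param log_matrix Numeric matrix of (preprocessed) log volumes.
#' @return Matrix with all row and column means zero; the removed column
#'   means are kept in attribute `"col_means"` for later scoring.
#' @export
double_center <- function(log_matrix) {
  x <- unclass(as.matrix(log_matrix))
  if (!all(is.finite(x))) stop("non-finite entries in log matrix", call. = FALSE)
  rm <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  srp <- x - outer(rm, rep(1, ncol(x))) - outer(rep(1, nrow(x)), cm) + gm
  attr(srp, "col_means") <- cm
  attr(srp, "preprocessing") <- attr(log_matrix, "preprocessing")
  srp
}

#' Principal components of the subject residual profiles
#'
#' Singular value decomposition of the double-centered log matrix. Columns
#' of `gis` (group-invariant subprofiles) are orthonormal regional loading
#' vectors; `ssf` (subject scaling factors) are the subject scores
#' `srp %*% gis`; eigenvalues are squared singular values divided by
#' (subjects - 1), nonincreasing. Components with numerically zero singular
#' value (the rank deficiency induced by centering) are dropped.
#'
#' @param srp Double-centered matrix from [double_center()].
#' @return List with `srp`, `gis`, `ssf`, `eigenvalues`.
#' @export
derive_components <- function(srp) {
  x <- unclass(as.matrix(srp))
  n <- nrow(x); p <- ncol(x)
  sv <- svd(x)
  if (max(sv$d) <= 0 || !any(sv$d > max(sv$d) * 1e-9)) {
    warning("degenerate all-zero residual matrix; empty decomposition",
            call. = FALSE)
    return(structure(list(srp = x, gis = matrix(0, p, 0),
                          ssf = matrix(0, n, 0), eigenvalues = numeric(0)),
                     class = "ssm_decomposition"))
  }
  keep <- sv$d > max(sv$d) * 1e-9
  gis <- sv$v[, keep, drop = FALSE]
  rownames(gis) <- colnames(x)
  ssf <- x %*% gis
  structure(list(srp = x, gis = gis, ssf = ssf,
                 eigenvalues = sv$d[keep]^2 / (n - 1)),
            class = "ssm_decomposition")
}

#' Select the prefix of components best predicting a biomarker
#'
#' For each candidate k = 1..`max_k`, fits ordinary least squares of the
#' biomarker on the first k subject scores and computes the Gaussian
#' log-likelihood AIC, `n * log(RSS/n) + 2 * (k + 2)` (slopes, intercept and
#' error variance all counted as parameters). The retained set is the
#' sequential prefix with the lowest AIC; ties go to the smallest k. The RSS
#' is floored at `1e-12 * var(biomarker) * n` so a perfect fit keeps the AIC
#' finite.
#'
#' @param ssf Subjects-by-K score matrix.
#' @param biomarker Numeric vector (finite, non-constant).
#' @param max_k Largest candidate prefix; defaults to
#'   `min(8, components explaining 90 percent of variance, K)`.
#' @param eigenvalues Optional eigenvalue vector used for the 90-percent
#'   default rule.
#' @return List with `component_set` (1..k), `combine_coefs` (slopes),
#'   `aic_trace`.
#' @export
select_component_set <- function(ssf, biomarker, max_k = NULL,
                                 eigenvalues = NULL) {
  ssf <- as.matrix(ssf)
  n <- nrow(ssf); K <- ncol(ssf)
  if (K < 1L) stop("no components to select from", call. = FALSE)
  if (length(biomarker) != n)
    stop("biomarker length != subject count", call. = FALSE)
  if (!all(is.finite(biomarker)) || stats::sd(biomarker) == 0)
    stop("biomarker must be finite with positive variance", call. = FALSE)
  if (is.null(max_k)) {
    k90 <- if (!is.null(eigenvalues) && length(eigenvalues) == K) {
      which(cumsum(eigenvalues) / sum(eigenvalues) >= 0.9)[1L]
    } else K
    max_k <- min(8L, k90, K)
  }
  max_k <- stopifnot_scalar_count(max_k, "max_k")
  if (max_k > K) stop("max_k exceeds available components (", K, ")",
                      call. = FALSE)
  floor_rss <- 1e-12 * stats::var(biomarker) * n
  aic <- numeric(max_k)
  coefs <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    X <- cbind(intercept = 1, ssf[, seq_len(k), drop = FALSE])
    fit <- ols(X, biomarker)
    rss <- max(fit$rss, floor_rss)
    aic[k] <- n * log(rss / n) + 2 * (k + 2)
    coefs[[k]] <- fit$coef[-1L]
  }
  best <- which.min(aic)  # ties resolve to smallest k
  list(component_set = seq_len(best), combine_coefs = unname(coefs[[best]]),
       aic_trace = aic)
}

#' Combine retained components into a single pattern
#'
#' Merges the retained component loadings with their regression slopes into
#' one regional weight vector, rescaled to unit norm (the scale is absorbed
#' into expression scores), with the sign chosen so that pattern expression
#' correlates non-negatively with the biomarker.
#'
#' @param decomposition An `ssm_decomposition`.
#' @param component_set Integer prefix of retained components.
#' @param combine_coefs Regression slopes merging the components.
#' @param biomarker Biomarker vector fixing the sign convention.
#' @return List with unit-norm `weights` and `sign_convention` (+1/-1).
#' @export
combine_pattern <- function(decomposition, component_set, combine_coefs,
                            biomarker) {
  w <- drop(decomposition$gis[, component_set, drop = FALSE] %*% combine_coefs)
  nrm <- sqrt(sum(w^2))
  if (nrm <= 0) stop("zero-norm combined weights", call. = FALSE)
  w <- w / nrm
  expr <- drop(decomposition$srp %*% w)
  sgn <- if (stats::sd(expr) > 0 && stats::cor(expr, biomarker) < 0) -1 else 1
  list(weights = sgn * w, sign_convention = sgn)
}

#' Derive a biomarker-predicting covariance pattern
#'
#' End-to-end Scaled Subprofile Model derivation: preprocess, double-center,
#' decompose, select the AIC-best sequential component prefix predicting the
#' biomarker, and combine into a single unit-norm regional pattern. The
#' returned model carries everything needed to score new subjects
#' identically (preprocessing spec, derivation column means, z-scoring
#' reference statistics).
#'
#' @param volumes A [volume_matrix()].
#' @param tiv Per-subject total intracranial volume.
#' @param biomarker Biomarker vector the pattern is selected to predict
#'   (plasma homocysteine in the motivating application).
#' @param mode Preprocessing mode, see [preprocess_volumes()].
#' @param max_k Largest candidate component prefix (default rule in
#'   [select_component_set()]).
#' @param log_biomarker Log-transform the biomarker before the AIC
#'   regression (off by default).
#' @return An object of class `pattern_model`.
#' @export
derive_pattern <- function(volumes, tiv, biomarker,
                           mode = c("log_tiv_residual", "log_only"),
                           max_k = NULL, log_biomarker = FALSE) {
  mode <- match.arg(mode)
  vm <- as_volume_matrix(volumes)
  if (length(biomarker) != nrow(vm))
    stop("biomarker length != subject count", call. = FALSE)
  bm <- if (log_biomarker) log_transform(biomarker) else biomarker
  pre <- preprocess_volumes(vm, tiv, mode)
  srp <- double_center(pre)
  dec <- derive_components(srp)
  if (ncol(dec$gis) == 0L) stop("degenerate volume matrix; no components",
                                call. = FALSE)
  sel <- select_component_set(dec$ssf, bm, max_k = max_k,
                              eigenvalues = dec$eigenvalues)
  cmb <- combine_pattern(dec, sel$component_set, sel$combine_coefs, bm)
  raw <- drop(dec$srp %*% cmb$weights)
  structure(list(
    weights = stats::setNames(cmb$weights, colnames(vm)),
    component_set = sel$component_set,
    combine_coefs = sel$combine_coefs,
    aic_trace = sel$aic_trace,
    sign_convention = cmb$sign_convention,
    preprocessing = attr(pre, "preprocessing"),
    col_means = attr(srp, "col_means"),
    reference_stats = c(mean = mean(raw), sd = stats::sd(raw)),
    log_biomarker = log_biomarker,
    n_derivation = nrow(vm)
  ), class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("pattern_model:", length(x$weights), "regions;",
      length(x$component_set), "component(s) retained (AIC)\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' Score pattern expression for (new) subjects
#'
#' Applies the derivation preprocessing, subtracts the derivation-sample
#' regional means, removes each subject's own mean profile, projects onto
#' the pattern weights, and z-scores against the derivation-sample reference
#' statistics (so out-of-sample subjects are scored on the derivation
#' scale). Scoring the derivation sample returns scores with mean 0 and
#' SD 1.
#'
#' @param model A `pattern_model`.
#' @param matrix A [volume_matrix()] whose regions match the model.
#' @param tiv Per-subject total intracranial volume.
#' @return List with `raw` projections, `z` scores and the model
#'   `reference_stats`.
#' @export
express_pattern <- function(model, matrix, tiv) {
  stopifnot(inherits(model, "pattern_model"))
  vm <- as_volume_matrix(matrix)
  want <- model$preprocessing$region_names
  have <- colnames(vm)
  if (!identical(sort(want), sort(have))) {
    missing <- setdiff(want, have); extra <- setdiff(have, want)
    stop("region mismatch;",
         if (length(missing)) paste0(" missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0(" extra: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  vm <- vm[, want, drop = FALSE]  # align order
  logv <- apply_preprocessing(model$preprocessing,
                              volume_matrix(unclass(vm)), tiv)
  xc <- sweep(logv, 2L, model$col_means)
  xc <- xc - rowMeans(xc)
  raw <- drop(xc %*% model$weights)
  z <- (raw - model$reference_stats[["mean"]]) / model$reference_stats[["sd"]]
  list(raw = raw, z = z, reference_stats = model$reference_stats)
}

# shared percentile interval: endpoints are order statistics of the
# replicate vector (rank floor(a*B) clamped to [1, B], and its mirror);
# the small epsilon guards the floor against floating-point alpha
#' @noRd
percentile_ci <- function(x, level) {
  x <- sort(x)
  B <- length(x)
  k_lo <- min(max(1L, as.integer(floor(B * (1 - level) / 2 + 1e-9))), B)
  k_hi <- B + 1L - k_lo
  c(lower = x[k_lo], upper = x[k_hi])
}

#' Bootstrap reliability of pattern weights
#'
#' Resamples subjects with replacement, re-derives the full pattern on each
#' replicate, aligns each replicate weight vector to the point estimate by
#' the sign of their dot product, and summarizes per-region variability:
#' bootstrap SD, Z = point weight / SD, and percentile confidence bounds.
#' Degenerate replicates (constant biomarker, rank collapse) are skipped and
#' counted; more than 5 percent failures is an error.
#'
#' @param matrix A [volume_matrix()].
#' @param tiv Total intracranial volume vector.
#' @param biomarker Biomarker vector.
#' @param n_iterations Bootstrap iterations (>= 100; 10,000 for release
#'   runs).
#' @param seed Integer seed; each replicate uses its own substream so the
#'   procedure is reproducible and extendable.
#' @param level Confidence level for the percentile bounds.
#' @param ... Passed to [derive_pattern()] (`mode`, `max_k`,
#'   `log_biomarker`).
#' @return List of class `bootstrap_reliability` with the point model and a
#'   per-region table (`weight`, `boot_sd`, `z`, `ci_lower`, `ci_upper`).
#' @export
bootstrap_pattern <- function(matrix, tiv, biomarker, n_iterations = 10000L,
                              seed = 1L, level = 0.95, ...) {
  n_iterations <- stopifnot_scalar_count(n_iterations, "n_iterations",
                                         min = 100L)
  vm <- as_volume_matrix(matrix)
  n <- nrow(vm)
  point <- derive_pattern(vm, tiv, biomarker, ...)
  w0 <- point$weights
  reps <- matrix(NA_real_, n_iterations, length(w0),
                 dimnames = list(NULL, names(w0)))
  failures <- 0L
  for (b in seq_len(n_iterations)) {
    set.seed(substream_seed(seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    wb <- tryCatch({
      m <- derive_pattern(volume_matrix(unclass(vm)[idx, , drop = FALSE],
                                        region_names = colnames(vm),
                                        subject_ids = sprintf("b%06d", seq_len(n))),
                          tiv[idx], biomarker[idx], ...)
      m$weights
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(wb)) { failures <- failures + 1L; next }
    if (sum(wb * w0) < 0) wb <- -wb
    reps[b, ] <- wb
  }
  if (failures > 0.05 * n_iterations)
    stop("bootstrap failure rate ", failures, "/", n_iterations,
         " exceeds 5%", call. = FALSE)
  ok <- stats::complete.cases(reps)
  reps <- reps[ok, , drop = FALSE]
  boot_sd <- apply(reps, 2L, stats::sd)
  cis <- apply(reps, 2L, percentile_ci, level = level)
  structure(list(
    model = point,
    n_iterations = n_iterations,
    failures = failures,
    table = data.frame(
      region = names(w0),
      weight = unname(w0),
      boot_sd = unname(boot_sd),
      z = unname(w0 / boot_sd),
      ci_lower = unname(cis["lower", ]),
      ci_upper = unname(cis["upper", ]),
      row.names = NULL, stringsAsFactors = FALSE
    )
  ), class = "bootstrap_reliability")
}

#' Average left and right homologous regions
#'
#' Collapses a bilateral volume matrix (columns labelled `L_*`/`R_*`) to one
#' column per structure by averaging hemispheres; an option for analyses
#' preferring 7 rather than 14 subcortical regions.
#'
#' @param matrix A [volume_matrix()] with `L_`/`R_` prefixed region names.
#' @return A [volume_matrix()] with one column per structure.
#' @export
average_hemispheres <- function(matrix) {
  vm <- as_volume_matrix(matrix)
  nm <- colnames(vm)
  base <- sub("^[LR]_", "", nm)
  if (!all(grepl("^[LR]_", nm)))
    stop("region names must be prefixed L_/R_", call. = FALSE)
  structs <- unique(base)
  out <- sapply(structs, function(s)
    rowMeans(unclass(vm)[, base == s, drop = FALSE]))
  volume_matrix(out, region_names = structs, subject_ids = rownames(vm))
}
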