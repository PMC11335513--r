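#' Default subcortical region set
#'
#' Seven bilateral subcortical gray-matter structures (hippocampus, amygdala,
#' thalamus, caudate, putamen, pallidum, nucleus accumbens), left then right
#' within each structure, giving the 14 regions of the default volume matrix.
#'
#' @return Character vector of 14 region labels.
#' @export
sgm_regions <- function() {
  structures <- c("hippocampus", "amygdala", "thalamus", "caudate",
                  "putamen", "pallidum", "accumbens")
  as.vector(t(outer(structures, c("L", "R"), function(s, h) paste(h, s, sep = "_"))))
}

# typical per-hemisphere volumes (mL) used as the baseline regional profile
sgm_baseline_volumes <- function() {
  rep(c(hippocampus = 4.3, amygdala = 1.7, thalamus = 7.5, caudate = 3.6,
        putamen = 4.9, pallidum = 1.8, accumbens = 0.6), each = 2)
}

#' Default covariance-pattern weights
#'
#' Unit-norm regional weight vector used to plant a homocysteine-related
#' subcortical covariance pattern: negative weights on hippocampus and
#' nucleus accumbens (volume reductions with greater pattern expression),
#' positive weights on the basal ganglia (relative preservation), near-zero
#' elsewhere.
#'
#' @return Named numeric vector of length 14 with unit Euclidean norm.
#' @export
default_pattern_weights <- function() {
  per_structure <- c(hippocampus = -0.50, amygdala = -0.10, thalamus = 0.05,
                     caudate = 0.35, putamen = 0.35, pallidum = 0.30,
                     accumbens = -0.45)
  w <- rep(per_structure, each = 2)
  names(w) <- sgm_regions()
  w / sqrt(sum(w^2))
}

#' Default standardized path coefficients
#'
#' Edge labels follow `parent_child` naming. The serial chain
#' age -> log_wmh -> expression -> parietal -> tmta_log carries the
#' hypothesized vascular pathway; direct age edges and head-size (TIV)
#' loadings on the lobar volumes complete the system. All coefficients are
#' on the standardized (correlation) scale.
#'
#' @return Named numeric vector of standardized edge coefficients.
#' @export
default_path_coefficients <- function() {
  c(
    age_log_wmh        = 0.526,
    log_wmh_expression = 0.241,
    expression_parietal = -0.186,
    age_parietal       = -0.35,
    parietal_tmta_log  = -0.409,
    age_tmta_log       = 0.246,
    # non-focal lobar volumes: weaker expression loadings, lobar age effects
    expression_frontal  = -0.116,
    expression_temporal = -0.096,
    expression_occipital = -0.092,
    age_frontal        = -0.35,
    age_temporal       = -0.30,
    age_occipital      = -0.15,
    tiv_frontal        = 0.40,
    tiv_temporal       = 0.40,
    tiv_parietal       = 0.40,
    tiv_occipital      = 0.40,
    # remaining cognitive outcomes load on age only (no planted mediation)
    age_tmtb_resid     = 0.165,
    age_srt_cltr       = -0.436
  )
}

#' Default marginal specifications
#'
#' Mean/SD pairs used to rescale each standardized variable to its reported
#' cohort marginal. WMH and TMT-A are specified on the log scale (the scale
#' on which they are analyzed); their log-scale moments are derived from the
#' raw-scale cohort mean/SD under a log-normal assumption. Plasma
#' homocysteine has no published marginal for this cohort and defaults to
#' 10 +/- 3 umol/L, typical of healthy older adults.
#'
#' @return Named list of `c(mean, sd)` pairs.
#' @export
default_marginal_specs <- function() {
  # log-normal moment matching: sd_log^2 = log(1 + (sd/mean)^2)
  lnorm_pars <- function(m, s) {
    s2 <- log(1 + (s / m)^2)
    c(mean = log(m) - s2 / 2, sd = sqrt(s2))
  }
  wmh <- lnorm_pars(6.57, 10.53)
  tmta <- lnorm_pars(32.18, 10.37)
  list(
    age           = c(mean = 69.66, sd = 9.95),
    education     = c(mean = 15.98, sd = 2.57),
    tiv           = c(mean = 1400, sd = 130),
    hcy           = c(mean = 10, sd = 3),
    b12           = c(mean = 500, sd = 200),
    vo2max        = c(mean = 22, sd = 5),
    gds           = c(mean = 1.5, sd = 2),
    interval_days = c(mean = 58.56, sd = 47.35),
    log_wmh       = c(mean = unname(wmh["mean"]), sd = unname(wmh["sd"])),
    frontal       = c(mean = 164.83, sd = 15.04),
    temporal      = c(mean = 96.83, sd = 9.62),
    parietal      = c(mean = 115.52, sd = 11.19),
    occipital     = c(mean = 44.91, sd = 5.46),
    tmta_log      = c(mean = unname(tmta["mean"]), sd = unname(tmta["sd"])),
    tmtb_resid    = c(mean = 0, sd = 1),
    srt_cltr      = c(mean = 64.62, sd = 37.07)
  )
}

#' Cohort generator configuration
#'
#' Bundles everything needed to simulate a cohort: sample size, seed,
#' marginal specifications, the planted subcortical pattern, standardized
#' path coefficients of the structural-equation chain, residual noise
#' overrides, and the loading of latent pattern expression on plasma
#' homocysteine.
#'
#' @param n_subjects Number of subjects (>= 20; the downstream models need
#'   residual degrees of freedom).
#' @param seed Integer master seed; every equation draws from its own
#'   deterministic substream so adding a variable does not perturb others.
#' @param marginal_specs Named list of `c(mean, sd)` for continuous
#'   variables; see [default_marginal_specs()].
#' @param prevalences Named vector of Bernoulli prevalences for binary
#'   covariates (`sex` codes female = 1; 86/160 female by default).
#' @param pattern_weights Unit-norm length-14 regional weight vector.
#' @param path_coefficients Named standardized edge coefficients; see
#'   [default_path_coefficients()].
#' @param noise_sds Optional named residual-SD overrides per endogenous
#'   equation (standardized scale). When absent, residual variance is set so
#'   each endogenous variable has unit population variance, making the
#'   planted coefficients exactly the population standardized betas.
#' @param hcy_loading Effect of latent pattern expression on standardized
#'   homocysteine (|loading| < 1).
#' @param pattern_scale Log-scale magnitude of the planted pattern in the
#'   subcortical volume matrix.
#' @param region_noise_sd Log-scale measurement noise SD per region.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 160L,
                          seed = 42L,
                          marginal_specs = default_marginal_specs(),
                          prevalences = c(sex = 86 / 160, apoe4 = 0.25,
                                          hypertension = 0.30, smoking = 0.30),
                          pattern_weights = default_pattern_weights(),
                          path_coefficients = default_path_coefficients(),
                          noise_sds = NULL,
                          hcy_loading = 0.5,
                          pattern_scale = 0.05,
                          region_noise_sd = 0.02) {
  n_subjects <- stopifnot_scalar_count(n_subjects, "n_subjects", min = 1L)
  if (n_subjects < 20L)
    stop("n_subjects must be at least 20 so downstream models retain ",
         "residual degrees of freedom", call. = FALSE)
  seed <- stopifnot_scalar_count(seed, "seed", min = 0L)
  if (length(pattern_weights) != 14L)
    stop("pattern_weights must have length 14", call. = FALSE)
  nrm <- sqrt(sum(pattern_weights^2))
  if (abs(nrm - 1) > 1e-6)
    stop("pattern_weights must have unit Euclidean norm", call. = FALSE)
  if (!is.null(noise_sds)) {
    if (any(noise_sds < 0)) stop("noise_sds must be non-negative", call. = FALSE)
  }
  for (nm in names(marginal_specs)) {
    sp <- marginal_specs[[nm]]
    if (length(sp) != 2L || sp[2] <= 0)
      stop("marginal spec for ", nm, " must be c(mean, sd) with sd > 0",
           call. = FALSE)
  }
  if (any(prevalences <= 0 | prevalences >= 1))
    stop("prevalences must lie strictly between 0 and 1", call. = FALSE)
  if (abs(hcy_loading) >= 1)
    stop("hcy_loading must satisfy |loading| < 1", call. = FALSE)
  if (pattern_scale < 0 || region_noise_sd < 0)
    stop("pattern_scale and region_noise_sd must be non-negative", call. = FALSE)
  structure(list(
    n_subjects = n_subjects, seed = seed, marginal_specs = marginal_specs,
    prevalences = prevalences, pattern_weights = pattern_weights,
    path_coefficients = path_coefficients, noise_sds = noise_sds,
    hcy_loading = hcy_loading, pattern_scale = pattern_scale,
    region_noise_sd = region_noise_sd
  ), class = "cohort_config")
}

# fixed equation order: substream indices and the topological order of the
# structural system both derive from this table
cohort_equations <- function(path) {
  # each endogenous variable lists its structural parents; coefficients are
  # looked up as "<parent>_<child>" in path_coefficients (0 when absent)
  exo <- c("age", "tiv", "sex", "education", "apoe4", "hypertension",
           "smoking", "b12", "vo2max", "gds", "interval_days")
  endo <- list(
    log_wmh    = c("age"),
    expression = c("log_wmh"),
    frontal    = c("tiv", "age", "expression"),
    temporal   = c("tiv", "age", "expression"),
    parietal   = c("tiv", "age", "expression"),
    occipital  = c("tiv", "age", "expression"),
    tmta_log   = c("age", "parietal"),
    tmtb_resid = c("age"),
    srt_cltr   = c("age")
  )
  list(exogenous = exo, endogenous = endo)
}

#' Generate a synthetic cohort
#'
#' Simulates a cohort table and a subjects-by-regions subcortical volume
#' matrix from a linear-Gaussian structural-equation system. Endogenous
#' variables are generated in topological order as a weighted sum of their
#' standardized parents plus Gaussian noise; by default the residual
#' variance of each equation is chosen so every variable has unit population
#' variance, which makes the configured path coefficients exactly the
#' population standardized regression coefficients. Each variable is then
#' rescaled affinely to its marginal specification. The volume matrix is a
#' TIV-proportional regional baseline with the unit-norm pattern planted on
#' the log scale, scaled by the latent `true_expression`, plus log-scale
#' region noise. Plasma homocysteine loads on `true_expression` with
#' configurable strength.
#'
#' The returned table retains the hidden `true_expression` column (population
#' standardized scale) for parameter-recovery tests.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cohort` (data.frame, one row per subject)
#'   and `volumes` (a [volume_matrix()] of positive volumes in mL).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  eqs <- cohort_equations()
  path <- config$path_coefficients
  specs <- config$marginal_specs
  prev <- config$prevalences

  stream_names <- c(eqs$exogenous, names(eqs$endogenous),
                    "hcy", "volumes_noise")
  stream_of <- stats::setNames(seq_along(stream_names), stream_names)
  draw <- function(stream, fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(substream_seed(config$seed, stream_of[[stream]]))
    fn()
  }

  z <- list()     # standardized values
  S <- diag(length(eqs$exogenous))  # population covariance bookkeeping
  dimnames(S) <- list(eqs$exogenous, eqs$exogenous)

  for (v in eqs$exogenous) {
    if (v %in% names(prev)) {
      b <- draw(v, function() stats::rbinom(n, 1L, prev[[v]]))
      # standardized version used if a binary ever parents an equation
      z[[v]] <- (b - prev[[v]]) / sqrt(prev[[v]] * (1 - prev[[v]]))
      attr(z[[v]], "raw01") <- b
    } else {
      z[[v]] <- draw(v, function() stats::rnorm(n))
    }
  }

  for (v in names(eqs$endogenous)) {
    parents <- eqs$endogenous[[v]]
    beta <- vapply(parents, function(p) {
      unname(path[paste(p, v, sep = "_")] %||% NA_real_)
    }, numeric(1))
    beta[is.na(beta)] <- 0
    sys_var <- if (length(parents))
      drop(t(beta) %*% S[parents, parents, drop = FALSE] %*% beta) else 0
    sd_e <- if (!is.null(config$noise_sds) && v %in% names(config$noise_sds)) {
      config$noise_sds[[v]]
    } else {
      if (sys_var >= 1)
        stop("path coefficients into '", v, "' imply systematic variance ",
             signif(sys_var, 4), " >= 1; reduce them or supply noise_sds",
             call. = FALSE)
      sqrt(1 - sys_var)
    }
    sys <- if (length(parents)) {
      Reduce(`+`, Map(function(p, b) b * as.numeric(z[[p]]), parents, beta))
    } else rep(0, n)
    eps <- draw(v, function() stats::rnorm(n))
    z[[v]] <- sys + sd_e * eps
    # extend covariance bookkeeping
    cov_new <- drop(S[, parents, drop = FALSE] %*% beta)
    S <- rbind(cbind(S, cov_new), c(cov_new, sys_var + sd_e^2))
    rownames(S)[nrow(S)] <- colnames(S)[ncol(S)] <- v
  }

  # homocysteine loads on latent expression
  lam <- config$hcy_loading
  z$hcy <- lam * z$expression +
    sqrt(max(0, 1 - lam^2)) * draw("hcy", function() stats::rnorm(n))

  rescale <- function(v) {
    sp <- specs[[v]]
    sp[["mean"]] + sp[["sd"]] * as.numeric(z[[v]])
  }
  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = rescale("age"),
    sex = attr(z$sex, "raw01"),
    education = rescale("education"),
    tiv = rescale("tiv"),
    hcy = rescale("hcy"),
    b12 = rescale("b12"),
    apoe4 = attr(z$apoe4, "raw01"),
    hypertension = attr(z$hypertension, "raw01"),
    smoking = attr(z$smoking, "raw01"),
    vo2max = rescale("vo2max"),
    gds = rescale("gds"),
    interval_days = rescale("interval_days"),
    log_wmh = rescale("log_wmh"),
    frontal = rescale("frontal"),
    temporal = rescale("temporal"),
    parietal = rescale("parietal"),
    occipital = rescale("occipital"),
    tmta_log = rescale("tmta_log"),
    tmtb_resid = rescale("tmtb_resid"),
    srt_cltr = rescale("srt_cltr"),
    true_expression = as.numeric(z$expression),
    stringsAsFactors = FALSE
  )
  if (any(cohort$tiv <= 0))
    stop("simulated TIV non-positive; marginal spec for tiv is unrealistic",
         call. = FALSE)

  # subcortical volumes: TIV-proportional baseline, planted pattern on the
  # log scale, per-region log-scale noise
  baseline <- sgm_baseline_volumes()
  regions <- sgm_regions()
  tiv_ref <- specs$tiv[["mean"]]
  log_base <- outer(log(cohort$tiv / tiv_ref), log(baseline), `+`)
  noise <- draw("volumes_noise",
                function() matrix(stats::rnorm(n * length(regions)),
                                  n, length(regions)))
  logv <- log_base + config$region_noise_sd * noise
  vm <- volume_matrix(exp(logv), region_names = regions,
                      subject_ids = cohort$subject_id)
  vm <- plant_pattern(vm, config$pattern_weights, cohort$true_expression,
                      config$pattern_scale)
  list(cohort = cohort, volumes = vm)
}

#' Plant a covariance pattern into a volume matrix
#'
#' Adds `scale * outer(expression, weights)` to the matrix on the log scale
#' and returns a new matrix; the input is not modified. Used by the cohort
#' generator and by pattern-recovery tests.
#'
#' @param matrix A [volume_matrix()] of positive volumes.
#' @param weights Regional weight vector (length = number of regions).
#' @param expression Per-subject expression vector (length = number of
#'   subjects).
#' @param scale Log-scale magnitude of the planted effect.
#' @return A new `volume_matrix`.
#' @export
plant_pattern <- function(matrix, weights, expression, scale) {
  vm <- as_volume_matrix(matrix)
  if (length(weights) != ncol(vm))
    stop("weights length (", length(weights), ") != region count (",
         ncol(vm), ")", call. = FALSE)
  if (length(expression) != nrow(vm))
    stop("expression length (", length(expression), ") != subject count (",
         nrow(vm), ")", call. = FALSE)
  out <- exp(log(unclass(vm)) + scale * outer(as.numeric(expression),
                                              as.numeric(weights)))
  volume_matrix(out, region_names = colnames(vm), subject_ids = rownames(vm))
}
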