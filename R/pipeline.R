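#' Study pipeline configuration
#'
#' Configures the end-to-end analysis: where the data come from (a synthetic
#' cohort configuration, or paths to a cohort CSV and a volume-matrix CSV),
#' the nested covariate tiers, the outcome families, bootstrap settings and
#' gating behaviour.
#'
#' Covariate tiers are nested in the incremental-adjustment order of the
#' study design: `base` (TIV, sex, education), then cardiovascular /
#' Alzheimer risk factors (`extended`: APOE e4, hypertension, smoking,
#' VO2max), then vitamin B12, then depression rating; cognition models add
#' the assessment time interval to every tier.
#'
#' @param simulate A [cohort_config()] used to generate data, or `NULL` when
#'   reading from files.
#' @param cohort_file,volumes_file CSV paths used when `simulate` is `NULL`.
#' @param lobar_outcomes Lobar gray-matter-volume outcome columns (the FDR
#'   family).
#' @param cognitive_outcomes Cognitive outcome columns for the 3-mediator
#'   models.
#' @param biomarker Column whose prediction selects the pattern components.
#' @param n_boot Bootstrap iterations for mediation (10,000 for release
#'   runs; scale down for tests).
#' @param n_boot_pattern Bootstrap iterations for pattern reliability; 0
#'   skips that stage.
#' @param seed Master seed for all stochastic stages.
#' @param fdr_level Gating threshold on FDR-adjusted p-values.
#' @param gate Run mediation only for FDR-significant lobes (override with
#'   `FALSE` for exploratory runs).
#' @param mode SSM preprocessing mode.
#' @return Object of class `study_config`.
#' @export
study_config <- function(simulate = cohort_config(),
                         cohort_file = NULL, volumes_file = NULL,
                         lobar_outcomes = c("frontal", "temporal",
                                            "parietal", "occipital"),
                         cognitive_outcomes = c("srt_cltr", "tmtb_resid",
                                                "tmta_log"),
                         biomarker = "hcy",
                         n_boot = 10000L, n_boot_pattern = 0L,
                         seed = 7L, fdr_level = 0.05, gate = TRUE,
                         mode = c("log_tiv_residual", "log_only")) {
  mode <- match.arg(mode)
  if (is.null(simulate) && (is.null(cohort_file) || is.null(volumes_file)))
    stop("either a simulation config or both input files are required",
         call. = FALSE)
  tiers <- list(
    base = c("tiv", "sex", "education"),
    extended = c("tiv", "sex", "education",
                 "apoe4", "hypertension", "smoking", "vo2max"),
    b12 = c("tiv", "sex", "education",
            "apoe4", "hypertension", "smoking", "vo2max", "b12")
  )
  structure(list(
    simulate = simulate, cohort_file = cohort_file,
    volumes_file = volumes_file, lobar_outcomes = lobar_outcomes,
    cognitive_outcomes = cognitive_outcomes, biomarker = biomarker,
    tiers = tiers, n_boot = as.integer(n_boot),
    n_boot_pattern = as.integer(n_boot_pattern),
    seed = as.integer(seed), fdr_level = fdr_level, gate = isTRUE(gate),
    mode = mode
  ), class = "study_config")
}

#' Run the full study pipeline
#'
#' Executes the analysis stages in order on synthetic or user-supplied
#' tables:
#' 1. obtain the cohort table and subcortical volume matrix;
#' 2. derive the biomarker-predicting covariance pattern and score
#'    per-subject expression (added as column `expression`);
#' 3. block-wise regressions of the lobar volumes on expression
#'    (block 1 = TIV, block 2 = age, sex, education) with
#'    Benjamini-Hochberg correction across the lobar family;
#' 4. for each FDR-significant lobe (gating rule, overridable), the
#'    2-mediator serial model age -> WMH -> expression -> lobe across the
#'    nested covariate tiers;
#' 5. 3-mediator models age -> WMH -> expression -> parietal -> cognition
#'    for each cognitive outcome (time interval added to the covariates),
#'    at the base and fully adjusted tiers, plus a depression-adjusted
#'    follow-up for the processing-speed outcome;
#' 6. reversed-mediator sensitivity model;
#' 7. follow-up regressions of the biomarker on each risk factor.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    invisible(msg)
  }

  # stage 0: data
  if (!is.null(config$simulate)) {
    gen <- generate_cohort(config$simulate)
    cohort <- gen$cohort; volumes <- gen$volumes
    say("data: simulated cohort, n = ", nrow(cohort),
        ", seed = ", config$simulate$seed)
  } else {
    cohort <- read_cohort_csv(config$cohort_file)
    volumes <- read_volume_csv(config$volumes_file)
    say("data: read from files, n = ", nrow(cohort))
  }
  need <- unique(c("age", "tiv", "log_wmh", config$biomarker,
                   config$lobar_outcomes, config$cognitive_outcomes,
                   unlist(config$tiers), "interval_days"))
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  # stage 1: pattern derivation and expression
  model <- derive_pattern(volumes, cohort$tiv, cohort[[config$biomarker]],
                          mode = config$mode)
  cohort$expression <- express_pattern(model, volumes, cohort$tiv)$z
  say("pattern: ", length(model$component_set), " component(s) retained")
  reliability <- NULL
  if (config$n_boot_pattern >= 100L) {
    reliability <- bootstrap_pattern(volumes, cohort$tiv,
                                     cohort[[config$biomarker]],
                                     n_iterations = config$n_boot_pattern,
                                     seed = config$seed, mode = config$mode)
    say("pattern reliability: ", config$n_boot_pattern, " iterations, ",
        reliability$failures, " failures")
  }

  # stage 2: lobar regressions with FDR
  blocks <- list("tiv", c("age", "sex", "education"))
  table2 <- regression_table(cohort, config$lobar_outcomes,
                             focal = "expression", blocks = blocks)
  sig_lobes <- table2$outcome[table2$p_fdr < config$fdr_level]
  say("regressions: FDR-significant lobes: ",
      if (length(sig_lobes)) paste(sig_lobes, collapse = ", ") else "none")

  gated <- if (config$gate) sig_lobes else config$lobar_outcomes
  run_med <- function(y, mediators, covs, seed_shift) {
    spec <- mediation_spec("age", y, mediators, covs,
                           n_boot = config$n_boot, seed = config$seed + seed_shift)
    bootstrap_mediation(cohort, spec)
  }

  # stage 3: 2-mediator models per gated lobe, across covariate tiers
  lobar_mediation <- list()
  if (length(gated)) {
    for (lb in gated) {
      lobar_mediation[[lb]] <- lapply(seq_along(config$tiers), function(ti)
        run_med(lb, c("log_wmh", "expression"), config$tiers[[ti]], ti))
      names(lobar_mediation[[lb]]) <- names(config$tiers)
    }
  } else {
    say("gating: no FDR-significant lobes; mediation stage skipped")
  }

  # stage 4: 3-mediator cognition models (interval added to covariates)
  cognition_mediation <- NULL
  sensitivity <- NULL
  if (length(gated)) {
    med3 <- c("log_wmh", "expression", "parietal")
    cognition_mediation <- lapply(config$cognitive_outcomes, function(y) {
      covs_base <- c(config$tiers$base, "interval_days")
      covs_full <- c(config$tiers$b12, "interval_days")
      out <- list(base = run_med(y, med3, covs_base, 10L),
                  full = run_med(y, med3, covs_full, 11L))
      if (y == "tmta_log")
        out$gds <- run_med(y, med3, c(covs_full, "gds"), 12L)
      out
    })
    names(cognition_mediation) <- config$cognitive_outcomes

    # stage 5: reversed-order sensitivity on the fully adjusted lobar model
    spec_rev <- reverse_mediators(
      mediation_spec("age", gated[[1L]], c("log_wmh", "expression"),
                     config$tiers$b12, n_boot = config$n_boot,
                     seed = config$seed + 20L))
    sensitivity <- bootstrap_mediation(cohort, spec_rev)
    say("sensitivity: reversed mediators on ", gated[[1L]])
  }

  # stage 6: biomarker vs risk factors
  followup <- hcy_riskfactor_followup(cohort, biomarker = config$biomarker)

  provenance <- list(
    seed = config$seed,
    timestamp = format(t0, "%Y-%m-%d %H:%M:%S"),
    package_version = as.character(utils::packageVersion("hcysgm")),
    r_version = R.version.string,
    config_json = config_fingerprint(config)
  )
  structure(list(
    config = config, cohort = cohort, volumes = volumes,
    pattern = model, reliability = reliability,
    regressions = table2, significant_lobes = sig_lobes,
    lobar_mediation = lobar_mediation,
    cognition_mediation = cognition_mediation,
    sensitivity = sensitivity, followup = followup,
    provenance = provenance, log = log_lines
  ), class = "study_report")
}

# deterministic config fingerprint for provenance (content hash of the
# canonical JSON serialization; avoids an external digest dependency)
#' @noRd
config_fingerprint <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null", force = TRUE)
  bytes <- utf8ToInt(as.character(json))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Biomarker versus risk-factor follow-up regressions
#'
#' For each cardiovascular / Alzheimer risk factor, regresses the biomarker
#' on the factor alone and with demographic adjustment (age, sex,
#' education), returning coefficients and p-values. A perfectly collinear
#' factor is flagged rather than silently dropped.
#'
#' @param data Cohort data frame.
#' @param risk_factors Factor columns to test.
#' @param demographics Demographic adjustment set.
#' @param biomarker Biomarker column.
#' @return Data frame with one row per (factor, model) pair.
#' @export
hcy_riskfactor_followup <- function(data,
                                    risk_factors = c("apoe4", "hypertension",
                                                     "smoking", "vo2max"),
                                    demographics = c("age", "sex", "education"),
                                    biomarker = "hcy") {
  miss <- setdiff(c(biomarker, risk_factors, demographics), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  rows <- list()
  for (rf in risk_factors) {
    for (mode in c("unadjusted", "adjusted")) {
      preds <- if (mode == "adjusted") c(rf, demographics) else rf
      vars <- c(biomarker, preds)
      df0 <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
      X <- cbind(`(Intercept)` = 1, as.matrix(df0[, preds, drop = FALSE]))
      fit <- ols(X, df0[[biomarker]])
      rows[[length(rows) + 1L]] <- data.frame(
        factor = rf, model = mode, B = fit$coef[[rf]], SE = fit$se[[rf]],
        t = fit$t[[rf]], df = fit$df, p = fit$p[[rf]], n = nrow(df0),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (config ", x$provenance$config_json, ")\n", sep = "")
  for (l in x$log) cat(" -", l, "\n")
  cat("\nLobar regression table:\n")
  print(x$regressions[c("outcome", "beta", "B", "SE", "p", "p_fdr")],
        digits = 3)
  invisible(x)
}
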