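#' Read and write cohort tables and volume matrices
#'
#' Cohort tables are plain CSV with a header row, one row per subject.
#' Volume matrices are CSV with the subject identifier in the first column
#' and one column per region.
#'
#' @param path File path.
#' @param x Object to write.
#' @return `read_cohort_csv` returns a data.frame; `read_volume_csv` a
#'   [volume_matrix()]; writers return the path invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_volume_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  volume_matrix(m, region_names = colnames(m), subject_ids = ids)
}

#' @rdname cohort_io
#' @export
write_volume_csv <- function(x, path) {
  vm <- as_volume_matrix(x)
  df <- data.frame(subject_id = rownames(vm), unclass(vm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a pattern model to JSON and back
#'
#' The JSON carries the regional weights, retained component set, combining
#' coefficients, AIC trace, sign convention, preprocessing spec, derivation
#' column means and z-scoring reference statistics: everything needed to
#' score new subjects identically.
#'
#' @param model A `pattern_model`.
#' @param path File path.
#' @return `read_pattern_json` returns a `pattern_model`; the writer returns
#'   the path invisibly.
#' @name pattern_io
NULL

#' @rdname pattern_io
#' @export
write_pattern_json <- function(model, path) {
  stopifnot(inherits(model, "pattern_model"))
  obj <- unclass(model)
  # named atomic vectors serialize as name-dropping arrays; keep names via lists
  obj$weights <- as.list(obj$weights)
  obj$col_means <- as.list(obj$col_means)
  obj$reference_stats <- as.list(obj$reference_stats)
  obj$preprocessing$slopes <- as.list(obj$preprocessing$slopes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pattern_io
#' @export
read_pattern_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights <- unlist(obj$weights)
  obj$col_means <- unlist(obj$col_means)
  obj$reference_stats <- unlist(obj$reference_stats)
  obj$preprocessing$slopes <- unlist(obj$preprocessing$slopes)
  structure(obj, class = "pattern_model")
}

#' Write a mediation result
#'
#' `write_mediation_json` stores the full result (paths, indirect-effect
#' table, total/direct effects); `write_mediation_csv` stores the flat
#' per-path table.
#'
#' @param result A `mediation_result`.
#' @param path File path.
#' @return The path, invisibly.
#' @name mediation_io
NULL

#' @rdname mediation_io
#' @export
write_mediation_json <- function(result, path) {
  stopifnot(inherits(result, "mediation_result"))
  paths <- result$paths
  obj <- list(
    spec = unclass(result$spec),
    coefficients = list(a = paths$a, d = paths$d, b = paths$b,
                        c_prime = paths$c_prime, c = paths$c,
                        std = paths$std),
    indirects = result$indirects[setdiff(names(result$indirects), "indices")],
    total = as.list(result$total), direct = as.list(result$direct),
    n_used = result$n_used, boot_failures = result$boot_failures
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname mediation_io
#' @export
write_mediation_csv <- function(result, path) {
  stopifnot(inherits(result, "mediation_result"))
  tab <- result$indirects[setdiff(names(result$indirects), "indices")]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write the study report to a directory
#'
#' Emits `pattern.json`, `table2.csv`, one `mediation_*.csv`/`.json` pair
#' per fitted model, `followup.csv`, `report.md` and `log.txt`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pattern_json(report$pattern, file.path(dir, "pattern.json"))
  utils::write.csv(report$regressions, file.path(dir, "table2.csv"),
                   row.names = FALSE)
  emit <- function(res, stem) {
    write_mediation_csv(res, file.path(dir, paste0(stem, ".csv")))
    write_mediation_json(res, file.path(dir, paste0(stem, ".json")))
  }
  for (lb in names(report$lobar_mediation))
    for (tier in names(report$lobar_mediation[[lb]]))
      emit(report$lobar_mediation[[lb]][[tier]],
           paste0("mediation_", lb, "_", tier))
  for (y in names(report$cognition_mediation))
    for (tier in names(report$cognition_mediation[[y]]))
      emit(report$cognition_mediation[[y]][[tier]],
           paste0("mediation_", y, "_", tier))
  if (!is.null(report$sensitivity))
    emit(report$sensitivity, "mediation_reversed_sensitivity")
  utils::write.csv(report$followup, file.path(dir, "followup.csv"),
                   row.names = FALSE)
  md <- c(
    "# Study report",
    "",
    paste0("Config fingerprint: ", report$provenance$config_json,
           "; seed: ", report$provenance$seed),
    "",
    "## Pattern",
    paste0("Components retained: ",
           paste(report$pattern$component_set, collapse = ", ")),
    "",
    "## Lobar regressions (final block)",
    paste(utils::capture.output(print(
      report$regressions[c("outcome", "beta", "B", "SE", "p", "p_fdr")],
      digits = 4)), collapse = "\n"),
    "",
    paste0("FDR-significant lobes: ",
           if (length(report$significant_lobes))
             paste(report$significant_lobes, collapse = ", ") else "none")
  )
  writeLines(md, file.path(dir, "report.md"))
  writeLines(c(report$log,
               paste0("generated: ", report$provenance$timestamp)),
             file.path(dir, "log.txt"))
  invisible(dir)
}
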