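#' Subjects-by-regions volume matrix
#'
#' A thin matrix class for ROI volume tables: rows are subjects, columns are
#' regions, entries are strictly positive volumes (mL). Labels must be
#' unique; a warning is issued when there are fewer subjects than regions
#' (the covariance analysis is then poorly determined).
#'
#' @param values Numeric matrix (subjects x regions), all entries > 0.
#' @param region_names Column labels; defaults to existing colnames.
#' @param subject_ids Row labels; defaults to existing rownames.
#' @return A `volume_matrix` object (a classed numeric matrix).
#' @export
volume_matrix <- function(values, region_names = colnames(values),
                          subject_ids = rownames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric", call. = FALSE)
  if (ncol(values) < 2L) stop("at least 2 regions required", call. = FALSE)
  if (is.null(region_names))
    region_names <- paste0("region_", seq_len(ncol(values)))
  if (is.null(subject_ids))
    subject_ids <- paste0("subj_", seq_len(nrow(values)))
  if (anyDuplicated(region_names)) stop("duplicated region names", call. = FALSE)
  if (anyDuplicated(subject_ids)) stop("duplicated subject ids", call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    show <- utils::head(apply(bad, 1L, function(ij)
      paste0("[", subject_ids[ij[1]], ", ", region_names[ij[2]], "]")), 5L)
    stop("non-positive or non-finite volume at ",
         paste(show, collapse = ", "),
         if (nrow(bad) > 5L) sprintf(" (and %d more)", nrow(bad) - 5L),
         call. = FALSE)
  }
  if (nrow(values) < ncol(values))
    warning("fewer subjects (", nrow(values), ") than regions (",
            ncol(values), "); covariance analysis will be unstable",
            call. = FALSE)
  dimnames(values) <- list(subject_ids, region_names)
  class(values) <- c("volume_matrix", "matrix", "array")
  values
}

#' @export
print.volume_matrix <- function(x, ...) {
  cat("volume_matrix:", nrow(x), "subjects x", ncol(x), "regions\n")
  cat("regions:", paste(utils::head(colnames(x), 6L), collapse = ", "),
      if (ncol(x) > 6L) "...", "\n")
  invisible(x)
}

#' @noRd
as_volume_matrix <- function(x) {
  if (inherits(x, "volume_matrix")) return(x)
  volume_matrix(x)
}
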