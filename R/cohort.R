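#' The nine demographic variables, in canonical order
#'
#' Age and education are continuous; the rest are binary (0/1). `sex` is
#' coded 1 = female, and `stenosis_side_right` 1 = severe stenosis or
#' occlusion on the right middle cerebral artery.
#' @return Character vector of length 9.
#' @export
demographic_fields <- function() {
  c("age", "sex", "education_years", "hypertension", "diabetes",
    "hyperlipidemia", "smoker", "drinker", "stenosis_side_right")
}

#' Construct one subject's multimodal record
#'
#' Bundles the four post-preprocessing modality blocks for a single subject:
#' the regional BOLD time-series matrix (N regions x M time points), the
#' symmetric white-matter fiber-count matrix (N x N, zero diagonal), the
#' regional gray-matter volume vector (N, mm^3), and the nine demographic
#' variables. Validation is strict: downstream network construction assumes
#' these invariants.
#'
#' @param subject_id Character scalar.
#' @param time_series Numeric N x M matrix of BOLD signal (M >= 3).
#' @param fiber_counts Numeric N x N symmetric nonnegative matrix with zero
#'   diagonal. Asymmetry up to 1e-8 is averaged away; larger is an error.
#' @param roi_volumes Positive numeric vector of length N.
#' @param demographics Named list or one-row data frame with the fields of
#'   [demographic_fields()].
#' @param label `NA`, `0` (no cognitive impairment) or `1` (MCI).
#' @return A list of class `brainfuse_subject`.
#' @export
subject_record <- function(subject_id, time_series, fiber_counts, roi_volumes,
                           demographics, label = NA_integer_) {
  stopifnot(is.character(subject_id), length(subject_id) == 1)
  time_series <- as.matrix(time_series)
  fiber_counts <- as.matrix(fiber_counts)
  roi_volumes <- as.numeric(roi_volumes)
  n <- nrow(time_series)
  if (ncol(time_series) < 3) {
    stop("subject ", subject_id, ": need at least 3 time points", call. = FALSE)
  }
  if (!all(is.finite(time_series))) {
    stop("subject ", subject_id, ": non-finite BOLD values", call. = FALSE)
  }
  if (!all(dim(fiber_counts) == c(n, n))) {
    stop("subject ", subject_id, ": fiber_counts must be ", n, " x ", n,
         " to match the time series", call. = FALSE)
  }
  asym <- max(abs(fiber_counts - t(fiber_counts)))
  if (asym > 1e-8) {
    stop("subject ", subject_id, ": fiber_counts asymmetric (max |D - t(D)| = ",
         format(asym), ")", call. = FALSE)
  }
  fiber_counts <- (fiber_counts + t(fiber_counts)) / 2
  if (any(fiber_counts < 0) || any(diag(fiber_counts) != 0)) {
    stop("subject ", subject_id,
         ": fiber_counts must be nonnegative with zero diagonal", call. = FALSE)
  }
  if (length(roi_volumes) != n || any(!is.finite(roi_volumes)) ||
      any(roi_volumes <= 0)) {
    stop("subject ", subject_id, ": roi_volumes must be ", n,
         " positive finite values", call. = FALSE)
  }
  demographics <- as.list(demographics)
  missing <- setdiff(demographic_fields(), names(demographics))
  if (length(missing)) {
    stop("subject ", subject_id, ": missing demographic field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  demographics <- demographics[demographic_fields()]
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("subject ", subject_id, ": label must be 0 (NMCI), 1 (MCI) or NA",
         call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, time_series = time_series,
         fiber_counts = fiber_counts, roi_volumes = roi_volumes,
         demographics = demographics,
         label = if (is.na(label)) NA_integer_ else as.integer(label)),
    class = "brainfuse_subject"
  )
}

#' Assemble subjects into a cohort
#'
#' @param atlas A [region_atlas()] whose region count matches every block.
#' @param subjects List of [subject_record()]s; order is preserved
#'   everywhere downstream.
#' @return A list of class `brainfuse_cohort`.
#' @export
cohort <- function(atlas, subjects) {
  stopifnot(inherits(atlas, "brainfuse_atlas"), is.list(subjects))
  n <- n_regions(atlas)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (s in subjects) {
    if (nrow(s$time_series) != n) {
      stop("subject ", s$subject_id, ": ", nrow(s$time_series),
           " regions but atlas has ", n, call. = FALSE)
    }
  }
  labs <- vapply(subjects, function(s) s$label, integer(1))
  if (!anyNA(labs)) {
    if (min(table(factor(labs, levels = 0:1))) < 2) {
      stop("need at least 2 subjects per class", call. = FALSE)
    }
  }
  structure(list(atlas = atlas, subjects = subjects),
            class = "brainfuse_cohort")
}

cohort_labels <- function(x) {
  vapply(x$subjects, function(s) s$label, integer(1))
}

cohort_ids <- function(x) {
  vapply(x$subjects, function(s) s$subject_id, character(1))
}

#' @export
print.brainfuse_cohort <- function(x, ...) {
  labs <- cohort_labels(x)
  cat("<brainfuse_cohort> ", length(x$subjects), " subjects, ",
      n_regions(x$atlas), " regions (", sum(labs == 1, na.rm = TRUE), " MCI / ",
      sum(labs == 0, na.rm = TRUE), " NMCI",
      if (anyNA(labs)) ", some unlabeled", ")\n", sep = "")
  invisible(x)
}

#' @export
print.brainfuse_subject <- function(x, ...) {
  cat("<brainfuse_subject> ", x$subject_id, ": ", nrow(x$time_series),
      " regions x ", ncol(x$time_series), " time points, label = ",
      if (is.na(x$label)) "NA" else x$label, "\n", sep = "")
  invisible(x)
}

#' Demographics of a cohort as a tibble
#'
#' One row per subject, in cohort order, with `subject_id`, `label` and the
#' nine demographic variables.
#' @param x A `brainfuse_cohort`.
#' @return A tibble.
#' @export
cohort_demographics <- function(x) {
  stopifnot(inherits(x, "brainfuse_cohort"))
  dplyr::bind_cols(
    tibble::tibble(subject_id = cohort_ids(x), label = cohort_labels(x)),
    purrr::map_dfr(x$subjects, function(s) tibble::as_tibble(s$demographics))
  )
}
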