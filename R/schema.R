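#' Build a feature schema
#'
#' A schema declares, for every feature column of a cohort table, whether it
#' is a numeric lab-test value or an integer-coded questionnaire response,
#' the declared level range for questionnaire features, and whether domain
#' experts flag the feature as informative for fatty liver disease.
#'
#' @param feature Character vector of feature names.
#' @param kind `"numeric"` or `"categorical"`, recycled if length 1.
#' @param levels Integer count of categorical levels (levels are coded
#'   `0 .. levels - 1`); `NA` for numeric features.
#' @param expert Logical expert flag, recycled if length 1.
#'
#' @return A tibble with columns `feature`, `kind`, `levels`, `expert`.
#' @export
#' @examples
#' fld_schema(c("bmi", "smoke"), c("numeric", "categorical"), c(NA, 3))
fld_schema <- function(feature, kind, levels = NA_integer_, expert = FALSE) {
  kind <- rep_len(kind, length(feature))
  levels <- rep_len(as.integer(levels), length(feature))
  expert <- rep_len(expert, length(feature))
  if (!all(kind %in% c("numeric", "categorical"))) {
    abort("schema kind must be 'numeric' or 'categorical'")
  }
  if (anyDuplicated(feature)) abort("duplicated feature names in schema")
  bad <- kind == "categorical" & (is.na(levels) | levels < 2L)
  if (any(bad)) {
    abort(sprintf("categorical feature(s) need >= 2 declared levels: %s",
                  paste(feature[bad], collapse = ", ")))
  }
  tibble::tibble(
    feature = as.character(feature),
    kind = kind,
    levels = ifelse(kind == "categorical", levels, NA_integer_),
    expert = expert
  )
}

#' @export
#' @rdname fld_schema
#' @param cohort A cohort table created by [simulate_cohort()] or
#'   [read_cohort()].
cohort_schema <- function(cohort) {
  sch <- attr(cohort, "schema")
  if (is.null(sch)) abort("table carries no schema attribute")
  sch
}

#' Names of the planted informative features of a synthetic cohort
#'
#' Only synthetic cohorts carry ground truth; for cohorts read from disk
#' without one this returns `NULL`.
#'
#' @inheritParams cohort_schema
#' @return Character vector of feature names, or `NULL`.
#' @export
cohort_ground_truth <- function(cohort) attr(cohort, "informative")

new_fld_cohort <- function(visits, schema, informative = NULL) {
  stray <- setdiff(feature_cols(visits), schema$feature)
  if (length(stray) > 0) {
    abort(sprintf("feature column(s) missing from schema: %s",
                  paste(stray, collapse = ", ")))
  }
  structure(
    visits,
    schema = schema[schema$feature %in% names(visits), , drop = FALSE],
    informative = informative,
    class = c("fld_cohort", class(tibble::as_tibble(visits)))
  )
}

#' @export
print.fld_cohort <- function(x, ...) {
  sch <- attr(x, "schema")
  cat(sprintf("<fld_cohort> %d visits, %d subjects, %d features\n",
              nrow(x), dplyr::n_distinct(x$subject_id), nrow(sch)))
  NextMethod()
}
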