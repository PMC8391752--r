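#' Write / read a cohort as CSV with a JSON schema sidecar
#'
#' The on-disk format is a long CSV (one row per visit) with the meta
#' columns `subject_id, gender, birth_year, visit_year, visit_month,
#' fld_label` followed by one column per feature; empty cells are missing
#' values. The schema (feature kinds, declared level counts, expert flags)
#' travels in a JSON sidecar so a file round-trips without guessing types.
#'
#' @param cohort An `fld_cohort` table.
#' @param path CSV file path.
#' @param schema_path JSON sidecar path; defaults to `path` with a
#'   `.schema.json` extension.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns an `fld_cohort`.
#' @export
write_cohort <- function(cohort, path,
                         schema_path = paste0(path, ".schema.json")) {
  sch <- cohort_schema(cohort)
  readr::write_csv(tibble::as_tibble(cohort), path, na = "")
  jsonlite::write_json(
    list(schema = sch,
         informative = cohort_ground_truth(cohort) %||% character(0)),
    schema_path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema_path = paste0(path, ".schema.json")) {
  meta <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  sch <- tibble::as_tibble(meta$schema)
  if (!"levels" %in% names(sch)) sch$levels <- NA_integer_
  if (!"expert" %in% names(sch)) sch$expert <- FALSE
  sch$levels <- as.integer(sch$levels)
  sch$expert[is.na(sch$expert)] <- FALSE
  sch <- sch[, c("feature", "kind", "levels", "expert")]
  visits <- readr::read_csv(
    path,
    col_types = do.call(readr::cols, c(
      list(subject_id = readr::col_character(),
           gender = readr::col_factor(levels = c("male", "female")),
           birth_year = readr::col_integer(),
           visit_year = readr::col_integer(),
           visit_month = readr::col_integer(),
           fld_label = readr::col_factor(levels = FLD_LEVELS)),
      setNames(rep(list(readr::col_double()), nrow(sch)), sch$feature)
    )),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  attr(visits, "spec") <- NULL
  attr(visits, "problems") <- NULL
  missing_meta <- setdiff(META_COLS, names(visits))
  if (length(missing_meta) > 0) {
    abort(sprintf("cohort file lacks column(s): %s",
                  paste(missing_meta, collapse = ", ")))
  }
  validate_visit_structure(visits)
  informative <- meta$informative
  if (length(informative) == 0) informative <- NULL
  new_fld_cohort(visits, sch, informative = informative)
}

## per-subject structural invariants shared by read_cohort and tests
validate_visit_structure <- function(visits) {
  if (nrow(visits) == 0) return(invisible(visits))
  idx <- month_index(visits$visit_year, visits$visit_month)
  bad <- visits |>
    dplyr::mutate(.idx = idx) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$.idx, .by_group = TRUE) |>
    dplyr::summarise(dup = anyDuplicated(.data$.idx) > 0, .groups = "drop") |>
    dplyr::filter(.data$dup)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "duplicated (subject, visit date) row(s) for subject(s): %s",
      paste(head(bad$subject_id, 5), collapse = ", ")
    ))
  }
  invisible(visits)
}

#' One subject's ordered visit history
#'
#' @param cohort An `fld_cohort` or plain visit table.
#' @param subject A `subject_id` value.
#' @return The subject's visits sorted by date (a tibble).
#' @export
subject_history <- function(cohort, subject) {
  h <- dplyr::filter(tibble::as_tibble(cohort), .data$subject_id == subject)
  if (nrow(h) == 0) abort(sprintf("no visits for subject '%s'", subject))
  dplyr::arrange(h, month_index(.data$visit_year, .data$visit_month))
}
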