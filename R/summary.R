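#' NFLD/FLD class-size ratio
#'
#' The field's convention for these screening cohorts: the count of
#' NFLD-labelled visits divided by the count of FLD-labelled visits.
#'
#' @param labels A vector of `"NFLD"`/`"FLD"` labels, or the NFLD count if
#'   `fld` is given.
#' @param fld FLD count (when calling with two counts).
#' @return The ratio; `Inf` (with a warning) when no FLD visits exist.
#' @export
#' @examples
#' class_ratio(34885, 53171) # 0.66
#' class_ratio(48574, 23990) # 2.02
class_ratio <- function(labels, fld = NULL) {
  if (is.null(fld)) {
    labels <- as_fld_factor(labels)
    nfld <- sum(labels == "NFLD", na.rm = TRUE)
    fld <- sum(labels == "FLD", na.rm = TRUE)
  } else {
    nfld <- labels
  }
  if (fld == 0) {
    warn("no FLD cases; class ratio reported as Inf")
    return(Inf)
  }
  nfld / fld
}

#' Imbalance factor of a label vector
#'
#' Count of the bigger class divided by count of the smaller class.
#'
#' @param labels `"NFLD"`/`"FLD"` labels.
#' @return A ratio `>= 1`; `Inf` with a warning if one class is absent.
#' @export
imbalance_factor <- function(labels) {
  labels <- as_fld_factor(labels)
  counts <- table(labels)
  if (any(counts == 0)) {
    warn("one class absent; imbalance factor reported as Inf")
    return(Inf)
  }
  max(counts) / min(counts)
}

#' Descriptive summary of a cohort
#'
#' Computes the descriptive statistics used to characterise a screening
#' cohort: per-year visit counts by gender, per-gender and per-gender-year
#' NFLD/FLD class ratios, per-feature missingness, and the yearly mean of a
#' named feature broken down by label and gender (the "BMI progression"
#' view).
#'
#' @param cohort A non-empty `fld_cohort`.
#' @param progression_feature Feature for the yearly-mean panel (default
#'   `"bmi"` when present, else the first feature).
#' @return An `fld_cohort_summary` list of tibbles:
#'   `yearly_counts`, `class_ratios`, `yearly_class_ratios`, `missingness`,
#'   `progression`.
#' @export
cohort_summary <- function(cohort, progression_feature = NULL) {
  if (nrow(cohort) == 0) abort("cohort is empty")
  tab <- tibble::as_tibble(cohort)
  feats <- feature_cols(tab)
  if (is.null(progression_feature)) {
    progression_feature <- if ("bmi" %in% feats) "bmi" else feats[1]
  }
  assert_features_present(tab, progression_feature)

  yearly_counts <- tab |>
    dplyr::count(.data$visit_year, .data$gender, name = "visits")

  ratio_of <- function(d) {
    nfld <- sum(d == "NFLD")
    fld <- sum(d == "FLD")
    if (fld == 0) Inf else nfld / fld
  }
  class_ratios <- tab |>
    dplyr::group_by(.data$gender) |>
    dplyr::summarise(nfld = sum(.data$fld_label == "NFLD"),
                     fld = sum(.data$fld_label == "FLD"),
                     ratio = ratio_of(.data$fld_label), .groups = "drop")
  yearly_class_ratios <- tab |>
    dplyr::group_by(.data$visit_year, .data$gender) |>
    dplyr::summarise(ratio = ratio_of(.data$fld_label), .groups = "drop")

  missingness <- tibble::tibble(
    feature = feats,
    missing_fraction = vapply(feats, function(f) mean(is.na(tab[[f]])),
                              numeric(1))
  )

  progression <- tab |>
    dplyr::group_by(.data$visit_year, .data$gender, .data$fld_label) |>
    dplyr::summarise(
      mean_value = mean(.data[[progression_feature]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(feature = progression_feature)

  structure(
    list(yearly_counts = yearly_counts,
         class_ratios = class_ratios,
         yearly_class_ratios = yearly_class_ratios,
         missingness = missingness,
         progression = progression,
         n_visits = nrow(tab),
         n_subjects = dplyr::n_distinct(tab$subject_id)),
    class = "fld_cohort_summary"
  )
}

#' @export
print.fld_cohort_summary <- function(x, ...) {
  cat(sprintf("<fld_cohort_summary> %d visits / %d subjects\n",
              x$n_visits, x$n_subjects))
  cat("Class ratios (NFLD/FLD):\n")
  print(x$class_ratios)
  invisible(x)
}
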