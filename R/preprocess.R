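## Preprocessing: drop -> impute -> consolidate -> z-score.
## Each step returns a table of the same shape contract and keeps the schema
## attribute in sync; normalisation refuses to run before imputation.

keep_cohort_attrs <- function(new, old, schema = NULL) {
  sch <- schema %||% attr(old, "schema")
  new_fld_cohort(new, sch[sch$feature %in% names(new), , drop = FALSE],
                 informative = attr(old, "informative"))
}

#' Drop features by name
#'
#' Configured deletion of useless or redundant features. Names not present
#' (or listed twice) raise a warning, not an error: drop lists are
#' configuration that may outlive a schema.
#'
#' @param table An `fld_cohort` table.
#' @param names Character vector of feature names to remove.
#' @return The table without those columns; column order preserved.
#' @export
drop_features <- function(table, names) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    warn("duplicated names in drop list; each feature removed once")
    names <- unique(names)
  }
  absent <- setdiff(names, feature_cols(table))
  if (length(absent) > 0) {
    warn(sprintf("drop list names not present: %s",
                 paste(absent, collapse = ", ")))
  }
  keep_cohort_attrs(
    dplyr::select(tibble::as_tibble(table), -dplyr::any_of(names)), table
  )
}

#' Drop features with too many missing values
#'
#' Features whose missing fraction is `>= threshold` are eliminated — such
#' features are too sparse to impute meaningfully.
#'
#' @param table An `fld_cohort` table.
#' @param threshold Missing-fraction cut-off in `(0, 1]`; default 0.9.
#' @return A list: `table` (surviving features) and `dropped` (names).
#' @export
drop_high_missing <- function(table, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  feats <- feature_cols(table)
  frac <- vapply(feats, function(f) mean(is.na(table[[f]])), numeric(1))
  dropped <- feats[frac >= threshold]
  out <- keep_cohort_attrs(
    dplyr::select(tibble::as_tibble(table), -dplyr::all_of(dropped)), table
  )
  list(table = out, dropped = dropped)
}

#' Mean/mode imputation
#'
#' Missing numeric cells are replaced by the column mean of the observed
#' values; missing questionnaire cells by the column mode (ties broken
#' toward the smallest level, deterministically). Observed values are never
#' altered.
#'
#' @param table An `fld_cohort` table.
#' @param schema Feature schema; defaults to the table's own.
#' @return The imputed table (no missing feature cells remain).
#' @export
impute_features <- function(table, schema = cohort_schema(table)) {
  out <- tibble::as_tibble(table)
  for (f in feature_cols(out)) {
    x <- out[[f]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      abort(sprintf("cannot impute column '%s': all values missing", f))
    }
    kind <- schema$kind[match(f, schema$feature)]
    fill <- if (identical(kind, "categorical")) stat_mode(x) else {
      mean(x, na.rm = TRUE)
    }
    x[is.na(x)] <- fill
    out[[f]] <- x
  }
  res <- keep_cohort_attrs(out, table, schema = schema)
  attr(res, "imputed") <- TRUE
  res
}

#' Consolidation rule for questionnaire items
#'
#' Derives one numeric feature from several questionnaire items as a gated
#' weighted product: `gate != 0` times the product of `weight[j] *
#' source[j]`. This reproduces how composite screening features such as
#' weekly alcohol grams (type x amount x density, zeroed for non-drinkers)
#' or weekly exercise metabolic equivalent (frequency x duration x
#' intensity) are built from questionnaire responses.
#'
#' @param name Name of the derived feature.
#' @param sources Character vector of source feature names.
#' @param weights Numeric coefficients, recycled over `sources`.
#' @param gate Optional name of a 0/1 gating item (e.g. "drinks or not").
#' @return A `consolidation_rule` object for [consolidate_features()].
#' @export
consolidation_rule <- function(name, sources, weights = 1, gate = NULL) {
  structure(list(name = name, sources = as.character(sources),
                 weights = rep_len(weights, length(sources)), gate = gate),
            class = "consolidation_rule")
}

#' Apply consolidation rules
#'
#' Each rule adds its derived numeric column and removes its source columns
#' (and gate column) from the table and schema.
#'
#' @param table An `fld_cohort` table.
#' @param rules A list of [consolidation_rule()] objects.
#' @return The consolidated table.
#' @export
consolidate_features <- function(table, rules) {
  if (inherits(rules, "consolidation_rule")) rules <- list(rules)
  out <- tibble::as_tibble(table)
  sch <- cohort_schema(table)
  for (rule in rules) {
    needed <- c(rule$sources, rule$gate)
    absent <- setdiff(needed, names(out))
    if (length(absent) > 0) {
      abort(sprintf("rule '%s' references missing column(s): %s",
                    rule$name, paste(absent, collapse = ", ")))
    }
    value <- rep(1, nrow(out))
    for (j in seq_along(rule$sources)) {
      value <- value * rule$weights[j] * out[[rule$sources[j]]]
    }
    if (!is.null(rule$gate)) value <- value * as.numeric(out[[rule$gate]] != 0)
    out <- dplyr::select(out, -dplyr::all_of(needed))
    out[[rule$name]] <- value
    sch <- sch[!sch$feature %in% needed, , drop = FALSE]
    sch <- rbind(sch, fld_schema(rule$name, "numeric"))
  }
  keep_cohort_attrs(out, table, schema = sch)
}

#' Z-score normalisation with training-only statistics
#'
#' Every feature value is replaced by \eqn{(x - \bar{x})/S}, where the
#' sample mean \eqn{\bar{x}} and standard deviation \eqn{S} are computed
#' from the designated fitting rows only — held-out rows are transformed
#' with the fitted statistics, never their own, so no test-set information
#' leaks into the normalisation. Must run after imputation.
#'
#' @param table An imputed `fld_cohort` table.
#' @param fit_rows Logical or integer row selector for the fitting subset;
#'   default all rows (whole-data normalisation).
#' @return The normalised table; the fitted per-feature statistics are
#'   attached as attribute `"norm_stats"` (a tibble `feature`, `mean`,
#'   `sd`).
#' @export
normalize_features <- function(table, fit_rows = NULL) {
  feats <- feature_cols(table)
  has_na <- vapply(feats, function(f) anyNA(table[[f]]), logical(1))
  if (any(has_na)) {
    abort(sprintf(
      "normalisation requires imputation first; missing values in: %s",
      paste(feats[has_na], collapse = ", ")
    ))
  }
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(table))
  if (is.logical(fit_rows)) fit_rows <- which(fit_rows)
  if (length(fit_rows) == 0) abort("fit_rows selects no rows")
  out <- tibble::as_tibble(table)
  stats <- tibble::tibble(feature = feats, mean = NA_real_, sd = NA_real_)
  constant <- character(0)
  for (i in seq_along(feats)) {
    f <- feats[i]
    xb <- mean(out[[f]][fit_rows])
    s <- sd(out[[f]][fit_rows])
    stats$mean[i] <- xb
    stats$sd[i] <- s
    if (is.na(s) || s == 0) {
      constant <- c(constant, f)
      out[[f]] <- rep(0, nrow(out))
    } else {
      out[[f]] <- (out[[f]] - xb) / s
    }
  }
  if (length(constant) > 0) {
    warn(sprintf("constant feature(s) on the fitting subset mapped to 0: %s",
                 paste(constant, collapse = ", ")))
  }
  res <- keep_cohort_attrs(out, table)
  attr(res, "imputed") <- TRUE
  attr(res, "norm_stats") <- stats
  res
}

#' @rdname normalize_features
#' @param table A normalised table.
#' @export
norm_stats <- function(table) {
  s <- attr(table, "norm_stats")
  if (is.null(s)) abort("table has not been normalised")
  s
}
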