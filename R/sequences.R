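## Turning irregular visit histories into sequence-classification samples.
##
## Two encodings: "fs1" resamples each history to a monthly grid and emits
## fixed 12-step windows predicting 12 months ahead; "fs2" keeps the raw
## visits and prepends two timing inputs per step (months since the
## previous visit, months to the prediction point), so a d-feature visit
## becomes a step of width d + 2.

new_samples <- function(rows) {
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      encoding = character(0), subject_id = character(0),
      input = list(), target = factor(character(0), levels = FLD_LEVELS),
      prev_label = factor(character(0), levels = FLD_LEVELS),
      anchor_index = integer(0), horizon = integer(0), n_steps = integer(0)
    )
  }
  class(out) <- c("fld_samples", class(tibble::tibble()))
  out
}

#' Extract prefix/target pairs from a visit history
#'
#' A history of `N` visits yields `N - 1` training pairs: the first `i`
#' visits as input and visit `i + 1` as the prediction target, for
#' `i = 1 .. N-1`. Subjects with a single visit yield nothing and are
#' thereby discarded from next-visit prediction.
#'
#' @param history One subject's visits (rows sorted by date; see
#'   [subject_history()]).
#' @return A tibble with one row per pair: `n_prefix`, `prefix`
#'   (list-column of visit tibbles), `target` (list-column of one-row
#'   tibbles).
#' @export
extract_prefix_pairs <- function(history) {
  history <- dplyr::arrange(tibble::as_tibble(history),
                            month_index(.data$visit_year, .data$visit_month))
  n <- nrow(history)
  if (n <= 1) {
    return(tibble::tibble(n_prefix = integer(0), prefix = list(),
                          target = list()))
  }
  tibble::tibble(
    n_prefix = seq_len(n - 1),
    prefix = lapply(seq_len(n - 1), function(i) history[seq_len(i), ]),
    target = lapply(seq_len(n - 1), function(i) history[i + 1, ])
  )
}

## direction-aware integer rounding for interpolated levels: exact halves
## round toward the later visit's value
round_toward <- function(vals, from, to) {
  if (to >= from) floor(vals + 0.5) else ceiling(vals - 0.5)
}

#' Resample a visit history to a monthly grid
#'
#' Numeric features are interpolated with a shape-preserving piecewise
#' cubic (monotone Hermite, `splinefun(method = "monoH.FC")`), which passes
#' through every observed visit exactly, never overshoots between
#' monotone observations, and degenerates to linear interpolation when only
#' two visits exist. Questionnaire features and the FLD label are linearly
#' interpolated and rounded to the nearest integer level, exact halves
#' rounding toward the later visit's value; levels are clamped to the
#' schema's declared range.
#'
#' @param history One subject's visits, at least two, with no missing
#'   feature values (impute first).
#' @param schema Feature schema; defaults to the history's cohort schema.
#' @return An `fld_monthly` tibble: one row per calendar month from first
#'   to last visit, with `month_index`, `is_visit`, the features, and
#'   `fld_label`.
#' @export
interpolate_monthly <- function(history, schema = NULL) {
  schema <- schema %||% attr(history, "schema")
  if (is.null(schema)) abort("interpolate_monthly needs a feature schema")
  h <- dplyr::arrange(tibble::as_tibble(history),
                      month_index(.data$visit_year, .data$visit_month))
  if (nrow(h) < 2) abort("monthly interpolation needs at least two visits")
  feats <- intersect(schema$feature, names(h))
  if (anyNA(h[, feats])) {
    abort("history contains missing feature values; impute before encoding")
  }
  tv <- month_index(h$visit_year, h$visit_month)
  if (anyDuplicated(tv)) abort("duplicate visit months in history")
  grid <- seq(tv[1], tv[length(tv)])

  out <- tibble::tibble(
    subject_id = h$subject_id[1],
    month_index = grid,
    visit_year = index_to_year(grid),
    visit_month = index_to_month(grid),
    is_visit = grid %in% tv
  )

  interp_levels <- function(y, lo, hi) {
    vals <- numeric(length(grid))
    for (s in seq_len(length(tv) - 1)) {
      seg <- grid >= tv[s] & grid <= tv[s + 1]
      frac <- (grid[seg] - tv[s]) / (tv[s + 1] - tv[s])
      vals[seg] <- round_toward(y[s] + frac * (y[s + 1] - y[s]),
                                y[s], y[s + 1])
    }
    pmin(pmax(vals, lo), hi)
  }

  for (f in feats) {
    kind <- schema$kind[match(f, schema$feature)]
    if (identical(kind, "categorical")) {
      lv <- schema$levels[match(f, schema$feature)]
      out[[f]] <- interp_levels(h[[f]], 0, lv - 1)
    } else {
      out[[f]] <- stats::splinefun(tv, h[[f]], method = "monoH.FC")(grid)
    }
  }
  out$fld_label <- factor(
    ifelse(interp_levels(as.integer(h$fld_label == "FLD"), 0, 1) == 1,
           "FLD", "NFLD"),
    levels = FLD_LEVELS
  )
  structure(out, schema = schema,
            class = c("fld_monthly", class(tibble::tibble())))
}

#' Fixed-interval (fs1) window samples from a monthly series
#'
#' Moving 12-step monthly windows predicting the label `horizon` months
#' past the anchor. Anchors advance by `stride` and are admissible only
#' while the target month stays within the observed series (no sample has a
#' fabricated target). When the series is long enough the first anchor sits
#' at month `window`, so inputs are fully observed; a series shorter than
#' `window + horizon` months still yields one sample anchored at its last
#' admissible month, with the input back-filled by duplicating the earliest
#' month.
#'
#' @param series An `fld_monthly` series from [interpolate_monthly()].
#' @param features Feature columns to include as the `d` input channels.
#' @param window Input length in months (steps), default 12.
#' @param horizon Months ahead of the anchor to predict, default 12.
#' @param stride Anchor step in months, default 1.
#' @param include_label Append the (interpolated) label as an extra input
#'   channel; off by default so the model cannot shortcut through label
#'   persistence.
#' @return An `fld_samples` tibble; every `input` matrix has exactly
#'   `window` rows.
#' @export
build_fs1_samples <- function(series, features, window = 12, horizon = 12,
                              stride = 1, include_label = FALSE) {
  assert_features_present(series, features)
  series <- dplyr::arrange(tibble::as_tibble(series), .data$month_index)
  m_total <- nrow(series)
  m_max <- m_total - horizon
  if (m_max < 1) return(new_samples(list()))
  m_min <- min(window, m_max)
  anchors <- seq(m_min, m_max, by = stride)
  x <- as.matrix(series[, features, drop = FALSE])
  if (include_label) {
    x <- cbind(x, .label = as.integer(series$fld_label == "FLD"))
  }
  rows <- lapply(anchors, function(m) {
    idx <- pmax(seq(m - window + 1, m), 1) # back-fill before month 1
    tibble::tibble(
      encoding = "fs1",
      subject_id = series$subject_id[1],
      input = list(x[idx, , drop = FALSE]),
      target = series$fld_label[m + horizon],
      prev_label = series$fld_label[m],
      anchor_index = series$month_index[m],
      horizon = as.integer(horizon),
      n_steps = as.integer(window)
    )
  })
  new_samples(rows)
}

#' Variable-interval (fs2) samples from a raw visit history
#'
#' One sample per prefix pair (see [extract_prefix_pairs()]): the steps are
#' the prefix visits in order, and each step vector is
#' `[months since previous visit, months to the target visit, features]` —
#' width `d + 2`. The first step's elapsed time is 0 (no previous visit);
#' the time-to-target is counted from the prefix's *last* visit and is the
#' same on every step. The encoding is lossless for timing: the visit
#' dates and horizon are reconstructible from the two extra inputs.
#'
#' @param history One subject's visits (>= 2, imputed).
#' @param features Feature columns for the `d` channels.
#' @param include_label Append each prefix visit's own FLD label (0/1) as
#'   an extra input channel. Past diagnoses are known at prediction time,
#'   so this is legitimate history — but it hands the model the persistence
#'   shortcut, so it is off by default.
#' @return An `fld_samples` tibble with `n_steps` = 1, 2, ..., N-1.
#' @export
build_fs2_samples <- function(history, features, include_label = FALSE) {
  assert_features_present(history, features)
  h <- dplyr::arrange(tibble::as_tibble(history),
                      month_index(.data$visit_year, .data$visit_month))
  n <- nrow(h)
  if (n <= 1) return(new_samples(list()))
  if (anyNA(h[, features])) {
    abort("history contains missing feature values; impute before encoding")
  }
  tv <- month_index(h$visit_year, h$visit_month)
  dt <- c(0L, diff(tv))
  x <- as.matrix(h[, features, drop = FALSE])
  if (include_label) {
    x <- cbind(x, .label = as.integer(h$fld_label == "FLD"))
  }
  rows <- lapply(seq_len(n - 1), function(i) {
    horizon <- tv[i + 1] - tv[i]
    input <- cbind(dt_prev = dt[seq_len(i)],
                   dt_target = rep(horizon, i),
                   x[seq_len(i), , drop = FALSE])
    tibble::tibble(
      encoding = "fs2",
      subject_id = h$subject_id[1],
      input = list(input),
      target = h$fld_label[i + 1],
      prev_label = h$fld_label[i],
      anchor_index = tv[i],
      horizon = as.integer(horizon),
      n_steps = i
    )
  })
  new_samples(rows)
}

#' Build next-visit-prediction samples for a whole cohort
#'
#' Maps the per-subject encoders over every multi-visit subject. Subjects
#' with a single visit are discarded (they carry no next visit).
#'
#' @param cohort An imputed `fld_cohort`.
#' @param features Feature columns to encode.
#' @param encoding `"fs2"` (raw visits + timing inputs) or `"fs1"`
#'   (monthly interpolation + moving windows).
#' @param ... Passed to the per-subject encoder: `include_label` for
#'   either encoding; `window`, `horizon`, `stride` for `"fs1"`.
#' @return An `fld_samples` tibble over the cohort.
#' @export
build_nvp_samples <- function(cohort, features = NULL,
                              encoding = c("fs2", "fs1"), ...) {
  encoding <- match.arg(encoding)
  features <- features %||% feature_cols(cohort)
  tab <- tibble::as_tibble(cohort)
  tab$.midx <- month_index(tab$visit_year, tab$visit_month)
  tab <- dplyr::arrange(tab, .data$subject_id, .data$.midx)
  tab$.midx <- NULL
  schema <- attr(cohort, "schema")
  histories <- split(tab, tab$subject_id)
  rows <- lapply(histories, function(h) {
    if (nrow(h) < 2) return(NULL)
    if (encoding == "fs2") {
      build_fs2_samples(h, features, ...)
    } else {
      build_fs1_samples(interpolate_monthly(h, schema), features, ...)
    }
  })
  new_samples(rows)
}

#' Stratified train/validation/test split of sequence samples
#'
#' Partitions samples into train/validation/test, stratified by the target
#' label. With `group_by_subject = TRUE` (the default) all samples of one
#' subject land in the same partition — windowed samples from one history
#' overlap heavily, and letting them straddle the split would leak
#' near-duplicates into the test set. Grouped allocation is greedy by
#' subject sample count, so realized fractions are approximate; with
#' `group_by_subject = FALSE` (sample-level splitting, as windowed-pair
#' pipelines often do) per-stratum counts are exact to +-1 sample.
#'
#' @param samples An `fld_samples` tibble.
#' @param train_frac Fraction for training (validation carved from it).
#' @param val_frac_of_train Fraction *of the training portion* held out for
#'   validation.
#' @param stratify Stratify by target label (default TRUE).
#' @param group_by_subject Keep each subject within one partition.
#' @param seed Integer seed; same seed, same split.
#' @return A list of `fld_samples`: `train`, `val`, `test`.
#' @export
split_samples <- function(samples, train_frac = 0.7, val_frac_of_train = 0.1,
                          stratify = TRUE, group_by_subject = TRUE,
                          seed = 1) {
  if (train_frac <= 0 || train_frac >= 1 ||
      val_frac_of_train < 0 || val_frac_of_train >= 1) {
    abort("fractions must lie in (0, 1)")
  }
  n <- nrow(samples)
  if (n == 0) abort("no samples to split")
  strata <- if (stratify) as.character(samples$target) else rep("all", n)
  small <- names(which(table(strata) < 3))
  if (length(small) > 0) {
    warn(sprintf("stratum(s) with < 3 samples assigned best-effort: %s",
                 paste(small, collapse = ", ")))
  }
  with_preserved_seed(seed, {
    in_train <- logical(n)
    if (group_by_subject) {
      subj <- samples$subject_id
      ## stratify subjects by their majority target, allocate greedily by
      ## sample count until the stratum's train quota is met
      subj_tab <- tibble::tibble(subject = subj, stratum = strata) |>
        dplyr::count(.data$subject, .data$stratum) |>
        dplyr::group_by(.data$subject) |>
        dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
        dplyr::ungroup()
      sizes <- table(subj)[subj_tab$subject]
      for (s in unique(subj_tab$stratum)) {
        rows_s <- which(subj_tab$stratum == s)
        rows_s <- shuffle(rows_s)
        quota <- train_frac * sum(sizes[rows_s])
        cum <- cumsum(as.numeric(sizes[rows_s]))
        take <- rows_s[cum <= quota | seq_along(rows_s) == 1]
        in_train[subj %in% subj_tab$subject[take]] <- TRUE
      }
    } else {
      for (s in unique(strata)) {
        idx <- which(strata == s)
        take <- sample(idx, round(train_frac * length(idx)))
        in_train[take] <- TRUE
      }
    }
    train_idx <- which(in_train)
    test_idx <- which(!in_train)
    ## validation carved out of the training portion, same grouping logic
    in_val <- logical(length(train_idx))
    if (val_frac_of_train > 0 && length(train_idx) > 0) {
      tr_strata <- strata[train_idx]
      if (group_by_subject) {
        tr_subj <- samples$subject_id[train_idx]
        for (s in unique(tr_strata)) {
          subj_s <- unique(tr_subj[tr_strata == s])
          subj_s <- shuffle(subj_s)
          sz <- table(tr_subj)[subj_s]
          quota <- val_frac_of_train * sum(tr_strata == s)
          cum <- cumsum(as.numeric(sz))
          take <- subj_s[cum <= quota]
          in_val[tr_subj %in% take] <- TRUE
        }
      } else {
        for (s in unique(tr_strata)) {
          idx <- which(tr_strata == s)
          in_val[sample(idx, round(val_frac_of_train * length(idx)))] <- TRUE
        }
      }
    }
    list(
      train = samples[train_idx[!in_val], ],
      val = samples[train_idx[in_val], ],
      test = samples[test_idx, ]
    )
  })
}
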