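#' Train on one table, evaluate on another (current-visit prediction)
#'
#' Fits the classifier on the training rows only and reports confusion
#' counts, accuracy, precision, recall, F1 and AUROC on the test rows, FLD
#' positive. AUROC uses the classifier's continuous score (class
#' probability; vote fraction for k-NN).
#'
#' @param train,test Feature tables sharing columns; both non-empty.
#' @param classifier An [fld_classifier()] or classifier name.
#' @param features Feature columns to use; default all shared feature
#'   columns.
#' @param seed Seed for stochastic learners (forests, boosting).
#' @return An [eval_report()] (`fld_eval`).
#' @export
train_eval_cvp <- function(train, test, classifier = fld_classifier("knn"),
                           features = NULL, seed = 1) {
  if (is.character(classifier)) classifier <- fld_classifier(classifier)
  if (nrow(train) == 0 || nrow(test) == 0) {
    abort("train and test tables must be non-empty")
  }
  features <- features %||% intersect(feature_cols(train), feature_cols(test))
  assert_features_present(train, features)
  assert_features_present(test, features)
  with_preserved_seed(seed, {
    fit <- classifier_fit(classifier,
                          tibble::as_tibble(train)[, features, drop = FALSE],
                          train$fld_label)
    pred <- classifier_predict(fit,
                               tibble::as_tibble(test)[, features,
                                                       drop = FALSE])
    eval_report(test$fld_label, pred$label, pred$score)
  })
}

#' Sweep over training-year windows
#'
#' For each candidate window — by default every suffix of the available
#' years ending the year before `test_year` — this runs feature selection
#' *inside the window only*, trains the classifier on the window's visits,
#' and evaluates on the held-out test year. The test year never enters
#' selection or training. The best window maximises test accuracy; ties go
#' to the longest window.
#'
#' @param cohort A preprocessed `fld_cohort` table.
#' @param test_year Held-out calendar year.
#' @param classifier Classifier for train/eval, default k-NN.
#' @param select_k Features to select per window; `NULL` disables per-window
#'   selection and uses all features.
#' @param select_classifier,select_spec Classifier and [eval_spec()] for
#'   the per-window feature selection (defaults: k-NN with leave-one-out).
#' @param windows Optional list of `c(start, end)` year pairs overriding
#'   the suffix construction.
#' @param seed Seed passed to [train_eval_cvp()].
#' @return An `fld_sweep`: tibble of per-window results plus the best
#'   window; see [tidy()] and [autoplot()].
#' @export
year_window_sweep <- function(cohort, test_year,
                              classifier = fld_classifier("knn"),
                              select_k = 24,
                              select_classifier = fld_classifier("knn"),
                              select_spec = eval_spec("loo"),
                              windows = NULL, seed = 1) {
  tab <- tibble::as_tibble(cohort)
  years <- sort(unique(tab$visit_year))
  if (length(years) < 2) abort("need at least two distinct visit years")
  test <- dplyr::filter(tab, .data$visit_year == test_year)
  if (nrow(test) == 0) abort(sprintf("no visits in test year %d", test_year))
  if (is.null(windows)) {
    starts <- years[years < test_year]
    windows <- lapply(starts, function(s) c(s, test_year - 1L))
  }
  rows <- purrr::map(windows, function(w) {
    train <- dplyr::filter(tab, .data$visit_year >= w[1],
                           .data$visit_year <= w[2])
    if (nrow(train) == 0) {
      warn(sprintf("window %d-%d is empty; skipped", w[1], w[2]))
      return(NULL)
    }
    train <- keep_cohort_attrs(train, cohort)
    feats <- feature_cols(train)
    if (!is.null(select_k)) {
      sel <- opr_rank(train, select_classifier, select_spec,
                      k = min(select_k, length(feats)))
      feats <- sel$selected
    }
    rep_ <- train_eval_cvp(train, test, classifier, features = feats,
                           seed = seed)
    tibble::tibble(
      window_start = w[1], window_end = w[2], n_train = nrow(train),
      accuracy = rep_$accuracy, auroc = rep_$auroc, f1 = rep_$f1,
      features = list(feats), report = list(rep_)
    )
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0) abort("all windows were empty")
  span <- res$window_end - res$window_start
  best <- which(res$accuracy == max(res$accuracy))
  best <- best[which.max(span[best])] # ties -> longest window
  structure(list(results = res, best = res[best, ], test_year = test_year),
            class = "fld_sweep")
}

#' @export
print.fld_sweep <- function(x, ...) {
  cat(sprintf("<fld_sweep> test year %d\n", x$test_year))
  print(dplyr::select(x$results, -"features", -"report"))
  cat(sprintf("best window: %d-%d (accuracy %.4f)\n",
              x$best$window_start, x$best$window_end, x$best$accuracy))
  invisible(x)
}

#' @export
tidy.fld_sweep <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$results, -"features", -"report"),
    best = .data$window_start == x$best$window_start
  )
}

#' Age-split (menopause/andropause) analysis
#'
#' Splits visits at each age threshold into "before" (age at visit below
#' the threshold) and "after" subsets, then trains and evaluates
#' independently inside each subset (training years vs a held-out test
#' year). Age at visit is `visit_year - birth_year`. Hormonal protection
#' hypotheses predict a before/after accuracy gap that is larger for women.
#'
#' @param cohort A preprocessed `fld_cohort`.
#' @param age_thresholds Integer vector; default 53–57.
#' @param classifier Default Gaussian naive Bayes.
#' @param train_years `c(first, last)` training-year range.
#' @param test_year Held-out year.
#' @param features Features to use; default all.
#' @param seed Seed for stochastic learners.
#' @return A tibble with one row per (threshold, side): `threshold`,
#'   `side`, `n_train`, `n_test`, `accuracy`, `auroc`, `report`
#'   (list-column). Empty subsets are reported with `NA` metrics, not
#'   errors.
#' @export
menopause_split <- function(cohort, age_thresholds = 53:57,
                            classifier = fld_classifier("gaussian_nb"),
                            train_years, test_year, features = NULL,
                            seed = 1) {
  tab <- tibble::as_tibble(cohort)
  tab$.age <- tab$visit_year - tab$birth_year
  purrr::map_dfr(age_thresholds, function(thr) {
    purrr::map_dfr(c("before", "after"), function(side) {
      sub <- if (side == "before") {
        dplyr::filter(tab, .data$.age < thr)
      } else {
        dplyr::filter(tab, .data$.age >= thr)
      }
      train <- dplyr::filter(sub, .data$visit_year >= train_years[1],
                             .data$visit_year <= train_years[2])
      test <- dplyr::filter(sub, .data$visit_year == test_year)
      base <- tibble::tibble(threshold = thr, side = side,
                             n_train = nrow(train), n_test = nrow(test))
      ok <- nrow(train) > 0 && nrow(test) > 0 &&
        dplyr::n_distinct(train$fld_label) == 2
      if (!ok) {
        return(dplyr::mutate(base, accuracy = NA_real_, auroc = NA_real_,
                             report = list(NULL)))
      }
      rep_ <- train_eval_cvp(dplyr::select(train, -".age"),
                             dplyr::select(test, -".age"),
                             classifier, features = features, seed = seed)
      dplyr::mutate(base, accuracy = rep_$accuracy, auroc = rep_$auroc,
                    report = list(rep_))
    })
  })
}
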