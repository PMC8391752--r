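#' Evaluation scheme for wrapper feature selection
#'
#' @param scheme `"loo"` (leave-one-out), `"kfold"`, or `"holdout"`.
#' @param k Number of folds for `"kfold"` (`>= 2`).
#' @param train_rows,test_rows Row indices for `"holdout"`.
#' @param seed Seed controlling fold assignment (folds depend only on the
#'   seed and the row count, so every candidate feature set is scored on
#'   identical splits).
#' @return An `eval_spec` object.
#' @export
eval_spec <- function(scheme = c("loo", "kfold", "holdout"), k = 3,
                      train_rows = NULL, test_rows = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold" && k < 2) abort("k-fold evaluation needs k >= 2")
  if (scheme == "holdout" &&
      (is.null(train_rows) || is.null(test_rows))) {
    abort("holdout evaluation needs train_rows and test_rows")
  }
  structure(list(scheme = scheme, k = as.integer(k),
                 train_rows = train_rows, test_rows = test_rows, seed = seed),
            class = "eval_spec")
}

## classification accuracy of `classifier` on feature columns `feats`,
## under the evaluation scheme; the single costed "evaluation" of the
## wrapper methods
wrapper_accuracy <- function(table, feats, classifier, spec) {
  x <- as.data.frame(tibble::as_tibble(table)[, feats, drop = FALSE])
  y <- as_fld_factor(table$fld_label)
  n <- nrow(x)
  acc <- tryCatch({
    if (spec$scheme == "loo" && classifier$name == "knn") {
      ## fast path: C implementation of LOO k-NN
      pred <- class::knn.cv(as.matrix(x), y, k = classifier$opts$k %||% 1L)
      mean(pred == y)
    } else if (spec$scheme == "loo") {
      pred <- vapply(seq_len(n), function(i) {
        fit <- classifier_fit(classifier, x[-i, , drop = FALSE], y[-i])
        as.character(classifier_predict(fit, x[i, , drop = FALSE])$label)
      }, character(1))
      mean(pred == as.character(y))
    } else if (spec$scheme == "kfold") {
      fold <- with_preserved_seed(spec$seed,
                                  sample(rep(seq_len(spec$k), length.out = n)))
      correct <- 0L
      for (f in seq_len(spec$k)) {
        te <- which(fold == f)
        fit <- classifier_fit(classifier, x[-te, , drop = FALSE], y[-te])
        pred <- classifier_predict(fit, x[te, , drop = FALSE])$label
        correct <- correct + sum(pred == y[te])
      }
      correct / n
    } else {
      fit <- classifier_fit(classifier, x[spec$train_rows, , drop = FALSE],
                            y[spec$train_rows])
      pred <- classifier_predict(fit, x[spec$test_rows, , drop = FALSE])$label
      mean(pred == y[spec$test_rows])
    }
  }, error = function(e) {
    warn(sprintf(
      "classifier failed on {%s} (%s); scored at chance level",
      paste(feats, collapse = ", "), conditionMessage(e)
    ))
    max(table(y)) / length(y)
  })
  acc
}

new_selection <- function(ranking, selected, method, classifier, spec,
                          n_evaluations, elapsed) {
  structure(
    list(ranking = ranking, selected = selected, method = method,
         classifier = classifier$name, eval_spec = spec,
         n_evaluations = n_evaluations, elapsed = elapsed),
    class = "fld_selection"
  )
}

#' One-pass ranking (OPR)
#'
#' Wrapper feature selection in a single pass: each feature is scored by
#' the evaluation accuracy of the classifier trained on that feature
#' *alone*, features are ranked by score (descending, ties broken by schema
#' order), and the top `k` are selected. Costs exactly one evaluation per
#' feature, which is what makes it practical on wide tables.
#'
#' @param table An `fld_cohort` / feature table with labels.
#' @param classifier An [fld_classifier()]; default 1-nearest-neighbour.
#' @param spec An [eval_spec()]; default leave-one-out.
#' @param k Number of features to select.
#' @param features Candidate features; default all feature columns in
#'   schema order.
#' @return An `fld_selection` with the full `ranking` (tibble `rank`,
#'   `feature`, `score`), the `selected` top-k set, and the evaluation
#'   count.
#' @export
opr_rank <- function(table, classifier = fld_classifier("knn"),
                     spec = eval_spec("loo"), k = 24, features = NULL) {
  features <- features %||% feature_cols(table)
  assert_features_present(table, features)
  if (k > length(features)) abort("k exceeds the number of features")
  t0 <- proc.time()[["elapsed"]]
  scores <- vapply(features, function(f) {
    wrapper_accuracy(table, f, classifier, spec)
  }, numeric(1))
  ord <- order(-scores, seq_along(features)) # stable: schema order on ties
  ranking <- tibble::tibble(
    rank = seq_along(features),
    feature = features[ord],
    score = unname(scores[ord])
  )
  new_selection(ranking, ranking$feature[seq_len(k)], "opr", classifier,
                spec, n_evaluations = length(features),
                elapsed = proc.time()[["elapsed"]] - t0)
}

#' Sequential forward selection (SFS)
#'
#' Greedy wrapper selection: starting from the empty set, repeatedly add
#' the feature whose inclusion maximises the evaluation accuracy of the
#' classifier on the augmented set (ties broken by schema order), until `k`
#' features are selected. Costs `sum(F - i)` evaluations for `i = 0 ..
#' k-1`, roughly `k` times the cost of [opr_rank()].
#'
#' @inheritParams opr_rank
#' @return An `fld_selection`; `ranking` records inclusion order with the
#'   running accuracy of each prefix.
#' @export
sfs_select <- function(table, classifier = fld_classifier("knn"),
                       spec = eval_spec("loo"), k = 24, features = NULL) {
  features <- features %||% feature_cols(table)
  assert_features_present(table, features)
  if (k > length(features)) abort("k exceeds the number of features")
  t0 <- proc.time()[["elapsed"]]
  chosen <- character(0)
  running <- numeric(0)
  n_eval <- 0L
  remaining <- features
  for (step in seq_len(k)) {
    scores <- vapply(remaining, function(f) {
      wrapper_accuracy(table, c(chosen, f), classifier, spec)
    }, numeric(1))
    n_eval <- n_eval + length(remaining)
    best <- remaining[which.max(scores)] # which.max is first-wins: schema order
    chosen <- c(chosen, best)
    running <- c(running, max(scores))
    remaining <- setdiff(remaining, best)
  }
  ranking <- tibble::tibble(rank = seq_len(k), feature = chosen,
                            score = running)
  new_selection(ranking, chosen, "sfs", classifier, spec,
                n_evaluations = n_eval,
                elapsed = proc.time()[["elapsed"]] - t0)
}

#' @export
print.fld_selection <- function(x, ...) {
  cat(sprintf(
    "<fld_selection> %s/%s, %d selected of %d ranked (%d evaluations)\n",
    toupper(x$method), x$classifier, length(x$selected), nrow(x$ranking),
    x$n_evaluations
  ))
  cat("top:", paste(head(x$selected, 8), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.fld_selection <- function(x, ...) {
  dplyr::mutate(x$ranking, selected = .data$feature %in% x$selected)
}

#' @export
glance.fld_selection <- function(x, ...) {
  tibble::tibble(
    method = x$method, classifier = x$classifier,
    n_selected = length(x$selected), n_ranked = nrow(x$ranking),
    n_evaluations = x$n_evaluations, best_score = max(x$ranking$score),
    elapsed = x$elapsed
  )
}

#' Agreement between two feature sets
#'
#' `feature_iou()` is the intersection-over-union
#' \eqn{|S_1 \cap S_2| / |S_1 \cup S_2|}; `feature_coverage()` is the
#' fraction of a reference (expert) set recovered,
#' \eqn{|S_1 \cap S_2| / |S_1|}.
#'
#' @param s1,s2 Character vectors of feature names (`s1` is the expert set
#'   for coverage).
#' @return A fraction in `[0, 1]`. Two empty sets have IoU 1 (with a
#'   warning); an empty expert set is an error for coverage.
#' @export
#' @examples
#' feature_iou(letters[1:24], c(letters[1:11], LETTERS[1:13]))   # 11/37
#' feature_coverage(letters[1:24], c(letters[1:11], LETTERS[1:13])) # 11/24
feature_iou <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  u <- length(union(s1, s2))
  if (u == 0) {
    warn("both sets empty; IoU defined as 1")
    return(1)
  }
  length(intersect(s1, s2)) / u
}

#' @rdname feature_iou
#' @export
feature_coverage <- function(s1, s2) {
  s1 <- unique(s1); s2 <- unique(s2)
  if (length(s1) == 0) abort("coverage needs a non-empty expert set")
  length(intersect(s1, s2)) / length(s1)
}

#' Read an expert feature list
#'
#' Plain-text file, one feature name per line; blank lines and `#` comments
#' ignored.
#'
#' @param path File path.
#' @return Character vector of feature names.
#' @export
read_expert_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
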