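#' Majority-class baseline (baseline 1)
#'
#' Always predicts the class with the larger share of the *training*
#' labels; its test accuracy is therefore exactly the test-set fraction of
#' that class. An exact tie predicts NFLD, with a warning.
#'
#' @param train_labels Training `"NFLD"`/`"FLD"` labels (both classes
#'   present).
#' @param test_samples `fld_samples` (or any tibble with a `target`
#'   column).
#' @return An `fld_baseline`: the majority class, the [eval_report()] on
#'   the test samples, and the baseline name.
#' @export
baseline_majority <- function(train_labels, test_samples) {
  train_labels <- as_fld_factor(train_labels)
  counts <- table(train_labels)
  if (any(counts == 0)) abort("training labels contain a single class")
  majority <- if (counts[["NFLD"]] == counts[["FLD"]]) {
    warn("exact class tie in training labels; predicting NFLD")
    "NFLD"
  } else {
    names(counts)[which.max(counts)]
  }
  truth <- as_fld_factor(test_samples$target)
  pred <- factor(rep(majority, length(truth)), levels = FLD_LEVELS)
  score <- rep(unname(counts[["FLD"]] / sum(counts)), length(truth))
  structure(
    list(baseline = "majority", majority_class = majority,
         report = eval_report(truth, pred, score), n_skipped = 0L),
    class = "fld_baseline"
  )
}

#' Persistence baseline (baseline 2)
#'
#' Always predicts the label of the previous (anchor) visit, so its
#' accuracy equals the label-persistence rate of the test pairs. This is
#' the baseline a next-visit model must beat to be worth anything: with
#' sticky labels it is already strong.
#'
#' @param test_samples `fld_samples` whose `prev_label` metadata carries
#'   the anchor visit's label.
#' @return An `fld_baseline`; samples with a missing anchor label are
#'   skipped and counted in `n_skipped`.
#' @export
baseline_persistence <- function(test_samples) {
  ok <- !is.na(test_samples$prev_label)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warn(sprintf("%d sample(s) without an anchor label skipped", n_skipped))
  }
  if (!any(ok)) abort("no samples with an anchor label")
  truth <- as_fld_factor(test_samples$target[ok])
  pred <- as_fld_factor(test_samples$prev_label[ok])
  score <- as.numeric(pred == "FLD")
  structure(
    list(baseline = "persistence", report = eval_report(truth, pred, score),
         n_skipped = n_skipped),
    class = "fld_baseline"
  )
}

#' @export
print.fld_baseline <- function(x, ...) {
  cat(sprintf("<fld_baseline> %s (accuracy %.4f)\n",
              x$baseline, x$report$accuracy))
  invisible(x)
}

#' Error reduction rate relative to a baseline
#'
#' `(e_b - e_m) / e_b` with `e = 1 - accuracy`: the fraction of the
#' baseline's error a model removes. Zero when the model merely matches
#' the baseline, 1 for a perfect model, negative when the model is worse.
#'
#' @param model_accuracy,baseline_accuracy Accuracies as fractions in
#'   `[0, 1]`; the baseline must make at least one error.
#' @return The error reduction rate (a fraction, at most 1).
#' @export
#' @examples
#' error_reduction(0.7929, 0.7522) # ~ 0.164
error_reduction <- function(model_accuracy, baseline_accuracy) {
  if (any(baseline_accuracy >= 1)) {
    abort("error reduction undefined for a perfect baseline")
  }
  e_b <- 1 - baseline_accuracy
  e_m <- 1 - model_accuracy
  (e_b - e_m) / e_b
}

#' Evaluate a model or baseline on next-visit test samples
#'
#' @param object An `fld_seq_model`, an `fld_baseline`, or a prediction
#'   tibble with `score` and `label` columns aligned to `test`.
#' @param test Non-empty `fld_samples`.
#' @return An [eval_report()].
#' @export
evaluate_nvp <- function(object, test) {
  if (nrow(test) == 0) abort("test sample set is empty")
  if (inherits(object, "fld_baseline")) return(object$report)
  pred <- if (inherits(object, "fld_seq_model")) {
    predict(object, test)
  } else {
    object
  }
  eval_report(test$target, pred$label, pred$score)
}
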