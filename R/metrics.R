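#' Classification evaluation report
#'
#' Confusion counts and derived metrics with FLD as the positive class.
#' AUROC uses the supplied continuous score; for scorers that emit a
#' constant (e.g. a majority baseline) the AUROC of an uninformative
#' classifier, 0.5, is reported.
#'
#' @param truth True `"NFLD"`/`"FLD"` labels.
#' @param estimate Predicted labels.
#' @param score Optional score in `[0, 1]` (probability of FLD) for AUROC.
#' @return An `fld_eval` object; see [tidy()] / [glance()] methods.
#' @export
eval_report <- function(truth, estimate, score = NULL) {
  truth <- as_fld_factor(truth)
  estimate <- as_fld_factor(estimate)
  if (length(truth) != length(estimate)) {
    abort("truth and estimate lengths differ")
  }
  n <- length(truth)
  if (n == 0) abort("cannot evaluate zero predictions")
  tp <- sum(truth == "FLD" & estimate == "FLD")
  fp <- sum(truth == "NFLD" & estimate == "FLD")
  tn <- sum(truth == "NFLD" & estimate == "NFLD")
  fn <- sum(truth == "FLD" & estimate == "NFLD")
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  auroc <- NA_real_
  if (!is.null(score)) {
    if (dplyr::n_distinct(truth) < 2) {
      auroc <- NA_real_
    } else if (dplyr::n_distinct(score) < 2) {
      auroc <- 0.5
    } else {
      auroc <- as.numeric(pROC::auc(
        pROC::roc(response = truth, predictor = as.numeric(score),
                  levels = FLD_LEVELS, direction = "<", quiet = TRUE)
      ))
    }
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
         accuracy = (tp + tn) / n, precision = precision, recall = recall,
         f1 = f1, auroc = auroc),
    class = "fld_eval"
  )
}

#' @export
print.fld_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<fld_eval> n=%d  acc=%.4f  prec=%s  rec=%s  F1=%s  AUROC=%s\n",
           "confusion: TP=%d FP=%d TN=%d FN=%d\n"),
    x$n, x$accuracy, fmt4(x$precision), fmt4(x$recall), fmt4(x$f1),
    fmt4(x$auroc), x$tp, x$fp, x$tn, x$fn
  ))
  invisible(x)
}

fmt4 <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' @export
tidy.fld_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "precision", "recall", "f1", "auroc"),
    value = c(x$accuracy, x$precision, x$recall, x$f1, x$auroc)
  )
}

#' @export
glance.fld_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
    accuracy = x$accuracy, precision = x$precision, recall = x$recall,
    f1 = x$f1, auroc = x$auroc
  )
}
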