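## Cross-sectional classifier registry.
##
## Every classifier is a pair of closures fit(x, y) / predict(fit, x) where
## x is a plain numeric data frame and y an NFLD/FLD factor; predict returns
## list(label = factor, score = P(FLD)). Implementations delegate to the
## usual packages; the exceptions are k-NN (lazy, "fit" just stores the
## training set) and AdaBoost, a compact in-package AdaBoost.M1 over rpart
## stumps. C4.5 is approximated by an entropy-criterion rpart tree.

CVP_CLASSIFIERS <- c("knn", "adaboost", "svm", "logistic", "random_forest",
                     "gaussian_nb", "c45_tree", "cart_tree")

#' Classifier specification
#'
#' @param name One of `"knn"`, `"adaboost"`, `"svm"`, `"logistic"`,
#'   `"random_forest"`, `"gaussian_nb"`, `"c45_tree"`, `"cart_tree"`.
#' @param ... Hyperparameters: `k` (neighbours, default 1) for knn;
#'   `n_rounds` (default 50) for adaboost; `n_trees` (default 200) for
#'   random_forest. Remaining classifiers use their package defaults.
#' @return An `fld_classifier` object usable by [train_eval_cvp()],
#'   [opr_rank()] and [sfs_select()].
#' @export
fld_classifier <- function(name = CVP_CLASSIFIERS, ...) {
  name <- match.arg(name)
  structure(list(name = name, opts = list(...)), class = "fld_classifier")
}

#' @export
print.fld_classifier <- function(x, ...) {
  cat(sprintf("<fld_classifier> %s\n", x$name))
  invisible(x)
}

classifier_fit <- function(classifier, x, y) {
  y <- as_fld_factor(y)
  if (dplyr::n_distinct(y) < 2) {
    abort("training labels contain a single class")
  }
  x <- as.data.frame(x)
  opts <- classifier$opts
  fit <- switch(
    classifier$name,
    knn = list(x = as.matrix(x), y = y, k = opts$k %||% 1L),
    adaboost = adaboost_fit(x, y, n_rounds = opts$n_rounds %||% 50L),
    svm = e1071::svm(x, y, probability = TRUE),
    logistic = {
      d <- cbind(x, .y = as.integer(y == "FLD"))
      suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
    },
    random_forest = randomForest::randomForest(
      x, y, ntree = opts$n_trees %||% 200L
    ),
    gaussian_nb = e1071::naiveBayes(x, y),
    c45_tree = rpart_fit(x, y, split = "information"),
    cart_tree = rpart_fit(x, y, split = "gini")
  )
  structure(list(name = classifier$name, fit = fit, features = names(x)),
            class = "fld_classifier_fit")
}

classifier_predict <- function(model, x) {
  x <- as.data.frame(x)[, model$features, drop = FALSE]
  fit <- model$fit
  switch(
    model$name,
    knn = {
      pred <- class::knn(fit$x, as.matrix(x), fit$y, k = fit$k, prob = TRUE)
      vote <- attr(pred, "prob") # fraction of votes for the winning class
      score <- ifelse(pred == "FLD", vote, 1 - vote)
      list(label = factor(as.character(pred), levels = FLD_LEVELS),
           score = score)
    },
    adaboost = adaboost_predict(fit, x),
    svm = {
      pred <- predict(fit, x, probability = TRUE)
      score <- attr(pred, "probabilities")[, "FLD"]
      list(label = factor(as.character(pred), levels = FLD_LEVELS),
           score = unname(score))
    },
    logistic = {
      score <- as.numeric(predict(fit, newdata = x, type = "response"))
      list(label = as_fld_factor(score >= 0.5), score = score)
    },
    random_forest = {
      score <- predict(fit, x, type = "prob")[, "FLD"]
      list(label = as_fld_factor(score >= 0.5), score = unname(score))
    },
    gaussian_nb = {
      score <- predict(fit, x, type = "raw")[, "FLD"]
      list(label = as_fld_factor(score >= 0.5), score = unname(score))
    },
    c45_tree = ,
    cart_tree = {
      score <- predict(fit, x)[, "FLD"]
      list(label = as_fld_factor(score >= 0.5), score = unname(score))
    }
  )
}

rpart_fit <- function(x, y, split) {
  d <- cbind(x, .y = y)
  rpart::rpart(.y ~ ., data = d, method = "class",
               parms = list(split = split))
}

## ---- AdaBoost.M1 with depth-1 rpart stumps ---------------------------------

adaboost_fit <- function(x, y, n_rounds = 50L) {
  n <- nrow(x)
  yy <- ifelse(y == "FLD", 1, -1)
  w <- rep(1 / n, n)
  d <- cbind(x, .y = y)
  stumps <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  for (m in seq_len(n_rounds)) {
    stump <- rpart::rpart(.y ~ ., data = d, weights = w, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 1, cp = -1, minsplit = 2, xval = 0
                          ))
    pred <- ifelse(predict(stump, x, type = "class") == "FLD", 1, -1)
    err <- sum(w[pred != yy])
    if (err >= 0.5 || err <= 1e-12) {
      if (err <= 1e-12) { # perfect stump: keep it with a large, finite vote
        used <- used + 1L
        stumps[[used]] <- stump
        alphas[used] <- 10
      }
      break
    }
    alpha <- 0.5 * log((1 - err) / err)
    used <- used + 1L
    stumps[[used]] <- stump
    alphas[used] <- alpha
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
  }
  if (used == 0L) abort("adaboost: no usable weak learner found")
  list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)])
}

adaboost_predict <- function(fit, x) {
  margin <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(predict(fit$stumps[[m]], x, type = "class") == "FLD", 1, -1)
    margin <- margin + fit$alphas[m] * pred
  }
  score <- plogis(2 * margin / sum(fit$alphas))
  list(label = as_fld_factor(margin >= 0), score = score)
}
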