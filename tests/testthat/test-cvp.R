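test_that("confusion metrics follow their closed forms", {
  truth <- c(rep("FLD", 110), rep("NFLD", 90))
  est <- c(rep("FLD", 80), rep("NFLD", 30), rep("FLD", 20), rep("NFLD", 70))
  r <- eval_report(truth, est)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(80, 20, 70, 30))
  expect_equal(r$tp + r$fp + r$tn + r$fn, r$n)
  expect_equal(r$precision, 0.8)
  expect_equal(round(r$recall, 3), 0.727)
  expect_equal(round(r$f1, 3), 0.762)
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
  expect_equal(r$accuracy, 150 / 200)
})

test_that("a perfectly separable table is classified perfectly by knn", {
  co <- separable_table(n = 80)
  train <- co[1:40 * 2 - 1, ] # odd rows
  test <- co[1:40 * 2, ]
  r <- train_eval_cvp(fldcast:::keep_cohort_attrs(train, co),
                      fldcast:::keep_cohort_attrs(test, co))
  expect_equal(r$accuracy, 1.0)
  expect_equal(r$auroc, 1.0)
})

test_that("label-independent features give chance accuracy and AUROC", {
  withr::with_seed(17, {
    n <- 2000
    v <- tibble::tibble(
      subject_id = sprintf("S%04d", 1:n),
      gender = factor(rep("male", n), levels = c("male", "female")),
      birth_year = rep(1970L, n),
      visit_year = rep(c(2015L, 2016L), each = n / 2),
      visit_month = rep(1L, n),
      fld_label = factor(sample(c("NFLD", "FLD"), n, replace = TRUE),
                         levels = c("NFLD", "FLD")),
      x1 = rnorm(n), x2 = rnorm(n)
    )
    co <- fldcast:::new_fld_cohort(v, fld_schema(c("x1", "x2"), "numeric"))
    r <- train_eval_cvp(co[co$visit_year == 2015, ],
                        co[co$visit_year == 2016, ],
                        fld_classifier("logistic"))
    expect_lt(abs(r$accuracy - 0.5), 0.03)
    expect_lt(abs(r$auroc - 0.5), 0.03)
  })
})

test_that("every classifier in the harness trains, predicts and scores", {
  co <- simulate_cohort(n_subjects = 150, n_noise_categorical = 0,
                        missing_rates = 0, seed = 19)
  train <- co[co$visit_year <= 2014, ]
  test <- co[co$visit_year > 2014, ]
  for (name in fldcast:::CVP_CLASSIFIERS) {
    r <- train_eval_cvp(train, test, fld_classifier(name), seed = 3)
    expect_true(r$accuracy >= 0 && r$accuracy <= 1, label = name)
    expect_false(is.na(r$auroc), label = name)
    # informative features make every one of them beat coin flipping
    expect_gt(r$accuracy, 0.55)
  }
  # deterministic under a fixed seed, including the stochastic learners
  r1 <- train_eval_cvp(train, test, fld_classifier("random_forest"), seed = 5)
  r2 <- train_eval_cvp(train, test, fld_classifier("random_forest"), seed = 5)
  expect_equal(glance(r1), glance(r2))
  expect_error(
    train_eval_cvp(train[train$fld_label == "FLD", ], test),
    "single class"
  )
})

test_that("the year-window sweep firewalls the test year and picks the best", {
  co <- simulate_cohort(n_subjects = 600, n_noise_numeric = 5,
                        n_noise_categorical = 0, missing_rates = 0,
                        start_years = c(2009, 2013), seed = 23)
  co <- normalize_features(impute_features(co))
  sw <- year_window_sweep(co, test_year = 2015, select_k = 4, seed = 1)
  res <- tidy(sw)
  expect_true(all(res$window_end < 2015))
  expect_equal(sw$best$accuracy, max(res$accuracy))
  # tie rule: among equal-accuracy windows the longest wins
  span <- res$window_end - res$window_start
  at_max <- res$accuracy == max(res$accuracy)
  expect_equal(sw$best$window_start, res$window_start[at_max][
    which.max(span[at_max])
  ])
  # single-window sweep: that window is best
  sw1 <- year_window_sweep(co, test_year = 2015, select_k = NULL,
                           windows = list(c(2012, 2014)), seed = 1)
  expect_equal(nrow(tidy(sw1)), 1)
  expect_equal(sw1$best$window_start, 2012)
})

test_that("a distribution shift makes recent-only windows win", {
  # labels follow +bmi before 2013 and -bmi from 2013 on; training windows
  # that reach back past the shift mix contradictory rules
  withr::with_seed(31, {
    n <- 3000
    year <- sample(2010:2016, n, replace = TRUE)
    x <- rnorm(n)
    flip <- ifelse(year >= 2013, 1, -1)
    y <- ifelse(plogis(5 * x * flip) > runif(n), "FLD", "NFLD")
    v <- tibble::tibble(
      subject_id = sprintf("S%04d", 1:n),
      gender = factor(rep("male", n), levels = c("male", "female")),
      birth_year = rep(1970L, n), visit_year = year,
      visit_month = rep(1L, n),
      fld_label = factor(y, levels = c("NFLD", "FLD")),
      bmi = x
    )
    co <- fldcast:::new_fld_cohort(v, fld_schema("bmi", "numeric"))
    # nearest-neighbour training sets are directly poisoned by pre-shift
    # rows, so windows reaching past the shift lose accuracy
    sw <- year_window_sweep(co, test_year = 2016, select_k = NULL,
                            classifier = fld_classifier("knn", k = 5))
    expect_gte(sw$best$window_start, 2013)
  })
})

test_that("age-split analysis detects a planted post-threshold weakening", {
  withr::with_seed(37, {
    n <- 4000
    age <- sample(40:70, n, replace = TRUE)
    x <- rnorm(n)
    slope <- ifelse(age < 55, 3, 0.3) # link weakens at 55 by construction
    y <- ifelse(plogis(slope * x) > runif(n), "FLD", "NFLD")
    v <- tibble::tibble(
      subject_id = sprintf("S%04d", 1:n),
      gender = factor(rep("female", n), levels = c("male", "female")),
      visit_year = sample(2009:2016, n, replace = TRUE),
      visit_month = rep(1L, n),
      fld_label = factor(y, levels = c("NFLD", "FLD")),
      bmi = x
    )
    v$birth_year <- v$visit_year - age
    co <- fldcast:::new_fld_cohort(v, fld_schema("bmi", "numeric"))
    res <- menopause_split(co, age_thresholds = 55,
                           train_years = c(2009, 2015), test_year = 2016)
    expect_equal(nrow(res), 2)
    before <- res$accuracy[res$side == "before"]
    after <- res$accuracy[res$side == "after"]
    expect_gt(before, after)
    # threshold below all ages: empty "before" flagged as missing, no error
    res2 <- menopause_split(co, age_thresholds = 20,
                            train_years = c(2009, 2015), test_year = 2016)
    expect_true(is.na(res2$accuracy[res2$side == "before"]))
    expect_equal(res2$n_train[res2$side == "before"], 0)
  })
})

test_that("the majority predictor scores exactly the bigger-class fraction", {
  co <- simulate_cohort(n_subjects = 400, seed = 41)
  test <- tibble::tibble(target = co$fld_label)
  b <- baseline_majority(rep(c("NFLD", "FLD"), c(70, 30)), test)
  expect_equal(b$majority_class, "NFLD")
  expect_equal(b$report$accuracy, mean(co$fld_label == "NFLD"))
})

test_that("tidy/glance on eval reports expose the metric table", {
  r <- eval_report(c("FLD", "NFLD"), c("FLD", "NFLD"), c(0.9, 0.1))
  td <- tidy(r)
  expect_equal(td$value[td$metric == "accuracy"], 1)
  g <- glance(r)
  expect_equal(g$n, 2)
  expect_equal(g$auroc, 1)
})
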