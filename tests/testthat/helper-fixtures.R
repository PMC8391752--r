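# Small hand-built fixtures used across test files.

feature_cols_of <- function(x) fldcast:::feature_cols(x)

# A tiny cohort with known values: 3 subjects, mixed visit counts.
toy_cohort <- function() {
  visits <- tibble::tibble(
    subject_id = c("A", "A", "A", "B", "C", "C"),
    gender = factor(c("male", "male", "male", "female", "female", "female"),
                    levels = c("male", "female")),
    birth_year = c(1960L, 1960L, 1960L, 1975L, 1980L, 1980L),
    visit_year = c(2010L, 2011L, 2012L, 2011L, 2012L, 2013L),
    visit_month = c(3L, 6L, 1L, 5L, 2L, 8L),
    fld_label = factor(c("NFLD", "FLD", "FLD", "NFLD", "FLD", "NFLD"),
                       levels = c("NFLD", "FLD")),
    bmi = c(22.1, 25.3, 26.0, 21.5, 27.2, 24.8),
    tg = c(100, 150, NA, 90, 210, 180),
    smoke = c(0, 1, 1, NA, 2, 2)
  )
  schema <- fld_schema(
    c("bmi", "tg", "smoke"),
    c("numeric", "numeric", "categorical"),
    c(NA, NA, 3L),
    expert = c(TRUE, TRUE, FALSE)
  )
  fldcast:::new_fld_cohort(visits, schema)
}

# One subject's history with visits at given month offsets from Jan 2010.
toy_history <- function(months, bmi, labels, smoke = NULL) {
  n <- length(months)
  visits <- tibble::tibble(
    subject_id = rep("H", n),
    gender = factor(rep("male", n), levels = c("male", "female")),
    birth_year = rep(1970L, n),
    visit_year = 2010L + months %/% 12L,
    visit_month = 1L + months %% 12L,
    fld_label = factor(labels, levels = c("NFLD", "FLD")),
    bmi = bmi
  )
  if (!is.null(smoke)) visits$smoke <- smoke
  schema <- fld_schema(
    c("bmi", if (!is.null(smoke)) "smoke"),
    c("numeric", if (!is.null(smoke)) "categorical"),
    c(NA, if (!is.null(smoke)) 4L)
  )
  fldcast:::new_fld_cohort(visits, schema)
}

# A linearly separable two-feature table for classifier sanity checks.
separable_table <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c("NFLD", "FLD"), each = n / 2)
    visits <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      gender = factor(rep("male", n), levels = c("male", "female")),
      birth_year = rep(1970L, n),
      visit_year = rep(2015L, n),
      visit_month = rep(1L, n),
      fld_label = factor(y, levels = c("NFLD", "FLD")),
      x1 = rnorm(n, mean = ifelse(y == "FLD", 3, -3), sd = 0.5),
      x2 = rnorm(n)
    )
    schema <- fld_schema(c("x1", "x2"), "numeric")
    fldcast:::new_fld_cohort(visits, schema)
  })
}
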