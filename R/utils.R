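## shared internal helpers

FLD_LEVELS <- c("NFLD", "FLD")

## meta columns of a cohort table; everything else is a feature column
META_COLS <- c(
  "subject_id", "gender", "birth_year",
  "visit_year", "visit_month", "fld_label"
)

as_fld_factor <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "FLD", "NFLD")
  if (is.numeric(x)) x <- ifelse(x >= 0.5, "FLD", "NFLD")
  bad <- !is.na(x) & !x %in% FLD_LEVELS
  if (any(bad)) {
    abort(sprintf("invalid FLD label(s): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  factor(x, levels = FLD_LEVELS)
}

## calendar month as a single integer so date arithmetic is plain subtraction
month_index <- function(year, month) year * 12L + (month - 1L)

index_to_year <- function(idx) idx %/% 12L
index_to_month <- function(idx) idx %% 12L + 1L

## run `code` under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

feature_cols <- function(table) setdiff(names(table), META_COLS)

assert_features_present <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing) > 0) {
    abort(sprintf("feature(s) not present in table: %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(features)
}

## length-safe permutation (sample() on a scalar means 1:n, not identity)
shuffle <- function(x) x[sample.int(length(x))]

## statistical mode with deterministic ties: smallest level wins
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which(tab == max(tab))][1])
}
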