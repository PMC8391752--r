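#' Integer distribution specification
#'
#' Visit counts and inter-visit gaps are drawn as `min + Poisson(mean - min)`
#' truncated at `max`, which gives a right-skewed integer distribution — a
#' reasonable shape for checkup counts and gaps, and fully determined by the
#' three numbers a user can actually state.
#'
#' @param min,max Integer support bounds (`min >= 1`).
#' @param mean Target mean before truncation; `min <= mean <= max`.
#' @return A `dist_spec` list.
#' @export
dist_spec <- function(min, max, mean) {
  if (min < 1 || min != round(min) || max != round(max)) {
    abort("dist_spec: min/max must be integers with min >= 1")
  }
  if (max < min || mean < min || mean > max) {
    abort("dist_spec: need min <= mean <= max")
  }
  structure(list(min = as.integer(min), max = as.integer(max), mean = mean),
            class = "dist_spec")
}

draw_dist <- function(spec, n) {
  if (!inherits(spec, "dist_spec")) abort("expected a dist_spec object")
  pmin(spec$max, spec$min + rpois(n, spec$mean - spec$min))
}

## reference means/sds for the planted "adiposity panel" analogues
INFORMATIVE_DEFAULTS <- data.frame(
  feature = c("bmi", "fat", "wc", "tg", "fg"),
  mu = c(23.5, 27, 84, 130, 98),
  sdv = c(3.5, 6, 10, 80, 18)
)

#' Simulate a longitudinal health-checkup cohort
#'
#' Generates a synthetic cohort with the statistical structure the fatty
#' liver analyses assume: irregular inter-visit intervals on a monthly
#' calendar, a mix of single- and multi-visit subjects, gender-dependent
#' NFLD:FLD class ratios, a small planted set of informative features among
#' many noise features, feature-wise missingness, and labels that persist
#' between consecutive visits.
#'
#' The label process is a per-subject latent "adiposity" random walk
#' \eqn{z_{it}} feeding a logistic link
#' \eqn{\pi_{it} = \mathrm{logit}^{-1}(\alpha_g + \gamma z_{it})}, with the
#' FLD label evolving as a two-state chain whose transitions are built so
#' that (i) the marginal per-visit FLD probability stays at \eqn{\pi_{it}}
#' (the gender intercept \eqn{\alpha_g} is calibrated against the realized
#' latent draws to hit `target_class_ratio`), and (ii) consecutive labels
#' agree with probability `label_persistence`. Informative feature \eqn{j}
#' is \eqn{x = \mu_j + \sigma_j (e_j z + \epsilon)/\sqrt{e_j^2+1}} with
#' \eqn{\epsilon \sim N(0,1)}, so `effect_sizes` \eqn{e_j} set the
#' feature–label correlation through the same latent link; noise features
#' are independent of the label.
#'
#' @param n_subjects Number of subjects.
#' @param visits_per_subject,interval_months [dist_spec()] objects for the
#'   visit count per subject and the gap (months) between visits.
#' @param gender_mix Fraction of male subjects.
#' @param n_informative,n_noise_numeric,n_noise_categorical Feature counts.
#' @param categorical_levels Number of levels (coded `0..L-1`) for
#'   questionnaire noise features.
#' @param effect_sizes Per-informative-feature latent loadings, recycled to
#'   `n_informative`. Zero means the feature carries no label signal.
#' @param label_persistence Probability that consecutive visits of a subject
#'   carry the same label. Low values constrain the achievable class ratios
#'   (at `label_persistence = p` the per-visit FLD probability is clamped to
#'   `[(1-p)/2, 1-(1-p)/2]`).
#' @param missing_rates Per-feature missing fractions: a scalar, or a named
#'   vector overriding the defaults (informative 0.05, questionnaire 0.10,
#'   lab noise cycling through 0–0.95 so that some features are >= 90%
#'   missing, as heavy-missingness screening data are).
#' @param target_class_ratio Named vector `c(male = , female = )` of target
#'   NFLD/FLD class-size ratios.
#' @param label_link_scale Latent-to-label logistic slope \eqn{\gamma}.
#' @param start_years Range of calendar years in which first visits fall.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   identical cohort. The caller's RNG stream is left untouched.
#'
#' @return An `fld_cohort` tibble, one row per visit, with meta columns
#'   `subject_id`, `gender`, `birth_year`, `visit_year`, `visit_month`,
#'   `fld_label` followed by feature columns; the schema is attached as an
#'   attribute (see [cohort_schema()]) and the planted informative feature
#'   names as ground truth (see [cohort_ground_truth()]).
#' @export
#' @examples
#' co <- simulate_cohort(n_subjects = 200, seed = 42)
#' cohort_ground_truth(co)
simulate_cohort <- function(n_subjects = 2000,
                            visits_per_subject = dist_spec(1, 12, 3.4),
                            interval_months = dist_spec(3, 36, 14),
                            gender_mix = 0.55,
                            n_informative = 5,
                            n_noise_numeric = 20,
                            n_noise_categorical = 5,
                            categorical_levels = 4L,
                            effect_sizes = 1.5,
                            label_persistence = 0.8,
                            missing_rates = NULL,
                            target_class_ratio = c(male = 0.66, female = 2.02),
                            label_link_scale = 2.5,
                            start_years = c(2009, 2014),
                            seed = 1) {
  check_fraction <- function(x, what) {
    if (any(x < 0 | x > 1)) abort(sprintf("%s must lie in [0, 1]", what))
  }
  check_fraction(gender_mix, "gender_mix")
  check_fraction(label_persistence, "label_persistence")
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  if (any(c(n_informative, n_noise_numeric, n_noise_categorical) < 0)) {
    abort("feature counts must be >= 0")
  }
  if (n_noise_categorical > 0 && categorical_levels < 2) {
    abort("categorical_levels must be >= 2")
  }
  if (any(target_class_ratio <= 0)) abort("target_class_ratio must be > 0")
  if (!all(c("male", "female") %in% names(target_class_ratio))) {
    abort("target_class_ratio needs named entries for male and female")
  }
  effect_sizes <- rep_len(effect_sizes, n_informative)

  inf_names <- character(0)
  if (n_informative > 0) {
    inf_names <- c(head(INFORMATIVE_DEFAULTS$feature, n_informative),
                   sprintf("inf_%02d", seq_len(max(0, n_informative - 5)) + 5))
  }
  lab_names <- sprintf("lab_%02d", seq_len(n_noise_numeric))
  quest_names <- sprintf("quest_%02d", seq_len(n_noise_categorical))
  feat_names <- c(inf_names, lab_names, quest_names)

  ## per-feature missing fractions
  default_lab_miss <- c(0, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.92, 0.95)
  miss <- c(
    setNames(rep(0.05, length(inf_names)), inf_names),
    setNames(rep_len(default_lab_miss, length(lab_names)), lab_names),
    setNames(rep(0.10, length(quest_names)), quest_names)
  )
  if (!is.null(missing_rates)) {
    if (is.null(names(missing_rates))) {
      miss[] <- rep_len(missing_rates, length(miss))
    } else {
      unknown <- setdiff(names(missing_rates), feat_names)
      if (length(unknown) > 0) {
        abort(sprintf("missing_rates name(s) not in schema: %s",
                      paste(unknown, collapse = ", ")))
      }
      miss[names(missing_rates)] <- missing_rates
    }
  }
  check_fraction(miss, "missing_rates")

  with_preserved_seed(seed, {
    gender <- factor(ifelse(runif(n_subjects) < gender_mix, "male", "female"),
                     levels = c("male", "female"))
    birth_year <- sample(1949:1989, n_subjects, replace = TRUE)
    nv <- draw_dist(visits_per_subject, n_subjects)
    n_rows <- sum(nv)
    subj_row <- rep(seq_len(n_subjects), nv)
    pos <- sequence(nv)

    gaps <- draw_dist(interval_months, n_rows)
    gaps[pos == 1L] <- 0L
    start_idx <- month_index(
      sample(start_years[1]:start_years[2], n_subjects, replace = TRUE),
      sample(1:12, n_subjects, replace = TRUE)
    )
    cum_gap <- cumsum(gaps)
    cum_gap <- cum_gap - cum_gap[pos == 1L][subj_row]
    midx <- start_idx[subj_row] + cum_gap

    ## latent adiposity random walk
    inc <- rnorm(n_rows, 0, 0.2)
    inc[pos == 1L] <- 0
    walk <- cumsum(inc)
    walk <- walk - walk[pos == 1L][subj_row]
    z <- rnorm(n_subjects)[subj_row] + walk

    ## gender intercepts calibrated on the realized latent draws
    d <- 1 - label_persistence
    lo <- d / 2 + 1e-9
    clamp_pi <- function(p) pmin(pmax(p, lo), 1 - lo)
    is_male <- gender[subj_row] == "male"
    alpha <- vapply(c(male = TRUE, female = FALSE), function(m) {
      zz <- z[is_male == m]
      if (length(zz) == 0) return(0)
      target <- 1 / (1 + unname(target_class_ratio[if (m) "male" else "female"]))
      uniroot(function(a) {
        mean(clamp_pi(plogis(a + label_link_scale * zz))) - target
      }, c(-15, 15))$root
    }, numeric(1))
    pi_v <- clamp_pi(plogis(ifelse(is_male, alpha["male"], alpha["female"]) +
                              label_link_scale * z))

    ## two-state label chain: marginal pi_v, consecutive agreement = persistence
    lab <- integer(n_rows)
    first <- pos == 1L
    lab[first] <- rbinom(sum(first), 1, pi_v[first])
    for (t in seq(2L, max(pos))) {
      rows <- which(pos == t)
      if (length(rows) == 0) break
      prev <- lab[rows - 1L]
      p_stay <- 1 - d / (2 * pi_v[rows])
      p_gain <- d / (2 * (1 - pi_v[rows]))
      lab[rows] <- rbinom(length(rows), 1, ifelse(prev == 1L, p_stay, p_gain))
    }

    visits <- tibble::tibble(
      subject_id = sprintf("S%05d", subj_row),
      gender = gender[subj_row],
      birth_year = birth_year[subj_row],
      visit_year = index_to_year(midx),
      visit_month = index_to_month(midx),
      fld_label = factor(ifelse(lab == 1L, "FLD", "NFLD"), levels = FLD_LEVELS)
    )
    for (j in seq_along(inf_names)) {
      e <- effect_sizes[j]
      mu <- if (j <= 5) INFORMATIVE_DEFAULTS$mu[j] else 50
      sdv <- if (j <= 5) INFORMATIVE_DEFAULTS$sdv[j] else 10
      visits[[inf_names[j]]] <-
        mu + sdv * (e * z + rnorm(n_rows)) / sqrt(e^2 + 1)
    }
    for (j in seq_along(lab_names)) {
      visits[[lab_names[j]]] <- rnorm(n_rows, 50, 10)
    }
    for (j in seq_along(quest_names)) {
      visits[[quest_names[j]]] <-
        sample(0:(categorical_levels - 1L), n_rows, replace = TRUE)
    }
    for (f in feat_names) {
      if (miss[f] > 0) {
        visits[[f]][rbinom(n_rows, 1, miss[f]) == 1L] <- NA
      }
    }

    schema <- fld_schema(
      feature = feat_names,
      kind = c(rep("numeric", length(inf_names) + length(lab_names)),
               rep("categorical", length(quest_names))),
      levels = c(rep(NA_integer_, length(inf_names) + length(lab_names)),
                 rep(as.integer(categorical_levels), length(quest_names))),
      expert = feat_names %in% inf_names
    )
    new_fld_cohort(visits, schema, informative = inf_names)
  })
}
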