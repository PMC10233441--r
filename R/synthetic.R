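# Synthetic survey populations with a known generative risk model.
#
# Every field is generated from an explicit logistic model so that
# downstream stages (classifier, calibration, Sullivan's method, policy
# simulation) can be tested against analytic ground truth: each disease
# flag is Bernoulli(plogis(baseline + age_slope * age + female_shift *
# is_female)) and the activity-limitation label is Bernoulli of a logistic
# linear predictor in age, sex and the disease flags.

# run code with a temporarily seeded RNG, restoring global state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Discretized age distribution of the synthetic population
#'
#' A mixture of a uniform component over working ages and a triangular
#' component concentrated in old age (60-110 years, mode 75), discretized
#' to integer ages. The old-age weight keeps elderly strata well populated,
#' which healthy-life-years computation needs; national health surveys of
#' ageing populations have a similar skew.
#'
#' @param age_range integer vector `c(min_age, max_age)`; the distribution
#'   is truncated to this range and renormalized.
#' @param uniform_weight mixture weight of the uniform(0, 60) component.
#' @return a tibble with columns `age` and `prob` (summing to 1).
#' @export
age_distribution <- function(age_range = c(0, 110), uniform_weight = 0.6) {
  stopifnot(length(age_range) == 2, age_range[1] >= 0, age_range[2] <= 110,
            age_range[1] < age_range[2])
  ages <- 0:109
  mid <- ages + 0.5
  unif <- ifelse(mid < 60, 1 / 60, 0)
  # triangular density on [60, 110] with mode 75
  tri <- ifelse(mid >= 60 & mid < 75, 2 * (mid - 60) / (50 * 15),
         ifelse(mid >= 75 & mid <= 110, 2 * (110 - mid) / (50 * 35), 0))
  prob <- uniform_weight * unif + (1 - uniform_weight) * tri
  keep <- ages >= age_range[1] & ages <= age_range[2]
  ages <- ages[keep]
  prob <- prob[keep] / sum(prob[keep])
  tibble::tibble(age = ages, prob = prob)
}

#' Default per-disease generative parameters
#'
#' One row per disease of the survey schema, giving the target marginal
#' prevalence (matched to published Japanese national survey rates for
#' diseases under treatment), the log-odds slope on age (per year), and the
#' additive female log-odds shift. The intercept (`baseline_logit`) that
#' achieves the target marginal under a given age/sex distribution is
#' solved for in [generator_config()].
#'
#' @return tibble with columns `disease`, `target_prevalence`, `age_slope`,
#'   `female_shift`.
#' @export
default_disease_params <- function() {
  tibble::tribble(
    ~disease,                                        ~target_prevalence, ~age_slope, ~female_shift,
    "diabetes",                                       0.0505, 0.080,  -0.20,
    "thyroid_disease",                                0.0129, 0.040,   1.50,
    "depression_or_other_mental_disease",             0.0189, 0.010,   0.40,
    "dementia",                                       0.0072, 0.120,   0.20,
    "parkinson_disease",                              0.0021, 0.100,   0.00,
    "other_neurological_disorder_pain_or_paralysis",  0.0072, 0.040,   0.00,
    "eye_disease",                                    0.0544, 0.070,   0.20,
    "ear_disease",                                    0.0107, 0.050,   0.00,
    "stroke_cerebral_hemorrhage_or_infarction",       0.0125, 0.080,  -0.40,
    "angina_or_myocardial_infarction",                0.0192, 0.080,  -0.50,
    "other_cardiovascular_disease",                   0.0187, 0.080,   0.00,
    "acute_nasopharyngitis_and_common_cold",          0.0033, 0.000,   0.20,
    "infertility",                                    0.0010, -0.020,  4.00,
    "dental_disease",                                 0.0524, 0.030,   0.10,
    "gout",                                           0.0100, 0.050,  -2.00,
    "obesity",                                        0.0052, 0.030,   0.20,
    "dyslipidemia",                                   0.0529, 0.080,   0.30,
    "hypertension",                                   0.1340, 0.090,  -0.10,
    "allergic_rhinitis",                              0.0210, -0.010,  0.20,
    "chronic_obstructive_pulmonary_disease",          0.0015, 0.090,  -0.80,
    "asthma",                                         0.0124, 0.000,   0.10,
    "other_respiratory_disease",                      0.0098, 0.050,  -0.20,
    "stomach_or_duodenum_disease",                    0.0171, 0.050,  -0.10,
    "liver_or_gallbladder_disease",                   0.0095, 0.050,  -0.20,
    "other_digestive_disease",                        0.0121, 0.040,   0.10,
    "atopic_dermatitis",                              0.0093, -0.030,  0.20,
    "other_skin_disease",                             0.0190, 0.020,   0.20,
    "rheumatoid_arthritis",                           0.0074, 0.060,   1.00,
    "arthritis",                                      0.0230, 0.080,   0.50,
    "stiff_shoulder",                                 0.0283, 0.030,   0.70,
    "back_pain",                                      0.0526, 0.050,   0.10,
    "osteoporosis",                                   0.0187, 0.120,   2.00,
    "kidney_disease",                                 0.0099, 0.060,  -0.30,
    "prostatic_hypertrophy",                          0.0130, 0.120,  -8.00,
    "menopausal_or_postmenopausal_disorder",          0.0020, 0.020,   8.00,
    "bone_fracture",                                  0.0068, 0.050,   0.30,
    "other_injury_or_burns",                          0.0067, 0.030,  -0.10,
    "anemia_or_blood_disease",                        0.0069, 0.030,   1.50,
    "malignant_neoplasm_or_cancer",                   0.0090, 0.070,   0.00,
    "pregnancy_puerperium_or_related_condition",      0.0014, -0.020,  8.00
  )
}

#' Default activity-limitation coefficients
#'
#' Log-odds of activity limitation given age, sex and disease flags. Age
#' carries the dominant effect; disease coefficients are largest for the
#' conditions most strongly tied to limitation in daily activity (mental
#' disease, neurological disorders, stroke, fractures, arthritis,
#' dementia). The intercept is calibrated so the marginal limitation
#' prevalence under the default configuration is approximately 13.5%,
#' a realistic class balance for this outcome.
#'
#' @return a list with elements `intercept`, `age_coeff`, `sex_coeff`
#'   (female shift) and `disease`, a named vector over the 40 diseases.
#' @export
default_limitation_coeffs <- function() {
  dis <- c(
    diabetes = 0.6, thyroid_disease = 0.5,
    depression_or_other_mental_disease = 1.7, dementia = 1.8,
    parkinson_disease = 1.8,
    other_neurological_disorder_pain_or_paralysis = 1.7,
    eye_disease = 0.7, ear_disease = 0.8,
    stroke_cerebral_hemorrhage_or_infarction = 1.5,
    angina_or_myocardial_infarction = 0.9,
    other_cardiovascular_disease = 0.9,
    acute_nasopharyngitis_and_common_cold = 0.5, infertility = 0.1,
    dental_disease = 0.3, gout = 0.4, obesity = 0.8, dyslipidemia = 0.3,
    hypertension = 0.4, allergic_rhinitis = 0.3,
    chronic_obstructive_pulmonary_disease = 1.4, asthma = 0.6,
    other_respiratory_disease = 1.0, stomach_or_duodenum_disease = 0.7,
    liver_or_gallbladder_disease = 0.7, other_digestive_disease = 0.9,
    atopic_dermatitis = 0.3, other_skin_disease = 0.5,
    rheumatoid_arthritis = 1.2, arthritis = 1.3, stiff_shoulder = 0.8,
    back_pain = 1.3, osteoporosis = 0.8, kidney_disease = 1.1,
    prostatic_hypertrophy = 0.5,
    menopausal_or_postmenopausal_disorder = 0.7, bone_fracture = 1.6,
    other_injury_or_burns = 1.4, anemia_or_blood_disease = 0.8,
    malignant_neoplasm_or_cancer = 1.1,
    pregnancy_puerperium_or_related_condition = 0.4
  )
  list(
    intercept = -6.675,
    age_coeff = 0.055,
    sex_coeff = 0.10,
    disease = dis[disease_names()]
  )
}

#' Build a synthetic-population generator configuration
#'
#' Assembles and validates the full generative model: population size, RNG
#' seed, age distribution, sex balance, per-disease logistic models and the
#' activity-limitation model. Per-disease intercepts are solved numerically
#' (by [stats::uniroot()] on the marginal prevalence integrated over the
#' age/sex distribution) so each disease hits its `target_prevalence`.
#'
#' @param n_records number of survey records to generate.
#' @param seed integer RNG seed; all generation is deterministic given it.
#' @param age_range integer `c(min, max)` ages, within 0-110.
#' @param sex_female_prob probability a respondent is female.
#' @param disease_params tibble as returned by [default_disease_params()];
#'   must cover exactly the 40 schema diseases. A `baseline_logit` column,
#'   if present, is used as-is; otherwise intercepts are calibrated to
#'   `target_prevalence`.
#' @param limitation_coeffs list as from [default_limitation_coeffs()].
#' @param uniform_weight weight of the uniform age component, see
#'   [age_distribution()].
#' @return an object of class `generator_config`.
#' @export
#' @examples
#' cfg <- generator_config(n_records = 500, seed = 1)
#' pop <- generate_population(cfg)
#' mean(pop$activity_limitation)
generator_config <- function(n_records,
                             seed = 1L,
                             age_range = c(0, 110),
                             sex_female_prob = 0.52,
                             disease_params = default_disease_params(),
                             limitation_coeffs = default_limitation_coeffs(),
                             uniform_weight = 0.6) {
  if (n_records < 1) {
    abort("n_records must be a positive count", class = "hlyr_empty_population")
  }
  check_probability(sex_female_prob, "sex_female_prob")
  if (!setequal(disease_params$disease, disease_names())) {
    abort("disease_params must cover exactly the 40 schema diseases",
          class = "hlyr_schema_error")
  }
  disease_params <- disease_params[match(disease_names(),
                                         disease_params$disease), ]
  ages <- age_distribution(age_range, uniform_weight)
  if (!("baseline_logit" %in% names(disease_params))) {
    check_probability(disease_params$target_prevalence, "target_prevalence")
    disease_params$baseline_logit <- purrr::pmap_dbl(
      disease_params[c("target_prevalence", "age_slope", "female_shift")],
      function(target_prevalence, age_slope, female_shift) {
        calibrate_logit_intercept(target_prevalence, age_slope, female_shift,
                                  ages, sex_female_prob)
      }
    )
  }
  lc <- limitation_coeffs
  stopifnot(is.list(lc),
            all(c("intercept", "age_coeff", "sex_coeff", "disease") %in% names(lc)),
            setequal(names(lc$disease), disease_names()))
  lc$disease <- lc$disease[disease_names()]
  structure(
    list(n_records = as.integer(n_records), seed = as.integer(seed),
         age_range = age_range, sex_female_prob = sex_female_prob,
         ages = ages, disease_params = disease_params,
         limitation_coeffs = lc),
    class = "generator_config"
  )
}

# marginal prevalence of a logistic disease model under the discrete
# age distribution and sex balance
marginal_disease_prevalence <- function(baseline, age_slope, female_shift,
                                        ages, p_female) {
  p_by_sex <- function(female) {
    sum(ages$prob * plogis(baseline + age_slope * ages$age +
                             female_shift * female))
  }
  (1 - p_female) * p_by_sex(0) + p_female * p_by_sex(1)
}

calibrate_logit_intercept <- function(target, age_slope, female_shift,
                                      ages, p_female) {
  f <- function(b) {
    marginal_disease_prevalence(b, age_slope, female_shift, ages, p_female) -
      target
  }
  uniroot(f, interval = c(-30, 10), tol = 1e-10)$root
}

#' Generate a synthetic survey population
#'
#' Draws `n_records` respondents from the configured generative model.
#' Output is deterministic given the configuration seed and leaves the
#' caller's RNG state untouched.
#'
#' @param config a [generator_config()].
#' @return a tibble of class `synthetic_population` with the survey schema
#'   columns (`age`, `sex`, 40 disease flags, `activity_limitation`, all
#'   flags integer 0/1) plus `true_probability`, the generative probability
#'   of activity limitation for each record.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_records
  dp <- config$disease_params
  lc <- config$limitation_coeffs
  with_seed(config$seed, {
    age <- sample(config$ages$age, n, replace = TRUE, prob = config$ages$prob)
    female <- rbinom(n, 1L, config$sex_female_prob)
    flags <- matrix(0L, nrow = n, ncol = nrow(dp),
                    dimnames = list(NULL, dp$disease))
    for (j in seq_len(nrow(dp))) {
      p_j <- plogis(dp$baseline_logit[j] + dp$age_slope[j] * age +
                      dp$female_shift[j] * female)
      flags[, j] <- rbinom(n, 1L, p_j)
    }
    eta <- lc$intercept + lc$age_coeff * age + lc$sex_coeff * female +
      as.vector(flags %*% lc$disease)
    p_lim <- plogis(eta)
    label <- rbinom(n, 1L, p_lim)
    out <- tibble::as_tibble(as.data.frame(flags))
    out <- dplyr::bind_cols(
      tibble::tibble(age = as.integer(age),
                     sex = ifelse(female == 1L, "female", "male")),
      out,
      tibble::tibble(activity_limitation = label, true_probability = p_lim)
    )
    class(out) <- c("synthetic_population", class(out))
    out
  })
}

#' AUROC of the generative probabilities (Bayes AUROC)
#'
#' The AUROC attained by the true conditional probabilities against the
#' generated labels: an upper reference for any model fitted to the same
#' synthetic population (no classifier can beat it except by sampling
#' noise).
#'
#' @param population a `synthetic_population` tibble.
#' @return the Bayes AUROC as a single number.
#' @export
bayes_auroc <- function(population) {
  stopifnot(all(c("activity_limitation", "true_probability") %in%
                  names(population)))
  auroc(population$activity_limitation, population$true_probability)
}

#' Generate a synthetic abridged life table from a mortality law
#'
#' Age-group central death rates follow the Gompertz-Makeham hazard
#' `m(x) = a + b * exp(c * x)` evaluated at group midpoints (and at five
#' years above the start of the open-ended last group); the remaining
#' life-table columns follow the standard abridged construction of
#' [build_life_table()]. Defaults give a life expectancy at birth of about
#' 84 years, typical of a contemporary low-mortality population such as
#' Japan's.
#'
#' @param a Makeham age-independent hazard (>= 0, per person-year).
#' @param b Gompertz baseline hazard (> 0).
#' @param c Gompertz rate of ageing (> 0, per year).
#' @param scheme age-group scheme as from [abridged_scheme()]; must be
#'   contiguous from age 0 with an open-ended last group.
#' @param a0 average years lived in the first interval by those dying in
#'   it, when that interval has width 1 (the infant group).
#' @return a `life_table` tibble, see [build_life_table()].
#' @export
#' @examples
#' lt <- generate_life_table()
#' lt$ex[1] # life expectancy at birth
generate_life_table <- function(a = 1.5e-4, b = 6e-6, c = 0.11,
                                scheme = abridged_scheme(), a0 = 0.3) {
  stopifnot(a >= 0, b > 0, c > 0)
  check_scheme(scheme)
  mid <- ifelse(is.finite(scheme$width), scheme$start + scheme$width / 2,
                scheme$start + 5)
  mx <- a + b * exp(c * mid)
  build_life_table(mx, scheme = scheme, a0 = a0)
}

#' Write / read synthetic survey populations as CSV
#'
#' The file holds exactly the survey schema columns (the
#' `true_probability` column of a synthetic population is dropped: it is
#' generator metadata, not survey data). Identical configurations produce
#' byte-identical files.
#'
#' @param population a survey tibble.
#' @param path file path.
#' @return `write_survey` returns `path` invisibly.
#' @export
write_survey <- function(population, path) {
  validate_survey(population)
  readr::write_csv(population[survey_columns()], path, progress = FALSE)
  invisible(path)
}
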