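#' Survey record schema
#'
#' The record layout mirrors the health questionnaire of the Japanese
#' Comprehensive Survey of Living Conditions: one row per respondent with
#' integer age, sex, 40 binary flags for diseases or injuries under
#' treatment, and a binary activity-limitation indicator ("Do you have any
#' health problem which limits your daily activity?").
#'
#' @return `disease_names()` returns the 40 disease column names in schema
#'   order. `feature_names()` returns the 42 model features (`age`, `sex`,
#'   then the diseases). `survey_columns()` returns all columns of a survey
#'   table including the `activity_limitation` target.
#' @export
#' @examples
#' length(disease_names())
#' head(feature_names())
disease_names <- function() {
  c(
    "diabetes",
    "thyroid_disease",
    "depression_or_other_mental_disease",
    "dementia",
    "parkinson_disease",
    "other_neurological_disorder_pain_or_paralysis",
    "eye_disease",
    "ear_disease",
    "stroke_cerebral_hemorrhage_or_infarction",
    "angina_or_myocardial_infarction",
    "other_cardiovascular_disease",
    "acute_nasopharyngitis_and_common_cold",
    "infertility",
    "dental_disease",
    "gout",
    "obesity",
    "dyslipidemia",
    "hypertension",
    "allergic_rhinitis",
    "chronic_obstructive_pulmonary_disease",
    "asthma",
    "other_respiratory_disease",
    "stomach_or_duodenum_disease",
    "liver_or_gallbladder_disease",
    "other_digestive_disease",
    "atopic_dermatitis",
    "other_skin_disease",
    "rheumatoid_arthritis",
    "arthritis",
    "stiff_shoulder",
    "back_pain",
    "osteoporosis",
    "kidney_disease",
    "prostatic_hypertrophy",
    "menopausal_or_postmenopausal_disorder",
    "bone_fracture",
    "other_injury_or_burns",
    "anemia_or_blood_disease",
    "malignant_neoplasm_or_cancer",
    "pregnancy_puerperium_or_related_condition"
  )
}

#' @rdname disease_names
#' @export
feature_names <- function() {
  c("age", "sex", disease_names())
}

#' @rdname disease_names
#' @export
survey_columns <- function() {
  c("age", "sex", disease_names(), "activity_limitation")
}

# Internal: check a survey tibble for schema conformity.
# Returns the tibble invisibly; aborts naming the first offending column.
validate_survey <- function(data, require_target = TRUE) {
  required <- c("age", "sex", disease_names())
  if (require_target) required <- c(required, "activity_limitation")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(
      paste0("survey table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "hlyr_schema_error"
    )
  }
  if (any(data$age < 0, na.rm = TRUE) || any(data$age > 110, na.rm = TRUE)) {
    abort("age must be between 0 and 110 years", class = "hlyr_schema_error")
  }
  bad_sex <- setdiff(unique(data$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(paste0("sex must be 'male' or 'female'; found: ",
                 paste(bad_sex, collapse = ", ")),
          class = "hlyr_schema_error")
  }
  invisible(data)
}
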