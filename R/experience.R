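# Classification of infants' face and language experience from parental
# reports: maternal race, diversity of regular face contacts, language
# exposure.

#' Classify language exposure
#'
#' An infant exposed to English more than 75% of the time is monolingual
#' English; exposed to some other single language more than 75% of the time,
#' monolingual for that other language; exposed to multiple languages with
#' none above 75%, multilingual; no report, unreported.
#'
#' @param exposure Named numeric vector of exposure fractions by language
#'   (e.g. `c(English = 0.6, Spanish = 0.4)`), or `NULL`/all-`NA` for a
#'   missing report. Fractions must be non-negative and sum to at most 1
#'   (plus a small tolerance).
#' @return One of `"monolingual English"`, `"other monolingual"`,
#'   `"multilingual"`, `"unreported"`.
#' @export
#' @examples
#' classify_language(c(English = 0.9, Spanish = 0.1))
#' classify_language(c(English = 0.6, Spanish = 0.4))
#' classify_language(c(Mandarin = 0.8, English = 0.2))
classify_language <- function(exposure) {
  if (is.null(exposure) || length(exposure) == 0 || all(is.na(exposure))) {
    return("unreported")
  }
  exposure <- exposure[!is.na(exposure)]
  if (any(exposure < 0)) data_error("Exposure fractions must be non-negative.")
  if (sum(exposure) > 1 + 1e-6) {
    data_error("Exposure fractions must sum to at most 1.")
  }
  english <- sum(exposure[names(exposure) == "English"])
  if (english > 0.75) return("monolingual English")
  others <- exposure[names(exposure) != "English"]
  if (length(others) > 0 && max(others) > 0.75) return("other monolingual")
  "multilingual"
}

#' Classify maternal race
#'
#' Mothers reported as White are White regardless of Hispanic ethnicity;
#' mothers reported as Asian American, alone or together with White, are
#' Asian American; mothers of some other race — or of no reported race but
#' reported Hispanic — are Other; no information at all is unclassified.
#'
#' @param races Character vector of reported races (may be empty).
#' @param hispanic Logical Hispanic-ethnicity flag.
#' @return One of `"White"`, `"Asian American"`, `"Other"`, `"unclassified"`.
#' @export
#' @examples
#' classify_mother_race("White", hispanic = TRUE)      # White
#' classify_mother_race(c("Asian American", "White"))  # Asian American
#' classify_mother_race(character(0), hispanic = TRUE) # Other
classify_mother_race <- function(races, hispanic = FALSE) {
  races <- races[!is.na(races) & races != ""]
  if (length(races) == 0) {
    return(if (isTRUE(hispanic)) "Other" else "unclassified")
  }
  others <- setdiff(races, c("White", "Asian American"))
  if ("Asian American" %in% races && length(others) == 0) {
    return("Asian American")
  }
  if (length(others) == 0) return("White") # White only
  "Other"
}

#' Classify diversity of face experience
#'
#' Counts the distinct racial groups among the women an infant regularly
#' encounters: the mother's classified race, any significant female
#' caregiver's race, and questionnaire-reported regular exposure to White,
#' Asian American, and Black women. (A mother classified as Other counts as
#' her own group.) Three or more groups is high, two is medium, one is low.
#' Undefined (`NA`) when the questionnaire is missing.
#'
#' @param mother_race Classified maternal race (see [classify_mother_race()]).
#' @param caregiver_race Classified race of a significant female caregiver,
#'   or `NA` if none.
#' @param exp_white,exp_asian,exp_black Logical questionnaire flags for
#'   regular exposure to White / Asian American / Black women.
#' @param questionnaire_present Whether the face-experience questionnaire
#'   was returned; if `FALSE` the classification is `NA`.
#' @return `"low"`, `"medium"`, `"high"`, or `NA`.
#' @export
#' @examples
#' classify_diversity("White", "Asian American", FALSE, FALSE, FALSE) # medium
#' classify_diversity("Asian American", "Asian American",
#'                    FALSE, FALSE, FALSE)                            # low
#' classify_diversity("Other", NA, TRUE, TRUE, FALSE)                 # high
classify_diversity <- function(mother_race, caregiver_race = NA,
                               exp_white = FALSE, exp_asian = FALSE,
                               exp_black = FALSE,
                               questionnaire_present = TRUE) {
  if (!isTRUE(questionnaire_present)) return(NA_character_)
  groups <- character(0)
  if (!is.na(mother_race) && mother_race != "unclassified") {
    groups <- c(groups, mother_race)
  }
  if (!is.na(caregiver_race)) groups <- c(groups, caregiver_race)
  if (isTRUE(exp_white)) groups <- c(groups, "White")
  if (isTRUE(exp_asian)) groups <- c(groups, "Asian American")
  if (isTRUE(exp_black)) groups <- c(groups, "Black")
  n <- length(unique(groups))
  if (n == 0) {
    data_error("No classifiable face-experience source for this infant.")
  }
  c("low", "medium", "high")[min(n, 3)]
}

#' Classify a cohort's experience variables
#'
#' Applies the three classification rules to a subject covariate table in
#' the raw-report schema produced by [simulate_session()].
#'
#' @param profiles Tibble with columns `subject_id`, `age_days`,
#'   `mother_races` (`"+"`-separated), `mother_hispanic`, `caregiver_race`,
#'   `questionnaire_present`, `exp_white`, `exp_asian`, `exp_black`,
#'   `lang_english`, `lang_other`, `lang_other_name`.
#' @return Tibble: `subject_id`, `age_days`, `mother_race`, `diversity`,
#'   `language`.
#' @export
classify_subjects <- function(profiles) {
  check_columns(profiles,
                c("subject_id", "age_days", "mother_races", "mother_hispanic",
                  "caregiver_race", "questionnaire_present", "exp_white",
                  "exp_asian", "exp_black", "lang_english", "lang_other",
                  "lang_other_name"),
                "profiles")
  purrr::pmap_dfr(profiles, function(subject_id, age_days, mother_races,
                                     mother_hispanic, caregiver_race,
                                     questionnaire_present, exp_white,
                                     exp_asian, exp_black, lang_english,
                                     lang_other, lang_other_name, ...) {
    races <- strsplit(mother_races, "+", fixed = TRUE)[[1]]
    mrace <- classify_mother_race(races, mother_hispanic)
    exposure <- c(English = lang_english)
    if (!is.na(lang_other) && !is.na(lang_other_name)) {
      exposure <- c(exposure, setNames(lang_other, lang_other_name))
    }
    tibble(
      subject_id = subject_id,
      age_days = age_days,
      mother_race = mrace,
      diversity = classify_diversity(mrace, caregiver_race, exp_white,
                                     exp_asian, exp_black,
                                     questionnaire_present),
      language = classify_language(exposure)
    )
  })
}
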