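#' Cohort selection policy
#'
#' @param require_binary_sex drop persons whose sex at birth is not
#'   female/male (default `TRUE`).
#' @param gender_policy `"cisgender_only"` keeps only persons whose gender
#'   identity conforms to their sex at birth (woman with female, man with
#'   male); every other answer — opposite gender, transgender, nonbinary,
#'   other, skip, prefer_not_to_answer — is excluded.
#'   `"include_all_binary_sex"` keeps every binary-sex person regardless of
#'   gender identity (the sensitivity analysis).
#' @param min_year_of_birth unused hook, present for datasets carrying birth
#'   year; `NULL` disables it.
#' @return a `cohort_policy` object.
#' @export
cohort_policy <- function(require_binary_sex = TRUE,
                          gender_policy = c("cisgender_only",
                                            "include_all_binary_sex"),
                          min_year_of_birth = NULL) {
  structure(
    list(
      require_binary_sex = isTRUE(require_binary_sex),
      gender_policy = match.arg(gender_policy),
      min_year_of_birth = min_year_of_birth
    ),
    class = "cohort_policy"
  )
}

is_cisgender <- function(sex, gender) {
  (sex == "female" & gender == "woman") | (sex == "male" & gender == "man")
}

#' Select the analysis cohort
#'
#' Applies the participant filters in order: restrict to binary sex at birth,
#' then apply the gender policy. Counts remaining after each step are
#' recorded in the `"steps"` attribute (a tibble with columns `step` and
#' `n_remaining`) and can be written as a flowchart report.
#'
#' @param dataset an [omop_dataset()].
#' @param policy a [cohort_policy()].
#' @return character vector of selected `person_id`s, with a `"steps"`
#'   attribute logging the filter cascade.
#' @export
select_cohort <- function(dataset, policy = cohort_policy()) {
  stopifnot(inherits(dataset, "omop_dataset"), inherits(policy, "cohort_policy"))
  p <- dataset$persons
  steps <- tibble(step = "all_persons", n_remaining = nrow(p))
  if (policy$require_binary_sex) {
    p <- p[p$sex_at_birth %in% c("female", "male"), ]
    steps <- bind_rows(steps,
                       tibble(step = "binary_sex", n_remaining = nrow(p)))
  }
  if (policy$gender_policy == "cisgender_only") {
    p <- p[is_cisgender(p$sex_at_birth, p$gender_identity), ]
    steps <- bind_rows(steps,
                       tibble(step = "sex_conforming_gender",
                              n_remaining = nrow(p)))
  }
  ids <- p$person_id
  attr(ids, "steps") <- steps
  ids
}

#' Restrict a cohort to persons with EHR condition data
#'
#' Keeps the subset of `ids` having at least one condition-occurrence record.
#' Duplicate records do not matter; presence of any record suffices.
#'
#' @param dataset an [omop_dataset()].
#' @param ids character vector of person ids.
#' @return character vector, a subset of `ids`, preserving the `"steps"`
#'   attribute with an `ehr_condition_data` row appended when present.
#' @export
restrict_to_ehr <- function(dataset, ids) {
  stopifnot(inherits(dataset, "omop_dataset"))
  steps <- attr(ids, "steps")
  keep <- ids[ids %in% unique(dataset$occurrences$person_id)]
  if (!is.null(steps)) {
    attr(keep, "steps") <- bind_rows(
      steps, tibble(step = "ehr_condition_data", n_remaining = length(keep))
    )
  }
  keep
}

#' Filter-cascade counts of a selected cohort
#'
#' @param ids result of [select_cohort()] / [restrict_to_ehr()].
#' @return tibble with columns `step`, `n_remaining`.
#' @export
cohort_steps <- function(ids) {
  attr(ids, "steps") %||%
    tibble(step = "selected", n_remaining = length(ids))
}
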