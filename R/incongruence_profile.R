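#' Flag persons carrying sex-incongruent conditions
#'
#' A person is flagged when they carry at least one screened condition whose
#' specific sex differs from their sex at birth. The distinct incongruent
#' concepts of each flagged person are returned in a list column.
#'
#' @param dataset an [omop_dataset()].
#' @param cohort character vector of person ids.
#' @param conditions tibble from [screen_conditions()].
#' @return tibble with columns `person_id`, `sex_at_birth`,
#'   `n_incongruent_conditions` and `concept_ids` (list of integer vectors).
#' @export
flag_incongruent_persons <- function(dataset, cohort, conditions) {
  stopifnot(inherits(dataset, "omop_dataset"))
  dataset$occurrences %>%
    filter(.data$person_id %in% cohort,
           .data$concept_id %in% conditions$concept_id) %>%
    distinct(.data$person_id, .data$concept_id) %>%
    inner_join(dataset$persons[c("person_id", "sex_at_birth")],
               by = "person_id") %>%
    inner_join(conditions[c("concept_id", "specific_sex")],
               by = "concept_id") %>%
    filter(.data$sex_at_birth != .data$specific_sex) %>%
    group_by(.data$person_id, .data$sex_at_birth) %>%
    summarise(
      n_incongruent_conditions = dplyr::n(),
      concept_ids = list(sort(.data$concept_id)),
      .groups = "drop"
    ) %>%
    arrange(.data$person_id)
}

#' Genomic-sex concordance of flagged persons
#'
#' Cross-checks survey sex at birth against genomic-inferred sex for the
#' flagged persons: how many have a genomic record with a definite sex, and
#' how many of those match their survey answer.
#'
#' @param dataset an [omop_dataset()] whose `genomic_sex` table is present.
#' @param flagged output of [flag_incongruent_persons()].
#' @return one-row tibble: `n_flagged`, `n_retrieved`, `n_matched`,
#'   `match_fraction` (`NA` when nothing is retrieved).
#' @export
genomic_concordance <- function(dataset, flagged) {
  stopifnot(inherits(dataset, "omop_dataset"))
  if (is.null(dataset$genomic_sex)) {
    abort("genomic_sex table not available in this dataset")
  }
  joined <- flagged %>%
    left_join(dataset$genomic_sex, by = "person_id") %>%
    filter(!is.na(.data$inferred_sex), .data$inferred_sex != "unknown")
  n_flagged <- nrow(flagged)
  n_retrieved <- nrow(joined)
  n_matched <- sum(joined$inferred_sex == joined$sex_at_birth)
  tibble(
    n_flagged = n_flagged, n_retrieved = n_retrieved, n_matched = n_matched,
    match_fraction = if (n_retrieved > 0) n_matched / n_retrieved else NA_real_
  )
}

# distinct person-condition pairs for the screened conditions, annotated with
# the person's sex and each condition's specific sex
screened_pairs <- function(dataset, cohort, conditions) {
  dataset$occurrences %>%
    filter(.data$person_id %in% cohort,
           .data$concept_id %in% conditions$concept_id) %>%
    distinct(.data$person_id, .data$concept_id) %>%
    inner_join(dataset$persons[c("person_id", "sex_at_birth")],
               by = "person_id") %>%
    inner_join(conditions[c("concept_id", "specific_sex")],
               by = "concept_id")
}

#' Concurrent congruent conditions among flagged persons
#'
#' Of the persons flagged with incongruent sex-specific conditions, the
#' fraction per sex who also carry at least one screened condition congruent
#' to their own sex — the signature separating record-level logging errors (a
#' mix of accurate and erroneous records) from wholesale sex mislabelling.
#'
#' @inheritParams flag_incongruent_persons
#' @return tibble with one row per sex present among flagged persons:
#'   `sex_at_birth`, `n_flagged`, `n_concurrent`, `proportion`.
#' @export
concurrence_rates <- function(dataset, cohort, conditions) {
  pairs <- screened_pairs(dataset, cohort, conditions)
  pairs %>%
    group_by(.data$person_id, .data$sex_at_birth) %>%
    summarise(
      any_incongruent = any(.data$sex_at_birth != .data$specific_sex),
      any_congruent = any(.data$sex_at_birth == .data$specific_sex),
      .groups = "drop"
    ) %>%
    filter(.data$any_incongruent) %>%
    group_by(.data$sex_at_birth) %>%
    summarise(
      n_flagged = dplyr::n(),
      n_concurrent = sum(.data$any_congruent),
      proportion = .data$n_concurrent / .data$n_flagged,
      .groups = "drop"
    )
}

#' Multiplicity of sex-specific conditions per person
#'
#' Per sex and congruence class, the fraction of persons with more than one
#' distinct screened condition of that class (repeat records of one concept
#' do not count). Denominators are the persons with at least one condition of
#' the class.
#'
#' @inheritParams flag_incongruent_persons
#' @return tibble with columns `sex_at_birth`, `congruence_class`
#'   (`incongruent`/`congruent`), `n_persons`, `n_multiple`, `proportion`.
#' @export
multiplicity_rates <- function(dataset, cohort, conditions) {
  pairs <- screened_pairs(dataset, cohort, conditions) %>%
    mutate(congruence_class = if_else(
      .data$sex_at_birth == .data$specific_sex, "congruent", "incongruent"
    ))
  pairs %>%
    count(.data$person_id, .data$sex_at_birth, .data$congruence_class,
          name = "n_conditions") %>%
    group_by(.data$sex_at_birth, .data$congruence_class) %>%
    summarise(
      n_persons = dplyr::n(),
      n_multiple = sum(.data$n_conditions > 1),
      proportion = .data$n_multiple / .data$n_persons,
      .groups = "drop"
    )
}

#' Geographic (zip3) profile of incongruent persons
#'
#' For every zip3 with at least one cohort member, the fraction of the
#' profiled population living there and the fraction of all flagged persons
#' living there (both columns sum to 1). The summary reports how many zip3s
#' contain a flagged person, the Pearson correlation between the two fraction
#' columns across zip3s, and quantiles of zip3 population size split by
#' whether the zip3 contains a flagged person — under uniform record
#' misassignment the flagged persons mirror the population, and unflagged
#' zip3s are the less populous ones.
#'
#' @param dataset an [omop_dataset()] whose `zip3` table is present.
#' @param cohort character vector of person ids.
#' @param flagged output of [flag_incongruent_persons()].
#' @return list with `profile` (tibble of `zip3`, `n_persons`, `n_flagged`,
#'   `population_fraction`, `incongruent_fraction`) and `summary` (list with
#'   `n_zip3`, `n_zip3_flagged`, `correlation`, and `population_quantiles`, a
#'   tibble of population-size quantiles by flagged status).
#' @export
geographic_profile <- function(dataset, cohort, flagged) {
  stopifnot(inherits(dataset, "omop_dataset"))
  if (is.null(dataset$zip3)) {
    abort("zip3 table not available in this dataset")
  }
  zips <- dataset$zip3 %>% filter(.data$person_id %in% cohort)
  profile <- zips %>%
    group_by(.data$zip3) %>%
    summarise(
      n_persons = dplyr::n(),
      n_flagged = sum(.data$person_id %in% flagged$person_id),
      .groups = "drop"
    )
  total_flagged <- sum(profile$n_flagged)
  profile <- profile %>%
    mutate(
      population_fraction = .data$n_persons / sum(.data$n_persons),
      incongruent_fraction = if (total_flagged > 0) {
        .data$n_flagged / total_flagged
      } else NA_real_
    )
  correlation <- if (nrow(profile) > 1 && total_flagged > 0) {
    stats::cor(profile$population_fraction, profile$incongruent_fraction)
  } else NA_real_
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  pop_q <- profile %>%
    mutate(has_flagged = .data$n_flagged > 0) %>%
    group_by(.data$has_flagged) %>%
    summarise(
      n_zip3 = dplyr::n(),
      q = list(stats::quantile(.data$n_persons, qs)),
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("q")
  list(
    profile = profile,
    summary = list(
      n_zip3 = nrow(profile),
      n_zip3_flagged = sum(profile$n_flagged > 0),
      correlation = correlation,
      population_quantiles = pop_q
    )
  )
}

#' Temporal profile of condition records
#'
#' Counts condition records (not persons) by calendar start year, split by
#' the condition's sex specificity and by whether the record's person is
#' congruent with it. Similar year distributions across the four classes
#' indicate the logging errors are not confined to a period.
#'
#' @inheritParams flag_incongruent_persons
#' @return tibble with columns `year`, `sex_specificity`
#'   (`female_specific`/`male_specific`), `congruence_class`, `n_records`.
#' @export
temporal_profile <- function(dataset, cohort, conditions) {
  stopifnot(inherits(dataset, "omop_dataset"))
  if (nrow(conditions) == 0) {
    return(tibble(year = integer(), sex_specificity = character(),
                  congruence_class = character(), n_records = integer()))
  }
  dataset$occurrences %>%
    filter(.data$person_id %in% cohort,
           .data$concept_id %in% conditions$concept_id) %>%
    inner_join(dataset$persons[c("person_id", "sex_at_birth")],
               by = "person_id") %>%
    inner_join(conditions[c("concept_id", "specific_sex")],
               by = "concept_id") %>%
    mutate(
      year = as.integer(format(.data$start_date, "%Y")),
      sex_specificity = paste0(.data$specific_sex, "_specific"),
      congruence_class = if_else(
        .data$sex_at_birth == .data$specific_sex, "congruent", "incongruent"
      )
    ) %>%
    count(.data$year, .data$sex_specificity, .data$congruence_class,
          name = "n_records") %>%
    arrange(.data$year, .data$sex_specificity, .data$congruence_class)
}

#' Sensitivity analysis: re-admit non-cisgender participants
#'
#' Recomputes the combined overall incongruence rate with the gender filter
#' relaxed to every binary-sex person (`include_all_binary_sex`), and
#' tabulates gender-identity composition among all binary-sex participants
#' versus flagged participants. Skip and prefer-not-to-answer responses are
#' removed from the composition table (they carry no identity information),
#' though such persons still enter the sensitivity rate.
#'
#' @param dataset an [omop_dataset()].
#' @param conditions tibble from [screen_conditions()].
#' @param z normal quantile for the interval.
#' @return list with `oir` (one-row tibble as [compute_oir()]) and
#'   `composition` (tibble of `gender_identity`, `fraction_all`,
#'   `fraction_flagged`; each fraction column sums to 1).
#' @export
sensitivity_noncisgender <- function(dataset, conditions, z = 1.96) {
  stopifnot(inherits(dataset, "omop_dataset"))
  cohort <- select_cohort(
    dataset, cohort_policy(gender_policy = "include_all_binary_sex")
  )
  cohort <- restrict_to_ehr(dataset, cohort)
  oir <- compute_oir(dataset, cohort, conditions, "combined", z = z)
  flagged <- flag_incongruent_persons(dataset, cohort, conditions)
  comp_base <- dataset$persons %>%
    filter(.data$person_id %in% cohort,
           !(.data$gender_identity %in% c("skip", "prefer_not_to_answer")))
  frac <- function(df) {
    df %>%
      count(.data$gender_identity) %>%
      mutate(fraction = .data$n / sum(.data$n)) %>%
      select("gender_identity", "fraction")
  }
  composition <- frac(comp_base) %>%
    rename(fraction_all = "fraction") %>%
    dplyr::full_join(
      frac(comp_base %>% filter(.data$person_id %in% flagged$person_id)) %>%
        rename(fraction_flagged = "fraction"),
      by = "gender_identity"
    ) %>%
    mutate(dplyr::across(dplyr::starts_with("fraction"),
                         ~ tidyr::replace_na(.x, 0)))
  list(oir = oir, composition = composition)
}
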