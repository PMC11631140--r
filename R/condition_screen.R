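#' Screening configuration for sex-specific conditions
#'
#' Thresholds for the data-driven condition screen: a minimum distinct
#' participant count, a strict single-sex bias threshold (analogous to the 5%
#' significance convention), name-based exclusions for breast/mammary
#' findings (which occur in both sexes), a higher prevalence cut for reliable
#' rate estimation, and an optional manual exclusion list for conditions a
#' clinical review rejects.
#'
#' @param min_condition_participants conditions in fewer distinct
#'   participants are dropped (default 20; exactly 20 is kept).
#' @param bias_threshold strict lower bound on the majority-sex fraction
#'   (default 0.95; exactly 0.95 is rejected). Must lie in (0.5, 1).
#' @param min_prevalent_participants prevalence cut (default 1000; exactly
#'   1000 is kept).
#' @param name_exclusion_patterns case-insensitive substrings; conditions
#'   whose name matches any are dropped.
#' @param manual_exclusion_concept_ids concept ids to drop after review.
#' @return a `screen_config` object.
#' @export
screen_config <- function(min_condition_participants = 20L,
                          bias_threshold = 0.95,
                          min_prevalent_participants = 1000L,
                          name_exclusion_patterns = c("breast", "mammary"),
                          manual_exclusion_concept_ids = integer()) {
  if (!(bias_threshold > 0.5 && bias_threshold < 1)) {
    abort("bias_threshold must be in (0.5, 1)")
  }
  if (min_condition_participants <= 0 || min_prevalent_participants <= 0) {
    abort("participant thresholds must be positive")
  }
  structure(
    list(
      min_condition_participants = as.integer(min_condition_participants),
      bias_threshold = bias_threshold,
      min_prevalent_participants = as.integer(min_prevalent_participants),
      name_exclusion_patterns = as.character(name_exclusion_patterns),
      manual_exclusion_concept_ids = as.integer(manual_exclusion_concept_ids)
    ),
    class = "screen_config"
  )
}

#' Distinct-participant condition counts by sex
#'
#' For every condition appearing in any cohort member's records, counts the
#' distinct female and male participants carrying it (a person is counted
#' once per condition however many records they have), and derives the
#' majority sex and majority fraction.
#'
#' @param dataset an [omop_dataset()].
#' @param cohort character vector of person ids with binary sex at birth.
#' @return tibble with columns `concept_id`, `concept_name`, `n_female`,
#'   `n_male`, `n_total`, `majority_sex` (`female`/`male`/`none`),
#'   `majority_fraction`.
#' @export
count_by_sex <- function(dataset, cohort) {
  stopifnot(inherits(dataset, "omop_dataset"))
  sex <- dataset$persons[c("person_id", "sex_at_birth")]
  occ <- dataset$occurrences %>%
    filter(.data$person_id %in% cohort) %>%
    distinct(.data$person_id, .data$concept_id) %>%
    inner_join(sex, by = "person_id")
  counts <- occ %>%
    group_by(.data$concept_id) %>%
    summarise(
      n_female = sum(.data$sex_at_birth == "female"),
      n_male = sum(.data$sex_at_birth == "male"),
      .groups = "drop"
    ) %>%
    mutate(
      n_total = .data$n_female + .data$n_male,
      majority_sex = dplyr::case_when(
        n_female > n_male ~ "female",
        n_male > n_female ~ "male",
        TRUE ~ "none"
      ),
      majority_fraction = if_else(
        .data$n_total > 0,
        pmax(.data$n_female, .data$n_male) / .data$n_total,
        NA_real_
      )
    )
  if (!is.null(dataset$concepts)) {
    counts <- counts %>%
      left_join(dataset$concepts, by = "concept_id")
  } else {
    counts$concept_name <- NA_character_
  }
  counts %>%
    select("concept_id", "concept_name", "n_female", "n_male", "n_total",
           "majority_sex", "majority_fraction") %>%
    arrange(.data$concept_id)
}

#' Screen conditions for sex specificity
#'
#' Applies the screening cascade to per-condition sex counts: (1) at least
#' `min_condition_participants` distinct participants; (2) majority-sex
#' fraction strictly greater than `bias_threshold`; (3) condition name
#' matches no exclusion pattern; (4) at least `min_prevalent_participants`
#' participants; (5) concept id not manually excluded. Surviving conditions
#' are labelled with their majority sex as `specific_sex`. The per-stage
#' surviving counts are recorded in the `"stages"` attribute.
#'
#' @param counts output of [count_by_sex()].
#' @param config a [screen_config()].
#' @return tibble of sex-specific conditions: `concept_id`, `concept_name`,
#'   `specific_sex`, `n_female`, `n_male`, `n_total`, `majority_fraction`;
#'   attribute `"stages"` is a tibble (`stage`, `n_conditions_remaining`).
#' @export
screen_conditions <- function(counts, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  zero <- counts$n_total == 0
  if (any(zero)) {
    warn(sprintf("%d condition(s) with zero participants skipped", sum(zero)))
    counts <- counts[!zero, ]
  }
  stages <- tibble(stage = "all_conditions",
                   n_conditions_remaining = nrow(counts))
  log_stage <- function(df, stage) {
    stages <<- bind_rows(stages,
                         tibble(stage = stage, n_conditions_remaining = nrow(df)))
    df
  }
  out <- counts %>%
    filter(.data$n_total >= config$min_condition_participants) %>%
    log_stage("min_participants") %>%
    filter(.data$majority_fraction > config$bias_threshold) %>%
    log_stage("sex_bias")
  if (length(config$name_exclusion_patterns)) {
    pat <- paste(config$name_exclusion_patterns, collapse = "|")
    out <- out %>%
      filter(is.na(.data$concept_name) |
               !grepl(pat, .data$concept_name, ignore.case = TRUE))
  }
  out <- log_stage(out, "name_exclusions") %>%
    filter(.data$n_total >= config$min_prevalent_participants) %>%
    log_stage("min_prevalent") %>%
    filter(!(.data$concept_id %in% config$manual_exclusion_concept_ids)) %>%
    log_stage("manual_exclusions") %>%
    mutate(specific_sex = .data$majority_sex) %>%
    select("concept_id", "concept_name", "specific_sex", "n_female",
           "n_male", "n_total", "majority_fraction")
  attr(out, "stages") <- stages
  out
}

#' Stage-by-stage condition counts of a screen
#'
#' @param screened output of [screen_conditions()].
#' @return tibble with columns `stage`, `n_conditions_remaining`.
#' @export
screen_stages <- function(screened) {
  attr(screened, "stages") %||%
    tibble(stage = "screened", n_conditions_remaining = nrow(screened))
}
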