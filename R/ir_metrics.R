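#' Wald confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`. Bounds are
#' deliberately not clamped to [0, 1]: published per-condition intervals for
#' small incongruent counts carry negative lower bounds, and clamping would
#' hide how uninformative those intervals are. Set `clamp = TRUE` to restrict
#' to the unit interval.
#'
#' @param p proportion(s) in [0, 1].
#' @param n positive count(s) used as the interval's sample size.
#' @param z normal quantile; 1.96 for a 95% interval.
#' @param clamp clamp bounds to [0, 1] (default `FALSE`).
#' @return tibble with columns `ci_low`, `ci_high`, one row per element of
#'   `p`/`n` (recycled).
#' @export
wald_ci <- function(p, n, z = 1.96, clamp = FALSE) {
  if (any(n <= 0)) abort("n must be positive")
  if (any(p < 0 | p > 1)) abort("p must be in [0,1]")
  half <- z * sqrt(p * (1 - p) / n)
  lo <- p - half
  hi <- p + half
  if (clamp) {
    lo <- pmax(lo, 0)
    hi <- pmin(hi, 1)
  }
  tibble(ci_low = lo, ci_high = hi)
}

#' Build a rate estimate from incongruent/congruent counts
#'
#' The incongruence rate is `n_incongruent / (n_incongruent + n_congruent)`.
#' The confidence interval is Wald; its `n` is the total count by default
#' (`ci_n_mode = "total"`, the formula's natural sample size) or the
#' incongruent count (`ci_n_mode = "incongruent"`, the convention under which
#' published per-condition intervals are reproducible).
#'
#' @param label row label (condition or collective-set name).
#' @param n_incongruent,n_congruent nonnegative counts (vectorised).
#' @param z normal quantile for the interval.
#' @param ci_n_mode `"total"` or `"incongruent"`.
#' @return tibble with columns `label`, `n_incongruent`, `n_congruent`,
#'   `n_total`, `rate`, `ci_low`, `ci_high`, `z`, `ci_n_mode`.
#' @export
rate_estimate <- function(label, n_incongruent, n_congruent, z = 1.96,
                          ci_n_mode = c("total", "incongruent")) {
  ci_n_mode <- match.arg(ci_n_mode)
  if (any(n_incongruent < 0) || any(n_congruent < 0)) {
    abort("counts must be nonnegative")
  }
  n_total <- n_incongruent + n_congruent
  if (any(n_total == 0)) {
    abort("rate undefined: no participants carry the condition(s)")
  }
  rate <- n_incongruent / n_total
  ci_n <- switch(ci_n_mode, total = n_total, incongruent = n_incongruent)
  lo <- rep(NA_real_, length(rate))
  hi <- rep(NA_real_, length(rate))
  ok <- ci_n > 0
  if (any(ok)) {
    ci <- wald_ci(rate[ok], ci_n[ok], z = z)
    lo[ok] <- ci$ci_low
    hi[ok] <- ci$ci_high
  }
  tibble(
    label = label, n_incongruent = as.integer(n_incongruent),
    n_congruent = as.integer(n_congruent), n_total = as.integer(n_total),
    rate = rate, ci_low = lo, ci_high = hi, z = z, ci_n_mode = ci_n_mode
  )
}

#' Condition-specific incongruence rates (CIR)
#'
#' For each screened sex-specific condition, counts the distinct cohort
#' members carrying it whose sex at birth conflicts with the condition's
#' specific sex (incongruent) and those whose sex matches (congruent), and
#' returns the per-condition rate with its confidence interval.
#'
#' @param dataset an [omop_dataset()].
#' @param cohort character vector of person ids (binary sex).
#' @param conditions tibble from [screen_conditions()] (needs `concept_id`,
#'   `concept_name`, `specific_sex`).
#' @param z normal quantile for the interval.
#' @param ci_n_mode see [rate_estimate()].
#' @return tibble with one row per condition: `concept_id`, `specific_sex`,
#'   plus the [rate_estimate()] columns.
#' @export
compute_cir <- function(dataset, cohort, conditions, z = 1.96,
                        ci_n_mode = c("total", "incongruent")) {
  ci_n_mode <- match.arg(ci_n_mode)
  stopifnot(inherits(dataset, "omop_dataset"))
  if (nrow(conditions) == 0) {
    abort("no conditions supplied")
  }
  sex <- dataset$persons[c("person_id", "sex_at_birth")]
  carriers <- dataset$occurrences %>%
    filter(.data$person_id %in% cohort,
           .data$concept_id %in% conditions$concept_id) %>%
    distinct(.data$person_id, .data$concept_id) %>%
    inner_join(sex, by = "person_id") %>%
    inner_join(conditions[c("concept_id", "concept_name", "specific_sex")],
               by = "concept_id")
  counts <- carriers %>%
    group_by(.data$concept_id, .data$concept_name, .data$specific_sex) %>%
    summarise(
      n_incongruent = sum(.data$sex_at_birth != .data$specific_sex),
      n_congruent = sum(.data$sex_at_birth == .data$specific_sex),
      .groups = "drop"
    )
  missing <- dplyr::anti_join(conditions, counts, by = "concept_id")
  if (nrow(missing)) {
    abort(sprintf(
      "rate undefined for %d condition(s) with no cohort carriers (e.g. %s)",
      nrow(missing), paste(utils::head(missing$concept_id, 3), collapse = ", ")
    ))
  }
  est <- rate_estimate(counts$concept_name, counts$n_incongruent,
                       counts$n_congruent, z = z, ci_n_mode = ci_n_mode)
  dplyr::bind_cols(
    counts[c("concept_id", "specific_sex")], est
  ) %>%
    arrange(dplyr::desc(.data$rate))
}

#' Overall incongruence rate (OIR)
#'
#' Treats a set of sex-specific conditions collectively. For the
#' female-specific (resp. male-specific) subset, the incongruent count is the
#' number of distinct cohort persons of the non-matching sex carrying at
#' least one listed condition, and the congruent count the distinct persons
#' of the matching sex carrying at least one — each person counted once
#' however many listed conditions they have. The combined subset sums the
#' female- and male-specific counts, so a person carrying conditions of both
#' specificities contributes to both components. The interval always uses
#' `n = n_total`.
#'
#' @param dataset an [omop_dataset()].
#' @param cohort character vector of person ids.
#' @param conditions tibble from [screen_conditions()].
#' @param sex_subset `"combined"`, `"female_specific"` or `"male_specific"`.
#' @param z normal quantile for the interval.
#' @return one-row tibble of [rate_estimate()] columns plus `n_conditions`.
#' @export
compute_oir <- function(dataset, cohort, conditions,
                        sex_subset = c("combined", "female_specific",
                                       "male_specific"),
                        z = 1.96) {
  sex_subset <- match.arg(sex_subset)
  stopifnot(inherits(dataset, "omop_dataset"))
  subset_counts <- function(spec_sex) {
    concept_ids <- conditions$concept_id[conditions$specific_sex == spec_sex]
    if (!length(concept_ids)) {
      abort(sprintf("no %s-specific conditions in the screened set", spec_sex))
    }
    persons <- dataset$occurrences %>%
      filter(.data$person_id %in% cohort,
             .data$concept_id %in% concept_ids) %>%
      distinct(.data$person_id) %>%
      inner_join(dataset$persons[c("person_id", "sex_at_birth")],
                 by = "person_id")
    c(
      incongruent = sum(persons$sex_at_birth != spec_sex),
      congruent = sum(persons$sex_at_birth == spec_sex),
      n_conditions = length(concept_ids)
    )
  }
  counts <- switch(sex_subset,
    female_specific = subset_counts("female"),
    male_specific = subset_counts("male"),
    combined = subset_counts("female") + subset_counts("male")
  )
  est <- rate_estimate(
    sex_subset, counts[["incongruent"]], counts[["congruent"]],
    z = z, ci_n_mode = "total"
  )
  est$n_conditions <- as.integer(counts[["n_conditions"]])
  est
}

#' Mask small counts in a report table
#'
#' Replaces every count strictly below `threshold` with the marker
#' `"<threshold>"` and masks rate/interval columns of the affected rows, for
#' public reporting under small-cell suppression policies. A count equal to
#' the threshold is never masked.
#'
#' @param tbl a data frame.
#' @param threshold suppression threshold (default 20).
#' @param count_cols columns holding counts; defaults to every numeric column
#'   whose name starts with `n_`.
#' @param rate_cols columns masked alongside; defaults to the intersection of
#'   `c("rate", "ci_low", "ci_high")` with the table's names.
#' @return tibble with masked columns converted to character.
#' @export
mask_small_counts <- function(tbl, threshold = 20L,
                              count_cols = NULL, rate_cols = NULL) {
  tbl <- as_tibble(tbl)
  if (is.null(count_cols)) {
    count_cols <- names(tbl)[startsWith(names(tbl), "n_") &
                               vapply(tbl, is.numeric, logical(1))]
  }
  if (is.null(rate_cols)) {
    rate_cols <- intersect(c("rate", "ci_low", "ci_high"), names(tbl))
  }
  marker <- paste0("<", threshold)
  masked_row <- rep(FALSE, nrow(tbl))
  for (col in count_cols) {
    v <- tbl[[col]]
    hit <- !is.na(v) & v < threshold
    masked_row <- masked_row | hit
    out <- as.character(v)
    out[hit] <- marker
    tbl[[col]] <- out
  }
  for (col in rate_cols) {
    out <- as.character(tbl[[col]])
    out[masked_row] <- "masked"
    tbl[[col]] <- out
  }
  tbl
}
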