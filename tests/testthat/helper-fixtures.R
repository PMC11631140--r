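# Hand-built fixtures and independent brute-force oracles. The oracles use
# plain loops over raw records on purpose: they must not share code paths
# with the package functions they check.

tiny_persons <- function() {
  tibble::tibble(
    person_id = c("f1", "f2", "f3", "m1", "m2", "m3", "x1", "tf1", "tm1"),
    sex_at_birth = c("female", "female", "female", "male", "male", "male",
                     "other_or_unknown", "female", "male"),
    gender_identity = c("woman", "woman", "woman", "man", "man", "man",
                        "man", "man", "woman")
  )
}

tiny_dataset <- function() {
  omop_dataset(
    persons = tiny_persons(),
    occurrences = tibble::tibble(
      person_id = c("f1", "f1", "f2", "m1", "m2", "m2", "f3", "tf1"),
      concept_id = c(10L, 10L, 10L, 20L, 20L, 10L, 30L, 20L),
      start_date = as.Date(c("2010-05-01", "2011-06-01", "2012-01-15",
                             "2015-03-03", "2016-08-08", "2017-09-09",
                             "2018-02-02", "2019-04-04"))
    ),
    concepts = tibble::tibble(
      concept_id = c(10L, 20L, 30L),
      concept_name = c("Ovarian cyst", "Testicular hypofunction",
                       "Essential hypertension")
    ),
    genomic_sex = tibble::tibble(
      person_id = c("f1", "f2", "m1", "m2", "tf1"),
      inferred_sex = c("female", "female", "male", "male", "female")
    ),
    zip3 = tibble::tibble(
      person_id = c("f1", "f2", "f3", "m1", "m2", "tf1"),
      zip3 = c("750", "750", "751", "750", "752", "751")
    )
  )
}

# small seeded synthetic dataset for property tests
small_cohort <- function(seed, n = 500, error_rate = 0.05) {
  generate_cohort(synthetic_config(
    n_persons = n,
    error_rate = error_rate,
    records_per_carrier = 2,
    seed = seed
  ))
}

# relaxed screen thresholds usable at a few hundred persons
small_screen <- function() {
  screen_config(min_condition_participants = 5L, bias_threshold = 0.8,
                min_prevalent_participants = 5L)
}

# sex lookup as a plain named vector
sex_of <- function(ds) {
  stats::setNames(ds$persons$sex_at_birth, ds$persons$person_id)
}

bf_count_by_sex <- function(ds, cohort) {
  sx <- sex_of(ds)
  occ <- ds$occurrences[ds$occurrences$person_id %in% cohort, ]
  out <- list()
  for (cid in sort(unique(occ$concept_id))) {
    carriers <- unique(occ$person_id[occ$concept_id == cid])
    nf <- 0L; nm <- 0L
    for (p in carriers) {
      if (sx[[p]] == "female") nf <- nf + 1L
      if (sx[[p]] == "male") nm <- nm + 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      concept_id = cid, n_female = nf, n_male = nm, n_total = nf + nm
    )
  }
  do.call(rbind, out)
}

bf_cir_counts <- function(ds, cohort, concept_id, specific_sex) {
  sx <- sex_of(ds)
  occ <- ds$occurrences
  carriers <- unique(occ$person_id[occ$concept_id == concept_id &
                                     occ$person_id %in% cohort])
  inc <- 0L; con <- 0L
  for (p in carriers) {
    if (sx[[p]] == specific_sex) con <- con + 1L else inc <- inc + 1L
  }
  c(incongruent = inc, congruent = con)
}

bf_oir_counts <- function(ds, cohort, conditions, spec_sex) {
  sx <- sex_of(ds)
  ids <- conditions$concept_id[conditions$specific_sex == spec_sex]
  occ <- ds$occurrences
  carriers <- unique(occ$person_id[occ$concept_id %in% ids &
                                     occ$person_id %in% cohort])
  inc <- 0L; con <- 0L
  for (p in carriers) {
    if (sx[[p]] == spec_sex) con <- con + 1L else inc <- inc + 1L
  }
  c(incongruent = inc, congruent = con)
}

bf_flagged <- function(ds, cohort, conditions) {
  sx <- sex_of(ds)
  spec <- stats::setNames(conditions$specific_sex, conditions$concept_id)
  occ <- ds$occurrences[ds$occurrences$person_id %in% cohort &
                          ds$occurrences$concept_id %in% conditions$concept_id, ]
  flagged <- list()
  for (p in unique(occ$person_id)) {
    cids <- unique(occ$concept_id[occ$person_id == p])
    bad <- cids[spec[as.character(cids)] != sx[[p]]]
    if (length(bad)) flagged[[p]] <- sort(bad)
  }
  flagged
}

bf_concurrence <- function(ds, cohort, conditions) {
  sx <- sex_of(ds)
  spec <- stats::setNames(conditions$specific_sex, conditions$concept_id)
  occ <- ds$occurrences[ds$occurrences$person_id %in% cohort &
                          ds$occurrences$concept_id %in% conditions$concept_id, ]
  res <- list(female = c(flagged = 0L, concurrent = 0L),
              male = c(flagged = 0L, concurrent = 0L))
  for (p in unique(occ$person_id)) {
    cids <- unique(occ$concept_id[occ$person_id == p])
    s <- sx[[p]]
    has_inc <- any(spec[as.character(cids)] != s)
    has_con <- any(spec[as.character(cids)] == s)
    if (has_inc) {
      res[[s]]["flagged"] <- res[[s]]["flagged"] + 1L
      if (has_con) res[[s]]["concurrent"] <- res[[s]]["concurrent"] + 1L
    }
  }
  res
}

bf_geo_fractions <- function(ds, cohort, flagged_ids) {
  zt <- ds$zip3[ds$zip3$person_id %in% cohort, ]
  zips <- sort(unique(zt$zip3))
  n_pop <- integer(length(zips))
  n_flag <- integer(length(zips))
  for (i in seq_along(zips)) {
    people <- zt$person_id[zt$zip3 == zips[i]]
    n_pop[i] <- length(people)
    n_flag[i] <- sum(people %in% flagged_ids)
  }
  data.frame(
    zip3 = zips, n_persons = n_pop, n_flagged = n_flag,
    population_fraction = n_pop / sum(n_pop),
    incongruent_fraction = if (sum(n_flag) > 0) n_flag / sum(n_flag) else NA_real_
  )
}

bf_multiplicity <- function(ds, cohort, conditions) {
  sx <- sex_of(ds)
  spec <- stats::setNames(conditions$specific_sex, conditions$concept_id)
  occ <- ds$occurrences[ds$occurrences$person_id %in% cohort &
                          ds$occurrences$concept_id %in% conditions$concept_id, ]
  out <- list()
  for (p in unique(occ$person_id)) {
    cids <- unique(occ$concept_id[occ$person_id == p])
    s <- sx[[p]]
    for (cls in c("congruent", "incongruent")) {
      k <- sum((spec[as.character(cids)] == s) == (cls == "congruent"))
      if (k > 0) {
        key <- paste(s, cls)
        prev <- out[[key]] %||% c(n = 0L, multiple = 0L)
        prev["n"] <- prev["n"] + 1L
        if (k > 1) prev["multiple"] <- prev["multiple"] + 1L
        out[[key]] <- prev
      }
    }
  }
  out
}
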