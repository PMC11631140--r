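screened_tiny <- function() {
  tibble::tibble(
    concept_id = c(10L, 20L),
    concept_name = c("Ovarian cyst", "Testicular hypofunction"),
    specific_sex = c("female", "male")
  )
}

test_that("flagging keeps only persons with cross-sex conditions", {
  ds <- tiny_dataset()
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  flagged <- flag_incongruent_persons(ds, cohort, screened_tiny())
  # m2 carries the female-specific concept 10; m1 only male-specific ones
  expect_equal(flagged$person_id, "m2")
  expect_equal(flagged$concept_ids[[1]], 10L)
  expect_equal(flagged$n_incongruent_conditions, 1L)
})

test_that("an error-free generator yields no flagged persons", {
  ds <- generate_cohort(synthetic_config(n_persons = 2000, error_rate = 0,
                                         seed = 3))
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  flagged <- flag_incongruent_persons(ds, cohort, conds)
  expect_equal(nrow(flagged), 0)
})

test_that("flagged persons reconcile exactly with the combined OIR numerator", {
  ds <- small_cohort(seed = 51, n = 800)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  flagged <- flag_incongruent_persons(ds, cohort, conds)
  comb <- compute_oir(ds, cohort, conds, "combined")
  expect_equal(nrow(flagged), comb$n_incongruent)
})

test_that("genomic concordance counts retrievals and matches", {
  ds <- tiny_dataset()
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  flagged <- flag_incongruent_persons(ds, cohort, screened_tiny())
  conc <- genomic_concordance(ds, flagged)
  expect_equal(conc$n_flagged, 1L)
  expect_equal(conc$n_retrieved, 1L)
  expect_equal(conc$match_fraction, 1)
  # no flagged persons: fraction undefined
  empty <- flagged[0, ]
  conc0 <- genomic_concordance(ds, empty)
  expect_equal(conc0$n_flagged, 0L)
  expect_true(is.na(conc0$match_fraction))
  # absent table is an explicit error, not a silent skip
  ds2 <- ds
  ds2$genomic_sex <- NULL
  expect_error(genomic_concordance(ds2, flagged), "not available")
})

test_that("perfect generator concordance and a seeded mismatch rate", {
  ds <- small_cohort(seed = 52, n = 2000)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  flagged <- flag_incongruent_persons(ds, cohort, conds)
  expect_gt(nrow(flagged), 0)
  expect_equal(genomic_concordance(ds, flagged)$match_fraction, 1)

  # with a 10% mismatch rate the match fraction sits in the binomial band
  ds2 <- generate_cohort(synthetic_config(
    n_persons = 20000, error_rate = 0.05, genomic_mismatch_rate = 0.1,
    records_per_carrier = 2, seed = 53
  ))
  cohort2 <- restrict_to_ehr(ds2, select_cohort(ds2))
  conds2 <- screen_conditions(count_by_sex(ds2, cohort2), small_screen())
  flagged2 <- flag_incongruent_persons(ds2, cohort2, conds2)
  conc2 <- genomic_concordance(ds2, flagged2)
  ci <- stats::binom.test(conc2$n_matched, conc2$n_retrieved)$conf.int
  expect_gte(0.9, ci[1])
  expect_lte(0.9, ci[2])
})

test_that("concurrence and multiplicity match brute-force recounts", {
  for (seed in c(54, 55)) {
    ds <- small_cohort(seed = seed, n = 800)
    cohort <- restrict_to_ehr(ds, select_cohort(ds))
    conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
    conc <- concurrence_rates(ds, cohort, conds)
    want <- bf_concurrence(ds, cohort, conds)
    for (s in conc$sex_at_birth) {
      row <- conc[conc$sex_at_birth == s, ]
      expect_equal(row$n_flagged, unname(want[[s]]["flagged"]))
      expect_equal(row$n_concurrent, unname(want[[s]]["concurrent"]))
    }
    mult <- multiplicity_rates(ds, cohort, conds)
    wantm <- bf_multiplicity(ds, cohort, conds)
    for (i in seq_len(nrow(mult))) {
      key <- paste(mult$sex_at_birth[i], mult$congruence_class[i])
      expect_equal(mult$n_persons[i], unname(wantm[[key]]["n"]))
      expect_equal(mult$n_multiple[i], unname(wantm[[key]]["multiple"]))
    }
  }
})

test_that("multiplicity counts distinct concepts, not repeat records", {
  ds <- omop_dataset(
    persons = tibble::tibble(
      person_id = c("f1", "f2", "m1"),
      sex_at_birth = c("female", "female", "male"),
      gender_identity = c("woman", "woman", "man")
    ),
    occurrences = tibble::tibble(
      # f1: two records of ONE concept; f2: two distinct concepts
      person_id = c("f1", "f1", "f2", "f2", "m1"),
      concept_id = c(10L, 10L, 10L, 11L, 20L),
      start_date = as.Date("2020-06-01")
    )
  )
  conds <- tibble::tibble(
    concept_id = c(10L, 11L, 20L),
    concept_name = c("a", "b", "c"),
    specific_sex = c("female", "female", "male")
  )
  cohort <- ds$persons$person_id
  mult <- multiplicity_rates(ds, cohort, conds)
  fem <- mult[mult$sex_at_birth == "female" &
                mult$congruence_class == "congruent", ]
  expect_equal(fem$n_persons, 2L)
  expect_equal(fem$n_multiple, 1L)  # only f2 has >1 distinct concept
})

test_that("geographic profile fractions, correlation and summary behave", {
  ds <- small_cohort(seed = 56, n = 1000)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  flagged <- flag_incongruent_persons(ds, cohort, conds)
  geo <- geographic_profile(ds, cohort, flagged)
  expect_equal(sum(geo$profile$population_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(geo$profile$incongruent_fraction), 1, tolerance = 1e-9)
  expect_equal(geo$summary$n_zip3_flagged, sum(geo$profile$n_flagged > 0))
  # dropping a zip3 with zero flagged persons leaves the incongruent
  # fractions of the remaining zip3s unchanged
  zero_zip <- geo$profile$zip3[geo$profile$n_flagged == 0][1]
  expect_false(is.na(zero_zip))
  ds2 <- ds
  keep <- !(ds2$zip3$zip3 == zero_zip)
  ds2$zip3 <- ds2$zip3[keep, ]
  cohort2 <- cohort
  geo2 <- geographic_profile(ds2, cohort2, flagged)
  common <- intersect(geo$profile$zip3, geo2$profile$zip3)
  expect_equal(
    geo2$profile$incongruent_fraction[match(common, geo2$profile$zip3)],
    geo$profile$incongruent_fraction[match(common, geo$profile$zip3)]
  )
  # absent zip3 table errors
  ds3 <- ds
  ds3$zip3 <- NULL
  expect_error(geographic_profile(ds3, cohort, flagged), "not available")
})

test_that("uniform misassignment makes incongruence mirror population", {
  ds <- generate_cohort(synthetic_config(
    n_persons = 50000, error_rate = 0.05, records_per_carrier = 2, seed = 57
  ))
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  flagged <- flag_incongruent_persons(ds, cohort, conds)
  geo <- geographic_profile(ds, cohort, flagged)
  expect_gt(geo$summary$correlation, 0.9)
})

test_that("single-zip3 profile degenerates as expected", {
  ds <- tiny_dataset()
  ds$zip3$zip3 <- "750"
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  flagged <- flag_incongruent_persons(ds, cohort, screened_tiny())
  geo <- geographic_profile(ds, cohort, flagged)
  expect_equal(nrow(geo$profile), 1)
  expect_equal(geo$profile$population_fraction, 1)
  expect_equal(geo$profile$incongruent_fraction, 1)
  expect_true(is.na(geo$summary$correlation))
})

test_that("temporal profile bins records by year and class", {
  ds <- tiny_dataset()
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  prof <- temporal_profile(ds, cohort, screened_tiny())
  # m2's 2017 record of the female-specific concept is incongruent
  inc <- prof[prof$congruence_class == "incongruent", ]
  expect_equal(inc$year, 2017L)
  expect_equal(inc$n_records, 1L)
  expect_equal(inc$sex_specificity, "female_specific")
  # record counts, not person counts: f1 contributes two congruent records
  expect_equal(sum(prof$n_records[prof$sex_specificity == "female_specific" &
                                    prof$congruence_class == "congruent"]), 3)
  # empty condition set gives an empty profile
  expect_equal(nrow(temporal_profile(ds, cohort, screened_tiny()[0, ])), 0)
})

test_that("uniform year range produces a uniform start-year histogram", {
  ds <- generate_cohort(synthetic_config(
    n_persons = 20000, error_rate = 0.02, year_range = c(2010L, 2019L),
    seed = 58
  ))
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  prof <- temporal_profile(ds, cohort, conds)
  fem <- prof[prof$sex_specificity == "female_specific" &
                prof$congruence_class == "congruent", ]
  expect_equal(sort(fem$year), 2010:2019)
  gof <- stats::chisq.test(fem$n_records)
  expect_gt(gof$p.value, 0.001)
})

test_that("sensitivity analysis equals the primary rate in an all-cis cohort", {
  cfg <- synthetic_config(
    n_persons = 5000,
    gender_identity_distribution = list(
      female = c(woman = 1), male = c(man = 1)
    ),
    error_rate = 0.05, seed = 59
  )
  ds <- generate_cohort(cfg)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  primary <- compute_oir(ds, cohort, conds, "combined")
  sens <- sensitivity_noncisgender(ds, conds)
  expect_equal(sens$oir$rate, primary$rate)
  expect_equal(sens$oir$n_total, primary$n_total)
})

test_that("true cross-sex diagnoses in non-cis persons inflate the sensitivity OIR", {
  cfg <- synthetic_config(
    n_persons = 30000, error_rate = 0.01, noncis_cross_rate = 0.5, seed = 60
  )
  ds <- generate_cohort(cfg)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  conds <- screen_conditions(count_by_sex(ds, cohort), small_screen())
  primary <- compute_oir(ds, cohort, conds, "combined")
  sens <- sensitivity_noncisgender(ds, conds)
  expect_gte(sens$oir$rate, primary$rate)
  comp <- sens$composition
  expect_equal(sum(comp$fraction_all), 1, tolerance = 1e-9)
  expect_equal(sum(comp$fraction_flagged), 1, tolerance = 1e-9)
  expect_false(any(c("skip", "prefer_not_to_answer") %in%
                     comp$gender_identity))
  # flagged persons are enriched for gender-crossing identities
  cross <- comp$gender_identity %in% c("transgender")
  expect_gt(sum(comp$fraction_flagged[cross]), sum(comp$fraction_all[cross]))
})
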