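test_that("count_by_sex counts distinct participants, not records", {
  ds <- tiny_dataset()
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  counts <- count_by_sex(ds, cohort)
  # f1 carries concept 10 twice but counts once; m2 also carries it
  row10 <- counts[counts$concept_id == 10L, ]
  expect_equal(row10$n_female, 2)
  expect_equal(row10$n_male, 1)
  expect_equal(row10$n_total, 3)
  expect_equal(row10$majority_sex, "female")
  expect_equal(row10$majority_fraction, 2 / 3)
  # tf1 is outside the cisgender cohort, so concept 20 counts only m1, m2
  row20 <- counts[counts$concept_id == 20L, ]
  expect_equal(row20$n_total, 2)
  expect_equal(row20$majority_sex, "male")
})

test_that("a strongly female-majority condition has the derived fraction", {
  # distinct-participant counts mirroring a prevalent pregnancy finding:
  # 209 males and 22 625 females
  counts <- tibble::tibble(
    concept_id = 1L, concept_name = "Finding related to pregnancy",
    n_female = 22625L, n_male = 209L, n_total = 22834L,
    majority_sex = "female", majority_fraction = 22625 / 22834
  )
  kept <- screen_conditions(counts, screen_config())
  expect_equal(nrow(kept), 1)
  expect_equal(kept$specific_sex, "female")
  expect_equal(kept$majority_fraction, 0.99085, tolerance = 1e-4)
})

test_that("count_by_sex equals a brute-force recount on a synthetic cohort", {
  ds <- small_cohort(seed = 31)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  got <- count_by_sex(ds, cohort)
  want <- bf_count_by_sex(ds, cohort)
  expect_equal(got$concept_id, want$concept_id)
  expect_equal(got$n_female, want$n_female)
  expect_equal(got$n_male, want$n_male)
  expect_equal(got$n_total, want$n_total)
})

counts_row <- function(n_female, n_male, name = "Ovarian cyst",
                       concept_id = 1L) {
  tibble::tibble(
    concept_id = concept_id, concept_name = name,
    n_female = n_female, n_male = n_male, n_total = n_female + n_male,
    majority_sex = dplyr::case_when(
      n_female > n_male ~ "female", n_male > n_female ~ "male", TRUE ~ "none"
    ),
    majority_fraction = pmax(n_female, n_male) / (n_female + n_male)
  )
}

test_that("screening thresholds sit exactly on their boundaries", {
  cfg <- screen_config(min_prevalent_participants = 20L)
  # fewer than 20 participants filtered out; exactly 20 kept
  expect_equal(nrow(screen_conditions(counts_row(19L, 0L), cfg)), 0)
  expect_equal(nrow(screen_conditions(counts_row(20L, 0L), cfg)), 1)
  # majority fraction must strictly exceed 95%
  cfg1000 <- screen_config()
  expect_equal(nrow(screen_conditions(counts_row(950L, 50L), cfg1000)), 0)
  kept <- screen_conditions(counts_row(999L, 1L), cfg1000)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$specific_sex, "female")
  # one participant short of the prevalence cut
  expect_equal(nrow(screen_conditions(counts_row(998L, 1L), cfg1000)), 0)
  # prevalence cut keeps exactly 1000
  expect_equal(nrow(screen_conditions(counts_row(1960L, 40L), cfg1000)), 1)
})

test_that("name patterns and manual lists exclude conditions", {
  counts <- dplyr::bind_rows(
    counts_row(5000L, 10L, "Benign neoplasm of breast", 1L),
    counts_row(5000L, 10L, "Malignant neoplasm of MAMMARY gland", 2L),
    counts_row(5000L, 10L, "Ovarian cyst", 3L),
    counts_row(10L, 5000L, "Testicular hypofunction", 4L)
  )
  kept <- screen_conditions(counts, screen_config())
  expect_setequal(kept$concept_id, c(3L, 4L))
  kept2 <- screen_conditions(
    counts, screen_config(manual_exclusion_concept_ids = 4L)
  )
  expect_equal(kept2$concept_id, 3L)
})

test_that("ties have no majority sex and never pass the bias filter", {
  counts <- counts_row(2000L, 2000L)
  expect_equal(counts$majority_sex, "none")
  expect_equal(nrow(screen_conditions(counts, screen_config())), 0)
})

test_that("raising any threshold never enlarges the selected set", {
  ds <- small_cohort(seed = 33, n = 800)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  counts <- count_by_sex(ds, cohort)
  grid <- expand.grid(
    min_p = c(2L, 5L, 10L, 20L),
    bias = c(0.7, 0.8, 0.9, 0.95),
    min_prev = c(2L, 10L, 50L)
  )
  sets <- lapply(seq_len(nrow(grid)), function(i) {
    screen_conditions(counts, screen_config(
      min_condition_participants = grid$min_p[i],
      bias_threshold = grid$bias[i],
      min_prevalent_participants = grid$min_prev[i]
    ))$concept_id
  })
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      dominates <- grid$min_p[j] >= grid$min_p[i] &&
        grid$bias[j] >= grid$bias[i] && grid$min_prev[j] >= grid$min_prev[i]
      if (dominates) expect_true(all(sets[[j]] %in% sets[[i]]))
    }
  }
})

test_that("screened output satisfies its own post-conditions", {
  ds <- small_cohort(seed = 34, n = 1000)
  cohort <- restrict_to_ehr(ds, select_cohort(ds))
  counts <- count_by_sex(ds, cohort)
  cfg <- small_screen()
  kept <- screen_conditions(counts, cfg)
  expect_gt(nrow(kept), 0)
  expect_true(all(kept$majority_fraction > cfg$bias_threshold))
  expect_true(all(kept$n_total >= cfg$min_prevalent_participants))
  expect_true(all(kept$specific_sex %in% c("female", "male")))
  stages <- screen_stages(kept)
  expect_true(all(diff(stages$n_conditions_remaining) <= 0))
})

test_that("true sex-specific conditions are recovered with the right sex", {
  # prevalent catalogue conditions above the cut must be recovered whenever
  # the error rate is small relative to the bias threshold
  hits <- 0L
  for (seed in 1:5) {
    ds <- generate_cohort(synthetic_config(
      n_persons = 20000, error_rate = 0.01, seed = seed
    ))
    cohort <- restrict_to_ehr(ds, select_cohort(ds))
    counts <- count_by_sex(ds, cohort)
    kept <- screen_conditions(counts, screen_config(
      min_prevalent_participants = 50L
    ))
    cat <- default_condition_catalogue()
    expected <- cat[cat$sex_target != "neutral" &
                      !grepl("breast|mammary", cat$concept_name,
                             ignore.case = TRUE), ]
    # restrict to conditions that clear the count cut and the strict bias
    # threshold with a wide margin, so sampling noise around either boundary
    # cannot decide the outcome
    prevalent <- expected[expected$prevalence * 10000 >= 200, ]
    found <- kept[match(prevalent$concept_id, kept$concept_id), ]
    if (all(!is.na(found$specific_sex)) &&
        all(found$specific_sex == sub("_only", "", prevalent$sex_target))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 4L)
})
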