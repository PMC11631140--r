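#' Default synthetic condition catalogue
#'
#' A small catalogue mixing prevalent and rare sex-specific conditions with
#' sex-neutral ones, including a breast finding so that the name-based
#' screening exclusion is exercised. Prevalences are the probability that a
#' member of the target sex (or anyone, for neutral conditions) carries the
#' condition.
#'
#' @return tibble with columns `concept_id`, `concept_name`, `sex_target`
#'   (`female_only`/`male_only`/`neutral`) and `prevalence`.
#' @export
default_condition_catalogue <- function() {
  tibble::tribble(
    ~concept_id, ~concept_name,                                  ~sex_target,   ~prevalence,
    1001L, "Finding related to pregnancy",                        "female_only", 0.150,
    1002L, "Female infertility",                                  "female_only", 0.025,
    1003L, "Ovarian cyst",                                        "female_only", 0.050,
    1004L, "Primary ovarian failure",                             "female_only", 0.020,
    1005L, "Endometriosis",                                       "female_only", 0.040,
    1006L, "Benign neoplasm of breast",                           "female_only", 0.030,
    1007L, "Placenta previa",                                     "female_only", 0.0005,
    2001L, "Primary malignant neoplasm of prostate",              "male_only",   0.060,
    2002L, "Testicular hypofunction",                             "male_only",   0.030,
    2003L, "Inflammatory disorder of male genital organ",         "male_only",   0.015,
    2004L, "Benign prostatic hyperplasia",                        "male_only",   0.080,
    3001L, "Essential hypertension",                              "neutral",     0.300,
    3002L, "Type 2 diabetes mellitus",                            "neutral",     0.150,
    3003L, "Asthma",                                              "neutral",     0.120,
    3004L, "Low back pain",                                       "neutral",     0.200,
    3005L, "Anxiety disorder",                                    "neutral",     0.180
  )
}

default_gender_distribution <- function() {
  # Per-sex gender-identity mix; gender-crossing categories (opposite gender
  # plus transgender) total 1.1% of the cohort, with survey skips and
  # declines on top of that.
  base <- c(
    transgender = 0.005, nonbinary = 0.008, other = 0.002,
    skip = 0.012, prefer_not_to_answer = 0.006
  )
  list(
    female = c(woman = 0.961, man = 0.006, base),
    male = c(man = 0.961, woman = 0.006, base)
  )
}

default_zip3_weights <- function(n_zip = 40L) {
  w <- 1 / seq_len(n_zip)
  names(w) <- sprintf("%03d", 100L + seq_len(n_zip) - 1L)
  w
}

#' Configure the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates an OMOP-lite research extract: a two-sex cohort with a
#' gender-identity mix including non-cisgender categories, a condition
#' catalogue with per-condition prevalence, repeat condition records per
#' carrier, zip3 assignment proportional to population weights, uniform
#' condition start dates, genomic-inferred sex, and an injected logging-error
#' rate that relocates sex-specific condition records onto persons of the
#' opposite sex.
#'
#' @param n_persons cohort size.
#' @param female_fraction probability a person is female at birth.
#' @param gender_identity_distribution list with elements `female` and `male`,
#'   each a named probability vector over the gender-identity categories,
#'   conditional on sex at birth; each must sum to 1.
#' @param condition_catalogue tibble as in [default_condition_catalogue()].
#' @param error_rate probability that a sex-specific condition record is
#'   attached to a uniformly chosen person of the opposite sex instead of its
#'   carrier (record-level logging error).
#' @param error_mode `"record_misassign"` (default; individual records land on
#'   the wrong person, so affected persons keep a mix of accurate and
#'   erroneous records) or `"person_swap"` (a person's recorded sex is flipped
#'   wholesale; provided for contrast experiments).
#' @param genomic_mismatch_rate probability that genomic-inferred sex differs
#'   from sex at birth; default 0 (survey and genomic sex agree).
#' @param noncis_cross_rate multiplier on opposite-sex condition prevalence
#'   for binary-sex persons whose gender identity crosses their sex at birth
#'   (opposite gender or transgender); default 0. Models true diagnoses such
#'   as those following gender-affirming care.
#' @param zip3_weights named positive weights; zip3 of each person with any
#'   condition record is drawn proportional to these.
#' @param year_range inclusive pair of calendar years for condition start
#'   dates, drawn uniformly by day.
#' @param records_per_carrier mean number of records per carrier per
#'   condition; each carrier receives `1 + Poisson(records_per_carrier - 1)`
#'   records. Must be >= 1.
#' @param seed integer seed; identical configs generate identical datasets.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_persons = 50000L,
                             female_fraction = 0.5,
                             gender_identity_distribution = default_gender_distribution(),
                             condition_catalogue = default_condition_catalogue(),
                             error_rate = 0.01,
                             error_mode = c("record_misassign", "person_swap"),
                             genomic_mismatch_rate = 0,
                             noncis_cross_rate = 0,
                             zip3_weights = default_zip3_weights(),
                             year_range = c(2000L, 2022L),
                             records_per_carrier = 2,
                             seed = 1L) {
  error_mode <- match.arg(error_mode)
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)

  chk(is.numeric(n_persons) && length(n_persons) == 1 && n_persons >= 0 &&
        n_persons == floor(n_persons), "n_persons must be a nonnegative integer")
  chk(is.numeric(female_fraction) && female_fraction >= 0 &&
        female_fraction <= 1, "female_fraction must be in [0,1]")
  chk(is.list(gender_identity_distribution) &&
        all(c("female", "male") %in% names(gender_identity_distribution)),
      "gender_identity_distribution needs 'female' and 'male' entries")
  for (s in c("female", "male")) {
    d <- gender_identity_distribution[[s]]
    if (is.numeric(d)) {
      chk(abs(sum(d) - 1) < 1e-9,
          sprintf("gender distribution for %s must sum to 1", s))
      chk(all(names(d) %in% GENDER_LEVELS),
          sprintf("unknown gender category for %s", s))
      chk(all(d >= 0), sprintf("gender probabilities for %s must be >= 0", s))
    }
  }
  condition_catalogue <- tibble::as_tibble(condition_catalogue)
  chk(all(c("concept_id", "concept_name", "sex_target", "prevalence") %in%
            names(condition_catalogue)),
      "condition_catalogue lacks required columns")
  if ("prevalence" %in% names(condition_catalogue)) {
    chk(all(condition_catalogue$prevalence >= 0 &
              condition_catalogue$prevalence <= 1),
        "prevalence must be in [0,1]")
  }
  if ("sex_target" %in% names(condition_catalogue)) {
    chk(all(condition_catalogue$sex_target %in%
              c("female_only", "male_only", "neutral")),
        "sex_target must be female_only, male_only or neutral")
  }
  chk(is.numeric(error_rate) && error_rate >= 0 && error_rate <= 1,
      "error_rate must be in [0,1]")
  chk(is.numeric(genomic_mismatch_rate) && genomic_mismatch_rate >= 0 &&
        genomic_mismatch_rate <= 1, "genomic_mismatch_rate must be in [0,1]")
  chk(is.numeric(noncis_cross_rate) && noncis_cross_rate >= 0,
      "noncis_cross_rate must be >= 0")
  chk(is.numeric(zip3_weights) && length(zip3_weights) > 0 &&
        all(zip3_weights > 0) && !is.null(names(zip3_weights)) &&
        all(grepl("^[0-9]{3}$", names(zip3_weights))),
      "zip3_weights must be positive and named by 3-digit codes")
  chk(length(year_range) == 2 && year_range[1] <= year_range[2],
      "year_range must be an increasing pair of years")
  chk(is.numeric(records_per_carrier) && records_per_carrier >= 1,
      "records_per_carrier must be >= 1")
  chk(is.numeric(seed) && length(seed) == 1 && seed == floor(seed),
      "seed must be an integer")
  if (length(errs)) abort(paste(errs, collapse = "; "))

  structure(
    list(
      n_persons = as.integer(n_persons),
      female_fraction = female_fraction,
      gender_identity_distribution = gender_identity_distribution,
      condition_catalogue = condition_catalogue,
      error_rate = error_rate,
      error_mode = error_mode,
      genomic_mismatch_rate = genomic_mismatch_rate,
      noncis_cross_rate = noncis_cross_rate,
      zip3_weights = zip3_weights,
      year_range = as.integer(year_range),
      records_per_carrier = records_per_carrier,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic OMOP-lite cohort
#'
#' Draws a full dataset from a [synthetic_config()]: sexes by
#' `female_fraction`; gender identity per sex from the configured
#' distribution; condition carriers by prevalence within the target sex
#' (everyone, for neutral conditions); `1 + Poisson` records per carrier with
#' uniform start dates over `year_range`; each sex-specific condition record
#' independently relocated to a uniformly chosen opposite-sex person with
#' probability `error_rate`; zip3 for every person with any record, drawn by
#' `zip3_weights`; genomic-inferred sex equal to sex at birth except with
#' probability `genomic_mismatch_rate`. Identical configs (including the
#' seed) yield identical datasets.
#'
#' @param config a [synthetic_config()].
#' @return an [omop_dataset()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_preserved_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_persons
  cat <- config$condition_catalogue
  empty <- function() {
    omop_dataset(
      persons = tibble(person_id = character(), sex_at_birth = character(),
                       gender_identity = character()),
      occurrences = tibble(person_id = character(), concept_id = integer(),
                           start_date = as.Date(character())),
      concepts = tibble(concept_id = as.integer(cat$concept_id),
                        concept_name = cat$concept_name),
      genomic_sex = tibble(person_id = character(), inferred_sex = character()),
      zip3 = tibble(person_id = character(), zip3 = character())
    )
  }
  if (n == 0) return(empty())

  person_id <- sprintf("P%07d", seq_len(n))
  true_sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  gender <- character(n)
  for (s in c("female", "male")) {
    idx <- which(true_sex == s)
    d <- config$gender_identity_distribution[[s]]
    if (length(idx)) {
      gender[idx] <- sample(names(d), length(idx), replace = TRUE, prob = d)
    }
  }
  cross_gender <- (true_sex == "female" & gender %in% c("man", "transgender")) |
    (true_sex == "male" & gender %in% c("woman", "transgender"))

  day0 <- as.Date(sprintf("%d-01-01", config$year_range[1]))
  day1 <- as.Date(sprintf("%d-12-31", config$year_range[2]))
  n_days <- as.integer(day1 - day0) + 1L
  lambda <- config$records_per_carrier - 1

  females <- which(true_sex == "female")
  males <- which(true_sex == "male")

  occ <- vector("list", nrow(cat))
  for (i in seq_len(nrow(cat))) {
    target <- cat$sex_target[i]
    q <- cat$prevalence[i]
    pool <- switch(target,
      female_only = females, male_only = males, neutral = seq_len(n)
    )
    carriers <- pool[stats::runif(length(pool)) < q]
    # true cross-sex diagnoses in gender-crossing persons (e.g. after
    # gender-affirming care), off by default
    if (config$noncis_cross_rate > 0 && target != "neutral") {
      opp_pool <- if (target == "female_only") males else females
      opp_cross <- opp_pool[cross_gender[opp_pool]]
      extra <- opp_cross[stats::runif(length(opp_cross)) <
                           config$noncis_cross_rate * q]
      carriers <- c(carriers, extra)
    }
    if (!length(carriers)) next
    n_rec <- 1L + stats::rpois(length(carriers), lambda)
    rec_person <- rep(carriers, n_rec)
    m <- length(rec_person)
    # record-level logging error: the record lands on a uniformly chosen
    # person of the opposite sex to its carrier
    if (config$error_mode == "record_misassign" && target != "neutral" &&
        config$error_rate > 0 && m > 0) {
      flip <- stats::runif(m) < config$error_rate
      if (any(flip)) {
        fem_rec <- true_sex[rec_person] == "female"
        to_male <- which(flip & fem_rec)
        to_female <- which(flip & !fem_rec)
        if (length(to_male) && length(males)) {
          rec_person[to_male] <- males[sample.int(length(males),
                                                  length(to_male),
                                                  replace = TRUE)]
        }
        if (length(to_female) && length(females)) {
          rec_person[to_female] <- females[sample.int(length(females),
                                                      length(to_female),
                                                      replace = TRUE)]
        }
      }
    }
    occ[[i]] <- tibble(
      person_id = person_id[rec_person],
      concept_id = as.integer(cat$concept_id[i]),
      start_date = day0 + (sample.int(n_days, m, replace = TRUE) - 1L)
    )
  }
  occurrences <- dplyr::bind_rows(occ)
  if (is.null(occurrences) || nrow(occurrences) == 0) {
    occurrences <- tibble(person_id = character(), concept_id = integer(),
                          start_date = as.Date(character()))
  }

  recorded_sex <- true_sex
  if (config$error_mode == "person_swap" && config$error_rate > 0) {
    swap <- stats::runif(n) < config$error_rate
    recorded_sex[swap] <- ifelse(true_sex[swap] == "female", "male", "female")
  }

  genomic <- true_sex
  if (config$genomic_mismatch_rate > 0) {
    mm <- stats::runif(n) < config$genomic_mismatch_rate
    genomic[mm] <- ifelse(true_sex[mm] == "female", "male", "female")
  }

  with_cond <- sort(unique(occurrences$person_id))
  zip_codes <- names(config$zip3_weights)
  zip_tbl <- tibble(
    person_id = with_cond,
    zip3 = zip_codes[sample.int(length(zip_codes), length(with_cond),
                                replace = TRUE,
                                prob = config$zip3_weights)]
  )

  omop_dataset(
    persons = tibble(person_id = person_id, sex_at_birth = recorded_sex,
                     gender_identity = gender),
    occurrences = occurrences,
    concepts = tibble(concept_id = as.integer(cat$concept_id),
                      concept_name = cat$concept_name),
    genomic_sex = tibble(person_id = person_id, inferred_sex = genomic),
    zip3 = zip_tbl
  )
}

#' Analytic expectation of the overall incongruence rate under the generator
#'
#' Closed-form expectation of the person-level combined overall incongruence
#' rate (OIR) that the record-misassignment error model induces, as measured
#' by the pipeline on a cisgender-only cohort. For each sex-specific
#' condition with prevalence q, a carrier receives R = 1 + Poisson(m - 1)
#' records (m = `records_per_carrier`); each record is independently moved to
#' a uniform opposite-sex person with probability e = `error_rate`. A person
#' of the opposite sex receives at least one record of the condition with
#' probability `1 - (1 - q(1 - a))^N`, where `N` is the size of the carrier
#' sex, `a = (1 - e/M) exp(-(m-1) e/M)` is the chance that one carrier's
#' records all miss that person, and `M` is the size of the receiving sex. A
#' carrier retains at least one of their own records with probability
#' `1 - e exp(-(m-1)(1-e))`. Expected incongruent and congruent person counts
#' for the female- and male-specific condition sets follow by independence
#' across conditions, scaled by the cisgender fraction of each sex; the
#' combined OIR sums both sets' counts.
#'
#' @param config a [synthetic_config()] with `error_mode = "record_misassign"`
#'   and at least one sex-specific condition. Assumes `noncis_cross_rate = 0`.
#' @return the expected combined OIR, a proportion.
#' @export
expected_oir <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$error_mode != "record_misassign") {
    abort("expected_oir is defined for the record_misassign error model only")
  }
  cat <- config$condition_catalogue
  fem_q <- cat$prevalence[cat$sex_target == "female_only"]
  mal_q <- cat$prevalence[cat$sex_target == "male_only"]
  if (!length(fem_q) && !length(mal_q)) {
    abort("catalogue has no sex-specific condition; OIR is undefined")
  }
  n_f <- config$n_persons * config$female_fraction
  n_m <- config$n_persons * (1 - config$female_fraction)
  kappa_f <- config$gender_identity_distribution$female[["woman"]]
  kappa_m <- config$gender_identity_distribution$male[["man"]]
  e <- config$error_rate
  lam <- config$records_per_carrier - 1
  # P(a carrier loses every record of one condition)
  lose_all <- e * exp(-lam * (1 - e))

  set_counts <- function(q, n_carrier_sex, n_recv_sex, kap_carrier, kap_recv) {
    if (!length(q)) return(c(incongruent = 0, congruent = 0))
    if (n_recv_sex > 0) {
      a <- (1 - e / n_recv_sex) * exp(-lam * e / n_recv_sex)
      p_hit <- 1 - exp(n_carrier_sex * log1p(-q * (1 - a)))
      p_inc <- 1 - prod(1 - p_hit)
    } else p_inc <- 0
    p_cong <- 1 - prod(1 - q * (1 - lose_all))
    c(incongruent = kap_recv * n_recv_sex * p_inc,
      congruent = kap_carrier * n_carrier_sex * p_cong)
  }
  f_set <- set_counts(fem_q, n_f, n_m, kappa_f, kappa_m)
  m_set <- set_counts(mal_q, n_m, n_f, kappa_m, kappa_f)
  inc <- f_set[["incongruent"]] + m_set[["incongruent"]]
  tot <- inc + f_set[["congruent"]] + m_set[["congruent"]]
  if (tot == 0) abort("expected denominator is zero; OIR is undefined")
  inc / tot
}
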