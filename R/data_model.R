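#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   distinct left_join inner_join anti_join semi_join n n_distinct across
#'   bind_rows count rename if_else pull
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

# Canonical enum tokens used in files and in memory.
SEX_LEVELS <- c("female", "male", "other_or_unknown")
GENDER_LEVELS <- c(
  "woman", "man", "transgender", "nonbinary", "other",
  "skip", "prefer_not_to_answer"
)
GENOMIC_SEX_LEVELS <- c("female", "male", "unknown")

# Survey-literal spellings accepted on load (matched case-insensitively).
SEX_ALIASES <- c(
  "female" = "female", "male" = "male",
  "other_or_unknown" = "other_or_unknown"
)
GENDER_ALIASES <- c(
  "woman" = "woman", "man" = "man",
  "transgender" = "transgender", "nonbinary" = "nonbinary",
  "non-binary" = "nonbinary", "other" = "other", "skip" = "skip",
  "prefernottoanswer" = "prefer_not_to_answer",
  "prefer_not_to_answer" = "prefer_not_to_answer"
)

normalize_enum <- function(x, aliases, fallback, field, strict) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(aliases[key])
  bad <- !is.na(key) & is.na(out)
  if (any(bad)) {
    vals <- unique(x[bad])
    if (strict) {
      abort(sprintf(
        "Unrecognised %s value(s): %s", field,
        paste(utils::head(vals, 5), collapse = ", ")
      ))
    }
    warn(sprintf(
      "%d unrecognised %s value(s) mapped to '%s' (e.g. %s)",
      sum(bad), field, fallback, paste(utils::head(vals, 3), collapse = ", ")
    ))
    out[bad] <- fallback
  }
  out[is.na(key)] <- fallback
  out
}

#' Assemble an OMOP-lite dataset
#'
#' Bundles the person, condition-occurrence and concept tables (plus the
#' optional genomic-sex and zip3 tables) into a single validated object that
#' every analysis function consumes. Validation enforces unique, non-empty
#' person identifiers, positive concept ids, parseable dates and referential
#' integrity of occurrences against persons.
#'
#' @param persons tibble with columns `person_id`, `sex_at_birth`
#'   (`female`/`male`/`other_or_unknown`), `gender_identity` (`woman`, `man`,
#'   `transgender`, `nonbinary`, `other`, `skip`, `prefer_not_to_answer`).
#' @param occurrences tibble with columns `person_id`, `concept_id`
#'   (positive integer), `start_date` (`Date` or ISO-8601 string). Multiple
#'   records per person-condition are allowed and retained.
#' @param concepts optional tibble with `concept_id`, `concept_name`.
#' @param genomic_sex optional tibble with `person_id`, `inferred_sex`
#'   (`female`/`male`/`unknown`); at most one row per person.
#' @param zip3 optional tibble with `person_id`, `zip3` (3-digit string).
#' @param strict when `TRUE`, referential-integrity violations are errors;
#'   otherwise offending occurrence rows are dropped with a warning.
#' @return an object of class `omop_dataset`: a list of validated tibbles.
#' @export
omop_dataset <- function(persons, occurrences, concepts = NULL,
                         genomic_sex = NULL, zip3 = NULL, strict = TRUE) {
  persons <- as_tibble(persons)
  occurrences <- as_tibble(occurrences)
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(sprintf("%s table lacks column(s): %s", what,
                    paste(miss, collapse = ", ")))
    }
  }
  req(persons, c("person_id", "sex_at_birth", "gender_identity"), "person")
  req(occurrences, c("person_id", "concept_id", "start_date"),
      "condition_occurrence")

  persons$person_id <- as.character(persons$person_id)
  if (any(is.na(persons$person_id) | persons$person_id == "")) {
    abort("person_id must be non-empty")
  }
  if (anyDuplicated(persons$person_id)) {
    abort("duplicate person_id in person table")
  }
  persons$sex_at_birth <- normalize_enum(
    persons$sex_at_birth, SEX_ALIASES, "other_or_unknown",
    "sex_at_birth", strict
  )
  persons$gender_identity <- normalize_enum(
    persons$gender_identity, GENDER_ALIASES, "other",
    "gender_identity", strict
  )

  occurrences$person_id <- as.character(occurrences$person_id)
  occurrences$concept_id <- as.integer(occurrences$concept_id)
  if (nrow(occurrences) &&
      any(is.na(occurrences$concept_id) | occurrences$concept_id <= 0)) {
    abort("concept_id must be a positive integer")
  }
  occurrences$start_date <- as.Date(occurrences$start_date)
  if (anyNA(occurrences$start_date) && nrow(occurrences)) {
    abort("start_date must be a parseable ISO-8601 date")
  }
  orphan <- !(occurrences$person_id %in% persons$person_id)
  if (any(orphan)) {
    if (strict) {
      abort(sprintf(
        "%d condition_occurrence row(s) reference unknown person_id",
        sum(orphan)
      ))
    }
    warn(sprintf("dropped %d occurrence row(s) with unknown person_id",
                 sum(orphan)))
    occurrences <- occurrences[!orphan, ]
  }

  if (!is.null(concepts)) {
    concepts <- as_tibble(concepts)
    req(concepts, c("concept_id", "concept_name"), "concept")
    concepts$concept_id <- as.integer(concepts$concept_id)
    concepts$concept_name <- as.character(concepts$concept_name)
    if (anyDuplicated(concepts$concept_id)) {
      abort("duplicate concept_id in concept table")
    }
  }
  if (!is.null(genomic_sex)) {
    genomic_sex <- as_tibble(genomic_sex)
    req(genomic_sex, c("person_id", "inferred_sex"), "genomic_sex")
    genomic_sex$person_id <- as.character(genomic_sex$person_id)
    genomic_sex$inferred_sex <- normalize_enum(
      genomic_sex$inferred_sex,
      c("female" = "female", "male" = "male", "unknown" = "unknown"),
      "unknown", "inferred_sex", strict
    )
    if (anyDuplicated(genomic_sex$person_id)) {
      abort("at most one genomic_sex record per person")
    }
  }
  if (!is.null(zip3)) {
    zip3 <- as_tibble(zip3)
    req(zip3, c("person_id", "zip3"), "zip3")
    zip3$person_id <- as.character(zip3$person_id)
    zip3$zip3 <- as.character(zip3$zip3)
    if (nrow(zip3) && any(!grepl("^[0-9]{3}$", zip3$zip3))) {
      abort("zip3 must be a 3-digit string")
    }
  }

  structure(
    list(
      persons = persons,
      occurrences = occurrences,
      concepts = concepts,
      genomic_sex = genomic_sex,
      zip3 = zip3
    ),
    class = "omop_dataset"
  )
}

#' @export
print.omop_dataset <- function(x, ...) {
  cat("<omop_dataset>\n")
  cat(sprintf("  persons:     %d\n", nrow(x$persons)))
  cat(sprintf("  occurrences: %d (%d distinct conditions)\n",
              nrow(x$occurrences), dplyr::n_distinct(x$occurrences$concept_id)))
  cat(sprintf("  concepts:    %s\n",
              if (is.null(x$concepts)) "absent" else nrow(x$concepts)))
  cat(sprintf("  genomic_sex: %s\n",
              if (is.null(x$genomic_sex)) "absent" else nrow(x$genomic_sex)))
  cat(sprintf("  zip3:        %s\n",
              if (is.null(x$zip3)) "absent" else nrow(x$zip3)))
  invisible(x)
}

csv_spec <- function(file) {
  switch(file,
    person = readr::cols(
      person_id = readr::col_character(),
      sex_at_birth = readr::col_character(),
      gender_identity = readr::col_character()
    ),
    condition_occurrence = readr::cols(
      person_id = readr::col_character(),
      concept_id = readr::col_integer(),
      start_date = readr::col_date()
    ),
    concept = readr::cols(
      concept_id = readr::col_integer(),
      concept_name = readr::col_character()
    ),
    genomic_sex = readr::cols(
      person_id = readr::col_character(),
      inferred_sex = readr::col_character()
    ),
    zip3 = readr::cols(
      person_id = readr::col_character(),
      zip3 = readr::col_character()
    )
  )
}

read_table_csv <- function(dir, file) {
  path <- file.path(dir, paste0(file, ".csv"))
  if (!file.exists(path)) return(NULL)
  readr::read_csv(path, col_types = csv_spec(file), progress = FALSE)
}

#' Load an OMOP-lite dataset from a directory of CSV files
#'
#' Reads `person.csv` and `condition_occurrence.csv` (required) plus
#' `concept.csv`, `genomic_sex.csv` and `zip3.csv` (optional) and returns a
#' validated [omop_dataset()]. Survey-literal enum spellings such as
#' `"Female"`, `"Woman"`, `"Skip"` or `"PreferNotToAnswer"` are accepted
#' case-insensitively and normalised to the package's lowercase tokens.
#'
#' @param dir directory containing the CSV files.
#' @param strict when `TRUE` (default) unknown enum values and occurrences
#'   referencing absent persons are fatal; when `FALSE` they are mapped to
#'   `other_or_unknown`/`other` or dropped, with a warning.
#' @return an `omop_dataset`.
#' @export
load_dataset <- function(dir, strict = TRUE) {
  for (f in c("person", "condition_occurrence")) {
    if (!file.exists(file.path(dir, paste0(f, ".csv")))) {
      abort(sprintf("required file %s.csv not found in %s", f, dir))
    }
  }
  omop_dataset(
    persons = read_table_csv(dir, "person"),
    occurrences = read_table_csv(dir, "condition_occurrence"),
    concepts = read_table_csv(dir, "concept"),
    genomic_sex = read_table_csv(dir, "genomic_sex"),
    zip3 = read_table_csv(dir, "zip3"),
    strict = strict
  )
}

#' Write an OMOP-lite dataset to a directory of CSV files
#'
#' Emits the same UTF-8, comma-separated, header-first files that
#' [load_dataset()] reads, with fixed column order and the package's
#' lowercase enum spellings, so that a write/load round trip reproduces the
#' dataset exactly.
#'
#' @param dataset an [omop_dataset()].
#' @param dir output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "omop_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, file) {
    readr::write_csv(df, file.path(dir, paste0(file, ".csv")), progress = FALSE)
  }
  wr(dataset$persons[c("person_id", "sex_at_birth", "gender_identity")],
     "person")
  wr(dataset$occurrences[c("person_id", "concept_id", "start_date")],
     "condition_occurrence")
  if (!is.null(dataset$concepts)) {
    wr(dataset$concepts[c("concept_id", "concept_name")], "concept")
  }
  if (!is.null(dataset$genomic_sex)) {
    wr(dataset$genomic_sex[c("person_id", "inferred_sex")], "genomic_sex")
  }
  if (!is.null(dataset$zip3)) {
    wr(dataset$zip3[c("person_id", "zip3")], "zip3")
  }
  invisible(dir)
}
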