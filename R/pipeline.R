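#' Validate a pipeline run configuration
#'
#' Parses and defaults a raw configuration (a named list, or a path to a
#' YAML/JSON file) into a run configuration, collecting every validation
#' error rather than stopping at the first. Exactly one input source is
#' required: `input_dir` (a directory of OMOP-lite CSVs) or `synthetic` (a
#' list of [synthetic_config()] arguments).
#'
#' @param raw named list, or path to a YAML or JSON file.
#' @return a `run_config` object.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) {
    raw <- if (grepl("\\.json$", raw, ignore.case = TRUE)) {
      jsonlite::read_json(raw, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(raw)
    }
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config must be a named list or a file path")
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)

  has_input <- !is.null(raw$input_dir)
  has_synth <- !is.null(raw$synthetic)
  chk(has_input || has_synth,
      "config needs an input source: input_dir or synthetic")
  chk(!(has_input && has_synth),
      "input_dir and synthetic are mutually exclusive")

  gender_policy <- raw$gender_policy %||% "cisgender_only"
  chk(gender_policy %in% c("cisgender_only", "include_all_binary_sex"),
      "gender_policy: must be cisgender_only or include_all_binary_sex")

  screen_args <- raw$screen %||% list()
  screen <- tryCatch(do.call(screen_config, screen_args),
                     error = function(e) {
                       errs <<- c(errs, paste0("screen: ", conditionMessage(e)))
                       NULL
                     })
  synth <- NULL
  if (has_synth && is.list(raw$synthetic)) {
    sargs <- raw$synthetic
    if (!is.null(sargs$condition_catalogue)) {
      sargs$condition_catalogue <- as_tibble(sargs$condition_catalogue)
    }
    if (!is.null(sargs$zip3_weights) && is.list(sargs$zip3_weights)) {
      sargs$zip3_weights <- unlist(sargs$zip3_weights)
    }
    if (!is.null(sargs$gender_identity_distribution)) {
      sargs$gender_identity_distribution <-
        lapply(sargs$gender_identity_distribution, unlist)
    }
    synth <- tryCatch(do.call(synthetic_config, sargs),
                      error = function(e) {
                        errs <<- c(errs,
                                   paste0("synthetic: ", conditionMessage(e)))
                        NULL
                      })
  }

  z <- raw$z %||% 1.96
  chk(is.numeric(z) && z > 0, "z: must be a positive number")
  ci_n_mode <- raw$ci_n_mode %||% "total"
  chk(ci_n_mode %in% c("total", "incongruent"),
      "ci_n_mode: must be total or incongruent")
  mask_threshold <- raw$mask_threshold %||% 20L
  chk(is.numeric(mask_threshold) && mask_threshold > 0,
      "mask_threshold: must be positive")
  output_dir <- raw$output_dir %||% "sexcheck_output"
  if (has_input) {
    chk(!identical(normalizePath(output_dir, mustWork = FALSE),
                   normalizePath(raw$input_dir, mustWork = FALSE)),
        "output_dir must differ from input_dir")
  }
  stages <- raw$stages %||% c("screen", "metrics", "profile", "sensitivity")
  chk(length(stages) > 0 &&
        all(stages %in% c("screen", "metrics", "profile", "sensitivity")),
      "stages: nonempty subset of screen, metrics, profile, sensitivity")
  if (any(stages %in% c("metrics", "profile", "sensitivity")) &&
      !("screen" %in% stages)) {
    errs <- c(errs,
              "stages: metrics/profile/sensitivity require the screen stage")
  }
  seed <- raw$seed %||% 1L
  chk(is.numeric(seed) && seed == floor(seed), "seed: must be an integer")
  if (length(errs)) {
    abort(paste0("invalid config:\n", paste0("- ", errs, collapse = "\n")))
  }

  structure(
    list(
      input_dir = raw$input_dir, synthetic = synth,
      policy = cohort_policy(gender_policy = gender_policy),
      screen = screen, z = z, ci_n_mode = ci_n_mode,
      mask_threshold = as.integer(mask_threshold),
      output_dir = output_dir, seed = as.integer(seed),
      stages = unique(stages)
    ),
    class = "run_config"
  )
}

write_report_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(df, path, progress = FALSE)
  path
}

#' Run the end-to-end incongruence pipeline
#'
#' Loads (or generates) the dataset, selects the cohort, and executes the
#' requested stages in dependency order: `screen` (condition counting and
#' sex-specificity screening), `metrics` (CIR/OIR tables with masked public
#' variants), `profile` (genomic concordance, concurrence, multiplicity,
#' zip3 and temporal profiles), `sensitivity` (non-cisgender re-admission).
#' All outputs are CSV/JSON files under `output_dir`; a `manifest.json`
#' records the configuration, per-stage counts and content hashes. Re-running
#' with an identical configuration and inputs reproduces identical
#' non-timestamp content.
#'
#' @param config a `run_config` from [validate_config()], or a raw list/path
#'   accepted by it.
#' @return invisibly, a list with elements `status` (`"ok"` or `"partial"`),
#'   `manifest`, `files`, and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  dataset <- if (!is.null(config$synthetic)) {
    generate_cohort(config$synthetic)
  } else {
    load_dataset(config$input_dir)
  }

  cohort <- restrict_to_ehr(dataset, select_cohort(dataset, config$policy))
  files <- character()
  status <- "ok"
  results <- list(cohort = cohort)
  files["flowchart_counts"] <- write_report_csv(
    cohort_steps(cohort), config$output_dir, "flowchart_counts.csv"
  )

  counts <- count_by_sex(dataset, cohort)
  conditions <- screen_conditions(counts, config$screen)
  results$conditions <- conditions
  files["sex_specific_conditions"] <- write_report_csv(
    conditions, config$output_dir, "sex_specific_conditions.csv"
  )
  files["screen_log"] <- write_report_csv(
    screen_stages(conditions), config$output_dir, "screen_log.csv"
  )

  if ("metrics" %in% config$stages && nrow(conditions)) {
    cir <- compute_cir(dataset, cohort, conditions, z = config$z,
                       ci_n_mode = config$ci_n_mode)
    have <- unique(conditions$specific_sex)
    subsets <- c(
      if ("female" %in% have) "female_specific",
      if ("male" %in% have) "male_specific",
      if (all(c("female", "male") %in% have)) "combined"
    )
    oir <- bind_rows(lapply(subsets, function(s) {
      compute_oir(dataset, cohort, conditions, s, z = config$z)
    }))
    results$cir <- cir
    results$oir <- oir
    files["cir_table"] <- write_report_csv(cir, config$output_dir,
                                           "cir_table.csv")
    files["oir_table"] <- write_report_csv(oir, config$output_dir,
                                           "oir_table.csv")
    files["cir_public"] <- write_report_csv(
      mask_small_counts(cir, config$mask_threshold),
      config$output_dir, "cir_table_public.csv"
    )
    files["oir_public"] <- write_report_csv(
      mask_small_counts(oir, config$mask_threshold),
      config$output_dir, "oir_table_public.csv"
    )
  }

  if ("profile" %in% config$stages && nrow(conditions)) {
    flagged <- flag_incongruent_persons(dataset, cohort, conditions)
    results$flagged <- flagged
    files["concurrence"] <- write_report_csv(
      concurrence_rates(dataset, cohort, conditions),
      config$output_dir, "concurrence.csv"
    )
    files["multiplicity"] <- write_report_csv(
      multiplicity_rates(dataset, cohort, conditions),
      config$output_dir, "multiplicity.csv"
    )
    files["temporal_profile"] <- write_report_csv(
      temporal_profile(dataset, cohort, conditions),
      config$output_dir, "temporal_profile.csv"
    )
    if (!is.null(dataset$genomic_sex)) {
      conc <- genomic_concordance(dataset, flagged)
      results$concordance <- conc
      path <- file.path(config$output_dir, "concordance.json")
      jsonlite::write_json(as.list(conc), path, auto_unbox = TRUE,
                           digits = NA)
      files["concordance"] <- path
    } else {
      status <- "partial"
      inform("genomic_sex table absent; concordance skipped")
    }
    if (!is.null(dataset$zip3)) {
      geo <- geographic_profile(dataset, cohort, flagged)
      results$geographic <- geo
      files["zip3_profile"] <- write_report_csv(
        geo$profile, config$output_dir, "zip3_profile.csv"
      )
    } else {
      status <- "partial"
      inform("zip3 table absent; geographic profile skipped")
    }
  }

  if ("sensitivity" %in% config$stages && nrow(conditions) &&
      all(c("female", "male") %in% conditions$specific_sex)) {
    sens <- sensitivity_noncisgender(dataset, conditions, z = config$z)
    results$sensitivity <- sens
    files["sensitivity_oir"] <- write_report_csv(
      sens$oir, config$output_dir, "sensitivity_oir.csv"
    )
    files["gender_composition"] <- write_report_csv(
      sens$composition, config$output_dir, "gender_composition.csv"
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sexcheck")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    status = status,
    stages = config$stages,
    seed = config$seed,
    n_cohort = length(cohort),
    n_conditions = nrow(conditions),
    files = as.list(stats::setNames(unname(tools::md5sum(unname(files))),
                                    basename(unname(files))))
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  results$status <- status
  results$manifest <- manifest
  results$files <- files
  invisible(results)
}
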