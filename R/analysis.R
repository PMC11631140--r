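#' Run the full incongruence-rate analysis on a dataset
#'
#' Convenience wrapper chaining cohort selection, EHR restriction, condition
#' counting, sex-specificity screening, per-condition rates (CIR) and
#' collective rates (OIR) into one fitted-analysis object with
#' [generics::tidy()] and [generics::glance()] methods.
#'
#' @param dataset an [omop_dataset()].
#' @param policy a [cohort_policy()].
#' @param screen a [screen_config()].
#' @param z normal quantile for intervals.
#' @param ci_n_mode interval convention for per-condition rates, see
#'   [rate_estimate()].
#' @return an object of class `ir_analysis` with elements `cohort`, `steps`,
#'   `counts`, `conditions`, `stages`, `cir`, `oir`.
#' @export
ir_analysis <- function(dataset, policy = cohort_policy(),
                        screen = screen_config(), z = 1.96,
                        ci_n_mode = c("total", "incongruent")) {
  ci_n_mode <- match.arg(ci_n_mode)
  cohort <- restrict_to_ehr(dataset, select_cohort(dataset, policy))
  counts <- count_by_sex(dataset, cohort)
  conditions <- screen_conditions(counts, screen)
  have <- unique(conditions$specific_sex)
  cir <- if (nrow(conditions)) {
    compute_cir(dataset, cohort, conditions, z = z, ci_n_mode = ci_n_mode)
  } else NULL
  oir_rows <- list()
  if ("female" %in% have) {
    oir_rows$f <- compute_oir(dataset, cohort, conditions, "female_specific",
                              z = z)
  }
  if ("male" %in% have) {
    oir_rows$m <- compute_oir(dataset, cohort, conditions, "male_specific",
                              z = z)
  }
  if (all(c("female", "male") %in% have)) {
    oir_rows$c <- compute_oir(dataset, cohort, conditions, "combined", z = z)
  }
  structure(
    list(
      cohort = cohort, steps = cohort_steps(cohort), counts = counts,
      conditions = conditions, stages = screen_stages(conditions),
      cir = cir, oir = bind_rows(oir_rows)
    ),
    class = "ir_analysis"
  )
}

#' @export
print.ir_analysis <- function(x, ...) {
  cat("<ir_analysis>\n")
  cat(sprintf("  cohort: %d persons with EHR condition data\n",
              length(x$cohort)))
  cat(sprintf("  screened sex-specific conditions: %d (%d female, %d male)\n",
              nrow(x$conditions),
              sum(x$conditions$specific_sex == "female"),
              sum(x$conditions$specific_sex == "male")))
  if (!is.null(x$oir) && nrow(x$oir)) {
    comb <- x$oir[x$oir$label == "combined", ]
    if (nrow(comb)) {
      cat(sprintf("  combined OIR: %.4f%% [%.4f%%, %.4f%%]\n",
                  100 * comb$rate, 100 * comb$ci_low, 100 * comb$ci_high))
    }
  }
  invisible(x)
}

#' Tidy the per-condition incongruence rates
#'
#' @param x an [ir_analysis()] object.
#' @param ... unused.
#' @return the per-condition rate tibble (one row per screened condition).
#' @export
tidy.ir_analysis <- function(x, ...) {
  x$cir %||% tibble()
}

#' One-row analysis summary
#'
#' @param x an [ir_analysis()] object.
#' @param ... unused.
#' @return one-row tibble: cohort size, numbers of screened conditions, and
#'   the combined OIR with its interval (NA when only one sex's conditions
#'   survived screening).
#' @export
glance.ir_analysis <- function(x, ...) {
  comb <- if (!is.null(x$oir)) x$oir[x$oir$label == "combined", ] else NULL
  tibble(
    n_cohort = length(x$cohort),
    n_conditions = nrow(x$conditions),
    n_female_specific = sum(x$conditions$specific_sex == "female"),
    n_male_specific = sum(x$conditions$specific_sex == "male"),
    oir = if (!is.null(comb) && nrow(comb)) comb$rate else NA_real_,
    oir_ci_low = if (!is.null(comb) && nrow(comb)) comb$ci_low else NA_real_,
    oir_ci_high = if (!is.null(comb) && nrow(comb)) comb$ci_high else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
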