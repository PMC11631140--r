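#' Plot condition-specific incongruence rates against participant counts
#'
#' Scatter of log10 total participant count versus CIR, panelled by the
#' condition's specific sex; low-count conditions show inflated, unstable
#' rates, motivating the prevalence cut.
#'
#' @param cir tibble from [compute_cir()].
#' @return a ggplot object.
#' @export
plot_cir <- function(cir) {
  ggplot2::ggplot(cir, ggplot2::aes(x = log10(.data$n_total),
                                    y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~specific_sex) +
    ggplot2::labs(x = "log10 total participants with condition",
                  y = "condition-specific incongruence rate") +
    ggplot2::theme_minimal()
}

#' Plot the zip3 geographic profile
#'
#' Population fraction versus incongruent-person fraction per zip3, with the
#' identity line; points on the line indicate incongruence mirroring
#' population size rather than concentrating in particular regions.
#'
#' @param profile the `profile` tibble from [geographic_profile()].
#' @return a ggplot object.
#' @export
plot_zip3_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$population_fraction,
                                        y = .data$incongruent_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "fraction of profiled population",
                  y = "fraction of incongruent persons") +
    ggplot2::theme_minimal()
}

#' Plot condition start-year histograms
#'
#' Record counts per start year, panelled by sex specificity and coloured by
#' congruence class; similar shapes across classes indicate errors spread
#' over the whole period.
#'
#' @param profile tibble from [temporal_profile()].
#' @return a ggplot object.
#' @export
plot_temporal_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$year, y = .data$n_records,
                                        fill = .data$congruence_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~sex_specificity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "condition start year", y = "records") +
    ggplot2::theme_minimal()
}
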