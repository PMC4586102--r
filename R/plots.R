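#' Plot the epimutation burden against age
#'
#' Scatter of the log epimutation burden over age with a linear trend and
#' per-age-range mean markers — the diagnostic view of the exponential
#' growth of SEM counts with age.
#'
#' @param cohort A [build_cohort_table()] tibble.
#' @return A ggplot object.
#' @export
plot_sem_burden <- function(cohort) {
  range_means <- cohort |>
    dplyr::group_by(.data$age_range) |>
    dplyr::summarise(age = mean(.data$age), log_sem = mean(.data$log_sem),
                     .groups = "drop")
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$age, y = .data$log_sem)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "grey40") +
    ggplot2::geom_point(data = range_means, colour = "red", shape = 15, size = 3) +
    ggplot2::labs(x = "Age (years)", y = "log(SEM + 1)",
                  title = "Epimutation burden vs age",
                  subtitle = "red squares: age-range means")
}

#' Density of per-sample mean methylation by group
#'
#' @param cohort A [build_cohort_table()] tibble.
#' @param group Grouping column (default `"age_range"`).
#' @return A ggplot object.
#' @export
plot_beta_density <- function(cohort, group = "age_range") {
  ggplot2::ggplot(dplyr::filter(cohort, !is.na(.data[[group]])),
                  ggplot2::aes(x = .data$avg_beta,
                               colour = as.factor(.data[[group]]))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Mean methylation (beta)", colour = group,
                  title = "Mean methylation profile by group")
}

#' Per-probe methylation distribution with SEM calls highlighted
#'
#' Box-style summary of selected probes with the extreme fences and any
#' called samples overlaid.
#'
#' @param x Beta-matrix tibble the calls were made on.
#' @param calls A [call_sems()] result.
#' @param probes Probe ids to display (default: the 9 most-called probes).
#' @return A ggplot object.
#' @export
plot_probe_calls <- function(x, calls, probes = NULL) {
  stopifnot(inherits(calls, "sem_calls"))
  if (is.null(probes)) {
    probes <- calls$calls |>
      dplyr::count(.data$probe_id, sort = TRUE) |>
      dplyr::slice_head(n = 9) |>
      dplyr::pull("probe_id")
  }
  long <- x |>
    dplyr::filter(.data$probe_id %in% probes) |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample_id", values_to = "beta")
  called <- dplyr::semi_join(long, calls$calls, by = c("probe_id", "sample_id"))
  fences <- dplyr::filter(calls$stats, .data$probe_id %in% probes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$probe_id, y = .data$beta)) +
    ggplot2::geom_boxplot(outlier.shape = NA, coef = 0) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = called, colour = "red", size = 2) +
    ggplot2::geom_errorbar(data = fences,
                           ggplot2::aes(x = .data$probe_id, y = NULL,
                                        ymin = .data$lower_fence,
                                        ymax = .data$upper_fence),
                           width = 0.4, linetype = 2, colour = "blue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "beta",
                  title = "Per-probe distributions, extreme fences and SEM calls") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Coefficient plot for a path analysis
#'
#' Forest-style display of the standardized path coefficients with their
#' confidence intervals; significant edges are highlighted.
#'
#' @param object A [path_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sem_path
#' @export
autoplot.sem_path <- function(object, ...) {
  e <- object$edges |>
    dplyr::mutate(edge = paste(.data$from, "→", .data$to))
  ggplot2::ggplot(e, ggplot2::aes(x = .data$beta_std, y = .data$edge,
                                  colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_colour_manual(values = c("TRUE" = "red", "FALSE" = "grey40")) +
    ggplot2::labs(x = "Standardized path coefficient", y = NULL,
                  colour = paste0("p < ", object$alpha))
}

#' @rdname plot_probe_calls
#' @param object A `sem_calls` object.
#' @param ... Unused.
#' @method autoplot sem_calls
#' @export
autoplot.sem_calls <- function(object, ...) {
  counts <- count_sems(object)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_sem)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "SEM count per sample", y = "Samples",
                  title = "Distribution of per-sample epimutation burden")
}
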