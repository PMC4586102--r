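#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an SEM call set
#'
#' @param x A [call_sems()] result.
#' @param ... Unused.
#' @return The calls tibble (`probe_id`, `sample_id`, `direction`, `beta`)
#'   joined with the per-probe fence statistics.
#' @method tidy sem_calls
#' @export
tidy.sem_calls <- function(x, ...) {
  dplyr::left_join(x$calls, x$stats, by = "probe_id")
}

#' @rdname tidy.sem_calls
#' @method glance sem_calls
#' @export
glance.sem_calls <- function(x, ...) {
  tibble::tibble(
    n_calls = nrow(x$calls),
    n_hyper = sum(x$calls$direction == "hyper"),
    n_hypo = sum(x$calls$direction == "hypo"),
    n_probes = nrow(x$stats),
    n_samples = length(x$sample_ids),
    n_probes_epimutated = dplyr::n_distinct(x$calls$probe_id),
    k = x$k,
    quantile_method = x$quantile_method
  )
}

#' Tidy a path-analysis fit
#'
#' @param x A [path_analysis()] result.
#' @param ... Unused.
#' @return The per-edge coefficient tibble.
#' @method tidy sem_path
#' @export
tidy.sem_path <- function(x, ...) x$edges

#' @rdname tidy.sem_path
#' @method glance sem_path
#' @export
glance.sem_path <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x$edges),
    n_significant = sum(x$edges$significant),
    n_endogenous = dplyr::n_distinct(x$edges$to),
    alpha = x$alpha
  )
}
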