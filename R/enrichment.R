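#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `s_i` or more epimutated probes in a gene of
#' `g_i` probes, when `n_s` of the `n_g` probes on the array are epimutated:
#' `P(X >= s_i)` for `X ~ Hypergeometric(n_g, n_s, g_i)`. Computed in
#' log-space via `stats::phyper()` for numerical stability.
#'
#' @param n_g Total probes on the array (population size).
#' @param n_s Epimutated probes in the selected sample (successes).
#' @param g_i Probes in the gene (draws). Vectorised together with `s_i`.
#' @param s_i Epimutated probes in the gene.
#' @return Upper-tail p-value(s) in (0, 1].
#' @examples
#' hypergeom_upper_tail(100, 10, 5, 3)
#' @export
hypergeom_upper_tail <- function(n_g, n_s, g_i, s_i) {
  if (any(n_g < 0 | n_s < 0 | g_i < 0 | s_i < 0)) stop("counts must be non-negative")
  if (any(n_s > n_g)) stop("n_s cannot exceed n_g")
  if (any(g_i > n_g)) stop("g_i cannot exceed n_g")
  if (any(s_i > pmin(g_i, n_s))) stop("s_i cannot exceed min(g_i, n_s)")
  # also S_I cannot be below the forced minimum of the support
  if (any(s_i < pmax(0, g_i + n_s - n_g))) {
    stop("s_i below the hypergeometric support minimum g_i + n_s - n_g")
  }
  exp(stats::phyper(s_i - 1, n_s, n_g - n_s, g_i,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Gene-level enrichment of epimutated probes
#'
#' Tests every gene for over-representation of a sample's epimutated probes
#' with the upper-tail hypergeometric test and Bonferroni correction, the
#' positive-control validation used for imprinting-disorder samples: a gene
#' harbouring a true regional epigenetic alteration should surface with a
#' small corrected p-value.
#'
#' Probes annotated to several genes (semicolon-separated `gene` field)
#' count once per gene in the gene-level tallies but once in the array-wide
#' totals. Probes with an empty `gene` contribute to the totals only.
#'
#' @param calls A [call_sems()] result.
#' @param sample_id Sample to test.
#' @param annot Probe annotation covering the probe universe.
#' @param alpha Significance level on the Bonferroni-corrected p (default
#'   0.05).
#' @param universe Probe ids forming the array universe `N_G`; defaults to
#'   the probes the call set was computed on (the post-QC universe).
#' @return A tibble with `gene`, `n_probes` (G_I), `n_epimutated` (S_I),
#'   `p_raw`, `p_bonferroni`, `significant`, sorted by `p_raw` (ties broken
#'   by gene name).
#' @export
gene_enrichment <- function(calls, sample_id, annot, alpha = 0.05, universe = NULL) {
  stopifnot(inherits(calls, "sem_calls"))
  if (!sample_id %in% calls$sample_ids) stop("unknown sample id: ", sample_id)
  annot <- validate_probe_annotation(annot)
  universe <- universe %||% calls$stats$probe_id
  miss <- setdiff(universe, annot$probe_id)
  if (length(miss) > 0) {
    stop("annotation missing probe(s): ", paste(utils::head(miss, 10), collapse = ", "))
  }
  called <- unique(calls$calls$probe_id[calls$calls$sample_id == sample_id])
  called <- intersect(called, universe)
  n_g <- length(universe)
  n_s <- length(called)

  gene_map <- annot |>
    dplyr::filter(.data$probe_id %in% universe, .data$gene != "") |>
    dplyr::select("probe_id", "gene") |>
    tidyr::separate_longer_delim("gene", delim = ";") |>
    dplyr::filter(.data$gene != "") |>
    dplyr::distinct()

  res <- gene_map |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_probes = dplyr::n(),
                     n_epimutated = sum(.data$probe_id %in% called),
                     .groups = "drop")
  n_genes <- nrow(res)
  if (n_genes == 0) {
    return(tibble::tibble(gene = character(), n_probes = integer(),
                          n_epimutated = integer(), p_raw = double(),
                          p_bonferroni = double(), significant = logical()))
  }
  res |>
    dplyr::mutate(
      p_raw = hypergeom_upper_tail(n_g, n_s, .data$n_probes, .data$n_epimutated),
      p_bonferroni = pmin(1, .data$p_raw * n_genes),
      significant = .data$p_bonferroni < alpha
    ) |>
    dplyr::arrange(.data$p_raw, .data$gene)
}
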