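#' Extreme-outlier fences for one probe
#'
#' Computes quartiles of a probe's beta values across samples and the extreme
#' Tukey fences `Q1 - k*IQR` and `Q3 + k*IQR`. With the default `k = 3` a
#' value beyond a fence is a stochastic epigenetic mutation (SEM) call for
#' that probe.
#'
#' @param values Numeric vector of beta values (>= 4, no missing).
#' @param k Fence multiplier (default 3).
#' @param quantile_method `"linear"` (default): quartiles by linear
#'   interpolation of order statistics at position `p * (n - 1)`
#'   (`stats::quantile()` type 7); `"hinges"`: Tukey hinges as in
#'   `stats::fivenum()`.
#' @return A one-row tibble with `q1`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`.
#' @examples
#' probe_fences(c(0.49, 0.49, 0.5, 0.5, 0.5, 0.51, 0.51, 0.52, 0.52, 0.95))
#' @export
probe_fences <- function(values, k = 3, quantile_method = c("linear", "hinges")) {
  quantile_method <- match.arg(quantile_method)
  if (anyNA(values)) stop("missing values; resolve missingness before computing fences")
  if (length(values) < 4) stop("at least 4 values are required for stable quartiles")
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  q <- row_quartiles(matrix(values, nrow = 1), quantile_method)
  iqr <- q[, 2] - q[, 1]
  tibble::tibble(q1 = q[, 1], q3 = q[, 2], iqr = iqr,
                 lower_fence = q[, 1] - k * iqr,
                 upper_fence = q[, 2] + k * iqr)
}

# Vectorised per-row quartiles. "linear" reproduces quantile(type = 7):
# position p*(n-1) on the 0-indexed sorted values; "hinges" reproduces the
# Tukey hinges of fivenum().
row_quartiles <- function(v, quantile_method = "linear") {
  n <- ncol(v)
  s <- matrixsort_rows(v)
  if (quantile_method == "linear") {
    qpos <- function(p) {
      h <- p * (n - 1)
      lo <- floor(h)
      s[, lo + 1] * (1 - (h - lo)) + s[, pmin(lo + 2, n)] * (h - lo)
    }
    cbind(qpos(0.25), qpos(0.75))
  } else {
    h <- floor((n + 3) / 2) / 2
    lo <- floor(h); frac <- h - lo
    q1 <- s[, lo] * (1 - frac) + s[, lo + (frac > 0)] * frac
    hi <- n + 1 - h
    lo2 <- floor(hi); frac2 <- hi - lo2
    q3 <- s[, lo2] * (1 - frac2) + s[, lo2 + (frac2 > 0)] * frac2
    unname(cbind(q1, q3))
  }
}

matrixsort_rows <- function(v) {
  t(apply(v, 1, sort.int, method = "quick"))
}

#' Call stochastic epigenetic mutations
#'
#' For every probe, computes the extreme fences (see [probe_fences()]) over
#' all samples and calls each sample whose beta value lies strictly above the
#' upper fence (`hyper`) or strictly below the lower fence (`hypo`) as
#' epimutated at that probe. Values exactly equal to a fence are not called.
#'
#' @param x Complete beta-matrix tibble (no missing values, >= 4 samples).
#' @inheritParams probe_fences
#' @return An object of class `sem_calls`: a list with `calls` (tibble of
#'   `probe_id`, `sample_id`, `direction`, `beta`), `stats` (per-probe fence
#'   tibble), `k`, `quantile_method` and `sample_ids`. Use [tidy()] /
#'   [glance()] / [count_sems()] on it.
#' @export
call_sems <- function(x, k = 3, quantile_method = c("linear", "hinges")) {
  quantile_method <- match.arg(quantile_method)
  x <- validate_beta_matrix(x)
  v <- beta_values(x)
  if (anyNA(v)) stop("missing beta values; filter or impute before calling SEMs")
  if (ncol(v) < 4) stop("at least 4 samples are required")
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  q <- row_quartiles(v, quantile_method)
  iqr <- q[, 2] - q[, 1]
  lower <- q[, 1] - k * iqr
  upper <- q[, 2] + k * iqr
  hyper <- which(v > upper, arr.ind = TRUE)     # fence recycles along rows
  hypo <- which(v < lower, arr.ind = TRUE)
  calls <- tibble::tibble(
    probe_id = c(rownames(v)[hyper[, 1]], rownames(v)[hypo[, 1]]),
    sample_id = c(colnames(v)[hyper[, 2]], colnames(v)[hypo[, 2]]),
    direction = rep(c("hyper", "hypo"), c(nrow(hyper), nrow(hypo))),
    beta = c(v[hyper], v[hypo])
  )
  calls <- dplyr::arrange(calls, match(.data$probe_id, rownames(v)),
                          match(.data$sample_id, colnames(v)))
  stats <- tibble::tibble(probe_id = rownames(v), q1 = q[, 1], q3 = q[, 2],
                          iqr = iqr, lower_fence = lower, upper_fence = upper)
  structure(
    list(calls = calls, stats = stats, k = k, quantile_method = quantile_method,
         sample_ids = colnames(v)),
    class = "sem_calls"
  )
}

#' @export
print.sem_calls <- function(x, ...) {
  cat("SEM call set: ", nrow(x$calls), " calls (",
      sum(x$calls$direction == "hyper"), " hyper, ",
      sum(x$calls$direction == "hypo"), " hypo) over ",
      nrow(x$stats), " probes x ", length(x$sample_ids),
      " samples [k = ", x$k, ", quartiles: ", x$quantile_method, "]\n", sep = "")
  invisible(x)
}

#' Per-subject epimutation burden
#'
#' Counts SEM calls per sample and adds the log-transformed burden
#' `log_sem = ln(n_sem + 1)`; the +1 keeps zero-burden subjects (typically
#' children) defined on the log scale.
#'
#' @param calls A [call_sems()] result.
#' @param samples Sample ids to report (default: all samples of the call
#'   set); samples with no calls get `n_sem = 0`.
#' @return A tibble with `sample_id`, `n_sem`, `n_hyper`, `n_hypo`,
#'   `log_sem`.
#' @export
count_sems <- function(calls, samples = NULL) {
  stopifnot(inherits(calls, "sem_calls"))
  samples <- samples %||% calls$sample_ids
  extra <- setdiff(unique(calls$calls$sample_id), samples)
  if (length(extra) > 0) {
    stop("`samples` must cover every called sample; missing: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  tab <- calls$calls |>
    dplyr::count(.data$sample_id, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n", values_fill = 0L)
  for (d in c("hyper", "hypo")) if (!d %in% names(tab)) tab[[d]] <- 0L
  tibble::tibble(sample_id = samples) |>
    dplyr::left_join(tab, by = "sample_id") |>
    dplyr::mutate(
      n_hyper = dplyr::coalesce(.data$hyper, 0L),
      n_hypo = dplyr::coalesce(.data$hypo, 0L),
      n_sem = .data$n_hyper + .data$n_hypo,
      log_sem = log(.data$n_sem + 1)
    ) |>
    dplyr::select("sample_id", "n_sem", "n_hyper", "n_hypo", "log_sem")
}

#' Concordance of epimutation calls between technical duplicates
#'
#' For each pair, correlates the two samples' binary per-probe epimutation
#' indicator vectors (Pearson) over the full probe universe of the call
#' set. Identical non-empty call sets score exactly 1, disjoint non-empty
#' sets score below 0, and duplicates sharing a fraction `s` of their calls
#' score close to `s`. Pairs where the correlation is undefined — both
#' members call-free, or a member calling every probe — are reported as
#' `NA`.
#'
#' @param calls A [call_sems()] result.
#' @param pairs Data frame whose first two columns name the paired samples.
#' @return A tibble with `sample_1`, `sample_2`, `n_union`, `n_shared`,
#'   `concordance`.
#' @export
duplicate_concordance <- function(calls, pairs) {
  stopifnot(inherits(calls, "sem_calls"))
  pairs <- as.data.frame(pairs)[, 1:2]
  names(pairs) <- c("sample_1", "sample_2")
  unknown <- setdiff(unique(c(pairs$sample_1, pairs$sample_2)), calls$sample_ids)
  if (length(unknown) > 0) {
    stop("unknown sample id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  universe <- calls$stats$probe_id
  by_sample <- split(calls$calls$probe_id, calls$calls$sample_id)
  purrr::pmap(pairs, function(sample_1, sample_2) {
    a <- unique(by_sample[[sample_1]]) %||% character()
    b <- unique(by_sample[[sample_2]]) %||% character()
    ia <- as.numeric(universe %in% a)
    ib <- as.numeric(universe %in% b)
    conc <- if (stats::sd(ia) == 0 || stats::sd(ib) == 0) {
      NA_real_
    } else {
      stats::cor(ia, ib)
    }
    tibble::tibble(sample_1 = sample_1, sample_2 = sample_2,
                   n_union = length(union(a, b)),
                   n_shared = length(intersect(a, b)),
                   concordance = conc)
  }) |> purrr::list_rbind()
}
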