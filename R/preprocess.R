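#' Sample-level quality control
#'
#' Removes samples in two ordered steps: (1) bisulfite-conversion failures,
#' i.e. samples whose `bs_control_intensity` in the sheet is strictly below
#' `bs_threshold` (samples with no recorded intensity pass this step); then
#' (2) a PCA screen on the remaining samples — probes are standardized,
#' sample scores on the first two principal components are computed, and any
#' sample whose score lies more than `pca_sd` standard deviations from the
#' component mean is dropped as an aberrant methylation profile.
#'
#' @param x Beta-matrix tibble.
#' @param sheet Sample sheet covering every sample of `x`.
#' @param bs_threshold Bisulfite-control intensity cut-off (default 4000;
#'   comparison is strict, intensity < threshold is removed).
#' @param pca_sd Score deviation multiplier for the PCA screen (default 4).
#' @return A list with `beta` (the filtered matrix) and `qc` (a QC report:
#'   tibble of removed ids with reasons plus retained counts).
#' @export
filter_samples <- function(x, sheet, bs_threshold = 4000, pca_sd = 4) {
  x <- validate_beta_matrix(x)
  sheet <- validate_sample_sheet(sheet)
  ids <- sample_ids(x)
  miss <- setdiff(ids, sheet$sample_id)
  if (length(miss) > 0) {
    stop("sample sheet does not cover sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  bs <- sheet$bs_control_intensity[match(ids, sheet$sample_id)]
  fail_bs <- !is.na(bs) & bs < bs_threshold
  removed <- tibble::tibble(id = ids[fail_bs], axis = "sample", reason = "bs_control")

  keep <- ids[!fail_bs]
  if (length(keep) < 3) stop("fewer than 3 samples remain; PCA screen undefined")
  v <- beta_values(x)[, keep, drop = FALSE]
  scores <- pca_sample_scores(v)
  out_pc <- rep(FALSE, length(keep))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    sdev <- stats::sd(s)
    if (sdev > 0) out_pc <- out_pc | abs(s - mean(s)) > pca_sd * sdev
  }
  removed <- dplyr::bind_rows(
    removed,
    tibble::tibble(id = keep[out_pc], axis = "sample", reason = "pca_outlier")
  )
  keep <- keep[!out_pc]
  beta <- x[, c("probe_id", keep)]
  new_qc(beta, removed)
}

# Sample scores on PC1/PC2 after per-probe standardization; zero-variance
# probes carry no information and are excluded from the decomposition.
pca_sample_scores <- function(v) {
  z <- t(v)                                   # samples x probes
  z <- scale(z)
  z <- z[, colSums(!is.finite(z)) == 0, drop = FALSE]
  if (ncol(z) == 0) return(matrix(0, ncol(v), 2))
  sv <- svd(z, nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(ncol(sv$u))], ncol(sv$u))
  if (ncol(scores) < 2) scores <- cbind(scores, 0)
  scores[, 1:2, drop = FALSE]
}

#' Probe-level quality control
#'
#' Removes probes in a fixed order, recording the first applicable reason:
#' (1) `missing_beta` — any missing beta value; (2) `detection_p` — fewer
#' than `call_rate` of samples with detection p-value below `detp_alpha`
#' (skipped with a warning when no detection p-value matrix is supplied);
#' (3) `sex_chromosome` — probes annotated to chromosome X or Y.
#'
#' @param x Beta-matrix tibble.
#' @param annot Probe annotation covering every probe of `x`.
#' @param detp Optional detection p-value matrix with the same probes and
#'   samples as `x`.
#' @param detp_alpha Detection p-value threshold (default 0.05).
#' @param call_rate Minimum fraction of samples passing `detp_alpha`
#'   (default 0.95; the comparison is `fraction < call_rate` removed).
#' @return A list with `beta` and `qc`, as in [filter_samples()].
#' @export
filter_probes <- function(x, annot, detp = NULL, detp_alpha = 0.05, call_rate = 0.95) {
  x <- validate_beta_matrix(x)
  annot <- validate_probe_annotation(annot)
  miss <- setdiff(x$probe_id, annot$probe_id)
  if (length(miss) > 0) {
    stop("annotation missing probe(s): ", paste(utils::head(miss, 10), collapse = ", "))
  }
  v <- beta_values(x)
  reason <- rep(NA_character_, nrow(v))

  has_missing <- rowSums(is.na(v)) > 0
  reason[has_missing] <- "missing_beta"

  if (is.null(detp)) {
    warning("no detection p-value matrix supplied; detection-p filter skipped")
  } else {
    detp <- validate_beta_matrix(detp, what = "detection p-value")
    if (!identical(detp$probe_id, x$probe_id) ||
        !identical(sample_ids(detp), sample_ids(x))) {
      stop("detection p-value matrix must match the beta matrix's probes and samples")
    }
    pv <- beta_values(detp)
    frac_pass <- rowMeans(pv < detp_alpha, na.rm = FALSE)
    fail <- is.na(frac_pass) | frac_pass < call_rate
    reason[is.na(reason) & fail] <- "detection_p"
  }

  chrom <- annot$chromosome[match(x$probe_id, annot$probe_id)]
  reason[is.na(reason) & chrom %in% c("X", "Y")] <- "sex_chromosome"

  removed <- tibble::tibble(id = x$probe_id[!is.na(reason)], axis = "probe",
                            reason = reason[!is.na(reason)])
  beta <- x[is.na(reason), , drop = FALSE]
  new_qc(beta, removed)
}

new_qc <- function(beta, removed) {
  structure(
    list(beta = beta,
         qc = tibble::as_tibble(removed),
         n_probes_retained = nrow(beta),
         n_samples_retained = ncol(beta) - 1L),
    class = "sem_qc"
  )
}

#' @export
print.sem_qc <- function(x, ...) {
  cat("QC result:", x$n_probes_retained, "probes x", x$n_samples_retained,
      "samples retained\n")
  if (nrow(x$qc) > 0) {
    tab <- table(x$qc$axis, x$qc$reason)
    cat("removed:\n")
    print(tab)
  } else {
    cat("nothing removed\n")
  }
  invisible(x)
}

#' Quantile normalisation of a beta matrix
#'
#' Forces every sample to share the same value distribution: the reference
#' distribution is the across-sample mean of order statistics, and each
#' sample's values are replaced by the reference value at their rank. Ties
#' within a sample receive the mean of the reference values over the tied
#' rank span, so the within-sample ordering is preserved.
#'
#' @param x Complete beta-matrix tibble (no missing values; run
#'   [filter_probes()] first).
#' @return The normalized beta-matrix tibble.
#' @export
quantile_normalize <- function(x) {
  x <- validate_beta_matrix(x)
  v <- beta_values(x)
  if (anyNA(v)) stop("missing beta values; filter or impute probes before normalising")
  if (ncol(v) <= 1 || nrow(v) == 0) return(x)
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    stats::ave(assigned, col, FUN = mean)
  })
  rownames(out) <- rownames(v)
  beta_matrix(out)
}

#' Pool 27K and 450K beta matrices
#'
#' Restricts both matrices to their common probes and concatenates the
#' samples (27K samples first). Probe order follows the 450K matrix.
#'
#' @param m27,m450 QC'd beta-matrix tibbles with disjoint sample ids.
#' @return The pooled beta-matrix tibble.
#' @export
pool_platforms <- function(m27, m450) {
  m27 <- validate_beta_matrix(m27)
  m450 <- validate_beta_matrix(m450)
  overlap <- intersect(sample_ids(m27), sample_ids(m450))
  if (length(overlap) > 0) {
    stop("overlapping sample ids: ", paste(utils::head(overlap, 5), collapse = ", "))
  }
  shared <- m450$probe_id[m450$probe_id %in% m27$probe_id]
  if (length(shared) == 0) stop("no probes in common between the two platforms")
  a <- m27[match(shared, m27$probe_id), , drop = FALSE]
  b <- m450[match(shared, m450$probe_id), , drop = FALSE]
  dplyr::bind_cols(b["probe_id"], a[, -1, drop = FALSE], b[, -1, drop = FALSE])
}
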