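#' Degree of X-inactivation skewing from HUMARA peak heights
#'
#' In the HUMARA assay, HpaII/HhaI digestion destroys the unmethylated
#' (active-X) allele of the androgen receptor CAG repeat, so each allele's
#' digested peak reflects its methylated, inactive-X fraction. The
#' undigested reaction corrects allele-specific PCR amplification bias:
#' the corrected ratio is `r = (d1/d2) / (u1/u2)`, the inactive fraction of
#' allele 1 is `f = r / (1 + r)`, its active fraction is `1 - f`, and the
#' degree of skewing is `DS = |(1 - f) - 0.5| * 100`, from 0 (random XCI)
#' to 50 (completely skewed).
#'
#' A zero digested peak is taken at the formula's limit (`r = 0` or
#' `r = Inf`), giving complete skew (`DS = 50`); both digested peaks zero is
#' an error.
#'
#' @param peaks Data frame with columns `sample_id`, `d1`, `d2` (digested
#'   peak heights, >= 0, not both zero) and `u1`, `u2` (undigested peak
#'   heights, > 0).
#' @return A tibble with `sample_id`, `active_fraction` (of allele 1) and
#'   `ds` (percent in \[0, 50\]).
#' @examples
#' degree_of_skewing(data.frame(sample_id = "F1",
#'                              d1 = 1800, d2 = 200, u1 = 1000, u2 = 1000))
#' @export
degree_of_skewing <- function(peaks) {
  peaks <- validate_humara_peaks(peaks)
  r <- (peaks$d1 / peaks$d2) / (peaks$u1 / peaks$u2)
  f <- ifelse(is.infinite(r), 1, r / (1 + r))   # inactive-X fraction of allele 1
  active <- 1 - f
  tibble::tibble(sample_id = peaks$sample_id,
                 active_fraction = active,
                 ds = abs(active - 0.5) * 100)
}

validate_humara_peaks <- function(peaks) {
  peaks <- tibble::as_tibble(peaks)
  need <- c("sample_id", "d1", "d2", "u1", "u2")
  miss <- setdiff(need, names(peaks))
  if (length(miss) > 0) stop("peak table missing column(s): ", paste(miss, collapse = ", "))
  num <- c("d1", "d2", "u1", "u2")
  for (col in num) {
    if (!is.numeric(peaks[[col]]) || anyNA(peaks[[col]])) {
      stop("column ", col, " must be numeric with no missing values")
    }
  }
  neg <- peaks$d1 < 0 | peaks$d2 < 0 | peaks$u1 < 0 | peaks$u2 < 0
  if (any(neg)) stop("negative peak height(s) for sample(s): ",
                     paste(utils::head(peaks$sample_id[neg], 5), collapse = ", "))
  zero_u <- peaks$u1 == 0 | peaks$u2 == 0
  if (any(zero_u)) stop("undigested peak height zero for sample(s): ",
                        paste(utils::head(peaks$sample_id[zero_u], 5), collapse = ", "))
  zero_d <- peaks$d1 == 0 & peaks$d2 == 0
  if (any(zero_d)) stop("both digested peaks zero for sample(s): ",
                        paste(utils::head(peaks$sample_id[zero_d], 5), collapse = ", "))
  peaks
}

#' Read a HUMARA peak-height table
#'
#' TSV/CSV with columns `sample_id`, `d1`, `d2`, `u1`, `u2`.
#'
#' @inheritParams read_beta_matrix
#' @return A validated peak tibble.
#' @export
read_peak_table <- function(path, format = "tsv") {
  validate_humara_peaks(read_delim_strict(path, format))
}

#' Write a HUMARA peak-height table
#'
#' @param peaks A peak tibble as accepted by [degree_of_skewing()].
#' @inheritParams write_beta_matrix
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path, format = "tsv") {
  peaks <- validate_humara_peaks(peaks)
  writer <- if (match.arg(format, c("tsv", "csv")) == "tsv") readr::write_tsv else readr::write_csv
  writer(peaks, path, na = "NA", progress = FALSE)
  invisible(path)
}
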