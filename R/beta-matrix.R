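#' Build a beta-value matrix tibble
#'
#' A beta matrix is the package's central container: a tibble whose first
#' column `probe_id` holds CpG probe identifiers and whose remaining columns
#' hold per-sample methylation beta values in \[0, 1\] (`NA` for missing).
#' Row order is probe order and column order is sample order; neither is ever
#' silently sorted.
#'
#' @param values Numeric matrix (probes x samples) of beta values.
#' @param probe_ids Character vector of probe identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids Character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @return A tibble with columns `probe_id` and one numeric column per sample.
#' @examples
#' m <- matrix(runif(6), 3, 2, dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' beta_matrix(m)
#' @export
beta_matrix <- function(values, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(probe_ids)) {
    if (nrow(values) > 0) stop("`probe_ids` are required (or rownames on `values`)")
    probe_ids <- character()
  }
  if (is.null(sample_ids)) stop("`sample_ids` are required (or colnames on `values`)")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  out <- tibble::as_tibble(values, .name_repair = "minimal")
  names(out) <- sample_ids
  out <- dplyr::bind_cols(tibble::tibble(probe_id = as.character(probe_ids)), out)
  validate_beta_matrix(out)
}

#' Extract the numeric value grid of a beta matrix
#'
#' @param x A beta-matrix tibble (see [beta_matrix()]).
#' @return A numeric matrix with probe rownames and sample colnames.
#' @export
beta_values <- function(x) {
  v <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- x$probe_id
  v
}

#' @rdname beta_values
#' @export
sample_ids <- function(x) names(x)[-1]

#' @rdname beta_values
#' @export
probe_ids <- function(x) x$probe_id

# Strict structural validation; `what` only changes the noun in messages so the
# same contract serves detection p-value matrices.
validate_beta_matrix <- function(x, what = "beta value", range01 = TRUE) {
  if (!is.data.frame(x) || ncol(x) < 1 || names(x)[1] != "probe_id") {
    stop("malformed ", what, " matrix: first column must be `probe_id`")
  }
  x <- tibble::as_tibble(x)
  x$probe_id <- as.character(x$probe_id)
  if (anyDuplicated(x$probe_id)) {
    dup <- unique(x$probe_id[duplicated(x$probe_id)])
    stop("duplicate probe ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(names(x))) {
    dup <- unique(names(x)[duplicated(names(x))])
    stop("duplicate sample ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (j in seq_along(x)[-1]) {
    if (!is.numeric(x[[j]])) {
      stop("sample ", names(x)[j], ": non-numeric ", what, "s")
    }
  }
  if (range01 && ncol(x) > 1) {
    v <- beta_values(x)
    bad <- which(!is.na(v) & (v < 0 | v > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("%s out of [0,1] at probe %s, sample %s (value %g)",
                   what, rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]],
                   v[bad[1, 1], bad[1, 2]]))
    }
  }
  x
}

read_delim_strict <- function(path, format) {
  format <- match.arg(format, c("tsv", "csv"))
  reader <- if (format == "tsv") readr::read_tsv else readr::read_csv
  reader(path, na = "NA", show_col_types = FALSE, progress = FALSE,
         name_repair = "minimal")
}

# Matrix files are parsed with base R: its strtod-based number parser is
# correctly rounded, which keeps write -> read -> write byte-stable.
read_matrix_file <- function(path, format) {
  format <- match.arg(format, c("tsv", "csv"))
  sep <- if (format == "tsv") "\t" else ","
  first <- readLines(path, n = 1)
  if (length(first) == 0) stop("malformed header: empty file")
  header <- strsplit(first, sep, fixed = TRUE)[[1]]
  if (length(header) == 0) stop("malformed header: no columns")
  x <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                         na.strings = "NA", quote = "\"", comment.char = "",
                         colClasses = c("character",
                                        rep("numeric", length(header) - 1)))
  tibble::as_tibble(x, .name_repair = "minimal")
}

#' Read a beta-value matrix from TSV/CSV
#'
#' The first column must contain probe ids and the header row sample ids;
#' cells are numeric beta values or the missing token `"NA"`.
#'
#' @param path Path to the file.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A validated beta-matrix tibble.
#' @export
read_beta_matrix <- function(path, format = "tsv") {
  x <- read_matrix_file(path, format)
  names(x)[1] <- "probe_id"
  validate_beta_matrix(x)
}

#' Write a beta-value matrix to TSV/CSV
#'
#' Probe and sample order are preserved exactly; missing values are written as
#' `"NA"`. `read_beta_matrix()` of the result returns an identical matrix.
#'
#' @inheritParams read_beta_matrix
#' @param x A beta-matrix tibble.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, format = "tsv") {
  x <- validate_beta_matrix(x)
  format <- match.arg(format, c("tsv", "csv"))
  writer <- if (format == "tsv") readr::write_tsv else readr::write_csv
  writer(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a detection p-value matrix
#'
#' Same layout contract as [read_beta_matrix()]; values are per-probe,
#' per-sample detection p-values in \[0, 1\].
#'
#' @inheritParams read_beta_matrix
#' @return A validated tibble with `probe_id` plus one column per sample.
#' @export
read_detection_p <- function(path, format = "tsv") {
  x <- read_matrix_file(path, format)
  names(x)[1] <- "probe_id"
  validate_beta_matrix(x, what = "detection p-value")
}

chrom_levels <- c(as.character(1:22), "X", "Y")

#' Read a probe annotation table
#'
#' Expected columns: `probe_id`, `chromosome` (1-22, X, Y), `position`
#' (1-based bp), `gene` (symbol, `""`/`NA` for intergenic; multiple genes
#' separated by `;`), `platforms` (subset of `27K`,`450K`, `;`-separated).
#'
#' @inheritParams read_beta_matrix
#' @return A validated annotation tibble.
#' @export
read_probe_annotation <- function(path, format = "tsv") {
  x <- read_delim_strict(path, format)
  validate_probe_annotation(x)
}

validate_probe_annotation <- function(x) {
  need <- c("probe_id", "chromosome", "position")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  x <- tibble::as_tibble(x)
  x$probe_id <- as.character(x$probe_id)
  x$chromosome <- sub("^chr", "", as.character(x$chromosome))
  if (!"gene" %in% names(x)) x$gene <- ""
  x$gene <- dplyr::coalesce(as.character(x$gene), "")
  if (!"platforms" %in% names(x)) x$platforms <- "27K;450K"
  if (anyDuplicated(x$probe_id)) {
    stop("duplicate probe ids in annotation: ",
         paste(utils::head(unique(x$probe_id[duplicated(x$probe_id)]), 5), collapse = ", "))
  }
  bad <- !x$chromosome %in% chrom_levels
  if (any(bad)) stop("invalid chromosome for probe(s): ",
                     paste(utils::head(x$probe_id[bad], 5), collapse = ", "))
  x$position <- as.integer(x$position)
  if (any(is.na(x$position) | x$position < 1)) {
    stop("positions must be integers >= 1 (1-based)")
  }
  x
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `age` (years), `sex` (`F`/`M`), `platform`
#' (`27K`/`450K`); optional: `bmi`, `bs_control_intensity`, `ds_xci`
#' (percent in \[0, 50\]), `replicate_of`.
#'
#' @inheritParams read_beta_matrix
#' @return A validated sample-sheet tibble.
#' @export
read_sample_sheet <- function(path, format = "tsv") {
  x <- read_delim_strict(path, format)
  validate_sample_sheet(x)
}

validate_sample_sheet <- function(x) {
  need <- c("sample_id", "age", "sex", "platform")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  x <- tibble::as_tibble(x)
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) stop("duplicate sample ids in sheet")
  if (any(!is.na(x$age) & x$age < 0)) stop("ages must be >= 0")
  if (any(!x$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (any(!x$platform %in% c("27K", "450K"))) stop("platform must be 27K or 450K")
  for (opt in c("bmi", "bs_control_intensity", "ds_xci")) {
    if (!opt %in% names(x)) x[[opt]] <- NA_real_
  }
  if (!"replicate_of" %in% names(x)) x$replicate_of <- NA_character_
  x$replicate_of <- dplyr::na_if(as.character(x$replicate_of), "")
  bad <- !is.na(x$ds_xci) & (x$ds_xci < 0 | x$ds_xci > 50)
  if (any(bad)) stop("ds_xci must lie in [0, 50]; offending sample(s): ",
                     paste(utils::head(x$sample_id[bad], 5), collapse = ", "))
  bad <- !is.na(x$bmi) & x$bmi <= 0
  if (any(bad)) stop("bmi must be positive")
  orphan <- !is.na(x$replicate_of) & !x$replicate_of %in% x$sample_id
  if (any(orphan)) stop("replicate_of names unknown sample(s): ",
                        paste(utils::head(x$replicate_of[orphan], 5), collapse = ", "))
  x
}

#' Write epimutation calls as a BED file
#'
#' Converts 1-based probe positions to 0-based half-open BED intervals
#' (`start = position - 1`, `end = position`), names each line
#' `probe|sample|direction`, and sorts by chromosome then start.
#'
#' @param calls A [call_sems()] result.
#' @param annot A probe annotation tibble covering every called probe.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sem_bed <- function(calls, annot, path) {
  stopifnot(inherits(calls, "sem_calls"))
  annot <- validate_probe_annotation(annot)
  tab <- calls$calls
  miss <- setdiff(unique(tab$probe_id), annot$probe_id)
  if (length(miss) > 0) {
    stop("probe(s) missing from annotation: ", paste(utils::head(miss, 10), collapse = ", "))
  }
  bed <- tab |>
    dplyr::inner_join(annot[, c("probe_id", "chromosome", "position")], by = "probe_id") |>
    dplyr::transmute(
      chrom = paste0("chr", .data$chromosome),
      start = .data$position - 1L,
      end = .data$position,
      name = paste(.data$probe_id, .data$sample_id, .data$direction, sep = "|"),
      .chr_rank = match(.data$chromosome, chrom_levels)
    ) |>
    dplyr::arrange(.data$.chr_rank, .data$start, .data$name) |>
    dplyr::select(-".chr_rank")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
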