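#' Read a feature-by-sample count matrix from TSV
#'
#' The canonical on-disk form is a tab-separated table whose first column,
#' `feature_id`, holds unique feature identifiers and whose remaining columns
#' hold non-negative integer counts, one column per sample, with sample IDs in
#' the header row.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `feature_id` column followed by one integer column
#'   per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_counts(tibble::tibble(feature_id = c("g1", "g2"), s1 = 1:2, s2 = 3:4), tf)
#' read_counts(tf)
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) abort(sprintf("count table needs >= 2 columns: %s", path))
  types <- do.call(readr::cols, c(
    setNames(list(readr::col_character()), header[1]),
    list(.default = readr::col_double())
  ))
  tab <- readr::read_tsv(path, col_types = types, progress = FALSE)
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed count table %s (first problem at line %d: %s)",
                  path, prob$row[1] + 1L, prob$expected[1]))
  }
  # first column is the feature id regardless of its header label
  names(tab)[1] <- "feature_id"
  validate_counts(tab)
  tab
}

#' Write a count matrix to TSV
#'
#' @param counts A count tibble as returned by [read_counts()] or
#'   [simulate_paired_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read or write a sample-metadata table
#'
#' Metadata is a two-plus-column TSV with at least `sample_id` and `group`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id` and `group`.
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  validate_meta(meta)
  meta
}

#' @rdname read_meta
#' @param meta Metadata tibble.
#' @export
write_meta <- function(meta, path) {
  validate_meta(meta)
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read or write a differential-expression result table
#'
#' The on-disk schema is `feature_id, base_mean, log2fc, se, stat, pvalue,
#' padj` as TSV; missing `padj` (features removed by the independent low-count
#' filter) is stored as the literal `NA`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of class `mirlink_de`.
#' @export
read_de <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  de <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), filtered = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("feature_id", "base_mean", "log2fc", "pvalue")
  miss <- setdiff(need, names(de))
  if (length(miss) > 0) abort(sprintf("DE table lacks columns: %s", paste(miss, collapse = ", ")))
  new_de_result(de)
}

#' @rdname read_de
#' @param de A `mirlink_de` tibble.
#' @export
write_de <- function(de, path) {
  readr::write_tsv(de, path, progress = FALSE)
  invisible(path)
}

#' Read or write a correlation table
#'
#' Schema: `mirna_id, gene_id, n, r, pvalue, scope` as TSV.
#'
#' @param path Path to a TSV file.
#' @return A correlation tibble.
#' @export
read_correlations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), gene_id = readr::col_character(),
    scope = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_correlations
#' @param records Correlation tibble from [correlate_pairs()].
#' @export
write_correlations <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
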