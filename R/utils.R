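# internal helpers shared across modules

# A count table is a tibble whose first column is `feature_id` and whose
# remaining columns are one non-negative integer column per sample.
counts_to_matrix <- function(counts) {
  validate_counts(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

matrix_to_counts <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

validate_counts <- function(counts, arg = "counts") {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    abort(sprintf("`%s` must be a data frame with a feature_id column and >= 1 sample column.", arg))
  }
  if (names(counts)[1] != "feature_id") {
    abort(sprintf("first column of `%s` must be named 'feature_id'.", arg))
  }
  dup <- counts$feature_id[duplicated(counts$feature_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature IDs in `%s`: %s", arg,
                  paste(unique(dup), collapse = ", ")))
  }
  sn <- names(counts)[-1]
  if (anyDuplicated(sn)) {
    abort(sprintf("duplicate sample IDs in `%s`: %s", arg,
                  paste(unique(sn[duplicated(sn)]), collapse = ", ")))
  }
  vals <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort(sprintf("`%s` sample columns must be numeric.", arg))
  if (anyNA(vals)) abort(sprintf("`%s` contains missing values.", arg))
  if (any(vals < 0)) abort(sprintf("`%s` contains negative values.", arg))
  if (any(vals != round(vals))) abort(sprintf("`%s` contains non-integer values.", arg))
  invisible(counts)
}

validate_meta <- function(meta, sample_ids = NULL) {
  if (!is.data.frame(meta) || !all(c("sample_id", "group") %in% names(meta))) {
    abort("`meta` must be a data frame with columns sample_id and group.")
  }
  if (anyDuplicated(meta$sample_id)) abort("`meta` has duplicated sample IDs.")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, meta$sample_id)
    if (length(missing) > 0) {
      abort(sprintf("samples absent from `meta`: %s", paste(missing, collapse = ", ")))
    }
  }
  invisible(meta)
}

# deterministic child seeds below 2^31, derived from a user seed and a stream tag
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 20011L + (as.integer(stream) %% 20011L)
}
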