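#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated format used for GO/KEGG collections: one set per
#' line, fields `name, description, member1, member2, ...`. Lines with fewer
#' than three fields are rejected with their line number; empty member fields
#' are dropped; duplicate members within a set are collapsed.
#'
#' @param path Path to a `.gmt` file.
#' @param namespace Optional tag carried on the collection (e.g. `"GO:BP"`,
#'   `"KEGG"`).
#' @return A named list of character vectors with attributes `description`
#'   (named character) and `namespace`.
#' @export
read_gmt <- function(path, namespace = NA_character_) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0) {
    abort(sprintf("malformed GMT line %d in %s: fewer than 3 fields", lineno[bad[1]], path))
  }
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    abort(sprintf("duplicate gene-set name in %s: %s", path,
                  names_[duplicated(names_)][1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  empty <- which(lengths(sets) == 0L)
  if (length(empty) > 0) {
    abort(sprintf("malformed GMT line %d in %s: set has no members", lineno[empty[1]], path))
  }
  names(sets) <- names_
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L), names_)
  attr(sets, "namespace") <- namespace
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors (optionally carrying a
#'   `description` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("`sets` must be a uniquely named list.")
  }
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
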