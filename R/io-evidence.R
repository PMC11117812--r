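VALIDATED_DBS <- c("mirtarbase", "tarbase")
PREDICTED_DBS <- c("diana_microt", "elmmo", "pita")

#' Read a miRNA-target evidence table
#'
#' Evidence tables carry one row per (database, miRNA, target) assertion with
#' the columns `database, mirna_acc, mirna_id, target_symbol, target_entrez,
#' target_ensembl, type, pubmed, score`. Validated rows come from curated
#' experimental databases (miRTarBase, TarBase) and carry a PubMed ID;
#' predicted rows come from prediction tools (DIANA-microT, ElMMo, PITA) and
#' carry a score in \[0, 1\].
#'
#' @param path Path to a TSV file with the schema above.
#' @return A validated evidence tibble.
#' @export
#' @examples
#' ev <- read_evidence(mirlink_example("table3_evidence.tsv"))
#' dplyr::count(ev, type)
read_evidence <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ev <- readr::read_tsv(path, col_types = readr::cols(
    database = readr::col_character(),
    mirna_acc = readr::col_character(),
    mirna_id = readr::col_character(),
    target_symbol = readr::col_character(),
    target_entrez = readr::col_character(),
    target_ensembl = readr::col_character(),
    type = readr::col_character(),
    pubmed = readr::col_character(),
    score = readr::col_double()
  ), progress = FALSE)
  validate_evidence(ev)
}

#' @rdname read_evidence
#' @param evidence An evidence tibble.
#' @export
write_evidence <- function(evidence, path) {
  validate_evidence(evidence)
  readr::write_tsv(evidence, path, progress = FALSE, na = "")
  invisible(path)
}

#' Validate an evidence table against its schema
#'
#' Checks the database vocabulary, the type/database consistency (validated
#' rows must come from a curated database and vice versa) and the score range.
#'
#' @param evidence A data frame in the evidence schema.
#' @return The evidence tibble, invisibly usable downstream.
#' @export
validate_evidence <- function(evidence) {
  need <- c("database", "mirna_acc", "mirna_id", "target_symbol", "type")
  miss <- setdiff(need, names(evidence))
  if (length(miss) > 0) {
    abort(sprintf("evidence table lacks columns: %s", paste(miss, collapse = ", ")))
  }
  bad_db <- setdiff(unique(evidence$database), c(VALIDATED_DBS, PREDICTED_DBS))
  if (length(bad_db) > 0) {
    abort(sprintf("unknown evidence database(s): %s (row %d)",
                  paste(bad_db, collapse = ", "),
                  which(evidence$database %in% bad_db)[1]))
  }
  bad_type <- setdiff(unique(evidence$type), c("validated", "predicted"))
  if (length(bad_type) > 0) {
    abort(sprintf("unknown evidence type(s): %s", paste(bad_type, collapse = ", ")))
  }
  inconsistent <- (evidence$type == "validated") != (evidence$database %in% VALIDATED_DBS)
  if (any(inconsistent)) {
    abort(sprintf("evidence row %d: type '%s' inconsistent with database '%s'",
                  which(inconsistent)[1], evidence$type[which(inconsistent)[1]],
                  evidence$database[which(inconsistent)[1]]))
  }
  if ("score" %in% names(evidence)) {
    sc <- evidence$score[evidence$type == "predicted"]
    if (any(!is.na(sc) & (sc < 0 | sc > 1))) abort("predicted scores must lie in [0, 1].")
    if (any(!is.na(evidence$score[evidence$type == "validated"]))) {
      abort("validated rows must not carry a prediction score.")
    }
  }
  tibble::as_tibble(evidence)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
mirlink_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "mirlink"))
  } else {
    path <- system.file("extdata", file, package = "mirlink")
    if (!nzchar(path)) abort(sprintf("no packaged file '%s'", file))
    path
  }
}
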