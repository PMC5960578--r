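#' Write ranked predictions as TSV
#'
#' Writes the six-column prediction table (`disease_id`, `lncRNA_id`,
#' `miRNA_id`, `score`, `rank`, `known`) with scores printed to six
#' decimal digits. Records must already be sorted by non-increasing
#' score (use [rank_predictions()]); unsorted input is an error rather
#' than silently re-ranked.
#'
#' @param records prediction tibble as returned by [rank_predictions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(records, path) {
  req <- c("disease_id", "lncRNA_id", "miRNA_id", "score", "rank", "known")
  if (!all(req %in% names(records))) {
    abort(sprintf("prediction records must have columns: %s",
                  paste(req, collapse = ", ")))
  }
  if (nrow(records) > 1L && any(diff(records$score) > 0)) {
    abort("prediction records must be sorted by descending score; rank them first")
  }
  out <- tibble(
    disease_id = as.character(records$disease_id),
    lncRNA_id = as.character(records$lncRNA_id),
    miRNA_id = as.character(records$miRNA_id),
    score = sprintf("%.6f", records$score),
    rank = as.integer(records$rank),
    known = tolower(as.character(records$known))
  )
  readr::write_tsv(out, path, col_names = TRUE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path path to the prediction TSV.
#' @return tibble with the six prediction columns.
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) abort(sprintf("prediction file not found: %s", path))
  readr::read_tsv(
    path,
    col_types = readr::cols(
      disease_id = readr::col_character(),
      lncRNA_id = readr::col_character(),
      miRNA_id = readr::col_character(),
      score = readr::col_double(),
      rank = readr::col_integer(),
      known = readr::col_logical()
    )
  )
}
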