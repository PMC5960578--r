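#' Association table kinds
#'
#' The three edge-list catalogues the predictor consumes. Each kind fixes
#' the semantic names of the two columns.
#'
#' @keywords internal
assoc_kinds <- c("lncRNA-disease", "miRNA-disease", "lncRNA-miRNA")

#' Column roles for an association kind
#' @param kind one of `"lncRNA-disease"`, `"miRNA-disease"`, `"lncRNA-miRNA"`.
#' @return character vector of length 2: left and right column names.
#' @keywords internal
assoc_roles <- function(kind) {
  switch(kind,
    "lncRNA-disease" = c("lncRNA", "disease"),
    "miRNA-disease"  = c("miRNA", "disease"),
    "lncRNA-miRNA"   = c("lncRNA", "miRNA"),
    abort(sprintf("unknown association kind '%s'", kind))
  )
}

#' Build an association table from an edge data frame
#'
#' Constructor for the in-memory representation of one association
#' catalogue: a tibble of unique (left, right) edges carrying the kind and
#' the deterministic entity orderings as attributes. All matrices built
#' downstream are indexed by these orderings, so two constructions from the
#' same edges always give identical layouts.
#'
#' @param edges data frame with two character columns (any names); each row
#'   is one association. Ids are whitespace-trimmed, case preserved.
#' @param kind association kind, see [assoc_roles()].
#' @param id_order `"first"` (default, order of first appearance) or
#'   `"lexicographic"`.
#' @return a tibble of class `assoc_tbl` with columns named after the two
#'   roles, and attributes `kind`, `left_ids`, `right_ids`, `n_duplicates`.
#' @export
#' @examples
#' association_table(data.frame(l = c("l1", "l2"), d = c("d1", "d1")),
#'                   kind = "lncRNA-disease")
association_table <- function(edges, kind, id_order = c("first", "lexicographic")) {
  kind <- match.arg(kind, assoc_kinds)
  id_order <- match.arg(id_order)
  roles <- assoc_roles(kind)
  if (ncol(edges) != 2L) {
    abort(sprintf("association edges must have exactly 2 columns, got %d",
                  ncol(edges)))
  }
  left <- trimws(as.character(edges[[1L]]))
  right <- trimws(as.character(edges[[2L]]))
  if (any(!nzchar(left)) || any(!nzchar(right))) {
    abort("association ids must be non-empty strings")
  }
  tab <- tibble(left = left, right = right)
  n_before <- nrow(tab)
  tab <- dplyr::distinct(tab)
  if (nrow(tab) == 0L) abort("association table has no edges")
  names(tab) <- roles
  out <- structure(
    tab,
    class = c("assoc_tbl", class(tab)),
    kind = kind,
    left_ids = order_ids(tab[[1L]], id_order),
    right_ids = order_ids(tab[[2L]], id_order),
    n_duplicates = n_before - nrow(tab)
  )
  out
}

#' Read an association edge list from a TSV file
#'
#' Expects two tab-separated columns per line. Lines starting with `#` and
#' blank lines are skipped. A header is auto-detected when the first
#' retained line's tokens equal the column roles of `kind` (for example
#' `lncRNA<TAB>disease`). Duplicate edges are collapsed and their count
#' reported via a message and the `n_duplicates` attribute.
#'
#' @inheritParams association_table
#' @param path path to the TSV file.
#' @return an `assoc_tbl`, see [association_table()].
#' @export
read_association_table <- function(path, kind, id_order = c("first", "lexicographic")) {
  kind <- match.arg(kind, assoc_kinds)
  if (!file.exists(path)) abort(sprintf("association file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) abort(sprintf("association file is empty: %s", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("parse error in %s at line %d: expected 2 tab-separated columns, found %d",
                  path, idx[bad[1L]], lengths(fields)[bad[1L]]))
  }
  roles <- assoc_roles(kind)
  if (identical(trimws(fields[[1L]]), roles)) fields <- fields[-1L]
  if (length(fields) == 0L) abort(sprintf("association file has a header but no edges: %s", path))
  edges <- tibble(
    left = vapply(fields, `[[`, character(1), 1L),
    right = vapply(fields, `[[`, character(1), 2L)
  )
  out <- association_table(edges, kind, id_order)
  if (attr(out, "n_duplicates") > 0L) {
    inform(sprintf("dropped %d duplicate association(s) from %s",
                   attr(out, "n_duplicates"), path))
  }
  out
}

#' Write an association table as TSV
#'
#' Writes a header line with the two role names followed by one edge per
#' line; the result round-trips exactly through [read_association_table()].
#'
#' @param table an `assoc_tbl`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(table, path) {
  stopifnot(inherits(table, "assoc_tbl"))
  readr::write_tsv(as_tibble(table), path, col_names = TRUE)
  invisible(path)
}
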