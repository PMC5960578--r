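#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# stable unique ids in order of first appearance
first_appearance <- function(x) unique(x)

order_ids <- function(x, id_order = c("first", "lexicographic")) {
  id_order <- match.arg(id_order)
  if (id_order == "first") first_appearance(x) else sort(unique(x))
}

assert_same_ids <- function(a, b, what = "matrix") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("shape mismatch between %s inputs: %s vs %s",
                  what, paste(dim(a), collapse = "x"),
                  paste(dim(b), collapse = "x")))
  }
  ra <- rownames(a)
  rb <- rownames(b)
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb)) {
    abort(sprintf("%s inputs are indexed by different ids", what))
  }
  invisible(TRUE)
}

assert_finite <- function(x, what = "matrix") {
  if (!all(is.finite(x))) abort(sprintf("non-finite entries in %s", what))
  invisible(TRUE)
}

is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

symmetrize <- function(m) (m + t(m)) / 2
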