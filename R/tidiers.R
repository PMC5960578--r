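#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' One row per repeat with its AUC.
#'
#' @param x an `lmpair_cv`.
#' @param ... unused.
#' @return tibble with columns `repeat_id`, `auc`.
#' @export
tidy.lmpair_cv <- function(x, ...) {
  tibble(repeat_id = seq_along(x$per_repeat_auc), auc = x$per_repeat_auc)
}

#' Summarize a cross-validation result
#'
#' @param x an `lmpair_cv`.
#' @param ... unused.
#' @return one-row tibble: `scheme`, `mean_auc`, `std_auc`, `repeats`,
#'   `k` (NA for leave-one-out), `gamma`, `K`.
#' @export
glance.lmpair_cv <- function(x, ...) {
  tibble(
    scheme = x$scheme,
    mean_auc = x$mean_auc,
    std_auc = x$std_auc,
    repeats = length(x$per_repeat_auc),
    k = x$settings$k %||% NA_integer_,
    gamma = x$settings$gamma,
    K = x$settings$K
  )
}

#' Tidy a semantic profile
#'
#' @param x a [semantic_profile()].
#' @param ... unused.
#' @return tibble with `term` and `contribution`, descending.
#' @export
tidy.semantic_profile <- function(x, ...) {
  dplyr::arrange(
    tibble(term = names(x$contributions), contribution = unname(x$contributions)),
    dplyr::desc(.data$contribution)
  )
}

#' Summarize a fitted association model
#'
#' @param x an [lmpair_model()].
#' @param ... unused.
#' @return one-row tibble with entity, pair, and known-edge counts plus
#'   the main parameters.
#' @export
glance.lmpair_model <- function(x, ...) {
  tibble(
    n_lncRNAs = length(x$network$lncRNAs),
    n_miRNAs = length(x$network$miRNAs),
    n_diseases = length(x$network$diseases),
    n_pairs = nrow(x$network$pairs),
    n_known = nrow(x$network$known_edges),
    n_triangles = nrow(x$tripartite$triangles),
    delta = x$params$delta,
    pair_method = x$params$pair_method
  )
}
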