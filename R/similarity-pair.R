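#' Similarity between lncRNA-miRNA pairs
#'
#' Combines the lncRNA and miRNA similarity matrices into a similarity
#' over composite pair vertices `p = (l, m)`. Three schemes are
#' supported for pairs `p = (l_i, m_j)` and `q = (l_a, m_b)`:
#'
#' * `average`: `(lncSim(i,a) + miRSim(j,b)) / 2`
#' * `sqrt`: `sqrt(lncSim(i,a) * miRSim(j,b))`
#' * `centre`: `sqrt((lncSim(i,a) - avg_lnc)^2 + (miRSim(j,b) - avg_mir)^2)`
#'   where `avg_lnc` / `avg_mir` are the grand means of the two matrices
#'   (all entries, diagonal included). Note this is a centre *distance*
#'   used as-is as a similarity.
#'
#' For the full cross product in row-major order the `average` and
#' `sqrt` matrices have Kronecker structure, which is exploited by
#' [pair_sim_matmul()] so that the dense `N_p x N_p` matrix need not be
#' materialized for large problems.
#'
#' @param lncSim,miRSim symmetric similarity matrices with gene dimnames.
#' @param pairs optional pair tibble (`pair_id`, `lncRNA`, `miRNA`), e.g.
#'   from a `dlm_network`; defaults to the full row-major cross product.
#' @param method `"average"` (default), `"sqrt"` or `"centre"`.
#' @param materialize force (`TRUE`) or forbid (`FALSE`) building the
#'   dense matrix; default (`NULL`) materializes while
#'   `N_p^2 <= max_dense`.
#' @param max_dense densification guard (default 4e6 entries).
#' @return object of class `pair_similarity`: list with `method`,
#'   `values` (dense matrix or `NULL` when structured), `lncSim`,
#'   `miRSim`, `pairs`, `avg_lnc`, `avg_mir`, `structured`.
#' @export
lmpair_similarity <- function(lncSim, miRSim, pairs = NULL,
                              method = c("average", "sqrt", "centre"),
                              materialize = NULL, max_dense = 4e6) {
  method <- match.arg(method)
  lnc_ids <- rownames(lncSim)
  mir_ids <- rownames(miRSim)
  if (is.null(lnc_ids) || is.null(mir_ids)) {
    abort("lncSim and miRSim must carry gene ids as dimnames")
  }
  full_cross <- is.null(pairs)
  if (full_cross) {
    pairs <- tibble(
      lncRNA = rep(lnc_ids, each = length(mir_ids)),
      miRNA = rep(mir_ids, times = length(lnc_ids))
    )
    pairs$pair_id <- paste(pairs$lncRNA, pairs$miRNA, sep = "|")
    pairs <- pairs[, c("pair_id", "lncRNA", "miRNA")]
  } else {
    full_cross <- nrow(pairs) == length(lnc_ids) * length(mir_ids)
  }
  n_p <- nrow(pairs)
  dense <- materialize %||% (as.double(n_p)^2 <= max_dense)
  if (!dense && (method == "centre" || !full_cross)) {
    abort(paste0("structured (non-materialized) pair similarity is only available ",
                 "for the average/sqrt methods on the full cross product"))
  }
  avg_lnc <- mean(lncSim)
  avg_mir <- mean(miRSim)
  values <- NULL
  if (dense) {
    li <- match(pairs$lncRNA, lnc_ids)
    mi <- match(pairs$miRNA, mir_ids)
    a <- lncSim[li, li, drop = FALSE]
    b <- miRSim[mi, mi, drop = FALSE]
    values <- switch(method,
      average = (a + b) / 2,
      sqrt = sqrt(a * b),
      centre = sqrt((a - avg_lnc)^2 + (b - avg_mir)^2)
    )
    dimnames(values) <- list(pairs$pair_id, pairs$pair_id)
  }
  structure(
    list(method = method, values = values, lncSim = lncSim, miRSim = miRSim,
         pairs = pairs, avg_lnc = avg_lnc, avg_mir = avg_mir,
         structured = !dense, full_cross = full_cross),
    class = "pair_similarity"
  )
}

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("<pair_similarity> method '%s', %d pair(s)%s\n",
              x$method, nrow(x$pairs),
              if (x$structured) " (structured, not materialized)" else ""))
  invisible(x)
}

#' Dense pair similarity matrix
#'
#' Materializes the `N_p x N_p` matrix of a [lmpair_similarity()] object
#' (or passes a plain matrix through).
#'
#' @param ps a `pair_similarity` or a matrix.
#' @return numeric matrix.
#' @export
pair_sim_values <- function(ps) {
  if (is.matrix(ps)) return(ps)
  stopifnot(inherits(ps, "pair_similarity"))
  if (!is.null(ps$values)) return(ps$values)
  lmpair_similarity(ps$lncSim, ps$miRSim, method = ps$method,
                    materialize = TRUE)$values
}

#' Multiply the pair similarity matrix by a matrix
#'
#' Computes `PairSim %*% x` either densely or, for the structured
#' average/sqrt forms on the full row-major cross product, via the
#' Kronecker identities (so the cost is governed by the gene matrices,
#' not by `N_p^2`).
#'
#' @param ps a `pair_similarity`.
#' @param x numeric matrix with `N_p` rows (a vector is treated as one
#'   column).
#' @return matrix of the same shape as `x`.
#' @export
pair_sim_matmul <- function(ps, x) {
  if (is.matrix(ps)) return(ps %*% x)
  stopifnot(inherits(ps, "pair_similarity"))
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (!is.null(ps$values)) return(ps$values %*% x)
  n_l <- nrow(ps$lncSim)
  n_m <- nrow(ps$miRSim)
  out <- matrix(0, nrow = n_l * n_m, ncol = ncol(x))
  if (ps$method == "average") {
    for (q in seq_len(ncol(x))) {
      xm <- matrix(x[, q], nrow = n_m) # column i = block of lncRNA i
      lc <- ps$lncSim %*% colSums(xm)
      mr <- ps$miRSim %*% rowSums(xm)
      out[, q] <- 0.5 * (rep(lc, each = n_m) + rep(mr, times = n_l))
    }
  } else if (ps$method == "sqrt") {
    sl <- sqrt(ps$lncSim)
    sm <- sqrt(ps$miRSim)
    for (q in seq_len(ncol(x))) {
      xm <- matrix(x[, q], nrow = n_m)
      out[, q] <- as.vector(sm %*% xm %*% t(sl))
    }
  } else {
    abort("structured multiplication is not available for the centre method")
  }
  rownames(out) <- ps$pairs$pair_id
  colnames(out) <- colnames(x)
  out
}
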