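#' Semantic contribution profile of a disease
#'
#' Walks the disease hierarchy upward from `disease` and assigns each
#' ancestor term `t` a contribution that decays with distance: the disease
#' contributes 1 to itself, and every proper ancestor contributes
#' `delta` times the largest contribution among its children inside the
#' ancestor closure (the standard max-over-paths recursion for
#' hierarchy-based semantic similarity). The semantic value of the
#' disease is the sum of all contributions.
#'
#' @param dag a [disease_dag()].
#' @param disease disease id present in `dag`.
#' @param delta decay factor in (0, 1); default 0.5, the value commonly
#'   used with MeSH-style hierarchies.
#' @return object of class `semantic_profile`: list with `disease_id`,
#'   `contributions` (named numeric over the ancestor closure) and
#'   `semantic_value`.
#' @export
#' @examples
#' dag <- disease_dag(data.frame(child = c("a", "b"), parent = c("root", "a")))
#' semantic_profile(dag, "b")$semantic_value  # 1 + 0.5 + 0.25
semantic_profile <- function(dag, disease, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!(delta > 0 && delta < 1)) abort("delta must lie strictly between 0 and 1")
  if (!disease %in% dag$nodes) {
    abort(sprintf("unknown disease id '%s' (not in the hierarchy)", disease))
  }
  # ancestor closure T(D) by breadth-first walk over child -> parent edges
  closure <- disease
  frontier <- disease
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, closure)
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  # children of each closure node inside the closure
  children <- lapply(stats::setNames(closure, closure), function(t) {
    closure[vapply(closure, function(c) t %in% dag$parents[[c]], logical(1))]
  })
  contrib <- stats::setNames(rep(NA_real_, length(closure)), closure)
  contrib[[disease]] <- 1
  # process in topological order: a node is ready once all its in-closure
  # children have contributions (every closure node is reachable from the
  # disease, so this terminates)
  pending <- setdiff(closure, disease)
  while (length(pending) > 0L) {
    ready <- pending[vapply(pending, function(t) {
      all(!is.na(contrib[children[[t]]]))
    }, logical(1))]
    if (length(ready) == 0L) abort("internal error: hierarchy closure is not acyclic")
    for (t in ready) contrib[[t]] <- delta * max(contrib[children[[t]]])
    pending <- setdiff(pending, ready)
  }
  structure(
    list(disease_id = disease, contributions = contrib,
         semantic_value = sum(contrib)),
    class = "semantic_profile"
  )
}

#' @export
print.semantic_profile <- function(x, ...) {
  cat(sprintf("<semantic_profile> %s: %d ancestor term(s), semantic value %.4f\n",
              x$disease_id, length(x$contributions), x$semantic_value))
  invisible(x)
}

#' Semantic similarity between two diseases
#'
#' Diseases sharing more (and closer) ancestors in the hierarchy are more
#' similar: the score is the summed contributions of the common ancestor
#' terms from both profiles, normalized by the two semantic values, and
#' lies in \[0, 1\] with 1 for identical diseases and 0 for disjoint
#' ancestor sets.
#'
#' @inheritParams semantic_profile
#' @param di,dj disease ids present in `dag`.
#' @return numeric scalar in \[0, 1\].
#' @export
semantic_similarity <- function(dag, di, dj, delta = 0.5) {
  pi_ <- semantic_profile(dag, di, delta)
  pj_ <- semantic_profile(dag, dj, delta)
  semantic_similarity_from_profiles(pi_, pj_)
}

semantic_similarity_from_profiles <- function(pi_, pj_) {
  common <- intersect(names(pi_$contributions), names(pj_$contributions))
  if (length(common) == 0L) return(0)
  sum(pi_$contributions[common] + pj_$contributions[common]) /
    (pi_$semantic_value + pj_$semantic_value)
}

#' Semantic similarity matrix over a set of diseases
#'
#' Diseases missing from the hierarchy get similarity 0 against every
#' other disease (with a warning) and 1 to themselves, so they fall back
#' to the interaction-profile branch of [integrated_disease_similarity()].
#'
#' @inheritParams semantic_profile
#' @param diseases ordered character vector of disease ids.
#' @return symmetric numeric matrix with unit diagonal, dimnames
#'   `diseases`.
#' @export
semantic_similarity_matrix <- function(dag, diseases, delta = 0.5) {
  n <- length(diseases)
  missing <- setdiff(diseases, dag$nodes)
  if (length(missing) > 0L) {
    warn(sprintf("%d disease(s) absent from the hierarchy get semantic similarity 0: %s",
                 length(missing), paste(utils::head(missing, 5L), collapse = ", ")))
  }
  profiles <- lapply(stats::setNames(diseases, diseases), function(d) {
    if (d %in% dag$nodes) semantic_profile(dag, d, delta) else NULL
  })
  out <- matrix(0, n, n, dimnames = list(diseases, diseases))
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (i == j) {
        out[i, j] <- 1
      } else if (!is.null(profiles[[i]]) && !is.null(profiles[[j]])) {
        out[i, j] <- out[j, i] <-
          semantic_similarity_from_profiles(profiles[[i]], profiles[[j]])
      }
    }
  }
  out
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' Interprets each entity (column by default) of a binary association
#' matrix as an interaction profile and applies a Gaussian kernel to the
#' squared Euclidean distance between profiles. The bandwidth is the
#' reciprocal of the mean squared profile norm over the `n_k` entities,
#' so the kernel adapts to the density of the network.
#'
#' @param m binary matrix (association profiles).
#' @param margin `"columns"` (default) or `"rows"`: which margin holds
#'   the entities to compare.
#' @return symmetric similarity matrix with unit diagonal; entries in
#'   (0, 1\].
#' @export
gip_kernel <- function(m, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  if (margin == "rows") m <- t(m)
  if (ncol(m) < 1L) abort("interaction profile matrix must have at least one entity")
  m <- as.matrix(m) * 1.0
  sq <- colSums(m^2)
  if (all(sq == 0)) abort("empty interaction profiles: all-zero association matrix")
  gamma_k <- 1 / mean(sq)
  g <- crossprod(m)
  d2 <- outer(sq, sq, `+`) - 2 * g
  d2[d2 < 0] <- 0
  k <- exp(-gamma_k * d2)
  k <- symmetrize(k)
  diag(k) <- 1
  dimnames(k) <- list(colnames(m), colnames(m))
  k
}

#' Disease GIP similarity combining the two disease-linked networks
#'
#' Computes the GIP kernel over disease interaction profiles in the
#' lncRNA-disease network and in the miRNA-disease network, then combines
#' them by the entrywise geometric mean (square-root approach).
#'
#' @param g1 lncRNA-disease `bipartite_network`.
#' @param g2 miRNA-disease `bipartite_network`.
#' @param diseases ordered disease ids; must be present in both networks.
#' @param lncRNAs,miRNAs optional row restrictions (e.g. the vertices
#'   surviving triangle pruning); `NULL` keeps all rows.
#' @return symmetric similarity matrix over `diseases` with unit diagonal.
#' @export
disease_gip_similarity <- function(g1, g2, diseases, lncRNAs = NULL, miRNAs = NULL) {
  stopifnot(inherits(g1, "bipartite_network"), inherits(g2, "bipartite_network"))
  miss1 <- setdiff(diseases, g1$right_ids)
  miss2 <- setdiff(diseases, g2$right_ids)
  if (length(miss1) > 0L || length(miss2) > 0L) {
    abort(sprintf("disease(s) absent from a network: %s",
                  paste(utils::head(c(miss1, miss2), 5L), collapse = ", ")))
  }
  rows1 <- lncRNAs %||% g1$left_ids
  rows2 <- miRNAs %||% g2$left_ids
  k1 <- gip_kernel(g1$adjacency[rows1, diseases, drop = FALSE], "columns")
  k2 <- gip_kernel(g2$adjacency[rows2, diseases, drop = FALSE], "columns")
  sqrt(k1 * k2)
}

#' Integrated disease similarity
#'
#' Uses the GIP similarity alone where the semantic similarity is exactly
#' zero (no common ancestors), and the arithmetic mean of the two
#' otherwise.
#'
#' @param sem semantic similarity matrix.
#' @param gip GIP similarity matrix with matching id ordering.
#' @return symmetric similarity matrix.
#' @export
integrated_disease_similarity <- function(sem, gip) {
  assert_same_ids(sem, gip, "disease similarity")
  out <- ifelse(sem == 0, gip, (gip + sem) / 2)
  dimnames(out) <- dimnames(gip)
  out
}
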