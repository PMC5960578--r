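#' Disease sets associated with each gene
#'
#' For every left-side entity (lncRNA or miRNA) of a bipartite network,
#' collects the set of diseases it is associated with. These sets drive
#' the best-match-average functional similarity.
#'
#' @param network a `bipartite_network` with diseases as right entities.
#' @param rows optional restriction of the genes (row ids) to keep.
#' @param diseases optional restriction of the disease columns.
#' @return named list mapping gene id to a character vector of diseases.
#' @export
gene_disease_sets <- function(network, rows = NULL, diseases = NULL) {
  stopifnot(inherits(network, "bipartite_network"))
  rows <- rows %||% network$left_ids
  diseases <- diseases %||% network$right_ids
  adj <- network$adjacency[rows, diseases, drop = FALSE]
  lapply(stats::setNames(seq_along(rows), rows),
         function(i) diseases[adj[i, ] == 1L])
}

#' Best-match-average functional similarity between genes
#'
#' Two genes are functionally similar when the diseases associated with
#' one are semantically close to the diseases associated with the other:
#' each disease of either gene is matched to its most similar disease on
#' the other side, and the matched similarities are averaged over all
#' `m + n` diseases. Self-similarity is 1. A gene with an empty disease
#' set gets similarity 0 against every other gene (warned once), keeping
#' 1 on the diagonal.
#'
#' @param sets named list from [gene_disease_sets()].
#' @param dis_sem disease semantic similarity matrix covering every
#'   disease appearing in `sets`.
#' @return symmetric similarity matrix over the genes, unit diagonal.
#' @export
functional_similarity <- function(sets, dis_sem) {
  genes <- names(sets)
  all_dis <- unique(unlist(sets, use.names = FALSE))
  missing <- setdiff(all_dis, rownames(dis_sem))
  if (length(missing) > 0L) {
    abort(sprintf("disease(s) in gene sets missing from the semantic matrix: %s",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warn(sprintf("%d gene(s) have no associated disease; functional similarity set to 0",
                 sum(empty)))
  }
  n <- length(genes)
  out <- matrix(0, n, n, dimnames = list(genes, genes))
  diag(out) <- 1
  for (i in seq_len(n)) {
    if (empty[i]) next
    a <- sets[[i]]
    for (j in seq_len(n)) {
      if (j <= i || empty[j]) next
      b <- sets[[j]]
      sub <- dis_sem[a, b, drop = FALSE]
      val <- (sum(apply(sub, 1L, max)) + sum(apply(sub, 2L, max))) /
        (length(a) + length(b))
      out[i, j] <- out[j, i] <- val
    }
  }
  out
}

#' GIP similarity between genes
#'
#' Same Gaussian interaction-profile kernel as for diseases, but the
#' profiles are the rows of the gene-by-disease adjacency matrix and the
#' bandwidth is normalized over the number of genes.
#'
#' @param y binary gene-by-disease matrix (genes as rows).
#' @return symmetric similarity matrix over the genes, unit diagonal.
#' @export
gene_gip_similarity <- function(y) {
  gip_kernel(y, margin = "rows")
}

#' Integrated gene similarity
#'
#' Unconditional entrywise average of functional and GIP similarity
#' (unlike the disease integration there is no zero branch).
#'
#' @param fun functional similarity matrix.
#' @param gip GIP similarity matrix with matching id ordering.
#' @return symmetric similarity matrix.
#' @export
integrated_gene_similarity <- function(fun, gip) {
  assert_same_ids(fun, gip, "gene similarity")
  out <- (fun + gip) / 2
  dimnames(out) <- dimnames(gip)
  out
}
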