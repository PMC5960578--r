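#' Build a bipartite association network
#'
#' Converts an association table into a labeled two-mode graph with a
#' binary adjacency matrix (left entities as rows, right entities as
#' columns, indexed by the table's deterministic id orderings).
#'
#' @param table an `assoc_tbl` from [association_table()] or
#'   [read_association_table()].
#' @return object of class `bipartite_network`: list with `left_ids`,
#'   `right_ids`, `adjacency` (binary matrix with dimnames), `kind`,
#'   `roles`.
#' @export
build_bipartite <- function(table) {
  stopifnot(inherits(table, "assoc_tbl"))
  left_ids <- attr(table, "left_ids")
  right_ids <- attr(table, "right_ids")
  adj <- matrix(0L, nrow = length(left_ids), ncol = length(right_ids),
                dimnames = list(left_ids, right_ids))
  adj[cbind(match(table[[1L]], left_ids), match(table[[2L]], right_ids))] <- 1L
  structure(
    list(left_ids = left_ids, right_ids = right_ids, adjacency = adj,
         kind = attr(table, "kind"), roles = assoc_roles(attr(table, "kind"))),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network> %s: %d x %d, %d edge(s)\n",
              x$kind, length(x$left_ids), length(x$right_ids),
              sum(x$adjacency)))
  invisible(x)
}

#' Build the triangle-filtered tripartite network
#'
#' Intersects the three bipartite networks and keeps only the edges that
#' participate in at least one (disease, lncRNA, miRNA) triangle, i.e.
#' triples where the disease-lncRNA, disease-miRNA and lncRNA-miRNA edges
#' all exist simultaneously. Diseases are restricted to those shared by
#' the two disease-linked networks; lncRNAs/miRNAs are pruned to the
#' vertices incident to at least one retained disease edge.
#'
#' @param g1 lncRNA-disease `bipartite_network`.
#' @param g2 miRNA-disease `bipartite_network`.
#' @param g3 lncRNA-miRNA `bipartite_network`.
#' @return object of class `tripartite_network`: list with ordered vertex
#'   lists `lncRNAs`, `miRNAs`, `diseases`, edge tibbles `edges_ld`,
#'   `edges_md`, `edges_lm`, and the full `triangles` tibble
#'   (disease, lncRNA, miRNA).
#' @export
build_tripartite <- function(g1, g2, g3) {
  stopifnot(inherits(g1, "bipartite_network"), g1$kind == "lncRNA-disease",
            inherits(g2, "bipartite_network"), g2$kind == "miRNA-disease",
            inherits(g3, "bipartite_network"), g3$kind == "lncRNA-miRNA")
  v_l_cand <- intersect(g1$left_ids, g3$left_ids)
  v_m_cand <- intersect(g2$left_ids, g3$right_ids)
  v_d <- intersect(g1$right_ids, g2$right_ids)
  if (length(v_d) == 0L) abort("no shared diseases between the two disease networks")

  triangles <- purrr::map_dfr(v_d, function(d) {
    ld <- v_l_cand[g1$adjacency[v_l_cand, d] == 1L]
    md <- v_m_cand[g2$adjacency[v_m_cand, d] == 1L]
    if (length(ld) == 0L || length(md) == 0L) return(NULL)
    hits <- which(g3$adjacency[ld, md, drop = FALSE] == 1L, arr.ind = TRUE)
    if (nrow(hits) == 0L) return(NULL)
    tibble(disease = d, lncRNA = ld[hits[, 1L]], miRNA = md[hits[, 2L]])
  })
  if (nrow(triangles) == 0L) abort("no triangles: no (disease, lncRNA, miRNA) triple is fully connected")

  # keep first-appearance order of the source networks for determinism
  v_l <- v_l_cand[v_l_cand %in% triangles$lncRNA]
  v_m <- v_m_cand[v_m_cand %in% triangles$miRNA]
  v_d3 <- v_d[v_d %in% triangles$disease]
  structure(
    list(lncRNAs = v_l, miRNAs = v_m, diseases = v_d3,
         edges_ld = dplyr::distinct(triangles[, c("lncRNA", "disease")]),
         edges_md = dplyr::distinct(triangles[, c("miRNA", "disease")]),
         edges_lm = dplyr::distinct(triangles[, c("lncRNA", "miRNA")]),
         triangles = triangles),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  cat(sprintf("<tripartite_network> %d lncRNA(s), %d miRNA(s), %d disease(s), %d triangle(s)\n",
              length(x$lncRNAs), length(x$miRNAs), length(x$diseases),
              nrow(x$triangles)))
  invisible(x)
}

#' Build the disease vs lncRNA-miRNA pair bipartite network
#'
#' Pair vertices are the cross product of the retained lncRNAs and miRNAs
#' in row-major order (lncRNA outer, miRNA inner), so pair `(l_i, m_j)`
#' has index `(i-1) * n_miRNA + j`. A pair is linked to a disease exactly
#' when the corresponding triangle exists; the binary adjacency `DP` has
#' pairs as rows and diseases as columns.
#'
#' @param tri a `tripartite_network`.
#' @param pairs `"full"` (default, the complete cross product) or
#'   `"interacting"` (only pairs with an lncRNA-miRNA edge, useful when
#'   the cross product would be too large).
#' @param max_pairs size guard for the full cross product (default 2e6).
#' @return object of class `dlm_network`: list with `diseases`, `pairs`
#'   (tibble `pair_id`, `lncRNA`, `miRNA`), `DP` (binary `N_p x N_d`
#'   matrix), `known_edges` (tibble with pair/disease indices and ids),
#'   `lncRNAs`, `miRNAs`, `pairs_mode`.
#' @export
build_disease_lmpair_network <- function(tri, pairs = c("full", "interacting"),
                                         max_pairs = 2e6) {
  stopifnot(inherits(tri, "tripartite_network"))
  pairs <- match.arg(pairs)
  n_l <- length(tri$lncRNAs)
  n_m <- length(tri$miRNAs)
  if (pairs == "full" && n_l * n_m > max_pairs) {
    abort(sprintf(paste0("full pair cross product has %g vertices (> max_pairs = %g); ",
                         "use pairs = \"interacting\" to restrict to interacting pairs"),
                  n_l * n_m, max_pairs))
  }
  pair_tbl <- tibble(
    lncRNA = rep(tri$lncRNAs, each = n_m),
    miRNA = rep(tri$miRNAs, times = n_l)
  )
  if (pairs == "interacting") {
    pair_tbl <- dplyr::semi_join(pair_tbl, tri$edges_lm, by = c("lncRNA", "miRNA"))
  }
  pair_tbl$pair_id <- paste(pair_tbl$lncRNA, pair_tbl$miRNA, sep = "|")
  pair_tbl <- pair_tbl[, c("pair_id", "lncRNA", "miRNA")]

  diseases <- tri$diseases
  pair_index <- match(paste(tri$triangles$lncRNA, tri$triangles$miRNA, sep = "|"),
                      pair_tbl$pair_id)
  disease_index <- match(tri$triangles$disease, diseases)
  known <- dplyr::distinct(tibble(
    pair_index = pair_index, disease_index = disease_index,
    lncRNA = tri$triangles$lncRNA, miRNA = tri$triangles$miRNA,
    disease = tri$triangles$disease
  ))
  DP <- matrix(0L, nrow = nrow(pair_tbl), ncol = length(diseases),
               dimnames = list(pair_tbl$pair_id, diseases))
  DP[cbind(known$pair_index, known$disease_index)] <- 1L
  structure(
    list(diseases = diseases, pairs = pair_tbl, DP = DP, known_edges = known,
         lncRNAs = tri$lncRNAs, miRNAs = tri$miRNAs, pairs_mode = pairs),
    class = "dlm_network"
  )
}

#' @export
print.dlm_network <- function(x, ...) {
  cat(sprintf("<dlm_network> %d pair(s) x %d disease(s), %d known association(s) [pairs: %s]\n",
              nrow(x$pairs), length(x$diseases), nrow(x$known_edges), x$pairs_mode))
  invisible(x)
}
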