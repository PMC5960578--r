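#' Build a disease hierarchy (directed acyclic graph)
#'
#' The disease hierarchy is a MeSH-style DAG: every edge points from a
#' child term to a (more general) parent term, a node may have several
#' parents, and roots have none. Semantic similarity between diseases is
#' computed from shared ancestors in this structure.
#'
#' @param edges data frame with columns `child` and `parent`; a parent of
#'   `"-"` or `NA` declares the child as a root without adding an edge.
#' @param nodes optional character vector of extra (possibly isolated)
#'   node ids.
#' @return an object of class `disease_dag`: list with `nodes` (ordered,
#'   first appearance), `edges` (tibble child/parent), `roots`, and a
#'   `parents` lookup (named list).
#' @export
disease_dag <- function(edges, nodes = character()) {
  edges <- tibble(child = trimws(as.character(edges[[1L]])),
                  parent = trimws(as.character(edges[[2L]])))
  root_decl <- is.na(edges$parent) | edges$parent == "-"
  declared <- edges$child[root_decl]
  edges <- edges[!root_decl, , drop = FALSE]
  edges <- dplyr::distinct(edges)
  if (any(edges$child == edges$parent)) {
    bad <- edges$child[edges$child == edges$parent][1L]
    abort(sprintf("self-edge in disease hierarchy: '%s' is its own parent", bad))
  }
  all_nodes <- first_appearance(c(edges$child, edges$parent, declared,
                                  trimws(as.character(nodes))))
  all_nodes <- all_nodes[nzchar(all_nodes)]
  parents <- split(edges$parent, factor(edges$child, levels = all_nodes))
  cyc <- dag_find_cycle(all_nodes, parents)
  if (!is.null(cyc)) {
    abort(sprintf("disease hierarchy contains a cycle: %s",
                  paste(cyc, collapse = " -> ")))
  }
  has_parent <- lengths(parents) > 0L
  structure(
    list(nodes = all_nodes,
         edges = edges,
         roots = all_nodes[!has_parent],
         parents = parents),
    class = "disease_dag"
  )
}

# Depth-first search along child -> parent edges; returns one cycle as a
# character vector (closed walk) or NULL if the graph is acyclic.
dag_find_cycle <- function(nodes, parents) {
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, path = start))
    # iterative DFS with explicit path to extract the cycle
    visit <- function(node, path) {
      state[[node]] <<- 1L
      for (p in parents[[node]]) {
        if (state[[p]] == 1L) {
          i <- match(p, path)
          return(c(path[i:length(path)], p))
        }
        if (state[[p]] == 0L) {
          res <- visit(p, c(path, p))
          if (!is.null(res)) return(res)
        }
      }
      state[[node]] <<- 2L
      NULL
    }
    res <- visit(start, start)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Read a disease hierarchy from a child-parent TSV file
#'
#' Two tab-separated columns `child_id<TAB>parent_id`; a parent of `-`
#' declares an isolated root. Comment (`#`) and blank lines are skipped.
#' Cycles and self-edges are rejected.
#'
#' @param path path to the TSV file.
#' @return a [disease_dag()] object.
#' @export
read_disease_dag <- function(path) {
  if (!file.exists(path)) abort(sprintf("disease hierarchy file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) abort(sprintf("disease hierarchy file is empty: %s", path))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("parse error in %s at line %d: expected 2 tab-separated columns",
                  path, idx[bad[1L]]))
  }
  if (identical(trimws(fields[[1L]]), c("child", "parent"))) fields <- fields[-1L]
  disease_dag(tibble(
    child = vapply(fields, `[[`, character(1), 1L),
    parent = vapply(fields, `[[`, character(1), 2L)
  ))
}

#' Write a disease hierarchy as child-parent TSV
#'
#' Roots without any outgoing edge are written as `id<TAB>-` so the file
#' round-trips through [read_disease_dag()].
#'
#' @param dag a [disease_dag()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_dag <- function(dag, path) {
  stopifnot(inherits(dag, "disease_dag"))
  lines <- character()
  if (nrow(dag$edges) > 0L) {
    lines <- paste(dag$edges$child, dag$edges$parent, sep = "\t")
  }
  isolated <- setdiff(dag$roots, dag$edges$parent)
  # declare roots never mentioned as a parent, so they are not lost
  if (length(isolated) > 0L) lines <- c(lines, paste0(isolated, "\t-"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> %d nodes, %d edges, %d root(s)\n",
              length(x$nodes), nrow(x$edges), length(x$roots)))
  invisible(x)
}
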