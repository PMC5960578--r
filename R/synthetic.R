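#' Configuration for the synthetic association generator
#'
#' Entities are partitioned into matched communities; association edges
#' inside a community are drawn with a higher probability than across
#' communities, which plants recoverable block structure (diseases of a
#' community share lncRNA and miRNA partners, guaranteeing triangles and
#' giving the predictor a signal to find). The disease hierarchy is a
#' rooted tree whose subtrees align with the communities, so semantic
#' similarity carries the same signal.
#'
#' Defaults (30 diseases, 40 lncRNAs, 35 miRNAs, 3 communities,
#' within/between association probabilities 0.5/0.05 and interaction
#' probabilities 0.6/0.05, branching 3) yield hundreds of triangles and
#' sub-minute end-to-end runs. `p_between = p_within` is allowed and
#' produces the structureless null used for calibration checks.
#'
#' @param n_diseases,n_lncRNAs,n_miRNAs entity counts.
#' @param n_communities number of matched communities.
#' @param p_within,p_between probability of a gene-disease association
#'   inside / across the matched community.
#' @param p_lm_within,p_lm_between same for lncRNA-miRNA interactions.
#' @param dag_branching branching factor of the disease hierarchy tree.
#' @param dag_mode `"community"` (default: subtrees align with
#'   communities) or `"random"` (random tree, decoupled from the
#'   communities, for ablation).
#' @param seed RNG seed; the same seed always yields the same dataset.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_diseases = 30, n_lncRNAs = 40, n_miRNAs = 35,
                             n_communities = 3,
                             p_within = 0.5, p_between = 0.05,
                             p_lm_within = 0.6, p_lm_between = 0.05,
                             dag_branching = 3, dag_mode = c("community", "random"),
                             seed = 42) {
  dag_mode <- match.arg(dag_mode)
  stopifnot(n_diseases >= 1, n_lncRNAs >= 1, n_miRNAs >= 1,
            n_communities >= 1,
            n_communities <= min(n_diseases, n_lncRNAs, n_miRNAs),
            dag_branching >= 1)
  for (p in c(p_within, p_between, p_lm_within, p_lm_between)) {
    if (!(p >= 0 && p <= 1)) abort("probabilities must lie in [0, 1]")
  }
  if (p_between > p_within || p_lm_between > p_lm_within) {
    abort("between-community probabilities must not exceed within-community ones")
  }
  structure(
    list(n_diseases = n_diseases, n_lncRNAs = n_lncRNAs, n_miRNAs = n_miRNAs,
         n_communities = n_communities, p_within = p_within,
         p_between = p_between, p_lm_within = p_lm_within,
         p_lm_between = p_lm_between, dag_branching = dag_branching,
         dag_mode = dag_mode, seed = seed),
    class = "synthetic_config"
  )
}

# community labels in contiguous blocks, deterministic
community_blocks <- function(n, k) sort(rep_len(seq_len(k), n))

draw_block_edges <- function(left, right, comm_left, comm_right, p_in, p_out) {
  probs <- ifelse(outer(comm_left, comm_right, `==`), p_in, p_out)
  hits <- which(matrix(stats::runif(length(probs)) < probs,
                       nrow = length(left)), arr.ind = TRUE)
  tibble(left = left[hits[, 1L]], right = right[hits[, 2L]])
}

#' Generate a synthetic disease/lncRNA/miRNA dataset
#'
#' Draws the three association tables and the disease hierarchy under a
#' [synthetic_config()]. Generation is retried (fresh draws under the
#' same seeded stream, up to `max_retries`) until at least one
#' (disease, lncRNA, miRNA) triangle exists.
#'
#' @param config a [synthetic_config()].
#' @param max_retries bound on regeneration attempts (default 20).
#' @return object of class `lmpair_synth`: list with `lnc_disease`,
#'   `mir_disease`, `lnc_mir` (association tables), `dag`
#'   ([disease_dag()]), `ground_truth` (tibble `id`, `type`,
#'   `community`), and `config`.
#' @export
generate_lmpair_data <- function(config, max_retries = 20) {
  stopifnot(inherits(config, "synthetic_config"))
  d_ids <- sprintf("d%02d", seq_len(config$n_diseases))
  l_ids <- sprintf("l%02d", seq_len(config$n_lncRNAs))
  m_ids <- sprintf("m%02d", seq_len(config$n_miRNAs))
  cd <- community_blocks(config$n_diseases, config$n_communities)
  cl <- community_blocks(config$n_lncRNAs, config$n_communities)
  cm <- community_blocks(config$n_miRNAs, config$n_communities)

  withr::with_seed(config$seed, {
    dag <- synth_dag(d_ids, cd, config)
    for (attempt in seq_len(max_retries)) {
      ld <- draw_block_edges(l_ids, d_ids, cl, cd, config$p_within, config$p_between)
      md <- draw_block_edges(m_ids, d_ids, cm, cd, config$p_within, config$p_between)
      lm <- draw_block_edges(l_ids, m_ids, cl, cm, config$p_lm_within, config$p_lm_between)
      if (nrow(ld) > 0L && nrow(md) > 0L && nrow(lm) > 0L &&
          has_triangle(ld, md, lm, d_ids, l_ids, m_ids)) {
        ground_truth <- dplyr::bind_rows(
          tibble(id = d_ids, type = "disease", community = cd),
          tibble(id = l_ids, type = "lncRNA", community = cl),
          tibble(id = m_ids, type = "miRNA", community = cm)
        )
        return(structure(
          list(lnc_disease = association_table(ld, "lncRNA-disease"),
               mir_disease = association_table(md, "miRNA-disease"),
               lnc_mir = association_table(lm, "lncRNA-miRNA"),
               dag = dag, ground_truth = ground_truth, config = config),
          class = "lmpair_synth"
        ))
      }
    }
    abort(sprintf("no triangle after %d attempts; raise p_within/p_lm_within",
                  max_retries))
  })
}

has_triangle <- function(ld, md, lm, d_ids, l_ids, m_ids) {
  A1 <- matrix(FALSE, length(l_ids), length(d_ids), dimnames = list(l_ids, d_ids))
  A1[cbind(match(ld$left, l_ids), match(ld$right, d_ids))] <- TRUE
  A2 <- matrix(FALSE, length(m_ids), length(d_ids), dimnames = list(m_ids, d_ids))
  A2[cbind(match(md$left, m_ids), match(md$right, d_ids))] <- TRUE
  A3 <- matrix(FALSE, length(l_ids), length(m_ids), dimnames = list(l_ids, m_ids))
  A3[cbind(match(lm$left, l_ids), match(lm$right, m_ids))] <- TRUE
  for (j in seq_along(d_ids)) {
    ls <- A1[, j]
    ms <- A2[, j]
    if (any(ls) && any(ms) && any(A3[ls, ms])) return(TRUE)
  }
  FALSE
}

# rooted tree: root -> community nodes -> diseases in a b-ary tree per
# community ("community" mode) or a single random recursive tree
synth_dag <- function(d_ids, cd, config) {
  b <- config$dag_branching
  edges <- tibble(child = character(), parent = character())
  if (config$dag_mode == "community") {
    comm_nodes <- sprintf("grp%d", seq_len(config$n_communities))
    edges <- tibble(child = comm_nodes, parent = "root")
    for (g in seq_len(config$n_communities)) {
      ds <- d_ids[cd == g]
      parent <- vapply(seq_along(ds), function(t) {
        if (t <= b) comm_nodes[g] else ds[(t - b - 1) %/% b + 1]
      }, character(1))
      edges <- dplyr::bind_rows(edges, tibble(child = ds, parent = parent))
    }
  } else {
    parent <- vapply(seq_along(d_ids), function(t) {
      if (t == 1L) "root" else d_ids[sample.int(t - 1L, 1L)]
    }, character(1))
    edges <- tibble(child = d_ids, parent = parent)
  }
  disease_dag(edges)
}

#' @export
print.lmpair_synth <- function(x, ...) {
  cat(sprintf("<lmpair_synth> seed %d: %d/%d/%d disease/lncRNA/miRNA, edges %d/%d/%d\n",
              x$config$seed, x$config$n_diseases, x$config$n_lncRNAs,
              x$config$n_miRNAs, nrow(x$lnc_disease), nrow(x$mir_disease),
              nrow(x$lnc_mir)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `lnc_disease.tsv`, `mir_disease.tsv`, `lnc_mir.tsv`,
#' `disease_dag.tsv` and `ground_truth.tsv`; the association tables and
#' hierarchy round-trip exactly through the package readers.
#'
#' @param data an `lmpair_synth` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  stopifnot(inherits(data, "lmpair_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_association_table(data$lnc_disease, file.path(dir, "lnc_disease.tsv"))
  write_association_table(data$mir_disease, file.path(dir, "mir_disease.tsv"))
  write_association_table(data$lnc_mir, file.path(dir, "lnc_mir.tsv"))
  write_disease_dag(data$dag, file.path(dir, "disease_dag.tsv"))
  readr::write_tsv(data$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Generate data, fit the model, and cross-validate in one call
#'
#' Desk-scale benchmark: draws a synthetic dataset, builds the full
#' model, and runs repeated k-fold cross-validation.
#'
#' @param config a [synthetic_config()].
#' @param gamma,K KATZ parameters.
#' @param pair_method pair similarity scheme, see [lmpair_similarity()].
#' @param k,repeats,cv_seed cross-validation settings, see [kfold_cv()].
#' @param delta semantic decay factor.
#' @param ... further arguments passed to [lmpair_model()].
#' @return an `lmpair_cv` with the fitted model attached as attribute
#'   `model`.
#' @export
holdout_benchmark <- function(config, gamma = 0.01, K = 2,
                              pair_method = "average", k = 5, repeats = 5,
                              cv_seed = config$seed + 1000L, delta = 0.5, ...) {
  data <- generate_lmpair_data(config)
  model <- lmpair_model(data$lnc_disease, data$mir_disease, data$lnc_mir,
                        data$dag, delta = delta, pair_method = pair_method, ...)
  cv <- kfold_cv(model$network, model$pair_sim, model$dis_sim,
                 gamma = gamma, K = K, k = k, repeats = repeats, seed = cv_seed)
  attr(cv, "model") <- model
  cv
}
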