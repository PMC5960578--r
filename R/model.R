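#' Fit the disease / lncRNA-miRNA pair association model
#'
#' End-to-end construction from the three association tables and the
#' disease hierarchy: builds the bipartite and triangle-filtered
#' networks, the layered similarity matrices (semantic, interaction
#' profile, functional, integrated), and the pair similarity. The result
#' is ready for [predict_associations()] and the cross-validation
#' routines.
#'
#' @param lnc_disease,mir_disease,lnc_mir association tables
#'   (`assoc_tbl`) of the matching kinds.
#' @param dag a [disease_dag()] covering (ideally) the shared diseases.
#' @param delta semantic decay factor in (0, 1), default 0.5.
#' @param pair_method pair similarity scheme (`"average"`, `"sqrt"`,
#'   `"centre"`), default `"average"`.
#' @param gip_scope `"restricted"` (default: interaction profiles over
#'   the triangle-filtered vertex set, matching the prediction universe)
#'   or `"full"` (profiles over the complete source networks).
#' @param funsim_base `"semantic"` (default: functional similarity
#'   matches diseases by semantic similarity alone) or `"integrated"`.
#' @param pairs pair universe, `"full"` cross product (default) or
#'   `"interacting"`; see [build_disease_lmpair_network()].
#' @param max_pairs size guard for the full cross product.
#' @return object of class `lmpair_model`: list with the networks
#'   (`g1`, `g2`, `g3`, `tripartite`, `network`), similarity matrices
#'   (`dis_sem`, `dis_gip`, `dis_sim`, `lnc_fun`, `lnc_gip`, `lnc_sim`,
#'   `mir_fun`, `mir_gip`, `mir_sim`), the `pair_sim`, and `params`.
#' @export
lmpair_model <- function(lnc_disease, mir_disease, lnc_mir, dag,
                         delta = 0.5,
                         pair_method = c("average", "sqrt", "centre"),
                         gip_scope = c("restricted", "full"),
                         funsim_base = c("semantic", "integrated"),
                         pairs = c("full", "interacting"),
                         max_pairs = 2e6) {
  pair_method <- match.arg(pair_method)
  gip_scope <- match.arg(gip_scope)
  funsim_base <- match.arg(funsim_base)
  pairs <- match.arg(pairs)

  g1 <- build_bipartite(lnc_disease)
  g2 <- build_bipartite(mir_disease)
  g3 <- build_bipartite(lnc_mir)
  tri <- build_tripartite(g1, g2, g3)
  net <- build_disease_lmpair_network(tri, pairs = pairs, max_pairs = max_pairs)

  params <- list(delta = delta, pair_method = pair_method,
                 gip_scope = gip_scope, funsim_base = funsim_base,
                 pairs = pairs)
  sims <- model_similarities(g1, g2, dag, net, params)

  structure(
    c(list(g1 = g1, g2 = g2, g3 = g3, tripartite = tri, network = net,
           dag = dag),
      sims,
      list(params = params)),
    class = "lmpair_model"
  )
}

# All layered similarities for a fixed prediction universe `net`.
# Split out of lmpair_model() so strict-masking cross-validation can
# recompute them per fold from edge-masked copies of g1/g2.
model_similarities <- function(g1, g2, dag, net, params) {
  diseases <- net$diseases
  if (params$gip_scope == "restricted") {
    lnc_rows <- net$lncRNAs
    mir_rows <- net$miRNAs
    dis_cols <- diseases
  } else {
    lnc_rows <- g1$left_ids
    mir_rows <- g2$left_ids
    dis_cols <- NULL # full disease columns of each network
  }

  # disease similarities -------------------------------------------------
  sets_l <- gene_disease_sets(g1, rows = lnc_rows, diseases = dis_cols)
  sets_m <- gene_disease_sets(g2, rows = mir_rows, diseases = dis_cols)
  sem_ids <- first_appearance(c(diseases, unlist(sets_l, use.names = FALSE),
                                unlist(sets_m, use.names = FALSE)))
  dis_sem_all <- semantic_similarity_matrix(dag, sem_ids, params$delta)
  dis_sem <- dis_sem_all[diseases, diseases, drop = FALSE]
  if (params$gip_scope == "restricted") {
    dis_gip <- disease_gip_similarity(g1, g2, diseases,
                                      lncRNAs = lnc_rows, miRNAs = mir_rows)
  } else {
    shared <- intersect(g1$right_ids, g2$right_ids)
    dis_gip <- disease_gip_similarity(g1, g2, shared)[diseases, diseases,
                                                      drop = FALSE]
  }
  dis_sim <- integrated_disease_similarity(dis_sem, dis_gip)

  # gene similarities ----------------------------------------------------
  fun_base <- if (params$funsim_base == "semantic") dis_sem_all else dis_sim
  if (params$funsim_base == "integrated") {
    sets_l <- lapply(sets_l, intersect, diseases)
    sets_m <- lapply(sets_m, intersect, diseases)
  }
  lnc_fun <- functional_similarity(sets_l, fun_base)
  mir_fun <- functional_similarity(sets_m, fun_base)
  y1 <- g1$adjacency[lnc_rows, dis_cols %||% g1$right_ids, drop = FALSE]
  y2 <- g2$adjacency[mir_rows, dis_cols %||% g2$right_ids, drop = FALSE]
  lnc_gip <- gene_gip_similarity(y1)
  mir_gip <- gene_gip_similarity(y2)
  lnc_sim <- integrated_gene_similarity(lnc_fun, lnc_gip)[net$lncRNAs,
                                                          net$lncRNAs,
                                                          drop = FALSE]
  mir_sim <- integrated_gene_similarity(mir_fun, mir_gip)[net$miRNAs,
                                                          net$miRNAs,
                                                          drop = FALSE]

  pair_sim <- lmpair_similarity(
    lnc_sim, mir_sim,
    pairs = if (net$pairs_mode == "interacting") net$pairs else NULL,
    method = params$pair_method
  )

  list(dis_sem = dis_sem, dis_gip = dis_gip, dis_sim = dis_sim,
       lnc_fun = lnc_fun, lnc_gip = lnc_gip, lnc_sim = lnc_sim,
       mir_fun = mir_fun, mir_gip = mir_gip, mir_sim = mir_sim,
       pair_sim = pair_sim)
}

#' @export
print.lmpair_model <- function(x, ...) {
  net <- x$network
  cat("<lmpair_model>\n")
  cat(sprintf("  networks: %d lncRNA(s), %d miRNA(s), %d disease(s), %d triangle(s)\n",
              length(net$lncRNAs), length(net$miRNAs), length(net$diseases),
              nrow(x$tripartite$triangles)))
  cat(sprintf("  pair universe: %d pair(s) (%s), %d known association(s)\n",
              nrow(net$pairs), net$pairs_mode, nrow(net$known_edges)))
  cat(sprintf("  similarities: delta = %g, pair method = '%s', scope = %s\n",
              x$params$delta, x$params$pair_method, x$params$gip_scope))
  invisible(x)
}

#' Predict and rank disease / pair associations
#'
#' Scores every (pair, disease) cell of a fitted model with the
#' truncated KATZ measure and returns the ranked prediction table.
#'
#' @param model an [lmpair_model()].
#' @param gamma,K,engine KATZ parameters, see [katz_score()].
#' @return an `lmpair_predictions` tibble, see [rank_predictions()].
#' @export
predict_associations <- function(model, gamma = 0.01, K = 2,
                                 engine = c("auto", "closed_form", "power")) {
  stopifnot(inherits(model, "lmpair_model"))
  engine <- match.arg(engine)
  S <- katz_score(model$pair_sim, model$network$DP, model$dis_sim,
                  gamma = gamma, K = K, engine = engine)
  rank_predictions(S, model$network)
}

#' Cross-validate a fitted model
#'
#' Thin dispatcher over [loocv()] and [kfold_cv()].
#'
#' @param model an [lmpair_model()].
#' @param scheme `"kfold"` (default) or `"loocv"`.
#' @param ... passed to the scheme function.
#' @return an `lmpair_cv`.
#' @export
cross_validate <- function(model, scheme = c("kfold", "loocv"), ...) {
  stopifnot(inherits(model, "lmpair_model"))
  scheme <- match.arg(scheme)
  fn <- if (scheme == "kfold") kfold_cv else loocv
  fn(model$network, model$pair_sim, model$dis_sim, model = model, ...)
}

#' Run the full pipeline from files on disk
#'
#' Reads the three association tables and the disease hierarchy, fits
#' the model, writes the ranked predictions and a plain-text run log
#' (parameters, seeds, input checksums), and optionally cross-validates.
#' On error, partial outputs are removed.
#'
#' @param lnc_disease_path,mir_disease_path,lnc_mir_path,dag_path input
#'   TSV paths.
#' @param out_dir output directory.
#' @param gamma,K KATZ parameters.
#' @param cv `NULL` (no cross-validation) or a list of arguments for
#'   [cross_validate()] (e.g. `list(scheme = "kfold", k = 5,
#'   repeats = 10, seed = 1)`).
#' @param ... further arguments passed to [lmpair_model()].
#' @return (invisibly) list with `predictions`, `model`, and `cv`
#'   (or `NULL`).
#' @export
run_lmpair_pipeline <- function(lnc_disease_path, mir_disease_path,
                                lnc_mir_path, dag_path, out_dir,
                                gamma = 0.01, K = 2, cv = NULL, ...) {
  for (p in c(lnc_disease_path, mir_disease_path, lnc_mir_path, dag_path)) {
    if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  tryCatch({
    model <- lmpair_model(
      read_association_table(lnc_disease_path, "lncRNA-disease"),
      read_association_table(mir_disease_path, "miRNA-disease"),
      read_association_table(lnc_mir_path, "lncRNA-miRNA"),
      read_disease_dag(dag_path), ...
    )
    preds <- predict_associations(model, gamma = gamma, K = K)
    pred_path <- file.path(out_dir, "predictions.tsv")
    write_predictions(preds, pred_path)
    written <- c(written, pred_path)
    cv_res <- NULL
    if (!is.null(cv)) {
      cv_res <- do.call(cross_validate, c(list(model = model), cv))
      cv_path <- file.path(out_dir, "cv_summary.tsv")
      readr::write_tsv(tidy(cv_res), cv_path)
      written <- c(written, cv_path)
    }
    log_path <- file.path(out_dir, "run_log.txt")
    inputs <- c(lnc_disease_path, mir_disease_path, lnc_mir_path, dag_path)
    log_lines <- c(
      sprintf("delta: %g", model$params$delta),
      sprintf("gamma: %g", gamma),
      sprintf("K: %d", K),
      sprintf("pair_method: %s", model$params$pair_method),
      sprintf("gip_scope: %s", model$params$gip_scope),
      sprintf("funsim_base: %s", model$params$funsim_base),
      sprintf("cv_seed: %s", if (is.null(cv$seed)) "none" else cv$seed),
      sprintf("input_md5 %s: %s", basename(inputs), tools::md5sum(inputs))
    )
    readr::write_lines(log_lines, log_path)
    written <- c(written, log_path)
    invisible(list(predictions = preds, model = model, cv = cv_res))
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}
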