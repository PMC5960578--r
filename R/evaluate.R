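#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the pooled unique scores and records
#' the true/false positive rates; the trapezoidal area under the
#' resulting curve equals the Mann-Whitney statistic
#' `P(pos > neg) + 0.5 * P(pos = neg)`.
#'
#' @param positive,negative numeric score vectors (both non-empty).
#' @return list with `auc` (scalar) and `roc` (tibble `threshold`,
#'   `fpr`, `tpr`, starting at (0, 0) and ending at (1, 1)).
#' @export
roc_auc <- function(positive, negative) {
  if (length(positive) == 0L || length(negative) == 0L) {
    abort("both score vectors must be non-empty")
  }
  np <- length(positive)
  nn <- length(negative)
  r <- rank(c(positive, negative))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(positive, negative)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positive >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(negative >= t), numeric(1))
  roc <- tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (roc$fpr[nrow(roc)] < 1 || roc$tpr[nrow(roc)] < 1) {
    roc <- dplyr::bind_rows(roc, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  list(auc = auc, roc = roc)
}

# percentile of each score s within a candidate score distribution:
# P(candidate < s) + 0.5 * P(candidate = s)
percentile_in <- function(scores, candidates) {
  sorted <- sort(candidates)
  le <- findInterval(scores, sorted)                   # candidates <= s
  lt <- findInterval(scores, sorted, left.open = TRUE) # candidates <  s
  (lt + 0.5 * (le - lt)) / length(candidates)
}

new_lmpair_cv <- function(scheme, per_repeat_auc, percentiles, settings) {
  q <- sort(unique(c(0, percentiles, 1)), decreasing = TRUE)
  roc <- tibble(
    threshold = c(Inf, q),
    fpr = c(0, 1 - q),
    tpr = c(0, vapply(q, function(t) mean(percentiles >= t), numeric(1)))
  )
  structure(
    list(scheme = scheme,
         per_repeat_auc = per_repeat_auc,
         mean_auc = mean(per_repeat_auc),
         std_auc = if (length(per_repeat_auc) > 1L) stats::sd(per_repeat_auc) else NA_real_,
         percentiles = percentiles,
         roc_points = roc,
         settings = settings),
    class = "lmpair_cv"
  )
}

#' @export
print.lmpair_cv <- function(x, ...) {
  cat(sprintf("<lmpair_cv> %s: mean AUC %.4f%s over %d repeat(s)\n",
              x$scheme, x$mean_auc,
              if (is.na(x$std_auc)) "" else sprintf(" (sd %.4f)", x$std_auc),
              length(x$per_repeat_auc)))
  invisible(x)
}

# held-out percentiles of the test cells against the fold's candidates
fold_percentiles <- function(S, test_cells, cand_mask, candidates) {
  if (candidates == "global") {
    cand <- S[cand_mask]
    if (length(cand) == 0L) abort("no candidate cells available for ranking")
    return(percentile_in(S[test_cells], cand))
  }
  vapply(seq_len(nrow(test_cells)), function(i) {
    di_ <- test_cells[i, 2L]
    cand <- S[cand_mask[, di_], di_]
    if (length(cand) == 0L) abort("no candidate cells available for ranking")
    percentile_in(S[test_cells[i, , drop = FALSE]], cand)
  }, numeric(1))
}

# score one masked copy of DP and return held-out percentiles; when
# strict masking is on, the underlying disease-lncRNA and disease-miRNA
# edges of each held-out triangle are also removed and all similarities
# are recomputed from the masked source networks
cv_score_fold <- function(test_cells, network, pair_sim, dis_sim, gamma, K,
                          engine, candidates, model = NULL,
                          strict_masking = FALSE) {
  DPm <- network$DP
  DPm[test_cells] <- 0L
  if (strict_masking) {
    g1m <- model$g1
    g2m <- model$g2
    held_l <- network$pairs$lncRNA[test_cells[, 1L]]
    held_m <- network$pairs$miRNA[test_cells[, 1L]]
    held_d <- network$diseases[test_cells[, 2L]]
    g1m$adjacency[cbind(match(held_l, g1m$left_ids),
                        match(held_d, g1m$right_ids))] <- 0L
    g2m$adjacency[cbind(match(held_m, g2m$left_ids),
                        match(held_d, g2m$right_ids))] <- 0L
    sims <- suppressWarnings(
      model_similarities(g1m, g2m, model$dag, network, model$params)
    )
    pair_sim <- sims$pair_sim
    dis_sim <- sims$dis_sim
  }
  S <- katz_score(pair_sim, DPm, dis_sim, gamma = gamma, K = K, engine = engine)
  fold_percentiles(S, test_cells, network$DP == 0L, candidates)
}

#' Leave-one-out cross-validation of the association predictor
#'
#' Each known (pair, disease) association is masked from `DP` in turn,
#' the KATZ scores are recomputed (similarities stay fixed: they derive
#' from the three source networks, not from `DP`), and the held-out score
#' is converted to a percentile against the candidate cells (cells with
#' no known association) of its own fold. The pooled percentiles yield
#' one ROC, and the AUC is their mean - the probability that a held-out
#' known association outranks a random candidate.
#'
#' @param network a `dlm_network` with at least 2 known associations.
#' @param pair_sim a [lmpair_similarity()] object.
#' @param dis_sim disease similarity matrix aligned with
#'   `network$diseases`.
#' @param gamma,K KATZ parameters, see [katz_score()].
#' @param candidates `"global"` (default: all unknown cells) or
#'   `"per_disease"` (unknown cells of the held-out disease only).
#' @param engine score engine, see [katz_score()].
#' @param model the fitted [lmpair_model()]; only required with
#'   `strict_masking = TRUE`.
#' @param strict_masking also remove the held-out triangle's
#'   disease-lncRNA and disease-miRNA edges from the source networks and
#'   recompute every similarity per fold (slower, but removes the
#'   residual information the fixed similarity matrices carry about the
#'   held-out associations). Default `FALSE`: only `DP` is masked.
#' @return object of class `lmpair_cv`.
#' @export
loocv <- function(network, pair_sim, dis_sim, gamma = 0.01, K = 2,
                  candidates = c("global", "per_disease"),
                  engine = c("auto", "closed_form", "power"),
                  model = NULL, strict_masking = FALSE) {
  candidates <- match.arg(candidates)
  engine <- match.arg(engine)
  if (strict_masking && is.null(model)) {
    abort("strict_masking = TRUE needs the fitted model (argument `model`)")
  }
  known <- which(network$DP == 1L, arr.ind = TRUE)
  if (nrow(known) < 2L) abort("leave-one-out needs at least 2 known associations")
  perc <- vapply(seq_len(nrow(known)), function(i) {
    cv_score_fold(known[i, , drop = FALSE], network, pair_sim, dis_sim,
                  gamma, K, engine, candidates, model, strict_masking)
  }, numeric(1))
  new_lmpair_cv("loocv", per_repeat_auc = mean(perc), percentiles = perc,
                settings = list(gamma = gamma, K = K, candidates = candidates,
                                strict_masking = strict_masking))
}

#' Repeated k-fold cross-validation of the association predictor
#'
#' The known associations are randomly divided into `k` equal parts
#' (seeded, repeated `repeats` times with per-repeat seed offsets). Per
#' fold, the test associations are masked from `DP` together, scores are
#' recomputed, and each test association's percentile against the
#' fold's candidate cells is recorded; one AUC is produced per repeat
#' (the mean percentile over all its folds) and summarized by mean and
#' standard deviation. With `k` equal to the number of known
#' associations, this reduces to [loocv()].
#'
#' @inheritParams loocv
#' @param k number of folds, between 2 and the number of known
#'   associations.
#' @param repeats number of random re-partitions (default 100).
#' @param seed RNG seed for the partitions.
#' @return object of class `lmpair_cv`.
#' @export
kfold_cv <- function(network, pair_sim, dis_sim, gamma = 0.01, K = 2,
                     k = 5, repeats = 100, seed = 42,
                     candidates = c("global", "per_disease"),
                     engine = c("auto", "closed_form", "power"),
                     model = NULL, strict_masking = FALSE) {
  candidates <- match.arg(candidates)
  engine <- match.arg(engine)
  if (strict_masking && is.null(model)) {
    abort("strict_masking = TRUE needs the fitted model (argument `model`)")
  }
  known <- which(network$DP == 1L, arr.ind = TRUE)
  n <- nrow(known)
  if (!(k >= 2 && k <= n)) {
    abort(sprintf("k must lie between 2 and the number of known associations (%d)", n))
  }
  if (repeats < 1L) abort("repeats must be >= 1")
  per_repeat <- numeric(repeats)
  all_perc <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of <- withr::with_seed(seed + r - 1L, sample(rep_len(seq_len(k), n)))
    perc <- unlist(lapply(seq_len(k), function(f) {
      cv_score_fold(known[fold_of == f, , drop = FALSE], network, pair_sim,
                    dis_sim, gamma, K, engine, candidates, model, strict_masking)
    }))
    per_repeat[r] <- mean(perc)
    all_perc[[r]] <- perc
  }
  new_lmpair_cv("kfold", per_repeat_auc = per_repeat,
                percentiles = unlist(all_perc),
                settings = list(gamma = gamma, K = K, k = k, repeats = repeats,
                                seed = seed, candidates = candidates,
                                strict_masking = strict_masking))
}
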