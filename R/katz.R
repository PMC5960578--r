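#' Assemble the integrated block matrix
#'
#' Stacks the pair similarity, the pair-by-disease adjacency `DP` and the
#' disease similarity into the symmetric `(N_p + N_d)` square matrix
#' `[[PairSim, DP], [DP', DisSim]]` on which the KATZ walk measure is
#' evaluated.
#'
#' @param pair_sim a [lmpair_similarity()] object or dense `N_p x N_p`
#'   matrix.
#' @param DP binary `N_p x N_d` adjacency matrix.
#' @param dis_sim `N_d x N_d` disease similarity matrix.
#' @return `(N_p + N_d) x (N_p + N_d)` numeric matrix.
#' @export
assemble_dpstar <- function(pair_sim, DP, dis_sim) {
  p <- pair_sim_values(pair_sim)
  if (nrow(p) != nrow(DP) || ncol(dis_sim) != ncol(DP) || nrow(dis_sim) != ncol(DP)) {
    abort(sprintf("block shapes do not conform: PairSim %dx%d, DP %dx%d, DisSim %dx%d",
                  nrow(p), ncol(p), nrow(DP), ncol(DP), nrow(dis_sim), ncol(dis_sim)))
  }
  rbind(cbind(p, DP), cbind(t(DP), dis_sim))
}

#' Truncated KATZ association scores
#'
#' Scores every (pair, disease) cell by the weighted count of walks of
#' length at most `K` between the pair vertex and the disease vertex in
#' the integrated block matrix, a walk of length `l` weighing `gamma^l`.
#' The result is the pair-by-disease block of
#' `sum_{l=1..K} gamma^l (DP*)^l`.
#'
#' Two engines are available and give identical results: `closed_form`
#' uses the explicit block expansions for `K` in 2..4 (e.g. for `K = 2`,
#' `gamma*DP + gamma^2*(PairSim %*% DP + DP %*% DisSim)`), while `power`
#' accumulates the powers applied to the disease indicator block and
#' works for any `K >= 2` without materializing the square matrix, so it
#' composes with structured pair similarities.
#'
#' @inheritParams assemble_dpstar
#' @param gamma walk damping factor in (0, 1); default 0.01.
#' @param K maximum walk length, integer >= 2; default 2 (short walks
#'   predict best in sparse networks).
#' @param engine `"auto"` (closed form when `K <= 4`), `"closed_form"`,
#'   or `"power"`.
#' @return `N_p x N_d` score matrix with pair/disease dimnames and
#'   attributes `gamma`, `K`.
#' @export
katz_score <- function(pair_sim, DP, dis_sim, gamma = 0.01, K = 2,
                       engine = c("auto", "closed_form", "power")) {
  engine <- match.arg(engine)
  check_katz_params(gamma, K)
  DP <- as.matrix(DP) * 1.0
  assert_finite(DP, "DP")
  assert_finite(dis_sim, "DisSim")
  if (engine == "auto") engine <- if (K <= 4) "closed_form" else "power"
  if (engine == "closed_form" && K > 4) {
    abort("closed forms are only available for K in {2, 3, 4}; use engine = \"power\"")
  }
  S <- if (engine == "closed_form") {
    katz_closed_form(pair_sim, DP, dis_sim, gamma, K)
  } else {
    katz_power(pair_sim, DP, dis_sim, gamma, K)
  }
  dimnames(S) <- dimnames(DP)
  attr(S, "gamma") <- gamma
  attr(S, "K") <- K
  S
}

check_katz_params <- function(gamma, K) {
  if (!(is.numeric(gamma) && length(gamma) == 1L && gamma > 0 && gamma < 1)) {
    abort("gamma must be a single number strictly between 0 and 1")
  }
  if (!(is.numeric(K) && length(K) == 1L && K >= 2 && K == round(K))) {
    abort("K must be an integer >= 2")
  }
  invisible(TRUE)
}

# Explicit block expansions of the pair-by-disease block of the
# accumulated powers, for K = 2, 3, 4.
katz_closed_form <- function(P, DP, S, gamma, K) {
  pm <- function(x) pair_sim_matmul(P, x) # PairSim %*% x
  out <- gamma * DP + gamma^2 * (pm(DP) + DP %*% S)
  if (K >= 3) {
    out <- out + gamma^3 * (DP %*% crossprod(DP, DP) + pm(pm(DP)) +
                              pm(DP %*% S) + DP %*% S %*% S)
  }
  if (K >= 4) {
    DtD <- crossprod(DP, DP)   # DP' DP  (N_d x N_d)
    PD <- pm(DP)
    out <- out + gamma^4 * (pm(pm(PD)) +              # PairSim^3 DP
                              DP %*% crossprod(DP, PD) + # DP DP' PairSim DP
                              pm(DP %*% DtD) +           # PairSim DP DP' DP
                              DP %*% S %*% DtD +         # DP DisSim DP' DP
                              DP %*% DtD %*% S +         # DP DP' DP DisSim
                              pm(pm(DP %*% S)) +         # PairSim^2 DP DisSim
                              pm(DP %*% S %*% S) +       # PairSim DP DisSim^2
                              DP %*% S %*% S %*% S)      # DP DisSim^3
  }
  out
}

# Generic accumulation: Z_l = (DP*)^l applied to the disease indicator
# block [0; I]; its top block is the pair-by-disease block of (DP*)^l.
katz_power <- function(P, DP, S, gamma, K) {
  top <- DP
  bottom <- S
  acc <- gamma * top
  for (l in seq(2L, K)) {
    new_top <- pair_sim_matmul(P, top) + DP %*% bottom
    new_bottom <- crossprod(DP, top) + S %*% bottom
    top <- new_top
    bottom <- new_bottom
    acc <- acc + gamma^l * top
  }
  acc
}

#' Exact (untruncated) KATZ scores via the resolvent
#'
#' Sums walks of every length: the pair-by-disease block of
#' `solve(I - gamma * DPstar) - I`. Only valid when
#' `gamma * rho(DPstar) < 1` (rho the spectral radius); otherwise the
#' series diverges and an error names the bound. Intended for validating
#' the truncated scores on small problems.
#'
#' @inheritParams katz_score
#' @return `N_p x N_d` score matrix.
#' @export
katz_score_exact <- function(pair_sim, DP, dis_sim, gamma = 0.01) {
  check_katz_params(gamma, 2)
  DP <- as.matrix(DP) * 1.0
  dpstar <- assemble_dpstar(pair_sim, DP, dis_sim)
  rho <- max(abs(eigen(dpstar, only.values = TRUE)$values))
  if (gamma * rho >= 1) {
    abort(sprintf("KATZ series diverges: gamma = %g but convergence requires gamma < 1/rho = %g",
                  gamma, 1 / rho))
  }
  n <- nrow(dpstar)
  S <- solve(diag(n) - gamma * dpstar) - diag(n)
  np <- nrow(DP)
  out <- S[seq_len(np), np + seq_len(ncol(DP)), drop = FALSE]
  dimnames(out) <- dimnames(DP)
  out
}

#' Rank all (pair, disease) cells by predicted score
#'
#' Flattens a score matrix into a ranked prediction table: descending
#' score, ties broken deterministically by disease index then pair index
#' (both ascending). Known associations are flagged from the training
#' network.
#'
#' @param scores `N_p x N_d` score matrix from [katz_score()].
#' @param network the `dlm_network` the scores were computed on.
#' @return tibble of class `lmpair_predictions` with columns
#'   `disease_id`, `lncRNA_id`, `miRNA_id`, `score`, `rank`, `known`.
#' @export
rank_predictions <- function(scores, network) {
  stopifnot(inherits(network, "dlm_network"))
  np <- nrow(network$pairs)
  nd <- length(network$diseases)
  stopifnot(nrow(scores) == np, ncol(scores) == nd)
  cells <- tibble(
    pair_index = rep(seq_len(np), times = nd),
    disease_index = rep(seq_len(nd), each = np),
    disease_id = rep(network$diseases, each = np),
    lncRNA_id = rep(network$pairs$lncRNA, times = nd),
    miRNA_id = rep(network$pairs$miRNA, times = nd),
    score = as.vector(scores),
    known = as.vector(network$DP == 1L)
  )
  cells <- dplyr::arrange(cells, dplyr::desc(.data$score),
                          .data$disease_index, .data$pair_index)
  cells$rank <- seq_len(nrow(cells))
  out <- cells[, c("disease_id", "lncRNA_id", "miRNA_id", "score", "rank", "known")]
  class(out) <- c("lmpair_predictions", class(out))
  out
}
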