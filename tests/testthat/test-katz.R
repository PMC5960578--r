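test_that("the block matrix assembles and slices back exactly", {
  p <- matrix(1, 1, 1, dimnames = list("p1", "p1"))
  dp <- matrix(1, 1, 1, dimnames = list("p1", "d1"))
  s <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  expect_equal(unname(assemble_dpstar(p, dp, s)), matrix(1, 2, 2))

  withr::local_seed(2)
  P <- random_sim(4)
  DP <- matrix(rbinom(8, 1, 0.5), 4, 2)
  S <- random_sim(2)
  star <- assemble_dpstar(P, DP, S)
  expect_equal(unname(star), unname(t(star)))
  expect_equal(unname(star[1:4, 1:4]), unname(P))
  expect_equal(unname(star[1:4, 5:6]), DP + 0.0)
  expect_equal(unname(star[5:6, 5:6]), unname(S))
  expect_error(assemble_dpstar(P, DP, random_sim(3)), "conform")
})

test_that("K = 2 truncation matches the hand-computed 1x1 case", {
  p <- matrix(1, 1, 1)
  dp <- matrix(1, 1, 1, dimnames = list("p1", "d1"))
  s <- matrix(1, 1, 1)
  got <- katz_score(p, dp, s, gamma = 0.01, K = 2)
  expect_equal(unname(got[1, 1]), 0.01 + 1e-4 * 2)
})

test_that("scores vanish linearly as gamma approaches zero", {
  withr::local_seed(44)
  P <- random_sim(3)
  DP <- matrix(rbinom(6, 1, 0.7), 3, 2)
  S <- random_sim(2)
  got <- katz_score(P, DP, S, gamma = 1e-12, K = 2)
  expect_lte(max(abs(got)), 2e-12 * max(colSums(DP) + 1))
  expect_error(katz_score(P, DP, S, gamma = 0), "gamma")
  expect_error(katz_score(P, DP, S, gamma = 0.01, K = 1), "K must")
  DPbad <- DP; DPbad[1, 1] <- NA
  expect_error(katz_score(P, DPbad, S), "non-finite")
})

test_that("closed forms and the power engine match the dense block-power oracle", {
  withr::local_seed(71)
  for (i in 1:10) {
    np <- sample(2:6, 1)
    nd <- sample(2:4, 1)
    P <- random_sim(np, sprintf("p%d", 1:np))
    DP <- matrix(rbinom(np * nd, 1, 0.5), np, nd,
                 dimnames = list(rownames(P), sprintf("d%d", 1:nd)))
    S <- random_sim(nd, colnames(DP))
    for (gamma in c(0.01, 0.1)) {
      for (K in 2:4) {
        ref <- oracle_katz(unname(P), unname(DP), unname(S), gamma, K)
        cf <- katz_score(P, DP, S, gamma, K, engine = "closed_form")
        pw <- katz_score(P, DP, S, gamma, K, engine = "power")
        expect_equal(unname(cf), ref, tolerance = 1e-12, ignore_attr = TRUE)
        expect_equal(unname(pw), ref, tolerance = 1e-12, ignore_attr = TRUE)
      }
      ref6 <- oracle_katz(unname(P), unname(DP), unname(S), gamma, 6)
      expect_equal(unname(katz_score(P, DP, S, gamma, 6)), ref6,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("the resolvent form agrees with long truncations and obeys the tail bound", {
  withr::local_seed(83)
  for (i in 1:5) {
    P <- random_sim(4)
    DP <- matrix(rbinom(12, 1, 0.5), 4, 3,
                 dimnames = list(rownames(P), sprintf("d%d", 1:3)))
    S <- random_sim(3, colnames(DP))
    gamma <- 0.05
    star <- assemble_dpstar(P, DP, S)
    rho <- max(abs(eigen(star, only.values = TRUE)$values))
    if (gamma * rho >= 1) next
    exact <- katz_score_exact(P, DP, S, gamma)
    trunc60 <- katz_score(P, DP, S, gamma, K = 60, engine = "power")
    expect_equal(exact, trunc60, tolerance = 1e-12, ignore_attr = TRUE)
    for (K in c(5, 10)) {
      truncK <- katz_score(P, DP, S, gamma, K = K, engine = "power")
      bound <- (gamma * rho)^(K + 1) / (1 - gamma * rho)
      expect_lte(max(abs(exact - truncK)), bound + 1e-12)
    }
  }
  # divergence is detected
  P1 <- matrix(1, 1, 1); DP1 <- matrix(1, 1, 1); S1 <- matrix(1, 1, 1)
  expect_error(katz_score_exact(P1, DP1, S1, gamma = 0.9), "diverges")
})

test_that("adding a known edge never lowers a score and known edges score >= gamma", {
  withr::local_seed(90)
  P <- random_sim(5)
  DP <- matrix(rbinom(15, 1, 0.4), 5, 3,
               dimnames = list(rownames(P), sprintf("d%d", 1:3)))
  S <- random_sim(3, colnames(DP))
  base <- katz_score(P, DP, S, 0.01, 2)
  zero <- which(DP == 0, arr.ind = TRUE)
  for (r in seq_len(min(4, nrow(zero)))) {
    DP2 <- DP
    DP2[zero[r, 1], zero[r, 2]] <- 1
    bumped <- katz_score(P, DP2, S, 0.01, 2)
    expect_true(all(bumped - base >= -1e-15))
  }
  known <- which(DP == 1)
  expect_true(all(base[known] >= 0.01))
})

test_that("structured and dense pair similarities give identical scores", {
  withr::local_seed(12)
  l <- random_sim(4, sprintf("l%d", 1:4))
  m <- random_sim(3, sprintf("m%d", 1:3))
  DP <- matrix(rbinom(24, 1, 0.4), 12, 2,
               dimnames = list(NULL, c("d1", "d2")))
  S <- random_sim(2, colnames(DP))
  for (method in c("average", "sqrt")) {
    dense <- lmpair_similarity(l, m, method = method, materialize = TRUE)
    struct <- lmpair_similarity(l, m, method = method, materialize = FALSE)
    for (K in c(2, 5)) {
      expect_equal(unname(katz_score(dense, DP, S, 0.05, K, engine = "power")),
                   unname(katz_score(struct, DP, S, 0.05, K, engine = "power")),
                   tolerance = 1e-12)
    }
    expect_equal(unname(katz_score(dense, DP, S, 0.05, 2, engine = "closed_form")),
                 unname(katz_score(struct, DP, S, 0.05, 2, engine = "closed_form")),
                 tolerance = 1e-12)
  }
})

test_that("prediction ranking is deterministic and monotone-invariant", {
  m <- small_model()
  S <- katz_score(m$pair_sim, m$network$DP, m$dis_sim)
  preds <- rank_predictions(S, m$network)
  expect_equal(nrow(preds), nrow(m$network$pairs) * length(m$network$diseases))
  expect_true(all(diff(preds$score) <= 0))
  expect_equal(preds$rank, seq_len(nrow(preds)))
  expect_equal(sum(preds$known), sum(m$network$DP))

  # monotone transform leaves the ranking unchanged
  preds2 <- rank_predictions(log1p(S * 10), m$network)
  expect_equal(preds2[, c("disease_id", "lncRNA_id", "miRNA_id")],
               preds[, c("disease_id", "lncRNA_id", "miRNA_id")])

  # ties broken by disease index then pair index
  Sflat <- matrix(0.5, 2, 2, dimnames = list(c("p1", "p2"), c("d1", "d2")))
  net <- list(pairs = tibble::tibble(pair_id = c("p1", "p2"),
                                     lncRNA = c("l1", "l2"),
                                     miRNA = c("m1", "m1")),
              diseases = c("d1", "d2"),
              DP = matrix(0L, 2, 2))
  class(net) <- "dlm_network"
  tied <- rank_predictions(Sflat, net)
  expect_equal(tied$disease_id, c("d1", "d1", "d2", "d2"))
  expect_equal(tied$lncRNA_id, c("l1", "l2", "l1", "l2"))
})
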