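test_that("threshold-sweep AUC equals the pairwise comparison statistic", {
  r <- roc_auc(c(2, 3), c(0, 1))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(1, 5), rep(1, 7))$auc, 0.5)
  expect_error(roc_auc(numeric(), 1:3), "non-empty")

  withr::local_seed(19)
  for (i in 1:10) {
    pos <- sample(0:5, 20, replace = TRUE) + rnorm(20, sd = 0.3)
    neg <- sample(0:5, 30, replace = TRUE) + rnorm(30, sd = 0.3)
    r <- roc_auc(pos, neg)
    expect_equal(r$auc, oracle_auc(pos, neg), tolerance = 1e-12)
    # the trapezoidal area under the sweep curve is the same number
    trap <- sum(diff(r$roc$fpr) * (utils::head(r$roc$tpr, -1) +
                                     utils::tail(r$roc$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12)
    # curve shape
    expect_equal(unlist(r$roc[1, c("fpr", "tpr")], use.names = FALSE), c(0, 0))
    expect_equal(unlist(r$roc[nrow(r$roc), c("fpr", "tpr")], use.names = FALSE),
                 c(1, 1))
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC library", {
  withr::local_seed(47)
  for (i in 1:5) {
    pos <- rnorm(25, mean = 0.5)
    neg <- rnorm(40)
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(
        response = c(rep(1, 25), rep(0, 40)),
        predictor = c(pos, neg), direction = "<"
      )))
    )
    expect_equal(roc_auc(pos, neg)$auc, ref, tolerance = 1e-12)
  }
})

test_that("percentile ranking of random scores is centred on one half", {
  withr::local_seed(23)
  aucs <- replicate(20, {
    pos <- runif(40)
    cand <- runif(400)
    mean(lmpairnet:::percentile_in(pos, cand))
  })
  expect_true(all(aucs > 0.40 & aucs < 0.60))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # exact tie handling
  expect_equal(lmpairnet:::percentile_in(1, c(0, 1, 1, 2)), (1 + 0.5 * 2) / 4)
})

test_that("a held-out known association outranks a never-associated cell", {
  # pair (l1, m1) is linked to the sibling diseases d1 and d2; pair
  # (l2, m1) only to the unrelated root d3. Holding out (l1|m1, d1), its
  # remaining walk through d2 should beat the candidate cell (l2|m1, d1).
  ld <- association_table(data.frame(l = c("l1", "l1", "l2"),
                                     d = c("d1", "d2", "d3")),
                          "lncRNA-disease")
  md <- association_table(data.frame(m = c("m1", "m1", "m1"),
                                     d = c("d1", "d2", "d3")),
                          "miRNA-disease")
  lm <- association_table(data.frame(l = c("l1", "l2"), m = c("m1", "m1")),
                          "lncRNA-miRNA")
  dag <- disease_dag(data.frame(child = c("d1", "d2", "d3"),
                                parent = c("r", "r", "-")))
  m <- lmpair_model(ld, md, lm, dag)
  DPm <- m$network$DP
  i <- match("l1|m1", rownames(DPm))
  j <- match("d1", colnames(DPm))
  DPm[i, j] <- 0L
  S <- katz_score(m$pair_sim, DPm, m$dis_sim)
  candidate <- rownames(DPm)[m$network$DP[, j] == 0L]
  expect_gt(S[i, j], max(S[candidate, j]))
})

test_that("masking a test edge removes its direct walk contribution", {
  m <- small_model()
  S_train <- katz_score(m$pair_sim, m$network$DP, m$dis_sim)
  known <- which(m$network$DP == 1L, arr.ind = TRUE)
  for (r in 1:5) {
    DPm <- m$network$DP
    DPm[known[r, 1], known[r, 2]] <- 0L
    S_test <- katz_score(m$pair_sim, DPm, m$dis_sim)
    expect_lt(S_test[known[r, 1], known[r, 2]],
              S_train[known[r, 1], known[r, 2]])
  }
})

test_that("leave-one-out recovers planted structure well above chance", {
  m <- small_model()
  cv <- loocv(m$network, m$pair_sim, m$dis_sim)
  expect_s3_class(cv, "lmpair_cv")
  expect_gt(cv$mean_auc, 0.6)
  expect_equal(length(cv$percentiles), sum(m$network$DP))
  expect_true(all(cv$percentiles >= 0 & cv$percentiles <= 1))
  # ROC bookkeeping
  expect_equal(unlist(cv$roc_points[1, c("fpr", "tpr")], use.names = FALSE),
               c(0, 0))
  expect_equal(unlist(cv$roc_points[nrow(cv$roc_points), c("fpr", "tpr")],
                      use.names = FALSE), c(1, 1))
  expect_true(all(diff(cv$roc_points$fpr) >= 0))
  expect_true(all(diff(cv$roc_points$tpr) >= 0))
})

test_that("k-fold is seed-deterministic and degenerates to leave-one-out at k = n", {
  m <- small_model()
  n <- sum(m$network$DP)
  cv1 <- kfold_cv(m$network, m$pair_sim, m$dis_sim, k = 5, repeats = 3, seed = 9)
  cv2 <- kfold_cv(m$network, m$pair_sim, m$dis_sim, k = 5, repeats = 3, seed = 9)
  expect_identical(cv1$per_repeat_auc, cv2$per_repeat_auc)
  expect_equal(length(cv1$per_repeat_auc), 3L)
  expect_false(is.na(cv1$std_auc))

  cvn <- kfold_cv(m$network, m$pair_sim, m$dis_sim, k = n, repeats = 1, seed = 9)
  cvl <- loocv(m$network, m$pair_sim, m$dis_sim)
  expect_equal(sort(cvn$percentiles), sort(cvl$percentiles), tolerance = 1e-12)
  expect_equal(cvn$mean_auc, cvl$mean_auc, tolerance = 1e-12)

  expect_error(kfold_cv(m$network, m$pair_sim, m$dis_sim, k = n + 1), "k must")
})

test_that("strict masking recomputes similarities and needs the model", {
  m <- small_model()
  expect_error(loocv(m$network, m$pair_sim, m$dis_sim, strict_masking = TRUE),
               "model")
  cv_soft <- kfold_cv(m$network, m$pair_sim, m$dis_sim, k = 4, repeats = 1,
                      seed = 3)
  cv_strict <- kfold_cv(m$network, m$pair_sim, m$dis_sim, k = 4, repeats = 1,
                        seed = 3, model = m, strict_masking = TRUE)
  # same partitions, different (recomputed-similarity) scores
  expect_equal(length(cv_strict$percentiles), length(cv_soft$percentiles))
  expect_false(isTRUE(all.equal(cv_strict$percentiles, cv_soft$percentiles)))
})

test_that("cross-validation tidiers and plots expose the summaries", {
  m <- small_model()
  cv <- kfold_cv(m$network, m$pair_sim, m$dis_sim, k = 4, repeats = 2, seed = 5)
  td <- tidy(cv)
  expect_equal(nrow(td), 2L)
  expect_equal(td$auc, cv$per_repeat_auc)
  gl <- glance(cv)
  expect_equal(gl$mean_auc, mean(cv$per_repeat_auc))
  expect_equal(gl$k, 4)
  expect_s3_class(autoplot(cv), "ggplot")
})
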