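test_that("generation is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_diseases = 8, n_lncRNAs = 9, n_miRNAs = 7,
                          n_communities = 2, seed = 42)
  d1 <- generate_lmpair_data(cfg)
  d2 <- generate_lmpair_data(cfg)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_synthetic_dataset(d1, dir1)
  write_synthetic_dataset(d2, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }
  d3 <- generate_lmpair_data(synthetic_config(n_diseases = 8, n_lncRNAs = 9,
                                              n_miRNAs = 7, n_communities = 2,
                                              seed = 43))
  expect_false(identical(as.data.frame(d1$lnc_disease),
                         as.data.frame(d3$lnc_disease)))
})

test_that("the saturated one-community case yields every possible triangle", {
  cfg <- synthetic_config(n_diseases = 4, n_lncRNAs = 3, n_miRNAs = 3,
                          n_communities = 1, p_within = 1, p_between = 0,
                          p_lm_within = 1, p_lm_between = 0, seed = 1)
  dat <- generate_lmpair_data(cfg)
  tri <- build_tripartite(build_bipartite(dat$lnc_disease),
                          build_bipartite(dat$mir_disease),
                          build_bipartite(dat$lnc_mir))
  expect_equal(nrow(tri$triangles), 4 * 3 * 3)
})

test_that("within-community edge frequency matches the configured probability", {
  cfg <- synthetic_config(n_diseases = 40, n_lncRNAs = 50, n_miRNAs = 40,
                          n_communities = 2, p_within = 0.5, p_between = 0.05,
                          seed = 5)
  dat <- generate_lmpair_data(cfg)
  gt <- dat$ground_truth
  comm <- function(id) gt$community[match(id, gt$id)]
  # within-community lncRNA-disease cells: n >= 1000 Bernoulli draws
  cl <- comm(attr(dat$lnc_disease, "left_ids"))
  n_within <- sum(outer(comm(sprintf("l%02d", 1:50)),
                        comm(sprintf("d%02d", 1:40)), `==`))
  hits <- sum(comm(dat$lnc_disease$lncRNA) == comm(dat$lnc_disease$disease))
  p_hat <- hits / n_within
  se <- sqrt(0.5 * 0.5 / n_within)
  expect_gte(n_within, 1000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("the hierarchy aligns with communities and covers every disease", {
  cfg <- synthetic_config(seed = 42)
  dat <- generate_lmpair_data(cfg)
  expect_true(all(sprintf("d%02d", 1:30) %in% dat$dag$nodes))
  expect_equal(dat$dag$roots, "root")
  # two diseases of the same community are more semantically similar on
  # average than two diseases of different communities
  s <- semantic_similarity_matrix(dat$dag, sprintf("d%02d", 1:30))
  gt <- dat$ground_truth[dat$ground_truth$type == "disease", ]
  same <- outer(gt$community, gt$community, `==`) & upper.tri(s)
  diff_ <- (!outer(gt$community, gt$community, `==`)) & upper.tri(s)
  expect_gt(mean(s[same]), mean(s[diff_]))

  rnd <- generate_lmpair_data(synthetic_config(n_diseases = 12, n_lncRNAs = 12,
                                               n_miRNAs = 12, dag_mode = "random",
                                               seed = 2))
  expect_true(all(sprintf("d%02d", 1:12) %in% rnd$dag$nodes))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(p_within = 0.2, p_between = 0.5), "not exceed")
  expect_error(synthetic_config(n_communities = 50), "n_communities")
  expect_error(synthetic_config(p_within = 1.2), "probabilities")
  # equality is allowed: the structureless null is a supported condition
  expect_s3_class(synthetic_config(p_within = 0.3, p_between = 0.3),
                  "synthetic_config")
  # impossible triangle demand fails with advice
  cfg <- synthetic_config(n_diseases = 3, n_lncRNAs = 3, n_miRNAs = 3,
                          n_communities = 1, p_within = 0.01, p_between = 0,
                          p_lm_within = 0.01, p_lm_between = 0, seed = 1)
  expect_error(generate_lmpair_data(cfg, max_retries = 2), "triangle")
})

test_that("generated tables satisfy the ingestion round-trip invariants", {
  cfg <- synthetic_config(n_diseases = 6, n_lncRNAs = 8, n_miRNAs = 7,
                          n_communities = 2, seed = 77)
  dat <- generate_lmpair_data(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(dat, dir)
  for (spec in list(list(f = "lnc_disease.tsv", k = "lncRNA-disease", obj = dat$lnc_disease),
                    list(f = "mir_disease.tsv", k = "miRNA-disease", obj = dat$mir_disease),
                    list(f = "lnc_mir.tsv", k = "lncRNA-miRNA", obj = dat$lnc_mir))) {
    back <- read_association_table(file.path(dir, spec$f), spec$k)
    expect_equal(as.data.frame(back), as.data.frame(spec$obj), info = spec$f)
  }
  dag_back <- read_disease_dag(file.path(dir, "disease_dag.tsv"))
  expect_setequal(dag_back$nodes, dat$dag$nodes)
})
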