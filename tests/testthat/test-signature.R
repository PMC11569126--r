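test_that("super-samples are observed-only group means in label order", {
  v <- mat_with_names(matrix(c(2, 4, 1, 3,
                               2, NA, 5, 7), 2, 4, byrow = TRUE))
  m <- omics_matrix(v, space = "linear")
  g <- toy_labels(colnames(v), c("A", "A", "B", "B"))
  ss <- supersample(m, g)
  expect_equal(colnames(ss), c("A", "B"))
  expect_equal(unname(ss["g01", ]), c(3, 2))
  expect_equal(unname(ss["g02", "A"]), 2)       # observed-only mean

  # a group with all values missing for a gene -> gene dropped with warning
  v2 <- mat_with_names(matrix(c(1, 2, NA, NA,
                                1, 2, 3, 4), 2, 4, byrow = TRUE))
  m2 <- omics_matrix(v2, space = "linear")
  expect_warning(ss2 <- supersample(m2, g), "dropped")
  expect_equal(rownames(ss2), "g02")

  expect_error(supersample(m, toy_labels(colnames(v),
                                         c("A", "A", "A", "A"))),
               "two groups")
})

test_that("cosine scores reproduce the hand-computed reference cases", {
  X <- mat_with_names(matrix(c(1, 0, 0,
                               0, 1, 1,
                               1, 1, 1), 3, 3, byrow = TRUE),
                      c("sg1", "dsg1", "flat"), c("G1", "G2", "G3"))
  sg <- cosine_scores(as_supersample(X), "SG")
  expect_equal(sg$score[sg$gene_id == "sg1"], 1)
  expect_equal(sg$assigned_group[sg$gene_id == "sg1"], "G1")

  dsg <- cosine_scores(as_supersample(X), "DSG")
  expect_equal(dsg$score[dsg$gene_id == "dsg1"], 1)
  expect_equal(dsg$assigned_group[dsg$gene_id == "dsg1"], "G1")
  # uniform profile: cos((1,1,1),(0,1,1)) = 2 / (sqrt(3) sqrt(2))
  expect_equal(dsg$score[dsg$gene_id == "flat"], sqrt(2 / 3),
               tolerance = 1e-12)
  # ideal SG attains the DSG lower bound 1/sqrt(K-1)
  expect_equal(dsg$score[dsg$gene_id == "sg1"], 1 / sqrt(2),
               tolerance = 1e-12)

  # all-zero profile excluded with a flag
  X0 <- rbind(X, zero = c(0, 0, 0))
  expect_warning(s0 <- cosine_scores(as_supersample(X0), "DSG"),
                 "all-zero")
  expect_equal(attr(s0, "excluded"), "zero")
  expect_false("zero" %in% s0$gene_id)
})

test_that("cosine statistic is scale-invariant and permutation-equivariant", {
  set.seed(21)
  for (K in 3:5) {
    X <- matrix(abs(stats::rnorm(60 * K)), 60, K)
    dimnames(X) <- list(sprintf("g%02d", 1:60), paste0("G", 1:K))
    base <- cosine_scores(as_supersample(X), "DSG")
    scaled <- cosine_scores(as_supersample(X * 7.3), "DSG")
    expect_equal(scaled$score, base$score, tolerance = 1e-12)
    # per-gene scaling too (row-wise magnitudes cancel)
    rows <- X * stats::runif(60, 0.1, 10)
    dimnames(rows) <- dimnames(X)
    rowsc <- cosine_scores(as_supersample(rows), "DSG")
    expect_equal(rowsc$score[match(base$gene_id, rowsc$gene_id)],
                 base$score, tolerance = 1e-12)
    # permuting the group columns permutes assignments, scores unchanged
    perm <- sample(K)
    Xp <- X[, perm]
    permuted <- cosine_scores(as_supersample(Xp), "DSG")
    ord <- match(base$gene_id, permuted$gene_id)
    expect_equal(permuted$score[ord], base$score, tolerance = 1e-12)
    expect_equal(permuted$assigned_group[ord], base$assigned_group)
  }
})

test_that("DSG and SG scores respect their theoretical ranges", {
  set.seed(77)
  for (K in 3:5) {
    X <- matrix(abs(stats::rnorm(2000 * K)) + 1e-9, 2000, K)
    dimnames(X) <- list(sprintf("g%04d", 1:2000), paste0("G", 1:K))
    dsg <- cosine_scores(as_supersample(X), "DSG")
    expect_true(all(dsg$score >= 1 / sqrt(K - 1) - 1e-12))
    expect_true(all(dsg$score <= 1 + 1e-12))
    sg <- cosine_scores(as_supersample(X), "SG")
    expect_true(all(sg$score >= 1 / sqrt(K) - 1e-12))
    expect_true(all(sg$score <= 1 + 1e-12))
  }
})

test_that("empirical-null p-values are self-inclusive upper-tail proportions", {
  X <- mat_with_names(matrix(abs(stats::rnorm(400 * 3)), 400, 3),
                      samples = c("G1", "G2", "G3"))
  tab <- cosine_scores(as_supersample(X), "DSG")
  tab <- empirical_null_pvalues(tab)
  expect_equal(tab$p_value[1], 1 / 400)        # unique max
  expect_equal(max(tab$p_value), 1)
  expect_true(all(tab$q_value >= tab$p_value - 1e-12))

  # identical scores -> everything p = 1
  same <- cosine_scores(as_supersample(
    mat_with_names(matrix(1, 150, 3), samples = c("G1", "G2", "G3"))), "DSG")
  same <- suppressWarnings(empirical_null_pvalues(same))
  expect_true(all(same$p_value == 1))

  # null-only design: p-values uniform on {1/N, ..., 1}
  cfg <- simplex_sim_config(K = 3, n_sg_per_group = 0, n_dsg_per_group = 0,
                            seed = 19)
  sim <- simulate_simplex_profiles(cfg)
  nt <- empirical_null_pvalues(cosine_scores(as_supersample(sim$profiles),
                                             "DSG"))
  ks <- suppressWarnings(stats::ks.test(nt$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("OVR Welch t scores match stats::t.test and flip with direction", {
  v <- mat_with_names(matrix(c(0.0, 0.1, 5.0, 5.1, 4.9, 5.2), 1, 6))
  m <- omics_matrix(v, space = "log2")
  g <- toy_labels(colnames(v), c("A", "A", "B", "B", "B", "B"))
  dsg <- ovr_ttest_scores(m, g, "DSG")
  oracle <- stats::t.test(v[1, 1:2], v[1, 3:6])  # Welch by default
  expect_equal(dsg$score[1], -unname(oracle$statistic), tolerance = 1e-10)
  expect_gt(dsg$score[1], 10)
  expect_equal(dsg$assigned_group[1], "A")
  sg <- ovr_ttest_scores(m, g, "SG")
  # two groups: the optimal SG hypothesis is the mirror of the DSG one
  expect_equal(sg$score[1], -unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(sg$assigned_group[1], "B")

  # identical groups -> t ~ 0
  v2 <- mat_with_names(matrix(rep(c(1, 2), 3), 1, 6))
  m2 <- omics_matrix(v2, space = "log2")
  t2 <- ovr_ttest_scores(m2, g, "DSG")
  expect_equal(t2$score[1], 0, tolerance = 1e-10)
})

test_that("OVR fold change shows the failure mode eCOT avoids", {
  # two groups silent, one loud: OVR-FC flags group 1 as a huge DSG,
  # but its eCOT score is the non-ideal lower bound 1/sqrt(2)
  X <- mat_with_names(matrix(c(0, 0, 6), 1, 3),
                      "g1", c("G1", "G2", "G3"))
  v <- X[, rep(1:3, each = 2), drop = FALSE]
  colnames(v) <- sprintf("s%d", 1:6)
  m <- omics_matrix(v, space = "linear")
  g <- toy_labels(colnames(v), rep(c("G1", "G2", "G3"), each = 2))
  fc <- ovr_fc_scores(m, g, "DSG", pseudocount = 1e-9)
  expect_gt(fc$score[1], 1e6)                   # rest mean 3 over ~0
  expect_equal(fc$assigned_group[1], "G1")
  ec <- cosine_scores(supersample(m, g), "DSG")
  expect_equal(ec$score[1], 1 / sqrt(2), tolerance = 1e-12)

  # plain ratio case and flat gene
  v2 <- mat_with_names(matrix(c(0.5, 0.5, 4, 4, 4, 4), 1, 6),
                       "g1", sprintf("s%d", 1:6))
  m2 <- omics_matrix(v2, space = "linear")
  g2 <- toy_labels(colnames(v2), c("A", "A", "B", "B", "C", "C"))
  fc2 <- ovr_fc_scores(m2, g2, "DSG", pseudocount = 0)
  expect_equal(fc2$score[1], 4 / 0.5)
  flat <- ovr_fc_scores(omics_matrix(
    mat_with_names(matrix(2, 1, 6), "g1", sprintf("s%d", 1:6)),
    space = "linear"), g2, "DSG", pseudocount = 0)
  expect_equal(flat$score[1], 1)
})

test_that("detection rules filter and order score tables", {
  X <- mat_with_names(matrix(c(1, 0, 0,
                               0, 1, 1,
                               0.1, 1, 1,
                               1, 1, 1), 4, 3, byrow = TRUE),
                      c("a", "b", "c", "d"), c("G1", "G2", "G3"))
  tab <- empirical_null_pvalues(
    suppressWarnings(cosine_scores(as_supersample(X), "DSG")),
    min_genes = 0)
  expect_equal(nrow(detect(tab, "top_n", 0)), 0L)
  only_ideal <- detect(tab, "score_min", 1.0)
  expect_equal(only_ideal$gene_id, "b")
  full <- detect(tab, "top_n", nrow(tab))
  expect_setequal(full$gene_id, tab$gene_id)
  # within a group, scores descend
  grp1 <- full[full$assigned_group == "G1", ]
  expect_true(all(diff(grp1$score) <= 0))
  expect_error(detect(tab, "nope", 1))
})
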