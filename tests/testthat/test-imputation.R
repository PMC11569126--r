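test_that("complete-gene normalization median-matches samples", {
  # complete genes: sample medians 5 and 7, grand median 6
  v <- mat_with_names(matrix(c(4, 6,
                               5, 7,
                               6, 8,
                               9, NA), 4, 2, byrow = TRUE))
  m <- omics_matrix(v, space = "log2")
  norm <- normalize_complete_genes(m)
  expect_equal(unname(attr(norm, "offsets")), c(1, -1))
  expect_equal(norm$values[1:3, 1], c(5, 6, 7), ignore_attr = TRUE)
  expect_true(is.na(norm$values[4, 2]))         # masked cell untouched

  # already aligned -> zero offsets
  v2 <- mat_with_names(matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE))
  expect_equal(unname(attr(normalize_complete_genes(
    omics_matrix(v2, space = "log2")), "offsets")), c(0, 0))

  # no complete gene -> instructive error
  v3 <- mat_with_names(matrix(c(1, NA, NA, 2), 2, 2))
  expect_error(normalize_complete_genes(omics_matrix(v3, space = "log2")),
               "pre-normalize")
})

test_that("epsilon is the minimum observed log-space value", {
  v <- mat_with_names(matrix(c(3.2, 5.0, 7.1, -100), 2, 2))
  mask <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
  dimnames(mask) <- dimnames(v)
  m <- omics_matrix(v, mask = mask, space = "log2")
  expect_equal(estimate_epsilon(m), 3.2)        # masked -100 excluded
  vc <- mat_with_names(matrix(2.5, 2, 2))
  expect_equal(estimate_epsilon(omics_matrix(vc, space = "log2")), 2.5)
})

test_that("group model matches a numeric normal-CDF oracle", {
  # gene A, group A: values {4, 6} -> mean 5, sd sqrt(2)
  v <- mat_with_names(matrix(c(4, 6, NA,
                               2, 2, 2), 2, 3, byrow = TRUE))
  m <- omics_matrix(v, space = "log2")
  g <- toy_labels(colnames(v), c("A", "A", "B"))
  mod <- fit_group_model(m, g)
  expect_equal(mod$group_mean["g01", "A"], 5)
  expect_equal(mod$group_sd["g01", "A"], sqrt(2))
  expect_equal(mod$epsilon, 2)
  # gene fully missing in a group -> alpha = 1
  expect_equal(mod$llod_prob["g01", "B"], 1)

  # alpha = Phi((eps - mean)/sd): eps 2, mean 6, sd 2 -> Phi(-2)
  vv <- mat_with_names(matrix(c(6 - sqrt(2), 6 + sqrt(2), NA,
                                2, 2.5, 2.2), 2, 3, byrow = TRUE))
  mm <- omics_matrix(vv, space = "log2")
  gg <- toy_labels(colnames(vv), c("A", "A", "B"))
  mod2 <- fit_group_model(mm, gg)
  expect_equal(mod2$group_sd["g01", "A"], 2, tolerance = 1e-12)
  # independent oracle: numeric integration of the normal density
  oracle <- stats::integrate(stats::dnorm, -Inf, (2 - 6) / 2)$value
  a <- stats::pnorm((mod2$epsilon - 6) / 2)
  expect_equal(a, oracle, tolerance = 1e-6)
  expect_equal(oracle, 0.02275, tolerance = 1e-4)
})

test_that("MGpI fill obeys its limiting forms and the hand-computed case", {
  # gene g01, group A observed {6 - sqrt(2), 6 + sqrt(2)}: mean 6, sd 2;
  # global eps = 2 comes from gene g02
  v <- mat_with_names(matrix(c(6 - sqrt(2), 6 + sqrt(2), NA, 7,
                               2, 2.4, 2.2, 2.3), 2, 4, byrow = TRUE))
  m <- omics_matrix(v, space = "log2")
  g <- toy_labels(colnames(v), c("A", "A", "A", "B"))
  res <- mgpi_impute(m, g, normalize = "never")
  alpha <- stats::pnorm((2 - 6) / 2)
  expect_equal(res$matrix$values["g01", 3],
               alpha * 1 + (1 - alpha) * 6, tolerance = 1e-12)
  expect_equal(res$matrix$values["g01", 3], 5.8863, tolerance = 1e-4)

  # alpha ~ 0: mean far above eps -> fill = group mean
  v0 <- mat_with_names(matrix(c(50, 50.1, NA, 50.2,
                                0.9, 1.1, 1.0, 1.2), 2, 4, byrow = TRUE))
  m0 <- omics_matrix(v0, space = "log2")
  r0 <- mgpi_impute(m0, g, normalize = "never")
  expect_equal(r0$matrix$values["g01", 3], mean(c(50, 50.1)),
               tolerance = 1e-6)

  # alpha = 1 (group fully missing) -> fill = eps / 2
  v1 <- mat_with_names(matrix(c(NA, NA, 5, 6,
                                4, 5, 4.5, 5.5), 2, 4, byrow = TRUE))
  g2 <- toy_labels(colnames(v1), c("A", "A", "B", "B"))
  m1 <- omics_matrix(v1, space = "log2")
  r1 <- mgpi_impute(m1, g2, normalize = "never")
  expect_equal(unname(r1$matrix$values["g01", 1:2]), rep(4 / 2, 2)) # eps = 4
  # and the linear-min reading: eps - 1 in log2
  r1b <- mgpi_impute(m1, g2, llod_fill = "log_of_half_linear_min",
                     normalize = "never")
  expect_equal(unname(r1b$matrix$values["g01", 1]), 4 - 1)
})

test_that("MGpI fill lies between eps/2 and the group mean, monotone in alpha", {
  eps <- 2
  xbar <- 6
  alphas <- seq(0, 1, by = 0.05)
  fills <- alphas * eps / 2 + (1 - alphas) * xbar
  expect_true(all(fills >= eps / 2 - 1e-12 & fills <= xbar + 1e-12))
  expect_true(all(diff(fills) < 0))   # decreasing when xbar > eps/2
  # realized on data: more censoring (lower group mean) pulls the fill down
  v <- mat_with_names(rbind(c(10, 11, NA, 8),
                            c(3, 4, NA, 8),
                            c(2, 9, 2.5, 8)))
  m <- omics_matrix(v, space = "log2")
  g <- toy_labels(colnames(v), c("A", "A", "A", "B"))
  r <- mgpi_impute(m, g, normalize = "never")
  expect_gt(r$matrix$values["g01", 3], r$matrix$values["g02", 3])
  fillA <- r$matrix$values["g01", 3]
  fillB <- r$matrix$values["g02", 3]
  expect_true(fillA <= 10.5 && fillA >= 1)   # within [eps/2, group mean]
  expect_true(fillB <= 3.5 && fillB >= 1)
})

test_that("MGpI is group-aware: SG fills track the high group, floor elsewhere", {
  # SG high in group A, near-floor in B and C
  set.seed(5)
  high <- stats::rnorm(6, 12, 0.3)
  low <- stats::rnorm(12, 1.05, 0.05)
  v <- mat_with_names(rbind(c(high, low),
                            stats::rnorm(18, 6, 1)),
                      c("sg", "bg"), sprintf("s%02d", 1:18))
  mask <- matrix(FALSE, 2, 18, dimnames = dimnames(v))
  mask["sg", c(2, 8, 14)] <- TRUE     # one missing cell per group
  m <- omics_matrix(v, mask = mask, space = "log2")
  g <- toy_labels(colnames(v), rep(c("A", "B", "C"), each = 6))
  r <- mgpi_impute(m, g, normalize = "never")
  model <- r$params$model
  eps <- model$epsilon
  fillA <- r$matrix$values["sg", 2]
  fillB <- r$matrix$values["sg", 8]
  expect_lt(abs(fillA - model$group_mean["sg", "A"]), 0.01) # alpha ~ 0
  expect_lt(abs(fillB - eps / 2), 0.6)                      # near floor fill
  expect_gt(fillA, fillB + 5)
})

test_that("every imputation method returns observed cells bit-identically", {
  m <- random_masked_matrix(25, 12, 0.2, seed = 9)
  g <- random_labels(m, 2)
  obs <- !m$mask
  for (method in c("mgpi", "min2", "mean", "swknn", "ppca", "nipals",
                   "svd", "svt")) {
    args <- c(list(m = m, method = method, g = g),
              if (method == "ppca") list(seed = 1))
    r <- suppressWarnings(do.call(impute_matrix, args))
    expect_identical(r$matrix$values[obs], m$values[obs],
                     label = paste(method, "observed cells"))
    expect_false(any(r$matrix$mask), label = paste(method, "mask cleared"))
  }
})

test_that("half-minimum and mean fills follow their definitions", {
  v <- mat_with_names(matrix(c(4, 8, NA,
                               0.5, NA, NA,
                               1, 2, 3), 3, 3, byrow = TRUE))
  m <- omics_matrix(v, space = "linear")
  r <- halfmin_impute(m)
  expect_equal(r$matrix$values["g01", 3], 2)
  expect_equal(unname(r$matrix$values["g02", 2:3]), c(0.25, 0.25))
  expect_equal(r$matrix$values["g03", ], v["g03", ])   # no missing: identity

  vl <- mat_with_names(matrix(c(4, 8, NA, 3, NA, NA), 2, 3, byrow = TRUE))
  ml <- omics_matrix(vl, space = "log2")
  rm <- mean_impute(ml)
  expect_equal(rm$matrix$values["g01", 3], 6)
  expect_equal(rm$matrix$values["g02", 2], 3)   # single observed value

  vb <- mat_with_names(matrix(c(NA, NA, 1, 2), 2, 2, byrow = TRUE))
  expect_error(mean_impute(omics_matrix(vb, space = "log2")),
               "no observed value")
})

test_that("swknn uses co-observed distances, weights, and fallbacks", {
  # k = 1: fill equals the closest co-observed sample's value
  v <- mat_with_names(matrix(c(1, 1.1, 5,
                               2, 2.1, 6,
                               7, NA, 9), 3, 3, byrow = TRUE))
  m <- omics_matrix(v, space = "log2")
  r <- swknn_impute(m, k = 1)
  expect_equal(r$matrix$values["g03", 2], 7)    # s1 is nearest to s2

  # two equidistant neighbours with values 2 and 4 -> fill 3
  v2 <- mat_with_names(matrix(c(0, 1, -1,
                                0, 1, -1,
                                NA, 2, 4), 3, 3, byrow = TRUE))
  m2 <- omics_matrix(v2, space = "log2")
  r2 <- swknn_impute(m2, k = 2)
  expect_equal(r2$matrix$values["g03", 1], 3)

  # duplicated sample dominates as distance -> 0
  v3 <- mat_with_names(matrix(c(1, 1, 9,
                                2, 2, 8,
                                NA, 5, 100), 3, 3, byrow = TRUE))
  m3 <- omics_matrix(v3, space = "log2")
  r3 <- swknn_impute(m3, k = 2)
  expect_equal(r3$matrix$values["g03", 1], 5, tolerance = 1e-4)

  # no co-observed features between s1 and the only donor -> gene-mean fallback
  v4 <- mat_with_names(matrix(c(1, 2, NA,
                                NA, NA, 4,
                                NA, 5, 6), 3, 3, byrow = TRUE))
  m4 <- omics_matrix(v4, space = "log2")
  expect_message(r4 <- swknn_impute(m4, k = 1), "fell back")
  expect_equal(unname(r4$matrix$values["g02", 1:2]), c(4, 4))
  expect_error(swknn_impute(m4, k = 3), "smaller than the number of samples")
})

test_that("low-rank imputers recover a masked exact rank-1 matrix", {
  u <- c(1, 2, 3, 4, 5, 2.5)
  w <- c(2, 1, 4, 2, 3, 1.5, 5, 0.5)
  truth <- outer(u, w)
  v <- mat_with_names(truth)
  mask <- matrix(FALSE, 6, 8, dimnames = dimnames(v))
  mask[2, 3] <- TRUE
  m <- omics_matrix(v, mask = mask, space = "log2")
  rsvd <- lowrank_impute(m, "svd", rank = 1)
  expect_equal(rsvd$matrix$values[2, 3], truth[2, 3], tolerance = 1e-6)
  # nuclear-norm completion needs a sizeable threshold (~5 * sqrt(n*m))
  rsvt <- lowrank_impute(m, "svt", rank = 1, svt_tau = 50,
                         max_iter = 2000)
  expect_equal(rsvt$matrix$values[2, 3], truth[2, 3], tolerance = 1e-3)
  rppca <- lowrank_impute(m, "ppca", rank = 1, seed = 4)
  expect_equal(rppca$matrix$values[2, 3], truth[2, 3], tolerance = 0.05)
  rnip <- lowrank_impute(m, "nipals", rank = 1)
  expect_equal(rnip$matrix$values[2, 3], truth[2, 3], tolerance = 0.2)

  # no missing cells: identity for all four methods
  full <- omics_matrix(v, space = "log2")
  for (meth in c("ppca", "nipals", "svd", "svt")) {
    r <- lowrank_impute(full, meth, rank = 1, seed = 1)
    expect_identical(r$matrix$values, v, label = meth)
  }
  expect_error(lowrank_impute(m, "ppca", rank = 1), "seed")
})
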