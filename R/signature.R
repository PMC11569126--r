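#' @title Cosine-based one-sample signature tests (COT / eCOT)
#' @description A signature gene (SG) of group k is uniquely highly
#'   expressed in k and near-silent elsewhere; its ideal cross-group
#'   pattern is the Cartesian unit vector e_k. A downregulated signature
#'   gene (DSG) is uniquely silent in k and highly expressed in every other
#'   group; its ideal pattern is the XOR complement e_k XOR 1 (zero at k,
#'   one elsewhere). The test statistic is the cosine between a gene's
#'   group-averaged expression vector and the best-matching reference,
#'   maximized over the K enumerated hypotheses — a magnitude-invariant
#'   score in (0, 1].
#' @name signature_tests
NULL

#' Ideal SG / DSG reference vectors
#'
#' SG references are the K Cartesian unit vectors; DSG references are their
#' XOR complements with the all-ones vector (exactly one zero each), so
#' that each SG/DSG reference pair sums to the all-ones vector.
#'
#' @param K number of groups (>= 2).
#' @param direction `"SG"` or `"DSG"`.
#' @return A K x K matrix, one reference per row.
#' @export
signature_references <- function(K, direction = c("SG", "DSG")) {
  direction <- match.arg(direction)
  stopifnot(K >= 2)
  if (direction == "SG") diag(K) else 1 - diag(K)
}

#' Group-averaged super-sample matrix
#'
#' Collapses a linear-space expression matrix to one averaged "super
#' sample" per group: entry (i, k) is the mean of gene i's observed linear
#' values over the samples of group k. Genes for which some group has no
#' observed value are dropped with a warning (impute first to keep them).
#'
#' @param m an `omics_matrix`; log2 input is converted to linear first.
#' @param g a [group_labels()] object; every group must have >= 1 sample.
#' @param pseudo pseudo-count used if a log2 input must be converted.
#' @return A genes x K matrix (class `supersample_matrix`), columns in
#'   group order.
#' @export
supersample <- function(m, g, pseudo = 0) {
  stopifnot(inherits(m, "omics_matrix"), inherits(g, "group_labels"))
  work <- ensure_space(m, "linear", pseudo)
  grp <- match_labels(work, g)
  if (!all(g$groups %in% grp)) {
    empty <- setdiff(g$groups, grp)
    stop("group(s) with no sample: ", paste(empty, collapse = ", "))
  }
  v <- observed_values(work)
  st <- group_stats(v, grp, g$groups)
  prof <- st$mean
  bad <- rowSums(is.na(prof)) > 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) dropped: no observed value in some group")
    prof <- prof[!bad, , drop = FALSE]
  }
  structure(prof, class = c("supersample_matrix", "matrix", "array"))
}

# cosine of every row of X against every row of refs (rows unit-normalized)
cosine_to_refs <- function(X, refs) {
  xn <- sqrt(rowSums(X^2))
  rn <- sqrt(rowSums(refs^2))
  (X %*% t(refs)) / outer(xn, rn)
}

new_score_table <- function(gene_id, direction, assigned_group, score,
                            p_value = NA_real_) {
  out <- data.frame(gene_id = gene_id, direction = direction,
                    assigned_group = assigned_group, score = score,
                    p_value = p_value, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("signature_scores", "data.frame")
  out
}

#' COT / eCOT cosine scores against hypothesis-enumerated references
#'
#' For each gene, the statistic is the maximum over k of the cosine between
#' its group-averaged profile and the k-th SG (COT) or DSG (eCOT)
#' reference; the maximizing k is the assigned group (ties break to the
#' smallest group index). On nonnegative profiles the DSG statistic lies in
#' \eqn{[1/\sqrt{K-1}, 1]} and the SG statistic in \eqn{[1/\sqrt K, 1]}.
#' All-zero profiles have no direction and are excluded (recorded in
#' `attr(, "excluded")`).
#'
#' @param s a [supersample()] matrix (genes x K, nonnegative, linear space).
#' @param direction `"SG"` or `"DSG"`.
#' @return A `signature_scores` data.frame: gene_id, direction,
#'   assigned_group, score, p_value (NA until
#'   [empirical_null_pvalues()]), rank.
#' @export
cosine_scores <- function(s, direction = c("SG", "DSG")) {
  direction <- match.arg(direction)
  X <- unclass(s)
  stopifnot(is.matrix(X), ncol(X) >= 2)
  if (any(X < 0)) stop("super-sample profiles must be nonnegative")
  groups <- colnames(X)
  if (is.null(groups)) groups <- paste0("G", seq_len(ncol(X)))
  zero <- rowSums(X) == 0
  excluded <- rownames(X)[zero]
  if (any(zero)) {
    warning(sum(zero), " all-zero profile(s) excluded from scoring")
    X <- X[!zero, , drop = FALSE]
  }
  refs <- signature_references(ncol(X), direction)
  cs <- cosine_to_refs(X, refs)
  kstar <- max.col(cs, ties.method = "first")
  out <- new_score_table(rownames(X), direction, groups[kstar],
                         cs[cbind(seq_len(nrow(cs)), kstar)])
  attr(out, "excluded") <- excluded
  out
}

#' Empirical-null p-values for large-scale one-sample cosine testing
#'
#' Under the assumption that the large majority of genes follow the null,
#' the null distribution of the statistic is approximated by the empirical
#' histogram of all observed scores: the p-value of gene i is the
#' self-inclusive upper-tail proportion \eqn{\#\{j : t_j \ge t_i\} / N}
#' (never zero, conservative). Benjamini-Hochberg q-values are appended.
#'
#' @param scores a `signature_scores` table.
#' @param min_genes warn when fewer scores than this are available
#'   (default 100): the histogram is then a poor null estimate.
#' @return The table with `p_value` filled and `q_value` added.
#' @export
empirical_null_pvalues <- function(scores, min_genes = 100) {
  stopifnot(inherits(scores, "signature_scores"))
  n <- nrow(scores)
  if (n < min_genes)
    warning("only ", n, " scores: the empirical null may be unreliable")
  t <- scores$score
  # self-inclusive upper tail via ranking of -t
  scores$p_value <- vapply(t, function(ti) sum(t >= ti), 0) / n
  scores$q_value <- stats::p.adjust(scores$p_value, method = "BH")
  scores
}

# per-group / rest means, variances and counts in log space, vectorized
ovr_stats <- function(v, grp, groups) {
  st <- group_stats(v, grp, groups)
  n_tot <- rowSums(!is.na(v))
  s1_tot <- rowSums(v, na.rm = TRUE)
  s2_tot <- rowSums(v^2, na.rm = TRUE)
  K <- length(groups)
  rest <- list(n = st$n, mean = st$mean, var = st$mean)
  for (k in seq_len(K)) {
    nk <- st$n[, k]
    s1k <- ifelse(nk > 0, st$mean[, k] * nk, 0)
    sub <- v[, grp == groups[k], drop = FALSE]
    s2k <- rowSums(sub^2, na.rm = TRUE)
    nr <- n_tot - nk
    mr <- ifelse(nr > 0, (s1_tot - s1k) / nr, NA_real_)
    vr <- ifelse(nr > 1, pmax((s2_tot - s2k) - nr * mr^2, 0) / (nr - 1),
                 NA_real_)
    rest$n[, k] <- nr
    rest$mean[, k] <- mr
    rest$var[, k] <- vr
  }
  list(grp = st, rest = rest)
}

#' One-versus-rest Welch t-test scores
#'
#' The standard baseline: for each group k, a Welch two-sample t statistic
#' between group k and all remaining samples merged, computed on log2
#' values. The DSG score of a gene is \eqn{\max_k(-t_k)} (lower expression
#' in k is positive evidence); the SG score is \eqn{\max_k(+t_k)}. Cells
#' where both sides have zero variance give t = 0 (flagged via
#' `attr(, "zero_variance")` count).
#'
#' @param m an `omics_matrix`; linear input is log2-converted with `pseudo`.
#' @param g a [group_labels()] object; every group needs >= 2 samples.
#' @param direction `"SG"` or `"DSG"`.
#' @param pseudo pseudo-count for linear inputs.
#' @return A `signature_scores` table (p_value left NA; scores are t units).
#' @export
ovr_ttest_scores <- function(m, g, direction = c("SG", "DSG"), pseudo = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "omics_matrix"))
  work <- ensure_space(m, "log2", pseudo)
  grp <- match_labels(work, g)
  if (any(table(factor(grp, levels = g$groups)) < 2))
    stop("every group needs at least two samples for the OVR t-test")
  v <- observed_values(work)
  st <- ovr_stats(v, grp, g$groups)
  se2 <- st$grp$sd^2 / st$grp$n + st$rest$var / st$rest$n
  tmat <- (st$grp$mean - st$rest$mean) / sqrt(se2)
  zerovar <- !is.na(se2) & se2 == 0
  tmat[zerovar] <- 0
  tmat[is.na(tmat)] <- 0
  signed <- if (direction == "DSG") -tmat else tmat
  kstar <- max.col(signed, ties.method = "first")
  out <- new_score_table(rownames(v), direction, g$groups[kstar],
                         signed[cbind(seq_len(nrow(signed)), kstar)])
  attr(out, "zero_variance") <- sum(zerovar)
  out
}

#' One-versus-rest fold-change scores
#'
#' For each group k in linear space, the ratio of the mean expression in
#' the rest to the mean in group k (DSG direction) or group k over rest
#' (SG direction), stabilized by a pseudocount in the denominator; the
#' score is the max over k. Illustrates the classical failure mode: a low
#' rest-average does not mean the gene is low in every other group.
#'
#' @inheritParams ovr_ttest_scores
#' @param pseudocount added to the denominator; default 1e-6 x grand mean.
#' @return A `signature_scores` table (scores are ratios).
#' @export
ovr_fc_scores <- function(m, g, direction = c("SG", "DSG"),
                          pseudocount = NULL, pseudo = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "omics_matrix"))
  work <- ensure_space(m, "linear", pseudo)
  grp <- match_labels(work, g)
  v <- observed_values(work)
  if (is.null(pseudocount)) pseudocount <- 1e-6 * mean(v, na.rm = TRUE)
  st <- ovr_stats(v, grp, g$groups)
  ratio <- if (direction == "DSG") {
    st$rest$mean / (st$grp$mean + pseudocount)
  } else {
    st$grp$mean / (st$rest$mean + pseudocount)
  }
  ratio[is.na(ratio)] <- 0
  kstar <- max.col(ratio, ties.method = "first")
  new_score_table(rownames(v), direction, g$groups[kstar],
                  ratio[cbind(seq_len(nrow(ratio)), kstar)])
}

#' Filter a score table by a detection rule
#'
#' @param scores a `signature_scores` table.
#' @param rule `"top_n"` (keep the n best by score), `"score_min"` (keep
#'   scores >= value) or `"q_max"` (keep q-values <= value; requires
#'   [empirical_null_pvalues()] first).
#' @param value the rule's threshold.
#' @return The filtered table, sorted by score descending within assigned
#'   group (groups in their label order).
#' @export
detect <- function(scores, rule = c("top_n", "score_min", "q_max"), value) {
  rule <- match.arg(rule)
  stopifnot(inherits(scores, "signature_scores"))
  keep <- switch(rule,
    top_n = {
      n <- min(as.integer(value), nrow(scores))
      if (n <= 0) integer(0) else order(-scores$score,
                                        scores$gene_id)[seq_len(n)]
    },
    # 1e-12 float guard so ideal patterns pass an exact cutoff of 1.0
    score_min = which(scores$score >= value - 1e-12),
    q_max = {
      if (!"q_value" %in% names(scores))
        stop("q_max rule requires q-values; run empirical_null_pvalues() first")
      which(scores$q_value <= value)
    })
  out <- scores[keep, , drop = FALSE]
  grp_order <- match(out$assigned_group, unique(scores$assigned_group))
  out <- out[order(grp_order, -out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_scores", "data.frame")
  out
}
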