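#' @title Imputation and detection accuracy metrics
#' @description RMSE and NRMSE over the masked index set for imputation
#'   accuracy, partial ROC / pAUC at a false-positive-rate cutoff for
#'   detection accuracy, and the benchmark harnesses that tie simulators,
#'   methods and metrics together.
#' @name evaluation
NULL

imputed_values <- function(imputed) {
  if (inherits(imputed, "imputation_result")) imputed <- imputed$matrix
  stopifnot(inherits(imputed, "omics_matrix"))
  imputed$values
}

truth_positions <- function(v, truth) {
  rows <- match(truth$gene_id, rownames(v))
  cols <- match(truth$sample_id, colnames(v))
  if (anyNA(rows) || anyNA(cols))
    stop("truth table references positions absent from the imputed matrix")
  cbind(rows, cols)
}

#' Root mean square error over the masked entries
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\sum_\Omega (\hat X_\Omega - X_\Omega)^2 / |\Omega|}}
#' where \eqn{\Omega} is the set of masked positions recorded in `truth`.
#'
#' @param imputed an `imputation_result` or completed `omics_matrix`.
#' @param truth a [missingness_truth()] table.
#' @param genes optional gene-id subset (e.g. the SG rows) restricting
#'   \eqn{\Omega}.
#' @return Nonnegative scalar.
#' @export
rmse <- function(imputed, truth, genes = NULL) {
  stopifnot(inherits(truth, "missingness_truth"))
  if (!is.null(genes)) truth <- truth[truth$gene_id %in% genes, , drop = FALSE]
  if (nrow(truth) == 0) stop("empty masked index set")
  v <- imputed_values(imputed)
  pos <- truth_positions(v, truth)
  sqrt(sum((v[pos] - truth$true_value)^2) / nrow(truth))
}

#' Normalized RMSE over the masked entries
#'
#' [rmse()] divided by the population standard deviation (divisor
#' \eqn{|\Omega|}) of the true masked values; scale-invariant. Set
#' `variance = "sample"` for the n-1 divisor.
#'
#' @inheritParams rmse
#' @param variance `"population"` (default) or `"sample"`.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(imputed, truth, genes = NULL,
                  variance = c("population", "sample")) {
  variance <- match.arg(variance)
  stopifnot(inherits(truth, "missingness_truth"))
  if (!is.null(genes)) truth <- truth[truth$gene_id %in% genes, , drop = FALSE]
  n <- nrow(truth)
  if (n < 2) stop("NRMSE needs at least two masked entries")
  x <- truth$true_value
  varx <- if (variance == "population") sum((x - mean(x))^2) / n
          else stats::var(x)
  if (varx == 0) stop("zero variance of the true masked values")
  rmse(imputed, truth) / sqrt(varx)
}

#' Partial ROC curve and pAUC at a false-positive-rate cutoff
#'
#' The ROC is traced by descending score with tied scores grouped into a
#' single segment (one trapezoid, avoiding order dependence). `pauc_raw`
#' is the trapezoidal area under the curve for FPR in `[0, fpr_max]`
#' (interpolating at the cutoff); `pauc_standardized = pauc_raw / fpr_max`
#' lies in [0, 1] with 1 for a perfectly separating scorer.
#'
#' @param scores numeric vector, higher = more positive-like.
#' @param is_positive logical vector of true labels.
#' @param fpr_max cutoff in (0, 1]; 1 recovers the full AUC.
#' @return A list: `points` (data.frame fpr, tpr), `pauc_raw`,
#'   `pauc_standardized`, `fpr_max`.
#' @export
proc_pauc <- function(scores, is_positive, fpr_max = 0.05) {
  stopifnot(length(scores) == length(is_positive),
            fpr_max > 0, fpr_max <= 1)
  is_positive <- as.logical(is_positive)
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be nonempty for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- is_positive[ord]
  # one ROC vertex per distinct score value (ties form one segment)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y)[last_of_tie]
  cum_fp <- cumsum(!y)[last_of_tie]
  fpr <- c(0, cum_fp / n_neg)
  tpr <- c(0, cum_tp / n_pos)
  # clip the polyline at fpr_max by linear interpolation
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x0 <- fpr[i]; x1 <- fpr[i + 1]
    y0 <- tpr[i]; y1 <- tpr[i + 1]
    if (x0 >= fpr_max) break
    if (x1 > fpr_max) {
      y1 <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
      x1 <- fpr_max
    }
    area <- area + (x1 - x0) * (y0 + y1) / 2
    if (x1 >= fpr_max) break
  }
  list(points = data.frame(fpr = fpr, tpr = tpr),
       pauc_raw = area, pauc_standardized = area / fpr_max,
       fpr_max = fpr_max)
}

#' Simulate the SG-focused imputation benchmark data for one seed
#'
#' Builds the proteomics-style design: `n_background` null profiles from a
#' flat Dirichlet plus an SG panel with exactly controlled vertex cosines
#' (defaults: K = 4 groups sized 10/20/30/10, 713 features of which 120
#' SGs at cosines 0.7-0.95), expands them to a linear expression matrix,
#' converts to log2 (pseudo-count 1) and injects mixed LLOD/MAR
#' missingness.
#'
#' @param seed RNG seed.
#' @param K,group_sizes design shape.
#' @param n_background number of non-SG features.
#' @param n_sg_per_group,cosine_range SG panel parameters.
#' @param overall_rate,mar_proportion missingness rates.
#' @param replicate_noise_sd,magnitude_meanlog,magnitude_sdlog expansion law.
#' @return A list: `masked` (log2 `omics_matrix` with injected mask),
#'   `labels`, `truth` (missingness ground truth), `sg_genes` (ids of the
#'   SG rows), `complete` (the unmasked log2 matrix).
#' @export
simulate_sg_benchmark_data <- function(seed, K = 4,
                                       group_sizes = c(10, 20, 30, 10),
                                       n_background = 593,
                                       n_sg_per_group = 30,
                                       cosine_range = c(0.7, 0.95),
                                       overall_rate = 0.5,
                                       mar_proportion = 0.4,
                                       replicate_noise_sd = 0.05,
                                       magnitude_meanlog = 5,
                                       magnitude_sdlog = 1) {
  panel <- generate_sg_panel(K, n_sg_per_group, cosine_range, seed = seed)
  sg_prof <- panel$profiles / rowSums(panel$profiles)   # onto the simplex
  set.seed(seed + 1L)
  bg <- rdirichlet_mat(n_background, 1, K)
  dimnames(bg) <- list(sprintf("bg%04d", seq_len(n_background)),
                       colnames(sg_prof))
  profiles <- rbind(bg, sg_prof)
  cfg <- simplex_sim_config(K = K, group_sizes = group_sizes,
                            replicate_noise_sd = replicate_noise_sd,
                            magnitude_meanlog = magnitude_meanlog,
                            magnitude_sdlog = magnitude_sdlog, seed = seed)
  set.seed(seed + 2L)
  exp <- expand_to_samples(profiles, cfg)
  logm <- to_log2(exp$matrix, pseudo = 1)
  inj <- inject_missingness(logm, missingness_config(overall_rate,
                                                     mar_proportion,
                                                     seed = seed + 3L))
  # genes with no observed value left are unimputable by any observed-data
  # method: drop them from the benchmark matrix and its masked index set
  masked <- inj$masked
  dead <- rowSums(!masked$mask) == 0
  truth <- inj$truth
  if (any(dead)) {
    keep_ids <- rownames(masked$values)[!dead]
    masked <- omics_matrix(masked$values[!dead, , drop = FALSE],
                           mask = masked$mask[!dead, , drop = FALSE],
                           space = masked$space)
    truth <- truth[truth$gene_id %in% keep_ids, , drop = FALSE]
    class(truth) <- c("missingness_truth", "data.frame")
  }
  list(masked = masked, labels = exp$labels, truth = truth,
       sg_genes = rownames(sg_prof), complete = logm,
       n_dropped = sum(dead))
}

#' Benchmark imputation methods on the SG-focused design
#'
#' For each seed, simulates the design of
#' [simulate_sg_benchmark_data()], runs every requested method and
#' reports RMSE/NRMSE overall and restricted to the SG rows. A method
#' failure is recorded as NA metrics, not an error.
#'
#' @param seeds integer vector of seeds.
#' @param methods character vector of method names understood by
#'   [impute_matrix()].
#' @param ... design overrides passed to [simulate_sg_benchmark_data()].
#' @param method_args named list of per-method extra arguments.
#' @return A data.frame with one row per (seed, method): rmse_overall,
#'   nrmse_overall, rmse_sg, nrmse_sg, n_omega, error (NA or message).
#' @export
run_imputation_benchmark <- function(seeds,
                                     methods = c("mgpi", "min2", "mean"),
                                     ..., method_args = list()) {
  rows <- list()
  for (seed in seeds) {
    dat <- simulate_sg_benchmark_data(seed, ...)
    if (nrow(dat$truth) == 0) stop("benchmark requires injected missingness")
    for (method in methods) {
      args <- c(list(m = dat$masked, method = method),
                if (method == "mgpi") list(g = dat$labels),
                if (method == "ppca") list(seed = seed),
                method_args[[method]])
      res <- tryCatch(do.call(impute_matrix, args), error = identity)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          seed = seed, method = method, rmse_overall = NA_real_,
          nrmse_overall = NA_real_, rmse_sg = NA_real_, nrmse_sg = NA_real_,
          n_omega = nrow(dat$truth), error = conditionMessage(res),
          stringsAsFactors = FALSE)
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, method = method,
        rmse_overall = rmse(res, dat$truth),
        nrmse_overall = nrmse(res, dat$truth),
        rmse_sg = rmse(res, dat$truth, genes = dat$sg_genes),
        nrmse_sg = nrmse(res, dat$truth, genes = dat$sg_genes),
        n_omega = nrow(dat$truth), error = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Benchmark DSG detection methods on the simplex simulation design
#'
#' For each K and seed, simulates the two-Dirichlet-plus-clusters design,
#' expands to samples, scores every gene with eCOT, the OVR Welch t-test
#' and OVR fold change (all in DSG direction), and computes pROC/pAUC
#' with the DSG rows as positives and everything else (including SGs) as
#' negatives.
#'
#' @param K_values integer vector of group numbers (default 3:5).
#' @param seeds integer vector of seeds.
#' @param methods subset of `c("ecot", "ovr_t", "ovr_fc")`.
#' @param fpr_max pAUC cutoff (default 0.05).
#' @param ... overrides passed to [simplex_sim_config()].
#' @return A data.frame with one row per (K, seed, method): pauc_raw,
#'   pauc_standardized, n_pos, n_neg.
#' @export
run_detection_benchmark <- function(K_values = 3:5, seeds = 1:10,
                                    methods = c("ecot", "ovr_t", "ovr_fc"),
                                    fpr_max = 0.05, ...) {
  rows <- list()
  for (K in K_values) for (seed in seeds) {
    cfg <- simplex_sim_config(K = K, seed = seed, ...)
    sim <- simulate_simplex_profiles(cfg)
    exp <- expand_to_samples(sim$profiles, cfg)
    pos <- sim$truth$class == "DSG"
    score_sets <- list()
    if ("ecot" %in% methods) {
      ss <- supersample(exp$matrix, exp$labels)
      score_sets$ecot <- cosine_scores(ss, "DSG")
    }
    if ("ovr_t" %in% methods)
      score_sets$ovr_t <- ovr_ttest_scores(exp$matrix, exp$labels, "DSG",
                                           pseudo = 1)
    if ("ovr_fc" %in% methods)
      score_sets$ovr_fc <- ovr_fc_scores(exp$matrix, exp$labels, "DSG")
    for (method in names(score_sets)) {
      tab <- score_sets[[method]]
      sc <- tab$score[match(sim$truth$gene_id, tab$gene_id)]
      keep <- !is.na(sc)
      pr <- proc_pauc(sc[keep], pos[keep], fpr_max = fpr_max)
      rows[[length(rows) + 1]] <- data.frame(
        K = K, seed = seed, method = method, pauc_raw = pr$pauc_raw,
        pauc_standardized = pr$pauc_standardized,
        n_pos = sum(pos[keep]), n_neg = sum(!pos[keep]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
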