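#!/usr/bin/env Rscript
# Thin command-line wrapper over the installed simplexomics package.
#
#   Rscript scripts/suite.R simulate --k 3 --seed 1 --out-prefix sim
#   Rscript scripts/suite.R missingness --in sim.matrix.tsv --space linear \
#       --rate 0.4 --mar 0.3 --seed 1 --out-prefix simmiss
#   Rscript scripts/suite.R impute --in matrix.tsv --labels labels.tsv \
#       --method mgpi --space log2 --out imputed.tsv [--k 10] [--seed 1]
#   Rscript scripts/suite.R detect --in matrix.tsv --labels labels.tsv \
#       --direction DSG --method ecot --out scores.tsv [--top-n N]
#   Rscript scripts/suite.R heatmap --in matrix.tsv --labels labels.tsv \
#       --scores scores.tsv --out-prefix hm [--png]
#   Rscript scripts/suite.R evaluate-impute --imputed X.tsv --omega omega.tsv \
#       [--sg-list sg.txt] --out report.tsv
#   Rscript scripts/suite.R evaluate-detect --scores scores.tsv \
#       --truth truth.tsv --fpr-max 0.05 --out report.tsv
#   Rscript scripts/suite.R pipeline [--config cfg.yaml] [--seed 1] --out-dir out

suppressPackageStartupMessages({
  library(simplexomics)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: suite.R <subcommand> [options]")
cmd <- argv[1]
argv <- argv[-1]

opt <- function(flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) == 1 && i < length(argv)) return(argv[i + 1])
  default
}
has_flag <- function(flag) flag %in% argv

read_in <- function(path, space) {
  fmt <- if (grepl("\\.csv$", path)) "csv" else "tsv"
  read_omics_matrix(path, fmt, space)
}

log_msg <- function(...) cat(sprintf(...), "\n", file = stderr())

if (cmd == "simulate") {
  K <- as.integer(opt("--k", "3"))
  seed <- as.integer(opt("--seed", "1"))
  prefix <- opt("--out-prefix", "sim")
  cfg <- simplex_sim_config(K = K, seed = seed)
  sim <- simulate_simplex_profiles(cfg)
  exp <- expand_to_samples(sim$profiles, cfg)
  write_omics_matrix(exp$matrix, paste0(prefix, ".matrix.tsv"))
  write_group_labels(exp$labels, paste0(prefix, ".labels.tsv"))
  utils::write.table(sim$truth, paste0(prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg("simulate: K=%d seed=%d -> %s.{matrix,labels,truth}.tsv",
          K, seed, prefix)

} else if (cmd == "missingness") {
  m <- read_in(opt("--in"), opt("--space", "linear"))
  cfg <- missingness_config(as.numeric(opt("--rate", "0.5")),
                            as.numeric(opt("--mar", "0.4")),
                            nonzero_only = has_flag("--nonzero-only"),
                            seed = as.integer(opt("--seed", "1")))
  inj <- inject_missingness(m, cfg)
  prefix <- opt("--out-prefix", "simmiss")
  write_omics_matrix(inj$masked, paste0(prefix, ".masked.tsv"))
  write_suite_table(inj$truth, paste0(prefix, ".omega.tsv"))
  log_msg("missingness: |Omega|=%d -> %s.{masked,omega}.tsv",
          nrow(inj$truth), prefix)

} else if (cmd == "impute") {
  m <- read_in(opt("--in"), opt("--space", "log2"))
  method <- opt("--method", "mgpi")
  g <- if (!is.null(opt("--labels"))) read_group_labels(opt("--labels"))
  extra <- c(
    if (method == "swknn") list(k = as.integer(opt("--k", "10"))),
    if (method %in% c("ppca", "nipals", "svd", "svt") &&
        !is.null(opt("--rank"))) list(rank = as.integer(opt("--rank"))),
    if (method == "ppca") list(seed = as.integer(opt("--seed", "1"))))
  res <- do.call(impute_matrix, c(list(m = m, method = method, g = g), extra))
  write_omics_matrix(res$matrix, opt("--out", "imputed.tsv"))
  log_msg("impute: method=%s -> %s", method, opt("--out", "imputed.tsv"))

} else if (cmd == "detect") {
  space <- opt("--space", "linear")
  m <- read_in(opt("--in"), space)
  g <- read_group_labels(opt("--labels"))
  direction <- toupper(opt("--direction", "DSG"))
  method <- opt("--method", "ecot")
  tab <- switch(method,
    ecot = empirical_null_pvalues(
      cosine_scores(supersample(m, g, pseudo = 0), direction)),
    `ovr-t` = ovr_ttest_scores(m, g, direction,
                               pseudo = if (space == "linear") 1 else 0),
    `ovr-fc` = ovr_fc_scores(m, g, direction),
    stop("unknown detection method: ", method))
  if (!is.null(opt("--top-n"))) {
    tab <- detect(tab, "top_n", as.integer(opt("--top-n")))
  } else if (!is.null(opt("--score-min"))) {
    tab <- detect(tab, "score_min", as.numeric(opt("--score-min")))
  } else if (!is.null(opt("--q-max"))) {
    tab <- detect(tab, "q_max", as.numeric(opt("--q-max")))
  }
  write_suite_table(tab, opt("--out", "scores.tsv"))
  log_msg("detect: %s/%s, %d genes -> %s", method, direction, nrow(tab),
          opt("--out", "scores.tsv"))

} else if (cmd == "heatmap") {
  m <- read_in(opt("--in"), opt("--space", "linear"))
  g <- read_group_labels(opt("--labels"))
  scores <- read_score_table(opt("--scores"))
  floor <- if (!is.null(opt("--floor"))) as.numeric(opt("--floor"))
  layout <- build_layout(m, g, scores, floor = floor)
  files <- export_layout(layout, opt("--out-prefix", "hm"),
                         png = has_flag("--png"))
  log_msg("heatmap: wrote %s", paste(files, collapse = ", "))

} else if (cmd == "evaluate-impute") {
  m <- read_in(opt("--imputed"), opt("--space", "log2"))
  tr <- read_missingness_truth(opt("--omega"))
  sg <- if (!is.null(opt("--sg-list"))) readLines(opt("--sg-list"))
  rep <- data.frame(rmse_overall = rmse(m, tr), nrmse_overall = nrmse(m, tr))
  if (!is.null(sg)) {
    rep$rmse_sg <- rmse(m, tr, genes = sg)
    rep$nrmse_sg <- nrmse(m, tr, genes = sg)
  }
  utils::write.table(rep, opt("--out", "impute_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg("evaluate-impute -> %s", opt("--out", "impute_report.tsv"))

} else if (cmd == "evaluate-detect") {
  scores <- read_score_table(opt("--scores"))
  truth <- utils::read.table(opt("--truth"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  sc <- scores$score[match(truth$gene_id, scores$gene_id)]
  keep <- !is.na(sc)
  pr <- proc_pauc(sc[keep], truth$class[keep] == "DSG",
                  fpr_max = as.numeric(opt("--fpr-max", "0.05")))
  rep <- data.frame(pauc_raw = pr$pauc_raw,
                    pauc_standardized = pr$pauc_standardized,
                    fpr_max = pr$fpr_max)
  utils::write.table(rep, opt("--out", "detect_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg("evaluate-detect -> %s", opt("--out", "detect_report.tsv"))

} else if (cmd == "pipeline") {
  cfg <- if (!is.null(opt("--config"))) read_suite_config(opt("--config"))
         else suite_config(seed = as.integer(opt("--seed", "1")))
  man <- run_pipeline(cfg, opt("--out-dir", "pipeline_out"))
  log_msg("pipeline: %d artifacts in %s", nrow(man),
          opt("--out-dir", "pipeline_out"))

} else {
  stop("unknown subcommand: ", cmd)
}
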