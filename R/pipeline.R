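#' @title Suite configuration and end-to-end pipeline
#' @description A serializable configuration object covering every stage
#'   (simulation, missingness injection, imputation, detection, heatmap,
#'   evaluation) and a deterministic driver that chains them:
#'   simulate -> inject -> impute -> detect -> heatmap -> evaluate. One
#'   global seed fans out to per-stage seeds by fixed offsets so stages
#'   remain individually reproducible.
#' @name cli_config
NULL

default_suite_config <- function() {
  list(
    seed = 1L,
    simulation = list(K = 3L, n_null_flat = 1200L, n_null_peaked = 1200L,
                      n_sg_per_group = 20L, n_dsg_per_group = 50L,
                      vertex_noise_sd = 0.05, facet_noise_sd = 0.05,
                      group_sizes = NULL, magnitude_meanlog = 5,
                      magnitude_sdlog = 1, replicate_noise_sd = 0.05),
    missingness = list(enabled = TRUE, overall_rate = 0.5,
                       mar_proportion = 0.4, mode = "threshold_llod",
                       nonzero_only = FALSE),
    imputation = list(enabled = TRUE, method = "mgpi",
                      llod_fill = "half_log_min", pseudo = 1,
                      k = 10L, rank = NULL),
    detection = list(enabled = TRUE, direction = "DSG", method = "ecot",
                     rule = "top_n", value = 50),
    heatmap = list(enabled = TRUE, floor = NULL, png = FALSE),
    evaluation = list(enabled = TRUE, fpr_max = 0.05)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      base[[key]] <- merge_config(base[[key]],
                                  as.list(override[[key]]), full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Build a validated suite configuration
#'
#' Starts from the package defaults and applies overrides given as nested
#' lists; unknown keys are rejected. See `default` sections: `simulation`,
#' `missingness`, `imputation`, `detection`, `heatmap`, `evaluation`, and
#' the global `seed`.
#'
#' @param ... named overrides, e.g. `simulation = list(K = 4)`.
#' @return A `suite_config` list.
#' @export
suite_config <- function(...) {
  cfg <- merge_config(default_suite_config(), list(...))
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  structure(cfg, class = "suite_config")
}

#' Read a suite configuration from a YAML file
#' @param path YAML file of overrides (same nesting as [suite_config()]).
#' @return A `suite_config`.
#' @export
read_suite_config <- function(path) {
  do.call(suite_config, yaml::read_yaml(path))
}

stage_seed <- function(cfg, offset) as.integer(cfg$seed) + offset

#' Run the full pipeline: simulate, inject, impute, detect, lay out, evaluate
#'
#' Executes the stage chain deterministically for the configured seed and
#' writes every artifact under `out_dir`. A manifest (TSV + JSON) lists
#' each file with its producing stage. Any stage failure aborts with the
#' stage name; previously produced files remain on disk.
#'
#' @param cfg a [suite_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the manifest data.frame (file, stage).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "suite_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(0), stage = character(0),
                         stringsAsFactors = FALSE)
  note <- function(files, stage) {
    manifest <<- rbind(manifest,
                       data.frame(file = basename(files), stage = stage,
                                  stringsAsFactors = FALSE))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  s <- cfg$simulation
  sim_cfg <- run_stage("simulate", simplex_sim_config(
    K = s$K, n_null_flat = s$n_null_flat, n_null_peaked = s$n_null_peaked,
    n_sg_per_group = s$n_sg_per_group, n_dsg_per_group = s$n_dsg_per_group,
    vertex_noise_sd = s$vertex_noise_sd, facet_noise_sd = s$facet_noise_sd,
    group_sizes = if (is.null(s$group_sizes)) rep(10L, s$K) else s$group_sizes,
    magnitude_meanlog = s$magnitude_meanlog,
    magnitude_sdlog = s$magnitude_sdlog,
    replicate_noise_sd = s$replicate_noise_sd,
    seed = stage_seed(cfg, 0L)))
  sim <- run_stage("simulate", simulate_simplex_profiles(sim_cfg))
  expd <- run_stage("simulate", {
    set.seed(stage_seed(cfg, 1L))
    expand_to_samples(sim$profiles, sim_cfg)
  })
  run_stage("simulate", {
    write_omics_matrix(expd$matrix, file.path(out_dir, "matrix.tsv"))
    write_group_labels(expd$labels, file.path(out_dir, "labels.tsv"))
    utils::write.table(sim$truth, file.path(out_dir, "gene_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  note(c("matrix.tsv", "labels.tsv", "gene_truth.tsv"), "simulate")

  work <- to_log2(expd$matrix, pseudo = cfg$imputation$pseudo)
  inj <- NULL
  if (isTRUE(cfg$missingness$enabled)) {
    mc <- cfg$missingness
    inj <- run_stage("inject", inject_missingness(
      work, missingness_config(mc$overall_rate, mc$mar_proportion,
                               mode = mc$mode,
                               nonzero_only = mc$nonzero_only,
                               seed = stage_seed(cfg, 2L))))
    run_stage("inject", {
      write_omics_matrix(inj$masked, file.path(out_dir, "masked.tsv"))
      write_suite_table(inj$truth, file.path(out_dir, "omega.tsv"))
    })
    note(c("masked.tsv", "omega.tsv"), "inject")
  }

  imputed <- NULL
  if (isTRUE(cfg$imputation$enabled) && !is.null(inj)) {
    ic <- cfg$imputation
    extra <- switch(ic$method,
                    mgpi = list(llod_fill = ic$llod_fill),
                    swknn = list(k = ic$k),
                    ppca = list(rank = ic$rank, seed = stage_seed(cfg, 3L)),
                    nipals = ,
                    svd = ,
                    svt = list(rank = ic$rank),
                    list())
    imputed <- run_stage("impute", do.call(impute_matrix, c(
      list(m = inj$masked, method = ic$method, g = expd$labels), extra)))
    run_stage("impute",
              write_omics_matrix(imputed$matrix,
                                 file.path(out_dir, "imputed.tsv")))
    note("imputed.tsv", "impute")
  }

  analysis_matrix <- if (!is.null(imputed)) {
    to_linear(imputed$matrix, pseudo = cfg$imputation$pseudo)
  } else expd$matrix

  scores <- NULL
  if (isTRUE(cfg$detection$enabled)) {
    dc <- cfg$detection
    scores <- run_stage("detect", {
      tab <- switch(dc$method,
        ecot = empirical_null_pvalues(
          cosine_scores(supersample(analysis_matrix, expd$labels),
                        dc$direction)),
        ovr_t = ovr_ttest_scores(analysis_matrix, expd$labels,
                                 dc$direction, pseudo = cfg$imputation$pseudo),
        ovr_fc = ovr_fc_scores(analysis_matrix, expd$labels, dc$direction),
        stop("unknown detection method: ", dc$method))
      tab
    })
    run_stage("detect", {
      write_suite_table(scores, file.path(out_dir, "scores.tsv"))
      write_suite_table(detect(scores, dc$rule, dc$value),
                        file.path(out_dir, "detected.tsv"))
    })
    note(c("scores.tsv", "detected.tsv"), "detect")
  }

  if (isTRUE(cfg$heatmap$enabled) && !is.null(scores)) {
    layout <- run_stage("heatmap",
                        build_layout(analysis_matrix, expd$labels, scores,
                                     floor = cfg$heatmap$floor))
    files <- run_stage("heatmap",
                       export_layout(layout, file.path(out_dir, "hm"),
                                     png = isTRUE(cfg$heatmap$png)))
    note(files, "heatmap")
  }

  if (isTRUE(cfg$evaluation$enabled)) {
    ev <- list()
    if (!is.null(imputed) && !is.null(inj) && nrow(inj$truth) > 0) {
      ev$rmse <- rmse(imputed, inj$truth)
      ev$nrmse <- nrmse(imputed, inj$truth)
    }
    if (!is.null(scores)) {
      pos <- sim$truth$class == "DSG"
      sc <- scores$score[match(sim$truth$gene_id, scores$gene_id)]
      keep <- !is.na(sc)
      if (any(pos[keep]) && any(!pos[keep])) {
        pr <- proc_pauc(sc[keep], pos[keep],
                        fpr_max = cfg$evaluation$fpr_max)
        ev$pauc_raw <- pr$pauc_raw
        ev$pauc_standardized <- pr$pauc_standardized
      }
    }
    run_stage("evaluate",
              jsonlite::write_json(ev, file.path(out_dir, "evaluation.json"),
                                   auto_unbox = TRUE, digits = NA))
    note("evaluation.json", "evaluate")
  }

  cfg_plain <- unclass(cfg)
  run_stage("config",
            yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml")))
  note("config.yaml", "config")
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
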