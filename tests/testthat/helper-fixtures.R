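# small builders shared across test files

mat_with_names <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  values
}

toy_labels <- function(samples, groups_per_sample) {
  group_labels(stats::setNames(groups_per_sample, samples))
}

# a 3-group matrix with 2 samples per group, log2 space, no missing
toy_log_matrix <- function(values3) {
  # values3: genes x 3 matrix of per-group values; duplicated per sample
  v <- values3[, rep(1:3, each = 2), drop = FALSE]
  v <- mat_with_names(v, rownames(values3),
                      sprintf("s%d", 1:6))
  m <- omics_matrix(v, space = "log2")
  g <- toy_labels(sprintf("s%d", 1:6), rep(c("A", "B", "C"), each = 2))
  list(m = m, g = g)
}

# random masked log2 matrix for property checks
random_masked_matrix <- function(n_genes = 20, n_samples = 12,
                                 miss_rate = 0.2, seed = 42) {
  set.seed(seed)
  v <- mat_with_names(matrix(stats::rnorm(n_genes * n_samples, 8, 2),
                             n_genes, n_samples))
  mask <- matrix(stats::runif(n_genes * n_samples) < miss_rate,
                 n_genes, n_samples)
  # keep every gene and sample partly observed
  mask[, 1] <- FALSE
  mask[1, ] <- FALSE
  dimnames(mask) <- dimnames(v)
  omics_matrix(v, mask = mask, space = "log2")
}

random_labels <- function(m, K = 3) {
  s <- sample_ids(m)
  toy_labels(s, paste0("G", rep_len(seq_len(K), length(s))))
}

as_supersample <- function(x) {
  structure(x, class = c("supersample_matrix", "matrix", "array"))
}
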