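# loop-based reference implementations of the accuracy metrics, kept
# deliberately naive and independent of the package's vectorized code

rmse_oracle <- function(vhat, truth) {
  s <- 0
  for (r in seq_len(nrow(truth))) {
    s <- s + (vhat[truth$gene_id[r], truth$sample_id[r]] -
                truth$true_value[r])^2
  }
  sqrt(s / nrow(truth))
}

nrmse_oracle <- function(vhat, truth) {
  x <- truth$true_value
  rmse_oracle(vhat, truth) / sqrt(mean((x - mean(x))^2))
}
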