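# Small in-code fixtures shared across tests.

# Expression matrix with explicit group means and no noise.
mean_expression <- function(means, replicates = 3) {
  groups <- colnames(means)
  samples <- data.frame(
    sample = unlist(lapply(groups, function(g) paste0(g, "_", seq_len(replicates)))),
    group = rep(groups, each = replicates),
    stringsAsFactors = FALSE
  )
  expr <- means[, samples$group, drop = FALSE]
  colnames(expr) <- samples$sample
  list(expr = expr, samples = samples)
}

# Minimal EoR table from an eor matrix (genes x arms).
eor_fixture <- function(m) {
  out <- data.frame(gene = rownames(m), stringsAsFactors = FALSE)
  for (a in colnames(m)) {
    out[[paste0("eor_", a)]] <- m[, a]
    out[[paste0("recovered_", a)]] <- m[, a] > 0
  }
  out
}

# Brute-force Spearman of two vectors via explicit tie-corrected ranks and
# the Pearson formula: the independent oracle for spearman_matrix().
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
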