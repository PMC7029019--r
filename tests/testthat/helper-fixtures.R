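# shared fixtures built in code

# small two-group labels used across modules
two_group_labels <- function(n1 = 10, n2 = 11) {
  factor(rep(c("control", "treated"), c(n1, n2)),
         levels = c("control", "treated"))
}

# a quick null count table (no group structure)
null_count_table <- function(m = 20, n = 20, seed = 1, lib = 5000) {
  set.seed(seed)
  base <- stats::rnorm(m)
  generate_otu_counts(latent = rep(0, n), baselines = base,
                      loadings = numeric(m), library_size_mean = lib,
                      seed = seed + 1)
}

# area under the ROC curve for scores of positives vs negatives
auc_rank <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg))
  n_pos <- length(scores_pos)
  n_neg <- length(scores_neg)
  (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# adjusted Rand index between two label vectors (Hubert & Arabie)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_i * sum_j / comb2(n)
  maximum <- (sum_i + sum_j) / 2
  (sum_ij - expected) / (maximum - expected)
}

# binomial 95% band around rate p0 for n trials
binomial_band <- function(p0, n) {
  half <- 1.96 * sqrt(p0 * (1 - p0) / n)
  c(p0 - half, p0 + half)
}
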