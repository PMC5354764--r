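# Independent brute-force oracles and small fixture builders.
# These are written against the published definitions, not against the
# package internals, so they can serve as cross-checks.

# small expression matrix with arbitrary values
make_expr <- function(values, chrom = NULL, arm = NULL) {
  g <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%02d", seq_len(g))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  ann <- NULL
  if (!is.null(chrom)) {
    ann <- data.frame(gene_id = rownames(values), symbol = rownames(values),
                      chrom = chrom, arm = arm,
                      start = seq_len(g) * 1000L, stringsAsFactors = FALSE)
  }
  expr_matrix(values, ann)
}

# Brute-force modified t-statistic: elementwise loops, no shared code with
# the implementation. d_i = (mean_A - mean_B) / (s_i + s0) with the pooled
# standard error of the mean difference.
oracle_sam_d <- function(values, is_a, s0) {
  n_a <- sum(is_a); n_b <- sum(!is_a)
  d <- numeric(nrow(values))
  for (i in seq_len(nrow(values))) {
    xa <- values[i, is_a]; xb <- values[i, !is_a]
    r <- mean(xa) - mean(xb)
    ss <- sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)
    s <- sqrt((1 / n_a + 1 / n_b) * ss / (n_a + n_b - 2))
    d[i] <- r / (s + s0)
  }
  d
}

# Brute-force weighted Kolmogorov-Smirnov running sum: explicit loop over
# the ranked list. metric must be in ranked (descending) order.
oracle_gsea_es <- function(metric_sorted, in_set, weight_p) {
  n <- length(metric_sorted); nh <- sum(in_set)
  nr <- sum(abs(metric_sorted[in_set])^weight_p)
  run <- 0; best <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) run <- run + abs(metric_sorted[i])^weight_p / nr
    else run <- run - 1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Pearson chi-square from the textbook formula, explicit loops.
oracle_chi2 <- function(counts) {
  tot <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    e <- sum(counts[i, ]) * sum(counts[, j]) / tot
    stat <- stat + (counts[i, j] - e)^2 / e
  }
  stat
}

# default labels for a two-class fixture
half_labels <- function(n) rep(c("aneuploid", "diploid"), length.out = n)
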