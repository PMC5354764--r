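#' Two-class unpaired Significance Analysis of Microarrays
#'
#' Per-gene modified t-statistic `d_i = (mean_A - mean_B) / (s_i + s0)`
#' where `s_i` is the pooled standard error of the group mean difference
#' and the fudge factor `s0` is chosen from the 0,5,...,100 percentile
#' grid of the `s_i` to minimize the coefficient of variation of the
#' median absolute deviation of `d` across `s_i` strata. False-discovery
#' q-values come from plain label-shuffle permutations: the FDR at
#' threshold `t` is `pi0 * median_b #{|d*_b| >= t} / #{|d| >= t}`, with
#' `pi0` estimated from the fraction of permuted statistics falling inside
#' the observed interquartile range; q-values are monotonized along the
#' |d|-descending order.
#'
#' Class A defaults to the `"aneuploid"` label when present, so positive
#' `d` means higher expression in aneuploid samples. Fold change is
#' `2^(mean_A - mean_B)` and assumes log2 input.
#'
#' @param x An [expr_matrix], log2 scale.
#' @param labels Character/factor of two class labels, one per sample.
#' @param n_permutations Number of label permutations for the q-values.
#' @param seed Integer seed for the permutations.
#' @param class_a Label treated as class A (numerator group). Default
#'   `"aneuploid"` if present, else the first level.
#' @return A `sam_result`: list with `table` (data.frame `gene_id`, `d`,
#'   `fold_change`, `q_value`, `rank`), `s0`, `n_permutations`, `seed`,
#'   `class_a`, `class_b`, and any recorded `warnings`.
#' @references Tusher, Tibshirani & Chu (2001) PNAS 98:5116-5121.
#' @export
sam_two_class <- function(x, labels, n_permutations = 1000, seed = 1L,
                          class_a = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(x$values)) stop("labels must cover all samples")
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly two classes")
  if (is.null(class_a)) class_a <- if ("aneuploid" %in% lev) "aneuploid" else lev[1]
  if (!class_a %in% lev) stop("class_a not found in labels")
  class_b <- setdiff(lev, class_a)
  a <- labels == class_a
  n_a <- sum(a); n_b <- sum(!a)
  if (n_a < 2 || n_b < 2) stop("each class needs >= 2 samples")
  warnings <- character()
  if (n_permutations < 10) {
    warnings <- c(warnings, sprintf("n_permutations = %d is very small; q-values unreliable", n_permutations))
    warning(warnings[length(warnings)])
  }

  vals <- x$values
  stats_obs <- .sam_stats(vals, a)
  s0 <- .sam_s0(stats_obs$r, stats_obs$s)
  d <- stats_obs$r / (stats_obs$s + s0)

  # permutation null: same s0 as observed (Tusher), plain label shuffles
  n_genes <- nrow(vals)
  set.seed(seed)
  d_perm <- matrix(0, n_genes, n_permutations)
  for (b in seq_len(n_permutations)) {
    ab <- a[sample.int(length(a))]
    st <- .sam_stats(vals, ab)
    d_perm[, b] <- st$r / (st$s + s0)
  }

  ord <- order(-abs(d), rownames(vals))
  thr <- abs(d)[ord]                      # thresholds, descending
  # counts of permuted |d*| >= t for each threshold, per permutation
  abs_perm_sorted <- apply(abs(d_perm), 2, sort)
  counts <- vapply(seq_len(n_permutations), function(b) {
    n_genes - findInterval(thr - 1e-12, abs_perm_sorted[, b])
  }, numeric(length(thr)))
  v_med <- apply(counts, 1, stats::median)
  q25 <- stats::quantile(d, 0.25); q75 <- stats::quantile(d, 0.75)
  pi0 <- min(1, sum(d_perm > q25 & d_perm < q75) / (0.5 * n_genes * n_permutations))
  fdr <- pi0 * v_med / seq_along(thr)
  fdr <- pmin(fdr, 1)
  q_sorted <- rev(cummin(rev(fdr)))       # q_i = min FDR over thresholds <= |d_i|
  q <- numeric(n_genes); q[ord] <- q_sorted
  rank <- integer(n_genes); rank[ord] <- seq_len(n_genes)

  tab <- data.frame(gene_id = rownames(vals), d = d,
                    fold_change = 2^stats_obs$r, q_value = q, rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, s0 = s0, n_permutations = n_permutations,
                 seed = seed, class_a = class_a, class_b = class_b,
                 warnings = warnings),
            class = "sam_result")
}

# numerator r = mean_A - mean_B and pooled SE of the difference
.sam_stats <- function(vals, a) {
  n_a <- sum(a); n_b <- sum(!a)
  m_a <- rowMeans(vals[, a, drop = FALSE])
  m_b <- rowMeans(vals[, !a, drop = FALSE])
  ss_a <- rowSums((vals[, a, drop = FALSE] - m_a)^2)
  ss_b <- rowSums((vals[, !a, drop = FALSE] - m_b)^2)
  s <- sqrt((1 / n_a + 1 / n_b) * (ss_a + ss_b) / (n_a + n_b - 2))
  list(r = m_a - m_b, s = s)
}

# fudge factor: percentile grid 0,5,...,100 of s; minimize CV of the
# stratified MAD(d)/0.64 across ~100 s-quantile strata
.sam_s0 <- function(r, s, n_strata = 100) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE)
  n_strata <- min(n_strata, max(2L, length(s) %/% 2L))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = n_strata + 1), names = FALSE))
  strata <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    dd <- r / (s + s0)
    v <- tapply(dd, strata, function(z) stats::mad(z, constant = 1) / 0.64)
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cv)]
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("sam_result: %d genes, class A = %s (positive d = up in %s), s0 = %.4g, %d permutations\n",
              nrow(x$table), x$class_a, x$class_a, x$s0, x$n_permutations))
  cat(sprintf("  genes at q <= 0.05: %d\n", sum(x$table$q_value <= 0.05)))
  invisible(x)
}

#' Filter a SAM result by FDR and fold change
#'
#' Returns the up- and down-regulated gene lists at the given q-value and
#' linear fold-change cutoffs, each ordered by SAM rank. With
#' `max_fdr = 0` and `min_abs_fold = 1.5` this reproduces the filter used
#' to build perturbation-database query signatures.
#'
#' @param result A `sam_result`.
#' @param max_fdr Maximum q-value.
#' @param min_abs_fold Minimum linear fold change (>= 1); down-regulated
#'   genes must have `fold_change <= 1/min_abs_fold`.
#' @return List with `up` and `down` character vectors of gene ids.
#' @export
sam_filter <- function(result, max_fdr = 0, min_abs_fold = 1.5) {
  stopifnot(inherits(result, "sam_result"))
  if (min_abs_fold < 1) stop("min_abs_fold must be >= 1")
  tab <- result$table[order(result$table$rank), ]
  pass <- tab$q_value <= max_fdr
  list(up = tab$gene_id[pass & tab$fold_change >= min_abs_fold],
       down = tab$gene_id[pass & tab$fold_change <= 1 / min_abs_fold])
}

#' Write a SAM result as TSV plus JSON sidecar
#'
#' @param result A `sam_result`.
#' @param path TSV output path; the sidecar (`s0`, permutation count,
#'   seed, class orientation) goes to `<path>.json`.
#' @return Invisibly, the TSV path.
#' @export
write_sam_result <- function(result, path) {
  stopifnot(inherits(result, "sam_result"))
  tab <- result$table[order(result$table$rank), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result[c("s0", "n_permutations", "seed", "class_a", "class_b")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
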