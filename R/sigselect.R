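#' Minimal discriminating signature by incremental SVM selection
#'
#' Walks down the SAM-ranked gene list and, for each prefix size
#' `k = 1..k_max`, estimates the stratified n-fold cross-validated
#' accuracy of a linear maximum-margin classifier (support vector
#' machine, linear kernel, cost `C`) trained on the top-k genes.
#' Per-gene standardization (mean/sd) is estimated inside each training
#' fold only, so no information leaks from held-out samples. The chosen
#' signature size is the smallest `k` attaining the maximum accuracy —
#' the minimal gene set with the highest discriminatory power.
#'
#' @param x An [expr_matrix], log2 scale.
#' @param labels Two-class character/factor, one per sample.
#' @param ranking A `sam_result` providing the gene order.
#' @param k_max Largest prefix size to evaluate.
#' @param n_folds Number of cross-validation folds (stratified by class).
#' @param seed Integer seed fixing the fold assignment.
#' @param cost SVM margin penalty C.
#' @param repeats Number of repeated CV runs averaged per k (default 1).
#' @return A `selection_result`: list with `accuracies` (data.frame `k`,
#'   `accuracy`), `chosen_k`, `chosen_genes` (top `chosen_k` ids in SAM
#'   rank order), `n_folds`, `seed`.
#' @export
select_minimal_signature <- function(x, labels, ranking, k_max = 30,
                                     n_folds = 10, seed = 1L, cost = 1,
                                     repeats = 1) {
  stopifnot(inherits(x, "expr_matrix"), inherits(ranking, "sam_result"))
  labels <- factor(as.character(labels))
  if (length(labels) != ncol(x$values)) stop("labels must cover all samples")
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (k_max > nrow(x$values)) stop("k_max exceeds the number of genes")
  cls_n <- table(labels)
  if (any(cls_n < n_folds))
    stop(sprintf("class '%s' has %d samples, fewer than n_folds = %d; reduce n_folds",
                 names(cls_n)[which.min(cls_n)], min(cls_n), n_folds))

  ranked_genes <- ranking$table$gene_id[order(ranking$table$rank)][seq_len(k_max)]
  vals <- x$values[ranked_genes, , drop = FALSE]
  n <- ncol(vals)

  set.seed(seed)
  acc_mat <- matrix(0, k_max, repeats)
  for (rep_i in seq_len(repeats)) {
    folds <- integer(n)
    for (lv in levels(labels)) {           # stratified round-robin fold ids
      idx <- which(labels == lv)
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
    }
    for (k in seq_len(k_max)) {
      correct <- 0
      for (f in seq_len(n_folds)) {
        tr <- folds != f; te <- !tr
        xtr <- t(vals[seq_len(k), tr, drop = FALSE])
        xte <- t(vals[seq_len(k), te, drop = FALSE])
        mu <- colMeans(xtr)
        sdv <- apply(xtr, 2, stats::sd)
        sdv[sdv == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
        fit <- e1071::svm(xtr, labels[tr], kernel = "linear", cost = cost,
                          scale = FALSE)
        correct <- correct + sum(stats::predict(fit, xte) == labels[te])
      }
      acc_mat[k, rep_i] <- correct / n
    }
  }
  accuracies <- rowMeans(acc_mat)
  chosen_k <- which.max(accuracies)        # smallest k at the max (ties -> first)
  structure(list(accuracies = data.frame(k = seq_len(k_max), accuracy = accuracies),
                 chosen_k = as.integer(chosen_k),
                 chosen_genes = ranked_genes[seq_len(chosen_k)],
                 n_folds = n_folds, seed = seed, cost = cost, repeats = repeats),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: chosen k = %d (CV accuracy %.3f, %d-fold)\n",
              x$chosen_k, x$accuracies$accuracy[x$chosen_k], x$n_folds))
  cat("  genes:", paste(x$chosen_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection result as TSV plus JSON sidecar
#'
#' @param result A `selection_result`.
#' @param path TSV path for the per-k accuracies; chosen genes and
#'   parameters go to `<path>.json`.
#' @return Invisibly, the TSV path.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  utils::write.table(result$accuracies, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result[c("chosen_k", "chosen_genes", "seed", "n_folds")],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
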