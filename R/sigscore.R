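#' Signature model: directional gene sets with scaling parameters
#'
#' A signature is an ordered pair of disjoint gene sets — genes up- and
#' down-regulated in aneuploid relative to diploid tumors — together with
#' per-gene scaling parameters (mean, sd) estimated on a reference
#' matrix. Applying the model z-scales each gene with these parameters
#' and scores each sample as (sum of up-gene z-scores) minus (sum of
#' down-gene z-scores).
#'
#' @param up_genes,down_genes Disjoint, nonempty character vectors of
#'   gene ids.
#' @param reference An [expr_matrix] from which per-gene mean and sd are
#'   estimated.
#' @return A `signature_model`: list with `up_genes`, `down_genes`,
#'   `scaling` (data.frame `gene_id`, `mean`, `sd`).
#' @export
fit_signature_model <- function(up_genes, down_genes, reference) {
  stopifnot(inherits(reference, "expr_matrix"))
  up_genes <- as.character(up_genes); down_genes <- as.character(down_genes)
  if (!length(up_genes) || !length(down_genes))
    stop("both up_genes and down_genes must be nonempty")
  if (length(intersect(up_genes, down_genes)))
    stop("up_genes and down_genes must be disjoint")
  genes <- c(up_genes, down_genes)
  miss <- setdiff(genes, rownames(reference$values))
  if (length(miss)) stop("model genes absent from reference matrix: ", paste(miss, collapse = ", "))
  sub <- reference$values[genes, , drop = FALSE]
  s <- apply(sub, 1, stats::sd)
  if (any(s == 0)) stop("zero-variance model genes: ",
                        paste(genes[s == 0], collapse = ", "))
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 scaling = data.frame(gene_id = genes, mean = rowMeans(sub),
                                      sd = s, row.names = NULL)),
            class = "signature_model")
}

#' The published nine-gene aneuploidy signature (partial)
#'
#' Named members of the nine-gene endometrial-cancer aneuploidy
#' signature: six genes down-regulated in aneuploid tumors, all on
#' chromosome 15q (four of the six are named in the main text:
#' C15orf57, NDUFAF1, WVA9, RPL4 — the RPL4 row standing in for the
#' probe-level RPL4 variant used on the array), and two of the three
#' up-regulated genes (PGAM2, PPP2R3A). The remaining members were only
#' published in supplementary material not packaged here, so this model
#' is marked incomplete; synthetic analyses use planted truth instead.
#' Scaling must still be estimated on a user matrix via
#' [fit_signature_model].
#'
#' @return List with `up_genes`, `down_genes` symbol vectors and an
#'   `incomplete = TRUE` flag.
#' @export
published_signature_genes <- function() {
  list(up_genes = c("PGAM2", "PPP2R3A"),
       down_genes = c("C15orf57", "NDUFAF1", "WVA9", "RPL4"),
       incomplete = TRUE)
}

#' Aneuploidy signature score with upper-quartile dichotomization
#'
#' For each sample, the score is the sum of z-scaled expression of the
#' up-regulated signature genes minus the sum for the down-regulated
#' genes, using the model's scaling parameters (optionally re-estimated
#' on `x`, as is done when transferring the signature to an external
#' cohort). Samples at or above the 75th percentile of the score
#' (linear-interpolation quantile) are called `"high"`.
#'
#' @param x An [expr_matrix].
#' @param model A `signature_model`.
#' @param re_estimate_scaling Re-estimate per-gene mean/sd on `x` rather
#'   than using the model's reference scaling.
#' @return A `score_result`: list with `score` (named numeric), `call`
#'   (named `"high"`/`"low"`), `cutoff`.
#' @export
signature_score <- function(x, model, re_estimate_scaling = FALSE) {
  stopifnot(inherits(x, "expr_matrix"), inherits(model, "signature_model"))
  genes <- c(model$up_genes, model$down_genes)
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss)) stop("model genes absent from matrix: ", paste(miss, collapse = ", "))
  if (re_estimate_scaling) model <- fit_signature_model(model$up_genes, model$down_genes, x)
  sc <- model$scaling[match(genes, model$scaling$gene_id), ]
  if (any(sc$sd <= 0)) stop("nonpositive sd in scaling for: ",
                            paste(sc$gene_id[sc$sd <= 0], collapse = ", "))
  z <- (x$values[genes, , drop = FALSE] - sc$mean) / sc$sd
  sign_vec <- ifelse(genes %in% model$up_genes, 1, -1)
  score <- colSums(z * sign_vec)
  cutoff <- unname(stats::quantile(score, 0.75, type = 7))
  call <- ifelse(score >= cutoff, "high", "low")
  structure(list(score = score, call = call, cutoff = cutoff), class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score_result: %d samples, cutoff %.3f (upper quartile), %d high / %d low\n",
              length(x$score), x$cutoff, sum(x$call == "high"), sum(x$call == "low")))
  invisible(x)
}

#' Two-group hierarchical clustering of samples on signature genes
#'
#' Agglomerative clustering of samples restricted to the given signature
#' genes: genes are scaled (`mean_and_variance` or `mean_only`), sample
#' pairwise distance is 1 minus the Pearson correlation across genes,
#' linkage is complete, and the dendrogram is cut into exactly two
#' clusters. The cluster with the higher mean directional proxy score
#' (sum of up-gene z minus down-gene z) is labeled `aneuploid_cluster` —
#' phenotype labeling never consults true ploidy. If the two cluster
#' means tie, the cluster containing the first sample is labeled
#' `diploid_cluster`.
#'
#' @param x An [expr_matrix].
#' @param up_genes,down_genes Signature gene ids giving the cluster
#'   orientation (at least two genes in total).
#' @param scaling_mode Gene scaling before clustering.
#' @return A `cluster_result`: list with `labels` (named
#'   `"aneuploid_cluster"`/`"diploid_cluster"`), `hclust` (the merge
#'   record), `k = 2`.
#' @export
cluster_samples <- function(x, up_genes, down_genes = character(),
                            scaling_mode = c("mean_and_variance", "mean_only")) {
  stopifnot(inherits(x, "expr_matrix"))
  scaling_mode <- match.arg(scaling_mode)
  genes <- c(as.character(up_genes), as.character(down_genes))
  if (length(genes) < 2) stop("need >= 2 genes to cluster on")
  if (ncol(x$values) < 3) stop("need >= 3 samples to cluster")
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss)) stop("genes absent from matrix: ", paste(miss, collapse = ", "))
  sub <- expr_matrix(x$values[genes, , drop = FALSE],
                     if (is.null(x$genes)) NULL else x$genes[match(genes, x$genes$gene_id), ])
  scaled <- scale_genes(sub, scaling_mode)$values
  # zero-variance profiles produce NA correlations, reported as errors below
  cors <- suppressWarnings(stats::cor(scaled))   # sample x sample, across genes
  if (anyNA(cors)) {
    bad <- colnames(cors)[apply(is.na(cors), 2, any)]
    stop("undefined sample correlation (zero-variance profile): ",
         paste(bad, collapse = ", "))
  }
  hc <- stats::hclust(stats::as.dist(1 - cors), method = "complete")
  grp <- stats::cutree(hc, k = 2)

  # orientation proxy: z-scores with up positive, down negative
  zsub <- scale_genes(sub, "mean_and_variance")$values
  sign_vec <- ifelse(genes %in% up_genes, 1, -1)
  proxy <- colSums(zsub * sign_vec)
  m1 <- mean(proxy[grp == 1]); m2 <- mean(proxy[grp == 2])
  aneu_grp <- if (m1 > m2) 1L else if (m2 > m1) 2L else setdiff(1:2, grp[1])
  labels <- ifelse(grp == aneu_grp, "aneuploid_cluster", "diploid_cluster")
  names(labels) <- colnames(x$values)
  structure(list(labels = labels, hclust = hc, k = 2L), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d samples -> aneuploid_cluster n=%d, diploid_cluster n=%d\n",
              length(x$labels), sum(x$labels == "aneuploid_cluster"),
              sum(x$labels == "diploid_cluster")))
  invisible(x)
}

#' Cross-tabulate two per-sample labelings
#'
#' Builds an r x c contingency table of counts with row percentages, e.g.
#' cluster assignment versus flow-cytometry ploidy.
#'
#' @param a,b Equal-length label vectors (if both are named, names must
#'   agree as sets and are used to align samples).
#' @return A `contingency_table`: list with `counts` (matrix) and
#'   `row_pct`.
#' @export
cross_tabulate_calls <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("label vectors cover different samples")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("label vectors have different lengths")
  }
  counts <- as.matrix(table(a, b))
  names(dimnames(counts)) <- NULL
  contingency_table(counts)
}

#' Construct a contingency table
#'
#' @param counts Nonnegative integer matrix (optionally with dimnames).
#' @return A `contingency_table` with `counts` and `row_pct` (rows sum
#'   to 100).
#' @export
contingency_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  row_pct <- 100 * counts / rowSums(counts)
  structure(list(counts = counts, row_pct = row_pct), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  out <- matrix(sprintf("%d (%.0f)", x$counts, x$row_pct), nrow(x$counts),
                dimnames = dimnames(x$counts))
  print(out, quote = FALSE)
  invisible(x)
}
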