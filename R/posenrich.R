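#' Positional (chromosome-arm) gene sets from annotation
#'
#' Builds one gene set per (chromosome, arm) pair, named like `"chr15q"`,
#' dropping sets smaller than `min_size`. This is an arm-level analogue
#' of cytoband positional gene-set collections, generated directly from
#' the analyzed annotation so no external catalog is required; any GMT
#' collection can be supplied instead via [read_gmt].
#'
#' @param annotation Gene annotation data.frame with `gene_id`, `chrom`,
#'   `arm` columns (an [expr_matrix]'s `genes` element works).
#' @param min_size Minimum member count for a set to be kept.
#' @return A `gene_set_collection`: list with `sets` (named list of gene
#'   id vectors) and `source`.
#' @export
make_positional_sets <- function(annotation, min_size = 10) {
  if (inherits(annotation, "expr_matrix")) annotation <- annotation$genes
  stopifnot(all(c("gene_id", "chrom", "arm") %in% names(annotation)))
  key <- paste0("chr", annotation$chrom, annotation$arm)
  sets <- split(annotation$gene_id, key)
  sets <- sets[vapply(sets, length, 1L) >= min_size]
  gene_set_collection(sets, source = "positional:generated")
}

#' @rdname make_positional_sets
#' @param sets Named list of gene id character vectors.
#' @param source Provenance string.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  if (any(vapply(sets, length, 1L) == 0)) stop("empty gene sets are not allowed")
  structure(list(sets = lapply(sets, as.character), source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (source: %s)\n", length(x$sets), x$source))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path File path.
#' @return A `gene_set_collection` (descriptions are dropped on read).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_collection(sets, source = path)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection` to write.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$source, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# signal-to-noise ranking metric with the reference sd floor:
# sd is raised to max(sd, 0.2*|mean|), and to 0.2 if still zero.
.snr_metric <- function(vals, a) {
  m_a <- rowMeans(vals[, a, drop = FALSE]); m_b <- rowMeans(vals[, !a, drop = FALSE])
  s_a <- apply(vals[, a, drop = FALSE], 1, stats::sd)
  s_b <- apply(vals[, !a, drop = FALSE], 1, stats::sd)
  floor_sd <- function(s, m) { s <- pmax(s, 0.2 * abs(m)); ifelse(s == 0, 0.2, s) }
  (m_a - m_b) / (floor_sd(s_a, m_a) + floor_sd(s_b, m_b))
}

# weighted Kolmogorov-Smirnov running-sum ES for one set.
# metric must be sorted decreasing; hit is a logical along that order.
.running_es <- function(metric_sorted, hit, weight_p) {
  n <- length(metric_sorted); nh <- sum(hit)
  if (nh == 0 || nh == n) stop("gene set must be a proper nonempty subset of the universe")
  w <- abs(metric_sorted)^weight_p
  nr <- sum(w[hit])
  # all-zero hit weights (possible at weight_p > 0): fall back to equal steps
  inc <- if (nr > 0) ifelse(hit, w / nr, 0) else ifelse(hit, 1 / nh, 0)
  dev <- cumsum(inc) - cumsum(!hit) / (n - nh)
  dev[which.max(abs(dev))]
}

#' Gene set enrichment analysis with phenotype permutations
#'
#' Ranks genes by the signal-to-noise ratio between the two phenotype
#' classes (difference of class means over the sum of class standard
#' deviations, with the reference implementation's sd floor of
#' `0.2 * |mean|`), computes each set's weighted running-sum enrichment
#' score (hit increments proportional to `|metric|^weight_p`, miss
#' decrements `1/(N - set size)`, ES = maximal deviation from zero), and
#' derives normalized scores and FDR q-values from phenotype (label)
#' permutations: each null ES is normalized by the mean same-sign null
#' ES of its own set, and the FDR for a set compares the pooled null NES
#' tail with the observed NES tail. Positive ES means enrichment toward
#' class A (default `"aneuploid"`); negative means the set's genes sit
#' low in the ranking, i.e. enriched in class B (diploid).
#'
#' @param x An [expr_matrix].
#' @param labels Two-class labels per sample; each class needs >= 3
#'   samples under phenotype permutation.
#' @param sets A `gene_set_collection`; sets are intersected with the
#'   matrix genes, and sets covering the whole universe are rejected.
#' @param weight_p Running-sum weight exponent (0 = classic unweighted
#'   Kolmogorov-Smirnov statistic, 1 = the reference default).
#' @param n_permutations Phenotype permutations for NES/FDR.
#' @param seed Integer seed.
#' @param class_a Label treated as class A; default `"aneuploid"` if
#'   present.
#' @param min_size Sets with fewer overlapping genes are dropped.
#' @param permutation `"phenotype"` (labels reshuffled; default) or
#'   `"gene"` (ranking metric shuffled across genes — a fallback for
#'   tiny classes, flagged in the result).
#' @return An `enrichment_result`: data.frame `set`, `size`, `es`,
#'   `nes`, `fdr_q`, `direction` plus attributes `ranking_metric`,
#'   `n_permutations`, `seed`, `permutation`.
#' @export
gsea <- function(x, labels, sets, weight_p = 1, n_permutations = 1000,
                 seed = 1L, class_a = NULL, min_size = 5,
                 permutation = c("phenotype", "gene")) {
  stopifnot(inherits(x, "expr_matrix"), inherits(sets, "gene_set_collection"))
  permutation <- match.arg(permutation)
  labels <- as.character(labels)
  if (length(labels) != ncol(x$values)) stop("labels must cover all samples")
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must have exactly two classes")
  if (is.null(class_a)) class_a <- if ("aneuploid" %in% lev) "aneuploid" else lev[1]
  a <- labels == class_a
  if (permutation == "phenotype" && (sum(a) < 3 || sum(!a) < 3))
    stop("phenotype permutation needs >= 3 samples per class; use permutation = \"gene\"")

  vals <- x$values
  universe <- rownames(vals)
  keep_sets <- lapply(sets$sets, intersect, universe)
  sizes <- vapply(keep_sets, length, 1L)
  keep_sets <- keep_sets[sizes >= min_size]
  if (!length(keep_sets)) stop("no gene set passes min_size after intersection")
  if (any(vapply(keep_sets, length, 1L) == length(universe)))
    stop("a gene set covers the entire universe; miss decrement undefined")

  metric <- .snr_metric(vals, a)
  es_for_metric <- function(met) {
    ord <- order(-met, universe)
    met_s <- met[ord]
    in_set <- lapply(keep_sets, function(s) universe[ord] %in% s)
    vapply(in_set, function(h) .running_es(met_s, h, weight_p), numeric(1))
  }
  es <- es_for_metric(metric)

  set.seed(seed)
  es_null <- matrix(NA_real_, length(keep_sets), n_permutations,
                    dimnames = list(names(keep_sets), NULL))
  for (b in seq_len(n_permutations)) {
    met_b <- if (permutation == "phenotype") {
      .snr_metric(vals, a[sample.int(length(a))])
    } else {
      metric[sample.int(length(metric))]
    }
    es_null[, b] <- es_for_metric(met_b)
  }

  # set-wise sign-conditional normalization
  norm_one <- function(e, null_row) {
    pos <- null_row[null_row > 0]; neg <- null_row[null_row < 0]
    if (e >= 0) { if (!length(pos)) return(NA_real_); e / mean(pos) }
    else { if (!length(neg)) return(NA_real_); -e / mean(neg) }
  }
  nes <- vapply(seq_along(es), function(i) norm_one(es[i], es_null[i, ]), numeric(1))
  nes_null <- es_null
  for (i in seq_len(nrow(es_null)))
    nes_null[i, ] <- vapply(es_null[i, ], norm_one, numeric(1), null_row = es_null[i, ])

  pool <- nes_null[is.finite(nes_null)]
  fdr <- vapply(seq_along(nes), function(i) {
    v <- nes[i]
    if (!is.finite(v)) return(NA_real_)
    if (v >= 0) {
      num <- sum(pool >= v) / max(1, sum(pool >= 0))
      den <- sum(nes[is.finite(nes)] >= v) / max(1, sum(nes[is.finite(nes)] >= 0))
    } else {
      num <- sum(pool <= v) / max(1, sum(pool <= 0))
      den <- sum(nes[is.finite(nes)] <= v) / max(1, sum(nes[is.finite(nes)] <= 0))
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  out <- data.frame(set = names(keep_sets),
                    size = vapply(keep_sets, length, 1L),
                    es = es, nes = nes, fdr_q = fdr,
                    direction = ifelse(es >= 0, "enriched_in_A", "enriched_in_B"),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("enrichment_result", "data.frame"),
            ranking_metric = "signal_to_noise", n_permutations = n_permutations,
            seed = seed, class_a = class_a, permutation = permutation,
            weight_p = weight_p)
}

#' Write enrichment results as TSV
#'
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_enrichment_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
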