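#' Expression matrix with gene annotation
#'
#' Lightweight container for a genes x samples matrix of (typically log2)
#' expression values together with per-gene genomic annotation. Rows are
#' genes/probes, columns are samples; both must carry unique identifiers.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param gene_annotation Optional data.frame with columns `gene_id`,
#'   `symbol`, `chrom`, `arm` (one of `"p"`, `"q"`) and `start` (1-based bp).
#'   Row order is matched to `rownames(values)` by `gene_id`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `genes`.
#' @export
expr_matrix <- function(values, gene_annotation = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene_ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(gene_annotation)) {
    gene_annotation <- as.data.frame(gene_annotation)
    need <- c("gene_id", "symbol", "chrom", "arm", "start")
    miss <- setdiff(need, names(gene_annotation))
    if (length(miss)) stop("gene annotation lacks columns: ", paste(miss, collapse = ", "))
    if (!all(rownames(values) %in% gene_annotation$gene_id))
      stop("annotation is missing some gene_ids present in the matrix")
    gene_annotation <- gene_annotation[match(rownames(values), gene_annotation$gene_id), , drop = FALSE]
    rownames(gene_annotation) <- NULL
  }
  structure(list(values = values, genes = gene_annotation), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$genes)) " (no gene annotation)" else " (annotated)"))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x An `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' Quantile-normalize samples
#'
#' Replaces each sample's sorted values with the across-sample mean of the
#' order statistics, so every column shares one value multiset while
#' within-sample ranks are preserved. Ties receive the average of the
#' normalized values they span. Missing values are rejected rather than
#' silently imputed.
#'
#' @param x An [expr_matrix].
#' @return A quantile-normalized `expr_matrix`.
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x$values))
    stop("matrix contains missing values; impute or drop them before normalizing")
  norm <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(norm) <- dimnames(x$values)
  expr_matrix(norm, x$genes)
}

#' Log2-transform expression values
#'
#' @param x An [expr_matrix] on linear scale.
#' @param pseudocount Nonnegative offset added before taking log2.
#' @return `expr_matrix` with `log2(value + pseudocount)`.
#' @export
log2_transform <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  shifted <- x$values + pseudocount
  if (any(shifted <= 0, na.rm = TRUE)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("nonpositive value after pseudocount at gene '%s', sample '%s'",
                 rownames(x$values)[bad[1]], colnames(x$values)[bad[2]]))
  }
  expr_matrix(log2(shifted), x$genes)
}

#' Center (and scale) genes
#'
#' Per-gene standardization: `mean_only` subtracts the gene mean;
#' `mean_and_variance` additionally divides by the sample standard
#' deviation (n-1 denominator), producing per-gene z-scores.
#'
#' @param x An [expr_matrix].
#' @param mode `"mean_and_variance"` or `"mean_only"`.
#' @return Scaled `expr_matrix`.
#' @export
scale_genes <- function(x, mode = c("mean_and_variance", "mean_only")) {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  m <- rowMeans(x$values)
  v <- x$values - m
  if (mode == "mean_and_variance") {
    s <- apply(x$values, 1, stats::sd)
    zero <- s == 0 | !is.finite(s)
    if (any(zero))
      stop("zero-variance genes cannot be variance-scaled: ",
           paste(rownames(x$values)[zero], collapse = ", "))
    v <- v / s
  }
  expr_matrix(v, x$genes)
}

#' Collapse duplicate probes to one row per symbol
#'
#' Keeps, for each gene symbol, the probe with the largest mean expression.
#' Probes without a symbol (NA/empty) are kept as-is under their probe id.
#'
#' @param x An annotated [expr_matrix].
#' @return `expr_matrix` with one row per symbol.
#' @export
collapse_max_mean <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(x$genes)) stop("collapse requires gene annotation with symbols")
  sym <- x$genes$symbol
  sym[is.na(sym) | sym == ""] <- x$genes$gene_id[is.na(sym) | sym == ""]
  means <- rowMeans(x$values)
  keep <- unlist(lapply(split(seq_len(nrow(x$values)), sym), function(i) i[which.max(means[i])]),
                 use.names = FALSE)
  keep <- sort(keep)  # preserve original row order
  expr_matrix(x$values[keep, , drop = FALSE], x$genes[keep, , drop = FALSE])
}

# ---- readers / writers -------------------------------------------------

#' Read expression from TSV
#'
#' Tab-separated genes x samples table, first column the gene id, header
#' row the sample ids.
#'
#' @param path File path.
#' @param gene_annotation Optional annotation data.frame or TSV path
#'   (see [read_gene_annotation]).
#' @return An [expr_matrix].
#' @export
read_expression_tsv <- function(path, gene_annotation = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  if (is.character(gene_annotation)) gene_annotation <- read_gene_annotation(gene_annotation)
  expr_matrix(values, gene_annotation)
}

#' @rdname read_expression_tsv
#' @param x An `expr_matrix` to write.
#' @export
write_expression_tsv <- function(x, path) {
  tab <- data.frame(gene_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation TSV reader
#'
#' Expects columns `gene_id`, `symbol`, `chrom`, `arm`, `start`
#' (1-based bp).
#'
#' @param path File path.
#' @return data.frame of gene annotation.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "chrom", "arm", "start")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("gene annotation lacks columns: ", paste(miss, collapse = ", "))
  ann
}

#' Read / write GCT 1.2
#'
#' The Broad GCT 1.2 format: `#1.2` header line, a dimensions line, then a
#' table with `Name` and `Description` columns followed by one column per
#' sample.
#'
#' @param path File path.
#' @param gene_annotation Optional annotation (see [read_expression_tsv]).
#' @return An [expr_matrix]; `Description` is ignored on read.
#' @export
read_gct <- function(path, gene_annotation = NULL) {
  lines <- readLines(path, n = 2)
  if (!grepl("^#1\\.2", lines[1])) stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(lines[2], "\t")[[1]][1:2])
  tab <- utils::read.delim(path, skip = 2, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(values) <- tab[[1]]
  if (nrow(values) != dims[1] || ncol(values) != dims[2])
    stop("GCT dimension line disagrees with table body")
  if (is.character(gene_annotation)) gene_annotation <- read_gene_annotation(gene_annotation)
  expr_matrix(values, gene_annotation)
}

#' @rdname read_gct
#' @param x An `expr_matrix` to write.
#' @export
write_gct <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x$values), ncol(x$values), sep = "\t")), con)
  desc <- if (!is.null(x$genes)) x$genes$symbol else rownames(x$values)
  tab <- data.frame(Name = rownames(x$values), Description = desc, x$values,
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
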