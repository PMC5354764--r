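test_that("positional sets cover each populated arm and honor the size filter", {
  ann <- data.frame(gene_id = sprintf("g%03d", 1:88), symbol = sprintf("g%03d", 1:88),
                    chrom = rep(1:22, each = 4), arm = rep(c("p", "p", "q", "q"), 22),
                    start = 1:88)
  sets <- make_positional_sets(ann, min_size = 2)
  expect_length(sets$sets, 44)  # 22 chromosomes x 2 arms, all populated
  expect_true(all(grepl("^chr\\d+[pq]$", names(sets$sets))))
  # a lone gene on an arm is dropped by the size filter
  ann2 <- rbind(ann, data.frame(gene_id = "solo", symbol = "solo", chrom = 21,
                                arm = "p", start = 99))
  sets10 <- make_positional_sets(ann2, min_size = 10)
  expect_false("chr21p" %in% names(sets10$sets))
})

test_that("planted 15q genes all land in the generated chr15q set", {
  co <- simulate_cohort(sim_config(n_samples = 30, n_genes = 300, seed = 40))
  sets <- make_positional_sets(co$expression$genes)
  expect_true(all(co$truth$down_genes %in% sets$sets[["chr15q"]]))
})

test_that("GMT files round-trip", {
  sets <- gene_set_collection(list(A = c("g1", "g2"), B = c("g2", "g3", "g4")))
  tmp <- withr::local_tempfile()
  write_gmt(sets, tmp)
  back <- read_gmt(tmp)
  expect_equal(back$sets, sets$sets)
  expect_error(read_gmt(withr::local_tempfile(lines = "name_only\tdesc")), "malformed")
})

test_that("enrichment scores match the brute-force running sum exactly", {
  set.seed(41)
  for (rep_i in 1:5) {
    n_genes <- sample(10:20, 1)
    vals <- matrix(rnorm(n_genes * 12), n_genes, 12,
                   dimnames = list(sprintf("g%02d", seq_len(n_genes)), NULL))
    x <- make_expr(vals)
    labs <- half_labels(12)
    ids <- rownames(vals)
    set_members <- sample(ids, sample(2:5, 1))
    sets <- gene_set_collection(list(S = set_members))
    for (p in c(0, 1)) {
      res <- gsea(x, labs, sets, weight_p = p, n_permutations = 10, seed = 1,
                  min_size = 1)
      # oracle: recompute the metric independently and walk the ranked list
      a <- labs == "aneuploid"
      m_a <- rowMeans(vals[, a]); m_b <- rowMeans(vals[, !a])
      s_a <- apply(vals[, a], 1, sd); s_b <- apply(vals[, !a], 1, sd)
      fl <- function(s, m) pmax(pmax(s, 0.2 * abs(m)), ifelse(pmax(s, 0.2 * abs(m)) == 0, 0.2, 0))
      met <- (m_a - m_b) / (fl(s_a, m_a) + fl(s_b, m_b))
      ord <- order(-met, ids)
      es_o <- oracle_gsea_es(met[ord], ids[ord] %in% set_members, p)
      expect_equal(res$es[res$set == "S"], es_o, tolerance = 1e-12)
    }
  }
})

test_that("a set holding only the top-ranked gene reaches ES = 1 at weight 0", {
  vals <- matrix(rnorm(4 * 10, sd = 0.2), 4, 10,
                 dimnames = list(paste0("g", 1:4), NULL))
  vals[1, half_labels(10) == "aneuploid"] <- vals[1, half_labels(10) == "aneuploid"] + 5
  x <- make_expr(vals)
  sets <- gene_set_collection(list(top = rownames(vals)[1]))
  res <- gsea(x, half_labels(10), sets, weight_p = 0, n_permutations = 10,
              seed = 1, min_size = 1)
  expect_equal(res$es, 1.0)
})

test_that("weighted ES agrees with an established implementation on the same ranking", {
  skip_if_not_installed("fgsea")
  set.seed(42)
  vals <- matrix(rnorm(50 * 10), 50, 10,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  x <- make_expr(vals)
  labs <- half_labels(10)
  ids <- rownames(vals)
  members <- sample(ids, 8)
  res <- gsea(x, labs, gene_set_collection(list(S = members)), weight_p = 1,
              n_permutations = 10, seed = 1, min_size = 1)
  a <- labs == "aneuploid"
  met <- aneusig:::.snr_metric(vals, a)
  ord <- order(-met, ids)
  stats_ranked <- setNames(met[ord], ids[ord])
  es_fgsea <- fgsea::calcGseaStat(stats_ranked, which(names(stats_ranked) %in% members),
                                  gseaParam = 1, scoreType = "std")
  expect_equal(res$es, es_fgsea, tolerance = 1e-8)
})

test_that("negating the expression matrix flips every ES sign", {
  set.seed(43)
  vals <- matrix(rnorm(60 * 12), 60, 12)
  ann_chrom <- rep(1:6, each = 10)
  x <- make_expr(vals, chrom = ann_chrom, arm = rep("q", 60))
  labs <- half_labels(12)
  sets <- make_positional_sets(x$genes, min_size = 5)
  r1 <- gsea(x, labs, sets, n_permutations = 20, seed = 2)
  r2 <- gsea(make_expr(-vals, chrom = ann_chrom, arm = rep("q", 60)),
             labs, sets, n_permutations = 20, seed = 2)
  expect_equal(r1$es, -r2$es, tolerance = 1e-12)
})

test_that("degenerate sets and tiny classes are rejected; seed fixes the FDR", {
  vals <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20), NULL))
  x <- make_expr(vals)
  labs <- half_labels(10)
  all_set <- gene_set_collection(list(everything = rownames(vals)))
  expect_error(gsea(x, labs, all_set, n_permutations = 5, min_size = 1),
               "entire universe")
  expect_error(gsea(x, c(rep("aneuploid", 2), rep("diploid", 8)),
                    gene_set_collection(list(S = rownames(vals)[1:6])),
                    n_permutations = 5),
               ">= 3 samples")
  sets <- gene_set_collection(list(S = rownames(vals)[1:6], T = rownames(vals)[7:14]))
  r1 <- gsea(x, labs, sets, n_permutations = 30, seed = 5)
  r2 <- gsea(x, labs, sets, n_permutations = 30, seed = 5)
  expect_identical(r1$fdr_q, r2$fdr_q)
  expect_true(all(r1$fdr_q >= 0 & r1$fdr_q <= 1, na.rm = TRUE))
  expect_true(all(abs(r1$es) <= 1))
})
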