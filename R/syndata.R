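#' Simulation configuration for a synthetic tumor cohort
#'
#' Describes a two-class (diploid/aneuploid) cohort with a planted block of
#' chromosome 15q genes down-regulated in aneuploid tumors, a smaller
#' up-regulated set, Gaussian measurement noise on the log2 scale,
#' ploidy-linked exponential survival with uniform administrative
#' censoring, and a hormone-receptor (ER/PR) covariate whose negativity
#' probability depends on ploidy.
#'
#' Defaults mirror a mid-sized endometrial carcinoma microarray cohort:
#' 144 tumors of which 22% are aneuploid, a 9-gene planted signature
#' (6 down on 15q, 3 up), 1 log2-unit dosage effects, residual noise
#' sd 0.7 log2 units, diploid baseline hazard 0.0233 events/year (89%
#' 5-year disease-specific survival), aneuploid hazard ratio 3.3 (68%
#' 5-year DSS), half the cohort censored, and ER/PR negativity in 35% of
#' aneuploid vs 16% of diploid tumors.
#'
#' @param n_samples,n_genes Cohort and transcriptome size.
#' @param frac_aneuploid Proportion of aneuploid samples, in (0,1).
#' @param n_down_genes,n_up_genes Planted signature sizes; the down block
#'   is annotated to chromosome 15, arm q.
#' @param effect_down,effect_up Log2-unit shifts (>0): subtracted from /
#'   added to aneuploid samples for planted down / up genes.
#' @param noise_sd Gaussian noise sd, log2 units (> 0).
#' @param baseline_mean Baseline log2 expression level.
#' @param baseline_hazard Diploid disease-death hazard, events/year.
#' @param hr_aneuploid Hazard ratio (> 0) for aneuploid vs diploid.
#' @param censor_rate Target censored fraction, in \[0,1): uniform
#'   administrative censoring on \[0, T_max\] with T_max solved so the
#'   expected censored fraction matches.
#' @param erpr_neg_prob_given_aneuploid,erpr_neg_prob_given_diploid
#'   Conditional probabilities of ER/PR-negative status.
#' @param seed Integer; single root seed for all draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 144, n_genes = 1000, frac_aneuploid = 0.22,
                       n_down_genes = 6, n_up_genes = 3,
                       effect_down = 1.0, effect_up = 1.0,
                       noise_sd = 0.7, baseline_mean = 8,
                       baseline_hazard = 0.0233, hr_aneuploid = 3.3,
                       censor_rate = 0.5,
                       erpr_neg_prob_given_aneuploid = 0.35,
                       erpr_neg_prob_given_diploid = 0.16,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              frac_aneuploid = frac_aneuploid,
              n_down_genes = as.integer(n_down_genes), n_up_genes = as.integer(n_up_genes),
              effect_down = effect_down, effect_up = effect_up,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              baseline_hazard = baseline_hazard, hr_aneuploid = hr_aneuploid,
              censor_rate = censor_rate,
              erpr_neg_prob_given_aneuploid = erpr_neg_prob_given_aneuploid,
              erpr_neg_prob_given_diploid = erpr_neg_prob_given_diploid,
              seed = as.integer(seed))
  chk <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(cfg$n_samples >= 2, "n_samples must be >= 2")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(cfg$n_down_genes >= 0 && cfg$n_up_genes >= 0 &&
        cfg$n_down_genes + cfg$n_up_genes < cfg$n_genes,
      "n_down_genes + n_up_genes must be < n_genes")
  chk(cfg$frac_aneuploid > 0 && cfg$frac_aneuploid < 1, "frac_aneuploid must be in (0,1)")
  chk(cfg$noise_sd > 0, "noise_sd must be > 0")
  chk(cfg$effect_down >= 0 && cfg$effect_up >= 0, "effect sizes must be >= 0")
  chk(cfg$hr_aneuploid > 0, "hr_aneuploid must be > 0")
  chk(cfg$baseline_hazard > 0, "baseline_hazard must be > 0")
  chk(cfg$censor_rate >= 0 && cfg$censor_rate < 1, "censor_rate must be in [0,1)")
  for (p in c("erpr_neg_prob_given_aneuploid", "erpr_neg_prob_given_diploid"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be a probability"))
  class(cfg) <- "sim_config"
  cfg
}

# Expected censored fraction when T ~ Exp(lambda) and C ~ U(0, tmax):
# P(T > C) = (1/tmax) * integral_0^tmax exp(-lambda t) dt.
.censored_frac <- function(tmax, lambdas) {
  mean((1 - exp(-lambdas * tmax)) / (lambdas * tmax))
}

.solve_censor_tmax <- function(censor_rate, lambdas) {
  if (censor_rate <= 0) return(Inf)
  f <- function(tm) .censored_frac(tm, lambdas) - censor_rate
  # censored fraction decreases from 1 (tmax -> 0) to 0 (tmax -> Inf)
  upper <- 1
  while (f(upper) > 0 && upper < 1e8) upper <- upper * 2
  stats::uniroot(f, c(1e-8, upper))$root
}

#' Simulate a synthetic diploid/aneuploid cohort
#'
#' Generates log2 expression (`baseline_mean` + Gaussian noise, with the
#' planted dosage shifts applied to aneuploid samples), exponential
#' proportional-hazards survival with uniform censoring, ER/PR status, a
#' continuous ploidy value (near 2 for diploid, dispersed for aneuploid;
#' for the ABSOLUTE-style cutoff caller), and mildly ploidy-associated
#' FIGO stage, histology grade, recurrence and nodal-metastasis labels.
#' Fully reproducible for a fixed seed. Planted down genes are annotated
#' to chromosome 15q; remaining genes are assigned round-robin across
#' chromosomes 1-22 and arms p/q.
#'
#' @param config A [sim_config].
#' @return A `synthetic_cohort`: list with `expression` ([expr_matrix]),
#'   `annotation` (per-sample data.frame), and `truth` (planted down/up
#'   gene ids and true ploidy labels).
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_samples
  g <- cfg$n_genes
  sample_id <- sprintf("S%03d", seq_len(n))
  gene_id <- sprintf("G%04d", seq_len(g))

  n_aneu <- round(n * cfg$frac_aneuploid)
  n_aneu <- max(1L, min(n - 1L, n_aneu))
  ploidy <- rep("diploid", n)
  ploidy[sample.int(n, n_aneu)] <- "aneuploid"
  aneu <- ploidy == "aneuploid"

  # planted genes first in the index, then annotation assigned below
  down_idx <- seq_len(cfg$n_down_genes)
  up_idx <- cfg$n_down_genes + seq_len(cfg$n_up_genes)

  vals <- matrix(stats::rnorm(g * n, cfg$baseline_mean, cfg$noise_sd), g, n,
                 dimnames = list(gene_id, sample_id))
  if (length(down_idx)) vals[down_idx, aneu] <- vals[down_idx, aneu, drop = FALSE] - cfg$effect_down
  if (length(up_idx)) vals[up_idx, aneu] <- vals[up_idx, aneu, drop = FALSE] + cfg$effect_up

  # annotation: planted down block on 15q; everything else round-robin 1-22 p/q
  chrom <- integer(g); arm <- character(g)
  rest <- setdiff(seq_len(g), c(down_idx, up_idx))
  rr <- (seq_along(rest) - 1L) %% 44L
  chrom[rest] <- rr %/% 2L + 1L
  arm[rest] <- ifelse(rr %% 2L == 0L, "p", "q")
  if (length(down_idx)) { chrom[down_idx] <- 15L; arm[down_idx] <- "q" }
  if (length(up_idx)) {
    # planted up genes on non-15 chromosomes (deterministic)
    up_chr <- c(7L, 3L, 12L, 1L, 5L, 9L, 11L, 17L, 19L, 21L)
    chrom[up_idx] <- up_chr[((seq_along(up_idx) - 1L) %% length(up_chr)) + 1L]
    arm[up_idx] <- ifelse(seq_along(up_idx) %% 2L == 1L, "p", "q")
  }
  start <- integer(g)
  for (key in unique(paste0(chrom, arm))) {
    i <- which(paste0(chrom, arm) == key)
    start[i] <- seq_along(i) * 100000L + 1L
  }
  ann <- data.frame(gene_id = gene_id, symbol = gene_id,
                    chrom = chrom, arm = arm, start = start,
                    stringsAsFactors = FALSE)

  # survival: exponential PH, uniform administrative censoring
  lam <- cfg$baseline_hazard * ifelse(aneu, cfg$hr_aneuploid, 1)
  t_event <- stats::rexp(n, lam)
  tmax <- .solve_censor_tmax(cfg$censor_rate, lam)
  c_time <- if (is.finite(tmax)) stats::runif(n, 0, tmax) else rep(Inf, n)
  time_years <- pmin(t_event, c_time)
  event <- as.integer(t_event <= c_time)

  # covariates
  p_neg <- ifelse(aneu, cfg$erpr_neg_prob_given_aneuploid, cfg$erpr_neg_prob_given_diploid)
  erpr_status <- ifelse(stats::runif(n) < p_neg, "negative", "positive")
  ploidy_value <- ifelse(aneu,
                         2 + sample(c(-1, 1), n, TRUE) * stats::runif(n, 0.2, 1.5),
                         2 + stats::runif(n, -0.04, 0.04))
  figo_stage <- ifelse(stats::runif(n) < ifelse(aneu, 0.35, 0.18),
                       sample(c("III", "IV"), n, TRUE, prob = c(0.7, 0.3)),
                       sample(c("I", "II"), n, TRUE, prob = c(0.85, 0.15)))
  histology_grade <- ifelse(stats::runif(n) < ifelse(aneu, 0.5, 0.15),
                            sample(c("endometrioid_g3", "non_endometrioid"), n, TRUE),
                            "endometrioid_g1_2")
  recurrence <- as.integer(stats::runif(n) < ifelse(aneu, 0.30, 0.10))
  ln_metastasis <- as.integer(stats::runif(n) < ifelse(aneu, 0.25, 0.08))

  annotation <- data.frame(sample_id = sample_id, ploidy = ploidy,
                           ploidy_value = ploidy_value,
                           erpr_status = erpr_status, figo_stage = figo_stage,
                           histology_grade = histology_grade,
                           time_years = time_years, event = event,
                           recurrence = recurrence, ln_metastasis = ln_metastasis,
                           stringsAsFactors = FALSE)

  structure(list(expression = expr_matrix(vals, ann),
                 annotation = annotation,
                 truth = list(down_genes = gene_id[down_idx],
                              up_genes = gene_id[up_idx],
                              ploidy = stats::setNames(ploidy, sample_id)),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (%d aneuploid), %d down / %d up planted\n",
              nrow(x$expression$values), ncol(x$expression$values),
              sum(x$annotation$ploidy == "aneuploid"),
              length(x$truth$down_genes), length(x$truth$up_genes)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Expression as TSV (and optionally GCT 1.2), annotation as TSV, truth as
#' JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param gct Also write a GCT 1.2 copy of the expression matrix?
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, gct = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             genes = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression_tsv(cohort$expression, paths["expression"])
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$expression$genes, paths["genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = FALSE, digits = NA)
  if (gct) {
    paths <- c(paths, gct = file.path(dir, "expression.gct"))
    write_gct(cohort$expression, paths["gct"])
  }
  invisible(paths)
}
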