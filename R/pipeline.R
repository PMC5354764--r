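#' Run configuration for the end-to-end pipeline
#'
#' A declarative list (optionally loaded from a YAML file) controlling
#' every stage. All randomness is driven by a single root `seed`;
#' stage-level seeds are derived from it deterministically.
#'
#' @param out_dir Output directory for artifacts and the run manifest.
#' @param seed Root integer seed.
#' @param expression,annotation,genes Optional input paths (expression
#'   TSV/GCT, clinical TSV, gene-annotation TSV). When all are `NULL`, a
#'   synthetic cohort is simulated from `sim`.
#' @param sim List of [sim_config] overrides for the simulated cohort.
#' @param quantile_normalize Apply quantile normalization during prep?
#' @param n_permutations Permutation count shared by the differential
#'   expression and enrichment stages.
#' @param k_max,n_folds Signature-selection parameters.
#' @param weight_p Enrichment running-sum weight exponent.
#' @param min_set_size Minimum positional gene-set size.
#' @return A validated `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, expression = NULL, annotation = NULL,
                       genes = NULL, sim = list(), quantile_normalize = TRUE,
                       n_permutations = 200, k_max = 25, n_folds = 10,
                       weight_p = 1, min_set_size = 10) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), expression = expression,
              annotation = annotation, genes = genes, sim = sim,
              quantile_normalize = isTRUE(quantile_normalize),
              n_permutations = as.integer(n_permutations),
              k_max = as.integer(k_max), n_folds = as.integer(n_folds),
              weight_p = weight_p, min_set_size = as.integer(min_set_size))
  for (p in c("expression", "annotation", "genes")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("input file does not exist: ", cfg[[p]], " (", p, ")")
  }
  external <- !vapply(cfg[c("expression", "annotation", "genes")], is.null, TRUE)
  if (any(external) && !all(external))
    stop("supply expression, annotation and genes together, or none (simulate)")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with `run_config` fields.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full aneuploidy-signature pipeline
#'
#' Chains the analysis stages in order: cohort input (or simulation) ->
#' preparation (quantile normalization) -> SAM differential expression ->
#' cross-validated minimal signature selection -> signature scoring with
#' upper-quartile dichotomization and two-group hierarchical clustering ->
#' positional gene-set enrichment -> survival and association statistics.
#' Every artifact is written as TSV/JSON under `config$out_dir`, and a
#' run manifest records parameters, seeds and MD5 checksums of every
#' artifact; rerunning with an identical config reproduces identical
#' artifacts and checksums. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config].
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- input ------------------------------------------------------------
  simulated <- is.null(config$expression)
  if (simulated) {
    cohort <- stage("simulate", {
      sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
      simulate_cohort(do.call(sim_config, sim_args))
    })
    expr <- cohort$expression
    ann <- cohort$annotation
    art <- c(art, stage("simulate", write_cohort(cohort, config$out_dir)))
  } else {
    expr <- stage("load", {
      reader <- if (grepl("\\.gct$", config$expression)) read_gct else read_expression_tsv
      reader(config$expression, gene_annotation = config$genes)
    })
    ann <- stage("load", utils::read.delim(config$annotation, stringsAsFactors = FALSE))
  }
  labels <- stats::setNames(ann$ploidy, ann$sample_id)[colnames(expr$values)]

  # --- prep -------------------------------------------------------------
  if (config$quantile_normalize) expr <- stage("prep", quantile_normalize(expr))
  p_prep <- file.path(config$out_dir, "expression_prepared.tsv")
  art <- c(art, stage("prep", write_expression_tsv(expr, p_prep)))

  # --- SAM --------------------------------------------------------------
  sam <- stage("sam", sam_two_class(expr, labels,
                                    n_permutations = config$n_permutations,
                                    seed = config$seed + 1L))
  p_sam <- file.path(config$out_dir, "sam.tsv")
  art <- c(art, stage("sam", write_sam_result(sam, p_sam)), paste0(p_sam, ".json"))

  # --- signature selection ---------------------------------------------
  sel <- stage("select", select_minimal_signature(expr, labels, sam,
                                                  k_max = config$k_max,
                                                  n_folds = config$n_folds,
                                                  seed = config$seed + 2L))
  p_sel <- file.path(config$out_dir, "selection.tsv")
  art <- c(art, stage("select", write_selection_result(sel, p_sel)), paste0(p_sel, ".json"))

  # --- scoring & clustering --------------------------------------------
  sam_tab <- sam$table[match(sel$chosen_genes, sam$table$gene_id), ]
  up <- sam_tab$gene_id[sam_tab$d > 0]
  down <- sam_tab$gene_id[sam_tab$d <= 0]
  res_score <- NULL; res_cluster <- NULL
  if (length(up) && length(down)) {
    model <- stage("score", fit_signature_model(up, down, expr))
    res_score <- stage("score", signature_score(expr, model))
    res_cluster <- stage("cluster", cluster_samples(expr, up, down))
    score_tab <- data.frame(sample_id = names(res_score$score),
                            score = res_score$score, call = res_score$call,
                            cluster = res_cluster$labels[names(res_score$score)],
                            row.names = NULL)
    p_score <- file.path(config$out_dir, "scores.tsv")
    utils::write.table(score_tab, p_score, sep = "\t", quote = FALSE, row.names = FALSE)
    art <- c(art, p_score)
  }

  # --- positional enrichment -------------------------------------------
  res_gsea <- NULL
  if (!is.null(expr$genes)) {
    sets <- stage("gsea", make_positional_sets(expr$genes, min_size = config$min_set_size))
    res_gsea <- stage("gsea", gsea(expr, labels, sets, weight_p = config$weight_p,
                                   n_permutations = config$n_permutations,
                                   seed = config$seed + 3L))
    p_gsea <- file.path(config$out_dir, "enrichment.tsv")
    art <- c(art, stage("gsea", write_enrichment_result(res_gsea, p_gsea)))
  }

  # --- survival ---------------------------------------------------------
  surv_json <- stage("survival", {
    sd <- survival_data(ann$time_years, ann$event, group = ann$ploidy,
                        erpr_status = ann$erpr_status)
    lr <- logrank(sd)
    km <- km_estimate(sd)
    out <- list(logrank = lr,
                km_5yr = lapply(km, km_survival_at, at = 5))
    if (!is.null(res_score)) {
      out$score_by_ploidy <- rank_tests(res_score$score, ann$ploidy)
      out$highscore_vs_ploidy_fisher <- fisher_exact(
        cross_tabulate_calls(res_score$call, stats::setNames(ann$ploidy, ann$sample_id)))
    }
    cox <- tryCatch(cox_fit(sd, ~ group * erpr_status), error = function(e) NULL,
                    warning = function(w) NULL)
    if (!is.null(cox)) out$cox_ploidy_x_erpr <- cox$terms
    out
  })
  p_surv <- file.path(config$out_dir, "survival.json")
  jsonlite::write_json(surv_json, p_surv, auto_unbox = TRUE, digits = NA, force = TRUE)
  art <- c(art, p_surv)

  # --- manifest ---------------------------------------------------------
  art <- unname(art)
  manifest <- list(
    package = "aneusig",
    version = as.character(utils::packageVersion("aneusig")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    artifacts = lapply(stats::setNames(art, basename(art)), function(p)
      unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
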