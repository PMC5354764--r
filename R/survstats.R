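#' Survival data constructor
#'
#' Disease-specific survival: `event = 1` for death from disease,
#' `event = 0` for censoring (including deaths from other causes).
#'
#' @param time Follow-up time in years (>= 0).
#' @param event Binary event indicator.
#' @param group Optional per-sample group labels.
#' @param ... Further per-sample covariate vectors, collected into the
#'   data frame.
#' @return A data.frame of class `survival_data`.
#' @export
survival_data <- function(time, event, group = NULL, ...) {
  if (any(time < 0)) stop("time must be >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  df <- data.frame(time = time, event = as.integer(event), ...)
  if (!is.null(group)) df$group <- group
  class(df) <- c("survival_data", "data.frame")
  df
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator; at tied times, censored observations are
#' handled after events (the standard convention).
#'
#' @param data A [survival_data] (with a `group` column unless `group`
#'   is given).
#' @param group Optional group vector overriding `data$group`; omit both
#'   for a single pooled curve.
#' @return Named list of `km_curve` data.frames (`time`, `n_risk`,
#'   `n_event`, `survival`), one per group.
#' @export
km_estimate <- function(data, group = NULL) {
  if (is.null(group)) group <- if ("group" %in% names(data)) data$group else rep("all", nrow(data))
  group <- as.character(group)
  if (any(table(group) < 1)) stop("empty group")
  fit <- survival::survfit(survival::Surv(data$time, data$event) ~ group,
                           conf.type = "none")
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time), paste0("group=", unique(group)))
            else fit$strata
  idx <- rep(names(strata), strata)
  out <- lapply(split(seq_along(fit$time), idx), function(i) {
    structure(data.frame(time = fit$time[i], n_risk = fit$n.risk[i],
                         n_event = fit$n.event[i], survival = fit$surv[i]),
              class = c("km_curve", "data.frame"))
  })
  names(out) <- sub("^group=", "", names(out))
  out
}

#' Survival probability at a given time from a KM curve
#'
#' @param curve A `km_curve`.
#' @param at Time point (years).
#' @return S(at), the step-function value (1 before the first event).
#' @export
km_survival_at <- function(curve, at) {
  s <- c(1, curve$survival)
  s[findInterval(at, curve$time) + 1]
}

#' Two-sided log-rank (Mantel-Cox) test
#'
#' @param data A [survival_data].
#' @param group Group labels (2 or more levels); defaults to
#'   `data$group`.
#' @return List `chi2`, `df`, `p`.
#' @export
logrank <- function(data, group = NULL) {
  if (is.null(group)) group <- data$group
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(data$time, data$event) ~ group)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit with Wald intervals
#'
#' Partial-likelihood fit with Efron tie handling. Interaction terms are
#' written in the formula as usual (`a * b` or `a:b`). A
#' log(-log S(t)) diagnostic table (per level of the first term) is
#' attached for proportional-hazards assessment.
#'
#' @param data A [survival_data] holding all covariates.
#' @param formula Right-hand side only, e.g. `~ ploidy * erpr_status + age`.
#' @return A `cox_result`: list with `terms` (data.frame `term`, `hr`,
#'   `ci_low`, `ci_high`, `p`), `loglik`, `converged`, `loglog`
#'   (diagnostic), and the underlying `fit`.
#' @export
cox_fit <- function(data, formula) {
  if (sum(data$event) < 1) stop("no events; Cox model cannot be fit")
  full <- stats::update(formula, survival::Surv(time, event) ~ .)
  mf <- stats::model.frame(stats::update(formula, ~ .), data = data)
  if (any(vapply(mf, function(v) length(unique(v)) < 2, TRUE)))
    stop("constant covariate in model")
  fit <- survival::coxph(full, data = data, ties = "efron")
  s <- summary(fit)
  co <- s$coefficients
  conf <- s$conf.int
  converged <- all(is.finite(co[, "coef"])) &&
    all(is.finite(co[, "se(coef)"])) && all(co[, "se(coef)"] < 50)
  if (!converged)
    warning("Cox fit did not converge cleanly (possible separation); inspect $fit")
  terms <- data.frame(term = rownames(co), hr = co[, "exp(coef)"],
                      ci_low = conf[, "lower .95"], ci_high = conf[, "upper .95"],
                      p = co[, "Pr(>|z|)"], row.names = NULL)
  # log-minus-log diagnostic on the first model term, if categorical
  v1 <- mf[[1]]
  loglog <- NULL
  if (!is.numeric(v1)) {
    km <- km_estimate(data, group = as.character(v1))
    loglog <- do.call(rbind, lapply(names(km), function(g) {
      cc <- km[[g]]
      keep <- cc$survival > 0 & cc$survival < 1
      if (!any(keep)) return(NULL)
      data.frame(group = g, log_time = log(cc$time[keep]),
                 loglog_surv = log(-log(cc$survival[keep])))
    }))
  }
  structure(list(terms = terms, loglik = fit$loglik[2], converged = converged,
                 loglog = loglog, fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties)\n")
  tt <- x$terms
  tt$hr <- sprintf("%.2f", tt$hr)
  tt$ci <- sprintf("%.2f - %.2f", x$terms$ci_low, x$terms$ci_high)
  print(tt[, c("term", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Binary logistic regression with odds ratios
#'
#' Maximum-likelihood fit; odds ratios with Wald 95% intervals. Perfect
#' or quasi-perfect separation is flagged (huge coefficients / fitted
#' probabilities at the boundary), never silently returned.
#'
#' @param data data.frame of outcome and covariates.
#' @param formula e.g. `recurrence ~ ploidy + histology_grade`.
#' @return A `logistic_result`: list with `terms` (data.frame `term`,
#'   `or`, `ci_low`, `ci_high`, `p`), `separation_flag`, `fit`.
#' @export
logistic_fit <- function(data, formula) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (length(unique(y)) < 2) stop("outcome has a single class")
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  co <- summary(fit)$coefficients
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  separation <- any(abs(co[, "Estimate"]) > 15) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (separation) warning("possible separation in logistic fit; estimates unstable")
  terms <- data.frame(term = rownames(co), or = exp(co[, "Estimate"]),
                      ci_low = exp(co[, "Estimate"] - 1.96 * co[, "Std. Error"]),
                      ci_high = exp(co[, "Estimate"] + 1.96 * co[, "Std. Error"]),
                      p = co[, "Pr(>|z|)"], row.names = NULL)
  structure(list(terms = terms, separation_flag = separation, fit = fit),
            class = "logistic_result")
}

#' Pearson chi-square and Fisher exact tests on contingency tables
#'
#' `chi_square` applies the uncorrected Pearson statistic with
#' `df = (r-1)(c-1)` and warns when any expected count is below 5 (where
#' Fisher's exact test is recommended); `fisher_exact` gives the
#' two-sided exact p for a 2x2 table.
#'
#' @param table A `contingency_table` (or plain counts matrix).
#' @return `chi_square`: list `chi2`, `df`, `p`, `expected_below_5`.
#'   `fisher_exact`: list `p`, `odds_ratio`.
#' @export
chi_square <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else as.matrix(table)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: zero row or column margin")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  low <- any(expected < 5)
  if (low) warning("expected count < 5; consider fisher_exact")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected_below_5 = low)
}

#' @rdname chi_square
#' @export
fisher_exact <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else as.matrix(table)
  if (!all(dim(counts) == c(2, 2))) stop("fisher_exact implemented for 2x2 tables")
  ft <- stats::fisher.test(counts)
  list(p = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Rank tests for group differences in a continuous variable
#'
#' Two groups: Mann-Whitney U (normal approximation with tie
#' correction); three or more: Kruskal-Wallis. If every value is tied
#' across all samples, returns p = 1 with a warning.
#'
#' @param values Numeric vector.
#' @param group Group labels (2 or more levels).
#' @return List `statistic`, `p`, `method`.
#' @export
rank_tests <- function(values, group) {
  group <- as.factor(group)
  if (any(table(group) < 1)) stop("each group needs >= 1 value")
  if (length(unique(values)) == 1) {
    warning("all values tied; no rank information")
    return(list(statistic = if (nlevels(group) == 2) prod(table(group)) / 2 else 0,
                p = 1, method = "degenerate"))
  }
  if (nlevels(group) == 2) {
    wt <- suppressWarnings(stats::wilcox.test(values ~ group, exact = FALSE,
                                              correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value, method = "mann_whitney_u")
  } else {
    kt <- stats::kruskal.test(values, group)
    list(statistic = unname(kt$statistic), p = kt$p.value, method = "kruskal_wallis")
  }
}

#' Quantile-based cutoff scan against survival
#'
#' Ranks `values` into tertiles, quartiles and/or quintiles; within each
#' scheme, every contiguous split of the ordered categories into two
#' groups is scored by the log-rank statistic, and the split with the
#' largest statistic is reported. Because the best of several correlated
#' tests is selected, the winning p-value is optimistically biased; the
#' output carries an explicit `multiple_testing_caveat` flag and this
#' procedure should be treated as exploratory.
#'
#' @param values Numeric per-sample variable (e.g. a signature score).
#' @param data A [survival_data] for the same samples.
#' @param schemes Subset of `c("tertiles", "quartiles", "quintiles")`.
#' @return A `cutoff_scan`: list per scheme with `cut_after` (ordered
#'   category index), `cutoff_value`, `chi2`, `p`, `n_splits_tested`;
#'   plus `multiple_testing_caveat = TRUE`. Schemes degenerate under
#'   ties are skipped with a warning.
#' @export
quartile_cutoff_scan <- function(values, data,
                                 schemes = c("tertiles", "quartiles", "quintiles")) {
  stopifnot(all(is.finite(values)))
  kmap <- c(tertiles = 3L, quartiles = 4L, quintiles = 5L)
  schemes <- match.arg(schemes, names(kmap), several.ok = TRUE)
  out <- list()
  for (sch in schemes) {
    k <- kmap[[sch]]
    br <- unique(stats::quantile(values, seq(0, 1, length.out = k + 1)))
    if (length(br) < 3) {
      warning(sprintf("scheme '%s' degenerate under ties; skipped", sch))
      out[[sch]] <- NULL
      next
    }
    cats <- cut(values, br, include.lowest = TRUE, labels = FALSE)
    ncat <- max(cats)
    best <- list(chi2 = -Inf)
    for (j in seq_len(ncat - 1)) {
      grp <- ifelse(cats <= j, "low", "high")
      lr <- logrank(data, grp)
      if (lr$chi2 > best$chi2)
        best <- list(cut_after = j, cutoff_value = unname(br[j + 1]),
                     chi2 = lr$chi2, p = lr$p, n_splits_tested = ncat - 1)
    }
    out[[sch]] <- best
  }
  out$multiple_testing_caveat <- TRUE
  structure(out, class = "cutoff_scan")
}
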