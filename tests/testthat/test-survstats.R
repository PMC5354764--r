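test_that("Kaplan-Meier closed forms", {
  # 1 event at t=1, 1 censored at t=2: S(1) = 0.5 and stays 0.5
  km <- km_estimate(survival_data(c(1, 2), c(1, 0)))
  expect_equal(km_survival_at(km$all, 1), 0.5)
  expect_equal(km_survival_at(km$all, 2), 0.5)
  # no events: S identically 1
  km2 <- km_estimate(survival_data(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km2$all$survival == 1))
  # four distinct event times: steps 0.75, 0.5, 0.25, 0
  km3 <- km_estimate(survival_data(1:4, rep(1, 4)))
  expect_equal(km3$all$survival, c(0.75, 0.5, 0.25, 0))
  # without censoring, KM equals the empirical survival function
  set.seed(50)
  t <- rexp(40)
  km4 <- km_estimate(survival_data(t, rep(1, 40)))
  expect_equal(km4$all$survival,
               sapply(sort(t), function(u) mean(t > u)), tolerance = 1e-12)
})

test_that("log-rank is null on identical groups and matches the Cox score test", {
  d <- survival_data(time = rep(c(1, 2, 3, 4), 2), event = rep(c(1, 0, 1, 1), 2),
                     group = rep(c("a", "b"), each = 4))
  lr <- logrank(d)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank(survival_data(1:3, c(1, 1, 0), group = rep("a", 3))),
               ">= 2 groups")
  set.seed(51)
  d2 <- survival_data(time = rexp(60, rep(c(0.5, 1), 30)),
                      event = rbinom(60, 1, 0.8),
                      group = rep(c("a", "b"), 30))
  lr2 <- logrank(d2)
  sc <- summary(survival::coxph(survival::Surv(time, event) ~ group, data = d2,
                                ties = "breslow"))$sctest[["test"]]
  expect_lt(abs(lr2$chi2 - sc), 1e-6)
})

test_that("Cox recovers a simulated hazard ratio of 2", {
  set.seed(52)
  n <- 1000
  grp <- rep(c(0, 1), n / 2)
  t <- rexp(n, 0.1 * 2^grp)
  cens <- runif(n, 0, quantile(t, 0.9) * 2)
  d <- survival_data(pmin(t, cens), as.integer(t <= cens), group = factor(grp))
  fit <- cox_fit(d, ~ group)
  expect_gt(fit$terms$hr, 1.8)
  expect_lt(fit$terms$hr, 2.2)
  expect_true(fit$converged)
  expect_true(fit$terms$ci_low <= fit$terms$hr & fit$terms$hr <= fit$terms$ci_high)
})

test_that("Cox interaction terms are reported and degenerate input is rejected", {
  set.seed(53)
  n <- 400
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.1 * exp(0.5 * a + 0.3 * b + 0.6 * a * b))
  d <- survival_data(t, rep(1, n), group = factor(a), covb = factor(b))
  fit <- cox_fit(d, ~ group * covb)
  expect_true(any(grepl(":", fit$terms$term)))
  expect_false(is.null(fit$loglog))
  expect_error(cox_fit(survival_data(1:5, rep(0, 5), group = factor(c(1, 0, 1, 0, 1))),
                       ~ group), "no events")
  expect_error(cox_fit(survival_data(1:5, rep(1, 5), group = factor(rep("x", 5))),
                       ~ group), "constant")
})

test_that("logistic saturated 2x2 model returns the cross-product odds ratio", {
  counts <- matrix(c(30, 10, 12, 25), 2)  # a=30 b=12 / c=10 d=25
  df <- data.frame(
    y = rep(c(1, 1, 0, 0), c(30, 10, 12, 25)),
    xx = rep(c(0, 1, 0, 1), c(30, 10, 12, 25)))
  fit <- logistic_fit(df, y ~ xx)
  expect_equal(fit$terms$or, (10 * 12) / (30 * 25), tolerance = 1e-8)
  expect_error(logistic_fit(data.frame(y = rep(1, 10), xx = rnorm(10)), y ~ xx),
               "single class")
})

test_that("logistic CI covers 1 under independence and separation is flagged", {
  set.seed(54)
  cover <- replicate(100, {
    df <- data.frame(y = rbinom(80, 1, 0.5), xx = rnorm(80))
    fit <- logistic_fit(df, y ~ xx)
    fit$terms$ci_low <= 1 && 1 <= fit$terms$ci_high
  })
  expect_gt(mean(cover), 0.88)
  sep <- data.frame(y = rep(c(0, 1), each = 10), xx = rep(c(0, 1), each = 10))
  expect_warning(fit <- logistic_fit(sep, y ~ xx), "separation")
  expect_true(fit$separation_flag)
})

test_that("chi-square matches the textbook formula on published counts", {
  counts <- matrix(c(389, 72, 84, 46), 2)  # receptor status x ploidy
  res <- chi_square(counts)
  expect_equal(res$chi2, oracle_chi2(counts), tolerance = 1e-10)
  expect_equal(res$chi2, 24.794, tolerance = 1e-3)
  expect_lt(res$p, 0.001)
  expect_equal(res$df, 1)
  # proportional table has statistic 0
  prop <- matrix(c(20, 40, 10, 20), 2)
  expect_equal(chi_square(prop)$chi2, 0, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Fisher exact two-sided p matches hypergeometric enumeration", {
  res <- fisher_exact(matrix(c(1, 9, 9, 1), 2))
  # enumerate the hypergeometric tail: P(X <= 1) + P(X >= 9), margins 10/10
  p_enum <- sum(dhyper(c(0, 1, 9, 10), 10, 10, 10))
  expect_equal(res$p, p_enum, tolerance = 1e-9)
  expect_equal(res$p, 0.0011, tolerance = 0.01)
})

test_that("rank tests: U under identity, exact separation, Kruskal-Wallis null", {
  res <- rank_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 3 * 3 / 2)  # identical multisets: U = n1 n2 / 2
  sep <- rank_tests(c(1:5, 6:10), rep(c("a", "b"), each = 5))
  expect_equal(sep$statistic, 0)          # complete separation
  exact_p <- wilcox.test(1:5, 6:10, exact = TRUE)$p.value
  expect_equal(exact_p, 2 / 252, tolerance = 1e-12)
  kw <- rank_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$method, "kruskal_wallis")
  expect_warning(res0 <- rank_tests(rep(5, 6), rep(c("a", "b"), 3)), "tied")
  expect_equal(res0$p, 1)
})

test_that("cutoff scan picks the top-quartile split under an increasing hazard", {
  set.seed(55)
  hits <- replicate(10, {
    n <- 200
    v <- runif(n)
    t <- rexp(n, 0.1 * exp(2.5 * (v > 0.75)))
    d <- survival_data(t, rep(1, n))
    sc <- quartile_cutoff_scan(v, d, schemes = "quartiles")
    sc$quartiles$cut_after == 3
  })
  expect_gte(mean(hits), 0.7)
})

test_that("cutoff scan flags selection inflation and skips constant values", {
  set.seed(56)
  n <- 120
  d <- survival_data(rexp(n), rbinom(n, 1, 0.7))
  sc <- quartile_cutoff_scan(rnorm(n), d)
  expect_true(sc$multiple_testing_caveat)
  expect_equal(sc$quartiles$n_splits_tested, 3)
  # null values: the selected chi2 exceeds the 1-df expectation on average
  best <- replicate(30, {
    dd <- survival_data(rexp(n), rbinom(n, 1, 0.7))
    quartile_cutoff_scan(rnorm(n), dd, schemes = "quartiles")$quartiles$chi2
  })
  expect_gt(median(best), 1)
  expect_warning(quartile_cutoff_scan(rep(2, n), d, schemes = "quartiles"),
                 "degenerate")
})
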