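test_that("C-index reproduces worked examples and the exhaustive oracle", {
  expect_equal(harrell_cindex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(harrell_cindex(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_equal(harrell_cindex(c(1.0, 0.5, 0.2), c(2, 1, 3), c(1, 1, 0)), 2 / 3)

  und <- harrell_cindex(c(1, 2), c(5, 3), c(0, 0))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))

  set.seed(1)
  for (i in 1:20) {
    n <- sample(4:40, 1)
    r <- sample(rnorm(n - 2), n, replace = TRUE)       # induces risk ties
    t <- round(rexp(n, 0.1), 1) + 0.1                  # induces time ties
    e <- rbinom(n, 1, 0.6)
    expect_equal(harrell_cindex(r, t, e), cindex_brute(r, t, e))
  }
})

test_that("C-index matches the survival package on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(2)
  for (i in 1:15) {
    n <- sample(5:40, 1)
    r <- rnorm(n); t <- rexp(n) + 0.01; e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1
    ref <- survival::concordance(survival::Surv(t, e) ~ r,
                                 reverse = TRUE)$concordance
    expect_equal(harrell_cindex(r, t, e), ref, tolerance = 1e-12)
  }
})

test_that("C-index reversal identity holds without risk ties", {
  set.seed(3)
  r <- rnorm(20); t <- rexp(20) + 0.01; e <- rbinom(20, 1, 0.7); e[1] <- 1
  expect_equal(harrell_cindex(r, t, e) + harrell_cindex(-r, t, e), 1)
})

test_that("time-dependent AUC reproduces its oracles", {
  # perfect model without censoring discriminates perfectly at every time
  set.seed(4)
  t <- rexp(60) + 0.1; e <- rep(1, 60)
  td <- time_dependent_auc(-t, t, e)
  expect_equal(td$mean_auc, 1)
  expect_equal(nrow(td$grid), 4L)

  # single grid time, no censoring: equals brute-force pair counting
  r <- rnorm(60)
  td1 <- time_dependent_auc(r, t, e, n_times = 1L)
  expect_equal(td1$mean_auc, auc_brute_at(r, t, e, td1$grid$time[1]),
               tolerance = 1e-12)

  # unweighted estimator equals brute force also under censoring
  e2 <- rbinom(60, 1, 0.6); e2[1] <- 1
  td2 <- time_dependent_auc(r, t, e2, n_times = 3L, ipcw = FALSE)
  for (k in seq_len(3)) {
    expect_equal(td2$grid$auc[k], auc_brute_at(r, t, e2, td2$grid$time[k]),
                 tolerance = 1e-12)
  }

  # IPCW weights are all 1 without censoring: both variants agree
  td3 <- time_dependent_auc(r, t, e, n_times = 3L, ipcw = TRUE)
  td4 <- time_dependent_auc(r, t, e, n_times = 3L, ipcw = FALSE)
  expect_equal(td3$grid$auc, td4$grid$auc, tolerance = 1e-12)

  # degenerate grid point dropped with a warning
  expect_warning(
    td5 <- time_dependent_auc(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0), n_times = 2L),
    class = "pcm_auc_grid_dropped")
  expect_true(is.na(td5$mean_auc))
})

test_that("random risks score near 0.5 mean AUC", {
  set.seed(5)
  aucs <- replicate(20, {
    n <- 400
    t <- rexp(n, 0.05); e <- rbinom(n, 1, 0.7)
    time_dependent_auc(rnorm(n), t, e)$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(length(aucs)) + 0.01)
})

test_that("Kaplan-Meier estimator matches hand products and the empirical CDF", {
  # n = 4, one event at t = 1: S(1) = 3/4
  km <- km_curve(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_equal(km$surv[1], 0.75)

  # n = 2, events at 1 and 2: S = 1/2 then 0
  km2 <- km_curve(c(1, 2), c(1, 1))
  expect_equal(km2$surv, c(0.5, 0))

  # no events: flat curve at 1
  km3 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km3$surv, rep(1, 3))

  # without censoring the estimator is the empirical survival function
  set.seed(6)
  t <- sample(1:50, 30, replace = TRUE)
  km4 <- km_curve(t, rep(1, 30))
  expect_equal(km4$surv, vapply(km4$time, function(u) mean(t > u), numeric(1)))
})

test_that("Kaplan-Meier curve and Greenwood band match the survival package", {
  skip_if_not_installed("survival")
  set.seed(7)
  for (i in 1:5) {
    n <- sample(10:60, 1)
    t <- rexp(n, 0.1) + 0.01; e <- rbinom(n, 1, 0.6)
    km <- km_curve(t, e)
    sf <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "log-log")
    sm <- summary(sf, times = km$time)
    expect_equal(km$surv, sm$surv, tolerance = 1e-8)
    expect_equal(km$n_risk, as.numeric(sm$n.risk), tolerance = 1e-8)
    # the log-log Greenwood band is defined for S strictly inside (0, 1);
    # survfit reports NA at S = 1 and S = 0 where we clip to [1,1]/[0,0]
    ok <- km$surv > 0 & km$surv < 1 & !is.na(sm$lower)
    expect_equal(km$lower[ok], sm$lower[ok], tolerance = 1e-8)
    expect_equal(km$upper[ok], sm$upper[ok], tolerance = 1e-8)
  }
})

test_that("log-rank test matches the hand hypergeometric oracle and survdiff", {
  # identical samples in both groups: O = E, statistic 0, p = 1
  t <- c(1, 2, 3, 1, 2, 3); e <- c(1, 0, 1, 1, 0, 1)
  g <- rep(c("A", "B"), each = 3)
  same <- logrank_test(g, t, e)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # hand-computed worked example: chi-square = 49/17, p ~ 0.090
  lr <- logrank_test(c("A", "A", "B", "B"), c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$p, stats::pchisq(49 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # relabeling symmetry
  lr_swap <- logrank_test(c("B", "B", "A", "A"), c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(lr_swap$chisq, lr$chisq, tolerance = 1e-12)
  expect_equal(lr_swap$p, lr$p, tolerance = 1e-12)

  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    t <- rexp(n, 0.1) + 0.01; e <- rbinom(n, 1, 0.7)
    g <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(g)) < 2) g[1:2] <- c("A", "B")
    ours <- logrank_test(g, t, e)
    ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(ours$chisq, ref$chisq, tolerance = 1e-8)
  }
})

test_that("median split follows the >=-median rule with upper-middle threshold", {
  s4 <- median_risk_split(c(1, 2, 3, 4))
  expect_equal(as.character(s4), c("low", "low", "high", "high"))
  s3 <- median_risk_split(c(1, 2, 3))
  expect_equal(as.character(s3), c("low", "high", "high"))
  expect_warning(deg <- median_risk_split(c(2, 2, 2)),
                 class = "pcm_degenerate_split")
  expect_true(attr(deg, "degenerate"))
  # monotone-rescaling invariance of the grouping
  set.seed(9)
  r <- rnorm(11)
  expect_equal(as.character(median_risk_split(r)),
               as.character(median_risk_split(exp(r))))
})

test_that("paired bootstrap z-test behaves on identical models and fixed seeds", {
  set.seed(10)
  n <- 30
  r <- rnorm(n); t <- rexp(n) + 0.1; e <- rbinom(n, 1, 0.7); e[1] <- 1
  same <- bootstrap_ci_and_ztest(r, r, t, e, n_boot = 50, seed = 3)
  expect_equal(same$p, 1)
  expect_equal(same$z, 0)

  # identical seeds give bit-identical results
  set.seed(11)
  rb <- rnorm(n)
  c1 <- bootstrap_ci_and_ztest(r, rb, t, e, n_boot = 50, seed = 5)
  c2 <- bootstrap_ci_and_ztest(r, rb, t, e, n_boot = 50, seed = 5)
  expect_identical(c1$ci_a, c2$ci_a)
  expect_identical(c1$ci_b, c2$ci_b)
  expect_identical(c1$p, c2$p)
})

test_that("bootstrap intervals match an independent seeded re-implementation", {
  n <- 5
  r_a <- c(0.2, 1.5, -0.3, 0.8, 0.1)
  r_b <- c(1.0, 0.0, 0.4, -0.2, 0.6)
  t <- c(2, 5, 3, 9, 4); e <- c(1, 0, 1, 1, 1)
  got <- suppressWarnings(
    bootstrap_ci_and_ztest(r_a, r_b, t, e, n_boot = 50, seed = 13))
  # independent loop reproducing the documented resampling scheme
  ref <- withr::with_seed(13, {
    ca <- cb <- numeric(50)
    for (rr in 1:50) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        va <- cindex_brute(r_a[idx], t[idx], e[idx])
        vb <- cindex_brute(r_b[idx], t[idx], e[idx])
        if (!is.na(va) && !is.na(vb)) break
      }
      ca[rr] <- va; cb[rr] <- vb
    }
    list(ci_a = quantile(ca, c(0.025, 0.975), names = FALSE),
         ci_b = quantile(cb, c(0.025, 0.975), names = FALSE))
  })
  expect_equal(got$ci_a, ref$ci_a, tolerance = 1e-12)
  expect_equal(got$ci_b, ref$ci_b, tolerance = 1e-12)
})

test_that("Mann-Whitney comparison is exact for fold-level scores", {
  same <- mannwhitney_compare(c(0.7, 0.8, 0.6, 0.9, 0.5),
                              c(0.7, 0.8, 0.6, 0.9, 0.5))
  expect_equal(same$p, 1)

  sep <- mannwhitney_compare(rep(0.9, 5), rep(0.1, 5))
  expect_equal(sep$U, 25)
  expect_equal(sep$p, 2 * factorial(5)^2 / factorial(10), tolerance = 1e-12)

  swap <- mannwhitney_compare(rep(0.1, 5), rep(0.9, 5))
  expect_equal(swap$p, sep$p)
  expect_equal(swap$U, 25 - sep$U)

  skip_if_not_installed("survival")  # just gates on suggests being present
  set.seed(12)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(mannwhitney_compare(a, b)$p,
               stats::wilcox.test(a, b, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("cross-validation aggregation pools folds with integrity checks", {
  set.seed(13)
  n <- 40
  preds <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:n),
    cancer_type = rep(c("BLCA", "BRCA"), each = n / 2),
    time = rexp(n, 0.05) + 0.1,
    event = rbinom(n, 1, 0.7),
    fold = rep(1:2, n / 2),
    risk = rnorm(n))
  preds$event[1] <- 1L
  rep_ <- aggregate_cv(preds)
  expect_s3_class(rep_, "pcm_eval_report")
  # pooled C-index equals brute-force counting over the union of folds
  expect_equal(rep_$overall$c_index,
               cindex_brute(preds$risk, preds$time, preds$event))
  # per-cancer subsets partition the pooled set
  expect_equal(sum(rep_$per_cancer$n), n)
  expect_equal(sum(rep_$per_cancer$n_events), sum(preds$event))

  # perfect ordering gives C-index 1
  perf <- preds; perf$risk <- -perf$time; perf$event <- 1L
  expect_equal(aggregate_cv(perf)$overall$c_index, 1)

  dup <- dplyr::bind_rows(preds, preds[1, ])
  expect_error(aggregate_cv(dup), class = "pcm_integrity_error")
  expect_error(aggregate_cv(preds, expected_ids = c(preds$patient_id, "extra")),
               class = "pcm_integrity_error")
  expect_error(aggregate_cv(preds[, -1]), class = "pcm_schema_error")

  td <- tidy(rep_)
  expect_equal(nrow(td), 3L)   # two cancers + overall
  expect_s3_class(glance(rep_), "tbl_df")
  expect_s3_class(autoplot(rep_), "ggplot")
})
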