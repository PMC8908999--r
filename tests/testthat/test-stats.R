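test_that("ANCOVA matches an explicit normal-equations oracle", {
  withr::with_seed(17, {
    for (k in 1:5) {
      n <- 12
      group <- rep(c("a", "b"), each = n / 2)
      covariate <- runif(n, 10, 40)
      y <- 2 + 0.05 * covariate + 0.4 * (group == "b") + rnorm(n, sd = 0.5)
      fit <- ancova_group_effect(y, group, covariate)
      orc <- ancova_oracle(y, group, covariate)
      expect_equal(fit$F, orc$F, tolerance = 1e-8)
      expect_equal(fit$p_raw, orc$p, tolerance = 1e-8)
      expect_equal(fit$df, c(1, n - 3))
    }
  })
})

test_that("ANCOVA is null by construction when groups are identical", {
  y <- rep(c(1.2, 3.4, 2.2, 4.1, 0.7, 2.9), 2)
  group <- rep(c("a", "b"), each = 6)
  covariate <- rep(c(5, 8, 7, 9, 4, 6), 2)
  fit <- ancova_group_effect(y, group, covariate)
  expect_equal(fit$F, 0, tolerance = 1e-20)
  expect_equal(fit$p_raw, 1, tolerance = 1e-12)
})

test_that("Bonferroni adjustment multiplies and caps", {
  y <- c(1, 2, 3, 4, 2, 3, 4, 5)
  group <- rep(c("a", "b"), each = 4)
  covariate <- c(1, 2, 3, 4, 1, 2, 3, 4)
  fit <- ancova_group_effect(y, group, covariate, m_comparisons = 3)
  expect_equal(fit$p_bonferroni, min(1, 3 * fit$p_raw))
  expect_equal(tidy(fit)$p.adjusted, fit$p_bonferroni)
  expect_named(glance(fit),
               c("statistic", "df", "df.residual", "p.value", "p.adjusted",
                 "m.comparisons"))
})

test_that("ANCOVA reports inestimable designs", {
  group <- rep(c("a", "b"), each = 4)
  covariate <- as.numeric(group == "b")  # collinear with group
  y <- rnorm(8)
  expect_error(ancova_group_effect(y, group, covariate), "inestimable")
})

test_that("Pearson correlation matches the closed-form and flags degeneracy", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1))$r, -1)
  withr::with_seed(3, {
    x <- rnorm(10); y <- rnorm(10)
  })
  got <- pearson_correlation(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("Mann-Whitney U enumerates exactly for small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 2 / 20)  # the two fully separated assignments of C(6,3)
  expect_equal(res$method, "exact enumeration")

  # identical multisets: symmetric, p = 1
  same <- mann_whitney_u(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$p, 1)

  # two-sided symmetry under sample swap
  a <- c(0.3, 1.2, 2.2, 2.5); b <- c(0.9, 1.4, 3.3)
  expect_equal(mann_whitney_u(a, b)$p, mann_whitney_u(b, a)$p)
})

test_that("Mann-Whitney large-sample branch agrees with the base implementation", {
  withr::with_seed(21, {
    a <- rnorm(15); b <- rnorm(18, mean = 0.6)
  })
  got <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$method, "normal approximation")
})

test_that("ROC analysis reproduces the pair-counting AUC and confusion metrics", {
  scores <- c(1, 2, 3, 2, 3, 4)
  labels <- rep(c("GBM", "met"), each = 3)
  roc <- roc_analysis(scores, labels, positive_class = "met")
  expect_equal(roc$auc, 7 / 9)
  expect_equal(roc$auc, paircount_auc(scores, labels, "met"))
  expect_equal(roc$direction, ">=")

  # perfect separation
  sep <- roc_analysis(c(1, 2, 3, 10, 11, 12), labels, positive_class = "met")
  expect_equal(sep$auc, 1)
  expect_equal(sep$sens, 1)
  expect_equal(sep$spec, 1)
  expect_equal(sep$ppv, 1)

  # rank invariance under strictly increasing transforms
  tr <- roc_analysis(exp(scores), labels, positive_class = "met")
  expect_equal(tr$auc, roc$auc)
  expect_equal(c(tr$sens, tr$spec, tr$ppv, tr$npv),
               c(roc$sens, roc$spec, roc$ppv, roc$npv))

  expect_error(roc_analysis(scores, rep("met", 6), "met"), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  withr::with_seed(41, {
    scores <- c(rnorm(20, 1), rnorm(15))
    labels <- c(rep("pos", 20), rep("neg", 15))
  })
  roc <- roc_analysis(scores, labels, "pos")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc$auc, ref, tolerance = 1e-12)
})

test_that("the lower-is-positive direction is auto-detected", {
  scores <- c(5, 6, 7, 1, 2, 3)
  labels <- rep(c("neg", "pos"), each = 3)
  roc <- roc_analysis(scores, labels, positive_class = "pos")
  expect_equal(roc$direction, "<=")
  expect_equal(roc$auc, 1)
})

test_that("ROC AUC equals the Mann-Whitney statistic and the cutpoint search is exhaustive", {
  withr::with_seed(31, {
    for (k in 1:25) {
      n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
      scores <- c(sample(1:8, n1, replace = TRUE) + 0.2,
                  sample(2:9, n2, replace = TRUE))
      labels <- c(rep("pos", n1), rep("neg", n2))
      roc <- roc_analysis(scores, labels, "pos")
      auc_pairs <- paircount_auc(scores, labels, "pos")
      expected <- if (roc$direction == ">=") auc_pairs else 1 - auc_pairs
      expect_equal(roc$auc, expected, tolerance = 1e-12)

      # exhaustive cutpoint oracle over the same candidate set
      j <- roc$sensitivity + roc$specificity
      expect_equal(j[match(roc$optimal_cutpoint, roc$thresholds)], max(j))
    }
  })
})

test_that("cohort-level wrappers return tidy per-metric and per-group tables", {
  cohort <- simulate_cohort(default_cohort_config(seed = 12))
  res <- analyze_cohort(cohort)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_bonferroni >= res$p_raw - 1e-15))
  expect_true(all(res$auc >= 0 & res$auc <= 1))

  cors <- cohort_correlations(cohort)
  expect_equal(nrow(cors), 4)
  expect_true(all(abs(cors$r) <= 1))

  cmp <- cohort_group_comparisons(cohort)
  expect_equal(cmp$variable, c("age", "t2_volume"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})

test_that("ROC results plot and tidy", {
  cohort <- simulate_cohort(default_cohort_config(seed = 12))
  roc <- roc_analysis(cohort$v_csf_norm, cohort$group, "GBM")
  curve <- tidy(roc)
  expect_named(curve, c("threshold", "sensitivity", "specificity"))
  gl <- glance(roc)
  expect_equal(gl$auc, roc$auc)
  p <- autoplot(roc)
  expect_s3_class(p, "ggplot")
  p2 <- plot_cohort_metrics(cohort)
  expect_s3_class(p2, "ggplot")
})
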