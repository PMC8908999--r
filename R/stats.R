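#' One-way ANCOVA group effect controlling for a covariate
#'
#' Fits the linear model `y = b0 + b1 group + b2 covariate` and tests the
#' group term with a partial F-test against the full-model residual
#' (equivalent to the Type-III test for this two-predictor design). For two
#' groups the degrees of freedom are (1, n - 3). The raw p-value is
#' Bonferroni-adjusted for `m_comparisons` tests.
#'
#' @param y Numeric response (one metric).
#' @param group Two-or-more-level grouping vector.
#' @param covariate Numeric covariate (here: perilesional T2 lesion volume).
#' @param m_comparisons Number of comparisons in the Bonferroni family.
#' @return An object of class `dmi_ancova` with fields `F`, `df`, `p_raw`,
#'   `p_bonferroni`, `adjusted_means` and the fitted `model`.
#' @export
ancova_group_effect <- function(y, group, covariate, m_comparisons = 1L) {
  group <- factor(group)
  n <- length(y)
  assert_that(nlevels(group) >= 2, "need at least 2 groups")
  assert_that(n >= 4 && length(group) == n && length(covariate) == n,
              "y, group and covariate must have equal length >= 4")
  assert_that(all(is.finite(y)) && all(is.finite(covariate)),
              "y and covariate must be finite")
  dat <- data.frame(y = y, group = group, covariate = covariate)
  full <- stats::lm(y ~ covariate + group, data = dat)
  if (full$rank < nlevels(group) + 1) {
    stopf(paste("group effect is inestimable: covariate is collinear with",
                "the group factor"))
  }
  reduced <- stats::lm(y ~ covariate, data = dat)
  aov_tab <- stats::anova(reduced, full)
  f_stat <- aov_tab$F[2]
  df1 <- aov_tab$Df[2]
  df2 <- full$df.residual
  p_raw <- aov_tab$`Pr(>F)`[2]
  # Group means adjusted to the grand mean of the covariate.
  newdata <- data.frame(group = levels(group), covariate = mean(covariate))
  adj <- setNames(as.numeric(stats::predict(full, newdata)), levels(group))
  structure(
    list(F = f_stat, df = c(df1, df2), p_raw = p_raw,
         p_bonferroni = min(1, m_comparisons * p_raw),
         m_comparisons = as.integer(m_comparisons),
         adjusted_means = adj, model = full),
    class = "dmi_ancova"
  )
}

#' @export
print.dmi_ancova <- function(x, ...) {
  cat(sprintf("<dmi_ancova> F(%d, %d) = %.3f, p = %.4g (Bonferroni x%d: %.4g)\n",
              x$df[1], x$df[2], x$F, x$p_raw, x$m_comparisons, x$p_bonferroni))
  invisible(x)
}

#' @rdname ancova_group_effect
#' @param x A `dmi_ancova` object.
#' @param ... Unused.
#' @export
tidy.dmi_ancova <- function(x, ...) {
  tibble(term = "group", statistic = x$F, df = x$df[1], df.residual = x$df[2],
         p.value = x$p_raw, p.adjusted = x$p_bonferroni)
}

#' @rdname ancova_group_effect
#' @export
glance.dmi_ancova <- function(x, ...) {
  tibble(statistic = x$F, df = x$df[1], df.residual = x$df[2],
         p.value = x$p_raw, p.adjusted = x$p_bonferroni,
         m.comparisons = x$m_comparisons)
}

#' Pearson product-moment correlation with significance
#'
#' Standard Pearson r with the two-sided p-value from the t transform
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A tibble with columns `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  n <- length(x)
  assert_that(n >= 3 && length(y) == n, "need paired vectors of length >= 3")
  assert_that(sd(x) > 0 && sd(y) > 0,
              "correlation undefined for zero-variance input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  tibble(r = r, p = p, n = n)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U. For combined sample size <= `exact_max` the
#' p-value is computed by exact enumeration of all group assignments over the
#' midranks (so tied data are handled by the same midrank convention); larger
#' samples use the normal approximation with the tie-corrected variance.
#'
#' @param a,b Numeric samples.
#' @param exact_max Largest combined size for exact enumeration.
#' @return A tibble with columns `U` (statistic of sample `a`), `p`,
#'   `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  n1 <- length(a); n2 <- length(b)
  assert_that(n1 > 0 && n2 > 0, "both samples must be nonempty")
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_of <- function(first_idx) sum(rk[first_idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  n <- n1 + n2
  if (n <= exact_max) {
    assign_sets <- combn(n, n1)
    u_all <- apply(assign_sets, 2, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- (u_obs - mu) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(U = u_obs, p = p, method = method)
}

#' ROC analysis with the Youden-optimal cutpoint
#'
#' Builds the empirical ROC curve over candidate cutpoints (midpoints between
#' consecutive distinct scores, plus -Inf and +Inf sentinels), selects the
#' classification direction (`">="` or `"<="` predicts positive) as the one
#' whose best sensitivity + specificity is higher, computes the trapezoidal
#' AUC, and reports the cutpoint maximizing sensitivity + specificity
#' ("equally weighted" Youden criterion). Exact ties in the objective are
#' broken toward the smallest candidate cutpoint.
#'
#' @param scores Numeric classifier scores.
#' @param labels Class labels (two classes present).
#' @param positive_class The label treated as positive.
#' @return An object of class `dmi_roc` with the curve, `auc`,
#'   `optimal_cutpoint`, `direction`, and `sens`/`spec`/`ppv`/`npv` at the
#'   cutpoint.
#' @export
roc_analysis <- function(scores, labels, positive_class) {
  assert_that(length(scores) == length(labels), "scores and labels must align")
  is_pos <- labels == positive_class
  assert_that(any(is_pos) && any(!is_pos),
              "both classes must be present (positive class: %s)",
              as.character(positive_class))
  s_sorted <- sort(unique(scores))
  cand <- c(-Inf, if (length(s_sorted) > 1)
    (s_sorted[-1] + s_sorted[-length(s_sorted)]) / 2, Inf)
  curve_for <- function(direction) {
    pos_call <- if (direction == ">=") {
      function(t) scores >= t
    } else {
      function(t) scores <= t
    }
    sens <- vapply(cand, function(t) mean(pos_call(t)[is_pos]), numeric(1))
    spec <- vapply(cand, function(t) mean(!pos_call(t)[!is_pos]), numeric(1))
    list(direction = direction, sens = sens, spec = spec,
         best = max(sens + spec))
  }
  c_ge <- curve_for(">=")
  c_le <- curve_for("<=")
  cur <- if (c_ge$best >= c_le$best) c_ge else c_le
  # Trapezoidal AUC over the empirical curve in (FPR, TPR) space.
  ord <- order(1 - cur$spec, cur$sens)
  fpr <- (1 - cur$spec)[ord]; tpr <- cur$sens[ord]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  j <- cur$sens + cur$spec
  best_idx <- which(j >= max(j) - 1e-12)
  opt_idx <- best_idx[which.min(cand[best_idx])]
  cut <- cand[opt_idx]
  called_pos <- if (cur$direction == ">=") scores >= cut else scores <= cut
  tp <- sum(called_pos & is_pos); fp <- sum(called_pos & !is_pos)
  fn <- sum(!called_pos & is_pos); tn <- sum(!called_pos & !is_pos)
  structure(
    list(thresholds = cand, sensitivity = cur$sens, specificity = cur$spec,
         auc = auc, optimal_cutpoint = cut, direction = cur$direction,
         sens = tp / (tp + fn), spec = tn / (tn + fp),
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         positive_class = positive_class,
         n_pos = sum(is_pos), n_neg = sum(!is_pos)),
    class = "dmi_roc"
  )
}

#' @export
print.dmi_roc <- function(x, ...) {
  cat(sprintf(
    "<dmi_roc> AUC = %.3f; cutpoint %.4g (%s predicts %s); sens %.3f, spec %.3f\n",
    x$auc, x$optimal_cutpoint, x$direction, as.character(x$positive_class),
    x$sens, x$spec))
  invisible(x)
}

#' @rdname roc_analysis
#' @param x A `dmi_roc` object.
#' @param ... Unused.
#' @export
tidy.dmi_roc <- function(x, ...) {
  tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
         specificity = x$specificity)
}

#' @rdname roc_analysis
#' @export
glance.dmi_roc <- function(x, ...) {
  tibble(auc = x$auc, cutpoint = x$optimal_cutpoint, direction = x$direction,
         sens = x$sens, spec = x$spec, ppv = x$ppv, npv = x$npv,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Group-level analysis of a cohort table
#'
#' Runs, per normalized metric, the ANCOVA group test controlling for the T2
#' lesion volume (Bonferroni-corrected over the three metrics) and the ROC
#' analysis with the Youden-optimal cutpoint, with GBM as the positive class.
#'
#' @param cohort A cohort tibble as produced by [simulate_cohort()] (or an
#'   assembled imaging cohort with the same columns).
#' @param metrics Metric columns to analyze.
#' @param positive_class Label treated as ROC-positive.
#' @return A tibble with one row per metric: `metric`, `F`, `df1`, `df2`,
#'   `p_raw`, `p_bonferroni`, `auc`, `cutpoint`, `direction`, `sens`,
#'   `spec`, `ppv`, `npv`.
#' @export
#' @examples
#' analyze_cohort(simulate_cohort(default_cohort_config(seed = 3)))
analyze_cohort <- function(cohort,
                           metrics = c("v_intra_norm", "v_extra_norm",
                                       "v_csf_norm"),
                           positive_class = "GBM") {
  assert_that(all(metrics %in% names(cohort)),
              "cohort is missing metric columns")
  m <- length(metrics)
  purrr::map_dfr(metrics, function(met) {
    anc <- ancova_group_effect(cohort[[met]], cohort$group,
                               cohort$t2_volume, m_comparisons = m)
    roc <- roc_analysis(cohort[[met]], cohort$group, positive_class)
    tibble(metric = met, F = anc$F, df1 = anc$df[1], df2 = anc$df[2],
           p_raw = anc$p_raw, p_bonferroni = anc$p_bonferroni,
           auc = roc$auc, cutpoint = roc$optimal_cutpoint,
           direction = roc$direction, sens = roc$sens, spec = roc$spec,
           ppv = roc$ppv, npv = roc$npv)
  })
}

#' Within-group correlation summary
#'
#' Pearson correlations reported per group: V-CSF against perilesional T2
#' volume, and age against V-CSF.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `group`, `pair`, `r`, `p`, `n`.
#' @export
cohort_correlations <- function(cohort) {
  purrr::map_dfr(split(cohort, cohort$group), function(g) {
    dplyr::bind_rows(
      dplyr::mutate(pearson_correlation(g$v_csf_norm, g$t2_volume),
                    pair = "v_csf_norm~t2_volume", .before = 1),
      dplyr::mutate(pearson_correlation(g$age, g$v_csf_norm),
                    pair = "age~v_csf_norm", .before = 1)
    ) |>
      dplyr::mutate(group = g$group[1], .before = 1)
  })
}

#' Group comparisons of age and lesion volume
#'
#' Mann-Whitney U comparisons of age and perilesional T2 volume between the
#' two groups.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `variable`, `U`, `p`, `method`.
#' @export
cohort_group_comparisons <- function(cohort) {
  groups <- unique(cohort$group)
  assert_that(length(groups) == 2, "cohort must contain exactly 2 groups")
  a <- cohort[cohort$group == groups[1], ]
  b <- cohort[cohort$group == groups[2], ]
  dplyr::bind_rows(
    dplyr::mutate(mann_whitney_u(a$age, b$age), variable = "age", .before = 1),
    dplyr::mutate(mann_whitney_u(a$t2_volume, b$t2_volume),
                  variable = "t2_volume", .before = 1)
  )
}
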