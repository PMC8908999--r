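#' Log-normal parameters from a target median and IQR
#'
#' A log-normal with log-mean `mu` and log-sd `sigma` has median `exp(mu)`
#' and IQR `2 exp(mu) sinh(z sigma)` with `z = qnorm(0.75)`, so both
#' parameters invert in closed form:
#' `mu = log(median)`, `sigma = asinh(IQR / (2 median)) / z`.
#'
#' @param median,iqr Target population median and interquartile range (> 0).
#' @return Named numeric vector `c(mu, sigma)`.
#' @export
lognormal_from_median_iqr <- function(median, iqr) {
  assert_that(median > 0 && iqr > 0, "median and IQR must be positive")
  c(mu = log(median), sigma = asinh(iqr / (2 * median)) / qnorm(0.75))
}

# Pearson correlation induced between two lognormals by latent correlation r.
lnln_pearson <- function(r, s1, s2) {
  (exp(r * s1 * s2) - 1) / sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))
}

# Latent correlation needed so two lognormals (log-sds s1, s2) show Pearson
# correlation `target` on the observed scale.
latent_for_lnln <- function(target, s1, s2, pair = "pair") {
  arg <- 1 + target * sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))
  assert_that(arg > 0, "correlation target for %s is infeasible", pair)
  r <- log(arg) / (s1 * s2)
  assert_that(abs(r) < 1, "correlation target for %s needs |latent r| >= 1", pair)
  r
}

# Latent correlation so a normal and a lognormal (log-sd s2) show Pearson
# correlation `target`.
latent_for_nln <- function(target, s2, pair = "pair") {
  r <- target * sqrt(exp(s2^2) - 1) / s2
  assert_that(abs(r) < 1, "correlation target for %s needs |latent r| >= 1", pair)
  r
}

group_config <- function(n, age_mean, age_sd, sex_mf, steroid_n,
                         volume_median, volume_iqr,
                         v_intra, v_extra, v_csf,
                         r_vcsf_volume, r_age_vcsf) {
  list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
       sex_mf = sex_mf, steroid_n = as.integer(steroid_n),
       volume_median = volume_median, volume_iqr = volume_iqr,
       v_intra = v_intra, v_extra = v_extra, v_csf = v_csf,
       r_vcsf_volume = r_vcsf_volume, r_age_vcsf = r_age_vcsf)
}

#' Cohort simulator configuration
#'
#' Targets for the patient-level simulator: per-group sample sizes, (median,
#' IQR) targets for the NAWM-normalized metrics and the perilesional T2
#' volume, age mean/SD, sex counts, steroid counts, and the two reported
#' correlation structures (V-CSF with T2 volume; age with V-CSF).
#'
#' @param gbm,metastasis Per-group lists as built by the defaults; each
#'   metric entry is `c(median, iqr)`.
#' @param seed Integer seed.
#' @return An object of class `dmi_cohort_config`.
#' @seealso [default_cohort_config()]
#' @export
cohort_config <- function(gbm, metastasis, seed = 1L) {
  cfg <- structure(list(gbm = gbm, metastasis = metastasis,
                        seed = as.integer(seed)),
                   class = "dmi_cohort_config")
  for (gname in c("gbm", "metastasis")) {
    g <- cfg[[gname]]
    assert_that(g$n >= 2, "group sizes must be at least 2")
    for (m in c("v_intra", "v_extra", "v_csf")) {
      assert_that(g[[m]][1] > 0 && g[[m]][2] > 0,
                  "%s %s median and IQR must be positive", gname, m)
    }
    assert_that(g$volume_median > 0 && g$volume_iqr > 0,
                "%s volume median and IQR must be positive", gname)
    assert_that(abs(g$r_vcsf_volume) < 1 && abs(g$r_age_vcsf) < 1,
                "%s correlation targets must lie in (-1, 1)", gname)
    # Fail early if the compensated latent matrix is not positive definite.
    latent_correlation(g, gname)
  }
  cfg
}

# 5x5 latent Gaussian correlation matrix for one group, in variable order
# (age, t2_volume, v_intra, v_extra, v_csf). Pearson targets are analytically
# compensated for the lognormal transforms so the observed-scale correlations
# hit the configured values.
latent_correlation <- function(g, gname = "group") {
  s_vol <- lognormal_from_median_iqr(g$volume_median, g$volume_iqr)[["sigma"]]
  s_csf <- lognormal_from_median_iqr(g$v_csf[1], g$v_csf[2])[["sigma"]]
  r <- diag(5)
  r[2, 5] <- r[5, 2] <- latent_for_lnln(
    g$r_vcsf_volume, s_vol, s_csf, paste0(gname, " (v_csf, t2_volume)"))
  r[1, 5] <- r[5, 1] <- latent_for_nln(
    g$r_age_vcsf, s_csf, paste0(gname, " (age, v_csf)"))
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > 1e-10,
              paste("latent correlation matrix for %s is not positive",
                    "definite; pairs (v_csf, t2_volume) and (age, v_csf)",
                    "are jointly infeasible"), gname)
  r
}

#' Default cohort configuration
#'
#' Group sizes 19 (GBM) and 17 (metastasis); NAWM-normalized metric targets
#' (median, IQR): GBM V-intra 0.25/0.13, V-extra 0.88/0.30, V-CSF 3.17/1.26;
#' metastasis 0.20/0.03, 0.81/0.18, 4.52/0.86; perilesional T2 volume
#' 20.7/22.1 and 19.5/35.1 ml; ages Normal(66.4, 14.1) and Normal(63.5,
#' 11.8); V-CSF/T2-volume correlations 0.33 and 0.51; age/V-CSF correlations
#' -0.67 and -0.62; steroid counts 7/19 and 6/17; sex counts (m/f) 10/9 and
#' 9/8.
#'
#' @param seed Integer seed.
#' @return A [cohort_config()] object.
#' @export
default_cohort_config <- function(seed = 1L) {
  cohort_config(
    gbm = group_config(
      n = 19, age_mean = 66.4, age_sd = 14.1, sex_mf = c(10, 9),
      steroid_n = 7, volume_median = 20.7, volume_iqr = 22.1,
      v_intra = c(0.25, 0.13), v_extra = c(0.88, 0.30), v_csf = c(3.17, 1.26),
      r_vcsf_volume = 0.33, r_age_vcsf = -0.67),
    metastasis = group_config(
      n = 17, age_mean = 63.5, age_sd = 11.8, sex_mf = c(9, 8),
      steroid_n = 6, volume_median = 19.5, volume_iqr = 35.1,
      v_intra = c(0.20, 0.03), v_extra = c(0.81, 0.18), v_csf = c(4.52, 0.86),
      r_vcsf_volume = 0.51, r_age_vcsf = -0.62),
    seed = seed
  )
}

simulate_group <- function(g, gname, n = NULL) {
  n <- n %||% g$n
  r <- latent_correlation(g, gname)
  z <- matrix(rnorm(n * 5), n, 5) %*% chol(r)
  u <- pnorm(z)
  ln <- function(col, med_iqr) {
    p <- lognormal_from_median_iqr(med_iqr[1], med_iqr[2])
    stats::qlnorm(u[, col], p[["mu"]], p[["sigma"]])
  }
  sexes <- sample(rep(c("m", "f"), times = round(g$sex_mf * n / sum(g$sex_mf)))[seq_len(n)])
  steroid <- seq_len(n) %in% sample.int(n, min(n, round(g$steroid_n * n / g$n)))
  tibble(
    group = gname,
    age = qnorm(u[, 1], g$age_mean, g$age_sd),
    sex = sexes,
    steroid = steroid,
    t2_volume = ln(2, c(g$volume_median, g$volume_iqr)),
    v_intra_norm = ln(3, g$v_intra),
    v_extra_norm = ln(4, g$v_extra),
    v_csf_norm = ln(5, g$v_csf)
  )
}

#' Simulate a patient cohort
#'
#' Draws per-patient records for both groups. Marginals: log-normal for the
#' normalized metrics and the T2 lesion volume (positive, right-skewed,
#' parameterized so the population median and IQR equal the configured
#' targets), normal for age. Cross-variable dependence is imposed through a
#' Gaussian copula whose latent correlations are analytically compensated so
#' the observed-scale Pearson correlations match the configured targets.
#' Deterministic given the config seed.
#'
#' @param config A [cohort_config()] object.
#' @param n_per_group Optional override of both group sizes (used for
#'   large-sample fidelity checks).
#' @return A tibble with one row per patient: `id`, `group`, `age`, `sex`,
#'   `steroid`, `t2_volume`, `v_intra_norm`, `v_extra_norm`, `v_csf_norm`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_cohort_config(seed = 7))
#' dplyr::count(cohort, group)
simulate_cohort <- function(config, n_per_group = NULL) {
  assert_that(inherits(config, "dmi_cohort_config"),
              "config must be a dmi_cohort_config")
  with_seed(config$seed, {
    out <- dplyr::bind_rows(
      simulate_group(config$gbm, "GBM", n_per_group),
      simulate_group(config$metastasis, "metastasis", n_per_group)
    )
    dplyr::mutate(out, id = sprintf("P%03d", dplyr::row_number()),
                  .before = 1)
  })
}
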