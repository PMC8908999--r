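# Shared fixtures and independent oracles.
# Everything here is computed once per test run.

the_scheme <- default_scheme()

# Estimator trained under the default (wide, physiologic) prior: the study
# condition used for recovery and pipeline tests.
the_estimator <- train_estimator(prior_spec(seed = 42L), the_scheme)

# Estimator trained with the prior concentrated at the canonical
# diffusivities; used for estimator-vs-grid-oracle equivalence checks, where
# both routes must condition on the same diffusivities.
the_canonical_estimator <- train_estimator(
  prior_spec(D_i_range = c(2.0, 2.0), D_e_par_range = c(1.5, 1.5),
             perp_ratio_range = c(1 / 3, 1 / 3), seed = 42L),
  the_scheme
)

# n fraction triplets uniform on the simplex, plus unit orientations.
draw_simplex <- function(n, seed) {
  withr::with_seed(seed, {
    e <- matrix(-log(runif(3 * n)), n, 3)
    u <- matrix(rnorm(3 * n), n, 3)
    list(v = e / rowSums(e), u = u / sqrt(rowSums(u^2)))
  })
}

# Parameter table at the canonical diffusivities for given fractions.
canonical_draws <- function(v, u) {
  tibble::tibble(v_i = v[, 1], v_e = v[, 2], v_f = v[, 3],
                 D_i = 2.0, D_e_par = 1.5, D_e_perp = 0.5, D_f = 3.0,
                 ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

render_signals <- function(draws, scheme = the_scheme) {
  dmisim:::render_signal_matrix(draws, scheme)
}

add_noise_matrix <- function(s, snr, seed) {
  withr::with_seed(seed, {
    e1 <- matrix(rnorm(length(s)), nrow(s)) / snr
    e2 <- matrix(rnorm(length(s)), nrow(s)) / snr
    sqrt((s + e1)^2 + e2^2)
  })
}

# Quadrature oracle: spherical mean of a directional attenuation by
# averaging over a dense deterministic direction set (Fibonacci spiral).
quad_dirs <- dmisim:::fibonacci_sphere(10000)
quadrature_stick_mean <- function(b, D, u = c(0, 0, 1)) {
  mean(exp(-b * D * as.numeric(quad_dirs %*% u)^2))
}
quadrature_zeppelin_mean <- function(b, D_par, D_perp, u = c(0, 0, 1)) {
  t2 <- as.numeric(quad_dirs %*% u)^2
  mean(exp(-b * (D_perp + (D_par - D_perp) * t2)))
}

# Pair-counting AUC oracle: (concordant + ties/2) / (n_pos * n_neg), for the
# direction "higher score predicts positive".
paircount_auc <- function(scores, labels, positive_class) {
  pos <- scores[labels == positive_class]
  neg <- scores[labels != positive_class]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Normal-equations ANCOVA oracle: explicit design matrices, RSS comparison.
ancova_oracle <- function(y, group, covariate) {
  g <- as.integer(factor(group)) - 1L
  n <- length(y)
  x_full <- cbind(1, covariate, g)
  x_red <- cbind(1, covariate)
  beta_full <- solve(t(x_full) %*% x_full, t(x_full) %*% y)
  beta_red <- solve(t(x_red) %*% x_red, t(x_red) %*% y)
  rss_full <- sum((y - x_full %*% beta_full)^2)
  rss_red <- sum((y - x_red %*% beta_red)^2)
  f_stat <- (rss_red - rss_full) / (rss_full / (n - 3))
  list(F = f_stat, p = stats::pf(f_stat, 1, n - 3, lower.tail = FALSE))
}

# A signal vector whose per-shell powder means equal the closed-form
# compartment means exactly (every volume in a shell carries the shell mean),
# for zero-residual oracle checks.
closed_form_shell_signal <- function(v, scheme = the_scheme,
                                     D_i = 2.0, D_e_par = 1.5,
                                     D_e_perp = 0.5, D_f = 3.0) {
  s <- numeric(length(scheme$bvalues))
  s[scheme$shell_id == 0] <- 1
  for (j in seq_along(scheme$shells)) {
    b <- scheme$shells[j]
    m <- v[1] * dmisim:::stick_mean(b, D_i) +
      v[2] * dmisim:::zeppelin_mean(b, D_e_par, D_e_perp) +
      v[3] * exp(-b * D_f)
    s[scheme$shell_id == j] <- m
  }
  s
}
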