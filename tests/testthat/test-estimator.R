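test_that("prior draws are uniform on the simplex and deterministic", {
  pr <- prior_spec(seed = 9, n_samples = 3000)
  d1 <- sample_prior(pr)
  d2 <- sample_prior(pr)
  expect_identical(d1, d2)
  expect_lt(abs(mean(d1$v_i) - 1 / 3), 0.02)
  expect_lt(abs(mean(d1$v_e) - 1 / 3), 0.02)
  expect_lt(abs(mean(d1$v_f) - 1 / 3), 0.02)
  expect_true(all(abs(d1$v_i + d1$v_e + d1$v_f - 1) < 1e-12))
  expect_true(all(d1$D_e_perp <= d1$D_e_par))
  expect_true(all(d1$D_i >= 1.0 & d1$D_i <= 2.5))
})

test_that("prior specification rejects invalid ranges and sizes", {
  expect_error(prior_spec(n_samples = 500), "1000")
  expect_error(prior_spec(D_i_range = c(2.5, 1.0)), "interval")
  expect_error(prior_spec(D_i_range = c(0, 3.0)), "interval")
  expect_error(prior_spec(perp_ratio_range = c(0.5, 1.2)), "interval")
})

test_that("signal features are per-shell powder means normalized by b0", {
  sch <- the_scheme
  ball <- microstructure_params(0, 0, 1)
  f <- signal_features(voxel_signal(ball, sch), sch)
  expect_equal(unname(f), c(exp(-3), exp(-6)), tolerance = 1e-12)

  # scale invariance
  s <- voxel_signal(microstructure_params(0.4, 0.45, 0.15), sch)
  expect_equal(signal_features(5.5 * s, sch), signal_features(s, sch))

  # stick powder mean appears as the feature, cross-checked by quadrature
  stick <- microstructure_params(1, 0, 0, orientation = c(1, 0, 0))
  f_stick <- signal_features(voxel_signal(stick, sch), sch)
  expect_equal(unname(f_stick[1]), quadrature_stick_mean(1, 2),
               tolerance = 2e-3)

  # same-shell permutation invariance
  perm <- seq_along(sch$bvalues)
  shell1 <- which(sch$shell_id == 1)
  perm[shell1] <- rev(shell1)
  expect_equal(signal_features(s[perm], sch), signal_features(s, sch))

  # missing b = 0 rejected
  no_b0 <- sch
  no_b0$shell_id[no_b0$shell_id == 0] <- 1L
  expect_error(signal_features(s, no_b0), "no b = 0")
})

test_that("training is deterministic and informative", {
  pr <- prior_spec(seed = 31, n_samples = 1000)
  e1 <- train_estimator(pr, the_scheme)
  e2 <- train_estimator(pr, the_scheme)
  expect_identical(e1$beta, e2$beta)

  # predictions on noise-free versions of its own training draws must beat
  # the prior spread of v_f (sd of a flat simplex marginal, ~0.236)
  draws <- sample_prior(pr)
  s <- render_signals(draws)
  pred <- predict(e1, signal_features(s, the_scheme))
  rmse_vf <- sqrt(mean((pred$v_f - draws$v_f)^2))
  expect_lt(rmse_vf, sqrt(1 / 18))
})

test_that("estimator outputs always lie on the simplex", {
  # extreme and out-of-range feature inputs still map to the simplex
  withr::with_seed(4, {
    f <- cbind(runif(200, 0, 1.2), runif(200, 0, 1.2))
  })
  v <- predict(the_estimator, f)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(abs(rowSums(as.matrix(v)) - 1) < 1e-9))
})

test_that("posterior-mean regression beats the constant prior-mean predictor", {
  hold <- sample_prior(prior_spec(seed = 123), n = 400)
  s <- render_signals(hold)
  noisy <- add_noise_matrix(s, snr = 30, seed = 9)
  pred <- as.matrix(predict(the_estimator, signal_features(noisy, the_scheme)))
  truth <- as.matrix(hold[, c("v_i", "v_e", "v_f")])
  mse_est <- colMeans((pred - truth)^2)
  mse_prior <- colMeans((1 / 3 - truth)^2)
  expect_true(all(mse_est < mse_prior))
})

test_that("grid oracle recovers exactly at zero residual and within 0.02 off-grid", {
  # zero-residual: per-shell means equal the closed forms exactly
  v <- c(0.30, 0.50, 0.20)
  s <- closed_form_shell_signal(v)
  expect_equal(unname(grid_oracle_fit(s, the_scheme)), v, tolerance = 1e-9)

  v_off <- c(0.313, 0.471, 0.216)
  s_off <- closed_form_shell_signal(v_off)
  expect_equal(unname(grid_oracle_fit(s_off, the_scheme)), v_off,
               tolerance = 0.02)

  # pure ball
  ball <- closed_form_shell_signal(c(0, 0, 1))
  expect_equal(unname(grid_oracle_fit(ball, the_scheme)), c(0, 0, 1),
               tolerance = 1e-9)
})

test_that("volume fitting honors the mask and validates its inputs", {
  sch <- the_scheme
  shp <- c(4, 4, 3)
  draws <- canonical_draws(matrix(1 / 3, prod(shp), 3),
                           matrix(rep(c(0, 0, 1), each = prod(shp)),
                                  prod(shp), 3))
  s <- render_signals(draws)
  dwi <- array(s, c(shp, length(sch$bvalues)))

  empty <- array(0L, shp)
  maps0 <- fit_volume(dwi, sch, empty, the_estimator)
  expect_true(all(maps0$v_intra == 0) && all(maps0$v_csf == 0))

  mask <- array(1L, shp)
  maps <- fit_volume(dwi, sch, mask, the_estimator)
  sums <- maps$v_intra + maps$v_extra + maps$v_csf
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_lt(abs(mean(maps$v_csf) - 1 / 3), 0.1)

  expect_error(fit_volume(dwi, sch, array(1L, c(2, 2, 2)), the_estimator),
               "grid")
  other <- acquisition_scheme(c(0, 1, 3), rbind(c(0, 0, 0), diag(3)[1:2, ]))
  expect_error(fit_volume(dwi[, , , 1:3], other, mask, the_estimator),
               "different acquisition scheme")
})
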