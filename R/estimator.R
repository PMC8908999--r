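#' Prior specification for the simulated-regression estimator
#'
#' The Bayesian estimator is trained by simulation: microstructure parameters
#' are drawn from this prior, noisy signals are rendered under the acquisition
#' scheme, and a regression from rotation-invariant signal features to the
#' volume fractions approximates the posterior mean.
#'
#' @param D_i_range,D_e_par_range Uniform prior intervals for the intra-axonal
#'   and extra-axonal parallel diffusivities (um^2/ms).
#' @param perp_ratio_range Uniform interval for the ratio
#'   `D_e_perp / D_e_par` (guarantees `D_e_perp <= D_e_par`).
#' @param snr_range Uniform interval for the training-noise SNR at b = 0.
#' @param D_f Fixed free-water diffusivity (um^2/ms).
#' @param n_samples Training-set size (>= 1000).
#' @param seed Integer seed.
#' @return An object of class `dmi_prior`.
#' @export
prior_spec <- function(D_i_range = c(1.0, 2.5), D_e_par_range = c(0.5, 2.5),
                       perp_ratio_range = c(0.1, 1.0), snr_range = c(20, 50),
                       D_f = 3.0, n_samples = 4000, seed = 1L) {
  chk_range <- function(r, name, lo = 0, hi = 3.5) {
    assert_that(length(r) == 2 && r[1] <= r[2] && r[1] > lo && r[2] <= hi,
                "%s must be a non-empty interval within (%g, %g]", name, lo, hi)
  }
  chk_range(D_i_range, "D_i_range")
  chk_range(D_e_par_range, "D_e_par_range")
  chk_range(perp_ratio_range, "perp_ratio_range", hi = 1.0)
  assert_that(length(snr_range) == 2 && snr_range[1] <= snr_range[2] &&
                snr_range[1] > 0, "snr_range must be a positive interval")
  assert_that(n_samples >= 1000, "n_samples must be at least 1000")
  structure(
    list(D_i_range = D_i_range, D_e_par_range = D_e_par_range,
         perp_ratio_range = perp_ratio_range, snr_range = snr_range,
         D_f = D_f, n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "dmi_prior"
  )
}

#' Draw microstructure parameters from the prior
#'
#' Fractions are uniform on the 2-simplex (symmetric Dirichlet(1, 1, 1)),
#' diffusivities uniform on their intervals, orientations uniform on the
#' sphere. Deterministic given the prior's seed.
#'
#' @param prior A [prior_spec()] object.
#' @param n Number of draws; defaults to `prior$n_samples`.
#' @return A tibble with one row per draw and columns `v_i`, `v_e`, `v_f`,
#'   `D_i`, `D_e_par`, `D_e_perp`, `D_f`, `ux`, `uy`, `uz`, `snr`.
#' @export
sample_prior <- function(prior, n = prior$n_samples) {
  assert_that(inherits(prior, "dmi_prior"), "prior must be a dmi_prior")
  with_seed(prior$seed, {
    # Uniform simplex via normalized exponentials (Dirichlet(1,1,1)).
    e <- matrix(-log(runif(3 * n)), n, 3)
    v <- e / rowSums(e)
    D_i <- runif(n, prior$D_i_range[1], prior$D_i_range[2])
    D_e_par <- runif(n, prior$D_e_par_range[1], prior$D_e_par_range[2])
    ratio <- runif(n, prior$perp_ratio_range[1], prior$perp_ratio_range[2])
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    tibble(v_i = v[, 1], v_e = v[, 2], v_f = v[, 3],
           D_i = D_i, D_e_par = D_e_par, D_e_perp = ratio * D_e_par,
           D_f = prior$D_f, ux = u[, 1], uy = u[, 2], uz = u[, 3],
           snr = runif(n, prior$snr_range[1], prior$snr_range[2]))
  })
}

# Render the noise-free signal matrix (n draws x n volumes) for a prior table.
render_signal_matrix <- function(draws, scheme, s0 = 1) {
  g <- scheme$directions
  b <- scheme$bvalues
  u <- as.matrix(draws[, c("ux", "uy", "uz")])
  t2 <- (u %*% t(g))^2
  a_i <- exp(-t2 * outer(draws$D_i, b))
  a_e <- exp(-(outer(draws$D_e_perp, b) +
                 t2 * outer(draws$D_e_par - draws$D_e_perp, b)))
  a_f <- exp(-outer(draws$D_f, b))
  s0 * (draws$v_i * a_i + draws$v_e * a_e + draws$v_f * a_f)
}

#' Rotation-invariant signal features
#'
#' Per-shell powder means normalized by the mean b = 0 signal: for each
#' nonzero shell, the mean signal over that shell's directions divided by the
#' mean unweighted signal. Invariant to fibre orientation (and any same-shell
#' volume permutation), which makes them suitable regression inputs.
#'
#' @param signal Numeric vector (one value per volume) or matrix (voxels in
#'   rows, volumes in columns).
#' @param scheme The matching [acquisition_scheme()].
#' @return A numeric vector with one feature per nonzero shell (named
#'   `b<value>`), or a matrix of such rows.
#' @export
signal_features <- function(signal, scheme) {
  assert_that(inherits(scheme, "dmi_scheme"), "scheme must be a dmi_scheme")
  one_row <- is.null(dim(signal))
  s <- if (one_row) matrix(signal, nrow = 1) else as.matrix(signal)
  assert_that(ncol(s) == length(scheme$bvalues),
              "signal has %d volumes but scheme has %d",
              ncol(s), length(scheme$bvalues))
  b0_cols <- which(scheme$shell_id == 0)
  assert_that(length(b0_cols) > 0, "scheme has no b = 0 volume")
  b0 <- rowMeans(s[, b0_cols, drop = FALSE])
  k <- length(scheme$shells)
  out <- matrix(NA_real_, nrow(s), k,
                dimnames = list(NULL, paste0("b", format(scheme$shells, trim = TRUE))))
  for (j in seq_len(k)) {
    cols <- which(scheme$shell_id == j)
    out[, j] <- rowMeans(s[, cols, drop = FALSE]) / b0
  }
  if (one_row) out[1, ] else out
}

# Monomial exponent grid of total degree <= degree in k variables.
poly_exponents <- function(k, degree) {
  grid <- do.call(expand.grid, rep(list(0:degree), k))
  grid <- as.matrix(grid[rowSums(grid) <= degree, , drop = FALSE])
  grid[order(rowSums(grid), grid[, 1]), , drop = FALSE]
}

poly_design <- function(features, exponents) {
  f <- as.matrix(features)
  x <- matrix(1, nrow(f), nrow(exponents))
  for (j in seq_len(nrow(exponents))) {
    for (v in seq_len(ncol(exponents))) {
      if (exponents[j, v] > 0) x[, j] <- x[, j] * f[, v]^exponents[j, v]
    }
  }
  x
}

#' Train the posterior-mean fraction estimator
#'
#' Samples the prior, renders noisy training signals under the scheme
#' (Rician noise at each draw's SNR), expands the per-shell features in a
#' degree-3 polynomial basis, and fits least-squares regressions from the
#' basis to the three volume fractions. Predictions are clipped to \[0, 1\]
#' and renormalized to sum 1, so the output always lies on the simplex.
#'
#' @param prior A [prior_spec()] object.
#' @param scheme The acquisition scheme the estimator will be applied to.
#' @param degree Polynomial degree of the feature expansion.
#' @return An object of class `dmi_estimator`.
#' @export
train_estimator <- function(prior, scheme, degree = 3) {
  assert_that(inherits(prior, "dmi_prior"), "prior must be a dmi_prior")
  assert_that(inherits(scheme, "dmi_scheme"), "scheme must be a dmi_scheme")
  draws <- sample_prior(prior)
  s <- render_signal_matrix(draws, scheme)
  sigma <- 1 / draws$snr
  noisy <- with_seed(derive_seed(prior$seed, 101L), {
    e1 <- matrix(rnorm(length(s)), nrow(s)) * sigma
    e2 <- matrix(rnorm(length(s)), nrow(s)) * sigma
    sqrt((s + e1)^2 + e2^2)
  })
  feats <- signal_features(noisy, scheme)
  exponents <- poly_exponents(ncol(feats), degree)
  x <- poly_design(feats, exponents)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    stopf(paste("polynomial design matrix is rank deficient (rank %d < %d);",
                "increase n_samples in the prior"), qr_x$rank, ncol(x))
  }
  beta <- qr.coef(qr_x, as.matrix(draws[, c("v_i", "v_e", "v_f")]))
  structure(
    list(beta = beta, exponents = exponents, degree = degree,
         feature_names = colnames(feats), prior = prior,
         scheme_bvalues = scheme$bvalues),
    class = "dmi_estimator"
  )
}

#' @export
print.dmi_estimator <- function(x, ...) {
  cat(sprintf(
    "<dmi_estimator> degree-%d regression on %d features (%d basis terms), %d training draws\n",
    x$degree, length(x$feature_names), nrow(x$beta), x$prior$n_samples))
  invisible(x)
}

#' Predict volume fractions from signal features
#'
#' @param object A trained [train_estimator()] object.
#' @param features Feature vector or matrix as returned by
#'   [signal_features()].
#' @param ... Unused.
#' @return A tibble with columns `v_i`, `v_e`, `v_f`, rows on the simplex.
#' @export
predict.dmi_estimator <- function(object, features, ...) {
  f <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  assert_that(ncol(f) == length(object$feature_names),
              "expected %d features, got %d", length(object$feature_names), ncol(f))
  raw <- poly_design(f, object$exponents) %*% object$beta
  v <- pmin(pmax(raw, 0), 1)
  tot <- rowSums(v)
  # A degenerate all-zero prediction falls back to the prior mean.
  v[tot == 0, ] <- 1 / 3
  tot[tot == 0] <- 1
  v <- v / tot
  tibble(v_i = v[, 1], v_e = v[, 2], v_f = v[, 3])
}

#' Grid-search oracle fit of the volume fractions
#'
#' Independent verification oracle: exhaustive search over the fraction
#' simplex at step 0.02 with diffusivities fixed at canonical white-matter
#' values (D_i = 2.0, D_e_par = 1.5, D_e_perp = 0.5, D_f = 3.0), minimizing
#' the sum of squared differences between predicted and observed per-shell
#' features, followed by one exhaustive refinement pass at step/10 in a
#' +/- 2 step neighbourhood of the coarse optimum (the feature map is mildly
#' ill-conditioned, so a single 0.02 grid can land two steps away from the
#' continuous optimum). Deterministic; ties resolved in favour of the first
#' grid point in lexicographic (v_i, v_e) order.
#'
#' @param signal Signal vector (one value per volume of `scheme`).
#' @param scheme The matching [acquisition_scheme()].
#' @param step Simplex grid step.
#' @param D_i,D_e_par,D_e_perp,D_f Fixed canonical diffusivities (um^2/ms).
#' @return Named numeric vector `c(v_i, v_e, v_f)`.
#' @export
grid_oracle_fit <- function(signal, scheme, step = 0.02,
                            D_i = 2.0, D_e_par = 1.5, D_e_perp = 0.5,
                            D_f = 3.0) {
  feats <- signal_features(signal, scheme)
  shells <- scheme$shells
  comp <- cbind(intra = stick_mean(shells, D_i),
                extra = zeppelin_mean(shells, D_e_par, D_e_perp),
                free = exp(-shells * D_f))
  search <- function(lo_i, hi_i, lo_e, hi_e, by) {
    vi <- seq(lo_i, hi_i, by = by)
    grid <- do.call(rbind, lapply(vi, function(a) {
      ve <- seq(lo_e, min(hi_e, 1 - a), by = by)
      ve <- ve[ve >= 0]
      if (length(ve) == 0) return(NULL)
      cbind(a, ve, 1 - a - ve)
    }))
    pred <- grid %*% t(comp)
    ss <- rowSums((pred - matrix(feats, nrow(pred), length(feats),
                                 byrow = TRUE))^2)
    unname(grid[which.min(ss), ])
  }
  coarse <- search(0, 1, 0, 1, step)
  best <- search(max(0, coarse[1] - 2 * step), min(1, coarse[1] + 2 * step),
                 max(0, coarse[2] - 2 * step), min(1, coarse[2] + 2 * step),
                 step / 10)
  c(v_i = best[1], v_e = best[2], v_f = max(0, best[3]))
}

#' Fraction maps container
#'
#' Volumetric V-intra / V-extra / V-CSF maps sharing one grid, with voxel
#' size and a NIfTI-style affine.
#'
#' @param v_intra,v_extra,v_csf 3-D arrays in \[0, 1\].
#' @param voxel_size Voxel edge lengths in mm (length 3).
#' @param affine 4x4 voxel-to-world transform; default built from
#'   `voxel_size`.
#' @param mask Optional binary array; where `mask` is 1 the three maps must
#'   sum to 1 within 1e-6.
#' @return An object of class `dmi_fraction_maps`.
#' @export
fraction_maps <- function(v_intra, v_extra, v_csf, voxel_size = c(2, 2, 2),
                          affine = NULL, mask = NULL) {
  assert_that(all(dim(v_intra) == dim(v_extra)) && all(dim(v_intra) == dim(v_csf)),
              "the three maps must share one grid")
  for (m in list(v_intra, v_extra, v_csf)) {
    assert_that(all(m >= -1e-9 & m <= 1 + 1e-9), "fractions must lie in [0, 1]")
  }
  if (!is.null(mask)) {
    inside <- mask > 0
    sums <- v_intra[inside] + v_extra[inside] + v_csf[inside]
    assert_that(all(abs(sums - 1) <= 1e-6),
                "fractions must sum to 1 inside the mask")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(v_intra = v_intra, v_extra = v_extra, v_csf = v_csf,
         voxel_size = as.numeric(voxel_size), affine = affine),
    class = "dmi_fraction_maps"
  )
}

#' @export
print.dmi_fraction_maps <- function(x, ...) {
  cat(sprintf("<dmi_fraction_maps> grid %s, voxel %s mm\n",
              paste(dim(x$v_intra), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' Fit fraction maps to a 4-D diffusion volume
#'
#' Applies a trained estimator voxelwise inside a mask. Voxels outside the
#' mask are zero in all three maps.
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param scheme The acquisition scheme; must match both the 4th dimension of
#'   `dwi` and the scheme the estimator was trained on.
#' @param mask 3-D binary array congruent with the spatial grid.
#' @param estimator A [train_estimator()] object.
#' @param voxel_size Voxel size in mm for the output maps.
#' @return A [fraction_maps()] object.
#' @export
fit_volume <- function(dwi, scheme, mask, estimator, voxel_size = c(2, 2, 2)) {
  assert_that(inherits(estimator, "dmi_estimator"), "estimator must be trained")
  assert_that(length(dim(dwi)) == 4, "dwi must be a 4-D array")
  assert_that(all(dim(dwi)[1:3] == dim(mask)),
              "mask grid %s does not match dwi grid %s",
              paste(dim(mask), collapse = "x"),
              paste(dim(dwi)[1:3], collapse = "x"))
  assert_that(dim(dwi)[4] == length(scheme$bvalues),
              "dwi has %d volumes but scheme has %d",
              dim(dwi)[4], length(scheme$bvalues))
  assert_that(isTRUE(all.equal(scheme$bvalues, estimator$scheme_bvalues)),
              "estimator was trained on a different acquisition scheme")
  shp <- dim(dwi)[1:3]
  zero <- array(0, shp)
  idx <- which(mask > 0)
  if (length(idx) == 0) {
    return(fraction_maps(zero, zero, zero, voxel_size = voxel_size))
  }
  flat <- matrix(dwi, prod(shp), dim(dwi)[4])
  feats <- signal_features(flat[idx, , drop = FALSE], scheme)
  v <- predict(estimator, feats)
  vi <- zero; ve <- zero; vf <- zero
  vi[idx] <- v$v_i; ve[idx] <- v$v_e; vf[idx] <- v$v_f
  fraction_maps(vi, ve, vf, voxel_size = voxel_size, mask = mask)
}
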