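#' Single-voxel microstructure parameters
#'
#' One voxel of the stick-zeppelin-ball white-matter model: an intra-axonal
#' stick (one-dimensional diffusion along the axon axis), an axially symmetric
#' extra-axonal tensor (zeppelin) and an isotropic free-water ball. Volume
#' fractions live on the unit simplex.
#'
#' @param v_i,v_e,v_f Intra-axonal, extra-axonal and free-water volume
#'   fractions; must be in \[0, 1\] and sum to 1.
#' @param D_i Intra-axonal parallel diffusivity (um^2/ms).
#' @param D_e_par,D_e_perp Extra-axonal parallel/perpendicular diffusivities
#'   (um^2/ms), with `0 <= D_e_perp <= D_e_par`.
#' @param D_f Free-water diffusivity (um^2/ms); 3.0 is body-temperature water.
#' @param orientation Unit 3-vector, the axon axis.
#' @param s0 Non-diffusion-weighted signal amplitude (> 0, arbitrary units).
#'
#' @return An object of class `dmi_params` (a validated list).
#' @export
#' @examples
#' microstructure_params(0.4, 0.45, 0.15)
microstructure_params <- function(v_i, v_e, v_f,
                                  D_i = 2.0, D_e_par = 1.5, D_e_perp = 0.5,
                                  D_f = 3.0, orientation = c(0, 0, 1),
                                  s0 = 1.0) {
  v <- c(v_i, v_e, v_f)
  assert_that(all(v >= 0 & v <= 1), "volume fractions must lie in [0, 1]")
  assert_that(abs(sum(v) - 1) <= 1e-9,
              "volume fractions must sum to 1 (got %.12f)", sum(v))
  assert_that(D_i > 0 && D_f > 0, "D_i and D_f must be positive")
  assert_that(D_e_perp >= 0 && D_e_perp <= D_e_par,
              "need 0 <= D_e_perp <= D_e_par")
  assert_that(s0 > 0, "s0 must be positive")
  assert_that(is_unit_vector(orientation), "orientation must be a unit vector")
  structure(
    list(v_i = v_i, v_e = v_e, v_f = v_f, D_i = D_i, D_e_par = D_e_par,
         D_e_perp = D_e_perp, D_f = D_f,
         orientation = as.numeric(orientation), s0 = s0),
    class = "dmi_params"
  )
}

#' Per-compartment signal attenuation for one gradient
#'
#' Closed-form attenuations of the three compartments for one b-value and
#' gradient direction. With `t = g . u` (cosine between gradient and axon):
#' stick `exp(-b D_i t^2)`, zeppelin
#' `exp(-b (D_e_perp + (D_e_par - D_e_perp) t^2))`, ball `exp(-b D_f)`.
#'
#' @param params A [microstructure_params()] object.
#' @param b b-value (ms/um^2), >= 0.
#' @param g Unit gradient direction (ignored for b = 0).
#' @return Named numeric vector `c(intra, extra, free)`, each in (0, 1\].
#' @export
compartment_signal <- function(params, b, g) {
  assert_that(inherits(params, "dmi_params"), "params must be dmi_params")
  assert_that(is.numeric(b) && length(b) == 1 && b >= 0,
              "b must be a single non-negative number")
  if (b == 0) return(c(intra = 1, extra = 1, free = 1))
  assert_that(is_unit_vector(g), "g must be a unit vector for b > 0")
  t2 <- sum(g * params$orientation)^2
  c(intra = exp(-b * params$D_i * t2),
    extra = exp(-b * (params$D_e_perp + (params$D_e_par - params$D_e_perp) * t2)),
    free  = exp(-b * params$D_f))
}

#' Voxel signal over a whole acquisition scheme
#'
#' The fraction-weighted sum of the compartment attenuations, scaled by `s0`:
#' `S(b, g) = s0 (v_i A_intra + v_e A_extra + v_f A_free)`.
#'
#' @param params A [microstructure_params()] object.
#' @param scheme A [acquisition_scheme()] object.
#' @return Numeric vector, one signal value per acquired volume, each in
#'   (0, s0\].
#' @export
voxel_signal <- function(params, scheme) {
  assert_that(inherits(params, "dmi_params"), "params must be dmi_params")
  assert_that(inherits(scheme, "dmi_scheme"), "scheme must be a dmi_scheme")
  b <- scheme$bvalues
  t2 <- as.numeric(scheme$directions %*% params$orientation)^2
  a_i <- exp(-b * params$D_i * t2)
  a_e <- exp(-b * (params$D_e_perp + (params$D_e_par - params$D_e_perp) * t2))
  a_f <- exp(-b * params$D_f)
  params$s0 * (params$v_i * a_i + params$v_e * a_e + params$v_f * a_f)
}

#' Per-compartment spherical means (powder averages)
#'
#' Orientation-averaged attenuation of each compartment at one b-value, i.e.
#' the average over uniformly distributed gradient directions. These are
#' rotation invariants and do not depend on the axon orientation:
#' stick `sqrt(pi / (4 b D_i)) erf(sqrt(b D_i))`; zeppelin
#' `exp(-b D_e_perp) sqrt(pi / (4 b d)) erf(sqrt(b d))` with
#' `d = D_e_par - D_e_perp` (continuous isotropic limit `exp(-b D_e_par)`
#' as `d -> 0`); ball `exp(-b D_f)`.
#'
#' @inheritParams compartment_signal
#' @param b b-value (ms/um^2), strictly positive.
#' @return Named numeric vector `c(intra, extra, free)`.
#' @export
spherical_mean <- function(params, b) {
  assert_that(inherits(params, "dmi_params"), "params must be dmi_params")
  assert_that(is.numeric(b) && length(b) == 1 && b > 0,
              "b must be a single positive number")
  c(intra = stick_mean(b, params$D_i),
    extra = zeppelin_mean(b, params$D_e_par, params$D_e_perp),
    free  = exp(-b * params$D_f))
}

stick_mean <- function(b, D) {
  x <- b * D
  ifelse(x < 1e-6, 1 - x / 3, sqrt(pi / (4 * x)) * erf(sqrt(x)))
}

zeppelin_mean <- function(b, D_par, D_perp) {
  exp(-b * D_perp) * stick_mean(b, D_par - D_perp)
}

#' Add Rician noise to a signal vector
#'
#' Magnitude-MR noise: each value S is replaced by
#' `sqrt((S + e1)^2 + e2^2)` with `e1, e2 ~ N(0, sigma^2)` independent.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param signal Numeric vector of noise-free signal values.
#' @param sigma Gaussian noise scale (same units as `signal`), >= 0. The
#'   conventional parameterisation is `sigma = s0 / SNR` with SNR quoted at
#'   b = 0.
#' @param seed Integer seed.
#' @return Numeric vector of noisy magnitudes.
#' @export
add_rician_noise <- function(signal, sigma, seed) {
  assert_that(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
              "sigma must be a single non-negative number")
  if (sigma == 0) return(signal)
  n <- length(signal)
  with_seed(seed, {
    e1 <- rnorm(n, sd = sigma)
    e2 <- rnorm(n, sd = sigma)
    sqrt((signal + e1)^2 + e2^2)
  })
}
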