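#' Phantom configuration
#'
#' A synthetic "patient": a spherical contrast-enhancing core surrounded by a
#' perilesional T2-hyperintense rim inside a spherical brain of
#' normal-appearing white matter. The `mode` selects the perilesional
#' microstructure: metastasis-mode rims carry a higher free-water fraction
#' than GBM-mode rims (predominantly vasogenic edema vs edema plus tumour
#' infiltration), which is the contrast the downstream analysis must detect.
#'
#' @param grid_shape Integer triplet, voxels per axis.
#' @param voxel_size Voxel edge lengths in mm.
#' @param core_radius Radius of the enhancing core (mm).
#' @param rim_thickness Thickness of the perilesional rim (mm), > 0.
#' @param brain_radius Radius of the brain sphere (mm); defaults to 90% of
#'   the half-extent of the grid.
#' @param mode `"GBM"` or `"metastasis"`.
#' @param zone_means Named list of length-3 fraction vectors `(v_i, v_e, v_f)`
#'   for zones `nawm`, `gbm_rim`, `met_rim`.
#' @param jitter_concentration Dirichlet concentration of the per-voxel
#'   fraction jitter around the zone mean (larger = tighter).
#' @param snr Signal-to-noise ratio at b = 0 (`Inf` for noise-free).
#' @param s0 Unweighted signal amplitude.
#' @param seed Integer seed.
#' @return An object of class `dmi_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32, 32, 32), voxel_size = c(2, 2, 2),
                           core_radius = 8, rim_thickness = 8,
                           brain_radius = NULL,
                           mode = c("GBM", "metastasis"),
                           zone_means = list(
                             nawm = c(0.45, 0.45, 0.10),
                             gbm_rim = c(0.25, 0.40, 0.35),
                             met_rim = c(0.15, 0.30, 0.55)),
                           jitter_concentration = 100,
                           snr = 30, s0 = 1, seed = 1L) {
  mode <- match.arg(mode)
  assert_that(rim_thickness > 0, "rim_thickness must be positive")
  assert_that(core_radius >= 0, "core_radius must be non-negative")
  half_extent <- min(grid_shape * voxel_size) / 2
  if (is.null(brain_radius)) brain_radius <- 0.9 * half_extent
  assert_that(core_radius + rim_thickness < brain_radius,
              "core + rim (%.1f mm) must fit inside the brain radius (%.1f mm)",
              core_radius + rim_thickness, brain_radius)
  assert_that(brain_radius <= half_extent,
              "brain radius (%.1f mm) exceeds the grid half-extent (%.1f mm)",
              brain_radius, half_extent)
  for (z in zone_means) {
    assert_that(length(z) == 3 && all(z >= 0) && abs(sum(z) - 1) < 1e-9,
                "zone fraction means must lie on the unit simplex")
  }
  assert_that(zone_means$met_rim[3] > zone_means$gbm_rim[3],
              "metastasis rim mean v_f must exceed the GBM rim mean v_f")
  assert_that(snr > 0, "snr must be positive (use Inf for noise-free)")
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
         core_radius = core_radius, rim_thickness = rim_thickness,
         brain_radius = brain_radius, mode = mode, zone_means = zone_means,
         jitter_concentration = jitter_concentration, snr = snr, s0 = s0,
         seed = as.integer(seed)),
    class = "dmi_phantom_config"
  )
}

# Voxel-centre distance (mm) from the grid centre.
voxel_radii <- function(grid_shape, voxel_size) {
  centre <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(grid_shape[k]) - centre[k]) * voxel_size[k])
  x2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  sqrt(x2)
}

#' Build the phantom label map
#'
#' Concentric geometry around the grid centre: enhancing core (label 3),
#' perilesional T2 rim (2), remaining brain = NAWM (1), background (0).
#'
#' @param config A [phantom_config()] object.
#' @return Integer 3-D array of labels.
#' @export
make_labels <- function(config) {
  assert_that(inherits(config, "dmi_phantom_config"),
              "config must be a dmi_phantom_config")
  r <- voxel_radii(config$grid_shape, config$voxel_size)
  labels <- array(0L, config$grid_shape)
  labels[r <= config$brain_radius] <- 1L
  rim_outer <- config$core_radius + config$rim_thickness
  labels[r <= rim_outer] <- 2L
  labels[r <= config$core_radius] <- 3L
  labels
}

# Dirichlet draws around a mean with given concentration.
rdirichlet_mean <- function(n, mean, concentration) {
  alpha <- mean * concentration
  g <- matrix(stats::rgamma(n * 3, shape = rep(alpha, each = n)), n, 3)
  g / rowSums(g)
}

zone_mean_for <- function(config, label) {
  switch(as.character(label),
         "1" = config$zone_means$nawm,
         "2" = if (config$mode == "GBM") config$zone_means$gbm_rim
               else config$zone_means$met_rim,
         "3" = if (config$mode == "GBM") config$zone_means$gbm_rim
               else config$zone_means$met_rim)
}

#' Render a multi-shell DWI phantom
#'
#' For every brain voxel, draws compartment fractions from its zone's
#' Dirichlet distribution and a random fibre orientation, renders the
#' stick-zeppelin-ball signal under the scheme, and adds Rician noise at the
#' configured SNR (`sigma = s0 / snr`). The enhancing core is rendered with
#' its surrounding rim's microstructure; downstream analysis excludes it by
#' mask, matching how segmentation prevents core voxels from entering the
#' perilesional ROI.
#'
#' @param labels Label volume from [make_labels()].
#' @param config The same [phantom_config()].
#' @param scheme An [acquisition_scheme()].
#' @return A list with elements `dwi` (4-D array), `truth`
#'   (ground-truth [fraction_maps()]), `labels`, `scheme`, and `config`.
#' @export
render_dwi <- function(labels, config, scheme) {
  assert_that(inherits(config, "dmi_phantom_config"),
              "config must be a dmi_phantom_config")
  assert_that(inherits(scheme, "dmi_scheme"), "scheme must be a dmi_scheme")
  assert_that(all(dim(labels) == config$grid_shape),
              "labels grid does not match config")
  shp <- config$grid_shape
  n_vol <- length(scheme$bvalues)
  dwi <- array(0, c(shp, n_vol))
  zero <- array(0, shp)
  truth <- list(v_i = zero, v_e = zero, v_f = zero)
  flat <- matrix(0, prod(shp), n_vol)

  with_seed(derive_seed(config$seed, 7L), {
    for (lab in c(1L, 2L, 3L)) {
      idx <- which(labels == lab)
      if (length(idx) == 0) next
      n <- length(idx)
      v <- rdirichlet_mean(n, zone_mean_for(config, lab),
                           config$jitter_concentration)
      u <- matrix(rnorm(3 * n), n, 3)
      u <- u / sqrt(rowSums(u^2))
      draws <- tibble(v_i = v[, 1], v_e = v[, 2], v_f = v[, 3],
                      D_i = 2.0, D_e_par = 1.5, D_e_perp = 0.5, D_f = 3.0,
                      ux = u[, 1], uy = u[, 2], uz = u[, 3])
      flat[idx, ] <- render_signal_matrix(draws, scheme, s0 = config$s0)
      truth$v_i[idx] <- v[, 1]
      truth$v_e[idx] <- v[, 2]
      truth$v_f[idx] <- v[, 3]
    }
    if (is.finite(config$snr)) {
      sigma <- config$s0 / config$snr
      brain <- which(labels > 0)
      e1 <- matrix(rnorm(length(brain) * n_vol, sd = sigma), length(brain))
      e2 <- matrix(rnorm(length(brain) * n_vol, sd = sigma), length(brain))
      flat[brain, ] <- sqrt((flat[brain, , drop = FALSE] + e1)^2 + e2^2)
    }
  })
  dwi[] <- flat
  truth_maps <- fraction_maps(truth$v_i, truth$v_e, truth$v_f,
                              voxel_size = config$voxel_size,
                              mask = array(as.integer(labels > 0), shp))
  list(dwi = dwi, truth = truth_maps, labels = labels, scheme = scheme,
       config = config)
}

#' Extract analysis masks from a label volume
#'
#' @param labels Label volume from [make_labels()].
#' @return A list of binary arrays: `roi_mask` (perilesional rim, zone 2),
#'   `wm_mask` (zones 1 and 2), `core_mask` (zone 3), `brain_mask`
#'   (all nonzero zones). Warns if the perilesional zone is empty.
#' @export
export_masks <- function(labels) {
  if (!any(labels == 2L)) {
    warn("perilesional zone is empty; roi_mask has no voxels")
  }
  shp <- dim(labels)
  list(roi_mask = array(as.integer(labels == 2L), shp),
       wm_mask = array(as.integer(labels == 1L | labels == 2L), shp),
       core_mask = array(as.integer(labels == 3L), shp),
       brain_mask = array(as.integer(labels > 0L), shp))
}
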