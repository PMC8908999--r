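#' Build the normal-appearing white matter mask
#'
#' NAWM is defined by exclusion: white matter minus the perilesional
#' T2-hyperintense area and minus the contrast-enhancing core. Normalizing
#' ROI metrics to NAWM accounts for age-related global white-matter changes.
#'
#' @param wm_mask,t2_mask,core_mask Congruent binary 3-D arrays.
#' @return Binary array `wm & !t2 & !core`.
#' @export
build_nawm_mask <- function(wm_mask, t2_mask, core_mask) {
  assert_that(all(dim(wm_mask) == dim(t2_mask)) &&
                all(dim(wm_mask) == dim(core_mask)),
              "masks must share one grid")
  array(as.integer(wm_mask > 0 & t2_mask == 0 & core_mask == 0), dim(wm_mask))
}

#' Mean of a scalar map over a mask
#'
#' @param map Scalar 3-D array.
#' @param mask Congruent binary array with at least one nonzero voxel.
#' @return The arithmetic mean of `map` over `mask > 0`.
#' @export
roi_mean <- function(map, mask) {
  assert_that(all(dim(map) == dim(mask)), "map and mask must share one grid")
  idx <- which(mask > 0)
  assert_that(length(idx) > 0, "mask is empty: ROI mean is undefined")
  mean(map[idx])
}

#' Per-patient normalized ROI metrics
#'
#' For each fraction map, computes the ROI mean, the NAWM mean, and their
#' ratio (the NAWM-normalized metric), plus the ROI volume in ml.
#'
#' @param maps A [fraction_maps()] object.
#' @param roi_mask Binary array for the perilesional T2 ROI.
#' @param nawm_mask Binary array for normal-appearing white matter; must be
#'   disjoint from `roi_mask`.
#' @return A one-row tibble with columns `metric`-wise `roi_mean_*`,
#'   `nawm_mean_*`, `v_intra_norm`, `v_extra_norm`, `v_csf_norm`, and
#'   `roi_volume_ml`.
#' @export
patient_metrics <- function(maps, roi_mask, nawm_mask) {
  assert_that(inherits(maps, "dmi_fraction_maps"),
              "maps must be dmi_fraction_maps")
  assert_that(!any(roi_mask > 0 & nawm_mask > 0),
              "roi_mask and nawm_mask must be disjoint")
  vols <- list(v_intra = maps$v_intra, v_extra = maps$v_extra,
               v_csf = maps$v_csf)
  roi <- purrr::map_dbl(vols, roi_mean, mask = roi_mask)
  nawm <- purrr::map_dbl(vols, roi_mean, mask = nawm_mask)
  assert_that(all(nawm != 0), "NAWM mean is zero: normalized ratio undefined")
  voxel_ml <- prod(maps$voxel_size) / 1000
  tibble(
    roi_mean_v_intra = roi[["v_intra"]],
    roi_mean_v_extra = roi[["v_extra"]],
    roi_mean_v_csf = roi[["v_csf"]],
    nawm_mean_v_intra = nawm[["v_intra"]],
    nawm_mean_v_extra = nawm[["v_extra"]],
    nawm_mean_v_csf = nawm[["v_csf"]],
    v_intra_norm = roi[["v_intra"]] / nawm[["v_intra"]],
    v_extra_norm = roi[["v_extra"]] / nawm[["v_extra"]],
    v_csf_norm = roi[["v_csf"]] / nawm[["v_csf"]],
    roi_volume_ml = sum(roi_mask > 0) * voxel_ml
  )
}
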