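#' Simulate, fit and analyze a phantom pair end to end
#'
#' Renders one GBM-mode and one metastasis-mode phantom per seed, fits the
#' compartment fraction maps with the trained estimator, reduces them to
#' NAWM-normalized ROI metrics, and assembles the per-phantom rows into a
#' cohort-style table.
#'
#' @param seeds Integer vector; one phantom pair is generated per seed.
#' @param scheme Acquisition scheme (default [default_scheme()]).
#' @param estimator Optional pre-trained estimator (trained on `scheme`);
#'   trained on the fly when `NULL`.
#' @param snr Phantom SNR at b = 0.
#' @param grid_shape Phantom grid.
#' @return A tibble with one row per phantom: `id`, `group`, `mode_seed`,
#'   plus the [patient_metrics()] columns and the ground-truth normalized
#'   metrics (`truth_*`).
#' @export
phantom_cohort <- function(seeds, scheme = default_scheme(), estimator = NULL,
                           snr = 30, grid_shape = c(32, 32, 32)) {
  if (is.null(estimator)) {
    estimator <- train_estimator(prior_spec(seed = derive_seed(seeds[1], 55L)),
                                 scheme)
  }
  rows <- list()
  for (seed in seeds) {
    for (mode in c("GBM", "metastasis")) {
      cfg <- phantom_config(grid_shape = grid_shape, mode = mode, snr = snr,
                            seed = derive_seed(seed, if (mode == "GBM") 1L else 2L))
      labels <- make_labels(cfg)
      ph <- render_dwi(labels, cfg, scheme)
      masks <- export_masks(labels)
      nawm <- build_nawm_mask(masks$wm_mask, masks$roi_mask, masks$core_mask)
      fitted <- fit_volume(ph$dwi, scheme, masks$brain_mask, estimator,
                           voxel_size = cfg$voxel_size)
      met <- patient_metrics(fitted, masks$roi_mask, nawm)
      truth <- patient_metrics(ph$truth, masks$roi_mask, nawm)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(id = sprintf("phantom_%s_%d", mode, seed), group = mode,
               mode_seed = seed),
        met,
        tibble(truth_v_intra_norm = truth$v_intra_norm,
               truth_v_extra_norm = truth$v_extra_norm,
               truth_v_csf_norm = truth$v_csf_norm)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Full synthetic pipeline run
#'
#' Chains the whole analysis on synthetic data: phantom pair rendering,
#' estimator training and volume fitting, ROI reduction
#' (`phantom-derived` table), cohort simulation at the configured group
#' sizes, and the group-level statistics battery. Artifacts (cohort CSV,
#' results CSV, sidecars) are written under `out_dir` when given.
#'
#' @param seed Top-level seed; all module seeds derive from it.
#' @param out_dir Optional output directory (created if missing).
#' @param n_phantom_seeds Phantom pairs to render.
#' @param snr Phantom SNR.
#' @param cohort_config_fn Function `seed -> dmi_cohort_config`.
#' @return A list with `phantoms` (phantom metrics tibble), `cohort`
#'   (simulated cohort tibble), `results` (per-metric statistics tibble),
#'   `correlations`, and `group_comparisons`.
#' @export
full_run <- function(seed = 1L, out_dir = NULL, n_phantom_seeds = 1L,
                     snr = 30, cohort_config_fn = default_cohort_config) {
  scheme <- default_scheme()
  phantoms <- phantom_cohort(derive_seed(seed, 11L) + seq_len(n_phantom_seeds) - 1L,
                             scheme = scheme, snr = snr)
  cfg <- cohort_config_fn(seed = derive_seed(seed, 21L))
  cohort <- simulate_cohort(cfg)
  results <- analyze_cohort(cohort)
  correlations <- cohort_correlations(cohort)
  comparisons <- cohort_group_comparisons(cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cohort_path <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(cohort, cohort_path)
    write_sidecar(cohort_path, list(kind = "cohort", seed = cfg$seed), seed)
    results_path <- file.path(out_dir, "results.csv")
    utils::write.csv(results, results_path, row.names = FALSE)
    write_sidecar(results_path, list(kind = "results"), seed)
    phantom_path <- file.path(out_dir, "phantom_metrics.csv")
    utils::write.csv(phantoms, phantom_path, row.names = FALSE)
    write_sidecar(phantom_path, list(kind = "phantom_metrics", snr = snr), seed)
  }
  list(phantoms = phantoms, cohort = cohort, results = results,
       correlations = correlations, group_comparisons = comparisons)
}
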