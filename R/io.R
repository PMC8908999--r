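#' Read an FSL-style gradient table
#'
#' The bval file is one whitespace-separated row of b-values in s/mm^2
#' (converted internally to ms/um^2; 1000 s/mm^2 = 1.0 ms/um^2). The bvec
#' file holds three rows (x, y, z). Vectors within 1e-3 of unit norm are
#' renormalized; anything further off is rejected.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @param shell_tolerance Passed to [acquisition_scheme()].
#' @return An [acquisition_scheme()] object.
#' @export
read_gradient_table <- function(bval_path, bvec_path, shell_tolerance = 0.05) {
  assert_that(file.exists(bval_path), "bval file not found: %s", bval_path)
  assert_that(file.exists(bvec_path), "bvec file not found: %s", bvec_path)
  bval_tok <- scan(bval_path, what = character(), quiet = TRUE)
  bvals <- suppressWarnings(as.numeric(bval_tok))
  assert_that(!anyNA(bvals), "non-numeric token in bval file %s", bval_path)
  bvec_lines <- readLines(bvec_path)
  bvec_lines <- bvec_lines[nzchar(trimws(bvec_lines))]
  assert_that(length(bvec_lines) == 3,
              "bvec file must have 3 rows, found %d", length(bvec_lines))
  rows <- lapply(bvec_lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    assert_that(!anyNA(v), "non-numeric token in bvec file %s", bvec_path)
    v
  })
  n_col <- unique(lengths(rows))
  assert_that(length(n_col) == 1, "ragged bvec rows in %s", bvec_path)
  assert_that(n_col == length(bvals),
              "bval has %d entries but bvec has %d columns",
              length(bvals), n_col)
  g <- t(do.call(rbind, rows))
  b_ms <- bvals / 1000
  norms <- sqrt(rowSums(g^2))
  weighted <- b_ms > 0
  off <- weighted & abs(norms - 1) > 1e-3
  assert_that(!any(off),
              "%d direction(s) deviate from unit norm by more than 1e-3",
              sum(off))
  g[weighted, ] <- g[weighted, , drop = FALSE] / norms[weighted]
  acquisition_scheme(b_ms, g, shell_tolerance = shell_tolerance)
}

#' Write an FSL-style gradient table
#'
#' @param scheme An [acquisition_scheme()] object.
#' @param bval_path,bvec_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_gradient_table <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvalues * 1000, trim = TRUE, digits = 12),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$directions), 1, function(r)
    paste(format(r, trim = TRUE, digits = 12), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving data, shape, voxel size and affine.
#' Masks should be written with `datatype = "uint8"`.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume Numeric array to write.
#' @param voxel_size Voxel edge lengths in mm.
#' @param datatype NIfTI datatype string (e.g. `"float32"`, `"uint8"`).
#' @return `read_volume()` returns the array with attribute `voxel_size`;
#'   `write_volume()` returns the path invisibly.
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "volume not found: %s", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) {
    magic <- readBin(path, "raw", 4)
    stopf("not a readable NIfTI file: %s (magic bytes %s)", path,
          paste(magic, collapse = " "))
  })
  arr <- as.array(img)
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(arr))))]
  attr(arr, "affine") <- structure(RNifti::xform(img), class = NULL,
                                   code = NULL)
  arr
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path, voxel_size = c(2, 2, 2),
                         datatype = "float32") {
  img <- RNifti::asNifti(unclass(volume))
  RNifti::pixdim(img) <- voxel_size[seq_len(min(3, length(dim(volume))))]
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write fraction maps as NIfTI volumes
#'
#' Serializes the three maps with shared geometry as
#' `<prefix>_vintra.nii.gz`, `<prefix>_vextra.nii.gz`,
#' `<prefix>_vcsf.nii.gz`.
#'
#' @param maps A [fraction_maps()] object.
#' @param prefix Output path prefix.
#' @return Invisibly, the three written paths.
#' @export
write_fraction_maps <- function(maps, prefix) {
  paths <- paste0(prefix, c("_vintra", "_vextra", "_vcsf"), ".nii.gz")
  write_volume(maps$v_intra, paths[1], voxel_size = maps$voxel_size)
  write_volume(maps$v_extra, paths[2], voxel_size = maps$voxel_size)
  write_volume(maps$v_csf, paths[3], voxel_size = maps$voxel_size)
  invisible(paths)
}

#' Read or write a cohort table as CSV
#'
#' Fixed column order `id, group, age, sex, steroid, t2_volume,
#' v_intra_norm, v_extra_norm, v_csf_norm`; comma-separated, header row,
#' "." decimal mark, UTF-8.
#'
#' @param cohort A cohort tibble.
#' @param path CSV path.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()` the
#'   path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- c("id", "group", "age", "sex", "steroid", "t2_volume",
            "v_intra_norm", "v_extra_norm", "v_csf_norm")
  assert_that(all(cols %in% names(cohort)), "cohort is missing columns")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  assert_that(file.exists(path), "cohort CSV not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  df$steroid <- as.logical(df$steroid)
  as_tibble(df)
}

#' Write a reproducibility sidecar
#'
#' Every pipeline output is accompanied by a JSON sidecar recording the seed,
#' a hash of the generating configuration, and the package version, so a run
#' can be reproduced exactly.
#'
#' @param path Path of the artifact the sidecar describes (`.json` appended).
#' @param config The generating configuration (any serializable list).
#' @param seed The seed used.
#' @return Invisibly, the sidecar path.
#' @export
write_sidecar <- function(path, config, seed) {
  sidecar <- paste0(path, ".json")
  payload <- list(
    seed = as.integer(seed),
    config_hash = config_hash(config),
    package = "dmisim",
    version = as.character(utils::packageVersion("dmisim")),
    config = config
  )
  jsonlite::write_json(payload, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(sidecar)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  # Fletcher-32 over the serialized config; avoids a digest dependency.
  bytes <- as.integer(charToRaw(s))
  s1 <- 0; s2 <- 0
  for (b in bytes) {
    s1 <- (s1 + b) %% 65535
    s2 <- (s2 + s1) %% 65535
  }
  sprintf("%04x%04x", as.integer(s2), as.integer(s1))
}
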