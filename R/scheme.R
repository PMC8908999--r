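#' Multi-shell acquisition scheme
#'
#' An acquisition scheme pairs every acquired diffusion-weighted volume with a
#' b-value (in ms/um^2; 1.0 ms/um^2 = 1000 s/mm^2) and a unit gradient
#' direction. A valid scheme for a three-compartment fit needs at least one
#' b = 0 volume and at least two distinct nonzero shells.
#'
#' @param bvalues Numeric vector of per-volume b-values (ms/um^2).
#' @param directions Numeric matrix, one row per volume, three columns
#'   (x, y, z). Rows paired with b > 0 must have unit norm.
#' @param shell_tolerance b-values closer than this are clustered into one
#'   shell (ms/um^2).
#'
#' @return An object of class `dmi_scheme`: a list with elements `bvalues`,
#'   `directions`, `shell_tolerance`, `shell_id` (integer shell index per
#'   volume, 0 = unweighted) and `shells` (sorted distinct nonzero shell
#'   b-values).
#' @export
#' @examples
#' sch <- acquisition_scheme(c(0, 1, 1, 2, 2),
#'   rbind(c(0, 0, 0), diag(3)[c(1, 2), ], diag(3)[c(3, 1), ]))
#' sch$shells
acquisition_scheme <- function(bvalues, directions, shell_tolerance = 0.05) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  assert_that(all(is.finite(bvalues)) && all(bvalues >= 0),
              "b-values must be finite and non-negative")
  assert_that(nrow(directions) == length(bvalues),
              "direction count (%d) does not match b-value count (%d)",
              nrow(directions), length(bvalues))
  assert_that(ncol(directions) == 3, "directions must have 3 components")
  assert_that(shell_tolerance > 0, "shell_tolerance must be positive")
  weighted <- bvalues > 0
  assert_that(any(!weighted), "scheme must contain at least one b = 0 volume")
  norms <- sqrt(rowSums(directions^2))
  bad <- weighted & abs(norms - 1) > 1e-6
  assert_that(!any(bad),
              "%d diffusion-weighted direction(s) are not unit vectors", sum(bad))

  shells <- cluster_shells(bvalues[weighted], shell_tolerance)
  assert_that(length(shells$centers) >= 2,
              "at least 2 distinct nonzero shells are required (found %d)",
              length(shells$centers))
  shell_id <- integer(length(bvalues))
  shell_id[weighted] <- shells$id

  structure(
    list(bvalues = bvalues, directions = directions,
         shell_tolerance = shell_tolerance, shell_id = shell_id,
         shells = shells$centers),
    class = "dmi_scheme"
  )
}

# Greedy 1-D clustering of nonzero b-values by tolerance.
cluster_shells <- function(b, tol) {
  ord <- order(b)
  centers <- numeric(0)
  id <- integer(length(b))
  for (k in ord) {
    hit <- which(abs(centers - b[k]) <= tol)
    if (length(hit) == 0) {
      centers <- c(centers, b[k])
      hit <- length(centers)
    }
    id[k] <- hit[1]
  }
  list(centers = centers, id = id)
}

#' @export
print.dmi_scheme <- function(x, ...) {
  cat(sprintf("<dmi_scheme> %d volumes: %d x b=0, shells b = {%s} ms/um^2\n",
              length(x$bvalues), sum(x$bvalues == 0),
              paste(format(x$shells), collapse = ", ")))
  invisible(x)
}

#' Default two-shell synthetic acquisition scheme
#'
#' One b = 0 volume plus two shells at b = 1.0 and 2.0 ms/um^2 with 30
#' repulsion-optimized directions each (the minimum multi-shell layout that
#' identifies a three-compartment model). Deterministic.
#'
#' @param n_dir Directions per shell.
#' @param bshells Nonzero shell b-values (ms/um^2).
#' @param n_b0 Number of unweighted volumes.
#' @return A [acquisition_scheme()] object.
#' @export
default_scheme <- function(n_dir = 30, bshells = c(1, 2), n_b0 = 1) {
  dirs <- repulsion_directions(n_dir)
  b <- c(rep(0, n_b0), rep(bshells, each = n_dir))
  g <- rbind(matrix(0, n_b0, 3), do.call(rbind, rep(list(dirs), length(bshells))))
  acquisition_scheme(b, g)
}

#' Convert a scheme to a tibble
#'
#' @param x A `dmi_scheme`.
#' @param ... Unused.
#' @return A tibble with one row per volume: `volume`, `bvalue`, `gx`, `gy`,
#'   `gz`, `shell` (0 for unweighted volumes).
#' @export
as_tibble.dmi_scheme <- function(x, ...) {
  tibble(volume = seq_along(x$bvalues), bvalue = x$bvalues,
         gx = x$directions[, 1], gy = x$directions[, 2],
         gz = x$directions[, 3], shell = x$shell_id)
}
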