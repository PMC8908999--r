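# Internal helpers shared across modules.

# Error function; base R exposes only pnorm.
erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic split of one top-level seed into per-module substreams.
# Arithmetic in doubles (exact below 2^53), result a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(offset) * 12347) %%
               2147483562) + 1L
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

is_unit_vector <- function(v, tol = 1e-6) {
  abs(sqrt(sum(v^2)) - 1) <= tol
}

# n approximately uniformly distributed points on the unit sphere via the
# Fibonacci (golden-angle) spiral. Deterministic; used both for quadrature
# and as the starting point of the direction-set optimizer.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Electrostatic repulsion on the sphere with antipodal symmetry, the standard
# construction for diffusion gradient tables. Small fixed number of projected
# gradient steps from a Fibonacci start; deterministic.
repulsion_directions <- function(n, n_iter = 2000, step = 0.05) {
  p <- fibonacci_sphere(n)
  for (iter in seq_len(n_iter)) {
    a1 <- outer(p[, 1], p[, 1], "-")
    a2 <- outer(p[, 2], p[, 2], "-")
    a3 <- outer(p[, 3], p[, 3], "-")
    w <- (a1^2 + a2^2 + a3^2)^-1.5
    diag(w) <- 0
    b1 <- outer(p[, 1], p[, 1], "+")
    b2 <- outer(p[, 2], p[, 2], "+")
    b3 <- outer(p[, 3], p[, 3], "+")
    wm <- (b1^2 + b2^2 + b3^2)^-1.5
    force <- cbind(rowSums(a1 * w) + rowSums(b1 * wm),
                   rowSums(a2 * w) + rowSums(b2 * wm),
                   rowSums(a3 * w) + rowSums(b3 * wm))
    p <- p + step * force / n
    p <- p / sqrt(rowSums(p^2))
  }
  unname(p)
}

# Random rotation matrix (uniform over SO(3)) from the current RNG stream.
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_dec <- qr(m)
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
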