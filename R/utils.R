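# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# RNG kinds are pinned so results are bit-reproducible across sessions.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Uniform random rotation from normalized quaternions (no axis-angle bias).
.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# frames x atoms x 3 array -> frames x (3*atoms) matrix (x1 y1 z1 x2 ...)
.flattenCoords <- function(coords) {
  d <- dim(coords)
  m <- matrix(aperm(coords, c(1, 3, 2)), nrow = d[1])
  m
}

# inverse of .flattenCoords
.unflattenCoords <- function(m, nAtoms) {
  aperm(array(m, dim = c(nrow(m), 3, nAtoms)), c(1, 3, 2))
}

# single frame as atoms x 3 matrix
.frame <- function(traj, i) {
  matrix(traj@coords[i, , ], ncol = 3)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
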