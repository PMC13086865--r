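# Small internal helpers.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state so
# seeded generators are pure functions of their seed argument.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise Euclidean norm of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Random rigid transformation (rotation + translation), for invariance tests
# and jittered synthetic structures. Returns list(R = 3x3, t = length-3).
random_rigid_transform <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 20))
}

# Apply a rigid transform to an n x 3 coordinate matrix.
apply_rigid <- function(coords, transform) {
  sweep(coords %*% t(transform$R), 2, transform$t, "+")
}
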