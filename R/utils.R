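# Internal numeric helpers shared across modules.

# Squared Euclidean cross-distance matrix between rows of a (n x 3) and b (m x 3).
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- matrix(rowSums(a * a), nrow(a), nrow(b)) +
    matrix(rowSums(b * b), nrow(a), nrow(b), byrow = TRUE) -
    2 * tcrossprod(a, b)
  # guard tiny negatives from cancellation
  d2[d2 < 0] <- 0
  d2
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Any unit vector perpendicular to v, chosen deterministically.
perp_unit <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  unit(cross3(v, ref))
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG stream afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Random 3x3 rotation matrix (used by tests and equivariance checks).
#' Draw a random 3D rotation matrix
#'
#' Uniform random rotation via QR decomposition of a Gaussian matrix;
#' convenient for equivariance checks.
#'
#' @param seed Optional integer seed.
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    q <- qr.Q(qr_)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
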