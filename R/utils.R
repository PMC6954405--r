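## Small internal geometry / RNG helpers shared across modules.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Evaluate `expr` under a temporary RNG state seeded with `seed`, then
## restore the caller's stream. Keeps user-facing functions deterministic
## per their seed argument without clobbering the session RNG.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  force(expr)
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## Rodrigues rotation matrix for rotation by `angle` (radians) about unit
## axis `axis`; to be applied to row vectors as  x %*% t(R).
.rotationMatrix <- function(axis, angle) {
  u <- .unit(axis)
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -u[3L], u[2L],
                u[3L], 0, -u[1L],
                -u[2L], u[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) + sa * K + (1 - ca) * (K %*% K)
}

.randomUnitVector <- function() .unit(stats::rnorm(3L))

## Pairwise squared distances between rows of two coordinate matrices.
.crossDist2 <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

.rowDist <- function(a, b) sqrt(rowSums((a - b)^2))

## Pseudo-bond angle at b (degrees) for points a-b-c; rows of matrices.
.angleDeg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  num <- rowSums(v1 * v2)
  den <- sqrt(rowSums(v1 * v1) * rowSums(v2 * v2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

## Dihedral angle (degrees, in (-180, 180]) over points a-b-c-d.
.dihedralDeg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cbind(b1[, 2L] * b2[, 3L] - b1[, 3L] * b2[, 2L],
              b1[, 3L] * b2[, 1L] - b1[, 1L] * b2[, 3L],
              b1[, 1L] * b2[, 2L] - b1[, 2L] * b2[, 1L])
  n2 <- cbind(b2[, 2L] * b3[, 3L] - b2[, 3L] * b3[, 2L],
              b2[, 3L] * b3[, 1L] - b2[, 1L] * b3[, 3L],
              b2[, 1L] * b3[, 2L] - b2[, 2L] * b3[, 1L])
  m1 <- cbind(n1[, 2L] * b2[, 3L] - n1[, 3L] * b2[, 2L],
              n1[, 3L] * b2[, 1L] - n1[, 1L] * b2[, 3L],
              n1[, 1L] * b2[, 2L] - n1[, 2L] * b2[, 1L])
  b2n <- sqrt(rowSums(b2 * b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

## Shortest signed angular difference in degrees.
.angDiff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

.checkCoordMatrix <- function(x, n, what, allowNA = FALSE) {
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != 3L || nrow(x) != n)
    return(sprintf("'%s' must be a numeric %d x 3 matrix", what, n))
  if (!allowNA && anyNA(x))
    return(sprintf("'%s' must not contain NA", what))
  NULL
}
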