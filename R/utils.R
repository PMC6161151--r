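# Shared internal helpers: minimum-image geometry and small checks.

# Apply the minimum-image convention to a displacement matrix (n x 3)
# for an orthorhombic box (length-3 vector).  box = NULL means
# non-periodic: displacements returned unchanged.
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d <- as.matrix(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Pairwise squared-distance matrix under minimum image for an n x 3
# coordinate matrix.  Small-n (<~ 1000) dense implementation.
pair_dist2 <- function(coords, box = NULL) {
  n <- nrow(coords)
  d2 <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(coords[, k], coords[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  d2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  if (positive && x <= 0) stop(name, " must be > 0")
  invisible(x)
}

# Angle at vertex `b` of the triple a-b-c, in radians.
vertex_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang)))
}
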