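#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks and
#' semilandmarks to their centroid; the standard geometric-morphometrics
#' size measure. It is translation- and rotation-invariant and scales
#' linearly with the configuration.
#'
#' @param points A K x 2 numeric matrix (or a tibble with `x`, `y` columns).
#' @return A positive scalar.
#' @export
centroid_size <- function(points) {
  pts <- as_points_matrix(points)
  if (nrow(pts) < 2L) abort("centroid_size needs at least two points")
  if (!all(is.finite(pts))) abort("Non-finite coordinates")
  centred <- sweep(pts, 2L, colMeans(pts))
  cs <- sqrt(sum(centred^2))
  if (cs < .Machine$double.eps^0.5 * max(1, max(abs(pts)))) {
    abort("Degenerate configuration: all points coincide")
  }
  cs
}

as_points_matrix <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x", "y")])
  }
  stopifnot(is.matrix(points), ncol(points) == 2L)
  storage.mode(points) <- "double"
  points
}

centre_points <- function(pts) sweep(pts, 2L, colMeans(pts))

#' Optimal rotation aligning one centred configuration to another
#'
#' Rotation-only (no reflection) orthogonal Procrustes solution maximising
#' the cross-covariance trace; teeth are chiral so improper rotations are
#' never allowed.
#'
#' @param x,y Centred K x 2 matrices; `x` is rotated onto `y`.
#' @return A 2 x 2 rotation matrix `R` (determinant +1) such that `x %*% R`
#'   best fits `y` in least squares.
#' @keywords internal
optimal_rotation <- function(x, y) {
  m <- crossprod(x, y)
  sv <- svd(m)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Partial Procrustes distance between two shapes
#'
#' Both configurations are centred and scaled to unit centroid size, then one
#' is rotated (reflection disallowed) onto the other; the distance is the
#' square root of the residual sum of squares. It is zero exactly when the
#' shapes are similarity-equivalent without reflection, and symmetric.
#'
#' @param shape_a,shape_b K x 2 matrices with the same K.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  a <- as_points_matrix(shape_a)
  b <- as_points_matrix(shape_b)
  if (nrow(a) != nrow(b)) abort("Shapes must have the same number of points")
  a <- centre_points(a); a <- a / centroid_size(a)
  b <- centre_points(b); b <- b / centroid_size(b)
  r <- optimal_rotation(a, b)
  sqrt(max(0, sum((a %*% r - b)^2)))
}

#' Resample a polyline to equidistant points
#'
#' Places `n` points on an ordered polyline so that consecutive points are
#' separated by equal arc length, preserving both endpoints. Used to
#' construct equidistant semilandmark templates along outline segments.
#'
#' @param polyline Ordered K x 2 matrix (or `x`/`y` data frame) with at
#'   least two distinct points.
#' @param n Number of output points (>= 2).
#' @return An `n` x 2 matrix of points lying on the polyline.
#' @export
resample_equidistant <- function(polyline, n) {
  pts <- as_points_matrix(polyline)
  stopifnot(n >= 2L)
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  if (total <= 0) abort("Zero-length polyline")
  cum <- c(0, cumsum(seg_len))
  target <- seq(0, total, length.out = n)
  out <- matrix(NA_real_, n, 2L)
  j <- 1L
  for (i in seq_len(n)) {
    t <- target[[i]]
    while (j < length(seg_len) && cum[j + 1L] < t) j <- j + 1L
    # interpolate within segment j
    denom <- seg_len[[j]]
    frac <- if (denom > 0) (t - cum[[j]]) / denom else 0
    frac <- min(max(frac, 0), 1)
    out[i, ] <- pts[j, ] + frac * seg[j, ]
  }
  out
}
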