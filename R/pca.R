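#' Principal component analysis of Procrustes shape coordinates
#'
#' Runs PCA on the tangent-space shape coordinates of a superimposed sample.
#' Components are ordered by decreasing eigenvalue and the sign of each
#' component is fixed so that its largest-magnitude loading is positive,
#' making scores reproducible across platforms.
#'
#' @param aligned An `mm_gpa` object (at least 3 specimens).
#' @param tangent Use tangent-space projection (default `TRUE`).
#' @return An object of class `mm_pca` with `mean_shape` (K x 2, the mean of
#'   the analysed shape coordinates), `rotation` (2K x p loadings),
#'   `eigenvalues`, `variance_proportions` (summing to 1), and `scores`
#'   (n x p matrix, zero column means).
#' @export
pca_shapes <- function(aligned, tangent = TRUE) {
  stopifnot(inherits(aligned, "mm_gpa"))
  xmat <- shape_matrix(aligned, tangent = tangent)
  if (nrow(xmat) < 3L) abort("PCA needs at least 3 specimens")
  pc <- prcomp(xmat, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) {
    if (v[which.max(abs(v))] < 0) -1 else 1
  })
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  eig <- pc$sdev^2
  k <- nrow(aligned$consensus)
  structure(
    list(
      mean_shape = matrix(colMeans(xmat), k, 2L,
                          dimnames = list(NULL, c("x", "y"))),
      rotation = pc$rotation,
      eigenvalues = eig,
      variance_proportions = eig / sum(eig),
      scores = pc$x,
      metadata = aligned$metadata,
      centroid_sizes = aligned$centroid_sizes
    ),
    class = "mm_pca"
  )
}

#' @export
print.mm_pca <- function(x, ...) {
  vp <- x$variance_proportions
  cat(sprintf("<mm_pca> %d specimens, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(vp), 100 * vp[1],
              if (length(vp) > 1) 100 * vp[2] else NA_real_))
  invisible(x)
}

#' @describeIn pca_shapes Per-component eigenvalues and variance
#'   proportions.
#' @param x An `mm_pca` object.
#' @param ... Unused.
#' @export
tidy.mm_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_proportion = x$variance_proportions,
    cumulative_proportion = cumsum(x$variance_proportions)
  )
}

#' @describeIn pca_shapes One-row summary.
#' @export
glance.mm_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores), n_components = length(x$eigenvalues),
    pc1_proportion = x$variance_proportions[1],
    pc2_proportion = if (length(x$variance_proportions) > 1)
      x$variance_proportions[2] else NA_real_
  )
}

#' Specimen scores joined to metadata
#'
#' @param space An `mm_pca` object.
#' @param components Which components to return (default first two).
#' @return Tibble with `specimen_id`, one column per requested component
#'   (`PC1`, `PC2`, ...), joined to metadata when available.
#' @export
score_table <- function(space, components = 1:2) {
  stopifnot(inherits(space, "mm_pca"))
  components <- components[components <= ncol(space$scores)]
  out <- tibble::as_tibble(space$scores[, components, drop = FALSE])
  out <- tibble::add_column(out, specimen_id = rownames(space$scores),
                            .before = 1)
  if (!is.null(space$metadata)) {
    out <- dplyr::left_join(out, space$metadata, by = "specimen_id")
  }
  out
}

#' @describeIn pca_shapes PC1/PC2 scatter, coloured by a metadata factor
#'   when present.
#' @param object An `mm_pca` object.
#' @param colour_by Metadata column used for point colour (default
#'   `"population"` when available).
#' @export
autoplot.mm_pca <- function(object, colour_by = "population", ...) {
  df <- score_table(object, 1:2)
  vp <- object$variance_proportions
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if (colour_by %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]))
  } else {
    p <- p + ggplot2::geom_point()
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * vp[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * vp[2])
  )
}

#' Reconstruct a shape from principal component scores
#'
#' Deforms the mean shape along one component (`mean + score * loading`),
#' the standard visualisation of shape variation at negative and positive
#' scores.
#'
#' @param space An `mm_pca` object.
#' @param component Component index.
#' @param score Score value (scalar), or a full-length score vector when
#'   `component = NULL`.
#' @return K x 2 matrix.
#' @export
reconstruct_shape <- function(space, component = 1L, score = 0) {
  stopifnot(inherits(space, "mm_pca"))
  k <- nrow(space$mean_shape)
  if (is.null(component)) {
    stopifnot(length(score) == ncol(space$rotation))
    v <- as.vector(space$rotation %*% score)
  } else {
    if (component < 1L || component > ncol(space$rotation)) {
      abort(sprintf("Unknown component %s", component))
    }
    v <- score * space$rotation[, component]
  }
  space$mean_shape + matrix(v, k, 2L)
}

#' Retain the leading components expressing a variance threshold
#'
#' Keeps the smallest leading set of principal components whose cumulative
#' variance proportion reaches the threshold (default 95%), the
#' dimension-reduction rule applied before every canonical variate analysis
#' so as not to distort the cross-validation.
#'
#' @param space An `mm_pca` object.
#' @param threshold Cumulative variance proportion in (0, 1]; default 0.95.
#' @return List with `scores` (n x m reduced score matrix) and `n_retained`.
#' @export
retain_components <- function(space, threshold = 0.95) {
  stopifnot(inherits(space, "mm_pca"), threshold > 0, threshold <= 1)
  cum <- cumsum(space$variance_proportions)
  m <- which(cum >= threshold - 1e-12)[1]
  if (is.na(m)) m <- length(cum)
  m <- max(1L, m)
  list(scores = space$scores[, seq_len(m), drop = FALSE], n_retained = m)
}
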