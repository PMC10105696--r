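#' Generalized Procrustes Analysis with optional semilandmark sliding
#'
#' Superimposes all configurations by translating each to a common centroid,
#' scaling each to unit centroid size, and iteratively rotating to the
#' current consensus (the normalised mean shape), until the consensus stops
#' moving. Reflections are never allowed: molar outlines are chiral.
#' When a [sliding_spec()] is supplied, each outer cycle re-estimates the
#' consensus and lets the semilandmarks of every specimen slide along their
#' outline tangents to minimise thin-plate spline bending energy against the
#' consensus; slid coordinates replace the semilandmark positions before the
#' final alignment pass.
#'
#' The returned superimposition is put in a canonical orientation (consensus
#' principal axes, deterministic sign) so the result is invariant to the
#' input order of specimens and to arbitrary similarity transforms applied
#' to any input configuration.
#'
#' @param x An `mm_dataset`, a K x 2 x n array, or a list of K x 2 matrices.
#' @param slide Optional [sliding_spec()]; `NULL` disables sliding.
#' @param tol Convergence tolerance on the Frobenius displacement of the
#'   consensus between iterations.
#' @param max_iter Maximum number of alignment iterations.
#' @return An object of class `mm_gpa` with elements `shapes` (K x 2 x n
#'   aligned, unit centroid size, centred), `centroid_sizes` (named, in the
#'   input units), `consensus` (K x 2, unit centroid size), `n_iterations`,
#'   `final_change`, `converged`, and (when available) `metadata` and
#'   `layout` carried over from the dataset.
#' @export
gpa <- function(x, slide = NULL, tol = 1e-6, max_iter = 100L) {
  metadata <- NULL
  layout <- NULL
  if (inherits(x, "mm_dataset")) {
    metadata <- x$metadata
    layout <- x$layout
    arr <- coord_array(x)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else if (is.list(x)) {
    arr <- simplify2array(lapply(x, as_points_matrix))
    if (length(dim(arr)) != 3L) abort("Configurations must share K")
  } else {
    abort("Unsupported input to gpa()")
  }
  n <- dim(arr)[3]
  if (n < 2L) abort("GPA needs at least two configurations")
  ids <- dimnames(arr)[[3]] %||% as.character(seq_len(n))
  if (!is.null(slide)) {
    stopifnot(inherits(slide, "sliding_spec"))
    if (nrow(slide$layout) != dim(arr)[1]) {
      abort("Sliding layout does not match the number of points")
    }
  }

  sizes <- numeric(n)
  for (i in seq_len(n)) {
    sizes[[i]] <- tryCatch(centroid_size(arr[, , i]), error = function(e) {
      abort(paste0("Degenerate configuration for specimen ", ids[[i]]))
    })
    arr[, , i] <- centre_points(arr[, , i]) / sizes[[i]]
  }
  names(sizes) <- ids

  align_pass <- function(arr, consensus) {
    for (i in seq_len(dim(arr)[3])) {
      arr[, , i] <- arr[, , i] %*% optimal_rotation(arr[, , i], consensus)
    }
    arr
  }
  normalise_shape <- function(m) {
    m <- centre_points(m)
    m / sqrt(sum(m^2))
  }

  consensus <- normalise_shape(apply(arr, c(1, 2), mean))
  iterations <- 0L
  change <- Inf
  converged <- FALSE

  inner_gpa <- function(arr, consensus) {
    repeat {
      arr <- align_pass(arr, consensus)
      new_cons <- normalise_shape(apply(arr, c(1, 2), mean))
      iterations <<- iterations + 1L
      change <<- sqrt(sum((new_cons - consensus)^2))
      consensus <- new_cons
      if (change < tol || iterations >= max_iter) break
    }
    list(arr = arr, consensus = consensus)
  }

  if (is.null(slide)) {
    res <- inner_gpa(arr, consensus)
    arr <- res$arr; consensus <- res$consensus
  } else {
    # Two choices make the slide step well behaved. Tangents are evaluated
    # on the consensus, so sliding is one common linear projection for all
    # specimens: the mean sliding displacement is exactly zero and the
    # consensus cannot drift along the outline. And every cycle re-slides
    # from the specimen's original (digitised) semilandmark positions
    # rather than compounding earlier slides, so the converged shapes are a
    # history-free function of the data and the final consensus — the same
    # function project_unknowns() applies to new specimens.
    semi_idx <- slide$layout$point[slide$layout$role == "semi"]
    raw <- arr
    for (outer in seq_len(slide$max_outer_iterations)) {
      # align the current slid estimates; keep the raw copies co-rotated
      repeat {
        for (i in seq_len(n)) {
          r <- optimal_rotation(arr[, , i], consensus)
          arr[, , i] <- arr[, , i] %*% r
          raw[, , i] <- raw[, , i] %*% r
        }
        new_cons <- normalise_shape(apply(arr, c(1, 2), mean))
        iterations <- iterations + 1L
        change <- sqrt(sum((new_cons - consensus)^2))
        consensus <- new_cons
        if (change < tol || iterations >= max_iter) break
      }
      be <- bending_energy_model(consensus)
      cons_tang <- semilandmark_tangents(consensus, semi_idx, slide$closed)
      for (i in seq_len(n)) {
        slid <- slide_semilandmarks(raw[, , i], be, slide,
                                    tangents = cons_tang)
        arr[, , i] <- centre_points(slid) / centroid_size(slid)
      }
      new_cons <- normalise_shape(apply(arr, c(1, 2), mean))
      outer_change <- sqrt(sum((new_cons - consensus)^2))
      consensus <- new_cons
      if (outer_change < slide$tolerance) break
    }
    # final alignment pass, raw kept in step for reproducibility
    for (i in seq_len(n)) {
      r <- optimal_rotation(arr[, , i], consensus)
      arr[, , i] <- arr[, , i] %*% r
      raw[, , i] <- raw[, , i] %*% r
    }
    consensus <- normalise_shape(apply(arr, c(1, 2), mean))
  }
  converged <- change < tol
  if (!converged) {
    warn(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                 iterations, change))
  }

  rot <- canonical_rotation(consensus)
  consensus <- consensus %*% rot
  for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*% rot
  dimnames(arr) <- list(NULL, c("x", "y"), ids)

  structure(
    list(shapes = arr, centroid_sizes = sizes, consensus = consensus,
         n_iterations = iterations, final_change = change,
         converged = converged, slide = slide,
         metadata = metadata, layout = layout),
    class = "mm_gpa"
  )
}

# Deterministic canonical orientation: rotate (never reflect) so the
# consensus' major principal axis is x, with positive third moment along x
# (falls back to the sign of the first point's x when the moment vanishes).
canonical_rotation <- function(consensus) {
  ev <- eigen(cov(consensus), symmetric = TRUE)$vectors
  if (det(ev) < 0) ev[, 2] <- -ev[, 2]
  rotated <- consensus %*% ev
  m3 <- sum(rotated[, 1]^3)
  s <- if (abs(m3) > 1e-12) sign(m3) else {
    if (abs(rotated[1, 1]) > 1e-12) sign(rotated[1, 1]) else 1
  }
  if (s < 0) ev <- ev %*% diag(c(-1, -1))   # rotation by pi
  ev
}

#' Procrustes shape coordinates as a specimen x variable matrix
#'
#' Flattens aligned shapes to rows (x coordinates then y coordinates) and,
#' by default, projects them orthogonally onto the tangent space at the
#' consensus (removing the component along the consensus direction), the
#' standard small-variation treatment before any covariance-based
#' statistics.
#'
#' @param aligned An `mm_gpa` object.
#' @param tangent Project onto the tangent space (default `TRUE`).
#' @return n x 2K numeric matrix with specimen ids as row names.
#' @export
shape_matrix <- function(aligned, tangent = TRUE) {
  stopifnot(inherits(aligned, "mm_gpa"))
  arr <- aligned$shapes
  n <- dim(arr)[3]
  xmat <- t(apply(arr, 3L, as.vector))
  if (n == 1L) xmat <- matrix(as.vector(arr), nrow = 1L)
  rownames(xmat) <- dimnames(arr)[[3]]
  if (tangent) {
    cvec <- as.vector(aligned$consensus)
    cvec <- cvec / sqrt(sum(cvec^2))
    xmat <- xmat - (xmat %*% cvec) %*% t(cvec)
  }
  xmat
}

#' @export
print.mm_gpa <- function(x, ...) {
  cat(sprintf(
    "<mm_gpa> %d specimens, %d landmarks; %d iterations (final change %.2e)%s\n",
    dim(x$shapes)[3], dim(x$shapes)[1], x$n_iterations, x$final_change,
    if (is.null(x$slide)) "" else "; semilandmarks slid"
  ))
  invisible(x)
}

#' @describeIn gpa Aligned coordinates in long format, one row per landmark,
#'   with centroid sizes joined.
#' @param x An `mm_gpa` object.
#' @param ... Unused.
#' @export
tidy.mm_gpa <- function(x, ...) {
  out <- coords_to_tibble(x$shapes)
  out$centroid_size <- x$centroid_sizes[out$specimen_id]
  out
}

#' @describeIn gpa One-row summary of the superimposition.
#' @export
glance.mm_gpa <- function(x, ...) {
  tibble::tibble(
    n = dim(x$shapes)[3], k = dim(x$shapes)[1],
    n_iterations = x$n_iterations, final_change = x$final_change,
    converged = x$converged, slid = !is.null(x$slide)
  )
}

#' @describeIn gpa Scatter of all aligned landmarks with the consensus
#'   overlaid.
#' @param object An `mm_gpa` object.
#' @export
autoplot.mm_gpa <- function(object, ...) {
  pts <- tidy(object)
  cons <- tibble::tibble(x = object$consensus[, 1], y = object$consensus[, 2])
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_point(data = cons, colour = "red", size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes superimposition",
                  subtitle = "red: consensus shape")
}
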